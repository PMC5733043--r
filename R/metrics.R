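#' Peak amplitude of a response time course
#'
#' The amplitude of an evoked response is defined robustly as the 95th
#' percentile of the signal distribution over the analysis window (linear
#' interpolation between order statistics), expressed in percent.  The
#' default window runs from stimulus onset to the end of the trace.
#'
#' @param tc an `ois_timecourse` (or any list with `t`, `y` in fractional
#'   units and `stim_onset`).
#' @param window numeric `[start, end]` in seconds from trial start.
#' @return amplitude in percent.
#' @export
peak_amplitude <- function(tc, window = NULL) {
  if (is.null(window)) window <- c(tc$stim_onset, max(tc$t))
  sel <- tc$t >= window[1] - 1e-9 & tc$t <= window[2] + 1e-9
  if (!any(sel)) stop("peak_amplitude: empty analysis window")
  100 * stats::quantile(tc$y[sel], 0.95, type = 7, names = FALSE)
}

#' Peak position of a response time course
#'
#' Time from stimulus onset to the first sample at which the signal reaches
#' the given amplitude.  The granularity is one frame.
#'
#' @inheritParams peak_amplitude
#' @param amplitude amplitude in percent, as returned by [peak_amplitude()]
#'   on the same window.
#' @return seconds from stimulus onset.
#' @export
peak_position <- function(tc, amplitude = peak_amplitude(tc, window),
                          window = NULL) {
  if (is.null(window)) window <- c(tc$stim_onset, max(tc$t))
  sel <- which(tc$t >= window[1] - 1e-9 & tc$t <= window[2] + 1e-9)
  hit <- sel[100 * tc$y[sel] >= amplitude - 1e-12]
  if (length(hit) == 0)
    stop("peak_position: no sample reaches the requested amplitude")
  tc$t[hit[1]] - tc$stim_onset
}

#' Half-recovery time of a response
#'
#' Time span after the peak for the signal to first fall to half of its
#' amplitude, with linear interpolation between the bracketing samples.
#' Returns `NA_real_` (the "unresolved" sentinel) when the trace never
#' falls to half within its span.
#'
#' @inheritParams peak_amplitude
#' @param amplitude amplitude in percent.
#' @param peak_time peak position in seconds from stimulus onset.
#' @return seconds from the peak, or `NA_real_` if unresolved.
#' @export
half_recovery <- function(tc, amplitude, peak_time) {
  half <- amplitude / 2 / 100               # back to fractional units
  t_peak <- tc$stim_onset + peak_time
  post <- which(tc$t > t_peak + 1e-9)
  if (length(post) == 0) return(NA_real_)
  below <- post[tc$y[post] <= half + 1e-15]
  if (length(below) == 0) return(NA_real_)
  i1 <- below[1]
  if (i1 == 1 || tc$t[i1 - 1] <= t_peak - 1e-9) return(tc$t[i1] - t_peak)
  i0 <- i1 - 1                              # bracketing samples
  y0 <- tc$y[i0]; y1 <- tc$y[i1]
  t_cross <- if (y0 == y1) tc$t[i1] else
    tc$t[i0] + (tc$t[i1] - tc$t[i0]) * (y0 - half) / (y0 - y1)
  t_cross - t_peak
}

#' Average rectified LFP over the stimulation window
#'
#' Integrates the absolute LFP over the stimulation window (trapezoidal
#' rule) and divides by the window duration.  The convention (rectified
#' integral / duration, in uV) is recorded in the result's attributes.
#'
#' @param lfp an `lfp_trace` from [simulate_lfp()] (or list with `t`, `y`).
#' @param window numeric `[start, end]` seconds; defaults to the
#'   stimulation window of the trace's protocol.
#' @return average rectified LFP (uV), with attribute `"convention"`.
#' @export
average_lfp <- function(lfp, window = NULL) {
  if (is.null(window)) {
    p <- lfp$protocol
    window <- c(stim_onset(p), stim_onset(p) + p$stim_s)
  }
  sel <- which(lfp$t >= window[1] - 1e-12 & lfp$t <= window[2] + 1e-12)
  if (length(sel) < 2) stop("average_lfp: empty stimulation window")
  t <- lfp$t[sel]; a <- abs(lfp$y[sel])
  integral <- sum(diff(t) * (utils::head(a, -1) + utils::tail(a, -1)) / 2)
  structure(integral / (max(t) - min(t)),
            convention = "rectified integral / duration, uV")
}

#' Rank stimulation rates by response amplitude
#'
#' Returns the three stimulation rates with the largest response
#' amplitudes, in descending amplitude order; amplitude ties are broken
#' toward the lower rate.
#'
#' @param amplitudes named numeric vector (names = rates in Hz) or numeric
#'   vector with `rates` supplied.
#' @param rates stimulation rates, Hz, if `amplitudes` is unnamed.
#' @return numeric vector of the three optimal rates.
#' @export
rank_stimulation_rates <- function(amplitudes, rates = NULL) {
  if (is.null(rates)) {
    if (is.null(names(amplitudes)))
      stop("rank_stimulation_rates: supply rates or a named vector")
    rates <- as.numeric(names(amplitudes))
  }
  stopifnot(length(rates) == length(amplitudes))
  if (length(rates) < 3) stop("rank_stimulation_rates: need at least 3 rates")
  ord <- order(-amplitudes, rates)
  rates[ord[1:3]]
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length (>= 2) with nonzero variance.
#' @return the correlation coefficient.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("pearson_correlation: zero variance")
  stats::cor(x, y)
}

#' Fit a gamma-variate kernel to an evoked trace
#'
#' Least-squares fit of `A * k(t - onset - delay; peak, shape)` (see
#' [gamma_variate()]) to a sampled response.  Because the kernels are nearly
#' flat around their maximum, the sample argmax of a noisy trace is a poor
#' peak-time estimator; the fit pools information from the rising and
#' falling flanks and recovers peak times to a fraction of a frame.
#'
#' @param t sample times, seconds.
#' @param y sampled response (any units).
#' @param onset response onset reference, seconds (kernels are zero before
#'   `onset + delay`).
#' @param fit_delay estimate an onset lag (`TRUE`) or pin it at 0.
#' @return list with `amplitude`, `delay` (s), `peak_time` (s after
#'   `onset`), `shape`, `half_recovery` (s after the peak, from the fitted
#'   kernel), and the `fitted` values.
#' @export
fit_gamma_variate <- function(t, y, onset = 0, fit_delay = TRUE) {
  stopifnot(length(t) == length(y), all(is.finite(t)), all(is.finite(y)))
  sgn <- sign(y[which.max(abs(y))])
  if (sgn == 0) stop("fit_gamma_variate: all-zero trace")
  yy <- y * sgn
  a0 <- max(yy)
  i_on <- which(yy >= 0.1 * a0 & t > onset)
  delay0 <- if (fit_delay && length(i_on) > 0)
    max(0, t[i_on[1]] - onset - 0.5) else 0
  tp0 <- max(t[which.max(yy)] - onset - delay0, 1)
  obj <- function(par) {
    d <- if (fit_delay) par[2] else 0
    a <- par[1] * gamma_variate(t - onset - d, par[3], par[4])
    a - yy
  }
  par0 <- c(A = a0, delay = delay0, tp = tp0, shape = 1)
  lower <- c(0, 0, 0.1, 0.02)
  upper <- c(Inf, max(t) - onset, 10 * (max(t) - onset), 200)
  fit <- minpack.lm::nls.lm(par0, lower = lower, upper = upper, fn = obj,
                            control = minpack.lm::nls.lm.control(maxiter = 300))
  p <- fit$par
  d <- if (fit_delay) p[2] else 0
  fitted <- sgn * p[1] * gamma_variate(t - onset - d, p[3], p[4])
  list(amplitude = unname(sgn * p[1]), delay = unname(d),
       peak_time = unname(d + p[3]), shape = unname(p[4]),
       half_recovery = kernel_half_recovery(unname(p[3]), unname(p[4])),
       fitted = fitted, rss = sum((fitted - y)^2))
}

#' Kernel-fit summary metrics for decomposed chromophores
#'
#' Fits gamma-variate kernels to the scattering and total-hemoglobin
#' components of a decomposition and reports their peak times (seconds after
#' stimulus onset) and the scattering half-recovery time.
#'
#' @param chromophores a [chromophore_timecourses()].
#' @param onset stimulus onset, seconds from trial start.
#' @return data frame with one row per component (`S`, `HbT`): amplitude,
#'   peak time after onset (s), and half-recovery (s).
#' @export
chromophore_peak_metrics <- function(chromophores, onset) {
  stopifnot(inherits(chromophores, "chromophore_timecourses"))
  fs <- fit_gamma_variate(chromophores$t, chromophores$d_s, onset,
                          fit_delay = FALSE)
  fh <- fit_gamma_variate(chromophores$t, chromophores$hbt, onset,
                          fit_delay = TRUE)
  data.frame(component = c("S", "HbT"),
             amplitude = c(fs$amplitude, fh$amplitude),
             peak_time_s = c(fs$peak_time, fh$peak_time),
             half_recovery_s = c(fs$half_recovery, fh$half_recovery))
}
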