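#' OIS activation map
#'
#' Per-pixel relative intensity change between the stimulation and baseline
#' windows:
#' \deqn{OIS = (\bar I_{corr}(stim) - \bar I_{corr}(baseline)) /
#'       \bar I(baseline)}
#' where the numerator means are taken over the illumination-corrected stack
#' and the denominator over the raw stack.  In reflectance mode activated
#' tissue darkens, so responsive pixels are negative.
#'
#' @param corrected an illumination-corrected [frame_stack()].
#' @param raw_baseline the raw [frame_stack()] providing baseline intensity.
#' @param stim_window,baseline_window numeric `[start, end)` windows in
#'   seconds from trial start; defaults are the full stimulation train and
#'   the full pre-stimulus baseline.
#' @param mode `"reflectance"` or `"transmission"` (metadata, used by
#'   downstream polarity handling).
#' @return an `ois_map`: height-by-width matrix of dimensionless fractions
#'   plus mode metadata.
#' @export
compute_ois_map <- function(corrected, raw_baseline,
                            stim_window = NULL, baseline_window = NULL,
                            mode = c("reflectance", "transmission")) {
  mode <- match.arg(mode)
  stopifnot(inherits(corrected, "frame_stack"),
            inherits(raw_baseline, "frame_stack"))
  p <- corrected$protocol
  if (is.null(baseline_window)) baseline_window <- c(0, p$baseline_s)
  if (is.null(stim_window)) stim_window <- c(p$baseline_s, p$baseline_s + p$stim_s)
  bi <- window_frames(p, baseline_window)
  si <- window_frames(p, stim_window)
  Mc <- .as_tp(corrected)
  Mr <- .as_tp(raw_baseline)
  base_raw <- colMeans(Mr[bi, , drop = FALSE])
  if (any(base_raw == 0))
    stop("compute_ois_map: zero baseline intensity at some pixel")
  v <- (colMeans(Mc[si, , drop = FALSE]) - colMeans(Mc[bi, , drop = FALSE])) /
    base_raw
  d <- dim(corrected$data)
  structure(list(values = matrix(v, d[2], d[3]), mode = mode,
                 stim_window = stim_window, baseline_window = baseline_window),
            class = "ois_map")
}

#' @export
print.ois_map <- function(x, ...) {
  cat(sprintf("ois_map (%s): %d x %d px, extremum %+.4g%%\n", x$mode,
              nrow(x$values), ncol(x$values),
              100 * x$values[which.max(abs(x$values))[1]]))
  invisible(x)
}

#' Detect the active region in an OIS map
#'
#' Thresholds the map at a fraction of its absolute extremum and returns the
#' 4-connected component containing the extremum pixel.  The detection is
#' invariant to the overall sign and scale of the map.  When several pixels
#' tie for the extremum, the first in row-major scan order is used.
#'
#' @param map an `ois_map` (or plain numeric matrix).
#' @param threshold_frac fraction of the absolute extremum in `(0, 1)`.
#' @return an [roi_mask()] with role `"active"`.
#' @export
detect_active_region <- function(map, threshold_frac = 0.5) {
  v <- if (inherits(map, "ois_map")) map$values else map
  stopifnot(is.matrix(v), threshold_frac > 0, threshold_frac < 1)
  a <- abs(v)
  peak <- max(a)
  if (peak == 0) stop("detect_active_region: all-zero map, no region found")
  cand <- which(a == peak)
  rr <- (cand - 1L) %% nrow(v) + 1L
  cc <- (cand - 1L) %/% nrow(v) + 1L
  first <- order(rr, cc)[1L]                  # row-major tie-break
  seed <- c(rr[first], cc[first])
  above <- a >= threshold_frac * peak
  mask <- matrix(FALSE, nrow(v), ncol(v))
  # BFS flood fill, 4-connectivity
  queue <- matrix(seed, ncol = 2)
  mask[seed[1], seed[2]] <- TRUE
  while (nrow(queue) > 0) {
    cur <- queue[1, , drop = FALSE]
    queue <- queue[-1, , drop = FALSE]
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      ni <- cur[1] + d[1]; nj <- cur[2] + d[2]
      if (ni >= 1 && ni <= nrow(v) && nj >= 1 && nj <= ncol(v) &&
          above[ni, nj] && !mask[ni, nj]) {
        mask[ni, nj] <- TRUE
        queue <- rbind(queue, c(ni, nj))
      }
    }
  }
  roi_mask(mask, "active")
}

#' Extract the ROI-averaged response time course
#'
#' Averages the normalised corrected intensity over the active region:
#' `y(t) = mean over mask of I_corr(t) / I_baseline(pixel)`, re-zeroed to
#' the baseline window.  With polarity `"activation-positive"` the
#' reflectance-mode trace is multiplied by -1 so that activation (darkening)
#' points upward; transmission-mode traces keep their sign, since increased
#' tissue transparency already brightens the active region.  Polarity
#' `"raw"` keeps the physical intensity-change sign in both modes (a
#' scattering-driven response then inverts between modes).
#'
#' @inheritParams compute_ois_map
#' @param active an [roi_mask()] (role `"active"`) or logical matrix.
#' @param polarity `"activation-positive"` (default) or `"raw"`.
#' @param rebaseline subtract the baseline-window mean (default `TRUE`).
#' @return an `ois_timecourse`: list with `t` (s), `y` (dimensionless
#'   fraction), `stim_onset`, `mode`, `polarity`, `frame_rate`.
#' @export
extract_timecourse <- function(corrected, raw_baseline, active,
                               mode = c("reflectance", "transmission"),
                               polarity = c("activation-positive", "raw"),
                               baseline_window = NULL, rebaseline = TRUE) {
  mode <- match.arg(mode)
  polarity <- match.arg(polarity)
  stopifnot(inherits(corrected, "frame_stack"))
  m <- if (inherits(active, "roi_mask")) active$mask else active
  if (!any(m)) stop("extract_timecourse: empty active mask")
  p <- corrected$protocol
  if (is.null(baseline_window)) baseline_window <- c(0, p$baseline_s)
  bi <- window_frames(p, baseline_window)
  Mc <- .as_tp(corrected)[, as.vector(m), drop = FALSE]
  Mr <- .as_tp(raw_baseline)[, as.vector(m), drop = FALSE]
  base <- colMeans(Mr[bi, , drop = FALSE])
  if (any(base == 0))
    stop("extract_timecourse: zero baseline intensity inside the mask")
  y <- rowMeans(sweep(Mc, 2, base, "/"))
  if (rebaseline) y <- y - mean(y[bi])
  if (polarity == "activation-positive" && mode == "reflectance") y <- -y
  ois_timecourse(protocol_times(p), y, stim_onset = stim_onset(p),
                 mode = mode, polarity = polarity,
                 frame_rate = p$frame_rate_hz)
}

#' OIS time course container
#'
#' @param t sample times, seconds from trial start (strictly increasing,
#'   uniform).
#' @param y relative signal as a dimensionless fraction.
#' @param stim_onset stimulus onset, seconds from trial start.
#' @param mode `"reflectance"` or `"transmission"`.
#' @param polarity `"activation-positive"` or `"raw"`.
#' @param frame_rate sampling rate, Hz.
#' @return an object of class `ois_timecourse`.
#' @export
ois_timecourse <- function(t, y, stim_onset, mode = "reflectance",
                           polarity = "activation-positive",
                           frame_rate = NULL) {
  stopifnot(length(t) == length(y), !is.unsorted(t, strictly = TRUE))
  structure(list(t = t, y = y, stim_onset = stim_onset, mode = mode,
                 polarity = polarity,
                 frame_rate = if (is.null(frame_rate)) 1 / stats::median(diff(t)) else frame_rate),
            class = "ois_timecourse")
}

#' @export
print.ois_timecourse <- function(x, ...) {
  cat(sprintf("ois_timecourse (%s, %s): %d samples, peak %.4g%%\n",
              x$mode, x$polarity, length(x$t), 100 * max(abs(x$y))))
  invisible(x)
}
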