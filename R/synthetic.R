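#' Evoked-response parameters for the forward simulator
#'
#' Parameterises the chromophore dynamics of one evoked response: a
#' hemodynamic phase (oxy-/deoxy-hemoglobin sharing one gamma-variate kernel,
#' so that total hemoglobin peaks at `hr_peak_time`) and a light-scattering
#' phase (pseudo-chromophore `S` with its own kernel, whose shape is solved
#' numerically so the scattering transient falls to half of its peak exactly
#' `ls_half_recovery` seconds after the peak).
#'
#' All times are seconds relative to stimulus onset.  Concentration amplitudes
#' are micromolar changes from baseline and may be negative; `ls_amp` is the
#' dimensionless scattering change.
#'
#' @param hr_delay lag of the hemodynamic phase after stimulus onset, s.
#' @param hr_peak_time time of the total-hemoglobin peak after onset, s
#'   (must exceed `hr_delay`).
#' @param hbo_amp,hbr_amp signed oxy-/deoxy-hemoglobin amplitudes, uM.
#' @param ls_amp dimensionless scattering amplitude.
#' @param ls_peak_time time of the scattering peak after onset, s.
#' @param ls_half_recovery time for the scattering transient to fall to half
#'   of its peak, measured from the peak, s.
#' @param kernel_shape shape of the hemodynamic gamma-variate kernel.
#' @return an object of class `response_params`.
#' @seealso [neonatal_response_params()], [adult_response_params()],
#'   [simulate_chromophores()]
#' @export
response_params <- function(hr_delay, hr_peak_time, hbo_amp, hbr_amp,
                            ls_amp, ls_peak_time, ls_half_recovery,
                            kernel_shape = 2) {
  vals <- c(hr_delay = hr_delay, hr_peak_time = hr_peak_time,
            hbo_amp = hbo_amp, hbr_amp = hbr_amp, ls_amp = ls_amp,
            ls_peak_time = ls_peak_time, ls_half_recovery = ls_half_recovery,
            kernel_shape = kernel_shape)
  if (any(!is.finite(vals))) stop("response_params: all fields must be finite")
  if (hr_delay < 0 || hr_peak_time < 0 || ls_peak_time < 0 || ls_half_recovery < 0)
    stop("response_params: time parameters must be >= 0")
  if (hr_peak_time <= hr_delay)
    stop("response_params: hr_peak_time must exceed hr_delay")
  if (ls_peak_time <= 0) stop("response_params: ls_peak_time must be > 0")
  if (kernel_shape <= 0) stop("response_params: kernel_shape must be > 0")
  structure(as.list(vals), class = "response_params")
}

#' Preset response regimes
#'
#' Two illustrative parameter sets bracketing the developmental regimes the
#' package is designed around.  The *neonatal* preset has a two-phase
#' structure: the scattering transient peaks at the end of the 10 s
#' stimulation train and recovers to half amplitude 25 s later, while the
#' hemodynamic phase is delayed by 10 s and total hemoglobin peaks 30 s after
#' onset.  The *adult* preset overlaps both components inside the stimulation
#' train.  Timing parameters follow the neonatal/adult phenomenology the
#' package models; the concentration amplitudes are illustrative defaults
#' chosen for a realistic signal-to-noise ratio, not measured values.
#'
#' @param ... overrides passed to [response_params()].
#' @return a `response_params` object.
#' @export
neonatal_response_params <- function(...) {
  defaults <- list(hr_delay = 10, hr_peak_time = 30, hbo_amp = 2.0,
                   hbr_amp = -0.5, ls_amp = 0.003, ls_peak_time = 10,
                   ls_half_recovery = 25, kernel_shape = 2)
  do.call(response_params, utils::modifyList(defaults, list(...)))
}

#' @rdname neonatal_response_params
#' @export
adult_response_params <- function(...) {
  defaults <- list(hr_delay = 0.5, hr_peak_time = 6, hbo_amp = 3.0,
                   hbr_amp = -0.8, ls_amp = 0.002, ls_peak_time = 8,
                   ls_half_recovery = 6, kernel_shape = 2)
  do.call(response_params, utils::modifyList(defaults, list(...)))
}

#' Chromophore time courses
#'
#' Container for per-timepoint chromophore changes: oxy-hemoglobin `d_hbo`
#' and deoxy-hemoglobin `d_hbr` (uM), the dimensionless scattering
#' pseudo-chromophore `d_s`, and total hemoglobin `hbt`, which is always
#' computed as `d_hbo + d_hbr` so the identity holds bit-wise.
#'
#' @param t sample times, seconds from trial start.
#' @param d_hbo,d_hbr hemoglobin concentration changes, uM.
#' @param d_s dimensionless scattering change.
#' @return an object of class `chromophore_timecourses`.
#' @export
chromophore_timecourses <- function(t, d_hbo, d_hbr, d_s) {
  n <- length(t)
  stopifnot(length(d_hbo) == n, length(d_hbr) == n, length(d_s) == n,
            all(is.finite(t)), !is.unsorted(t, strictly = TRUE))
  structure(list(t = t, d_hbo = d_hbo, d_hbr = d_hbr, d_s = d_s,
                 hbt = d_hbo + d_hbr, units = "uM"),
            class = "chromophore_timecourses")
}

#' @export
print.chromophore_timecourses <- function(x, ...) {
  cat(sprintf("chromophore_timecourses: %d samples, t in [%g, %g] s\n",
              length(x$t), min(x$t), max(x$t)))
  cat(sprintf("  peak |dHbO| %.3g uM, |dHbR| %.3g uM, |dS| %.3g, |HbT| %.3g uM\n",
              max(abs(x$d_hbo)), max(abs(x$d_hbr)), max(abs(x$d_s)),
              max(abs(x$hbt))))
  invisible(x)
}

#' Simulate chromophore dynamics on the acquisition time grid
#'
#' Evaluates the two-phase forward model on the frame-time grid of a
#' protocol.  All chromophores are exactly zero before stimulus onset.  The
#' scattering component peaks at `ls_peak_time` after onset and first falls
#' to half of its peak `ls_half_recovery` seconds after the peak; total
#' hemoglobin peaks at `hr_peak_time` after onset.
#'
#' @param params a [response_params()] object.
#' @param protocol a [stim_protocol()].
#' @return a [chromophore_timecourses()] object.
#' @export
simulate_chromophores <- function(params, protocol = stim_protocol()) {
  stopifnot(inherits(params, "response_params"),
            inherits(protocol, "stim_protocol"))
  t <- protocol_times(protocol)
  onset <- stim_onset(protocol)
  hr_tau <- t - onset - params$hr_delay
  hr_kernel <- gamma_variate(hr_tau, params$hr_peak_time - params$hr_delay,
                             params$kernel_shape)
  if (params$ls_amp != 0) {
    ls_shape <- shape_for_half_recovery(params$ls_peak_time,
                                        params$ls_half_recovery)
    ls_kernel <- gamma_variate(t - onset, params$ls_peak_time, ls_shape)
  } else {
    ls_kernel <- numeric(length(t))
  }
  chromophore_timecourses(t,
                          d_hbo = params$hbo_amp * hr_kernel,
                          d_hbr = params$hbr_amp * hr_kernel,
                          d_s   = params$ls_amp * ls_kernel)
}

#' Project chromophore dynamics onto spectral bands
#'
#' Applies the modified Beer-Lambert forward model: for each band the
#' relative attenuation is
#' \deqn{OIS_\lambda(t) = (\Delta HbO\,\bar\epsilon_{HbO,\lambda} +
#'   \Delta HbR\,\bar\epsilon_{HbR,\lambda} + \mu_s'\,\Delta S)\, 2 d_{IV}}
#' an exact linear, noise-free map.  Positive values mean increased
#' attenuation (darkening under reflectance illumination).
#'
#' @param chromophores a [chromophore_timecourses()] object.
#' @param model an [mbll_model()] describing the bands and pathlength.
#' @return a `band_traces` object: list with `t`, a time-by-band `traces`
#'   matrix of dimensionless attenuations, and the band names.
#' @export
forward_project <- function(chromophores, model) {
  stopifnot(inherits(chromophores, "chromophore_timecourses"),
            inherits(model, "mbll_model"))
  if (!identical(chromophores$units, "uM"))
    stop("forward_project: chromophore concentrations must be in uM, got ",
         chromophores$units)
  C <- cbind(chromophores$d_hbo, chromophores$d_hbr, chromophores$d_s)
  traces <- C %*% t(model$matrix)
  colnames(traces) <- vapply(model$bands, function(b) b$name, character(1))
  structure(list(t = chromophores$t, traces = traces,
                 bands = colnames(traces), units = "relative attenuation"),
            class = "band_traces")
}

#' Scene geometry and acquisition parameters for the simulator
#'
#' Describes the imaged field of view and the nuisance structure of an
#' acquisition: a spatially localised Gaussian response blob, a slow global
#' multiplicative illumination fluctuation shared by all pixels, and
#' additive Gaussian pixel noise.  Defaults emulate the acquisition geometry
#' the package is designed for: 130 x 174 pixel frames at 5 Hz per band.
#'
#' @param height,width frame size in pixels.
#' @param blob_center response centre, 1-based `(row, col)` pixels; the blob
#'   must lie fully inside the frame (centre +/- 3 sigma within bounds).
#' @param blob_sigma Gaussian width of the response blob, pixels.
#' @param baseline_intensity mean camera signal, counts.
#' @param illumination_fluctuation_amp relative amplitude of the global
#'   multiplicative illumination fluctuation (e.g. 0.01 for 1 %).
#' @param illumination_fluctuation_hz frequency of the fluctuation, Hz.
#' @param noise_sigma additive Gaussian noise per pixel per frame, counts.
#' @param n_trials number of trials to render.
#' @param seed master seed; each (band, trial) pair uses its own substream.
#' @param protocol a [stim_protocol()].
#' @return an object of class `scene_params`.
#' @export
scene_params <- function(height = 130, width = 174, blob_center = c(66, 88),
                         blob_sigma = 10, baseline_intensity = 1000,
                         illumination_fluctuation_amp = 0.01,
                         illumination_fluctuation_hz = 0.1,
                         noise_sigma = 5, n_trials = 12, seed = 1,
                         protocol = stim_protocol()) {
  stopifnot(height >= 8, width >= 8, length(blob_center) == 2L,
            blob_sigma > 0, n_trials >= 1,
            illumination_fluctuation_amp >= 0, noise_sigma >= 0,
            inherits(protocol, "stim_protocol"))
  if (baseline_intensity < 0)
    stop("scene_params: baseline_intensity must be non-negative")
  if (blob_center[1] - 3 * blob_sigma < 1 || blob_center[1] + 3 * blob_sigma > height ||
      blob_center[2] - 3 * blob_sigma < 1 || blob_center[2] + 3 * blob_sigma > width)
    stop("scene_params: blob (center +/- 3 sigma) must lie inside the frame")
  structure(list(height = as.integer(height), width = as.integer(width),
                 blob_center = blob_center, blob_sigma = blob_sigma,
                 baseline_intensity = baseline_intensity,
                 illumination_fluctuation_amp = illumination_fluctuation_amp,
                 illumination_fluctuation_hz = illumination_fluctuation_hz,
                 noise_sigma = noise_sigma, n_trials = as.integer(n_trials),
                 seed = as.integer(seed), protocol = protocol),
            class = "scene_params")
}

#' Spatial profile of the response blob
#'
#' Unit-peak Gaussian profile of the simulated response.  With
#' `filter_sigma` the profile is convolved with the same reflected-boundary
#' Gaussian used by [spatial_filter()], which is what an analysis of filtered
#' frames effectively sees.
#'
#' @param scene a [scene_params()] object.
#' @param filter_sigma optional Gaussian filter width in pixels.
#' @return a height-by-width matrix with maximum 1 (before filtering).
#' @export
blob_profile <- function(scene, filter_sigma = NULL) {
  r <- outer((seq_len(scene$height) - scene$blob_center[1])^2,
             (seq_len(scene$width) - scene$blob_center[2])^2, "+")
  B <- exp(-r / (2 * scene$blob_sigma^2))
  if (!is.null(filter_sigma)) B <- conv2_sep(B, filter_sigma)
  B
}

#' Mask-shape attenuation factor
#'
#' An ROI average over a Gaussian-profiled blob underestimates the
#' blob-centre amplitude by the mean of the (filtered) blob profile over the
#' mask.  This factor makes ROI-extracted amplitudes comparable with the
#' injected centre amplitudes.
#'
#' @inheritParams blob_profile
#' @param mask logical matrix or [roi_mask()] selecting the ROI.
#' @return scalar in `(0, 1]`.
#' @export
mask_attenuation <- function(scene, mask, filter_sigma = NULL) {
  m <- if (inherits(mask, "roi_mask")) mask$mask else mask
  stopifnot(is.logical(m), any(m))
  mean(blob_profile(scene, filter_sigma)[m])
}

# deterministic per-(band, trial) substream seed below 2^31
.substream_seed <- function(master, band, trial) {
  h <- sum(utf8ToInt(as.character(band)) * seq_along(utf8ToInt(as.character(band))))
  as.integer((as.numeric(master) * 2654435 + h * 97003 + trial * 15485863) %%
               2147483629)
}

#' Render noisy trial stacks for one band
#'
#' Realises the acquisition forward model.  Each frame is
#' `baseline * (1 + g(t)) * (1 + s * trace(t) * B) + noise`, where `B` is the
#' unit-peak Gaussian blob profile, `g(t)` a sinusoidal global illumination
#' fluctuation shared by all pixels (random phase per trial), and `s = -1`
#' in reflectance mode (activation darkens the blob) or `+1` in transmission
#' mode (increased transparency brightens it).  Identical scene seeds give
#' bit-identical stacks.
#'
#' @param scene a [scene_params()] object.
#' @param trace per-frame relative attenuation (length = protocol frames),
#'   e.g. one column of [forward_project()] output.
#' @param band band label attached to the stacks.
#' @param mode `"reflectance"` or `"transmission"`.
#' @return a `trial_set`: list of [frame_stack()] trials plus scene metadata.
#' @export
render_trials <- function(scene, trace, band = "BAND",
                          mode = c("reflectance", "transmission")) {
  mode <- match.arg(mode)
  stopifnot(inherits(scene, "scene_params"))
  p <- scene$protocol
  nt <- n_frames(p)
  if (length(trace) != nt)
    stop("render_trials: trace length ", length(trace),
         " != protocol frame count ", nt)
  t <- protocol_times(p)
  Bv <- as.vector(blob_profile(scene))
  sgn <- if (mode == "reflectance") -1 else 1
  npx <- scene$height * scene$width
  trials <- vector("list", scene$n_trials)
  for (k in seq_len(scene$n_trials)) {
    set.seed(.substream_seed(scene$seed, band, k))
    phase <- stats::runif(1, 0, 2 * pi)
    g <- scene$illumination_fluctuation_amp *
      sin(2 * pi * scene$illumination_fluctuation_hz * t + phase)
    M <- (scene$baseline_intensity * (1 + g)) *
      (1 + outer(sgn * trace, Bv))
    if (scene$noise_sigma > 0)
      M <- M + stats::rnorm(nt * npx, sd = scene$noise_sigma)
    trials[[k]] <- frame_stack(array(M, dim = c(nt, scene$height, scene$width)),
                               band = band, protocol = p)
  }
  structure(list(trials = trials, n_trials = scene$n_trials, band = band,
                 mode = mode, scene = scene),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("trial_set: %d trials of band %s (%s mode)\n",
              x$n_trials, x$band, x$mode))
  invisible(x)
}

#' Simulate a local field potential trace
#'
#' One negative-going deflection per stimulus in the train, with amplitudes
#' depressed geometrically across the train (use-dependent synaptic
#' depression), plus additive Gaussian noise.  The deflection kernel is a
#' fast gamma-variate (10 ms rise).
#'
#' @param stim_rate stimulation rate within the train, Hz (0.1 to 20); a
#'   0.1 Hz train contains a single stimulus.
#' @param response_amp amplitude of the first deflection, uV.
#' @param depression per-stimulus geometric decay factor in `(0, 1]`.
#' @param noise_sigma additive noise, uV.
#' @param seed RNG seed for the noise.
#' @param protocol a [stim_protocol()]; stimuli fill the stimulation window.
#' @param sampling_rate_hz LFP sampling rate, Hz (>= 1000).
#' @return an `lfp_trace`: list with `t` (s), `y` (uV), and stimulus times.
#' @export
simulate_lfp <- function(stim_rate, response_amp, depression = 1,
                         noise_sigma = 0, seed = 1,
                         protocol = stim_protocol(),
                         sampling_rate_hz = 1000) {
  stopifnot(stim_rate >= 0.1, stim_rate <= 20,
            depression > 0, depression <= 1, noise_sigma >= 0)
  if (sampling_rate_hz <= 0) stop("simulate_lfp: sampling rate must be positive")
  if (sampling_rate_hz < 1000)
    stop("simulate_lfp: sampling rate must be >= 1000 Hz")
  dur <- protocol$baseline_s + protocol$stim_s + protocol$recovery_s
  t <- seq(0, dur, by = 1 / sampling_rate_hz)
  onset <- stim_onset(protocol)
  n_stim <- max(1L, as.integer(floor(protocol$stim_s * stim_rate)))
  stim_times <- onset + (seq_len(n_stim) - 1) / stim_rate
  y <- numeric(length(t))
  if (response_amp != 0) {
    tau_peak <- 0.01                      # 10 ms deflection rise
    for (k in seq_len(n_stim)) {
      amp <- response_amp * depression^(k - 1)
      tau <- t - stim_times[k]
      idx <- which(tau > 0 & tau < 12 * tau_peak)
      y[idx] <- y[idx] - amp * gamma_variate(tau[idx], tau_peak, 2)
    }
  }
  if (noise_sigma > 0) {
    set.seed(as.integer(seed))
    y <- y + stats::rnorm(length(y), sd = noise_sigma)
  }
  structure(list(t = t, y = y, units = "uV", stim_times = stim_times,
                 protocol = protocol),
            class = "lfp_trace")
}
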