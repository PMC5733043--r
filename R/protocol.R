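#' Trial timing protocol
#'
#' Describes the timing of one stimulation trial: a pre-stimulus baseline,
#' a stimulation train, and a recovery period, sampled at a fixed frame rate
#' per illumination band.  The defaults are the acquisition protocol the
#' package's analyses assume: 5 s baseline, 10 s whisker stimulation, 45 s
#' recovery at 5 Hz.
#'
#' @param baseline_s baseline duration before stimulus onset, seconds.
#' @param stim_s stimulation train duration, seconds.
#' @param recovery_s post-stimulus recovery duration, seconds.
#' @param frame_rate_hz camera frame rate per band, Hz.
#' @return an object of class `stim_protocol`.
#' @examples
#' p <- stim_protocol()
#' n_frames(p)          # 300 frames
#' range(protocol_times(p))
#' @export
stim_protocol <- function(baseline_s = 5, stim_s = 10, recovery_s = 45,
                          frame_rate_hz = 5) {
  stopifnot(baseline_s >= 0, stim_s > 0, recovery_s >= 0, frame_rate_hz > 0,
            all(is.finite(c(baseline_s, stim_s, recovery_s, frame_rate_hz))))
  structure(list(baseline_s = baseline_s, stim_s = stim_s,
                 recovery_s = recovery_s, frame_rate_hz = frame_rate_hz),
            class = "stim_protocol")
}

#' @rdname stim_protocol
#' @param protocol a `stim_protocol`.
#' @export
n_frames <- function(protocol) {
  as.integer(round((protocol$baseline_s + protocol$stim_s +
                      protocol$recovery_s) * protocol$frame_rate_hz))
}

#' @rdname stim_protocol
#' @export
protocol_times <- function(protocol) {
  (seq_len(n_frames(protocol)) - 1) / protocol$frame_rate_hz
}

#' @rdname stim_protocol
#' @export
stim_onset <- function(protocol) protocol$baseline_s

#' Frame indices of a time window
#'
#' @param protocol a `stim_protocol`.
#' @param window numeric length-2, `[start, end)` in seconds from trial start.
#' @return integer vector of frame indices.
#' @export
window_frames <- function(protocol, window) {
  t <- protocol_times(protocol)
  idx <- which(t >= window[1] - 1e-9 & t < window[2] - 1e-9)
  if (length(idx) == 0L) stop("empty time window [", window[1], ", ", window[2], ")")
  idx
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf("stim_protocol: %gs baseline + %gs stim + %gs recovery @ %g Hz (%d frames)\n",
              x$baseline_s, x$stim_s, x$recovery_s, x$frame_rate_hz, n_frames(x)))
  invisible(x)
}
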