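#' Write a frame stack as a multi-page TIFF with a JSON sidecar
#'
#' Intensities are stored as 32-bit samples scaled into `[0, 1]` by an
#' affine map recorded in the sidecar (`scale`, `offset`; counts =
#' `stored * scale + offset`), so signed corrected stacks round-trip too.
#' The sidecar carries the band name, frame rate, protocol windows and any
#' extra metadata supplied.
#'
#' @param stack a [frame_stack()].
#' @param path output TIFF path; the sidecar is written at `<path>.json`.
#' @param extra named list merged into the sidecar (e.g. seed, true
#'   simulation parameters for recovery tests).
#' @return `path`, invisibly.
#' @export
write_frame_stack <- function(stack, path, extra = list()) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$data)
  lo <- min(stack$data); hi <- max(stack$data)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(d[1]), function(i)
    (stack$data[i, , ] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32, compression = "none")
  meta <- c(list(band = stack$band,
                 frame_rate_hz = stack$protocol$frame_rate_hz,
                 protocol = unclass(stack$protocol),
                 n_frames = d[1], height = d[2], width = d[3],
                 corrected = stack$corrected,
                 scale = scale, offset = lo),
            extra)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a frame stack written by [write_frame_stack()]
#'
#' @param path TIFF path; the sidecar `<path>.json` must exist (or pass
#'   `sidecar`).
#' @param sidecar optional explicit sidecar path.
#' @return a [frame_stack()]; the sidecar metadata is attached as
#'   attribute `"meta"`.
#' @export
read_frame_stack <- function(path, sidecar = paste0(path, ".json")) {
  if (!file.exists(sidecar))
    stop("read_frame_stack: missing sidecar ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
  arr <- arr * meta$scale + meta$offset
  p <- stim_protocol(meta$protocol$baseline_s, meta$protocol$stim_s,
                     meta$protocol$recovery_s, meta$protocol$frame_rate_hz)
  out <- frame_stack(arr, band = meta$band, protocol = p,
                     corrected = isTRUE(meta$corrected))
  attr(out, "meta") <- meta
  out
}

#' Write all trials of a band to a directory
#'
#' One multi-page TIFF per trial (`<band>_trial01.tif`, ...) plus a shared
#' sidecar per trial; scene ground truth (seed, blob geometry) is stored so
#' parameter-recovery analyses can read it back.
#'
#' @param trial_set from [render_trials()].
#' @param dir output directory (created if needed).
#' @return character vector of the TIFF paths, invisibly.
#' @export
write_trial_set <- function(trial_set, dir) {
  stopifnot(inherits(trial_set, "trial_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sc <- trial_set$scene
  truth <- list(mode = trial_set$mode, seed = sc$seed,
                blob_center = sc$blob_center, blob_sigma = sc$blob_sigma,
                baseline_intensity = sc$baseline_intensity,
                noise_sigma = sc$noise_sigma,
                illumination_fluctuation_amp = sc$illumination_fluctuation_amp,
                illumination_fluctuation_hz = sc$illumination_fluctuation_hz)
  paths <- character(trial_set$n_trials)
  for (k in seq_len(trial_set$n_trials)) {
    paths[k] <- file.path(dir, sprintf("%s_trial%02d.tif", trial_set$band, k))
    write_frame_stack(trial_set$trials[[k]], paths[k],
                      extra = c(truth, list(trial = k)))
  }
  invisible(paths)
}

#' Read a directory of trials for one band
#'
#' @param dir directory written by [write_trial_set()].
#' @param band band label to read.
#' @return a `trial_set` (without scene parameters; metadata from the first
#'   trial's sidecar is attached as attribute `"meta"`).
#' @export
read_trial_set <- function(dir, band) {
  paths <- sort(Sys.glob(file.path(dir, sprintf("%s_trial*.tif", band))))
  if (length(paths) == 0)
    stop("read_trial_set: no stacks for band ", band, " under ", dir)
  trials <- lapply(paths, read_frame_stack)
  meta <- attr(trials[[1]], "meta")
  out <- structure(list(trials = trials, n_trials = length(trials),
                        band = band,
                        mode = if (!is.null(meta$mode)) meta$mode else "reflectance",
                        scene = NULL),
                   class = "trial_set")
  attr(out, "meta") <- meta
  out
}

#' Write / read a binary mask as an 8-bit single-page TIFF
#'
#' Nonzero pixels are `TRUE`.
#'
#' @param mask an [roi_mask()] or logical matrix.
#' @param path file path.
#' @export
write_mask <- function(mask, path) {
  m <- if (inherits(mask, "roi_mask")) mask$mask else mask
  tiff::writeTIFF(m * 1.0, path, bits.per.sample = 8, compression = "none")
  invisible(path)
}

#' @rdname write_mask
#' @param role role for the returned [roi_mask()].
#' @export
read_mask <- function(path, role = "active") {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  roi_mask(m > 0, role = role)
}

#' Write an OIS map as 32-bit TIFF plus PNG preview
#'
#' The TIFF stores the affinely rescaled map with scale/offset in a JSON
#' sidecar (as for stacks); the PNG preview is normalised to the symmetric
#' extremum range for quick visual inspection.
#'
#' @param map an `ois_map`.
#' @param path TIFF path; preview goes to `<path>.png`.
#' @export
write_ois_map <- function(map, path) {
  stopifnot(inherits(map, "ois_map"))
  v <- map$values
  lo <- min(v); scale <- if (max(v) > lo) max(v) - lo else 1
  tiff::writeTIFF((v - lo) / scale, path, bits.per.sample = 32,
                  compression = "none")
  jsonlite::write_json(list(mode = map$mode, scale = scale, offset = lo,
                            stim_window = map$stim_window,
                            baseline_window = map$baseline_window),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  r <- max(abs(v))
  png::writePNG((v + r) / (2 * r), paste0(path, ".png"))
  invisible(path)
}

#' Write a time course as CSV
#'
#' Columns: `time_s`, `signal_frac`, `signal_percent`.
#'
#' @param tc an `ois_timecourse`.
#' @param path file path.
#' @export
write_timecourse_csv <- function(tc, path) {
  utils::write.csv(data.frame(time_s = tc$t, signal_frac = tc$y,
                              signal_percent = 100 * tc$y),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write decomposed chromophore time courses as CSV
#'
#' Columns: `time_s`, `dHbO_uM`, `dHbR_uM`, `dS`, `HbT_uM`.
#'
#' @param chromophores a [chromophore_timecourses()].
#' @param path file path.
#' @export
write_chromophores_csv <- function(chromophores, path) {
  utils::write.csv(data.frame(time_s = chromophores$t,
                              dHbO_uM = chromophores$d_hbo,
                              dHbR_uM = chromophores$d_hbr,
                              dS = chromophores$d_s,
                              HbT_uM = chromophores$hbt),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write / read an LFP trace as two-column CSV
#'
#' Columns `time_s`, `microvolts`.
#'
#' @param lfp an `lfp_trace`.
#' @param path file path.
#' @export
write_lfp_csv <- function(lfp, path) {
  utils::write.csv(data.frame(time_s = lfp$t, microvolts = lfp$y),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lfp_csv
#' @param protocol protocol to attach (timing is not stored in the CSV).
#' @export
read_lfp_csv <- function(path, protocol = stim_protocol()) {
  df <- utils::read.csv(path)
  structure(list(t = df$time_s, y = df$microvolts, units = "uV",
                 stim_times = NULL, protocol = protocol),
            class = "lfp_trace")
}
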