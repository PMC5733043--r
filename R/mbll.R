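#' Spectral curve
#'
#' A tabulated curve over wavelength: an LED emission spectrum, a chromophore
#' extinction curve, or a reduced-scattering curve.  Wavelengths must be
#' strictly increasing; emission values must be non-negative.
#'
#' @param wavelength_nm wavelength grid, nm.
#' @param value curve values; units depend on `kind` and are carried along.
#' @param kind `"emission"`, `"extinction"` or `"mu_s_prime"`.
#' @param units unit string; defaults to the package conventions
#'   (extinction in natural-log mm^-1 uM^-1, scattering in mm^-1).
#' @return an object of class `spectrum_curve`.
#' @export
spectrum_curve <- function(wavelength_nm, value,
                           kind = c("emission", "extinction", "mu_s_prime"),
                           units = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(wavelength_nm) == length(value), length(value) >= 2L,
            all(is.finite(wavelength_nm)), all(is.finite(value)),
            !is.unsorted(wavelength_nm, strictly = TRUE))
  if (kind == "emission" && any(value < 0))
    stop("spectrum_curve: emission values must be non-negative")
  if (is.null(units))
    units <- switch(kind, emission = "arbitrary",
                    extinction = "mm^-1.uM^-1 (natural log)",
                    mu_s_prime = "mm^-1")
  structure(list(wavelength_nm = wavelength_nm, value = value,
                 kind = kind, units = units),
            class = "spectrum_curve")
}

#' Read / write two-column spectral CSV files
#'
#' The on-disk format is a plain CSV with columns `wavelength_nm,value`
#' preceded by `#`-comment header lines declaring the kind and units, e.g.
#' `# kind: extinction` and `# units: mm^-1.uM^-1 (natural log)`.
#'
#' @param path file path.
#' @return for `read_spectrum_csv`, a [spectrum_curve()].
#' @export
read_spectrum_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(name) {
    m <- grep(paste0("^#\\s*", name, ":"), hdr, value = TRUE)
    if (length(m) == 0) return(NULL)
    trimws(sub(paste0("^#\\s*", name, ":"), "", m[1]))
  }
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  kind <- get_field("kind")
  if (is.null(kind)) kind <- "emission"
  spectrum_curve(df$wavelength_nm, df$value, kind = kind,
                 units = get_field("units"))
}

#' @rdname read_spectrum_csv
#' @param curve a [spectrum_curve()].
#' @export
write_spectrum_csv <- function(curve, path) {
  stopifnot(inherits(curve, "spectrum_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# kind: %s", curve$kind),
               sprintf("# units: %s", curve$units)), con)
  utils::write.csv(data.frame(wavelength_nm = curve$wavelength_nm,
                              value = curve$value),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Band-average a spectral property over an emission spectrum
#'
#' Emission-weighted mean of a chromophore property over a light source:
#' \deqn{\bar\epsilon = \int L(\lambda) \epsilon(\lambda) d\lambda /
#'       \int L(\lambda) d\lambda}
#' evaluated by trapezoidal quadrature on the union of the two wavelength
#' grids with linear interpolation.  The emission support must lie inside
#' the property curve's grid.
#'
#' @param emission an emission [spectrum_curve()].
#' @param property an extinction or scattering [spectrum_curve()].
#' @return the band-averaged value, in the property's units.
#' @export
band_average_extinction <- function(emission, property) {
  stopifnot(inherits(emission, "spectrum_curve"),
            inherits(property, "spectrum_curve"))
  if (emission$kind != "emission")
    stop("band_average_extinction: first argument must be an emission curve")
  if (!any(emission$value > 0))
    stop("band_average_extinction: emission integrates to zero")
  supp <- range(emission$wavelength_nm[emission$value > 0])
  if (supp[1] < min(property$wavelength_nm) ||
      supp[2] > max(property$wavelength_nm))
    stop("band_average_extinction: emission support [", supp[1], ", ", supp[2],
         "] nm outside the property grid")
  if (length(emission$wavelength_nm) == 1L ||
      sum(emission$value > 0) == 1L) {    # single-line source
    wl0 <- emission$wavelength_nm[which.max(emission$value)]
    return(stats::approx(property$wavelength_nm, property$value, wl0)$y)
  }
  grid <- sort(unique(c(emission$wavelength_nm, property$wavelength_nm)))
  grid <- grid[grid >= supp[1] & grid <= supp[2]]
  L <- stats::approx(emission$wavelength_nm, emission$value, grid, rule = 2)$y
  eps <- stats::approx(property$wavelength_nm, property$value, grid)$y
  trap <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  denom <- trap(grid, L)
  if (denom <= 0) stop("band_average_extinction: emission integrates to zero")
  trap(grid, L * eps) / denom
}

#' Spectral band
#'
#' A named illumination band with its band-averaged optical coefficients:
#' extinction of oxy- and deoxy-hemoglobin (natural-log, per mm per uM) and
#' the reduced scattering coefficient (per mm).
#'
#' @param name band label, e.g. `"GREEN"`, `"RED"`, `"IR"`.
#' @param eps_hbo,eps_hbr band-averaged extinction coefficients, mm^-1 uM^-1
#'   (must be `>= 0`).
#' @param mu_s_prime band reduced scattering coefficient, mm^-1 (`> 0`).
#' @param units named list of unit strings (defaults to the package
#'   conventions); mismatched units are an error downstream.
#' @return an object of class `spectral_band`.
#' @export
spectral_band <- function(name, eps_hbo, eps_hbr, mu_s_prime, units = NULL) {
  stopifnot(is.character(name), length(name) == 1L,
            is.finite(eps_hbo), is.finite(eps_hbr), is.finite(mu_s_prime))
  if (eps_hbo < 0 || eps_hbr < 0)
    stop("spectral_band: extinction coefficients must be >= 0")
  if (mu_s_prime <= 0) stop("spectral_band: mu_s_prime must be > 0")
  if (is.null(units))
    units <- list(eps = "mm^-1.uM^-1 (natural log)", mu_s_prime = "mm^-1")
  structure(list(name = name, eps_hbo = eps_hbo, eps_hbr = eps_hbr,
                 mu_s_prime = mu_s_prime, units = units),
            class = "spectral_band")
}

#' Build a spectral band from measured curves
#'
#' Band-averages the hemoglobin extinction curves and the reduced-scattering
#' curve over a diode emission spectrum.
#'
#' @param name band label.
#' @param emission emission [spectrum_curve()].
#' @param hbo,hbr extinction [spectrum_curve()]s for oxy-/deoxy-hemoglobin.
#' @param musp reduced-scattering [spectrum_curve()] (or a single number to
#'   use directly).
#' @return a [spectral_band()].
#' @export
band_from_spectra <- function(name, emission, hbo, hbr, musp) {
  mu <- if (inherits(musp, "spectrum_curve"))
    band_average_extinction(emission, musp) else musp
  spectral_band(name,
                eps_hbo = band_average_extinction(emission, hbo),
                eps_hbr = band_average_extinction(emission, hbr),
                mu_s_prime = mu)
}

#' Default three-band set from the shipped synthetic spectra
#'
#' GREEN (525 nm), RED (626 nm) and IR (850 nm) bands, band-averaged over
#' the synthetic LED and chromophore curves under `inst/extdata/`.  The
#' GREEN band is mostly sensitive to blood volume (both hemoglobins absorb
#' strongly and similarly), RED mostly to oximetry (deoxy-hemoglobin
#' dominates), and IR mostly to tissue scattering.  These are editable
#' illustrative fixtures, not measured diode or blood data.
#'
#' @return a list of three [spectral_band()] objects.
#' @export
default_bands <- function() {
  ext <- function(f) read_spectrum_csv(system.file("extdata", f, package = "oisi"))
  hbo <- ext("extinction_hbo_synthetic.csv")
  hbr <- ext("extinction_hbr_synthetic.csv")
  musp <- ext("musp_synthetic.csv")
  list(band_from_spectra("GREEN", ext("led_green_525_synthetic.csv"), hbo, hbr, musp),
       band_from_spectra("RED",   ext("led_red_626_synthetic.csv"),   hbo, hbr, musp),
       band_from_spectra("IR",    ext("led_ir_850_synthetic.csv"),    hbo, hbr, musp))
}

#' Assemble the modified Beer-Lambert system
#'
#' Builds the linear chromophore system relating band attenuations to
#' chromophore changes, with the effective optical pathlength taken as twice
#' the layer-4 depth (`2 * d_iv`, the same for absorption and scattering):
#' row `b` of the coefficient matrix is
#' `(eps_hbo_b, eps_hbr_b, mu_s_prime_b) * 2 * d_iv`, and
#' `attenuation = matrix %*% c(dHbO, dHbR, dS)`.
#'
#' @param bands list of [spectral_band()] objects (>= 3 for a full
#'   three-chromophore decomposition; fewer are allowed for restricted
#'   inversions).
#' @param d_iv cortical layer-4 depth, mm (e.g. 0.35 for neonatal, 0.75 for
#'   adult rats).
#' @return an `mbll_model`: bands, `d_iv`, `pathlength = 2 * d_iv`, the
#'   coefficient `matrix` (bands x (HbO, HbR, S)), and its condition number.
#' @export
mbll_model <- function(bands, d_iv) {
  if (inherits(bands, "spectral_band")) bands <- list(bands)
  stopifnot(is.list(bands), length(bands) >= 1L,
            all(vapply(bands, inherits, logical(1), "spectral_band")),
            is.finite(d_iv), d_iv > 0)
  u0 <- bands[[1]]$units
  for (b in bands)
    if (!identical(b$units, u0))
      stop("mbll_model: bands carry mismatched units (",
           b$name, ": ", b$units$eps, " vs ", u0$eps, ")")
  M <- t(vapply(bands, function(b) c(b$eps_hbo, b$eps_hbr, b$mu_s_prime),
                numeric(3))) * (2 * d_iv)
  rownames(M) <- vapply(bands, function(b) b$name, character(1))
  colnames(M) <- c("HbO", "HbR", "S")
  cond <- if (nrow(M) >= 3) kappa(M, exact = TRUE) else NA_real_
  structure(list(bands = bands, d_iv = d_iv, pathlength = 2 * d_iv,
                 matrix = M, condition_number = cond, units = u0),
            class = "mbll_model")
}

#' @export
print.mbll_model <- function(x, ...) {
  cat(sprintf("mbll_model: %d bands, d_IV = %g mm (pathlength %g mm)\n",
              nrow(x$matrix), x$d_iv, x$pathlength))
  print(signif(x$matrix, 4))
  cat(sprintf("condition number: %.3g\n", x$condition_number))
  invisible(x)
}

# map an ois_timecourse (or plain vector) to the attenuation sign convention:
# positive attenuation = darkening under reflectance illumination
.as_attenuation <- function(tc) {
  if (!inherits(tc, "ois_timecourse")) return(as.numeric(tc))
  if (tc$polarity == "activation-positive") {
    tc$y                                  # both modes: activation = +attenuation
  } else if (tc$mode == "reflectance") {
    -tc$y                                 # raw darkening is negative
  } else {
    tc$y                                  # raw transmission brightening = +S
  }
}

#' Decompose multi-band OIS time courses into chromophores
#'
#' Solves the modified Beer-Lambert system per timepoint: exactly for a
#' square system, by least squares when over-determined (per-timepoint
#' residuals are then attached as attribute `"residuals"`).  Input traces
#' may be `ois_timecourse` objects in either polarity convention (the sign
#' convention and imaging mode are read from their metadata) or plain
#' attenuation vectors.  All traces must share one time grid.
#'
#' @param ois_by_band named list of traces, one per model band (names or
#'   order must match the model's bands).
#' @param model an [mbll_model()].
#' @param components chromophores to solve for, a subset of
#'   `c("HbO", "HbR", "S")`; excluded components are fixed at zero.  The
#'   number of bands must be at least the number of components.
#' @param max_condition refuse to invert systems whose coefficient-matrix
#'   condition number exceeds this value.
#' @return a [chromophore_timecourses()] object.
#' @export
mbll_decompose <- function(ois_by_band, model, components = c("HbO", "HbR", "S"),
                           max_condition = 1e8) {
  stopifnot(inherits(model, "mbll_model"))
  components <- match.arg(components, c("HbO", "HbR", "S"),
                          several.ok = TRUE)
  if (inherits(ois_by_band, "band_traces")) {
    tr <- ois_by_band$traces
    ois_by_band <- lapply(seq_len(ncol(tr)), function(j) tr[, j])
    names(ois_by_band) <- colnames(tr)
  }
  if (!is.list(ois_by_band)) ois_by_band <- list(ois_by_band)
  nb <- nrow(model$matrix)
  if (length(ois_by_band) != nb)
    stop("mbll_decompose: ", length(ois_by_band), " traces for ", nb, " bands")
  if (nb < length(components))
    stop("mbll_decompose: ", nb, " band(s) cannot resolve ", length(components),
         " chromophores; at least ", length(components), " bands required")
  if (!is.null(names(ois_by_band)) && all(nzchar(names(ois_by_band))) &&
      !identical(names(ois_by_band), rownames(model$matrix)))
    ois_by_band <- ois_by_band[rownames(model$matrix)]
  tcs <- ois_by_band[vapply(ois_by_band, inherits, logical(1), "ois_timecourse")]
  tgrid <- NULL
  if (length(tcs) > 0) {
    tgrid <- tcs[[1]]$t
    for (tc in tcs)
      if (!isTRUE(all.equal(tc$t, tgrid, tolerance = 1e-9)))
        stop("mbll_decompose: band traces do not share one time grid")
  }
  Y <- vapply(ois_by_band, .as_attenuation,
              numeric(length(.as_attenuation(ois_by_band[[1]]))))
  if (is.null(tgrid)) tgrid <- seq_len(nrow(Y)) - 1
  A <- model$matrix[, components, drop = FALSE]
  cond <- kappa(A, exact = TRUE)
  if (cond > max_condition)
    stop(sprintf(paste0("mbll_decompose: coefficient matrix is ill-conditioned ",
                        "(condition number %.3g > %.3g); use better-separated ",
                        "bands or fewer components"), cond, max_condition))
  qrA <- qr(A)
  X <- qr.coef(qrA, t(Y))                     # components x time
  out <- matrix(0, length(tgrid), 3,
                dimnames = list(NULL, c("HbO", "HbR", "S")))
  out[, components] <- t(X)
  ct <- chromophore_timecourses(tgrid, d_hbo = out[, "HbO"],
                                d_hbr = out[, "HbR"], d_s = out[, "S"])
  if (nrow(A) > length(components)) {
    res <- t(Y) - A %*% X
    attr(ct, "residuals") <- t(res)
  }
  attr(ct, "condition_number") <- cond
  ct
}

#' Serialise an MBLL model to JSON
#'
#' @param model an [mbll_model()].
#' @param path output file.
#' @export
write_mbll_json <- function(model, path) {
  stopifnot(inherits(model, "mbll_model"))
  jsonlite::write_json(list(
    d_iv_mm = model$d_iv, pathlength_mm = model$pathlength,
    bands = lapply(model$bands, function(b)
      list(name = b$name, eps_hbo = b$eps_hbo, eps_hbr = b$eps_hbr,
           mu_s_prime = b$mu_s_prime, units = b$units)),
    matrix = apply(model$matrix, 1, identity, simplify = FALSE),
    condition_number = model$condition_number
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
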