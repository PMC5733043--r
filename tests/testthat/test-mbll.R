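test_that("band averaging is the emission-weighted mean", {
  # constant property over the emission support
  em <- spectrum_curve(500:540, exp(-((500:540 - 520) / 8)^2), "emission")
  flat <- spectrum_curve(seq(450, 600, 5), rep(3.3e-3, 31), "extinction")
  expect_equal(band_average_extinction(em, flat), 3.3e-3)

  # single-line source picks the property at that wavelength
  line <- spectrum_curve(c(519, 520, 521), c(0, 1, 0), "emission")
  ramp <- spectrum_curve(seq(450, 600, 1), seq(450, 600, 1) * 1e-5, "extinction")
  expect_equal(band_average_extinction(line, ramp), 520 * 1e-5, tolerance = 1e-9)

  # triangular emission on [600, 620] against linear property -> centroid 610,
  # cross-checked with dense 0.01 nm quadrature
  tri <- spectrum_curve(c(600, 610, 620), c(0, 1, 0), "emission")
  lin <- spectrum_curve(seq(590, 630, 1), seq(590, 630, 1), "extinction")
  got <- band_average_extinction(tri, lin)
  g <- seq(600, 620, 0.01)
  L <- approx(c(600, 610, 620), c(0, 1, 0), g)$y
  dense <- sum(L * g) / sum(L)
  expect_equal(got, 610, tolerance = 1e-9)
  expect_equal(got, dense, tolerance = 1e-6)

  zero <- spectrum_curve(c(600, 610, 620), c(0, 0, 0), "emission")
  expect_error(band_average_extinction(zero, lin))
  outside <- spectrum_curve(c(700, 710, 720), c(0, 1, 0), "emission")
  expect_error(band_average_extinction(outside, lin), "outside")
})

test_that("system assembly scales by the doubled layer-4 depth", {
  bands <- test_bands()
  m <- mbll_model(bands, 0.35)
  expect_equal(m$pathlength, 0.7)
  raw <- t(vapply(bands, function(b) c(b$eps_hbo, b$eps_hbr, b$mu_s_prime),
                  numeric(3)))
  expect_equal(unname(m$matrix), raw * 0.7)
  expect_true(is.finite(m$condition_number))

  # near-identity band set gives a near-diagonal matrix
  idb <- list(spectral_band("H", 1, 0, 1e-12),
              spectral_band("R", 0, 1, 1e-12),
              spectral_band("S", 0, 0, 1))
  expect_equal(unname(mbll_model(idb, 0.5)$matrix), diag(3), tolerance = 1e-9)

  # permuting bands permutes rows
  m2 <- mbll_model(bands[c(2, 3, 1)], 0.35)
  expect_identical(m2$matrix, m$matrix[c(2, 3, 1), ])

  # unit mismatch across bands is an error
  odd <- spectral_band("X", 1e-3, 1e-3, 1,
                       units = list(eps = "cm^-1.M^-1", mu_s_prime = "mm^-1"))
  expect_error(mbll_model(c(bands[1:2], list(odd)), 0.35), "units")
})

test_that("three-band decomposition inverts the forward model to machine precision", {
  model <- mbll_model(test_bands(), 0.35)
  ct <- simulate_chromophores(neonatal_response_params())
  rec <- mbll_decompose(forward_project(ct, model), model)
  scale <- max(abs(c(ct$d_hbo, ct$d_hbr, ct$d_s)))
  err <- max(abs(c(rec$d_hbo - ct$d_hbo, rec$d_hbr - ct$d_hbr,
                   rec$d_s - ct$d_s))) / scale
  expect_lt(err, 1e-10)
  expect_identical(rec$hbt, rec$d_hbo + rec$d_hbr)  # bitwise by construction

  # zero traces -> zero chromophores
  z <- mbll_decompose(list(A = rep(0, 5), B = rep(0, 5), C = rep(0, 5)), model)
  expect_true(all(z$d_hbo == 0) && all(z$d_s == 0))
})

test_that("restricted single-band scattering inversion matches the scalar formula", {
  b <- spectral_band("S", eps_hbo = 0, eps_hbr = 0, mu_s_prime = 1)
  m1 <- mbll_model(list(b), 0.35)
  rec <- mbll_decompose(list(S = c(0, 0.007)), m1, components = "S")
  expect_equal(rec$d_s, c(0, 0.01))
  expect_true(all(rec$d_hbo == 0) && all(rec$hbt == 0))
  expect_error(mbll_decompose(list(S = c(0, 0.007)), m1), "cannot resolve")
})

test_that("ill-conditioned and mismatched systems are refused with diagnostics", {
  b <- test_bands()[[1]]
  dup <- mbll_model(list(b, b, b), 0.35)           # identical rows
  y <- list(A = c(0, 1e-3), A2 = c(0, 1e-3), A3 = c(0, 1e-3))
  expect_error(mbll_decompose(y, dup), "ill-conditioned")

  model <- mbll_model(test_bands(), 0.35)
  t1 <- ois_timecourse(0:9 / 5, rep(0, 10), stim_onset = 1)
  t2 <- ois_timecourse(0:9 / 5 + 0.01, rep(0, 10), stim_onset = 1)
  expect_error(mbll_decompose(list(A = t1, B = t2, C = t1), model),
               "time grid")
})

test_that("timecourse polarity metadata maps to one attenuation convention", {
  model <- mbll_model(test_bands(), 0.35)
  ct <- simulate_chromophores(neonatal_response_params())
  att <- forward_project(ct, model)$traces
  t <- ct$t
  mk <- function(y, mode, pol) ois_timecourse(t, y, 5, mode = mode, polarity = pol)
  variants <- list(
    lapply(1:3, function(j) mk(att[, j], "reflectance", "activation-positive")),
    lapply(1:3, function(j) mk(-att[, j], "reflectance", "raw")),
    lapply(1:3, function(j) mk(att[, j], "transmission", "raw")),
    lapply(1:3, function(j) mk(att[, j], "transmission", "activation-positive")))
  for (v in variants) {
    names(v) <- rownames(model$matrix)
    rec <- mbll_decompose(v, model)
    expect_equal(rec$d_s, ct$d_s, tolerance = 1e-10)
    expect_equal(rec$hbt, ct$hbt, tolerance = 1e-10)
  }
})

test_that("recovered noise scales like the pseudo-inverse prediction", {
  model <- mbll_model(test_bands(), 0.35)
  A <- model$matrix
  Ainv <- solve(A)
  pred <- unname(sqrt(rowSums(Ainv^2)))    # per-component gain on white noise
  set.seed(3)
  n <- 4000
  for (s in c(1e-4, 4e-4)) {
    Y <- matrix(rnorm(3 * n, sd = s), n, 3)
    rec <- mbll_decompose(list(A = Y[, 1], B = Y[, 2], C = Y[, 3]), model)
    got <- c(sd(rec$d_hbo), sd(rec$d_hbr), sd(rec$d_s))
    expect_equal(got, s * pred, tolerance = 0.2)
  }
})

test_that("over-determined systems report per-timepoint residuals", {
  bands <- c(test_bands(),
             list(spectral_band("D", 2e-3, 2.4e-3, 1.5)))
  model <- mbll_model(bands, 0.35)
  ct <- simulate_chromophores(adult_response_params())
  tr <- forward_project(ct, model)
  rec <- mbll_decompose(tr, model)
  expect_equal(rec$d_s, ct$d_s, tolerance = 1e-9)
  res <- attr(rec, "residuals")
  expect_identical(dim(res), c(length(ct$t), 4L))
  expect_lt(max(abs(res)), 1e-12)
})

test_that("spectrum CSV round trip preserves values, kind and units", {
  f <- tempfile(fileext = ".csv")
  sc <- spectrum_curve(seq(500, 550, 2.5), runif(21), "extinction")
  write_spectrum_csv(sc, f)
  back <- read_spectrum_csv(f)
  expect_equal(back$wavelength_nm, sc$wavelength_nm)
  expect_equal(back$value, sc$value, tolerance = 1e-9)
  expect_identical(back$kind, "extinction")
  expect_identical(back$units, sc$units)
})

test_that("shipped band set has the expected spectral ordering", {
  bands <- default_bands()
  names(bands) <- vapply(bands, `[[`, "", "name")
  # green: strong, similar extinction for both hemoglobins
  expect_gt(bands$GREEN$eps_hbo, 10 * bands$RED$eps_hbo)
  # red: deoxy dominates oxy
  expect_gt(bands$RED$eps_hbr / bands$RED$eps_hbo, 3)
  # IR: oxy above deoxy, both small; scattering decreases with wavelength
  expect_gt(bands$IR$eps_hbo, bands$IR$eps_hbr)
  expect_gt(bands$GREEN$mu_s_prime, bands$IR$mu_s_prime)
})
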