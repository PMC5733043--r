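test_that("zero-amplitude parameters give all-zero chromophores", {
  p <- neonatal_response_params(hbo_amp = 0, hbr_amp = 0, ls_amp = 0)
  ct <- simulate_chromophores(p)
  expect_true(all(ct$d_hbo == 0) && all(ct$d_hbr == 0) && all(ct$d_s == 0) &&
                all(ct$hbt == 0))
})

test_that("neonatal chromophores peak and recover at the preset times", {
  proto <- stim_protocol()
  ct <- simulate_chromophores(neonatal_response_params(), proto)
  onset <- stim_onset(proto)
  expect_true(all(ct$d_s[ct$t < onset] == 0))
  expect_true(all(ct$hbt[ct$t < onset] == 0))
  # scattering peaks at the end of the 10 s stimulation train
  t_s_peak <- ct$t[which.max(ct$d_s)] - onset
  expect_equal(t_s_peak, 10, tolerance = 1 / proto$frame_rate_hz)
  # first post-peak sample at/below half occurs 25 s later; cross-check the
  # same kernel on a dense 1 ms grid
  post <- which(ct$t > ct$t[which.max(ct$d_s)])
  t_half <- ct$t[post[which(ct$d_s[post] <= 0.5 * max(ct$d_s))[1]]] -
    ct$t[which.max(ct$d_s)]
  expect_equal(t_half, 25, tolerance = 1 / proto$frame_rate_hz)
  shape <- shape_for_half_recovery(10, 25)
  dense_t <- seq(0, 60, by = 1e-3)
  dense <- gamma_variate(dense_t, 10, shape)
  dense_half <- dense_t[dense_t > 10][which(dense[dense_t > 10] <= 0.5)[1]] - 10
  expect_equal(t_half, dense_half, tolerance = 1 / proto$frame_rate_hz)
  # total hemoglobin peaks at 30 s
  expect_equal(ct$t[which.max(ct$hbt)] - onset, 30,
               tolerance = 1 / proto$frame_rate_hz)
})

test_that("neonatal and adult presets separate or overlap the two phases", {
  proto <- stim_protocol()
  onset <- stim_onset(proto)
  neo <- simulate_chromophores(neonatal_response_params(), proto)
  expect_lte(neo$t[which.max(neo$d_s)] - onset, 10)
  expect_gt(neo$t[which.max(neo$hbt)] - onset, 10)
  ad <- simulate_chromophores(adult_response_params(), proto)
  expect_lte(ad$t[which.max(ad$d_s)] - onset, 10)
  expect_lte(ad$t[which.max(ad$hbt)] - onset, 10)
})

test_that("invalid response parameters are rejected", {
  expect_error(neonatal_response_params(hr_delay = -1), "time parameters")
  expect_error(neonatal_response_params(ls_peak_time = NaN), "finite")
  expect_error(neonatal_response_params(kernel_shape = 0), "kernel_shape")
  expect_error(neonatal_response_params(hr_peak_time = 5, hr_delay = 6),
               "hr_peak_time")
})

test_that("forward projection is the exact linear Beer-Lambert map", {
  model <- mbll_model(test_bands(), 0.35)
  proto <- stim_protocol()
  zero <- simulate_chromophores(
    neonatal_response_params(hbo_amp = 0, hbr_amp = 0, ls_amp = 0), proto)
  expect_true(all(forward_project(zero, model)$traces == 0))

  # single scattering-only band: OIS = mu_s' * dS * 2 d_IV = 1 * 0.01 * 0.7
  b <- spectral_band("S", eps_hbo = 0, eps_hbr = 0, mu_s_prime = 1)
  m1 <- mbll_model(list(b), 0.35)
  ct <- chromophore_timecourses(c(0, 1), d_hbo = c(0, 0), d_hbr = c(0, 0),
                                d_s = c(0, 0.01))
  expect_equal(unname(forward_project(ct, m1)$traces[2, 1]), 0.007)

  # homogeneity: doubling all chromophores doubles every band trace
  ct1 <- simulate_chromophores(neonatal_response_params(), proto)
  ct2 <- simulate_chromophores(
    neonatal_response_params(hbo_amp = 4, hbr_amp = -1, ls_amp = 0.006), proto)
  expect_equal(forward_project(ct2, model)$traces,
               2 * forward_project(ct1, model)$traces, tolerance = 1e-12)
})

test_that("rendering obeys the null-scene, determinism and formula contracts", {
  proto <- stim_protocol(baseline_s = 1, stim_s = 2, recovery_s = 1)
  sc <- small_scene(protocol = proto, n_trials = 2)
  nt <- n_frames(proto)

  # null scene: every frame equals the baseline intensity everywhere
  ts0 <- render_trials(sc, rep(0, nt), band = "G")
  expect_true(all(ts0$trials[[1]]$data == sc$baseline_intensity))

  # fixed seed: bit-identical stacks, even with noise and drift
  scn <- small_scene(protocol = proto, noise_sigma = 4,
                     illumination_fluctuation_amp = 0.01, seed = 7)
  tr <- 0.01 * gamma_variate(protocol_times(proto) - 1, 1, 2)
  a1 <- render_trials(scn, tr, band = "G")
  a2 <- render_trials(scn, tr, band = "G")
  expect_identical(a1$trials[[1]]$data, a2$trials[[1]]$data)
  expect_identical(a1$trials[[2]]$data, a2$trials[[2]]$data)
  # distinct trials and bands use distinct noise substreams
  expect_false(identical(a1$trials[[1]]$data, a1$trials[[2]]$data))
  b1 <- render_trials(scn, tr, band = "R")
  expect_false(identical(a1$trials[[1]]$data, b1$trials[[1]]$data))

  # noiseless 1% trace darkens the blob-centre pixel to baseline * 0.99
  tr2 <- rep(0, nt); tr2[10] <- 0.01
  ts2 <- render_trials(sc, tr2, band = "G", mode = "reflectance")
  expect_equal(ts2$trials[[1]]$data[10, sc$blob_center[1], sc$blob_center[2]],
               sc$baseline_intensity * (1 - 0.01))
  # transmission mode brightens instead
  ts3 <- render_trials(sc, tr2, band = "G", mode = "transmission")
  expect_equal(ts3$trials[[1]]$data[10, sc$blob_center[1], sc$blob_center[2]],
               sc$baseline_intensity * (1 + 0.01))

  expect_error(render_trials(sc, rep(0, nt - 1)), "trace length")
  expect_error(scene_params(baseline_intensity = -5), "baseline_intensity")
  expect_error(small_scene(blob_center = c(3, 30)), "inside the frame")
})

test_that("LFP simulator produces one depressed deflection per stimulus", {
  proto <- stim_protocol()
  flat <- simulate_lfp(1, response_amp = 0, noise_sigma = 0, protocol = proto)
  expect_true(all(flat$y == 0))

  # 1 Hz, 10 s train: exactly 10 deflections
  lfp <- simulate_lfp(1, response_amp = 100, depression = 1, noise_sigma = 0,
                      protocol = proto)
  expect_identical(length(lfp$stim_times), 10L)
  excursions <- sum(diff(lfp$y < -50) == 1)   # distinct dips below half-amp
  expect_equal(excursions, 10)

  # geometric depression: peaks 100 then 50 uV
  two <- simulate_lfp(0.2, response_amp = 100, depression = 0.5,
                      noise_sigma = 0, protocol = proto)
  expect_identical(length(two$stim_times), 2L)
  w1 <- two$t >= two$stim_times[1] & two$t < two$stim_times[2]
  w2 <- two$t >= two$stim_times[2]
  expect_equal(min(two$y[w1]), -100)
  expect_equal(min(two$y[w2]), -50)

  expect_error(simulate_lfp(1, 10, sampling_rate_hz = 0), "positive")
  expect_error(simulate_lfp(1, 10, sampling_rate_hz = 500), ">= 1000")
})

test_that("noiseless generator is a deterministic function of its parameters", {
  proto <- stim_protocol(baseline_s = 1, stim_s = 2, recovery_s = 1)
  sc <- small_scene(protocol = proto, noise_sigma = 0,
                    illumination_fluctuation_amp = 0.01, seed = 9)
  tr <- rep(0.005, n_frames(proto))
  expect_identical(render_trials(sc, tr, "G")$trials[[1]]$data,
                   render_trials(sc, tr, "G")$trials[[1]]$data)
})
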