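test_that("peak amplitude is the interpolated 95th percentile in percent", {
  t <- 0:19 / 5
  tc <- test_tc(t, rep(0.02, 20))
  expect_equal(peak_amplitude(tc), 2)                # constant signal
  tc2 <- test_tc(t, (0:19) / 100)                    # percent values 0..19
  expect_equal(peak_amplitude(tc2), 18.05)           # (n-1)p interpolation
  expect_equal(peak_amplitude(test_tc(t, 3 * (0:19) / 100)), 3 * 18.05)
  expect_error(peak_amplitude(tc, window = c(100, 200)), "empty")
})

test_that("peak metrics match brute-force reimplementations on random traces", {
  set.seed(101)
  for (i in 1:1000) {
    n <- sample(5:60, 1)
    t <- (0:(n - 1)) / 5
    y <- rnorm(n)
    onset <- t[sample.int(max(1, n %/% 3), 1)]
    tc <- test_tc(t, y, onset = onset)
    amp <- peak_amplitude(tc)
    expect_equal(amp, 100 * oracle_percentile(y[t >= onset], 0.95),
                 tolerance = 1e-12)
    pos <- peak_position(tc, amp)
    expect_identical(pos, oracle_peak_position(t, 100 * y, onset, amp))
    hr <- half_recovery(tc, amp, pos)
    hr_oracle <- oracle_half_recovery(t, y, onset + pos, amp / 200)
    if (is.na(hr)) expect_true(is.na(hr_oracle)) else
      expect_equal(hr, hr_oracle, tolerance = 1e-12)
  }
})

test_that("peak position takes the first crossing sample", {
  t <- 0:10
  ramp <- test_tc(t, t / 100, onset = 2)             # monotone to the end
  expect_equal(peak_position(ramp, 100 * max(ramp$y)), 10 - 2)
  plateau <- test_tc(t, c(0, 0, 0, 1, 1, 1, 0, 0, 0, 0, 0) / 100, onset = 0)
  expect_equal(peak_position(plateau, 1), 3)         # earlier of the plateau
  expect_error(peak_position(ramp, 1e6), "no sample")
})

test_that("a trace built to peak 26 s after onset is measured at 26 s", {
  proto <- stim_protocol()
  t <- protocol_times(proto)
  y <- 0.001 * gamma_variate(t - 5, 26, 2)
  tc <- test_tc(t, y, onset = 5)
  expect_equal(peak_position(tc, 100 * max(y)), 26, tolerance = 0.2)
})

test_that("half recovery interpolates linearly and handles closed forms", {
  # symmetric triangle with rise time R recovers in R/2
  R <- 4
  t <- seq(0, 10, 0.5)
  y <- pmax(0, 1 - abs(t - R) / R) / 100
  tc <- test_tc(t, y, onset = 0)
  expect_equal(half_recovery(tc, 1, R), R / 2, tolerance = 1e-12)

  # exponential decay: t_half = log(2) / k
  k <- 0.3
  t2 <- seq(0, 30, 0.2)
  tc2 <- test_tc(t2, exp(-k * t2) / 100, onset = 0)
  expect_equal(half_recovery(tc2, 1, 0), log(2) / k, tolerance = 0.2)

  # neonatal scattering component recovers in 25 s
  ct <- simulate_chromophores(neonatal_response_params())
  tcs <- test_tc(ct$t, ct$d_s, onset = 5)
  amp <- 100 * max(ct$d_s)
  pk <- ct$t[which.max(ct$d_s)] - 5
  expect_equal(half_recovery(tcs, amp, pk), 25, tolerance = 0.2)

  # never recovering -> NA sentinel
  flat <- test_tc(0:10, rep(0.01, 11), onset = 0)
  expect_true(is.na(half_recovery(flat, 1, 2)))
})

test_that("average LFP is the rectified integral over the stimulation window", {
  proto <- stim_protocol()
  lfp <- simulate_lfp(1, response_amp = 0, protocol = proto)
  expect_equal(as.numeric(average_lfp(lfp)), 0)
  lfp$y <- rep(-40, length(lfp$t))                   # constant 40 uV magnitude
  expect_equal(as.numeric(average_lfp(lfp)), 40)
  lfp2 <- simulate_lfp(2, response_amp = 80, protocol = proto)
  expect_equal(as.numeric(average_lfp(list(t = lfp2$t, y = 2 * lfp2$y,
                                           protocol = proto))),
               2 * as.numeric(average_lfp(lfp2)))
})

test_that("optimal-rate ranking returns the top three, ties toward lower rates", {
  amps <- c(`1` = 0.1, `2` = 0.3, `5` = 0.2, `10` = 0.05)
  expect_equal(rank_stimulation_rates(amps), c(2, 5, 1))
  expect_equal(rank_stimulation_rates(rep(1, 5), rates = c(10, 1, 5, 2, 20)),
               c(1, 2, 5))
  perm <- sample(seq_along(amps))
  expect_equal(rank_stimulation_rates(amps[perm]), c(2, 5, 1))
  expect_error(rank_stimulation_rates(c(`1` = 1, `2` = 2)), "at least 3")
})

test_that("pearson correlation handles exact linear and degenerate cases", {
  x <- c(1, 3, 4, 7, 9)
  expect_equal(pearson_correlation(x, 2 * x + 1), 1)
  expect_equal(pearson_correlation(x, -x), -1)
  expect_error(pearson_correlation(x, rep(2, 5)), "zero variance")
})

test_that("kernel fit recovers peak time and half recovery from sampled traces", {
  t <- protocol_times(stim_protocol())
  shape <- shape_for_half_recovery(10, 25)
  y <- 0.003 * gamma_variate(t - 5, 10, shape)
  fit <- fit_gamma_variate(t, y, onset = 5, fit_delay = FALSE)
  expect_equal(fit$peak_time, 10, tolerance = 1e-3)
  expect_equal(fit$half_recovery, 25, tolerance = 1e-2)
  expect_equal(fit$amplitude, 0.003, tolerance = 1e-4)

  # delayed negative-going component
  y2 <- -1.5 * gamma_variate(t - 5 - 10, 20, 2)
  fit2 <- fit_gamma_variate(t, y2, onset = 5, fit_delay = TRUE)
  expect_equal(fit2$peak_time, 30, tolerance = 1e-2)
  expect_equal(fit2$amplitude, -1.5, tolerance = 1e-3)

  # moderate noise: peak time still within a fraction of a frame
  set.seed(9)
  fitn <- fit_gamma_variate(t, y + rnorm(length(t), sd = 0.05 * max(y)),
                            onset = 5, fit_delay = FALSE)
  expect_equal(fitn$peak_time, 10, tolerance = 0.2)
})

test_that("OIS amplitude tracks average LFP through a saturating link", {
  # synthetic experiment: both observables driven by one saturating response
  rates <- c(0.5, 1, 2, 5, 10, 20)
  n_ok <- 0
  for (seed in 1:20) {
    set.seed(seed)
    drive <- rep(rates^0.7 / (1 + rates^0.7 / 3), length.out = 200)
    ois <- drive * 0.08 + rnorm(200, sd = 0.015)
    lfp <- drive * 40 + rnorm(200, sd = 8)
    if (pearson_correlation(ois, lfp) >= 0.6) n_ok <- n_ok + 1
  }
  expect_gte(n_ok / 20, 0.9)
})
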