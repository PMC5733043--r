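# Shared fixtures: small scenes and band sets that keep unit tests fast,
# plus brute-force oracles used by the equivalence suites.

small_scene <- function(...) {
  defaults <- list(height = 60, width = 60, blob_center = c(30, 30),
                   blob_sigma = 6, n_trials = 2, seed = 42,
                   noise_sigma = 0, illumination_fluctuation_amp = 0)
  do.call(scene_params, utils::modifyList(defaults, list(...)))
}

# plain numeric band set: no file I/O involved
test_bands <- function() {
  list(spectral_band("A", eps_hbo = 5.3e-3, eps_hbr = 4.9e-3, mu_s_prime = 2.1),
       spectral_band("B", eps_hbo = 1.9e-4, eps_hbr = 1.26e-3, mu_s_prime = 1.7),
       spectral_band("C", eps_hbo = 2.4e-4, eps_hbr = 1.6e-4, mu_s_prime = 1.2))
}

test_tc <- function(t, y, onset = 0, mode = "reflectance",
                    polarity = "activation-positive") {
  ois_timecourse(t, y, stim_onset = onset, mode = mode, polarity = polarity)
}

# --- independent oracles -------------------------------------------------

# percentile by explicit sort-and-interpolate (linear between order stats)
oracle_percentile <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p
  lo <- floor(h)
  if (lo >= length(s) - 1) return(s[length(s)])
  s[lo + 1] + (h - lo) * (s[lo + 2] - s[lo + 1])
}

# first sample at/after onset reaching the amplitude, by explicit loop
oracle_peak_position <- function(t, y_pct, onset, amplitude) {
  for (i in seq_along(t)) {
    if (t[i] >= onset && y_pct[i] >= amplitude - 1e-12) return(t[i] - onset)
  }
  NA_real_
}

# first post-peak half crossing with linear interpolation, by explicit loop
oracle_half_recovery <- function(t, y, t_peak, half) {
  for (i in seq_along(t)) {
    if (t[i] <= t_peak + 1e-9) next
    if (y[i] <= half + 1e-15) {
      if (i == 1 || t[i - 1] <= t_peak - 1e-9) return(t[i] - t_peak)
      y0 <- y[i - 1]; y1 <- y[i]
      tc <- if (y0 == y1) t[i] else
        t[i - 1] + (t[i] - t[i - 1]) * (y0 - half) / (y0 - y1)
      return(tc - t_peak)
    }
  }
  NA_real_
}

# exact MWU tail by enumeration using the rank-sum (midrank) formula --
# a code path independent of the package's pairwise-count statistic
oracle_mwu_p <- function(a, b) {
  m <- length(a); n <- length(b)
  pooled <- c(a, b)
  u_of <- function(idx) {
    r <- rank(pooled)                     # midranks
    sum(r[idx]) - n * (n + 1) / 2
  }
  u_obs <- u_of(m + seq_len(n))
  picks <- utils::combn(m + n, n)
  u_all <- apply(picks, 2, u_of)
  mean(u_all >= u_obs - 1e-9)
}

# one-tailed sign-test tail by direct binomial-coefficient summation
oracle_sign_p <- function(k, n) sum(choose(n, k:n)) / 2^n
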