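#' One-tailed Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples.  For small problems
#' (`m + n <= exact_max_n`) the p-value is exact: the U statistic is
#' enumerated over all `choose(m + n, n)` assignments of the pooled values
#' (ties handled by the half-count convention).  Larger problems use the
#' tie-corrected normal approximation with continuity correction.
#'
#' The direction is an explicit argument, never inferred from the data:
#' `"b_greater"` tests the alternative that values in `b` tend to exceed
#' those in `a` (and vice versa).
#'
#' @param a,b numeric samples.
#' @param direction `"b_greater"` or `"a_greater"`.
#' @param exact_max_n enumerate exactly up to this pooled size.
#' @return list with `statistic` (the U of the favoured group), `p.value`,
#'   and `method` (`"exact enumeration"` or `"normal approximation"`).
#' @export
mann_whitney_u_one_tailed <- function(a, b,
                                      direction = c("b_greater", "a_greater"),
                                      exact_max_n = 12) {
  direction <- match.arg(direction)
  stopifnot(length(a) >= 1, length(b) >= 1,
            all(is.finite(a)), all(is.finite(b)))
  if (direction == "a_greater") {
    tmp <- a; a <- b; b <- tmp               # reduce to the b_greater case
  }
  m <- length(a); n <- length(b)
  u_stat <- function(av, bv)                  # U of group b
    sum(vapply(bv, function(x) sum(x > av) + 0.5 * sum(x == av), numeric(1)))
  u_obs <- u_stat(a, b)
  pooled <- c(a, b)
  if (m + n <= exact_max_n) {
    picks <- utils::combn(m + n, n)
    u_all <- apply(picks, 2, function(idx)
      u_stat(pooled[-idx], pooled[idx]))
    p <- mean(u_all >= u_obs - 1e-9)
    method <- "exact enumeration"
  } else {
    N <- m + n
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- m * n / 12 * ((N + 1) - tie_term)
    z <- (u_obs - m * n / 2 - 0.5) / sqrt(sigma2)
    p <- stats::pnorm(z, lower.tail = FALSE)
    method <- "normal approximation"
  }
  list(statistic = u_obs, p.value = p, method = method, direction = direction)
}

#' One-tailed sign test against a fixed threshold
#'
#' Exact binomial tail probability of observing at least the observed
#' number of values on the tested side of `threshold`, with success
#' probability 1/2 per observation.  Values exactly equal to the threshold
#' are dropped first; if all values tie, the test is undefined and an error
#' is raised.
#'
#' @param values numeric sample.
#' @param threshold reference value.
#' @param direction `"greater"` or `"less"`: the side being tested.
#' @return list with `statistic` (count on the tested side), `n` (non-tied
#'   sample size) and `p.value`.
#' @export
sign_test_one_tailed <- function(values, threshold,
                                 direction = c("greater", "less")) {
  direction <- match.arg(direction)
  stopifnot(all(is.finite(values)), is.finite(threshold))
  keep <- values != threshold
  if (!any(keep))
    stop("sign_test_one_tailed: all values tie the threshold")
  v <- values[keep]
  k <- if (direction == "greater") sum(v > threshold) else sum(v < threshold)
  n <- length(v)
  p <- stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE)
  list(statistic = k, n = n, p.value = p, direction = direction)
}
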