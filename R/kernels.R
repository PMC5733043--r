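#' Gamma-variate kernel with unit peak
#'
#' Evaluates the gamma-variate kernel
#' \deqn{k(\tau) = (\tau/t_p)^a \exp\{a (1 - \tau/t_p)\}}
#' which rises from zero at \eqn{\tau = 0}, attains its maximum of exactly 1 at
#' \eqn{\tau = t_p} for every shape \eqn{a > 0}, and decays with a tail whose
#' heaviness decreases as the shape grows.  It is the standard smooth, positive
#' kernel family for modelling evoked hemodynamic and scattering transients.
#'
#' @param tau times since response onset, in seconds; values `<= 0` map to 0.
#' @param peak_time time of the kernel maximum, seconds (`> 0`).
#' @param shape positive shape parameter; small values give heavy tails.
#' @return numeric vector of kernel values in `[0, 1]`.
#' @seealso [shape_for_half_recovery()] to pick the shape from a target
#'   half-recovery time.
#' @export
gamma_variate <- function(tau, peak_time, shape) {
  stopifnot(is.numeric(tau), length(peak_time) == 1L, length(shape) == 1L,
            is.finite(peak_time), is.finite(shape), peak_time > 0, shape > 0)
  k <- numeric(length(tau))
  pos <- which(tau > 0)
  x <- tau[pos] / peak_time
  k[pos] <- exp(shape * (log(x) + 1 - x))
  k
}

#' Half-recovery time of a gamma-variate kernel
#'
#' Time elapsed from the kernel peak until the kernel first falls to half of
#' its peak value, solved from the closed-form kernel by root finding.
#'
#' @inheritParams gamma_variate
#' @return half-recovery time in seconds (relative to the peak).
#' @export
kernel_half_recovery <- function(peak_time, shape) {
  stopifnot(peak_time > 0, shape > 0)
  # solve x > 1 with a (log x + 1 - x) = -log 2
  f <- function(x) shape * (log(x) + 1 - x) + log(2)
  upper <- 2
  while (f(upper) > 0) upper <- upper * 2
  x_half <- stats::uniroot(f, c(1 + 1e-12, upper), tol = 1e-12)$root
  peak_time * (x_half - 1)
}

#' Solve the kernel shape giving a requested half-recovery time
#'
#' Inverts [kernel_half_recovery()] in the shape parameter: the half-recovery
#' time is a strictly decreasing function of the shape, so for any positive
#' target a unique shape exists.
#'
#' @param peak_time kernel peak time, seconds.
#' @param t_half requested half-recovery time, seconds (`> 0`).
#' @return the shape parameter.
#' @export
shape_for_half_recovery <- function(peak_time, t_half) {
  stopifnot(peak_time > 0, is.finite(t_half), t_half > 0)
  g <- function(a) kernel_half_recovery(peak_time, a) - t_half
  lo <- 1e-4; hi <- 1e4
  if (g(lo) < 0) stop("requested half-recovery too long for this peak time")
  if (g(hi) > 0) stop("requested half-recovery too short for this peak time")
  stats::uniroot(g, c(lo, hi), tol = 1e-10)$root
}
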