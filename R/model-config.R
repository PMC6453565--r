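#' Model configuration for the closed-loop tracking controller
#'
#' Bundles all constants of the discrete-time optimal feedback control model:
#' the plant time step, the intrinsic (physiological) and extrinsic
#' (experimentally imposed) feedback delays, the process/measurement noise
#' ratio that shapes the state estimator, and the LQR weights that yield the
#' proportional-integral control law.
#'
#' The process noise is accelerative: white noise of standard deviation
#' `sigma_a` enters the velocity state, while the position measurement is
#' corrupted by white noise of standard deviation `sigma_eps`.  Only the
#' ratio `rho = sigma_a / sigma_eps` affects the estimator gains and all
#' closed-loop transfer functions; the absolute scales only set the units of
#' simulated traces.  By default `sigma_eps = 1` position unit (1 unit = 1%
#' of the task radius) and `sigma_a = rho * sigma_eps`.
#'
#' @param dt time step (s).
#' @param tau_int intrinsic feedback delay (s); rounded to an integer number
#'   of steps with `round(tau_int / dt)`.
#' @param tau_ext extrinsic feedback delay (s); same rounding rule.
#' @param rho ratio of accelerative process noise to position measurement
#'   noise (1/s^2).
#' @param sigma_eps measurement noise SD (position units).
#' @param sigma_a process noise SD (position units/s^2).  Defaults to
#'   `rho * sigma_eps`; if both `sigma_a` and `sigma_eps` are supplied they
#'   must satisfy `rho = sigma_a / sigma_eps`.
#' @param q LQR weight on squared position error.
#' @param r LQR weight on the squared rate of change of the motor command.
#' @param duration simulated time (s).
#' @param seed integer RNG seed used by the stochastic simulators.
#' @return an object of class `ofc_config` (a named list).
#' @examples
#' cfg <- ofc_config()
#' cfg$tau_int
#' @export
ofc_config <- function(dt = 0.01, tau_int = 0.26, tau_ext = 0, rho = 250,
                       sigma_eps = 1, sigma_a = rho * sigma_eps,
                       q = 1, r = dt^2, duration = 20, seed = 1L) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("invalid config: 'dt' must be a single positive number", call. = FALSE)
  if (tau_int < 0 || tau_ext < 0)
    stop("invalid config: delays must be non-negative", call. = FALSE)
  if (rho < 0) stop("invalid config: 'rho' must be >= 0", call. = FALSE)
  if (sigma_eps < 0 || sigma_a < 0)
    stop("invalid config: noise SDs must be >= 0", call. = FALSE)
  if (sigma_eps > 0 && abs(sigma_a / sigma_eps - rho) > 1e-8 * max(1, rho))
    stop("invalid config: 'rho' must equal sigma_a / sigma_eps", call. = FALSE)
  if (q < 0) stop("invalid config: 'q' must be >= 0", call. = FALSE)
  if (r <= 0) stop("invalid config: 'r' must be > 0", call. = FALSE)
  if (duration <= 0) stop("invalid config: 'duration' must be > 0", call. = FALSE)
  structure(list(
    dt = dt, tau_int = tau_int, tau_ext = tau_ext, rho = rho,
    sigma_eps = sigma_eps, sigma_a = sigma_a, q = q, r = r,
    duration = duration, seed = as.integer(seed)
  ), class = "ofc_config")
}

#' @export
print.ofc_config <- function(x, ...) {
  cat("Optimal feedback control model configuration\n")
  cat(sprintf("  dt = %g s   tau_int = %g s   tau_ext = %g s\n",
              x$dt, x$tau_int, x$tau_ext))
  cat(sprintf("  rho = %g 1/s^2  (sigma_a = %g, sigma_eps = %g)\n",
              x$rho, x$sigma_a, x$sigma_eps))
  cat(sprintf("  LQR weights q = %g, r = %g;  duration = %g s;  seed = %d\n",
              x$q, x$r, x$duration, x$seed))
  invisible(x)
}

#' Number of buffer samples for a delay
#'
#' Delays are discretized with round-to-nearest-sample, so the default
#' intrinsic delay of 0.26 s at dt = 0.01 s occupies exactly 26 samples.
#'
#' @param tau delay (s).
#' @param dt time step (s).
#' @return integer number of samples.
#' @export
delay_steps <- function(tau, dt) {
  if (tau < 0) stop("invalid config: delay must be >= 0", call. = FALSE)
  as.integer(round(tau / dt))
}

# deterministic fan-out of one user seed into per-stage child seeds,
# kept below .Machine$integer.max
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647)
}
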