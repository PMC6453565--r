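#' Transfer function of the PI controller inside the fast loop
#'
#' The PI controller with an undelayed internal model of the plant forms a
#' fast feedback loop whose transfer function is
#' \deqn{H_{PI}(i\omega) = \frac{K_P + K_I/(i\omega)}
#'                               {1 + K_P + K_I/(i\omega)},}
#' equal to 1 at \eqn{\omega = 0} (the removable singularity is evaluated
#' as its analytic limit) and tending to \eqn{K_P/(1+K_P)} at high
#' frequencies.  With `dt` supplied, the exact discrete-time counterpart
#' is evaluated at \eqn{z = e^{i\omega\Delta t}}, using the cumulative-sum
#' integrator of the simulated controller; the two agree closely below the
#' Nyquist frequency.
#'
#' @param freqs frequency grid (Hz).
#' @param gains a `pi_gains` object.
#' @param dt optional time step (s) for the discrete-time evaluation.
#' @return object of class `transfer_function`: list with `freqs`, complex
#'   `h`, and `kind = "pi-loop"`.
#' @export
transfer_h_pi <- function(freqs, gains, dt = NULL) {
  w <- 2 * pi * freqs
  kp <- gains$k_p; ki <- gains$k_i
  if (kp == 0 && ki == 0) {
    h <- rep(0 + 0i, length(w))
  } else if (is.null(dt)) {
    # multiply through by iw so w = 0 needs no special case when ki > 0
    num <- kp * 1i * w + ki
    den <- (1 + kp) * 1i * w + ki
    h <- num / den
    if (ki == 0) h[] <- kp / (1 + kp)
    h[w == 0 & ki > 0] <- 1 + 0i
  } else {
    zi <- exp(1i * w * dt)
    num <- kp * (zi - 1) + ki * dt * zi
    den <- (1 + kp) * (zi - 1) + ki * dt * zi
    h <- num / den
    if (ki == 0) h[] <- kp / (1 + kp)
    h[w == 0 & ki > 0] <- 1 + 0i
  }
  structure(list(freqs = freqs, h = h, kind = "pi-loop"),
            class = "transfer_function")
}

#' Transfer functions of the steady-state Kalman estimator
#'
#' Exact discrete-time responses of the constant-gain estimator evaluated
#' at \eqn{z = e^{i\omega\Delta t}}: from the measurement to the position
#' estimate (`kind = "position"`), the velocity estimate
#' (`kind = "velocity"`), or the forward-projected position estimate
#' (`kind = "projected"`, which composes the projection
#' `z = x_hat + tau_int * v_hat`).
#'
#' @param freqs frequency grid (Hz).
#' @param gains a `kalman_gains` object.
#' @param dt time step (s).
#' @param tau_int intrinsic delay used by the projection (s).
#' @param kind which response to return.
#' @return `transfer_function` object with `kind` one of
#'   `"kalman-position"`, `"kalman-velocity"`, `"kalman-projected"`.
#' @export
transfer_kalman <- function(freqs, gains, dt, tau_int = 0.26,
                            kind = c("position", "velocity", "projected")) {
  kind <- match.arg(kind)
  w <- 2 * pi * freqs
  zi <- exp(1i * w * dt)
  kpos <- gains$k_pos; kvel <- gains$k_vel
  det <- (zi - 1 + kpos) * (zi - 1) + dt * kvel
  hx <- ((zi - 1) * kpos + dt * kvel) / det
  hv <- kvel * (zi - 1) / det
  h <- switch(kind,
              position = hx,
              velocity = hv,
              projected = hx + tau_int * hv)
  structure(list(freqs = freqs, h = h,
                 kind = paste0("kalman-", kind)),
            class = "transfer_function")
}

#' Closed-loop force and cursor transfer functions
#'
#' The intrinsic dynamics (fast-loop PI controller composed with the
#' projected Kalman estimate) delayed by the total loop delay give the
#' force response
#' \deqn{H_{force}(i\omega) = e^{-i\omega(\tau_{int}+\tau_{ext})}
#'       H_{PI}(i\omega)\, H_{y\to\hat{z}}(i\omega),}
#' and the cursor response is its complement,
#' \eqn{H_{cursor} = 1 - H_{force}}: the displayed cursor combines the
#' original error with the delayed correction, producing comb-filter
#' structure with constructive-interference peaks at odd multiples of
#' \eqn{1/(2(\tau_{int}+\tau_{ext}))}.
#'
#' The delay factor uses the discretized delay (`round(tau/dt)` samples)
#' so that analytic responses match the simulation loop exactly.
#'
#' @param freqs frequency grid (Hz).
#' @param config an [ofc_config()].
#' @return list with elements `force` and `cursor`, both
#'   `transfer_function` objects.
#' @examples
#' tf <- closed_loop_transfer(seq(0.1, 5, by = 0.1), ofc_config())
#' max(Mod(tf$cursor$h))
#' @export
closed_loop_transfer <- function(freqs, config) {
  stopifnot(inherits(config, "ofc_config"))
  dt <- config$dt
  kg <- design_kalman_gains(dt, config$rho)
  pg <- design_pi_gains(dt, config$q, config$r)
  d_tot <- delay_steps(config$tau_int, dt) + delay_steps(config$tau_ext, dt)
  w <- 2 * pi * freqs
  h_pi <- transfer_h_pi(freqs, pg, dt = dt)$h
  h_z <- transfer_kalman(freqs, kg, dt, config$tau_int, "projected")$h
  h_force <- exp(-1i * w * d_tot * dt) * h_pi * h_z
  list(
    force = structure(list(freqs = freqs, h = h_force, kind = "force"),
                      class = "transfer_function"),
    cursor = structure(list(freqs = freqs, h = 1 - h_force, kind = "cursor"),
                       class = "transfer_function")
  )
}

#' Imaginary cross-spectrum between position and velocity estimates
#'
#' Under broadband measurement input the position and velocity estimates
#' are out of phase, so their cross-spectral density has an imaginary
#' component \eqn{\mathrm{Im}[H_{y\to\hat{x}}\overline{H_{y\to\hat{v}}}]}
#' with a single low-frequency resonance set by the estimator dynamics
#' (between 2 and 3 Hz for the default noise ratio of 250).  The
#' extrinsic feedback delay never enters this quantity.
#'
#' @param freqs frequency grid (Hz).
#' @param gains a `kalman_gains` object.
#' @param dt time step (s).
#' @return numeric vector of imaginary cross-spectral values on `freqs`.
#' @export
kalman_cross_spectrum <- function(freqs, gains, dt) {
  hx <- transfer_kalman(freqs, gains, dt, kind = "position")$h
  hv <- transfer_kalman(freqs, gains, dt, kind = "velocity")$h
  Im(hx * Conj(hv))
}

#' @export
print.transfer_function <- function(x, ...) {
  cat(sprintf("Transfer function (%s): %d frequencies in [%g, %g] Hz\n",
              x$kind, length(x$freqs), min(x$freqs), max(x$freqs)))
  invisible(x)
}
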