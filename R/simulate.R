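#' Simulate closed-loop tracking with the Smith-Predictor controller
#'
#' Runs the full discrete-time loop.  White accelerative noise drives a
#' double integrator (the stochastic motor error); the motor command maps
#' one-to-one onto position, so the force output is
#' `cursor = u + integrated noise`.  The measurement is the displayed
#' position delayed by the total loop delay (intrinsic + extrinsic) plus
#' white measurement noise.  A Smith Predictor subtracts an equally delayed
#' internal copy of the motor command from the measurement, so the
#' estimator tracks only the noise-driven error.  The steady-state Kalman
#' estimate is projected forward over the intrinsic delay and fed to the
#' PI controller, whose internal (undelayed) model of the command closes
#' the fast feedback loop: the command solves
#' `u = -k_p (z + u) - k_i * integral(z + u)` algebraically at each step.
#'
#' An optional perturbation series is added to the displayed cursor (it
#' enters the measurement after the intrinsic delay and the displayed
#' output, but not the plant state), mirroring a visual displacement of
#' the cursor.
#'
#' All per-step quantities are returned, including the estimator increments
#' `d_xhat`, `d_vhat` used as the synaptic-input proxy for simulated field
#' potentials.
#'
#' @param config an [ofc_config()].
#' @param pert optional numeric perturbation series (position units), one
#'   value per step; recycled with zeros if shorter than the simulation.
#' @return object of class `sim_trace`: list of aligned numeric series
#'   `t`, `a`, `x`, `y`, `y_smith`, `u`, `cursor`, `x_hat`, `v_hat`, `z`,
#'   `d_xhat`, `d_vhat`, plus `fs`, `config`, and `pert`.
#' @examples
#' tr <- simulate_tracking(ofc_config(duration = 5, seed = 2))
#' sd(tr$cursor)
#' @export
simulate_tracking <- function(config, pert = NULL) {
  stopifnot(inherits(config, "ofc_config"))
  dt <- config$dt
  n <- as.integer(round(config$duration / dt))
  d_int <- delay_steps(config$tau_int, dt)
  d_ext <- delay_steps(config$tau_ext, dt)
  d_tot <- d_int + d_ext
  if (n < d_tot)
    stop("invalid config: duration shorter than one loop delay", call. = FALSE)
  kg <- design_kalman_gains(dt, config$rho)
  pg <- design_pi_gains(dt, config$q, config$r)

  p <- numeric(n)
  if (!is.null(pert)) p[seq_len(min(n, length(pert)))] <- pert[seq_len(min(n, length(pert)))]

  set.seed(config$seed)
  a <- stats::rnorm(n, 0, config$sigma_a)
  eps <- stats::rnorm(n, 0, config$sigma_eps)

  nx <- numeric(n); nv <- numeric(n)          # noise double integrator
  u <- numeric(n); cursor <- numeric(n)
  y <- numeric(n); ys <- numeric(n)
  xh <- numeric(n); vh <- numeric(n); z <- numeric(n)
  dxh <- numeric(n); dvh <- numeric(n)

  kpos <- kg$k_pos; kvel <- kg$k_vel
  kp <- pg$k_p; ki <- pg$k_i
  tau_proj <- config$tau_int
  fast_den <- 1 + kp + ki * dt                 # algebraic fast-loop solution
  integ <- 0
  nx_p <- 0; nv_p <- 0; xh_p <- 0; vh_p <- 0

  for (k in seq_len(n)) {
    # plant: double-integrated accelerative noise
    nx_k <- nx_p + dt * nv_p
    nv_k <- nv_p + dt * a[k]
    # estimator driven by the previous Smith-corrected measurement
    yprev <- if (k > 1) ys[k - 1] else 0
    dx <- -kpos * xh_p + dt * vh_p + kpos * yprev
    dv <- -kvel * xh_p + kvel * yprev
    xh_k <- xh_p + dx
    vh_k <- vh_p + dv
    zk <- xh_k + tau_proj * vh_k
    # PI controller on (z + u): fast internal loop solved algebraically
    uk <- -((kp + ki * dt) * zk + ki * integ) / fast_den
    integ <- integ + (zk + uk) * dt
    # force output; the display shows it delayed by the extrinsic delay,
    # plus the perturbation, and is itself seen after the intrinsic delay
    ck <- uk + nx_k
    yk <- (if (k > d_tot) cursor[k - d_tot] else 0) +
      (if (k > d_int) p[k - d_int] else 0) + eps[k]
    ysk <- yk - (if (k > d_tot) u[k - d_tot] else 0)

    nx[k] <- nx_k; nv[k] <- nv_k
    xh[k] <- xh_k; vh[k] <- vh_k; z[k] <- zk
    dxh[k] <- dx; dvh[k] <- dv
    u[k] <- uk; cursor[k] <- ck
    y[k] <- yk; ys[k] <- ysk
    nx_p <- nx_k; nv_p <- nv_k; xh_p <- xh_k; vh_p <- vh_k
  }

  structure(list(
    t = (seq_len(n) - 1) * dt, a = a, x = cursor, y = y, y_smith = ys,
    u = u, cursor = cursor, x_hat = xh, v_hat = vh, z = z,
    d_xhat = dxh, d_vhat = dvh, fs = 1 / dt, config = config,
    pert = if (is.null(pert)) NULL else p
  ), class = "sim_trace")
}

#' @export
print.sim_trace <- function(x, ...) {
  cat(sprintf("Closed-loop tracking simulation: %d steps at %g samples/s (%.4g s)\n",
              length(x$t), x$fs, length(x$t) / x$fs))
  cat(sprintf("  tau_int = %g s, tau_ext = %g s, rho = %g\n",
              x$config$tau_int, x$config$tau_ext, x$config$rho))
  invisible(x)
}

#' @export
as.data.frame.sim_trace <- function(x, ...) {
  cols <- c("t", "a", "x", "y", "y_smith", "u", "cursor",
            "x_hat", "v_hat", "z", "d_xhat", "d_vhat")
  out <- as.data.frame(x[cols])
  if (!is.null(x$pert)) out$pert <- x$pert
  out
}

#' Impulse excitation of the disconnected state estimator
#'
#' Runs the state estimator with motor and sensory connections to the
#' world severed: no command is applied and the measurement input is
#' replaced by a rectangular pulse drive.  Transient excitation of the
#' estimator elicits its intrinsic impulse response, the model's analogue
#' of the burst of delta-band oscillation around a cortical K-complex.
#'
#' @param config an [ofc_config()]; only `dt`, `rho`, `tau_int` and
#'   `duration` are used.
#' @param pulse list with `time` (pulse onset, s), `amplitude`
#'   (position units), and `width` (s; a width of one `dt` gives a single
#'   -sample impulse).
#' @return object of class `sim_trace` with the estimator series and the
#'   per-step synaptic inputs; `u` and plant series are identically zero.
#' @export
simulate_kcomplex <- function(config,
                              pulse = list(time = 1, amplitude = 1,
                                           width = config$dt)) {
  stopifnot(inherits(config, "ofc_config"))
  dt <- config$dt
  n <- as.integer(round(config$duration / dt))
  kg <- design_kalman_gains(dt, config$rho)
  drive <- numeric(n)
  t <- (seq_len(n) - 1) * dt
  on <- t >= pulse$time & t < pulse$time + pulse$width
  drive[on] <- pulse$amplitude

  xh <- numeric(n); vh <- numeric(n)
  dxh <- numeric(n); dvh <- numeric(n)
  kpos <- kg$k_pos; kvel <- kg$k_vel
  xh_p <- 0; vh_p <- 0
  for (k in seq_len(n)) {
    yprev <- if (k > 1) drive[k - 1] else 0
    dx <- -kpos * xh_p + dt * vh_p + kpos * yprev
    dv <- -kvel * xh_p + kvel * yprev
    xh_p <- xh_p + dx
    vh_p <- vh_p + dv
    xh[k] <- xh_p; vh[k] <- vh_p
    dxh[k] <- dx; dvh[k] <- dv
  }
  zero <- numeric(n)
  structure(list(
    t = t, a = zero, x = zero, y = drive, y_smith = drive, u = zero,
    cursor = zero, x_hat = xh, v_hat = vh,
    z = xh + config$tau_int * vh, d_xhat = dxh, d_vhat = dvh,
    fs = 1 / dt, config = config, pert = NULL
  ), class = "sim_trace")
}
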