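#' Steady-state Kalman innovation gains for the tracking plant
#'
#' Solves the discrete-time steady-state Kalman filtering problem for the
#' constant-velocity plant
#' \deqn{x_k = x_{k-1} + \Delta t\, v_{k-1}, \qquad
#'       v_k = v_{k-1} + \Delta t\, a_k,}
#' with accelerative process noise \eqn{a_k \sim N(0, \sigma_a^2)} and a
#' position-only measurement \eqn{y_k = x_k + \epsilon_k},
#' \eqn{\epsilon_k \sim N(0, \sigma_\epsilon^2)}.  The estimator is written
#' in one-step-predictor form,
#' \deqn{\hat{x}_k = (1 - K_{pos})\hat{x}_{k-1} + \Delta t\, \hat{v}_{k-1}
#'       + K_{pos} y_{k-1}, \qquad
#'       \hat{v}_k = -K_{vel}\hat{x}_{k-1} + \hat{v}_{k-1} + K_{vel} y_{k-1},}
#' whose innovation gains depend only on the noise ratio
#' `rho = sigma_a / sigma_eps` and on `dt`.
#'
#' The gains are the fixed point of the predict-update covariance recursion
#' (the discrete algebraic Riccati equation), iterated from the identity
#' covariance until the largest entry changes by less than `tol`.
#'
#' @param dt time step (s).
#' @param rho process-to-measurement noise ratio (1/s^2).
#' @param tol convergence tolerance on the covariance fixed point.
#' @param max_iter iteration cap before a numerical error is raised.
#' @return an object of class `kalman_gains`: list with elements `k_pos`
#'   (dimensionless) and `k_vel` (1/s, as applied per step to a position
#'   innovation), plus the converged prediction covariance `p` and the
#'   estimator state-update matrix `f`.
#' @examples
#' g <- design_kalman_gains(0.01, 250)
#' c(g$k_pos, g$k_vel)
#' @export
design_kalman_gains <- function(dt, rho, tol = 1e-14, max_iter = 1e6) {
  if (!is.finite(dt) || dt <= 0)
    stop("invalid config: 'dt' must be positive", call. = FALSE)
  if (!is.finite(rho) || rho < 0)
    stop("invalid config: 'rho' must be >= 0", call. = FALSE)
  a <- matrix(c(1, 0, dt, 1), 2, 2)       # state transition
  cvec <- c(1, 0)                          # position measurement
  qm <- diag(c(0, (rho * dt)^2))           # process noise covariance (unit sigma_eps)
  rm <- 1                                  # measurement noise variance
  p <- diag(2)                             # a-priori covariance, iterated to the DARE fixed point
  for (i in seq_len(max_iter)) {
    s <- drop(cvec %*% p %*% cvec) + rm
    k <- (p %*% cvec) / s                  # filter gain
    pu <- p - k %*% t(cvec) %*% p          # measurement update
    pn <- a %*% pu %*% t(a) + qm           # time update
    if (max(abs(pn - p)) < tol) { p <- pn; break }
    p <- pn
    if (i == max_iter)
      stop("numerical error: Riccati iteration did not converge (dt=", dt,
           ", rho=", rho, ")", call. = FALSE)
  }
  s <- drop(cvec %*% p %*% cvec) + rm
  l <- drop(a %*% p %*% cvec) / s          # predictor-form innovation gains
  gains <- list(k_pos = l[1], k_vel = l[2], p = p,
                f = estimator_matrix(l[1], l[2], dt))
  class(gains) <- "kalman_gains"
  gains
}

# estimator state-update matrix [[1 - k_pos, dt], [-k_vel, 1]]
estimator_matrix <- function(k_pos, k_vel, dt) {
  matrix(c(1 - k_pos, -k_vel, dt, 1), 2, 2)
}

#' @export
print.kalman_gains <- function(x, ...) {
  cat(sprintf("Steady-state Kalman innovation gains: k_pos = %.6g, k_vel = %.6g /s\n",
              x$k_pos, x$k_vel))
  invisible(x)
}

#' Proportional-integral gains from the infinite-horizon LQR
#'
#' The controller penalises squared position error and the squared rate of
#' change of the motor command,
#' \deqn{J = \sum_k \left( q x_k^2 + r (\Delta u_k / \Delta t)^2 \right),}
#' for the double-integrator transition
#' \eqn{[x_k; v_k] = [[1, \Delta t], [0, 1]][x_{k-1}; v_{k-1}] + [0; 1] w_k}
#' with control \eqn{w_k = \Delta u_k / \Delta t}.  The optimal state
#' feedback \eqn{w_k = -[K_I\; K_P][x_k; v_k]} integrates to a PI law on
#' position, \eqn{u_k = -K_P x_k - K_I \sum_j x_j \Delta t}.
#'
#' The stabilising solution is found by value-iterating the control Riccati
#' recursion to a fixed point.
#'
#' @param dt time step (s).
#' @param q state (position) cost weight; `q = 0` gives zero gains.
#' @param r control-rate cost weight (> 0).
#' @param tol fixed-point tolerance.
#' @param max_iter iteration cap.
#' @return object of class `pi_gains`: list with `k_p` (dimensionless
#'   proportional gain) and `k_i` (integral gain, 1/s).
#' @examples
#' design_pi_gains(0.01, q = 1, r = 0.01^2)
#' @export
design_pi_gains <- function(dt, q = 1, r = dt^2, tol = 1e-14, max_iter = 1e6) {
  if (!is.finite(r) || r <= 0)
    stop("invalid config: 'r' must be > 0", call. = FALSE)
  if (!is.finite(q) || q < 0)
    stop("invalid config: 'q' must be >= 0", call. = FALSE)
  if (q == 0) {
    out <- list(k_p = 0, k_i = 0)
    class(out) <- "pi_gains"
    return(out)
  }
  a <- matrix(c(1, 0, dt, 1), 2, 2)
  b <- c(0, 1)
  qc <- diag(c(q, 0))
  s <- qc
  for (i in seq_len(max_iter)) {
    sb <- s %*% b
    denom <- drop(crossprod(b, sb)) + r
    k <- drop(crossprod(b, s %*% a)) / denom
    sn <- t(a) %*% s %*% a - (t(a) %*% sb) %*% t(k) + qc
    sn <- (sn + t(sn)) / 2
    if (max(abs(sn - s)) < tol) { s <- sn; break }
    s <- sn
    if (i == max_iter)
      stop("numerical error: LQR Riccati iteration did not converge", call. = FALSE)
  }
  sb <- s %*% b
  k <- drop(crossprod(b, s %*% a)) / (drop(crossprod(b, sb)) + r)
  out <- list(k_i = k[1], k_p = k[2])
  class(out) <- "pi_gains"
  out
}

#' @export
print.pi_gains <- function(x, ...) {
  cat(sprintf("LQR-derived PI gains: k_p = %.6g, k_i = %.6g /s\n", x$k_p, x$k_i))
  invisible(x)
}
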