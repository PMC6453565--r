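# Independent oracles used across the suite.  These deliberately
# re-derive results through different formulations than the package code.

# steady-state Kalman predictor gains by explicit predict/update value
# iteration with a Joseph-form measurement update, started from zero
kalman_gain_oracle <- function(dt, rho, iters = 200000, tol = 1e-13) {
  a <- matrix(c(1, 0, dt, 1), 2, 2)
  cvec <- matrix(c(1, 0), 1, 2)
  qm <- diag(c(0, (rho * dt)^2))
  rv <- 1
  p <- matrix(0, 2, 2)
  for (i in seq_len(iters)) {
    s <- drop(cvec %*% p %*% t(cvec)) + rv
    k <- p %*% t(cvec) / s
    ikc <- diag(2) - k %*% cvec
    pu <- ikc %*% p %*% t(ikc) + k %*% t(k) * rv       # Joseph form
    pn <- a %*% pu %*% t(a) + qm
    if (max(abs(pn - p)) < tol) { p <- pn; break }
    p <- pn
  }
  s <- drop(cvec %*% p %*% t(cvec)) + rv
  drop(a %*% p %*% t(cvec)) / s
}

# infinite-horizon LQR gain by backward value iteration on the cost-to-go
lqr_gain_oracle <- function(dt, q, r, iters = 200000, tol = 1e-13) {
  a <- matrix(c(1, 0, dt, 1), 2, 2)
  b <- matrix(c(0, 1), 2, 1)
  qc <- diag(c(q, 0))
  s <- matrix(0, 2, 2)
  k <- c(0, 0)
  for (i in seq_len(iters)) {
    den <- drop(t(b) %*% s %*% b) + r
    kn <- drop(t(b) %*% s %*% a) / den
    sn <- qc + t(a - b %*% t(kn)) %*% s %*% (a - b %*% t(kn)) +
      kn %*% t(kn) * r
    sn <- (sn + t(sn)) / 2
    if (max(abs(sn - s)) < tol) { k <- kn; break }
    s <- sn
    k <- kn
  }
  k   # (gain on x, gain on v)
}

# feedforward comb rearrangement of the Smith-Predictor loop: the
# estimator/controller chain is driven open-loop by the delayed noise
# position, and the force output is added back to the noise
feedforward_sim_oracle <- function(config, pert = NULL) {
  dt <- config$dt
  n <- as.integer(round(config$duration / dt))
  d_int <- delay_steps(config$tau_int, dt)
  d_tot <- d_int + delay_steps(config$tau_ext, dt)
  kg <- design_kalman_gains(dt, config$rho)
  pg <- design_pi_gains(dt, config$q, config$r)
  p <- numeric(n)
  if (!is.null(pert)) p[seq_len(min(n, length(pert)))] <-
      pert[seq_len(min(n, length(pert)))]
  set.seed(config$seed)
  a <- rnorm(n, 0, config$sigma_a)
  eps <- rnorm(n, 0, config$sigma_eps)
  nv <- cumsum(dt * a)                       # velocity after step k
  nv_prev <- c(0, nv[-n])
  nx <- cumsum(dt * nv_prev)
  lagged <- function(x, d) c(rep(0, d), x)[1:n]
  ys <- lagged(nx, d_tot) + lagged(p, d_int) + eps
  # open-loop estimator -> projection -> fast-loop PI
  kpos <- kg$k_pos; kvel <- kg$k_vel
  kp <- pg$k_p; ki <- pg$k_i
  fast_den <- 1 + kp + ki * dt
  u <- numeric(n)
  xh <- 0; vh <- 0; integ <- 0
  for (k in seq_len(n)) {
    yprev <- if (k > 1) ys[k - 1] else 0
    dx <- -kpos * xh + dt * vh + kpos * yprev
    dv <- -kvel * xh + kvel * yprev
    xh <- xh + dx; vh <- vh + dv
    zk <- xh + config$tau_int * vh
    uk <- -((kp + ki * dt) * zk + ki * integ) / fast_den
    integ <- integ + (zk + uk) * dt
    u[k] <- uk
  }
  list(cursor = u + nx, u = u, nx = nx, ys = ys)
}

# batch matrix-form estimator recursion
estimator_matrix_oracle <- function(ys, gains, dt) {
  f <- matrix(c(1 - gains$k_pos, -gains$k_vel, dt, 1), 2, 2)
  l <- c(gains$k_pos, gains$k_vel)
  n <- length(ys)
  out <- matrix(0, 2, n)
  state <- c(0, 0)
  for (k in seq_len(n)) {
    yprev <- if (k > 1) ys[k - 1] else 0
    state <- drop(f %*% state) + l * yprev
    out[, k] <- state
  }
  out
}

# empirical transfer function between two series by Welch cross/auto ratio
fft_transfer_oracle <- function(x, y, fs, nfft = 4096) {
  n <- length(x)
  hop <- nfft %/% 2
  starts <- seq(1, n - nfft + 1, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nfft - 1) / (nfft - 1))
  sxy <- 0; sxx <- 0
  for (s in starts) {
    fx <- stats::fft((x[s:(s + nfft - 1)] - mean(x[s:(s + nfft - 1)])) * w)
    fy <- stats::fft((y[s:(s + nfft - 1)] - mean(y[s:(s + nfft - 1)])) * w)
    sxy <- sxy + fy * Conj(fx)
    sxx <- sxx + Mod(fx)^2
  }
  half <- nfft %/% 2
  list(freqs = (1:half) * fs / nfft, h = (sxy / sxx)[2:(half + 1)])
}

small_task_cfg <- function(trial_duration = 20) {
  task_config(trial_duration = trial_duration)
}
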