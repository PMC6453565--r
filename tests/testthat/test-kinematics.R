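test_that("velocity spectra put a bin-centered sinusoid in its bin", {
  fs <- 50
  n <- 250 + 512
  t <- (0:(n - 1)) / fs
  f0 <- 20 * fs / 512              # exact bin frequency
  x <- sin(2 * pi * f0 * t)
  sp <- velocity_power_spectrum(x, fs)
  expect_equal(sp$freqs[which.max(sp$power)], f0)
  expect_gt(sp$power[which.max(sp$power)] / sum(sp$power), 0.99)
})

test_that("velocity spectra satisfy Parseval's identity", {
  set.seed(8)
  fs <- 50
  x <- rnorm(250 + 1024)          # two windows after the 5 s offset
  sp <- velocity_power_spectrum(x, fs, demean = FALSE)
  w1 <- x[251:762]; w2 <- x[763:1274]
  # the DC bin is excluded, so the spectrum integrates to the variance
  # about each window mean
  expect_equal(sum(sp$power) * fs / 512,
               mean(c(mean(w1^2) - mean(w1)^2, mean(w2^2) - mean(w2)^2)),
               tolerance = 1e-10)
  expect_error(velocity_power_spectrum(rnorm(100), fs), "windowing error")
})

test_that("spectral peaks are recovered at constructed locations", {
  freqs <- (1:256) * 50 / 512
  power <- rep(0.1, 256)
  power[60] <- 2        # 5.86 Hz
  power[20] <- 1.5      # 1.95 Hz
  spec <- structure(list(freqs = freqs, power = power,
                         meta = list(fs = 50)), class = "velocity_spectrum")
  pk <- find_spectral_peaks(spec, band = c(0.5, 6))
  expect_equal(pk$freq, freqs[c(20, 60)])
  # plateau resolves to its first bin
  power2 <- rep(0.1, 256); power2[30:33] <- 1
  spec$power <- power2
  pk2 <- find_spectral_peaks(spec, band = c(0.5, 6), refine_bins = 0)
  expect_equal(pk2$freq, freqs[30])
  expect_error(find_spectral_peaks(spec, band = c(3, 3)), "empty band")
})

test_that("comb frequencies, their inversion, and the regression agree", {
  expect_equal(eq_comb_frequency(1, 0.26, 0), 1 / 0.52)
  expect_equal(eq_comb_frequency(3, 0.26, 0.2), 3 / 0.92)
  expect_error(eq_comb_frequency(2, 0.26), "odd")
  expect_error(eq_comb_frequency(1, 0, 0), "delay")

  # round trip
  for (N in c(1, 3, 5)) {
    f <- eq_comb_frequency(N, 0.26, 0.3)
    expect_equal(eq_comb_tau_int(1 / f, N, 0.3), 0.26, tolerance = 1e-12)
  }
  expect_equal(eq_comb_tau_int(0.589, 1, 0), 0.2945)
  expect_equal(eq_comb_tau_int(0.226, 3, 0), 0.339)
  expect_equal(eq_comb_tau_int(0.4, 1, 0.2), 0)
  expect_warning(eq_comb_tau_int(0.1, 1, 0.2), "unphysical")
})

test_that("period-versus-delay regression matches the normal equations", {
  delays <- c(0, 0.1, 0.2, 0.3, 0.4)
  pts <- data.frame(tau_ext = delays,
                    period = 1 / eq_comb_frequency(3, 0.26, delays))
  reg <- suppressWarnings(regress_period_vs_delay(pts, N = 3))
  expect_equal(reg$slope, 2 / 3, tolerance = 1e-12)
  expect_equal(reg$r2, 1)
  expect_equal(reg$tau_int_est, 0.26, tolerance = 1e-12)

  set.seed(3)
  pts$period <- pts$period + rnorm(5, 0, 0.02)
  reg <- regress_period_vs_delay(pts, N = 3)
  x <- cbind(1, pts$tau_ext)
  beta <- solve(t(x) %*% x, t(x) %*% pts$period)
  expect_equal(c(reg$intercept, reg$slope), drop(beta), tolerance = 1e-12)
  expect_error(regress_period_vs_delay(data.frame(tau_ext = c(0, 0),
                                                  period = c(1, 1)), 1),
               "degenerate")
})

make_pert_trial <- function(f_pert, tau_ext, amp = 1, fs = 50,
                            duration = 20, direction = "ccw") {
  cfg <- task_config()
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  wt <- 2 * pi * cfg$f_target
  wp <- 2 * pi * f_pert
  s <- if (direction == "ccw") 1 else -1
  theta_f <- s * wt * t
  force <- 100 * cbind(cos(theta_f), sin(theta_f))
  # cursor carries the full perturbation (amp = 1 reproduces it exactly)
  theta_c <- s * (wt * t + amp * wt / wp * sin(wp * t))
  cursor <- 100 * cbind(cos(theta_c), sin(theta_c))
  structure(list(condition = list(tau_ext = tau_ext, f_pert = f_pert,
                                  direction = direction),
                 t = t, target_xy = target_trajectory(t, cfg, direction),
                 cursor_xy = cursor, force_xy = force,
                 theta_force = theta_f,
                 theta_cursor = theta_c, fs = fs),
            class = "trial_recording")
}

test_that("transfer estimation normalizes a pure perturbation to unity", {
  cfg <- task_config()
  tr <- make_pert_trial(f_pert = 2, tau_ext = 0)
  est <- estimate_transfer(list(tr), cfg)
  expect_equal(Mod(est$h_cursor), 1, tolerance = 0.02)
  expect_lt(abs(Arg(est$h_cursor)), 0.05)
  # a force that never responds gives a null force transfer
  expect_lt(Mod(est$h_force), 0.02)
  # direction handling: a clockwise trial gives the same estimate
  est_cw <- estimate_transfer(list(make_pert_trial(2, 0, direction = "cw")),
                              cfg)
  expect_equal(Mod(est_cw$h_cursor), Mod(est$h_cursor), tolerance = 0.02)
  expect_error(estimate_transfer(list(tr), cfg, start_s = 15), "window")
})

test_that("intrinsic phase delay recovers a pure loop delay", {
  for (tau_ext in c(0, 0.2)) {
    w <- 2 * pi * 1
    h <- exp(-1i * w * (0.26 + tau_ext))
    expect_equal(intrinsic_phase_delay(h, 1, tau_ext), 0.26,
                 tolerance = 1e-12)
  }
  expect_error(intrinsic_phase_delay(0 + 0i, 1, 0), "undefined phase")
})

test_that("simulated perturbation responses match the analytic transfer", {
  cfg <- task_config()
  mc <- ofc_config()
  ses <- generate_human_session(cfg, mc, "exp2", seed = 12)
  for (cell in list(c(2, 0), c(1, 0.2))) {
    idx <- which(ses$schedule$f_pert == cell[1] &
                 ses$schedule$tau_ext == cell[2])
    est <- estimate_transfer(ses$trials[idx], cfg)
    tf <- closed_loop_transfer(cell[1], ofc_config(tau_ext = cell[2]))
    expect_equal(Mod(est$h_cursor), Mod(tf$cursor$h), tolerance = 0.15)
    expect_equal(Mod(est$h_force), Mod(tf$force$h), tolerance = 0.15)
    # complementarity of the measured responses
    expect_lt(Mod(est$h_cursor + est$h_force - 1), 0.3)
  }
})
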