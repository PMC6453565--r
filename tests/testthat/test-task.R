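cfg <- task_config()

test_that("target follows the circle at the configured rate", {
  expect_equal(target_trajectory(0, cfg)[1, ], c(x = 100, y = 0))
  quarter <- 1 / (4 * cfg$f_target)
  expect_equal(target_trajectory(quarter, cfg, "ccw")[1, ],
               c(x = 0, y = 100), tolerance = 1e-9)
  t <- seq(0, 10, by = 0.02)
  for (s in c(ccw = 1, cw = -1)) {
    dir <- if (s > 0) "ccw" else "cw"
    w <- angular_velocity(target_trajectory(t, cfg, dir), fs = 50)
    expect_equal(w[5:(length(w) - 5)],
                 rep(s * 2 * pi * 0.2, length(w) - 9), tolerance = 1e-6)
  }
})

test_that("perturbation offsets vanish at t = 0 and scale to the target velocity", {
  expect_equal(perturbation_offset(0, 2, cfg)[1, ], c(x = 0, y = 0))
  t <- seq(0, 10, by = 1 / 500)
  for (fp in c(1, 3, 5)) {
    pert_pos <- target_trajectory(t, cfg) + perturbation_offset(t, fp, cfg)
    w <- angular_velocity(pert_pos, fs = 500)
    added <- w[10:(length(w) - 10)] - 2 * pi * 0.2
    # added angular velocity is ~ w_target * cos(w_pert t), peak w_target
    expect_equal(max(abs(added)), 2 * pi * 0.2, tolerance = 1e-3)
  }
  # maximum offset magnitude against a dense-grid chord-length oracle
  off <- perturbation_offset(t, 2, cfg)
  r <- sqrt(rowSums(off^2))
  beta <- (0.2 / 2) * sin(2 * pi * 2 * t)     # angular deviation (rad)
  oracle <- max(2 * 100 * abs(sin(beta / 2)))
  expect_equal(max(r), oracle, tolerance = 1e-9)
})

test_that("cursor composition applies delay and perturbation correctly", {
  t <- seq(0, 4 - 0.02, by = 0.02)
  force <- target_trajectory(t, cfg)
  expect_equal(compose_cursor(force, NULL, 0, 50), force)
  shifted <- compose_cursor(force, NULL, 0.2, 50)
  expect_equal(shifted[11:200, ], force[1:190, ])
  expect_equal(shifted[1:10, ], force[rep(1, 10), ])   # zero-order history
  off <- perturbation_offset(t, 2, cfg)
  expect_equal(compose_cursor(force, off, 0.2, 50), shifted + off)
  expect_error(compose_cursor(force, NULL, -0.1, 50), "invalid config")
})

test_that("angular velocity unwraps and matches a spectral derivative", {
  t <- seq(0, 20 - 0.02, by = 0.02)
  theta <- 2 * pi * 0.2 * t + 0.3 * sin(2 * pi * 1.5 * t)
  xy <- cbind(cos(theta), sin(theta))
  w <- angular_velocity(xy, 50)
  expect_lt(max(abs(diff(w))) * 50, 50)   # no 2 pi jumps (would be ~300)
  # spectral derivative oracle on the periodic deviation
  n <- length(t)
  dev <- theta - 2 * pi * 0.2 * t
  freqs <- c(0:(n / 2), -(n / 2 - 1):-1) / n * 50
  ddev <- Re(fft(fft(dev) * 2i * pi * freqs, inverse = TRUE) / n)
  expect_equal(w[10:(n - 10)], (2 * pi * 0.2 + ddev)[10:(n - 10)],
               tolerance = 1e-2)
  expect_error(angular_velocity(cbind(c(1, 0, 1), c(0, 0, 1)), 50),
               "undefined angle")
})

test_that("trial score follows its closed forms in both variants", {
  t <- seq(0, 2, by = 0.02)
  target <- target_trajectory(t, cfg)
  expect_equal(score_trial(target, target, 50), 0)
  expect_equal(score_trial(target, target, 50, variant = "complement"), 1000)
  shifted <- target
  shifted[, 1] <- shifted[, 1] + 50
  expect_equal(score_trial(shifted, target, 50), 1000 * (1 - exp(-1)),
               tolerance = 1e-12)
  far <- target
  far[, 1] <- far[, 1] + 1e6
  expect_gt(score_trial(far, target, 50), 999.9)
})

test_that("RMSE matches direct computation and is rotation invariant", {
  t <- seq(0, 2, by = 0.02)
  target <- target_trajectory(t, cfg)
  expect_equal(rmse(target, target), 0)
  shifted <- target
  shifted[, 1] <- shifted[, 1] + 7
  expect_equal(rmse(shifted, target), 7)
  set.seed(2)
  cursor <- target + matrix(rnorm(length(target)), ncol = 2)
  expect_equal(rmse(cursor, target),
               sqrt(mean(rowSums((cursor - target)^2))))
  # common rotation leaves score and RMSE unchanged
  a <- 0.7
  rot <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  expect_equal(rmse(cursor %*% rot, target %*% rot), rmse(cursor, target))
  expect_equal(score_trial(cursor %*% rot, target %*% rot, 50),
               score_trial(cursor, target, 50))
})
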