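freqs <- 1:5

test_that("Smith-Predictor gain inference removes exactly the loop delay", {
  cfg <- ofc_config(tau_ext = 0.2)
  tf <- closed_loop_transfer(freqs, cfg)
  d_tot <- (delay_steps(0.26, 0.01) + delay_steps(0.2, 0.01)) * 0.01
  g <- infer_gain_smith(tf$force$h, freqs, d_tot)
  kgn <- design_kalman_gains(0.01, 250)
  pgn <- design_pi_gains(0.01, 1, 1e-4)
  intrinsic <- transfer_h_pi(freqs, pgn, dt = 0.01)$h *
    transfer_kalman(freqs, kgn, 0.01, 0.26, "projected")$h
  expect_equal(g$g, intrinsic, tolerance = 1e-12)
  expect_equal(infer_gain_smith(rep(0 + 0i, 5), freqs, 0.46)$g,
               rep(0 + 0i, 5))
})

test_that("inferred Smith gain magnitude is delay invariant", {
  gs <- lapply(c(0, 0.2, 0.4), function(tx) {
    tf <- closed_loop_transfer(freqs, ofc_config(tau_ext = tx))
    d_tot <- (26 + delay_steps(tx, 0.01)) * 0.01
    Mod(infer_gain_smith(tf$force$h, freqs, d_tot)$g)
  })
  expect_equal(gs[[1]], gs[[2]], tolerance = 1e-10)
  expect_equal(gs[[1]], gs[[3]], tolerance = 1e-10)
})

test_that("simple-architecture inference inverts its forward model", {
  w <- 2 * pi * freqs
  g_true <- 0.8 / (1 + 1i * w / (2 * pi * 3))
  tau <- 0.46
  h <- g_true * exp(-1i * w * tau) / (1 + g_true * exp(-1i * w * tau))
  rec <- infer_gain_simple(h, freqs, tau)
  expect_equal(rec$g, g_true, tolerance = 1e-12)
  expect_false(any(rec$flagged))
  expect_equal(infer_gain_simple(rep(0 + 0i, 5), freqs, tau)$g,
               rep(0 + 0i, 5))
  flagged <- infer_gain_simple(c(1 + 0i, h[-1]), freqs, tau)
  expect_true(flagged$flagged[1])
})

test_that("architecture misattribution is diagnosable from delay dependence", {
  # Smith-Predictor data: G_FB differs across delays, G_SP does not
  gfb <- lapply(c(0, 0.2), function(tx) {
    tf <- closed_loop_transfer(freqs, ofc_config(tau_ext = tx))
    d_tot <- (26 + delay_steps(tx, 0.01)) * 0.01
    list(simple = Mod(infer_gain_simple(tf$force$h, freqs, d_tot)$g),
         smith = Mod(infer_gain_smith(tf$force$h, freqs, d_tot)$g))
  })
  expect_gt(mean(abs(gfb[[1]]$simple - gfb[[2]]$simple)), 0.05)
  expect_lt(mean(abs(gfb[[1]]$smith - gfb[[2]]$smith)), 1e-10)

  # simple-controller data: the reverse
  w <- 2 * pi * freqs
  g_true <- 0.6 / (1 + 1i * w / (2 * pi * 2.5))
  rec <- lapply(c(0.26, 0.46), function(tau) {
    h <- g_true * exp(-1i * w * tau) / (1 + g_true * exp(-1i * w * tau))
    list(simple = Mod(infer_gain_simple(h, freqs, tau)$g),
         smith = Mod(infer_gain_smith(h, freqs, tau)$g))
  })
  expect_lt(mean(abs(rec[[1]]$simple - rec[[2]]$simple)), 1e-10)
  expect_gt(mean(abs(rec[[1]]$smith - rec[[2]]$smith)), 0.02)
})

test_that("delay dependence is zero for identical profiles and c^2 for offsets", {
  gp <- function(g, cond) structure(
    list(freqs = freqs, g = g, architecture = "smith",
         window = list(start_s = 0, duration_s = 5), condition = cond,
         flagged = rep(FALSE, 5)), class = "gain_profile")
  g0 <- complex(modulus = c(1, .9, .8, .7, .6), argument = -(1:5) / 4)
  same <- delay_dependence(list(list(gp(g0, 0)), list(gp(g0, 0.2))))
  expect_equal(same$msd, 0)
  offset <- delay_dependence(list(list(gp(g0, 0)),
                                  list(gp(g0 * (1 + 0.3 / Mod(g0)), 0.2))))
  expect_equal(offset$msd, 0.09, tolerance = 1e-12)

  # brute-force double-loop oracle on random inputs
  set.seed(6)
  gs <- lapply(1:3, function(i) complex(real = rnorm(5),
                                        imaginary = rnorm(5)))
  dd <- delay_dependence(lapply(gs, function(g) list(gp(g, 0))))
  acc <- 0; np <- 0
  for (i in 1:2) for (j in (i + 1):3) {
    acc <- acc + mean((Mod(gs[[i]]) - Mod(gs[[j]]))^2); np <- np + 1
  }
  expect_equal(dd$msd, acc / np, tolerance = 1e-12)
  expect_error(delay_dependence(list(list(gp(g0, 0)))), "2 delay")
})

test_that("gain phase delay reads off pure delays and real gains", {
  gp <- structure(list(freqs = 1:5,
                       g = exp(-1i * 2 * pi * (1:5) * 0.1),
                       architecture = "smith", window = NULL,
                       condition = 0, flagged = rep(FALSE, 5)),
                  class = "gain_profile")
  expect_equal(gain_phase_delay_at(gp, 1), 0.1, tolerance = 1e-12)
  expect_equal(gain_phase_delay_at(gp, 2.5), 0.1, tolerance = 1e-12)
  gp$g <- rep(2 + 0i, 5)
  expect_equal(gain_phase_delay_at(gp, 1), 0)
})

test_that("sliding windows honor their schedule contracts", {
  ses <- generate_human_session(task_config(), ofc_config(), "exp2",
                                seed = 31)
  idx <- which(ses$schedule$f_pert == 2 & ses$schedule$tau_ext == 0)
  trials <- ses$trials[idx[1:4]]
  one <- sliding_window_gains(trials, task_config(), window = 5, step = 15)
  expect_length(one, 2)      # starts at 0 and 15 s in a 20 s trial
  expect_equal(one[[1]]$window$start_s, 0)
  expect_equal(one[[2]]$window$start_s, 15)
  expect_error(sliding_window_gains(trials, task_config(), window = 25),
               "window exceeds")
})

test_that("cursor-target lag is recovered from delayed tracking angles", {
  fs <- 50
  t <- seq(0, 40 - 1 / fs, by = 1 / fs)
  set.seed(9)
  theta_t <- 2 * pi * 0.2 * t
  wob <- as.numeric(arima.sim(list(ar = 0.98), length(t))) * 0.01
  theta_c <- 2 * pi * 0.2 * (t - 0.2) + c(rep(0, 10), wob[1:(length(t) - 10)])
  expect_equal(cursor_target_lag(theta_c, theta_t, fs, max_lag = 1), 0.2)
  expect_equal(cursor_target_lag(theta_t, theta_t, fs), 0)
  expect_error(cursor_target_lag(rep(1, 100), rep(1, 100), fs),
               "undefined lag")
})
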