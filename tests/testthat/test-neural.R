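test_that("low-pass filtering is zero-phase and attenuates the stop band", {
  fs <- 488
  t <- (0:9999) / fs
  tone2 <- sin(2 * pi * 2 * t)
  tone20 <- sin(2 * pi * 20 * t)
  f2 <- lowpass_filter(tone2, fs, 10)
  f20 <- lowpass_filter(tone20, fs, 10)
  expect_gt(sd(f2) / sd(tone2), 0.95)
  expect_lt(sd(f20[1000:9000]) / sd(tone20), 0.05)
  # symmetric pulse stays symmetric
  pulse <- exp(-((t - t[5000])^2) / (2 * 0.05^2))
  fp <- lowpass_filter(pulse, fs, 10)
  expect_equal(fp[5000 + 1:300], fp[5000 - 1:300], tolerance = 1e-6)
})

test_that("block preprocessing centers channels and derives speed", {
  ses <- generate_monkey_session(task_config(), ofc_config(), seed = 1,
                                 delays = 0, n_trials = 4,
                                 trial_duration = 3)
  prep <- preprocess_block(ses$blocks[[1]])
  expect_lt(max(abs(rowMeans(prep$lfp_raw))), 1e-10)
  expect_length(prep$speed, length(ses$blocks[[1]]$radial))
  expect_error(preprocess_block(ses$blocks[[1]],
                                channel_mask = rep(FALSE, 12)),
               "all channels masked")
})

test_that("submovement detection applies threshold and plateau rules", {
  fs <- 100
  t <- (0:999) / fs
  speed <- 150 * exp(-((t - 3)^2) / (2 * 0.1^2))
  ev <- detect_submovements(speed, fs, 100)
  expect_length(ev$times, 1)
  expect_equal(ev$times, 3, tolerance = 1 / fs)
  expect_equal(ev$peak_speeds, 150, tolerance = 0.5)

  ev90 <- detect_submovements(0.6 * speed, fs, 100)
  expect_length(ev90$times, 0)

  # exhaustive scan oracle on a long random series
  set.seed(5)
  x <- 100 + 40 * as.numeric(arima.sim(list(ar = 0.95), 5000))
  ev <- detect_submovements(x, fs, 100)
  oracle <- which(x[2:4999] > x[1:4998] & x[2:4999] > x[3:5000] &
                    x[2:4999] > 100) + 1
  expect_equal(ev$times, (oracle - 1) / fs)
})

test_that("event-triggered averages isolate event-locked structure", {
  fs <- 100
  n <- 20000
  set.seed(7)
  times <- sort(sample(200:(n - 200), 60)) / fs
  sig <- numeric(n)
  sig[round(times * fs) + 1] <- 1
  av <- smta(sig, fs, list(times = times), half_window = 0.5)
  expect_equal(av$mean[1, av$lags == 0], 1)
  expect_lt(max(av$mean[1, av$lags != 0]), 0.2)
  expect_equal(av$n_events, 60)

  # events hugging the record edge are excluded
  av2 <- smta(sig, fs, list(times = c(0.1, times)), half_window = 0.5)
  expect_equal(av2$n_events, 60)

  # shuffled events against structured signal average to ~0
  osc <- sin(2 * pi * 3 * (0:(n - 1)) / fs)
  set.seed(8)
  rand_times <- sort(runif(300, 2, (n - 200) / fs))
  av3 <- smta(osc, fs, list(times = rand_times), half_window = 0.5)
  expect_lt(max(abs(av3$mean)), 0.25)
  expect_error(smta(sig, fs, list(times = numeric(0)), 0.5), "no usable")
})

test_that("task-locked removal zeroes shared profiles and reduces variance", {
  prof <- sin(seq(0, 2 * pi, length.out = 64))
  sections <- matrix(rep(prof, 5), nrow = 5, byrow = TRUE)
  expect_equal(remove_task_locked(sections), rep(0, 320))

  set.seed(1)
  sections <- sections + matrix(rnorm(320), 5)
  res <- matrix(remove_task_locked(sections), nrow = 5, byrow = TRUE)
  expect_lt(max(abs(colMeans(res))), 1e-12)
  expect_true(all(colSums(res^2) <= colSums(sweep(sections, 2,
                                                  0)^2) + 1e-12))
  expect_error(remove_task_locked(sections[1, , drop = FALSE]), "two")
})

test_that("spectral suite obeys coherence identities", {
  set.seed(10)
  fs <- 100
  n <- 60000
  x <- as.numeric(arima.sim(list(ar = 0.7), n))
  lfp <- rbind(x, 2 * x)
  suite <- spectral_suite(lfp, x, fs, nfft = 4096)
  # coherence of (scaled copies of) the same signal is 1 everywhere
  expect_true(all(abs(suite$coh_lfp_cursor - 1) < 1e-8))
  # scaled copies have purely real coherency
  expect_lt(max(abs(suite$imcoh_pairs)), 1e-8)

  # two channels 90 degrees apart at f0 show imaginary coherence there
  t <- (0:(n - 1)) / fs
  a <- sin(2 * pi * 3 * t) + 0.2 * rnorm(n)
  b <- cos(2 * pi * 3 * t) + 0.2 * rnorm(n)
  s2 <- spectral_suite(rbind(a, b), x, fs, nfft = 4096)
  pk <- peak_frequency(s2$freqs, s2$imcoh_lfp_lfp, c(1, 10))
  expect_equal(pk, 3, tolerance = 0.25)
  expect_gt(max(abs(s2$imcoh_pairs[1, s2$freqs > 2.8 & s2$freqs < 3.2])),
            0.8)
  expect_error(spectral_suite(lfp, x, fs, nfft = n + 1), "record shorter")
})

test_that("spectral averages are invariant to channel relabeling", {
  set.seed(12)
  lfp <- matrix(rnorm(4 * 20000), 4)
  lfp[2, ] <- lfp[1, ] * 0.5 + lfp[2, ]
  cur <- rnorm(20000)
  s1 <- spectral_suite(lfp, cur, 100, nfft = 2048)
  s2 <- spectral_suite(lfp[c(3, 1, 4, 2), ], cur, 100, nfft = 2048)
  expect_equal(s1$p_lfp, s2$p_lfp)
  expect_equal(s1$coh_lfp_cursor, s2$coh_lfp_cursor)
  expect_equal(s1$imcoh_lfp_lfp, s2$imcoh_lfp_lfp)
})

test_that("PCA recovers orthogonal sources and fixes signs", {
  n <- 5000
  t <- (0:(n - 1)) / 100
  s1 <- sin(2 * pi * 2 * t)
  s2 <- cos(2 * pi * 5 * t)
  set.seed(3)
  lfp <- rbind(s1 + 0.01 * rnorm(n), s2 + 0.01 * rnorm(n),
               -s1 + 0.01 * rnorm(n))
  pc <- lfp_pca(lfp)
  expect_true(all(diff(pc$var_explained) <= 1e-12))
  expect_gt(abs(cor(pc$scores[, 1], s1)), 0.99)
  expect_gt(abs(cor(pc$scores[, 2], s2)), 0.99)
  # sign convention: dominant loading positive
  for (j in 1:2) {
    v <- pc$loadings[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }
  proj <- project_on_pcs(lfp, pc)
  expect_equal(proj, pc$trajectory, tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(lfp_pca(lfp[1, , drop = FALSE]), "two channels")
})

test_that("rotation direction reads the signed circulation", {
  th <- seq(0, 2 * pi, length.out = 200)
  expect_equal(rotation_direction(cbind(cos(th), sin(th))), 1)
  expect_equal(rotation_direction(cbind(cos(-th), sin(-th))), -1)
})
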