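#' Angular-velocity power spectrum
#'
#' Averaged one-sided periodogram of angular-velocity windows: FFTs are
#' taken on non-overlapping rectangular windows of `window_samples`
#' points (512 samples, about 10 s at 50 samples/s) starting `start_s`
#' seconds into each series, and averaged across windows and across
#' series (e.g. across the trials of one condition).  The raw spectrum is
#' stored; peak extraction applies a seven-point moving average (see
#' [find_spectral_peaks()]).
#'
#' The scaling satisfies Parseval's identity: the sum of power times the
#' bin width equals the mean square of the windowed data.
#'
#' @param omega a numeric vector of angular velocities (rad/s), or a list
#'   of such vectors (one per trial).
#' @param fs sampling rate (samples/s).
#' @param start_s analysis start within each series (s).
#' @param window_samples FFT window length (samples).
#' @param demean subtract each window's mean before transforming
#'   (removes the steady target-rotation component).
#' @return object of class `velocity_spectrum`: `freqs` (Hz, bin centers
#'   from df to Nyquist), `power` (signal-units^2/Hz), and `meta`.
#' @export
velocity_power_spectrum <- function(omega, fs, start_s = 5,
                                    window_samples = 512, demean = TRUE) {
  series <- if (is.list(omega)) omega else list(omega)
  offset <- as.integer(round(start_s * fs))
  nw <- window_samples
  acc <- NULL
  n_windows <- 0L
  for (x in series) {
    avail <- length(x) - offset
    k <- avail %/% nw
    if (k < 1)
      stop("windowing error: series too short for one window after start_s",
           call. = FALSE)
    for (j in seq_len(k)) {
      seg <- x[offset + ((j - 1) * nw + 1):(j * nw)]
      if (demean) seg <- seg - mean(seg)
      p <- Mod(stats::fft(seg))^2 / (nw^2)
      # fold to one-sided density
      half <- nw %/% 2
      ps <- p[2:(half + 1)]
      ps[seq_len(half - 1)] <- 2 * ps[seq_len(half - 1)]
      ps <- ps / (fs / nw)
      acc <- if (is.null(acc)) ps else acc + ps
      n_windows <- n_windows + 1L
    }
  }
  half <- nw %/% 2
  structure(list(
    freqs = (1:half) * fs / nw,
    power = acc / n_windows,
    meta = list(window_len_samples = nw, n_windows = n_windows,
                smoothing = "none (7-point moving average at peak finding)",
                fs = fs, analysis_start_s = start_s, demean = demean)
  ), class = "velocity_spectrum")
}

#' @export
print.velocity_spectrum <- function(x, ...) {
  cat(sprintf("Velocity power spectrum: %d bins, df = %.4g Hz, %d windows\n",
              length(x$freqs), x$freqs[1], x$meta$n_windows))
  invisible(x)
}

# centered moving average; shorter symmetric windows at the edges
moving_average <- function(x, k = 7) {
  h <- k %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - h); hi <- min(n, i + h)
    mean(x[lo:hi])
  }, numeric(1))
}

#' Locate submovement peaks in a smoothed power spectrum
#'
#' Peaks are detected on the seven-point moving-average smoothed power
#' (a strict local maximum is a bin greater than both neighbours;
#' plateaus of tied bins flanked by lower values resolve to their first,
#' lowest-frequency bin) and then localized on the raw spectrum: each
#' detection snaps to the raw maximum within `refine_bins` bins and is
#' refined by quadratic interpolation through the three raw bins around
#' it.  Detecting on the smoothed spectrum suppresses sampling noise
#' while localizing on the raw spectrum avoids the downward bias that
#' smoothing introduces for peaks riding on the sloped low-frequency
#' noise background.  Peaks are returned ordered by frequency.
#'
#' @param spec a `velocity_spectrum`.
#' @param band numeric length-2 frequency band (Hz).
#' @param smooth_points moving-average length (bins).
#' @param refine_bins half-width (bins) of the raw-localization window;
#'   0 disables refinement.
#' @return data frame with columns `freq` (Hz, interpolated), `period`
#'   (s), `power` (raw power at the peak bin).
#' @export
find_spectral_peaks <- function(spec, band = c(0.5, 6), smooth_points = 7,
                                refine_bins = 3) {
  if (length(band) != 2 || band[2] <= band[1])
    stop("empty band", call. = FALSE)
  s <- moving_average(spec$power, smooth_points)
  raw <- spec$power
  df <- spec$freqs[2] - spec$freqs[1]
  idx <- local_maxima(s)
  keep <- spec$freqs[idx] >= band[1] & spec$freqs[idx] <= band[2]
  idx <- idx[keep]
  if (length(idx) == 0)
    return(data.frame(freq = numeric(0), period = numeric(0),
                      power = numeric(0)))
  located <- vapply(idx, function(i) {
    lo <- max(2, i - refine_bins)
    hi <- min(length(raw) - 1, i + refine_bins)
    j <- (lo:hi)[which.max(raw[lo:hi])]
    curv <- raw[j - 1] - 2 * raw[j] + raw[j + 1]
    d <- if (refine_bins > 0 && curv < 0) {
      (raw[j - 1] - raw[j + 1]) / (2 * curv)
    } else 0
    c(j, spec$freqs[j] + d * df)
  }, numeric(2))
  dup <- !duplicated(located[1, ])
  j <- located[1, dup]
  f <- located[2, dup]
  o <- order(f)
  data.frame(freq = f[o], period = 1 / f[o], power = raw[j][o])
}

# indices of strict local maxima; plateaus resolved to the first sample
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  out <- integer(0)
  i <- 2
  while (i <= n - 1) {
    if (x[i] > x[i - 1]) {
      j <- i
      while (j < n && x[j + 1] == x[i]) j <- j + 1
      if (j < n && x[j + 1] < x[i]) out <- c(out, i)
      i <- j + 1
    } else i <- i + 1
  }
  out
}

#' Predicted constructive-interference frequency
#'
#' Odd harmonics of the half-period of the total feedback loop delay:
#' \eqn{f = N / (2(\tau_{int} + \tau_{ext}))} for odd `N`.
#'
#' @param N odd harmonic number (1, 3, 5, ...).
#' @param tau_int,tau_ext delays (s); their sum must be positive.
#' @return frequency (Hz).
#' @export
eq_comb_frequency <- function(N, tau_int, tau_ext = 0) {
  if (any(N %% 2 != 1) || any(N < 1))
    stop("harmonic number must be odd and >= 1", call. = FALSE)
  tot <- tau_int + tau_ext
  if (any(tot <= 0)) stop("total delay must be > 0", call. = FALSE)
  N / (2 * tot)
}

#' Intrinsic delay implied by a submovement period
#'
#' Inverts the comb relation: `tau_int = period * N / 2 - tau_ext`.
#' A negative result is returned but flagged with a warning, since an
#' unphysical negative intrinsic delay indicates a mis-assigned harmonic.
#'
#' @param period submovement period (s).
#' @param N odd harmonic number.
#' @param tau_ext extrinsic delay (s).
#' @return implied intrinsic delay (s).
#' @export
eq_comb_tau_int <- function(period, N, tau_ext = 0) {
  if (any(period <= 0)) stop("period must be > 0", call. = FALSE)
  if (any(N %% 2 != 1)) stop("harmonic number must be odd", call. = FALSE)
  out <- period * N / 2 - tau_ext
  if (any(out < 0)) warning("negative implied intrinsic delay (unphysical)")
  out
}

#' Regress submovement period on extrinsic delay
#'
#' Ordinary least squares of period against extrinsic delay for one
#' harmonic group.  The comb relation predicts a slope of `2/N` and an
#' intercept of `2 tau_int / N`, so the intrinsic delay is recovered as
#' `intercept * N / 2`.
#'
#' @param points data frame with columns `tau_ext` (s) and `period` (s);
#'   at least two distinct delays required.
#' @param N odd harmonic number of the group.
#' @return object of class `peak_regression`: slope, intercept (s), their
#'   95% confidence intervals, `r2`, `p`, `tau_int_est` (s), `n`, and the
#'   fitted points.
#' @export
regress_period_vs_delay <- function(points, N = 1) {
  if (length(unique(points$tau_ext)) < 2)
    stop("degenerate design: need >= 2 distinct delays", call. = FALSE)
  fit <- stats::lm(period ~ tau_ext, data = points)
  ci <- stats::confint(fit)
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  structure(list(
    harmonic_n = N, points = points, slope = slope, intercept = intercept,
    ci95_slope = unname(ci[2, ]), ci95_intercept = unname(ci[1, ]),
    r2 = sm$r.squared,
    p = if (nrow(points) > 2) unname(sm$coefficients[2, 4]) else NA_real_,
    tau_int_est = intercept * N / 2, n = nrow(points)
  ), class = "peak_regression")
}

#' @export
print.peak_regression <- function(x, ...) {
  cat(sprintf("Period-vs-delay regression (harmonic N = %d, %d points)\n",
              x$harmonic_n, x$n))
  cat(sprintf("  slope = %.3f [%.3f, %.3f] (predicted 2/N = %.3f)\n",
              x$slope, x$ci95_slope[1], x$ci95_slope[2], 2 / x$harmonic_n))
  cat(sprintf("  intercept = %.1f ms; implied tau_int = %.1f ms; R2 = %.3f\n",
              1000 * x$intercept, 1000 * x$tau_int_est, x$r2))
  invisible(x)
}

#' Estimate perturbation transfer functions from trials of one cell
#'
#' For each trial the cursor and force angular velocities are demodulated
#' at the perturbation frequency over a fixed window,
#' \deqn{H = \frac{2}{\omega_t T}\int_0^T \omega(t)\, e^{-i\omega_p t} dt,}
#' which normalizes the pure perturbation component (peak angular
#' velocity \eqn{\omega_t}) to unity.  The window mean is subtracted
#' before demodulation to remove leakage from the steady target rotation,
#' the trial's rotation direction is applied so the perturbation phase is
#' common across trials, and trials are averaged as complex means.
#'
#' The stored force response is reported in the convention of the
#' closed-loop decomposition `H_cursor = 1 - H_force`: a delayed
#' correction opposing the displayed perturbation has positive gain, and
#' the response is referred to the displayed (extrinsically delayed)
#' force timeline.  Equivalently, the raw demodulated force response is
#' negated and rotated by the extrinsic delay phase; at
#' constructive-interference frequencies the delayed opposing correction
#' appears in phase with the perturbation.  The intrinsic phase delay
#' then follows by removing the extrinsic delay from the total response
#' phase.
#'
#' @param trials list of trial recordings from one
#'   (perturbation frequency, delay) cell.
#' @param cfg the session's [task_config()].
#' @param start_s window start within the trial (s).
#' @param duration_s window length (s); the default uses
#'   `window_samples/fs` of the spectral analysis (10.24 s at 50
#'   samples/s).
#' @return object of class `transfer_estimate` with `f_pert`, complex
#'   `h_cursor` and `h_force`, magnitudes `amp_cursor`, `amp_force`,
#'   intrinsic phase delay `tau_phi` (s), the window, and `n_trials`.
#' @export
estimate_transfer <- function(trials, cfg, start_s = 5,
                              duration_s = 512 / cfg$fs) {
  stopifnot(length(trials) >= 1)
  f_pert <- trials[[1]]$condition$f_pert
  tau_ext <- trials[[1]]$condition$tau_ext
  if (f_pert <= 0) stop("transfer estimation needs f_pert > 0", call. = FALSE)
  fs <- trials[[1]]$fs
  i0 <- as.integer(round(start_s * fs))
  nwin <- as.integer(round(duration_s * fs))
  if (i0 + nwin > length(trials[[1]]$t))
    stop("window exceeds trial length", call. = FALSE)
  wt <- 2 * pi * cfg$f_target
  wp <- 2 * pi * f_pert
  tw <- trials[[1]]$t[i0 + seq_len(nwin)]
  demod <- exp(-1i * wp * tw)
  dt <- 1 / fs
  tt <- duration_s

  one <- function(trial) {
    s <- dir_sign(trial$condition$direction)
    wc <- s * angular_velocity(trial$cursor_xy, fs)[i0 + seq_len(nwin)]
    wf <- s * angular_velocity(trial$force_xy, fs)[i0 + seq_len(nwin)]
    hc <- 2 / (wt * tt) * sum((wc - mean(wc)) * demod) * dt
    hf <- 2 / (wt * tt) * sum((wf - mean(wf)) * demod) * dt
    c(hc, hf)
  }
  hh <- vapply(trials, one, complex(2))
  h_cursor <- mean(hh[1, ])
  # closed-loop sign and timeline convention, see Details
  h_force <- -mean(hh[2, ]) * exp(-1i * wp * tau_ext)
  structure(list(
    f_pert = f_pert, tau_ext = tau_ext,
    h_cursor = h_cursor, h_force = h_force,
    amp_cursor = Mod(h_cursor), amp_force = Mod(h_force),
    tau_phi = intrinsic_phase_delay(h_force, f_pert, tau_ext),
    window = list(start_s = start_s, duration_s = duration_s),
    n_trials = length(trials)
  ), class = "transfer_estimate")
}

#' Intrinsic phase delay of the force response
#'
#' Converts the phase of the force transfer function at the perturbation
#' frequency into a latency and removes the extrinsic delay:
#' \eqn{\tau_\phi = -\arg H_{force}/\omega_p - \tau_{ext}}, with the phase
#' branch chosen so that the intrinsic delay lies in `[0, 1/f_pert)`
#' (whole perturbation periods are added or removed after the extrinsic
#' delay is subtracted).  The phase is only identified up to whole
#' periods, so an intrinsic delay exceeding one perturbation period
#' (possible at the highest perturbation frequencies) wraps; the raw
#' complex response is always stored alongside so alternative branches
#' can be recomputed.
#'
#' @param h_force complex force response.
#' @param f_pert perturbation frequency (Hz).
#' @param tau_ext extrinsic delay (s).
#' @return intrinsic phase delay (s), in `[0, 1/f_pert)`.
#' @export
intrinsic_phase_delay <- function(h_force, f_pert, tau_ext = 0) {
  if (Mod(h_force) == 0)
    stop("undefined phase: zero force response", call. = FALSE)
  wp <- 2 * pi * f_pert
  (-Arg(h_force) / wp - tau_ext) %% (1 / f_pert)
}

#' Pool a session's spectra and extract peak periods per delay
#'
#' Convenience chain for delay-condition analysis: computes the averaged
#' cursor angular-velocity spectrum per extrinsic delay (unperturbed
#' trials only) and extracts the lowest-frequency submovement peak.
#'
#' @param session a human `trial_set`.
#' @param band peak-search band (Hz).
#' @param ... passed to [velocity_power_spectrum()].
#' @return list with `spectra` (named by delay) and `peaks` (data frame
#'   `tau_ext`, `freq`, `period`).
#' @export
session_peak_periods <- function(session, band = c(0.5, 6), ...) {
  stopifnot(inherits(session, "trial_set"))
  cond <- vapply(session$trials, function(tr) tr$condition$tau_ext, 1)
  fp <- vapply(session$trials, function(tr) tr$condition$f_pert, 1)
  delays <- sort(unique(cond[fp == 0]))
  fs <- session$task_cfg$fs
  spectra <- list()
  peaks <- data.frame()
  for (d in delays) {
    idx <- which(cond == d & fp == 0)
    om <- lapply(session$trials[idx], function(tr) {
      s <- dir_sign(tr$condition$direction)
      s * angular_velocity(tr$cursor_xy, fs)
    })
    sp <- velocity_power_spectrum(om, fs, ...)
    spectra[[as.character(d)]] <- sp
    f <- primary_peak_frequency(sp, band)
    peaks <- rbind(peaks, data.frame(tau_ext = d, freq = f, period = 1 / f))
  }
  list(spectra = spectra, peaks = peaks)
}
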