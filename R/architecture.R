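#' Intrinsic gain under the Smith-Predictor architecture
#'
#' In the Smith-Predictor loop the measured force response is the
#' intrinsic dynamics delayed by the total loop delay,
#' `H_force = G * exp(-iw tau_total)`, so the intrinsic gain is recovered
#' by removing the pure delay: `G = H_force * exp(+iw tau_total)`.
#'
#' @param h_force complex force responses on `freqs`.
#' @param freqs frequency grid (Hz).
#' @param tau_total total loop delay (s), intrinsic plus extrinsic.
#' @param architecture label stored on the result.
#' @param window optional window metadata (list with `start_s`,
#'   `duration_s`).
#' @param condition optional extrinsic delay label (s).
#' @return object of class `gain_profile`: `freqs`, complex `g`,
#'   `architecture`, `window`, `condition`, `flagged` (logical per
#'   frequency; always FALSE here).
#' @export
infer_gain_smith <- function(h_force, freqs, tau_total,
                             window = NULL, condition = NA_real_) {
  w <- 2 * pi * freqs
  structure(list(freqs = freqs, g = h_force * exp(1i * w * tau_total),
                 architecture = "smith", window = window,
                 condition = condition,
                 flagged = rep(FALSE, length(freqs))),
            class = "gain_profile")
}

#' Intrinsic gain under the simple delayed-feedback architecture
#'
#' A simple feedback controller with intrinsic gain `G` and loop delay
#' `tau` has closed-loop force response
#' `H_force = G e^{-iw tau} / (1 + G e^{-iw tau})`, whose algebraic
#' inverse is `G = H_force e^{+iw tau} / (1 - H_force)`.  Frequencies
#' where `|1 - H_force|` falls below `singular_tol` are returned but
#' flagged rather than silently dropped.
#'
#' @param h_force complex force responses on `freqs`.
#' @param freqs frequency grid (Hz).
#' @param tau_total total loop delay (s).
#' @param singular_tol flag threshold on `|1 - H_force|`.
#' @param window,condition metadata as in [infer_gain_smith()].
#' @return a `gain_profile` with `architecture = "simple"`.
#' @export
infer_gain_simple <- function(h_force, freqs, tau_total,
                              singular_tol = 1e-6,
                              window = NULL, condition = NA_real_) {
  w <- 2 * pi * freqs
  den <- 1 - h_force
  flagged <- Mod(den) < singular_tol
  g <- h_force * exp(1i * w * tau_total) / den
  structure(list(freqs = freqs, g = g, architecture = "simple",
                 window = window, condition = condition, flagged = flagged),
            class = "gain_profile")
}

#' @export
print.gain_profile <- function(x, ...) {
  cat(sprintf("Inferred intrinsic gain (%s architecture), %d frequencies",
              x$architecture, length(x$freqs)))
  if (!is.na(x$condition)) cat(sprintf(", tau_ext = %g s", x$condition))
  cat("\n")
  invisible(x)
}

#' Sliding-window transfer estimates and gain inference
#'
#' Estimates the perturbation transfer functions in successive windows
#' through the trial (the same demodulation as [estimate_transfer()])
#' and inverts each window's force response under one architecture,
#' giving the within-trial evolution of the inferred intrinsic gain.
#'
#' @param trials list of trial recordings from one
#'   (perturbation frequency, delay) cell, or a list of such lists over
#'   several perturbation frequencies (the gain profile then spans the
#'   perturbation grid).
#' @param cfg the session's [task_config()].
#' @param tau_int assumed intrinsic delay (s).
#' @param architecture `"smith"` or `"simple"`.
#' @param window window length (s).
#' @param step window step (s).
#' @return list of `gain_profile` objects, one per window position.
#' @export
sliding_window_gains <- function(trials, cfg, tau_int = 0.26,
                                 architecture = c("smith", "simple"),
                                 window = 5, step = 1) {
  architecture <- match.arg(architecture)
  cells <- if (inherits(trials[[1]], "trial_recording")) list(trials) else trials
  trial_len <- cells[[1]][[1]]$t[length(cells[[1]][[1]]$t)] +
    1 / cells[[1]][[1]]$fs
  if (window > trial_len) stop("window exceeds trial length", call. = FALSE)
  tau_ext <- cells[[1]][[1]]$condition$tau_ext
  starts <- seq(0, trial_len - window, by = step)
  lapply(starts, function(s0) {
    est <- lapply(cells, function(cell)
      estimate_transfer(cell, cfg, start_s = s0, duration_s = window))
    freqs <- vapply(est, function(e) e$f_pert, 1)
    hf <- vapply(est, function(e) e$h_force, complex(1))
    o <- order(freqs)
    fun <- if (architecture == "smith") infer_gain_smith else infer_gain_simple
    fun(hf[o], freqs[o], tau_total = tau_int + tau_ext,
        window = list(start_s = s0, duration_s = window),
        condition = tau_ext)
  })
}

#' Delay-dependence of inferred intrinsic gains
#'
#' For each window position, the mean over frequencies of the squared
#' difference in gain magnitude between every pair of delay conditions,
#' averaged over pairs.  Identical profiles give zero; profiles whose
#' magnitudes differ by a constant `c` at every frequency give `c^2`.
#'
#' @param profiles_by_condition list over delay conditions; each element
#'   is a list of `gain_profile` objects over window positions (as
#'   returned by [sliding_window_gains()]), on a common frequency grid
#'   and window schedule.
#' @return object of class `delay_dependence`: `window_centers` (s) and
#'   `msd`.
#' @export
delay_dependence <- function(profiles_by_condition) {
  if (length(profiles_by_condition) < 2)
    stop("need >= 2 delay conditions", call. = FALSE)
  nw <- length(profiles_by_condition[[1]])
  freqs <- profiles_by_condition[[1]][[1]]$freqs
  for (cond in profiles_by_condition) {
    if (length(cond) != nw) stop("mismatched window schedules", call. = FALSE)
    for (pr in cond) {
      if (length(pr$freqs) != length(freqs) || any(pr$freqs != freqs))
        stop("mismatched frequency grids", call. = FALSE)
    }
  }
  centers <- vapply(profiles_by_condition[[1]], function(pr) {
    if (is.null(pr$window)) NA_real_
    else pr$window$start_s + pr$window$duration_s / 2
  }, 1)
  pairs <- utils::combn(length(profiles_by_condition), 2)
  msd <- vapply(seq_len(nw), function(wi) {
    vals <- vapply(seq_len(ncol(pairs)), function(k) {
      g1 <- Mod(profiles_by_condition[[pairs[1, k]]][[wi]]$g)
      g2 <- Mod(profiles_by_condition[[pairs[2, k]]][[wi]]$g)
      mean((g1 - g2)^2)
    }, 1)
    mean(vals)
  }, 1)
  structure(list(window_centers = centers, msd = msd),
            class = "delay_dependence")
}

#' Phase delay of an inferred gain at one frequency
#'
#' `-arg(g)/(2 pi f)` with the phase branch placing the delay in
#' `[0, 1/f)`; the gain is linearly interpolated onto `f` if it is not a
#' grid point.
#'
#' @param g a `gain_profile`.
#' @param f frequency (Hz).
#' @return phase delay (s).
#' @export
gain_phase_delay_at <- function(g, f = 1) {
  if (f %in% g$freqs) {
    gv <- g$g[g$freqs == f][1]
  } else {
    gv <- complex(real = stats::approx(g$freqs, Re(g$g), f)$y,
                  imaginary = stats::approx(g$freqs, Im(g$g), f)$y)
  }
  if (is.na(gv) || Mod(gv) == 0)
    stop("undefined phase delay: zero or missing gain", call. = FALSE)
  (-Arg(gv) / (2 * pi * f)) %% (1 / f)
}

#' Time lag between cursor and target angles
#'
#' Scans lags in `[-max_lag, max_lag]` and returns the one that best
#' aligns the unwrapped cursor angle with the unwrapped target angle, by
#' least squares.  (For angle series dominated by the steady target
#' rotation a normalized correlation is offset-invariant and cannot see
#' the lag, so the alignment is scored by the mean squared angle
#' difference instead; the two agree for fluctuation-dominated series.)
#' Positive values mean the cursor trails the target; exact ties resolve
#' to the smallest absolute lag.
#'
#' @param theta_cursor,theta_target unwrapped angle series (rad).
#' @param fs sampling rate (samples/s).
#' @param max_lag maximum scanned lag (s).
#' @return lag (s).
#' @export
cursor_target_lag <- function(theta_cursor, theta_target, fs, max_lag = 1) {
  if (stats::sd(theta_cursor) < 1e-12 && stats::sd(theta_target) < 1e-12)
    stop("undefined lag: flat signals", call. = FALSE)
  ml <- as.integer(round(max_lag * fs))
  n <- length(theta_cursor)
  lags <- -ml:ml
  mse <- vapply(lags, function(l) {
    # positive l: compare cursor now with target l samples earlier
    if (l >= 0) {
      a <- theta_cursor[(1 + l):n]; b <- theta_target[1:(n - l)]
    } else {
      a <- theta_cursor[1:(n + l)]; b <- theta_target[(1 - l):n]
    }
    mean((a - b)^2)
  }, 1)
  best <- which(mse <= min(mse) + 1e-15)
  lags[best[which.min(abs(lags[best]))]] / fs
}
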