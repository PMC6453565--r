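#' Zero-phase low-pass filter for time-domain analyses
#'
#' 4th-order Butterworth low-pass applied forward and backward
#' (zero-phase), the documented filter for all time-domain products
#' (field potentials and cursor speed).
#'
#' @param x numeric vector, or matrix with one channel per row.
#' @param fs sampling rate (Hz).
#' @param cutoff cutoff frequency (Hz).
#' @param order filter order.
#' @return filtered data, same shape as the input.
#' @export
lowpass_filter <- function(x, fs, cutoff = 10, order = 4) {
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  if (is.matrix(x)) {
    out <- t(apply(x, 1, function(row) signal::filtfilt(bf, row)))
    dimnames(out) <- dimnames(x)
    out
  } else {
    signal::filtfilt(bf, x)
  }
}

#' Preprocess a monkey-style block for analysis
#'
#' Channel means are subtracted (after dropping any masked channels);
#' zero-phase 10 Hz low-passed copies of the field potentials and of the
#' radial cursor speed are prepared for time-domain products, and the raw
#' mean-subtracted potentials are kept for frequency-domain analysis.
#' Radial speed is the central-difference derivative of the radial torque
#' position (task %/s).
#'
#' @param block a `monkey_block` from [generate_monkey_session()].
#' @param channel_mask optional logical vector (TRUE = keep).
#' @return list with `lfp_raw` (centered), `lfp_filt` (10 Hz low-passed),
#'   `speed` and `speed_filt` (model rate, %/s), and rates `fs`,
#'   `lfp_fs`.
#' @export
preprocess_block <- function(block, channel_mask = NULL) {
  lfp <- block$lfp
  if (!is.null(channel_mask)) {
    if (!any(channel_mask)) stop("all channels masked", call. = FALSE)
    lfp <- lfp[channel_mask, , drop = FALSE]
  }
  lfp <- lfp - rowMeans(lfp)
  speed <- central_diff(block$radial) * block$fs
  list(lfp_raw = lfp,
       lfp_filt = lowpass_filter(lfp, block$lfp_fs, 10),
       speed = speed,
       speed_filt = lowpass_filter(speed, block$fs, 10),
       fs = block$fs, lfp_fs = block$lfp_fs)
}

central_diff <- function(x) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  d[1] <- x[2] - x[1]
  d[n] <- x[n] - x[n - 1]
  d
}

#' Detect submovements as peaks in radial cursor speed
#'
#' A submovement is a strict local maximum of the (low-pass filtered)
#' radial speed exceeding the threshold; plateaus are resolved to their
#' first sample.  No minimum inter-event interval is imposed.
#'
#' @param speed radial speed series (%/s).
#' @param fs sampling rate of `speed` (Hz).
#' @param threshold peak-speed threshold (%/s).
#' @return object of class `submovement_events`: `times` (s, zero-based
#'   like the series), `peak_speeds`, `threshold`.
#' @export
detect_submovements <- function(speed, fs, threshold = 100) {
  idx <- local_maxima(speed)
  idx <- idx[speed[idx] > threshold]
  structure(list(times = (idx - 1) / fs, peak_speeds = speed[idx],
                 threshold = threshold, fs = fs),
            class = "submovement_events")
}

#' @export
print.submovement_events <- function(x, ...) {
  cat(sprintf("%d submovements above %g %%/s\n", length(x$times), x$threshold))
  invisible(x)
}

#' Submovement-triggered average
#'
#' Averages signal segments in a symmetric window around each event time.
#' Events closer than the half-window to either record edge are excluded.
#'
#' @param signals numeric vector or channels-by-samples matrix.
#' @param fs sampling rate of `signals` (Hz).
#' @param events a `submovement_events` (or any list with `times` in s).
#' @param half_window half-width of the lag window (s).
#' @return object of class `smta`: `lags` (s), `mean`
#'   (channels x lags matrix), `n_events`, `channel_ids`.
#' @export
smta <- function(signals, fs, events, half_window = 0.5) {
  if (!is.matrix(signals)) signals <- matrix(signals, nrow = 1)
  hw <- as.integer(round(half_window * fs))
  n <- ncol(signals)
  centers <- as.integer(round(events$times * fs)) + 1L
  centers <- centers[centers - hw >= 1 & centers + hw <= n]
  if (length(centers) == 0)
    stop("no usable events inside the record", call. = FALSE)
  acc <- matrix(0, nrow(signals), 2 * hw + 1)
  for (c0 in centers) acc <- acc + signals[, (c0 - hw):(c0 + hw), drop = FALSE]
  structure(list(
    lags = seq(-hw, hw) / fs, mean = acc / length(centers),
    n_events = length(centers),
    channel_ids = rownames(signals) %||% paste0("ch", seq_len(nrow(signals)))
  ), class = "smta")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Remove task-locked components from per-trial sections
#'
#' Subtracts the across-trial mean profile from each equal-length section
#' and concatenates the residuals, leaving no consistent low-frequency
#' component tied to the trial cycle.
#'
#' @param sections numeric matrix, one section per row.
#' @return numeric vector of concatenated residuals.
#' @export
remove_task_locked <- function(sections) {
  if (!is.matrix(sections) || nrow(sections) < 2)
    stop("need at least two equal-length sections", call. = FALSE)
  res <- sweep(sections, 2, colMeans(sections))
  as.vector(t(res))
}

#' Welch power, coherence and imaginary-coherence suite
#'
#' Computes Welch auto- and cross-spectra with overlapping Hanning
#' windows (by default 2^round(log2(34 fs)) points, about 34 s, with 75%
#' overlap) and derives: cursor-speed power, per-channel field-potential
#' power averaged over channels, field-potential/cursor coherence
#' averaged over channels, and pairwise imaginary coherence averaged (in
#' magnitude) over channel pairs, with signed pair values stored.  All
#' spectra are smoothed last with a 16-point Hanning window.
#'
#' Coherence uses the standard magnitude-squared estimator
#' \eqn{|S_{ab}|^2/(S_{aa}S_{bb})} with \eqn{S} the window-averaged
#' cross-spectrum; imaginary coherence is
#' \eqn{\mathrm{Im}(S_{ab})/\sqrt{S_{aa}S_{bb}}}.
#'
#' @param lfp channels-by-samples matrix of (residual) field potentials.
#' @param cursor_vel residual cursor-velocity vector, same rate and
#'   length.
#' @param fs sampling rate (Hz).
#' @param nfft window length; defaults to the ~34 s rule above.
#' @param overlap fractional window overlap.
#' @param smooth_points length of the final Hanning smoothing.
#' @return object of class `coherence_suite`: `freqs`, `p_cursor`,
#'   `p_lfp`, `coh_lfp_cursor`, `imcoh_lfp_lfp` (averaged magnitudes),
#'   `imcoh_pairs` (signed, pairs in rows), `meta`.
#' @export
spectral_suite <- function(lfp, cursor_vel, fs, nfft = NULL,
                           overlap = 0.75, smooth_points = 16) {
  if (!is.matrix(lfp)) lfp <- matrix(lfp, nrow = 1)
  n <- ncol(lfp)
  stopifnot(length(cursor_vel) == n)
  if (is.null(nfft)) nfft <- 2^round(log2(34 * fs))
  if (n < nfft)
    stop("record shorter than one spectral window", call. = FALSE)
  hop <- max(1L, as.integer(round(nfft * (1 - overlap))))
  starts <- seq(1L, n - nfft + 1L, by = hop)
  m <- length(starts)
  win <- hanning_window(nfft)
  nb <- nfft %/% 2
  nc <- nrow(lfp)

  # Fourier coefficients: windows in columns
  fc <- function(x) {
    out <- matrix(0 + 0i, nb, m)
    for (j in seq_len(m)) {
      seg <- x[starts[j]:(starts[j] + nfft - 1L)]
      out[, j] <- stats::fft((seg - mean(seg)) * win)[2:(nb + 1)]
    }
    out
  }
  f_cur <- fc(cursor_vel)
  f_lfp <- lapply(seq_len(nc), function(i) fc(lfp[i, ]))

  avg <- function(a, b) rowMeans(a * Conj(b))
  s_cc <- Re(avg(f_cur, f_cur))
  s_ll <- lapply(f_lfp, function(f) Re(avg(f, f)))
  p_lfp <- Reduce(`+`, s_ll) / nc

  coh <- vapply(seq_len(nc), function(i) {
    Mod(avg(f_lfp[[i]], f_cur))^2 / (s_ll[[i]] * s_cc)
  }, numeric(nb))
  coh_mean <- rowMeans(coh)

  pairs <- utils::combn(nc, 2)
  imcoh_pairs <- t(vapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    Im(avg(f_lfp[[i]], f_lfp[[j]])) / sqrt(s_ll[[i]] * s_ll[[j]])
  }, numeric(nb)))
  sm <- function(x) hanning_smooth(x, smooth_points)
  # smooth each pair's signed spectrum before taking magnitudes: the sign
  # of a pair's coupling is arbitrary (it depends on electrode geometry),
  # but rectifying unsmoothed estimates would floor the average at the
  # estimator noise level
  imcoh_mean <- colMeans(abs(t(apply(imcoh_pairs, 1, sm))))
  u <- sum(win^2) / nfft                       # window power normalization
  scale <- 1 / (fs * nfft * u)
  df <- fs / nfft
  structure(list(
    freqs = (1:nb) * df,
    p_cursor = sm(2 * s_cc * scale),
    p_lfp = sm(2 * p_lfp * scale),
    coh_lfp_cursor = sm(coh_mean),
    imcoh_lfp_lfp = imcoh_mean,
    imcoh_pairs = imcoh_pairs,
    meta = list(nfft = nfft, overlap = overlap, taper = "hanning",
                smoothing = sprintf("%d-point hanning", smooth_points),
                n_windows = m, fs = fs)
  ), class = "coherence_suite")
}

hanning_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))

# smooth with a normalized Hanning kernel; edges renormalized
hanning_smooth <- function(x, k = 16) {
  if (k < 2) return(x)
  ker <- hanning_window(k)
  ker <- ker / sum(ker)
  num <- stats::filter(x, ker, sides = 2)
  den <- stats::filter(rep(1, length(x)), ker, sides = 2)
  out <- as.numeric(num / den)
  na <- is.na(out)
  if (any(na)) {            # edge bins: renormalize over the in-range kernel
    h <- k %/% 2
    for (i in which(na)) {
      lo <- max(1, i - h); hi <- min(length(x), i + (k - 1 - h))
      kk <- ker[(lo - i + h + 1):(hi - i + h + 1)]
      out[i] <- sum(x[lo:hi] * kk) / sum(kk)
    }
  }
  out
}

#' @export
print.coherence_suite <- function(x, ...) {
  cat(sprintf("Spectral suite: %d bins (df = %.4g Hz), %d windows of %d points\n",
              length(x$freqs), x$freqs[1], x$meta$n_windows, x$meta$nfft))
  invisible(x)
}

#' Principal components of multichannel field potentials
#'
#' Eigendecomposition of the channel covariance of (centered, typically
#' low-passed) field potentials.  Components are ordered by explained
#' variance and their signs fixed so each component's largest-magnitude
#' loading is positive; the trajectory is the projection onto the top two
#' components.
#'
#' @param lfp channels-by-samples matrix (>= 2 channels).
#' @return object of class `lfp_pca`: `loadings` (channels x components),
#'   `scores` (samples x components), `var_explained`, `trajectory`
#'   (samples x 2).
#' @export
lfp_pca <- function(lfp) {
  if (!is.matrix(lfp) || nrow(lfp) < 2)
    stop("need at least two channels", call. = FALSE)
  pc <- stats::prcomp(t(lfp), center = TRUE, scale. = FALSE)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    v <- pc$rotation[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  loadings <- sweep(pc$rotation, 2, flip, `*`)
  scores <- sweep(pc$x, 2, flip, `*`)
  structure(list(
    loadings = loadings, scores = scores,
    var_explained = pc$sdev^2 / sum(pc$sdev^2),
    trajectory = scores[, 1:2, drop = FALSE]
  ), class = "lfp_pca")
}

#' Project field potentials onto an existing component plane
#'
#' Reuses the loadings of a previously computed [lfp_pca()] (for
#' instance, the no-delay block's plane) so trajectories from different
#' delay conditions or from impulse-response simulations are directly
#' comparable.
#'
#' @param lfp channels-by-samples matrix with the same channel order as
#'   the PCA input.
#' @param pca an `lfp_pca`.
#' @return samples x 2 matrix of projections onto the first two
#'   components.
#' @export
project_on_pcs <- function(lfp, pca) {
  x <- sweep(t(lfp), 2, rowMeans(lfp))
  (x %*% pca$loadings)[, 1:2, drop = FALSE]
}

#' Net rotation direction of a 2D trajectory
#'
#' Sign of the accumulated cross product of successive displacement
#' vectors about the trajectory centroid: +1 for counterclockwise, -1
#' for clockwise.
#'
#' @param traj n x 2 matrix.
#' @return +1 or -1 (0 for a degenerate trajectory).
#' @export
rotation_direction <- function(traj) {
  p <- sweep(traj, 2, colMeans(traj))
  x <- p[, 1]; y <- p[, 2]
  n <- nrow(p)
  area <- sum(x[-n] * y[-1] - x[-1] * y[-n])
  sign(area)
}
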