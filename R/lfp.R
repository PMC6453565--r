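#' Spectrally shaped 1/f background noise
#'
#' White Gaussian noise shaped in the frequency domain with amplitude
#' proportional to \eqn{f^{-1/2}} (i.e. 1/f power), zero DC component,
#' rescaled to unit standard deviation.  Used as the common background
#' shared by all simulated field-potential channels, standing in for
#' volume conduction from distant sources.
#'
#' @param n number of samples.
#' @param fs sampling rate (Hz).
#' @param seed integer seed.
#' @return numeric vector of length `n`, unit SD.
#' @export
one_over_f_noise <- function(n, fs, seed) {
  set.seed(seed)
  x <- stats::rnorm(n)
  xf <- stats::fft(x)
  f <- seq(0, n - 1) / n * fs
  f[f > fs / 2] <- fs - f[f > fs / 2]          # two-sided frequency axis
  shape <- ifelse(f > 0, 1 / sqrt(f), 0)
  y <- Re(stats::fft(xf * shape, inverse = TRUE)) / n
  y / stats::sd(y)
}

#' Synthesize field-potential channels from estimator synaptic inputs
#'
#' The two latent components are the per-step synaptic inputs to the
#' position and velocity populations of the state estimator (`d_xhat`,
#' `d_vhat`), each normalized to unit variance.  With `n_channels = 2` and
#' no mixing the channels are exactly these components plus one shared
#' 1/f background.  With more channels, each channel mixes the two
#' components with a channel-specific gain and phase (a seeded rotation in
#' the component plane), emulating a multi-electrode array that sees the
#' same two underlying populations from different vantage points, plus the
#' shared background and independent per-channel white noise.
#'
#' @param trace a `sim_trace` containing `d_xhat` and `d_vhat`.
#' @param common_1f_amplitude SD of the shared 1/f background, in units of
#'   the (unit) component SD.
#' @param per_channel_noise SD of independent white noise added per
#'   channel.
#' @param n_channels number of channels (>= 2).
#' @param mixing_seed integer seed for the channel gains/phases (fix it
#'   across blocks of a session to emulate a fixed electrode array).
#' @param noise_seed integer seed for the 1/f background and the
#'   per-channel noise; defaults to `mixing_seed`.
#' @param hp_cutoff optional acquisition high-pass cutoff (Hz) applied to
#'   the synaptic-input components before variance normalization
#'   (2nd-order zero-phase Butterworth).  In closed loop the
#'   position-population input inherits the slow random-walk drift of the
#'   motor error, which in a real recording chain is removed by AC
#'   coupling; high-passing before normalization lets the delta-band
#'   content of the components carry the channel variance, as it does in
#'   recorded field potentials.  `NULL` (the default) applies no filter.
#' @return numeric matrix `n_channels x n_samples`, with attributes
#'   `mixing` (the `n_channels x 2` mixing matrix) and `fs`.
#' @export
synthesize_lfp <- function(trace, common_1f_amplitude = 0.5,
                           per_channel_noise = 0.3, n_channels = 2,
                           mixing_seed = trace$config$seed + 1L,
                           noise_seed = mixing_seed,
                           hp_cutoff = NULL) {
  s1 <- stats::sd(trace$d_xhat)
  s2 <- stats::sd(trace$d_vhat)
  if (s1 == 0 || s2 == 0)
    stop("degenerate input: synaptic-input series have zero variance",
         call. = FALSE)
  n <- length(trace$d_xhat)
  d1 <- trace$d_xhat
  d2 <- trace$d_vhat
  if (!is.null(hp_cutoff) && hp_cutoff > 0) {
    bf <- signal::butter(2, hp_cutoff / (trace$fs / 2), type = "high")
    d1 <- signal::filtfilt(bf, d1)
    d2 <- signal::filtfilt(bf, d2)
  }
  c1 <- (d1 - mean(d1)) / stats::sd(d1)
  c2 <- (d2 - mean(d2)) / stats::sd(d2)
  common <- if (common_1f_amplitude > 0) {
    common_1f_amplitude * one_over_f_noise(n, trace$fs, noise_seed)
  } else numeric(n)

  if (n_channels == 2) {
    mix <- diag(2)
  } else {
    set.seed(mixing_seed)
    gain <- stats::runif(n_channels, 0.8, 1.2)
    phase <- stats::runif(n_channels, 0, 2 * pi)
    mix <- cbind(gain * cos(phase), gain * sin(phase))
  }
  lfp <- mix %*% rbind(c1, c2)
  lfp <- sweep(lfp, 2, common, `+`)
  if (per_channel_noise > 0) {
    set.seed(noise_seed + 1L)
    lfp <- lfp + matrix(stats::rnorm(length(lfp), 0, per_channel_noise),
                        nrow = n_channels)
  }
  rownames(lfp) <- paste0("ch", seq_len(n_channels))
  attr(lfp, "mixing") <- mix
  attr(lfp, "fs") <- trace$fs
  lfp
}
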