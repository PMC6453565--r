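#' Full neural analysis of a synthetic monkey session
#'
#' Runs the complete monkey-side chain on every delay block: channel
#' centering and zero-phase 10 Hz filtering, submovement detection on the
#' filtered radial speed, submovement-triggered averages of cursor speed,
#' field potentials and their principal-component projections, task-locked
#' removal of per-trial sections, and the Welch power/coherence/
#' imaginary-coherence suite on the residuals.
#'
#' The component plane is computed once, from the low-passed potentials
#' of the no-delay block (or the first block if none has zero delay), and
#' reused for every condition so that trajectories are comparable across
#' delays and with impulse-response simulations.
#'
#' @param session a monkey `trial_set` from [generate_monkey_session()].
#' @param threshold submovement peak-speed threshold (%/s).
#' @param half_window SmTA half-window (s).
#' @param channel_mask optional logical channel mask.
#' @return object of class `monkey_analysis`: `pca` (the shared
#'   [lfp_pca()]), and `blocks`, one entry per delay block with
#'   `tau_ext`, `events`, `smta_speed`, `smta_lfp`, `smta_pc`, and
#'   `suite` (a `coherence_suite`).
#' @export
analyze_monkey_session <- function(session, threshold = 100,
                                   half_window = 0.5, channel_mask = NULL) {
  stopifnot(inherits(session, "trial_set"), !is.null(session$blocks))
  preps <- lapply(session$blocks, preprocess_block,
                  channel_mask = channel_mask)
  delays <- vapply(session$blocks, function(b) b$tau_ext, 1)
  ref <- if (any(delays == 0)) which(delays == 0)[1] else 1L
  pca <- lfp_pca(preps[[ref]]$lfp_filt)

  blocks <- lapply(seq_along(session$blocks), function(i) {
    blk <- session$blocks[[i]]
    prep <- preps[[i]]
    # remove the stereotyped reach profile from the speed before event
    # detection and averaging, so submovements are not confounded with
    # task-locked reach transients
    ntl <- as.integer(round(blk$trial_duration * prep$fs))
    sections <- matrix(prep$speed[seq_len(blk$n_trials * ntl)],
                       nrow = blk$n_trials, byrow = TRUE)
    speed_res <- lowpass_filter(remove_task_locked(sections), prep$fs, 10)
    events <- detect_submovements(speed_res, prep$fs, threshold)
    traj <- project_on_pcs(prep$lfp_filt, pca)
    list(
      tau_ext = blk$tau_ext,
      events = events,
      smta_speed = smta(speed_res, prep$fs, events, half_window),
      smta_lfp = smta(prep$lfp_filt, prep$lfp_fs, events, half_window),
      smta_pc = smta(t(traj), prep$lfp_fs, events, half_window),
      suite = block_spectral_suite(blk, prep)
    )
  })
  structure(list(pca = pca, blocks = blocks,
                 threshold = threshold, half_window = half_window),
            class = "monkey_analysis")
}

# per-trial sectioning, task-locked removal, and the Welch suite for one
# block; frequency-domain products use the unfiltered centered potentials
block_spectral_suite <- function(blk, prep) {
  sec <- blk$section_samples
  ntl <- as.integer(round(blk$trial_duration * blk$lfp_fs))
  if (sec > ntl) stop("section longer than a trial", call. = FALSE)
  sec_idx <- function(j) ((j - 1) * ntl + ntl - sec + 1):((j - 1) * ntl + ntl)
  sections_of <- function(x) {
    t(vapply(seq_len(blk$n_trials), function(j) x[sec_idx(j)], numeric(sec)))
  }
  lfp_res <- t(apply(prep$lfp_raw, 1,
                     function(ch) remove_task_locked(sections_of(ch))))
  speed_hi <- as.numeric(resample_rows(matrix(prep$speed, nrow = 1),
                                       prep$fs, blk$lfp_fs))
  speed_hi <- speed_hi[seq_len(blk$n_trials * ntl)]
  cur_res <- remove_task_locked(sections_of(speed_hi))
  spectral_suite(lfp_res, cur_res, blk$lfp_fs)
}

#' Latency of the delayed second feature across delay blocks
#'
#' A submovement in one direction pools two causes: a correction to a
#' preceding error (cortical activity near lag zero) and an error whose
#' correction follows one loop delay later.  The triggered average
#' therefore contains a second, polarity-reversed copy of the central
#' feature whose latency tracks the loop delay.  Because the central
#' feature and the delay-independent intrinsic cycle are common to all
#' delay conditions, each block's curve first has the across-block mean
#' subtracted; the residual is then matched-filtered with that block's
#' own sharp central template, and the latency of the strongest
#' polarity-reversed match is returned.
#'
#' @param analysis a `monkey_analysis` from [analyze_monkey_session()].
#' @param template_halfwidth half-width (s) of the central template.
#' @param search length-2 latency range (s) to scan.
#' @return data frame with columns `tau_ext` and `latency` (s).
#' @export
smta_second_feature <- function(analysis, template_halfwidth = 0.05,
                                search = c(0.12, 1.15)) {
  stopifnot(inherits(analysis, "monkey_analysis"))
  curves <- lapply(analysis$blocks, function(b) b$smta_pc$mean)
  avg <- Reduce(`+`, curves) / length(curves)
  lags <- analysis$blocks[[1]]$smta_pc$lags
  ctr <- which(abs(lags) <= template_halfwidth)
  half <- (length(ctr) - 1) %/% 2
  sel <- which(lags >= search[1] & lags <= search[2] &
               seq_along(lags) + half <= length(lags))
  lat <- vapply(seq_along(curves), function(i) {
    res <- curves[[i]] - avg
    tpl <- curves[[i]][, ctr, drop = FALSE]
    score <- vapply(sel, function(i0)
      sum(tpl * res[, (i0 - half):(i0 + half), drop = FALSE]), 1)
    lags[sel[which.min(score)]]
  }, 1)
  data.frame(tau_ext = vapply(analysis$blocks, function(b) b$tau_ext, 1),
             latency = lat)
}

#' Characteristic frequency of a spectral feature within a band
#'
#' `method = "max"` returns the frequency of the largest value in the
#' band.  `method = "centroid"` returns the power-weighted mean frequency
#' of the region where the spectrum exceeds `level` times its band
#' maximum -- a low-variance estimator of the resonance frequency of
#' broad, flat-topped features (such as the delta-band imaginary
#' coherence), for which the argmax jitters across near-tied bins.
#'
#' @param freqs frequency grid (Hz).
#' @param vals spectral values.
#' @param band length-2 band (Hz).
#' @param method `"max"` or `"centroid"`.
#' @param level centroid threshold as a fraction of the band maximum.
#' @return frequency (Hz).
#' @export
peak_frequency <- function(freqs, vals, band = c(0.5, 6),
                           method = c("max", "centroid"), level = 0.5) {
  method <- match.arg(method)
  keep <- freqs >= band[1] & freqs <= band[2]
  if (!any(keep)) stop("empty band", call. = FALSE)
  f <- freqs[keep]; v <- vals[keep]
  if (method == "max") return(f[which.max(v)])
  top <- v >= level * max(v)
  sum(f[top] * v[top]) / sum(v[top])
}
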