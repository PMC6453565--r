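#' Generate a synthetic human tracking session
#'
#' Wraps the 1D closed-loop simulation into the circular task geometry.
#' Each trial runs the controller at its own extrinsic delay with a fresh
#' child seed; the simulated force deviation (motor command plus
#' integrated noise, in task % along the trajectory) becomes the angular
#' coordinate of the force, `theta_force = direction * w_target * t +
#' error / r_target`, with the radial coordinate held at the target
#' radius.  The displayed cursor composes the delayed force with the
#' perturbation offset, exactly as the task equations state, and the same
#' perturbation enters the simulated measurement path.
#'
#' Profiles: `"exp1"` yields 70 trials, 14 at each extrinsic delay in
#' `cfg$delay_conditions`, no perturbation; `"exp2"` yields 144 trials,
#' 12 per cell of perturbation frequency (0-5 Hz) crossed with delays
#' {0, 0.2} s.  Schedules and rotation directions are seeded pseudorandom
#' permutations (directions balanced), so the same seed reproduces the
#' session exactly.
#'
#' @param cfg a [task_config()]; `cfg$fs` must divide the model rate
#'   `1/model_cfg$dt`.
#' @param model_cfg an [ofc_config()] template; `tau_ext`, `duration` and
#'   `seed` are overridden per trial.
#' @param profile `"exp1"` or `"exp2"`.
#' @param seed session seed.
#' @return object of class `trial_set` with fields `trials` (list of
#'   trial recordings), `schedule` (data frame), `species_profile`,
#'   `seed`, `task_cfg`, `model_cfg`.
#' @export
generate_human_session <- function(cfg, model_cfg, profile = c("exp1", "exp2"),
                                   seed = 1L) {
  profile <- match.arg(profile)
  stopifnot(inherits(cfg, "task_config"), inherits(model_cfg, "ofc_config"))
  model_fs <- 1 / model_cfg$dt
  m <- model_fs / cfg$fs
  if (abs(m - round(m)) > 1e-9)
    stop("behavioral rate must divide the model rate", call. = FALSE)
  m <- as.integer(round(m))

  if (profile == "exp1") {
    cells <- expand.grid(tau_ext = cfg$delay_conditions, f_pert = 0)
    n_rep <- 14L
  } else {
    cells <- expand.grid(tau_ext = c(0, 0.2), f_pert = cfg$pert_freqs)
    n_rep <- 12L
  }
  cond <- cells[rep(seq_len(nrow(cells)), each = n_rep), , drop = FALSE]
  set.seed(child_seed(seed, 0))
  ord <- sample.int(nrow(cond))
  cond <- cond[ord, , drop = FALSE]
  n_trials <- nrow(cond)
  direction <- sample(rep(c("ccw", "cw"), length.out = n_trials))
  schedule <- data.frame(trial = seq_len(n_trials),
                         tau_ext = cond$tau_ext, f_pert = cond$f_pert,
                         direction = direction,
                         seed = vapply(seq_len(n_trials),
                                       function(i) child_seed(seed, i), 1L),
                         row.names = NULL)

  t_model <- (seq_len(cfg$trial_duration * model_fs) - 1) * model_cfg$dt
  keep <- seq(1, length(t_model), by = m)
  wt <- 2 * pi * cfg$f_target
  # band-limited decimation to the behavioral rate: the broadband
  # measurement-noise feedthrough in the force velocity would otherwise
  # alias into the submovement band
  decimate_err <- function(x) {
    if (m == 1L) return(x)
    as.numeric(resample_rows(matrix(x, nrow = 1), model_fs, cfg$fs))
  }

  trials <- lapply(seq_len(n_trials), function(i) {
    sc <- schedule[i, ]
    tc <- ofc_config(dt = model_cfg$dt, tau_int = model_cfg$tau_int,
                     tau_ext = sc$tau_ext, rho = model_cfg$rho,
                     sigma_eps = model_cfg$sigma_eps,
                     sigma_a = model_cfg$sigma_a,
                     q = model_cfg$q, r = model_cfg$r,
                     duration = cfg$trial_duration, seed = sc$seed)
    s <- dir_sign(sc$direction)
    # the along-track error coordinate is signed by the rotation
    # direction, so the displayed angular perturbation enters the loop
    # with the trial's direction sign
    pert_model <- if (sc$f_pert > 0) {
      wp <- 2 * pi * sc$f_pert
      s * cfg$r_target * (wt / wp) * sin(wp * t_model)
    } else NULL
    tr <- simulate_tracking(tc, pert = pert_model)
    t <- t_model[keep]
    err <- decimate_err(tr$cursor)[seq_along(t)]
    theta_force <- s * wt * t + err / cfg$r_target
    force_xy <- cfg$r_target * cbind(x = cos(theta_force),
                                     y = sin(theta_force))
    pert_xy <- if (sc$f_pert > 0) {
      perturbation_offset(t, sc$f_pert, cfg, sc$direction)
    } else NULL
    cursor_xy <- compose_cursor(force_xy, pert_xy, sc$tau_ext, cfg$fs)
    structure(list(
      condition = list(tau_ext = sc$tau_ext, f_pert = sc$f_pert,
                       direction = sc$direction),
      t = t, target_xy = target_trajectory(t, cfg, sc$direction),
      cursor_xy = cursor_xy, force_xy = force_xy,
      theta_force = theta_force,
      theta_cursor = signal::unwrap(atan2(cursor_xy[, 2], cursor_xy[, 1])),
      fs = cfg$fs
    ), class = "trial_recording")
  })

  structure(list(trials = trials, schedule = schedule,
                 species_profile = paste0("human-", profile),
                 seed = as.integer(seed), task_cfg = cfg,
                 model_cfg = model_cfg),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("Synthetic session (%s, seed %d): ", x$species_profile, x$seed))
  if (!is.null(x$trials)) {
    cat(sprintf("%d trials of %g s at %g samples/s\n",
                length(x$trials), x$task_cfg$trial_duration, x$task_cfg$fs))
  } else {
    cat(sprintf("%d delay blocks\n", length(x$blocks)))
  }
  invisible(x)
}

#' Generate a synthetic monkey session with multichannel field potentials
#'
#' Emulates a center-out isometric session in delay blocks.  Each block
#' runs one continuous closed-loop simulation at the model rate; the
#' radial torque trajectory is a per-trial reach profile (smooth rise to
#' 70% of full scale, hold, and return) plus the scaled simulated tracking
#' error, so radial speed carries submovements.  Twelve field-potential
#' channels are synthesized from the estimator's synaptic inputs with
#' channel-specific mixing and a shared 1/f background, then resampled to
#' `lfp_fs` by band-limited (polyphase) interpolation.
#'
#' @param cfg a [task_config()] (only the torque scale is consulted).
#' @param model_cfg an [ofc_config()] template.
#' @param seed session seed.
#' @param delays extrinsic delay per block (s).
#' @param n_trials trials per block.
#' @param trial_duration seconds per trial.
#' @param lfp_fs field-potential sampling rate (Hz).
#' @param n_channels number of channels.
#' @param error_scale task % of radial displacement per model position
#'   unit; the default of 2 gives radial speed fluctuations around
#'   115 %/s SD, producing submovement rates comparable to real sessions
#'   under the default threshold of 100 %/s.
#' @param section_samples samples (at `lfp_fs`) of the per-trial section
#'   used for frequency-domain analysis; sections are taken from the end
#'   of each trial (about 1.5 s before to 0.5 s after the end of the
#'   peripheral hold).
#' @param common_1f_amplitude,per_channel_noise,hp_cutoff passed to
#'   [synthesize_lfp()]; the default 0.5 Hz acquisition high-pass
#'   emulates the AC coupling of a recording chain.
#' @return object of class `trial_set` with `blocks`: each block holds
#'   `tau_ext`, model-rate `t` and `radial` (task %), the `lfp` matrix
#'   (`n_channels x samples`) with `lfp_fs`, trial bookkeeping, and the
#'   mixing matrix used for its channels.
#' @export
generate_monkey_session <- function(cfg, model_cfg, seed = 1L,
                                    delays = c(0, 0.2, 0.4, 0.6),
                                    n_trials = 50, trial_duration = 3,
                                    lfp_fs = 488, n_channels = 12,
                                    error_scale = 2, section_samples = 1024,
                                    common_1f_amplitude = 0.5,
                                    per_channel_noise = 0.3,
                                    hp_cutoff = 0.5) {
  stopifnot(inherits(cfg, "task_config"), inherits(model_cfg, "ofc_config"))
  model_fs <- 1 / model_cfg$dt
  dur <- n_trials * trial_duration
  profile1 <- reach_profile(trial_duration, model_fs)

  blocks <- lapply(seq_along(delays), function(b) {
    bc <- ofc_config(dt = model_cfg$dt, tau_int = model_cfg$tau_int,
                     tau_ext = delays[b], rho = model_cfg$rho,
                     sigma_eps = model_cfg$sigma_eps,
                     sigma_a = model_cfg$sigma_a,
                     q = model_cfg$q, r = model_cfg$r,
                     duration = dur, seed = child_seed(seed, b))
    tr <- simulate_tracking(bc)
    radial <- rep(profile1, n_trials) + error_scale * tr$cursor
    lfp_model <- synthesize_lfp(tr, common_1f_amplitude = common_1f_amplitude,
                                per_channel_noise = per_channel_noise,
                                n_channels = n_channels,
                                mixing_seed = child_seed(seed, 100),
                                noise_seed = child_seed(seed, 200 + b),
                                hp_cutoff = hp_cutoff)
    lfp <- resample_rows(lfp_model, model_fs, lfp_fs)
    structure(list(
      tau_ext = delays[b], fs = model_fs, t = tr$t, radial = radial,
      lfp = lfp, lfp_fs = lfp_fs, n_trials = n_trials,
      trial_duration = trial_duration, section_samples = section_samples,
      mixing = attr(lfp_model, "mixing"), model_seed = bc$seed
    ), class = "monkey_block")
  })

  structure(list(blocks = blocks, species_profile = "monkey",
                 seed = as.integer(seed), task_cfg = cfg,
                 model_cfg = model_cfg,
                 schedule = data.frame(block = seq_along(delays),
                                       tau_ext = delays)),
            class = "trial_set")
}

# smooth center-out reach: rise to 70% over 0.5 s, hold, return over the
# final 0.5 s
reach_profile <- function(trial_duration, fs) {
  t <- (seq_len(trial_duration * fs) - 1) / fs
  amp <- 70
  up <- pmin(t / 0.5, 1)
  down <- pmin(pmax((trial_duration - t) / 0.5, 0), 1)
  amp * (1 - cos(pi * up)) / 2 * (1 - cos(pi * down)) / 2
}

# band-limited resampling of each row of a matrix between integer rates
resample_rows <- function(x, fs_in, fs_out) {
  if (fs_in == fs_out) return(x)
  g <- gcd_int(round(fs_out), round(fs_in))
  p <- round(fs_out) / g
  q <- round(fs_in) / g
  out <- t(apply(x, 1, function(row) signal::resample(row, p, q)))
  attr(out, "fs") <- fs_out
  out
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)
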