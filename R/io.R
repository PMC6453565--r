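SCHEMA_VERSION <- "1"

#' Write an analysis product to disk
#'
#' Products are stored as plain-text columnar tables with a JSON sidecar
#' holding class, units and configuration metadata, so every domain
#' object round-trips losslessly through [read_product()].  Simulation
#' traces and tabular products write `<path>.csv` + `<path>.json`;
#' trial sets write a directory with a `manifest.json` and one table per
#' trial or block.
#'
#' @param x a `sim_trace`, `trial_set`, `velocity_spectrum`,
#'   `peak_regression`, or `coherence_suite`.
#' @param path file prefix (no extension) or, for trial sets, a
#'   directory.
#' @return `path`, invisibly.
#' @export
write_product <- function(x, path) UseMethod("write_product")

sidecar <- function(path, meta) {
  meta$schema_version <- SCHEMA_VERSION
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
}

write_table <- function(df, path) {
  utils::write.csv(df, paste0(path, ".csv"), row.names = FALSE)
}

#' @export
write_product.sim_trace <- function(x, path) {
  write_table(as.data.frame(x), path)
  sidecar(path, list(class = "sim_trace", fs = x$fs,
                     config = unclass(x$config),
                     units = list(position = "task %", time = "s")))
  invisible(path)
}

#' @export
write_product.velocity_spectrum <- function(x, path) {
  write_table(data.frame(freq = x$freqs, power = x$power), path)
  sidecar(path, list(class = "velocity_spectrum", meta = x$meta,
                     units = list(freq = "Hz", power = "(rad/s)^2/Hz")))
  invisible(path)
}

#' @export
write_product.peak_regression <- function(x, path) {
  write_table(x$points, path)
  sidecar(path, list(class = "peak_regression", harmonic_n = x$harmonic_n,
                     slope = x$slope, intercept = x$intercept,
                     ci95_slope = x$ci95_slope,
                     ci95_intercept = x$ci95_intercept,
                     r2 = x$r2, p = x$p, tau_int_est = x$tau_int_est,
                     n = x$n, units = list(period = "s", tau_ext = "s")))
  invisible(path)
}

#' @export
write_product.coherence_suite <- function(x, path) {
  write_table(data.frame(freq = x$freqs, p_cursor = x$p_cursor,
                         p_lfp = x$p_lfp,
                         coh_lfp_cursor = x$coh_lfp_cursor,
                         imcoh_lfp_lfp = x$imcoh_lfp_lfp), path)
  sidecar(path, list(class = "coherence_suite", meta = x$meta,
                     units = list(freq = "Hz")))
  invisible(path)
}

#' @export
write_product.trial_set <- function(x, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(x$trials)) {
    for (i in seq_along(x$trials)) {
      tr <- x$trials[[i]]
      write_table(data.frame(
        t = tr$t,
        target_x = tr$target_xy[, 1], target_y = tr$target_xy[, 2],
        cursor_x = tr$cursor_xy[, 1], cursor_y = tr$cursor_xy[, 2],
        force_x = tr$force_xy[, 1], force_y = tr$force_xy[, 2],
        theta_force = tr$theta_force, theta_cursor = tr$theta_cursor
      ), file.path(path, sprintf("trial_%03d", i)))
    }
  }
  if (!is.null(x$blocks)) {
    for (b in seq_along(x$blocks)) {
      blk <- x$blocks[[b]]
      write_table(data.frame(t = blk$t, radial = blk$radial),
                  file.path(path, sprintf("block_%d_radial", b)))
      utils::write.csv(as.data.frame(t(blk$lfp)),
                       file.path(path, sprintf("block_%d_lfp.csv", b)),
                       row.names = FALSE)
    }
  }
  manifest <- list(
    class = "trial_set", species_profile = x$species_profile,
    seed = x$seed, schedule = x$schedule,
    task_cfg = unclass(x$task_cfg), model_cfg = unclass(x$model_cfg),
    blocks = if (!is.null(x$blocks)) lapply(x$blocks, function(blk) {
      blk[c("tau_ext", "fs", "lfp_fs", "n_trials", "trial_duration",
            "section_samples", "model_seed")]
    }),
    units = list(position = "task %", angle = "rad", time = "s"),
    schema_version = SCHEMA_VERSION
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read an analysis product written by [write_product()]
#'
#' @param path the prefix or directory given to [write_product()].
#' @return the reconstructed object.
#' @export
read_product <- function(path) {
  if (dir.exists(path)) return(read_trial_set(path))
  sc <- paste0(path, ".json")
  if (!file.exists(sc))
    stop("schema error: sidecar ", sc, " not found", call. = FALSE)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (!identical(as.character(meta$schema_version), SCHEMA_VERSION))
    stop("schema error: version mismatch", call. = FALSE)
  tab <- utils::read.csv(paste0(path, ".csv"))
  switch(meta$class,
    sim_trace = {
      cfgl <- meta$config
      cfg <- ofc_config(dt = cfgl$dt, tau_int = cfgl$tau_int,
                        tau_ext = cfgl$tau_ext, rho = cfgl$rho,
                        sigma_eps = cfgl$sigma_eps, sigma_a = cfgl$sigma_a,
                        q = cfgl$q, r = cfgl$r, duration = cfgl$duration,
                        seed = cfgl$seed)
      out <- as.list(tab[c("t", "a", "x", "y", "y_smith", "u", "cursor",
                           "x_hat", "v_hat", "z", "d_xhat", "d_vhat")])
      out$fs <- meta$fs
      out$config <- cfg
      out$pert <- tab$pert
      structure(out, class = "sim_trace")
    },
    velocity_spectrum = structure(
      list(freqs = tab$freq, power = tab$power, meta = meta$meta),
      class = "velocity_spectrum"),
    peak_regression = structure(
      list(harmonic_n = meta$harmonic_n, points = tab, slope = meta$slope,
           intercept = meta$intercept, ci95_slope = meta$ci95_slope,
           ci95_intercept = meta$ci95_intercept, r2 = meta$r2, p = meta$p,
           tau_int_est = meta$tau_int_est, n = meta$n),
      class = "peak_regression"),
    coherence_suite = structure(
      list(freqs = tab$freq, p_cursor = tab$p_cursor, p_lfp = tab$p_lfp,
           coh_lfp_cursor = tab$coh_lfp_cursor,
           imcoh_lfp_lfp = tab$imcoh_lfp_lfp, meta = meta$meta),
      class = "coherence_suite"),
    stop("schema error: unknown product class ", meta$class, call. = FALSE)
  )
}

read_trial_set <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf))
    stop("schema error: manifest.json not found in ", path, call. = FALSE)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(as.character(meta$schema_version), SCHEMA_VERSION))
    stop("schema error: version mismatch", call. = FALSE)
  tc <- meta$task_cfg
  task_cfg <- task_config(f_target = tc$f_target, r_target = tc$r_target,
                          fs = tc$fs, trial_duration = tc$trial_duration,
                          delta = tc$delta,
                          delay_conditions = tc$delay_conditions,
                          pert_freqs = tc$pert_freqs,
                          torque_full_scale = tc$torque_full_scale)
  mc <- meta$model_cfg
  model_cfg <- ofc_config(dt = mc$dt, tau_int = mc$tau_int,
                          tau_ext = mc$tau_ext, rho = mc$rho,
                          sigma_eps = mc$sigma_eps, sigma_a = mc$sigma_a,
                          q = mc$q, r = mc$r, duration = mc$duration,
                          seed = mc$seed)
  schedule <- as.data.frame(meta$schedule)
  out <- list(schedule = schedule, species_profile = meta$species_profile,
              seed = meta$seed, task_cfg = task_cfg, model_cfg = model_cfg)
  if (startsWith(meta$species_profile, "human")) {
    files <- sort(list.files(path, pattern = "^trial_\\d+\\.csv$"))
    out$trials <- lapply(seq_along(files), function(i) {
      tab <- utils::read.csv(file.path(path, files[i]))
      sc <- schedule[i, ]
      structure(list(
        condition = list(tau_ext = sc$tau_ext, f_pert = sc$f_pert,
                         direction = sc$direction),
        t = tab$t,
        target_xy = cbind(x = tab$target_x, y = tab$target_y),
        cursor_xy = cbind(x = tab$cursor_x, y = tab$cursor_y),
        force_xy = cbind(x = tab$force_x, y = tab$force_y),
        theta_force = tab$theta_force, theta_cursor = tab$theta_cursor,
        fs = task_cfg$fs
      ), class = "trial_recording")
    })
  } else {
    nb <- nrow(as.data.frame(meta$blocks))
    binfo <- as.data.frame(meta$blocks)
    out$blocks <- lapply(seq_len(nb), function(b) {
      rad <- utils::read.csv(file.path(path, sprintf("block_%d_radial.csv", b)))
      lfp <- t(as.matrix(utils::read.csv(
        file.path(path, sprintf("block_%d_lfp.csv", b)))))
      rownames(lfp) <- paste0("ch", seq_len(nrow(lfp)))
      structure(list(
        tau_ext = binfo$tau_ext[b], fs = binfo$fs[b], t = rad$t,
        radial = rad$radial, lfp = lfp, lfp_fs = binfo$lfp_fs[b],
        n_trials = binfo$n_trials[b],
        trial_duration = binfo$trial_duration[b],
        section_samples = binfo$section_samples[b],
        model_seed = binfo$model_seed[b]
      ), class = "monkey_block")
    })
  }
  structure(out, class = "trial_set")
}

#' Run a complete seeded experiment and write its products
#'
#' Generates the synthetic data for one profile, runs the matching
#' analysis chain, and writes all products plus a run manifest to
#' `out_dir`.  Re-running with the same configuration and seed
#' reproduces every product bit for bit.
#'
#' Profiles: `"exp1"` (delay conditions; per-delay velocity spectra,
#' extracted peaks and the period-versus-delay regression), `"exp2"`
#' (delay x perturbation; transfer-function table), `"monkey"` (delay
#' blocks; per-block spectral suites and submovement-triggered
#' averages), `"kcomplex"` (impulse excitation of the disconnected
#' estimator; impulse-response traces and component-plane trajectories,
#' projected on the plane of a companion monkey block).
#'
#' @param profile one of `"exp1"`, `"exp2"`, `"monkey"`, `"kcomplex"`.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed for the whole run.
#' @param task_cfg a [task_config()].
#' @param model_cfg an [ofc_config()] template.
#' @param ... extra arguments passed to the profile's generator.
#' @return the run manifest (list), invisibly; written as
#'   `manifest.json`.
#' @export
run_experiment <- function(profile = c("exp1", "exp2", "monkey", "kcomplex"),
                           out_dir, seed = 1L,
                           task_cfg = task_config(),
                           model_cfg = ofc_config(), ...) {
  profile <- match.arg(profile)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  products <- character(0)
  t0 <- Sys.time()

  if (profile %in% c("exp1", "exp2")) {
    session <- generate_human_session(task_cfg, model_cfg,
                                      profile = profile, seed = seed, ...)
    sdir <- file.path(out_dir, "session")
    write_product(session, sdir)
    products <- c(products, session = sdir)
    if (profile == "exp1") {
      res <- session_peak_periods(session)
      for (d in names(res$spectra)) {
        p <- file.path(out_dir, paste0("spectrum_delay_", d))
        write_product(res$spectra[[d]], p)
        products <- c(products, p)
      }
      write_table(res$peaks, file.path(out_dir, "peaks"))
      if (nrow(res$peaks) >= 2) {
        reg <- regress_period_vs_delay(res$peaks, N = 1)
        p <- file.path(out_dir, "period_regression")
        write_product(reg, p)
        products <- c(products, p)
      }
    } else {
      cells <- unique(session$schedule[session$schedule$f_pert > 0,
                                       c("tau_ext", "f_pert")])
      est <- lapply(seq_len(nrow(cells)), function(i) {
        idx <- which(session$schedule$tau_ext == cells$tau_ext[i] &
                     session$schedule$f_pert == cells$f_pert[i])
        e <- estimate_transfer(session$trials[idx], task_cfg)
        data.frame(tau_ext = e$tau_ext, f_pert = e$f_pert,
                   amp_cursor = e$amp_cursor, amp_force = e$amp_force,
                   phase_force = Arg(e$h_force), tau_phi = e$tau_phi,
                   n_trials = e$n_trials)
      })
      write_table(do.call(rbind, est), file.path(out_dir, "transfers"))
      products <- c(products, file.path(out_dir, "transfers"))
    }
  } else if (profile == "monkey") {
    session <- generate_monkey_session(task_cfg, model_cfg, seed = seed, ...)
    sdir <- file.path(out_dir, "session")
    write_product(session, sdir)
    products <- c(products, sdir)
    ana <- analyze_monkey_session(session)
    for (i in seq_along(ana$blocks)) {
      blk <- ana$blocks[[i]]
      p <- file.path(out_dir, sprintf("suite_block_%d", i))
      write_product(blk$suite, p)
      write_table(data.frame(lag = blk$smta_speed$lags,
                             speed = blk$smta_speed$mean[1, ]),
                  file.path(out_dir, sprintf("smta_speed_block_%d", i)))
      write_table(data.frame(lag = blk$smta_pc$lags,
                             pc1 = blk$smta_pc$mean[1, ],
                             pc2 = blk$smta_pc$mean[2, ]),
                  file.path(out_dir, sprintf("smta_pc_block_%d", i)))
      products <- c(products, p)
    }
  } else {
    # impulse excitation of the disconnected estimator, projected on the
    # component plane of a small companion no-delay block
    kc_cfg <- ofc_config(dt = model_cfg$dt, tau_int = model_cfg$tau_int,
                         tau_ext = 0, rho = model_cfg$rho, q = model_cfg$q,
                         r = model_cfg$r, duration = 4, seed = seed)
    kc <- simulate_kcomplex(kc_cfg, ...)
    p <- file.path(out_dir, "kcomplex_trace")
    write_product(kc, p)
    products <- c(products, p)
    companion <- generate_monkey_session(task_cfg, model_cfg, seed = seed,
                                         delays = 0, n_trials = 10)
    blk <- companion$blocks[[1]]
    pca <- lfp_pca(preprocess_block(blk)$lfp_filt)
    kc_lfp <- blk$mixing %*% rbind(
      scale_unit(kc$d_xhat), scale_unit(kc$d_vhat))
    traj <- project_on_pcs(kc_lfp, pca)
    write_table(data.frame(t = kc$t, pc1 = traj[, 1], pc2 = traj[, 2]),
                file.path(out_dir, "kcomplex_pc_trajectory"))
    products <- c(products, file.path(out_dir, "kcomplex_pc_trajectory"))
  }

  manifest <- list(
    profile = profile, seed = as.integer(seed),
    task_cfg = unclass(task_cfg), model_cfg = unclass(model_cfg),
    products = unname(products),
    package_version = as.character(utils::packageVersion("ofctrack")),
    r_version = R.version.string,
    created = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    schema_version = SCHEMA_VERSION
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

scale_unit <- function(x) {
  s <- stats::sd(x)
  if (s == 0) stop("degenerate input: zero variance", call. = FALSE)
  (x - mean(x)) / s
}
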