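#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with the study's values
#' as defaults: 20 Hz high-pass and 15 Hz low-pass 4th-order zero-phase
#' Butterworth filters, 200-point cycle base, ensemble COI basis, 100 ms
#' causal smoothing window, rest-referenced 5% threshold rule, 400/800 Hz
#' beep pitches for VL/ST, and alpha = 0.05.
#'
#' @param sim A `study_config` describing the simulated study (or NULL when
#'   `data_dir` points at trials on disk).
#' @param data_dir Directory of trials written by [write_trial()]; overrides
#'   `sim` when given.
#' @param hp_hz,lp_hz,filter_order Envelope filter settings.
#' @param n_points Cycle base size.
#' @param coi_basis `"ensemble"` or `"per_cycle_mean"`.
#' @param window_ms,threshold_rule,threshold_fraction,debounce_ms Real-time
#'   feedback settings.
#' @param beep_freq_hz Named vector of beep pitches (Hz).
#' @param run_biofeedback Logical; simulate the beep system for the feedback
#'   muscles of each trial.
#' @param alpha Significance level reported with the ANOVA.
#' @param seed Seed forwarded to the simulation config when `sim` is NULL.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, data_dir = NULL,
                            hp_hz = 20, lp_hz = 15, filter_order = 4L,
                            n_points = 200L,
                            coi_basis = c("ensemble", "per_cycle_mean"),
                            window_ms = 100, threshold_rule = "relative",
                            threshold_fraction = 0.05, debounce_ms = 50,
                            beep_freq_hz = c(VL = 400, ST = 800),
                            run_biofeedback = TRUE,
                            alpha = 0.05, seed = 1L) {
  coi_basis <- match.arg(coi_basis)
  if (is.null(sim) && is.null(data_dir)) sim <- study_config(master_seed = seed)
  structure(
    list(sim = sim, data_dir = data_dir, hp_hz = hp_hz, lp_hz = lp_hz,
         filter_order = as.integer(filter_order), n_points = as.integer(n_points),
         coi_basis = coi_basis, window_ms = window_ms,
         threshold_rule = threshold_rule, threshold_fraction = threshold_fraction,
         debounce_ms = debounce_ms, beep_freq_hz = beep_freq_hz,
         run_biofeedback = isTRUE(run_biofeedback), alpha = alpha,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Write one trial to disk as delimited text
#'
#' Raw sEMG goes to `<prefix>_emg.csv` (`time_s`, one column per muscle),
#' markers to `<prefix>_markers.csv`, metadata (rates, labels, seed) to
#' `<prefix>_meta.json`.
#'
#' @param trial One element of `simulate_study()$trials`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_trial <- function(trial, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  prefix <- file.path(dir, paste0(trial$participant, "_",
                                  gsub("[^A-Za-z]", "", trial$condition)))
  fs <- trial$emg[[1]]$fs_hz
  n <- length(trial$emg[[1]]$samples)
  emg_df <- data.frame(time_s = (seq_len(n) - 1L) / fs)
  for (m in names(trial$emg)) emg_df[[m]] <- trial$emg[[m]]$samples
  paths <- c(emg = paste0(prefix, "_emg.csv"),
             markers = paste0(prefix, "_markers.csv"),
             meta = paste0(prefix, "_meta.json"))
  utils::write.csv(emg_df, paths["emg"], row.names = FALSE)
  utils::write.csv(trial$markers, paths["markers"], row.names = FALSE)
  jsonlite::write_json(
    list(participant = trial$participant, condition = trial$condition,
         emg_fs_hz = fs, mocap_fs_hz = 1 / stats::median(diff(trial$markers$time_s)),
         channels = names(trial$emg), seed = trial$seed),
    paths["meta"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read one trial back from disk
#'
#' Validates the schema: required columns present, time vectors strictly
#' increasing, and declared sampling rates consistent with the time stamps.
#'
#' @param emg_csv,markers_csv,meta_json Paths written by [write_trial()].
#' @return Trial list (`participant`, `condition`, `emg`, `markers`, `seed`)
#'   with the same layout as `simulate_study()$trials[[i]]`.
#' @export
read_trial <- function(emg_csv, markers_csv, meta_json) {
  for (f in c(emg_csv, markers_csv, meta_json)) {
    if (!file.exists(f)) stop("file not found: ", f)
  }
  meta <- jsonlite::read_json(meta_json, simplifyVector = TRUE)
  emg_df <- utils::read.csv(emg_csv)
  markers <- utils::read.csv(markers_csv)
  miss <- setdiff(c("time_s", meta$channels), names(emg_df))
  if (length(miss) > 0) stop("sEMG file missing column(s): ", paste(miss, collapse = ", "))
  need <- c("time_s", "pedal_x", "pedal_y", "pedal_z", "axis_x", "axis_y", "axis_z")
  miss <- setdiff(need, names(markers))
  if (length(miss) > 0) stop("marker file missing column(s): ", paste(miss, collapse = ", "))
  for (nm in list(c("time_s (sEMG)", "emg_df"), c("time_s (markers)", "markers"))) {
    tv <- get(nm[2])$time_s
    if (any(diff(tv) <= 0)) stop("non-monotone or duplicated time stamps in ", nm[1])
  }
  dt <- stats::median(diff(emg_df$time_s))
  if (abs(dt * meta$emg_fs_hz - 1) > 0.01) {
    stop("declared emg_fs_hz (", meta$emg_fs_hz,
         ") inconsistent with time stamps (median dt = ", signif(dt, 4), " s)")
  }
  emg <- lapply(meta$channels, function(m) {
    structure(list(fs_hz = meta$emg_fs_hz, t0 = emg_df$time_s[1],
                   samples = emg_df[[m]], muscle = m),
              class = "raw_emg_channel")
  })
  names(emg) <- meta$channels
  list(participant = meta$participant, condition = meta$condition,
       emg = emg, markers = markers, seed = meta$seed)
}

#' Process one trial: kinematics, envelopes, cycle sets
#'
#' @param trial Trial list (simulated or read from disk).
#' @param config `pipeline_config`.
#' @return List: `sets` (un-normalized `cycle_envelope_set` per muscle),
#'   `n_cycles`, `trace` (segmented `crank_trace`).
#' @export
process_trial <- function(trial, config = pipeline_config()) {
  trace <- segment_cycles(compute_crank_angle(trial$markers))
  sets <- lapply(trial$emg, function(ch) {
    env <- offline_envelope(ch, hp_hz = config$hp_hz, lp_hz = config$lp_hz,
                            order = config$filter_order)
    cut_and_resample(env, trace$cycle_bounds, n_points = config$n_points,
                     muscle = ch$muscle, participant = trial$participant,
                     condition = trial$condition)
  })
  list(sets = sets, n_cycles = n_cycles(trace), trace = trace)
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) every trial, segments cycles, extracts 200-point
#' cycle envelopes, normalizes each participant-muscle to its peak across
#' conditions, computes VL-ST and RF-BF co-contraction indices, screens
#' normality, runs the repeated-measures ANOVA per pair, and (optionally)
#' simulates the auditory feedback system for the feedback muscles.
#'
#' @param config `pipeline_config`.
#' @param out_dir Optional directory; when given, result tables are written as
#'   CSV and a JSON manifest of every parameter is recorded.
#' @return List of class `pipeline_result`: `coi_table` (per trial x pair,
#'   both bases), `summary_table` (condition means/SD per pair with p and
#'   partial eta squared), `anova` (per pair), `shapiro` (per pair x
#'   condition), `ensembles` (per participant/condition/muscle mean
#'   waveforms), `beeps` (per-trial overlap metrics, if enabled),
#'   `ground_truth` (when simulated), `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$data_dir)) {
    metas <- list.files(config$data_dir, "_meta\\.json$", full.names = TRUE)
    if (length(metas) == 0) stop("no trials found in ", config$data_dir)
    trials <- lapply(metas, function(mj) {
      prefix <- sub("_meta\\.json$", "", mj)
      read_trial(paste0(prefix, "_emg.csv"), paste0(prefix, "_markers.csv"), mj)
    })
    ground_truth <- NULL
  } else {
    study <- simulate_study(config$sim)
    trials <- study$trials
    ground_truth <- study$ground_truth
  }

  processed <- lapply(trials, process_trial, config = config)
  names(processed) <- vapply(trials, function(tr)
    paste(tr$participant, tr$condition, sep = "/"), character(1))

  # cross-condition peak normalization per participant-muscle
  participants <- unique(vapply(trials, `[[`, character(1), "participant"))
  muscles <- names(trials[[1]]$emg)
  for (p in participants) {
    idx <- which(vapply(trials, `[[`, character(1), "participant") == p)
    for (m in muscles) {
      sets <- lapply(processed[idx], function(pr) pr$sets[[m]])
      sets <- normalize_to_peak(sets)
      for (j in seq_along(idx)) processed[[idx[j]]]$sets[[m]] <- sets[[j]]
    }
  }

  pairs <- list(c("VL", "ST"), c("RF", "BF"))
  pairs <- Filter(function(pr) all(pr %in% muscles), pairs)
  coi_table <- do.call(rbind, unlist(lapply(processed, function(pr) {
    lapply(pairs, function(mp) {
      rbind(coi_for_trial(pr$sets[[mp[1]]], pr$sets[[mp[2]]], "ensemble"),
            coi_for_trial(pr$sets[[mp[1]]], pr$sets[[mp[2]]], "per_cycle_mean"))
    })
  }), recursive = FALSE))
  rownames(coi_table) <- NULL

  ensembles <- do.call(rbind, unlist(lapply(processed, function(pr) {
    lapply(pr$sets, function(s) {
      ens <- ensemble_average(s)
      data.frame(participant = s$participant, condition = s$condition,
                 muscle = s$muscle, point = seq_along(ens$mean),
                 mean = ens$mean, sd = ens$sd)
    })
  }), recursive = FALSE))
  rownames(ensembles) <- NULL

  primary <- coi_table[coi_table$basis == config$coi_basis, ]
  conditions <- unique(primary$condition)
  anova <- list(); shapiro <- NULL; summary_table <- NULL
  for (pair in unique(primary$pair)) {
    sub <- primary[primary$pair == pair, ]
    wide <- stats::reshape(sub[, c("participant", "condition", "coi_percent")],
                           idvar = "participant", timevar = "condition",
                           direction = "wide")
    m <- as.matrix(wide[, -1, drop = FALSE])
    colnames(m) <- sub("^coi_percent\\.", "", colnames(m))
    m <- m[, conditions, drop = FALSE]
    res <- if (ncol(m) >= 2 && nrow(m) >= 2) rm_anova(m) else NULL
    anova[[pair]] <- res
    for (cond in conditions) {
      sw <- tryCatch(shapiro_wilk(m[, cond]),
                     error = function(e) list(W = NA_real_, p_value = NA_real_))
      shapiro <- rbind(shapiro, data.frame(pair = pair, condition = cond,
                                           W = sw$W, p_value = sw$p_value))
    }
    summary_table <- rbind(summary_table, data.frame(
      pair = pair, condition = conditions,
      mean_coi = colMeans(m)[conditions],
      sd_coi = apply(m, 2, stats::sd)[conditions],
      p_value = if (is.null(res)) NA_real_ else res$p_value,
      partial_eta_sq = if (is.null(res)) NA_real_ else res$partial_eta_sq
    ))
  }
  rownames(summary_table) <- NULL

  beeps <- NULL
  if (config$run_biofeedback) {
    fb_muscles <- intersect(names(config$beep_freq_hz), muscles)
    beeps <- do.call(rbind, lapply(seq_along(trials), function(i) {
      tr <- trials[[i]]
      logs <- lapply(fb_muscles, function(m) {
        env <- causal_envelope(tr$emg[[m]], window_ms = config$window_ms)
        rest <- structure(list(fs_hz = env$fs_hz,
                               values = rep(mean(utils::head(
                                 sort(env$values), length(env$values) %/% 10)), 2)),
                          class = "envelope_trace")
        calib <- calibrate_threshold(rest, env,
                                     fraction = config$threshold_fraction,
                                     rule = config$threshold_rule, muscle = m)
        detect_beep_events(env, calib, config$beep_freq_hz[[m]],
                           debounce_ms = config$debounce_ms)
      })
      ov <- if (length(logs) == 2) overlap_metrics(logs[[1]], logs[[2]]) else
        list(overlap_s = NA_real_, overlap_fraction = NA_real_)
      data.frame(participant = tr$participant, condition = tr$condition,
                 n_events = sum(vapply(logs, function(l) nrow(l$events), numeric(1))),
                 total_on_s = sum(vapply(logs, `[[`, numeric(1), "total_on_s")),
                 overlap_s = ov$overlap_s, overlap_fraction = ov$overlap_fraction)
    }))
  }

  result <- structure(
    list(coi_table = coi_table, summary_table = summary_table, anova = anova,
         shapiro = shapiro, ensembles = ensembles, beeps = beeps,
         ground_truth = ground_truth, config = config),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) write_pipeline_result(result, out_dir)
  result
}

write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$coi_table, file.path(out_dir, "coi_per_trial.csv"),
                   row.names = FALSE)
  utils::write.csv(result$summary_table, file.path(out_dir, "coi_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(result$shapiro, file.path(out_dir, "shapiro.csv"),
                   row.names = FALSE)
  utils::write.csv(result$ensembles, file.path(out_dir, "ensemble_waveforms.csv"),
                   row.names = FALSE)
  if (!is.null(result$beeps)) {
    utils::write.csv(result$beeps, file.path(out_dir, "beep_metrics.csv"),
                     row.names = FALSE)
  }
  anova_df <- do.call(rbind, lapply(names(result$anova), function(pair) {
    a <- result$anova[[pair]]
    data.frame(pair = pair, f_value = a$f_value, df_effect = a$df_effect,
               df_error = a$df_error, p_value = a$p_value,
               partial_eta_sq = a$partial_eta_sq, gg_epsilon = a$gg_epsilon,
               p_value_gg = a$p_value_gg)
  }))
  utils::write.csv(anova_df, file.path(out_dir, "rm_anova.csv"), row.names = FALSE)
  cfg <- result$config
  cfg$sim <- unclass(cfg$sim)
  manifest <- c(unclass(cfg),
                list(package_version = as.character(utils::packageVersion("pedalcoi")),
                     r_version = R.version.string))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
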