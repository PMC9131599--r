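#' Synthetic study configuration
#'
#' Bundles every parameter of the simulated pedaling study. Defaults encode
#' the study design the package analyses: 13 participants, four auditory
#' feedback conditions (NFB, VLFB, STFB, VL-STFB), 90 s of pedaling at 80 rpm,
#' sEMG at 1000 Hz and motion capture at 100 Hz.
#'
#' @param n_participants Number of participants (default 13).
#' @param conditions Ordered condition labels.
#' @param cadence_rpm Pedaling cadence, revolutions per minute (default 80).
#' @param duration_s Trial duration in seconds (default 90).
#' @param emg_fs_hz sEMG sampling rate (Hz).
#' @param mocap_fs_hz Motion-capture frame rate (Hz).
#' @param noise_floor Baseline sEMG standard deviation at rest (mV).
#' @param snr Burst-amplitude-to-noise-floor ratio of the modulated signal.
#' @param condition_overlap_shift Named numeric: degrees added to the ST burst
#'   centers per condition (shifts the designed VL-ST overlap). All zero by
#'   default (null design).
#' @param crank_length_m Crank arm length (m).
#' @param marker_noise_m Isotropic Gaussian marker jitter, standard deviation
#'   in metres (default 0.5 mm, typical optical-capture noise).
#' @param participant_jitter Logical; draw per-participant variations of the
#'   burst parameters (center sd 8 deg, width and amplitude log-normal with
#'   sdlog 0.08 and 0.15) so participants differ as real subjects do.
#' @param master_seed Integer master seed; every per-trial stream is derived
#'   from it deterministically.
#' @return A list of class `study_config`.
#' @export
study_config <- function(n_participants = 13L,
                         conditions = CONDITIONS,
                         cadence_rpm = 80,
                         duration_s = 90,
                         emg_fs_hz = 1000,
                         mocap_fs_hz = 100,
                         noise_floor = 0.02,
                         snr = 10,
                         condition_overlap_shift = NULL,
                         crank_length_m = 0.17,
                         marker_noise_m = 5e-4,
                         participant_jitter = TRUE,
                         master_seed = 1L) {
  if (is.null(condition_overlap_shift)) {
    condition_overlap_shift <- stats::setNames(rep(0, length(conditions)), conditions)
  }
  bad <- setdiff(conditions, CONDITIONS)
  if (length(bad) > 0) {
    stop("unknown condition label(s): ", paste(bad, collapse = ", "),
         " (must be among ", paste(CONDITIONS, collapse = ", "), ")")
  }
  if (!all(conditions %in% names(condition_overlap_shift))) {
    stop("condition_overlap_shift must be named for every condition")
  }
  stopifnot(n_participants >= 1, cadence_rpm > 0, duration_s > 0,
            emg_fs_hz > 0, mocap_fs_hz > 0, noise_floor > 0, snr > 0,
            crank_length_m > 0, marker_noise_m >= 0)
  if (duration_s * cadence_rpm / 60 < 2) {
    stop("configuration yields fewer than 2 complete cycles")
  }
  structure(
    list(n_participants = as.integer(n_participants), conditions = conditions,
         cadence_rpm = cadence_rpm, duration_s = duration_s,
         emg_fs_hz = emg_fs_hz, mocap_fs_hz = mocap_fs_hz,
         noise_floor = noise_floor, snr = snr,
         condition_overlap_shift = condition_overlap_shift,
         crank_length_m = crank_length_m, marker_noise_m = marker_noise_m,
         participant_jitter = isTRUE(participant_jitter),
         master_seed = as.integer(master_seed)),
    class = "study_config"
  )
}

#' Derive a stable per-trial seed from the master seed
#'
#' A small multiplicative hash keeping the result in `[0, 2^31)`. Stable
#' across platforms and R versions (pure integer arithmetic in double space).
#'
#' @param master_seed Integer master seed.
#' @param participant Participant index (1-based).
#' @param condition Condition index (1-based).
#' @param stream Extra stream offset (e.g. one per channel).
#' @return Integer seed.
#' @export
derive_seed <- function(master_seed, participant, condition = 0L, stream = 0L) {
  h <- (as.numeric(master_seed) * 2654435761 +
          as.numeric(participant) * 97561 +
          as.numeric(condition) * 8191 +
          as.numeric(stream) * 131) %% 2147483647
  as.integer(h)
}

#' Simulate one raw sEMG channel
#'
#' Standard amplitude-modulated-noise surrogate: band-limited (20-450 Hz)
#' zero-mean unit-variance Gaussian noise `w_t` multiplied by the modulation
#' profile `noise_floor + gain * template(angle_t)`, with
#' `gain = snr * noise_floor / max(template)` so the envelope rises `snr`-fold
#' above the resting floor at the burst peak. Rectifying and smoothing such a
#' signal recovers an envelope proportional to the modulation profile, which
#' is what makes the surrogate a valid end-to-end test bed.
#'
#' @param template `activation_template` (may be a null template for rest
#'   recordings).
#' @param crank_angle_deg Crank angle at each sEMG sample (degrees, unwrapped
#'   or wrapped; only the value modulo 360 is used).
#' @param fs_hz Sampling rate; must exceed twice the 450 Hz noise band edge.
#' @param noise_floor Resting amplitude (mV).
#' @param snr Burst-to-floor ratio.
#' @param seed Integer seed; identical seed gives bitwise-identical output.
#' @return List of class `raw_emg_channel`: `fs_hz`, `t0`, `samples` (mV),
#'   `muscle`.
#' @export
simulate_raw_semg <- function(template, crank_angle_deg, fs_hz = 1000,
                              noise_floor = 0.02, snr = 10, seed = 1L) {
  stopifnot(inherits(template, "activation_template"),
            noise_floor > 0, snr > 0)
  if (fs_hz <= 2 * 450) {
    stop("fs_hz = ", fs_hz, " violates sampling assumptions: the 20-450 Hz ",
         "noise band requires fs_hz > 900")
  }
  n <- length(crank_angle_deg)
  w <- bandlimited_noise(n, fs_hz, lo_hz = 20, hi_hz = 450, seed = seed)
  tmpl_max <- max(template$profile)
  gain <- if (tmpl_max > 0) snr * noise_floor / tmpl_max else 0
  modulation <- noise_floor + gain * eval_template(template, crank_angle_deg)
  structure(
    list(fs_hz = fs_hz, t0 = 0, samples = modulation * w,
         muscle = template$muscle),
    class = "raw_emg_channel"
  )
}

# zero-mean unit-variance Gaussian noise band-passed to [lo, hi] Hz
bandlimited_noise <- function(n, fs_hz, lo_hz, hi_hz, seed) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  x <- stats::rnorm(n + 2000)  # margin absorbs the filter transient
  bf <- signal::butter(4, c(lo_hz, hi_hz) / (fs_hz / 2), type = "pass")
  y <- signal::filter(bf, x)[-seq_len(2000)]
  y <- y - mean(y)
  y / stats::sd(y)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Simulate pedal and crank-axis marker trajectories
#'
#' The pedal marker moves on a circle of radius `crank_length_m` about the
#' crank-axis marker at constant angular velocity `2*pi*cadence_rpm/60`,
#' starting at the upper dead center (pedal directly above the axis). The lab
#' frame is x forward, y lateral, z up; the crank plane is sagittal (x-z).
#' Frames are endpoint-inclusive and carry a 50 ms capture tail so the final
#' upper-dead-center crossing of a whole-cycle recording is always observed.
#'
#' @param cadence_rpm Cadence (rev/min).
#' @param duration_s Nominal trial duration (s).
#' @param mocap_fs_hz Frame rate (Hz).
#' @param crank_length_m Crank radius (m).
#' @param noise_m Isotropic Gaussian marker jitter sd (m); 0 disables.
#' @param seed Integer seed for the jitter.
#' @return Data frame with columns `time_s`, `pedal_x/y/z`, `axis_x/y/z` (m).
#' @export
simulate_crank_markers <- function(cadence_rpm, duration_s, mocap_fs_hz = 100,
                                   crank_length_m = 0.17, noise_m = 0,
                                   seed = 1L) {
  stopifnot(cadence_rpm > 0, duration_s > 0, mocap_fs_hz > 0,
            crank_length_m > 0, noise_m >= 0)
  n <- floor((duration_s + 0.05) * mocap_fs_hz) + 1L
  t <- (seq_len(n) - 1L) / mocap_fs_hz
  theta <- 2 * pi * cadence_rpm / 60 * t       # rad, 0 at upper dead center
  axis <- c(0, 0, 1)                           # arbitrary lab position (m)
  out <- data.frame(
    time_s  = t,
    pedal_x = axis[1] + crank_length_m * sin(theta),
    pedal_y = axis[2],
    pedal_z = axis[3] + crank_length_m * cos(theta),
    axis_x  = axis[1], axis_y = axis[2], axis_z = axis[3]
  )
  if (noise_m > 0) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(restore_rng(old), add = TRUE)
    set.seed(as.integer(seed))
    jit <- matrix(stats::rnorm(n * 6, sd = noise_m), nrow = n)
    out[, 2:7] <- out[, 2:7] + jit
  }
  out
}

#' Simulate a complete multi-participant study
#'
#' Emits one trial per participant x condition: a four-channel raw sEMG
#' recording, a marker trajectory, and metadata, plus a ground-truth record
#' (per-participant templates, designed COIs, and all derived seeds) against
#' which the offline pipeline can be validated.
#'
#' Per-participant burst-parameter jitter is shared across that participant's
#' conditions (a repeated-measures structure: conditions differ only through
#' the condition overlap shift and fresh noise realizations).
#'
#' @param config A `study_config`.
#' @return List of class `synthetic_study` with `trials` (list of trials,
#'   each `participant`, `condition`, `emg` (list of `raw_emg_channel` per
#'   muscle), `markers`, `seed`) and `ground_truth` (`templates[[participant]]
#'   [[condition]]`, `designed_coi` data frame, `config`).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  cad <- config$cadence_rpm
  n_emg <- floor(config$duration_s * config$emg_fs_hz)
  t_emg <- (seq_len(n_emg) - 1L) / config$emg_fs_hz
  angle_emg <- 360 * cad / 60 * t_emg

  trials <- list()
  gt_templates <- list()
  designed <- NULL
  for (p in seq_len(config$n_participants)) {
    pj <- participant_jitter_params(config, p)
    gt_templates[[p]] <- list()
    for (ci in seq_along(config$conditions)) {
      cond <- config$conditions[ci]
      shift <- config$condition_overlap_shift[[cond]]
      tmpls <- participant_templates(pj, shift)
      gt_templates[[p]][[cond]] <- tmpls
      trial_seed <- derive_seed(config$master_seed, p, ci)
      emg <- lapply(seq_along(MUSCLES), function(mi) {
        simulate_raw_semg(tmpls[[MUSCLES[mi]]], angle_emg,
                          fs_hz = config$emg_fs_hz,
                          noise_floor = config$noise_floor, snr = config$snr,
                          seed = derive_seed(config$master_seed, p, ci, mi))
      })
      names(emg) <- MUSCLES
      markers <- simulate_crank_markers(
        cad, config$duration_s, config$mocap_fs_hz, config$crank_length_m,
        noise_m = config$marker_noise_m,
        seed = derive_seed(config$master_seed, p, ci, 99L)
      )
      trials[[length(trials) + 1L]] <- list(
        participant = sprintf("P%02d", p), condition = cond,
        emg = emg, markers = markers, seed = trial_seed
      )
      designed <- rbind(designed, data.frame(
        participant = sprintf("P%02d", p), condition = cond,
        pair = c("VL-ST", "RF-BF"),
        designed_coi = c(
          designed_coi(tmpls$VL, tmpls$ST, config$noise_floor, config$snr),
          designed_coi(tmpls$RF, tmpls$BF, config$noise_floor, config$snr)
        )
      ))
    }
  }
  structure(
    list(trials = trials,
         ground_truth = list(templates = gt_templates, designed_coi = designed,
                             config = config)),
    class = "synthetic_study"
  )
}

# per-participant variations of the default bursts, drawn independently per
# muscle so agonist-antagonist timing genuinely differs between participants
# (a shared rigid shift or amplitude scaling would cancel in the normalized
# COI and produce unrealistically uniform subjects)
participant_jitter_params <- function(config, p) {
  if (!config$participant_jitter) {
    return(list(center = stats::setNames(rep(0, 4), MUSCLES),
                width = stats::setNames(rep(1, 4), MUSCLES),
                amp = stats::setNames(rep(1, 4), MUSCLES)))
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old), add = TRUE)
  set.seed(derive_seed(config$master_seed, p, 0L, 7L))
  list(
    center = stats::setNames(stats::rnorm(4, 0, 8), MUSCLES),
    width = stats::setNames(stats::rlnorm(4, 0, 0.08), MUSCLES),
    amp = stats::setNames(stats::rlnorm(4, 0, 0.15), MUSCLES)
  )
}

participant_templates <- function(pj, st_shift_deg) {
  base <- default_templates(st_shift_deg = st_shift_deg)
  out <- lapply(MUSCLES, function(m) {
    bp <- lapply(base[[m]]$burst_params, function(b) {
      c(b[1] + pj$center[[m]], b[2] * pj$width[[m]], b[3] * pj$amp[[m]])
    })
    build_template(m, bp)
  })
  stats::setNames(out, MUSCLES)
}
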