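#!/usr/bin/env Rscript
# Step 3 — the auditory feedback system on one trial, in detail.
#
# Reconstructs what a rider in the dual-feedback condition hears: causal
# rectified/weighted-moving-average envelopes for VL and ST, thresholds from
# the rest-referenced 5% rule, beep on/off events at 400 Hz (VL) and 800 Hz
# (ST), their overlap, and a rendered audio excerpt.

suppressPackageStartupMessages(library(pedalcoi))

seed <- 1L
out <- "results"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- study_config(master_seed = seed)
study <- simulate_study(study_config(n_participants = 1, master_seed = seed,
                                     duration_s = 30))
trial <- study$trials[[4]]  # the VL-STFB condition
cat("Trial:", trial$participant, trial$condition, "\n")

# rest recording for calibration: the same channels with no pedaling
rest_cfg <- study_config(n_participants = 1, duration_s = 10,
                         master_seed = seed + 500L)
null_tmpl <- build_template("VL", list(), null_template = TRUE)
logs <- list()
for (m in c("VL", "ST")) {
  rest_raw <- simulate_raw_semg(null_tmpl, rep(0, 10 * 1000),
                                noise_floor = rest_cfg$noise_floor,
                                seed = rest_cfg$master_seed + match(m, c("VL", "ST")))
  rest_env <- causal_envelope(rest_raw)
  ped_env <- causal_envelope(trial$emg[[m]])
  cal <- calibrate_threshold(rest_env, ped_env, muscle = m)
  cat(sprintf("  %s: rest %.4f mV, pedaling max %.4f mV -> threshold %.4f mV\n",
              m, cal$rest_amplitude, cal$pedaling_max, cal$threshold))
  freq <- c(VL = 400, ST = 800)[[m]]
  logs[[m]] <- detect_beep_events(ped_env, cal, freq)
  cat(sprintf("  %s: %d beep events, %.1f s total on-time at %d Hz\n",
              m, nrow(logs[[m]]$events), logs[[m]]$total_on_s, freq))
}

ov <- overlap_metrics(logs$VL, logs$ST)
cat(sprintf("Beep overlap: %.2f s (%.1f%% of the quieter muscle's on-time)\n",
            ov$overlap_s, 100 * ov$overlap_fraction))

ev <- rbind(cbind(muscle = "VL", logs$VL$events),
            cbind(muscle = "ST", logs$ST$events))
write.csv(ev, file.path(out, "beep_events_example.csv"), row.names = FALSE)

audio <- render_audio(logs, audio_fs_hz = 44100, duration_s = 30)
wav <- file.path(out, "beeps_example.wav")
write_wav(audio, wav, fs_hz = 44100)
cat("Rendered", wav, sprintf("(%.1f s, 44.1 kHz mono)\n", length(audio) / 44100))
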