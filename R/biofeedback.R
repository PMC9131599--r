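#' Causal real-time sEMG envelope
#'
#' The real-time chain of the feedback system: full-wave rectification
#' followed by a weighted moving average over a trailing window. Strictly
#' causal: the output at sample t uses samples at or before t only. The
#' default window is 100 ms with linearly increasing weights (most recent
#' sample weighted most), normalized to sum to 1; partial leading windows are
#' renormalized over the samples available.
#'
#' @param channel `raw_emg_channel` (or list with `samples`, `fs_hz`).
#' @param window_ms Trailing window length (ms, default 100).
#' @param weights `"linear"` (ramp up to the newest sample) or `"uniform"`.
#' @return `envelope_trace`, same length as the input.
#' @export
causal_envelope <- function(channel, window_ms = 100, weights = c("linear", "uniform")) {
  weights <- match.arg(weights)
  x <- abs(channel$samples)
  fs <- channel$fs_hz
  n <- length(x)
  w_len <- max(1L, round(window_ms / 1000 * fs))
  if (w_len > n) {
    stop("window (", w_len, " samples) longer than recording (", n, " samples)")
  }
  w <- if (weights == "linear") seq_len(w_len) else rep(1, w_len)
  w <- w / sum(w)
  # trailing weighted sum via causal convolution on a zero-padded prefix;
  # partial windows renormalized by the weight mass actually inside the record
  num <- stats::filter(c(rep(0, w_len - 1L), x), rev(w), method = "convolution",
                       sides = 1)
  num <- as.numeric(num)[w_len:(w_len + n - 1L)]
  # mass of the newest k weights (k = samples available inside the record)
  den <- cumsum(rev(w))[pmin(seq_len(n), w_len)]
  structure(list(fs_hz = fs, t0 = channel$t0 %||% 0, values = num / den,
                 muscle = channel$muscle %||% NA_character_),
            class = "envelope_trace")
}

#' Calibrate the beep threshold for one muscle
#'
#' The threshold lies 5% of the way from the resting envelope level to the
#' maximum envelope amplitude reached during about a minute of calibration
#' pedaling: `threshold = rest + 0.05 * (pedaling_max - rest)` (default
#' `rule = "relative"`). The alternative reading that ignores the resting
#' level, `threshold = 0.05 * pedaling_max`, is available as
#' `rule = "absolute"`.
#'
#' @param rest_env `envelope_trace` recorded at rest.
#' @param pedaling_env `envelope_trace` recorded while pedaling.
#' @param fraction Threshold fraction (default 0.05).
#' @param rule `"relative"` (rest-referenced) or `"absolute"`.
#' @param muscle Label carried into the result.
#' @return Object of class `threshold_calibration`: `muscle`,
#'   `rest_amplitude`, `pedaling_max`, `threshold` (mV).
#' @export
calibrate_threshold <- function(rest_env, pedaling_env, fraction = 0.05,
                                rule = c("relative", "absolute"),
                                muscle = pedaling_env$muscle %||% NA_character_) {
  rule <- match.arg(rule)
  stopifnot(length(rest_env$values) > 0, length(pedaling_env$values) > 0,
            fraction > 0, fraction < 1)
  rest <- mean(rest_env$values)
  peak <- max(pedaling_env$values)
  if (peak <= rest) {
    stop("uncalibratable channel: pedaling maximum (", signif(peak, 3),
         ") does not exceed resting level (", signif(rest, 3), ")")
  }
  thr <- if (rule == "relative") rest + fraction * (peak - rest) else
    fraction * peak
  structure(list(muscle = muscle, rest_amplitude = rest, pedaling_max = peak,
                 threshold = thr, fraction = fraction, rule = rule),
            class = "threshold_calibration")
}

#' Detect beep on/off events from a causal envelope
#'
#' A beep is on during maximal runs where the envelope exceeds the calibrated
#' threshold. Events are reported in seconds (onset at the first
#' supra-threshold sample, offset one sample past the last, so durations are
#' in whole sample periods). By default, gaps shorter than `debounce_ms` are
#' merged and events shorter than `debounce_ms` dropped, which suppresses
#' audible chatter when the envelope rides near the threshold.
#'
#' @param env `envelope_trace`.
#' @param calib `threshold_calibration` (or a bare numeric threshold).
#' @param freq_hz Beep pitch for this muscle (Hz): 400 for VL, 800 for ST.
#' @param debounce_ms Minimum event/gap duration (ms); 0 disables.
#' @return Object of class `beep_event_log`: `muscle`, `freq_hz`, `events`
#'   (data frame `onset_s`, `offset_s`), `total_on_s`.
#' @export
detect_beep_events <- function(env, calib, freq_hz, debounce_ms = 50) {
  thr <- if (inherits(calib, "threshold_calibration")) calib$threshold else
    as.numeric(calib)
  fs <- env$fs_hz
  above <- env$values > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values)
  events <- data.frame(
    onset_s = env$t0 %||% 0 + (starts[on] - 1L) / fs,
    offset_s = env$t0 %||% 0 + ends[on] / fs
  )
  if (debounce_ms > 0 && nrow(events) > 1) {
    # merge gaps shorter than the debounce time
    keep <- events[1, , drop = FALSE]
    for (i in seq_len(nrow(events))[-1]) {
      if (events$onset_s[i] - keep$offset_s[nrow(keep)] < debounce_ms / 1000) {
        keep$offset_s[nrow(keep)] <- events$offset_s[i]
      } else {
        keep <- rbind(keep, events[i, ])
      }
    }
    events <- keep
  }
  if (debounce_ms > 0 && nrow(events) > 0) {
    events <- events[events$offset_s - events$onset_s >= debounce_ms / 1000, ,
                     drop = FALSE]
    rownames(events) <- NULL
  }
  structure(list(muscle = env$muscle %||% NA_character_, freq_hz = freq_hz,
                 events = events,
                 total_on_s = sum(events$offset_s - events$onset_s)),
            class = "beep_event_log")
}

#' Overlap between two beep event logs
#'
#' Total time both beeps sound simultaneously (length of the intersection of
#' the two interval unions) and that time as a fraction of the smaller total
#' on-time. The fraction is the quantity participants in the dual-feedback
#' condition are asked to minimize.
#'
#' @param logA,logB `beep_event_log` objects from the same trial timeline.
#' @return List: `overlap_s`, `overlap_fraction` (0 when either log is empty).
#' @export
overlap_metrics <- function(logA, logB) {
  ea <- logA$events; eb <- logB$events
  if (nrow(ea) == 0 || nrow(eb) == 0) {
    return(list(overlap_s = 0, overlap_fraction = 0))
  }
  ov <- 0
  for (i in seq_len(nrow(ea))) {
    lo <- pmax(ea$onset_s[i], eb$onset_s)
    hi <- pmin(ea$offset_s[i], eb$offset_s)
    ov <- ov + sum(pmax(0, hi - lo))
  }
  tot_a <- sum(ea$offset_s - ea$onset_s)
  tot_b <- sum(eb$offset_s - eb$onset_s)
  list(overlap_s = ov, overlap_fraction = ov / min(tot_a, tot_b))
}

#' Render beep event logs to audio samples
#'
#' Each log contributes a pure sine tone at its pitch, gated by its events
#' with 10 ms raised-cosine on/off ramps; the sum is peak-normalized to 0.9
#' full scale (silence stays silent).
#'
#' @param logs List of `beep_event_log` objects.
#' @param audio_fs_hz Audio sampling rate (Hz); must be at least 4x the
#'   highest beep frequency.
#' @param duration_s Length of the rendered clip (s); all events must fit.
#' @param ramp_ms On/off ramp length (ms, default 10).
#' @return Numeric vector of audio samples in `[-0.9, 0.9]`.
#' @export
render_audio <- function(logs, audio_fs_hz = 44100, duration_s, ramp_ms = 10) {
  if (inherits(logs, "beep_event_log")) logs <- list(logs)
  fmax <- if (length(logs) > 0) max(vapply(logs, `[[`, numeric(1), "freq_hz")) else 0
  if (length(logs) > 0 && audio_fs_hz < 4 * fmax) {
    stop("audio_fs_hz must be >= 4x the highest beep frequency (", fmax, " Hz)")
  }
  n <- round(duration_s * audio_fs_hz)
  t <- (seq_len(n) - 1L) / audio_fs_hz
  out <- numeric(n)
  ramp_n <- round(ramp_ms / 1000 * audio_fs_hz)
  for (lg in logs) {
    ev <- lg$events
    if (nrow(ev) == 0) next
    if (any(ev$offset_s > duration_s + 1e-9)) {
      stop("event ending at ", max(ev$offset_s), " s exceeds duration ",
           duration_s, " s")
    }
    gate <- numeric(n)
    for (i in seq_len(nrow(ev))) {
      i0 <- floor(ev$onset_s[i] * audio_fs_hz) + 1L
      i1 <- min(n, ceiling(ev$offset_s[i] * audio_fs_hz))
      seg <- rep(1, i1 - i0 + 1L)
      nr <- min(ramp_n, floor(length(seg) / 2))
      if (nr > 0) {
        ramp <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
        seg[seq_len(nr)] <- seg[seq_len(nr)] * ramp
        seg[(length(seg) - nr + 1L):length(seg)] <-
          seg[(length(seg) - nr + 1L):length(seg)] * rev(ramp)
      }
      gate[i0:i1] <- pmax(gate[i0:i1], seg)
    }
    out <- out + gate * sin(2 * pi * lg$freq_hz * t)
  }
  pk <- max(abs(out))
  if (pk > 0) out <- out * 0.9 / pk
  out
}

#' Write mono audio samples as a 16-bit PCM WAV file
#'
#' Minimal RIFF/WAVE writer for the rendered beep track.
#'
#' @param samples Numeric samples in `[-1, 1]`.
#' @param path Output file path.
#' @param fs_hz Sampling rate (Hz).
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, path, fs_hz = 44100) {
  pcm <- as.integer(pmax(-32767, pmin(32767, round(samples * 32767))))
  con <- file(path, "wb")
  on.exit(close(con))
  data_len <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_len), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")        # PCM
  writeBin(1L, con, size = 2, endian = "little")        # mono
  writeBin(as.integer(fs_hz), con, size = 4, endian = "little")
  writeBin(as.integer(fs_hz * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_len), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
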