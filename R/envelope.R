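#' Zero-phase Butterworth filtering
#'
#' A 4th-order Butterworth design applied forward then backward (zero net
#' phase, doubled magnitude order — the dominant convention in biomechanics
#' when a "zero-lag fourth-order" filter is reported). Edges are handled by
#' odd-reflection padding so the transient of the uninitialized filter falls
#' on the mirrored extension, not the data.
#'
#' @param x Numeric signal.
#' @param cutoff_hz Cutoff (Hz); length 2 for band filters.
#' @param fs_hz Sampling rate (Hz).
#' @param type `"high"`, `"low"`, `"pass"` or `"stop"`.
#' @param order Design order (default 4; applied twice).
#' @return Filtered signal, same length as `x`.
#' @export
zero_phase_butter <- function(x, cutoff_hz, fs_hz, type, order = 4L) {
  bf <- signal::butter(order, cutoff_hz / (fs_hz / 2), type = type)
  nb <- max(length(bf$b), length(bf$a))
  pad <- 3L * (nb - 1L)
  n <- length(x)
  min_n <- 3L * pad + 1L
  if (n < min_n) {
    stop("signal too short for zero-phase filtering: ", n,
         " samples; minimum length is ", min_n)
  }
  left <- 2 * x[1] - x[(pad + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - pad)]
  xe <- c(left, x, right)
  # steady-state initialization: treat the first sample as having been
  # applied forever, so a constant input produces its DC response exactly
  # (no start-up transient)
  h1 <- sum(bf$b) / sum(bf$a)
  run <- function(z) {
    as.numeric(signal::filter(bf, z - z[1])) + z[1] * h1
  }
  y <- run(xe)
  y <- rev(run(rev(y)))
  y[(pad + 1):(pad + n)]
}

#' Offline sEMG linear envelope
#'
#' The offline conditioning chain, in this exact stage order: zero-phase
#' 4th-order Butterworth high-pass at 20 Hz (motion-artifact removal), mean
#' subtraction, full-wave rectification, zero-phase 4th-order Butterworth
#' low-pass at 15 Hz. Small negative excursions produced by the final low-pass
#' are clipped to zero.
#'
#' @param channel A `raw_emg_channel` (or any list with `samples` and `fs_hz`).
#' @param hp_hz High-pass cutoff (Hz, default 20).
#' @param lp_hz Low-pass cutoff (Hz, default 15).
#' @param order Butterworth design order (default 4).
#' @return Object of class `envelope_trace`: `fs_hz`, `t0`, `values` (mV, >= 0).
#' @export
offline_envelope <- function(channel, hp_hz = 20, lp_hz = 15, order = 4L) {
  x <- channel$samples
  fs <- channel$fs_hz
  stopifnot(is.numeric(x), fs > 2 * hp_hz)
  y <- zero_phase_butter(x, hp_hz, fs, "high", order)
  y <- y - mean(y)
  y <- abs(y)
  y <- zero_phase_butter(y, lp_hz, fs, "low", order)
  y[y < 0] <- 0
  structure(list(fs_hz = fs, t0 = channel$t0 %||% 0, values = y,
                 muscle = channel$muscle %||% NA_character_),
            class = "envelope_trace")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cut an envelope into cycles and resample onto the 200-point base
#'
#' Each cycle is linearly resampled onto `n_points` points uniformly spanning
#' its `[0%, 100%)` duration (half-open: point k sits at fraction k/n_points,
#' so the shared boundary sample is not duplicated). Cycle bounds are given in
#' seconds on the envelope's clock; envelope values at bound times are linearly
#' interpolated between samples, with constant extrapolation if a bound falls
#' within one frame past the recorded samples.
#'
#' @param env `envelope_trace`.
#' @param bounds Data frame with `start_s`, `end_s` (from [segment_cycles()]).
#' @param n_points Points per cycle (default 200).
#' @param muscle,participant,condition Metadata carried into the result.
#' @return Object of class `cycle_envelope_set`: `cycles` (n_cycles x n_points
#'   matrix), `muscle`, `participant`, `condition`, `normalization_peak`
#'   (NA until [normalize_to_peak()]).
#' @export
cut_and_resample <- function(env, bounds, n_points = 200L,
                             muscle = env$muscle, participant = NA_character_,
                             condition = NA_character_) {
  stopifnot(inherits(env, "envelope_trace"))
  if (is.null(bounds) || nrow(bounds) == 0L) stop("empty cycle bounds")
  nv <- length(env$values)
  t_env <- env$t0 + (seq_len(nv) - 1L) / env$fs_hz
  frac <- (seq_len(n_points) - 1L) / n_points
  too_short <- (bounds$end_s - bounds$start_s) * env$fs_hz < 20
  if (any(too_short)) {
    stop("cycle ", which(too_short)[1], " spans fewer than 20 envelope samples")
  }
  rows <- t(vapply(seq_len(nrow(bounds)), function(i) {
    xq <- bounds$start_s[i] + frac * (bounds$end_s[i] - bounds$start_s[i])
    stats::approx(t_env, env$values, xout = xq, method = "linear", rule = 2)$y
  }, numeric(n_points)))
  structure(
    list(cycles = rows, muscle = muscle, participant = participant,
         condition = condition, normalization_peak = NA_real_),
    class = "cycle_envelope_set"
  )
}

#' Normalize cycle envelopes to the peak across all conditions
#'
#' All cycle-envelope sets of one participant-muscle (one per condition) are
#' divided by the single maximum over every cycle of every set, so the global
#' peak becomes exactly 1 and amplitudes are comparable across conditions.
#'
#' @param sets List of `cycle_envelope_set` objects of one participant-muscle.
#' @return The same list, normalized, with `normalization_peak` recorded (mV).
#' @export
normalize_to_peak <- function(sets) {
  if (inherits(sets, "cycle_envelope_set")) sets <- list(sets)
  stopifnot(length(sets) >= 1,
            all(vapply(sets, inherits, logical(1), "cycle_envelope_set")))
  peak <- max(vapply(sets, function(s) max(s$cycles), numeric(1)))
  if (peak <= 0) {
    stop("dead channel: global peak across conditions is 0, cannot normalize")
  }
  lapply(sets, function(s) {
    s$cycles <- s$cycles / peak
    s$normalization_peak <- peak
    s
  })
}

#' Ensemble average of a cycle-envelope set
#'
#' @param set `cycle_envelope_set`.
#' @return List with `mean` (pointwise mean waveform) and `sd` (pointwise
#'   standard deviation; 0 for a single cycle).
#' @export
ensemble_average <- function(set) {
  stopifnot(inherits(set, "cycle_envelope_set"), nrow(set$cycles) >= 1)
  m <- colMeans(set$cycles)
  s <- if (nrow(set$cycles) > 1) apply(set$cycles, 2, stats::sd) else
    numeric(ncol(set$cycles))
  list(mean = m, sd = s, n_cycles = nrow(set$cycles))
}
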