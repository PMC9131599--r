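test_that("the causal envelope is causal, normalized and finite-memory", {
  expect_true(all(causal_envelope(make_channel(rep(0, 1000)))$values == 0))

  # constant input: steady state equals the constant everywhere (weights
  # renormalized on the partial leading window)
  ce <- causal_envelope(make_channel(rep(0.3, 500)))
  expect_equal(ce$values, rep(0.3, 500), tolerance = 1e-12)

  # unit step at sample s: no response before s, full plateau within a window
  s <- 400
  step <- causal_envelope(make_channel(c(rep(0, s - 1), rep(1, 1000))))
  expect_true(all(step$values[seq_len(s - 1)] == 0))
  expect_gte(step$values[s + 100], 0.99)  # 100 ms window at 1000 Hz

  expect_error(causal_envelope(make_channel(rep(1, 50)), window_ms = 100),
               "longer than recording")
})

test_that("future samples never influence past causal-envelope output", {
  set.seed(7)
  x <- abs(rnorm(2000))
  a <- causal_envelope(make_channel(x))
  for (cut in c(500, 1200, 1999)) {
    y <- x
    y[(cut + 1):2000] <- y[(cut + 1):2000] + 10 * runif(2000 - cut)
    b <- causal_envelope(make_channel(y))
    expect_identical(a$values[seq_len(cut)], b$values[seq_len(cut)])
  }
})

test_that("threshold calibration implements the rest-referenced 5% rule", {
  mkenv <- function(v) make_envelope(v)
  expect_equal(calibrate_threshold(mkenv(rep(0, 10)), mkenv(c(0, 1)))$threshold,
               0.05)
  cal <- calibrate_threshold(mkenv(rep(0.1, 10)), mkenv(c(0.1, 2.1)))
  expect_equal(cal$threshold, 0.2)
  expect_equal(cal$rest_amplitude, 0.1)
  expect_equal(cal$pedaling_max, 2.1)
  expect_true(cal$rest_amplitude <= cal$threshold &&
                cal$threshold <= cal$pedaling_max)
  # alternative absolute reading ignores the resting level
  expect_equal(calibrate_threshold(mkenv(rep(0.1, 10)), mkenv(c(0.1, 2.1)),
                                   rule = "absolute")$threshold, 0.105)
  expect_error(calibrate_threshold(mkenv(rep(1, 5)), mkenv(rep(1, 5))),
               "uncalibratable")
})

test_that("beep events delimit supra-threshold runs to within a sample", {
  fs <- 1000
  env <- make_envelope(c(rep(0, 1000), rep(1, 500), rep(0, 1500)), fs)
  lg <- detect_beep_events(env, 0.5, 400, debounce_ms = 0)
  expect_equal(nrow(lg$events), 1)
  expect_equal(lg$events$onset_s, 1.0, tolerance = 1.5 / fs)
  expect_equal(lg$events$offset_s, 1.5, tolerance = 1.5 / fs)
  expect_equal(lg$freq_hz, 400)

  expect_equal(nrow(detect_beep_events(make_envelope(rep(0.1, 1000)), 0.5, 400)$events), 0)
  always <- detect_beep_events(make_envelope(rep(1, 1000)), 0.5, 400)
  expect_equal(nrow(always$events), 1)
  expect_equal(always$total_on_s, 1.0)
})

test_that("debouncing merges chattery gaps and drops sub-threshold blips", {
  v <- numeric(3000)
  v[1001:1200] <- 1   # 200 ms event
  v[1220:1400] <- 1   # 20 ms gap -> merged
  v[2000:2010] <- 1   # 11 ms blip -> dropped
  lg <- detect_beep_events(make_envelope(v), 0.5, 800, debounce_ms = 50)
  expect_equal(nrow(lg$events), 1)
  expect_equal(lg$events$onset_s, 1.0)
  expect_equal(lg$events$offset_s, 1.4)
})

test_that("total beep-on time is non-increasing in the threshold", {
  set.seed(31)
  tm <- default_templates()
  ch <- simulate_raw_semg(tm$VL, 480 * (0:14999) / 1000, seed = 77)
  env <- causal_envelope(ch)
  ths <- quantile(env$values, c(0.05, 0.25, 0.5, 0.75, 0.95))
  on_time <- vapply(ths, function(th)
    detect_beep_events(env, th, 400)$total_on_s, numeric(1))
  expect_true(all(diff(on_time) <= 1e-12))
})

test_that("interval overlap matches the 1 ms brute-force oracle", {
  mk_log <- function(ev) structure(list(muscle = "VL", freq_hz = 400,
                                        events = ev,
                                        total_on_s = sum(ev$offset_s - ev$onset_s)),
                                   class = "beep_event_log")
  A <- mk_log(data.frame(onset_s = 0, offset_s = 2))
  B <- mk_log(data.frame(onset_s = 1, offset_s = 3))
  ov <- overlap_metrics(A, B)
  expect_equal(ov$overlap_s, 1.0)
  expect_equal(ov$overlap_fraction, 0.5)

  expect_equal(overlap_metrics(
    mk_log(data.frame(onset_s = 0, offset_s = 1)),
    mk_log(data.frame(onset_s = 2, offset_s = 3)))$overlap_s, 0)
  same <- mk_log(data.frame(onset_s = c(0, 2), offset_s = c(1, 2.5)))
  ovs <- overlap_metrics(same, same)
  expect_equal(ovs$overlap_s, 1.5)
  expect_equal(ovs$overlap_fraction, 1)
  expect_equal(overlap_metrics(same, mk_log(same$events[0, ]))$overlap_fraction, 0)

  set.seed(44)
  for (i in 1:25) {
    n_a <- sample(1:5, 1); n_b <- sample(1:5, 1)
    mk_rand <- function(k) {
      edges <- sort(round(runif(2 * k, 0, 10), 3))
      data.frame(onset_s = edges[seq(1, 2 * k, 2)], offset_s = edges[seq(2, 2 * k, 2)])
    }
    ea <- mk_rand(n_a); eb <- mk_rand(n_b)
    got <- overlap_metrics(mk_log(ea), mk_log(eb))$overlap_s
    want <- oracle_overlap_s(ea, eb, 10)
    expect_equal(got, want, tolerance = 2e-3)
  }
})

test_that("rendered beeps carry their pitch and respect event gating", {
  mk_log <- function(ev, f) structure(list(muscle = "VL", freq_hz = f,
                                           events = ev, total_on_s = 0),
                                      class = "beep_event_log")
  expect_true(all(render_audio(list(), 44100, 0.5) == 0))
  empty <- mk_log(data.frame(onset_s = numeric(0), offset_s = numeric(0)), 400)
  expect_true(all(render_audio(list(empty), 44100, 0.5) == 0))

  fs <- 44100
  lg4 <- mk_log(data.frame(onset_s = 0.2, offset_s = 1.0), 400)
  lg8 <- mk_log(data.frame(onset_s = 0.2, offset_s = 1.0), 800)
  au <- render_audio(list(lg4, lg8), fs, 1.2)
  expect_lte(max(abs(au)), 0.9 + 1e-12)
  expect_true(all(au[1:floor(0.18 * fs)] == 0))  # silent before onset
  seg <- au[round(0.3 * fs):round(0.9 * fs)]
  spec <- Mod(fft(seg))
  freqs <- (seq_along(seg) - 1) / length(seg) * fs
  half <- freqs <= fs / 2
  top2 <- order(spec[half], decreasing = TRUE)[1:4]
  peak_freqs <- sort(unique(round(freqs[half][top2] / 50) * 50))
  expect_true(400 %in% peak_freqs)
  expect_true(800 %in% peak_freqs)

  bad <- mk_log(data.frame(onset_s = 0.5, offset_s = 2), 400)
  expect_error(render_audio(list(bad), 44100, 1), "exceeds duration")
  expect_error(render_audio(list(lg8), 2000, 1.2), "4x")
})

test_that("events round-trip through audio rendering within 15 ms", {
  fs <- 8000
  ev <- data.frame(onset_s = c(0.2, 1.0), offset_s = c(0.6, 1.5))
  lg <- structure(list(muscle = "VL", freq_hz = 400, events = ev,
                       total_on_s = 0.9), class = "beep_event_log")
  au <- render_audio(list(lg), fs, 2)
  env <- causal_envelope(make_channel(au, fs_hz = fs), window_ms = 10)
  rec <- detect_beep_events(env, 0.2, 400, debounce_ms = 20)
  expect_equal(nrow(rec$events), 2)
  expect_lt(max(abs(rec$events$onset_s - ev$onset_s)), 0.015)
  expect_lt(max(abs(rec$events$offset_s - ev$offset_s)), 0.015)
})

test_that("write_wav produces a well-formed RIFF header and PCM payload", {
  path <- tempfile(fileext = ".wav")
  x <- sin(2 * pi * 400 * (0:799) / 8000)
  write_wav(x, path, fs_hz = 8000)
  con <- file(path, "rb")
  on.exit(close(con))
  expect_identical(readChar(con, 4), "RIFF")
  invisible(readBin(con, integer(), 1, 4, endian = "little"))
  expect_identical(readChar(con, 4), "WAVE")
  expect_equal(file.size(path), 44 + 800 * 2)
})
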