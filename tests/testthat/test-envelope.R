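test_that("the envelope chain is linear-silent and rejects DC", {
  ch <- make_channel(rep(0, 5000))
  expect_true(all(offline_envelope(ch)$values == 0))

  dc <- make_channel(rep(2.5, 5000))
  env <- offline_envelope(dc)
  mid <- env$values[500:4500]
  expect_lt(max(mid), 1e-6 * 2.5)
})

test_that("zero-phase filtering preserves the timing of a symmetric burst", {
  n <- 8000; c0 <- 4000
  t <- seq_len(n)
  carrier <- sin(2 * pi * 80 * t / 1000)
  win <- exp(-((t - c0) / 300)^2)
  set.seed(5)
  ch <- make_channel(win * carrier)
  env <- offline_envelope(ch)
  expect_lte(abs(which.max(env$values) - c0), 5)
  # cross-correlation with the known symmetric modulation peaks at lag ~0
  cc <- ccf(env$values, win, lag.max = 20, plot = FALSE)
  expect_lte(abs(cc$lag[which.max(cc$acf)]), 5)
})

test_that("signals below the filter warm-up length are rejected by name", {
  expect_error(offline_envelope(make_channel(rep(0, 10))), "minimum length")
})

test_that("cycles resample exactly onto the half-open 200-point base", {
  fs <- 1000
  env <- make_envelope(rep(0.7, 3000), fs)
  bounds <- data.frame(start_s = c(0, 0.75, 1.5), end_s = c(0.75, 1.5, 2.25))
  set <- cut_and_resample(env, bounds)
  expect_equal(dim(set$cycles), c(3, 200))
  expect_true(all(set$cycles == 0.7))

  # linear ramp: interpolation is exact, endpoints at fractions 0 and 199/200
  ramp <- make_envelope(seq(0, 1, length.out = 1001), fs)
  b1 <- data.frame(start_s = 0, end_s = 1)
  r <- cut_and_resample(ramp, b1)$cycles[1, ]
  expect_equal(r, (0:199) / 200, tolerance = 1e-9)
  expect_equal(max(diff(diff(r))), 0, tolerance = 1e-12)

  # odd cycle lengths still give 200-point rows
  b2 <- data.frame(start_s = 0.1, end_s = 0.85)  # 750 raw samples
  expect_equal(length(cut_and_resample(env, b2)$cycles[1, ]), 200)

  expect_error(cut_and_resample(env, bounds[0, ]), "empty")
  expect_error(cut_and_resample(env, data.frame(start_s = 0, end_s = 0.005)),
               "20 envelope samples")
})

test_that("peak normalization is global across conditions, exact and idempotent", {
  s1 <- cut_and_resample(make_envelope(rep(2, 1000)),
                         data.frame(start_s = 0, end_s = 0.9), muscle = "VL",
                         participant = "P01", condition = "NFB")
  s2 <- cut_and_resample(make_envelope(rep(4, 1000)),
                         data.frame(start_s = 0, end_s = 0.9), muscle = "VL",
                         participant = "P01", condition = "VLFB")
  norm <- normalize_to_peak(list(s1, s2))
  expect_equal(max(norm[[1]]$cycles), 0.5)
  expect_equal(max(norm[[2]]$cycles), 1)
  expect_equal(norm[[1]]$normalization_peak, 4)
  # idempotent: renormalizing changes nothing
  again <- normalize_to_peak(norm)
  expect_equal(again[[1]]$cycles, norm[[1]]$cycles)
  expect_equal(again[[2]]$cycles, norm[[2]]$cycles)

  dead <- s1; dead$cycles[] <- 0
  expect_error(normalize_to_peak(list(dead)), "dead channel")
})

test_that("normalized envelopes are invariant to raw input scaling", {
  tm <- default_templates()
  ang <- 480 * (0:14999) / 1000
  ch <- simulate_raw_semg(tm$VL, ang, seed = 8)
  ch_scaled <- ch
  ch_scaled$samples <- ch$samples * 7
  bounds <- data.frame(start_s = (0:18) * 0.75, end_s = (1:19) * 0.75)
  s <- cut_and_resample(offline_envelope(ch), bounds, muscle = "VL")
  ss <- cut_and_resample(offline_envelope(ch_scaled), bounds, muscle = "VL")
  n1 <- normalize_to_peak(list(s))[[1]]
  n2 <- normalize_to_peak(list(ss))[[1]]
  expect_equal(n1$cycles, n2$cycles, tolerance = 1e-10)
  expect_equal(n2$normalization_peak / n1$normalization_peak, 7, tolerance = 1e-10)
})

test_that("ensemble averaging reduces to the exact pointwise mean and sd", {
  set <- cut_and_resample(make_envelope(rep(1, 2000)),
                          data.frame(start_s = c(0, 1), end_s = c(1, 1.9)))
  set$cycles[1, ] <- 0.2
  set$cycles[2, ] <- 0.6
  ens <- ensemble_average(set)
  expect_equal(ens$mean, rep(0.4, 200))
  expect_equal(ens$sd, rep(sd(c(0.2, 0.6)), 200))

  one <- set; one$cycles <- one$cycles[1, , drop = FALSE]
  expect_equal(ensemble_average(one)$sd, rep(0, 200))
})
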