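test_that("common area and COI match hand-worked values", {
  e1 <- c(1, 1, 0, 0)
  e2 <- c(0, 1, 1, 0)
  # pointwise min = [0,1,0,0]; trapezoid with unit spacing -> 1.0
  expect_equal(common_area(e1, e2), 1.0)
  expect_equal(coi(e1, e2), 50.0)

  a <- c(0.2, 0.8, 0.5, 0.1, 0)
  expect_equal(coi(a, a), 100)
  expect_equal(coi(c(1, 1, 0, 0, 0), c(0, 0, 0, 1, 1)), 0)
  expect_equal(common_area(a, rep(0, 5)), 0)
})

test_that("degenerate COI inputs raise distinct errors", {
  expect_error(coi(c(0, 0, 0), c(0, 0, 0)), "undefined")
  expect_error(coi(c(1, -0.1, 0), c(0, 1, 0)), "rectified")
  expect_error(coi(c(1, 1), c(1, 1, 1)), "length")
  expect_error(common_area(numeric(1), numeric(1)), ">= 2")
})

test_that("COI is symmetric and scale-invariant over random envelope pairs", {
  set.seed(101)
  for (i in 1:1000) {
    a <- random_envelope(50)
    b <- random_envelope(50)
    v <- coi(a, b)
    expect_identical(v, coi(b, a))
    k <- runif(1, 0.01, 100)
    expect_equal(coi(k * a, k * b), v, tolerance = 1e-10)
    expect_true(v >= 0 && v <= 100)
  }
})

test_that("COI reaches 100 only for coincident envelopes", {
  set.seed(202)
  for (i in 1:200) {
    a <- random_envelope(80)
    b <- random_envelope(80)
    if (isTRUE(all.equal(a, b))) next
    expect_lt(coi(a, b), 100)
  }
})

test_that("trapezoidal common area agrees with the oversampled oracle", {
  set.seed(303)
  for (i in 1:100) {
    a <- random_envelope(200)
    b <- random_envelope(200)
    got <- common_area(a, b)
    want <- oracle_common_area(a, b, factor = 100)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("ignoring crossing sub-knots costs a small, one-sided discrepancy", {
  set.seed(304)
  for (i in 1:50) {
    a <- random_envelope(200)
    b <- random_envelope(200)
    grid_val <- common_area(a, b)
    dense_val <- oracle_common_area_crossings(a, b, factor = 100)
    # the dense value resolves the concave crossing wedges, so it can only
    # be larger, and only slightly (per-segment wedges are second order)
    expect_gte(dense_val, grid_val - 1e-12)
    expect_lt((dense_val - grid_val) / dense_val, 0.02)
  }
})

test_that("trial-level COI honours its basis and metadata contracts", {
  mk_set <- function(values_by_cycle, muscle, participant = "P01",
                     condition = "NFB") {
    structure(list(cycles = do.call(rbind, values_by_cycle), muscle = muscle,
                   participant = participant, condition = condition,
                   normalization_peak = 1),
              class = "cycle_envelope_set")
  }
  w <- abs(sin(seq(0, pi, length.out = 200))) + 0.05
  s1 <- mk_set(list(w, w), "VL")
  s2 <- mk_set(list(w, w), "ST")
  expect_equal(coi_for_trial(s1, s2, "ensemble")$coi_percent, 100)
  expect_equal(coi_for_trial(s1, s2, "per_cycle_mean")$coi_percent, 100)
  expect_equal(coi_for_trial(s1, s2)$pair, "VL-ST")

  # per_cycle_mean averages the per-cycle COIs
  rect <- function(lo, hi) { v <- numeric(200); v[lo:hi] <- 1; v }
  a1 <- rect(1, 101)
  b1 <- rect(61, 161)
  s3 <- mk_set(list(a1, a1), "VL")
  s4 <- mk_set(list(b1, a1), "ST")
  got <- coi_for_trial(s3, s4, "per_cycle_mean")$coi_percent
  expect_equal(got, mean(c(coi(a1, b1), coi(a1, a1))))

  s_bad <- mk_set(list(w), "ST", participant = "P02")
  expect_error(coi_for_trial(s1, s_bad), "mismatched")
  expect_error(coi_for_trial(s1, mk_set(list(w), "ST"), "per_cycle_mean"),
               "equal cycle counts")
})

test_that("pipeline COI lands within 3 points of the designed template COI", {
  tm <- default_templates()
  dur <- 30
  ang <- 480 * (seq_len(dur * 1000) - 1) / 1000
  mk <- simulate_crank_markers(80, dur, 100, noise_m = 5e-4, seed = 6)
  tr <- segment_cycles(compute_crank_angle(mk))
  vl <- cut_and_resample(offline_envelope(simulate_raw_semg(tm$VL, ang, seed = 61)),
                         tr$cycle_bounds, muscle = "VL")
  st <- cut_and_resample(offline_envelope(simulate_raw_semg(tm$ST, ang, seed = 62)),
                         tr$cycle_bounds, muscle = "ST")
  nvl <- normalize_to_peak(list(vl))[[1]]
  nst <- normalize_to_peak(list(st))[[1]]
  got <- coi_for_trial(nvl, nst, "ensemble")$coi_percent
  want <- designed_coi(tm$VL, tm$ST, noise_floor = 0.02, snr = 10)
  expect_lt(abs(got - want), 3)
})
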