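make_trace <- function(fl, conc = 1, t = seq(0, 40, by = 0.25)) {
  mst_trace("c1", conc, t, fl, laser_on_s = 5, laser_off_s = 35)
}

test_that("F_norm is the hot/cold window-mean ratio in permille", {
  t <- seq(0, 40, by = 0.25)
  expect_equal(compute_fnorm(make_trace(rep(1000, length(t))))$fnorm, 1000)
  fl <- ifelse(t < 5, 1000, 900)
  expect_equal(compute_fnorm(make_trace(fl))$fnorm, 900)
  # invariance under uniform rescaling of the counts
  p1 <- compute_fnorm(make_trace(fl))
  p2 <- compute_fnorm(make_trace(fl * 37.5))
  expect_equal(p1$fnorm, p2$fnorm)
  expect_equal(p1$cold_mean * 37.5, p2$cold_mean)
})

test_that("invalid traces and windows are rejected", {
  t <- seq(0, 40, by = 0.25)
  expect_error(mst_trace("c", 1, t, rep(c(1, -1), length.out = length(t))),
               "positive")
  expect_error(mst_trace("c", 1, rev(t), rep(1000, length(t))),
               "increasing")
  expect_error(mst_trace("c", 1, t, rep(1000, length(t)),
                         laser_on_s = 35, laser_off_s = 5), "precede")
  expect_error(analysis_windows(c(1, 6), c(10, 11)), "before laser-on")
  expect_error(analysis_windows(c(1, 4), c(36, 38)), "within")
  w <- analysis_windows(c(0.5, 4.5), c(30, 31))
  tr <- make_trace(rep(1000, 41), t = seq(2, 42, by = 1))
  expect_error(compute_fnorm(tr, w), "outside the trace")
})

test_that("simulated noiseless traces reproduce the closed-form F_norm", {
  # full depletion with amplitude -50 permille gives F_norm ~ 950
  des <- titration_design(n_points = 8, top_final_conc = 1e6,
                          tracer_final = 0.25)
  tr <- simulate_saturation_run(des, kd = 1e-9, noise = noiseless())
  expect_equal(compute_fnorm(tr[[1]])$fnorm, 950, tolerance = 1e-3)
  # arbitrary occupancy: F_norm = unbound + amplitude * f exactly
  des2 <- titration_design(top_final_conc = 50, tracer_final = 0.25)
  tr2 <- simulate_saturation_run(des2, kd = 7.65, noise = noiseless())
  f <- binary_bound_fraction(make_dilution_series(des2), 0.25, 7.65)
  fn <- vapply(tr2, function(x) compute_fnorm(x)$fnorm, numeric(1))
  expect_equal(fn, 1000 - 50 * f, tolerance = 1e-4)
})

test_that("hot-window selection favours the settled window and is deterministic", {
  des <- titration_design(top_final_conc = 50, tracer_final = 0.25)
  tr <- simulate_saturation_run(des, kd = 7.65, noise = noiseless())
  on_s <- 5; off_s <- 35
  grid <- lapply(c(6, 15, 30), function(s)
    analysis_windows(c(0.5, 4.5), c(s, s + 1), on_s, off_s))
  w <- select_hot_window(tr, grid)
  # amplitude grows as depletion settles, so the latest window wins
  expect_equal(w$hot_window, c(30, 31))
  w2 <- select_hot_window(tr, grid)
  expect_identical(w$hot_window, w2$hot_window)
  # identical candidates: the earlier (first listed) one is returned
  grid_tie <- list(grid[[3]], grid[[3]])
  expect_equal(select_hot_window(tr, grid_tie)$hot_window, c(30, 31))
  # zero amplitude everywhere cannot be scored
  flat <- lapply(tr, function(x) {
    mst_trace(x$capillary_id, x$titrant_conc, x$time_s,
              rep(1000, length(x$time_s)), x$laser_on_s, x$laser_off_s)
  })
  expect_error(select_hot_window(flat, grid), "zero response amplitude")
})

test_that("QC flags annotate without altering values", {
  des <- titration_design(top_final_conc = 50, tracer_final = 0.25)
  tr <- simulate_saturation_run(des, kd = 7.65, noise = noiseless())
  pts <- fnorm_table(tr)
  clean <- qc_capillaries(pts, tr)
  expect_identical(clean$fnorm, pts$fnorm)
  expect_true(all(!nzchar(clean$qc_flags)))

  # a doubled baseline is an outlier at the 10% default tolerance
  out <- pts
  out$cold_mean[3] <- 2 * median(pts$cold_mean)
  flagged <- qc_capillaries(out, NULL)
  expect_match(flagged$qc_flags[3], "BASELINE_OUTLIER")
  expect_equal(sum(nzchar(flagged$qc_flags)), 1)
  expect_equal(nrow(flagged), nrow(pts))

  # the top serum point can be excluded by request
  top <- qc_capillaries(pts, tr, exclude_top = TRUE)
  i <- which.max(top$titrant_conc)
  expect_match(top$qc_flags[i], "EXCLUDED_TOP_POINT")
  expect_equal(sum(nzchar(top$qc_flags)), 1)

  # a bleaching capillary is flagged from its cold-phase slope
  bl <- simulate_saturation_run(des, kd = 7.65,
                                noise = noiseless(bleach_rate = 0.05))
  mix <- c(tr[1:15], bl[16])
  pts_mix <- fnorm_table(mix)
  flagged2 <- qc_capillaries(pts_mix, mix)
  id16 <- pts_mix$capillary_id == "cap16"
  expect_match(flagged2$qc_flags[id16], "BLEACHING")
})

test_that("fraction bound is the affine map between the plateaus", {
  expect_equal(fraction_bound(940, 940, 990), 0)
  expect_equal(fraction_bound(990, 940, 990), 1)
  expect_equal(fraction_bound(965, 940, 990), 0.5)
  expect_error(fraction_bound(950, 960, 960), "zero response amplitude")
  # inverse affine map is the identity on [0, 1]
  fb <- seq(0, 1, by = 0.05)
  x <- 940 + fb * (990 - 940)
  expect_equal(fraction_bound(x, 940, 990), fb, tolerance = 1e-12)
  # noisy values outside the plateaus are not clipped
  expect_lt(fraction_bound(935, 940, 990), 0)
})
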