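test_that("dilution series follow the bench arithmetic", {
  d <- titration_design(n_points = 8, top_final_conc = 8)
  expect_equal(make_dilution_series(d), 8 / 2^(0:7))
  # 16,000 nM working solution: first 1:1 serial dilution then
  # equal-volume mixing with the complex gives a 4,000 nM top capillary
  d2 <- titration_design(top_working_conc = 16000, tracer_final = 0.25)
  s <- make_dilution_series(d2)
  expect_equal(s[1], 4000)
  expect_length(s, 16)
  expect_equal(unique(round(s[-length(s)] / s[-1], 12)), 2)
  expect_error(titration_design(n_points = 8, dilution_factor = 1,
                                top_final_conc = 8), "dilution_factor")
})

test_that("generators are pure functions of parameters and seed", {
  des <- titration_design(top_final_conc = 50, tracer_final = 0.25)
  a <- simulate_saturation_run(des, kd = 7.65, seed = 99)
  b <- simulate_saturation_run(des, kd = 7.65, seed = 99)
  expect_identical(a, b)
  c1 <- simulate_saturation_run(des, kd = 7.65, seed = 100)
  expect_false(identical(a, c1))
  dd <- dialysis_design(competitor_series = c(0, 1, 10, 100))
  expect_identical(simulate_dialysis_measurements(dd, 0.5, seed = 7),
                   simulate_dialysis_measurements(dd, 0.5, seed = 7))
  expect_identical(simulate_degradation_course("PRE_IMMUNE", 4000, seed = 3),
                   simulate_degradation_course("PRE_IMMUNE", 4000, seed = 3))
  # generators do not disturb the caller's RNG stream
  set.seed(123); before <- .Random.seed
  invisible(simulate_saturation_run(des, kd = 7.65, seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("trace fluorescence stays positive under default parameters", {
  des <- titration_design(top_final_conc = 50, tracer_final = 0.25)
  tr <- simulate_saturation_run(des, kd = 7.65, seed = 12)
  expect_true(all(vapply(tr, function(x) all(x$fluorescence > 0),
                         logical(1))))
})

test_that("competition traces are consistent with the saturation model", {
  # non-binding competitor: F_norm flat at the saturation-run level
  des <- standard_competition_design()
  tr <- simulate_competition_run(des, kd_tracer = 7.65, ki = 1e12,
                                 noise = noiseless())
  fn <- vapply(tr, function(x) compute_fnorm(x)$fnorm, numeric(1))
  expect_lt(diff(range(fn)), 1e-6)
  # ... at exactly the value of the saturation run at the same 10 nM sites
  sat <- simulate_saturation_run(titration_design(n_points = 8,
                                                  top_final_conc = 10,
                                                  tracer_final = 0.25),
                                 kd = 7.65, noise = noiseless())
  expect_equal(fn[1], compute_fnorm(sat[[1]])$fnorm, tolerance = 1e-6)
})

test_that("degradation generator reduces to first order without antibody", {
  t <- c(0, 0.25, 0.5, 1, 1.5, 2, 3)
  cr <- simulate_degradation_course("PRE_IMMUNE", 4000, k_free = 2,
                                    noise_cv = 0)
  expect_equal(cr$concentrations, 4000 * exp(-2 * t), tolerance = 1e-9)
  fit <- fit_one_phase_decay(cr$times, cr$concentrations)
  expect_equal(fit$t_half, log(2) / 2, tolerance = 1e-9)
  flat <- simulate_degradation_course("BUFFER", 100, noise_cv = 0)
  expect_equal(flat$concentrations, rep(100, 7))
})

test_that("noiseless dialysis measurements invert exactly", {
  series <- c(0, 0.3, 1, 3, 10, 30, 100, 300)
  dd <- dialysis_design(ab_sites_in_sample = 10,
                        competitor_series = series)
  m <- simulate_dialysis_measurements(dd, kd = 0.51, noise_cv = 0)
  expect_equal(m$b[1], dialysis_equilibrium(dd, 0.51)$b)
  expect_equal(estimate_kd_from_competition(m, dd)$kd, 0.51,
               tolerance = 1e-6)
})
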