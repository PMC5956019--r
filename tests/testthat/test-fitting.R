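sat_series <- function(kd, top = 50, tracer = 0.25, seed = NULL,
                       noise = noiseless(), exclude_top = FALSE) {
  des <- titration_design(top_final_conc = top, tracer_final = tracer)
  tr <- simulate_saturation_run(des, kd = kd, noise = noise, seed = seed)
  pts <- qc_capillaries(fnorm_table(tr), tr, exclude_top = exclude_top)
  titration_series(pts, "SATURATION", tracer_total = tracer)
}

comp_series <- function(ki, kd = 7.65, top_working = 16000, seed = NULL,
                        noise = noiseless()) {
  des <- standard_competition_design(top_working)
  tr <- simulate_competition_run(des, kd_tracer = kd, ki = ki,
                                 noise = noise, seed = seed)
  titration_series(fnorm_table(tr), "COMPETITION", tracer_total = 0.25,
                   antibody_sites = 10, tracer_kd = kd)
}

test_that("saturation fit recovers Kd exactly from noiseless data", {
  fit <- fit_saturation(sat_series(7.65))
  expect_equal(fit$estimate, 7.65, tolerance = 1e-6)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_equal(fit$fnorm_unbound, 1000, tolerance = 1e-3)
  expect_equal(fit$fnorm_bound, 950, tolerance = 1e-3)
  expect_equal(fit$n_used, 16)
})

test_that("saturation fit rejects flat series", {
  s <- sat_series(7.65)
  s$points$fnorm <- rep(1000, nrow(s$points))
  expect_error(fit_saturation(s), "flat curve")
})

test_that("fits are invariant to point order and to affine F_norm rescaling", {
  s <- sat_series(5, seed = 3, noise = trace_noise_model())
  fit <- fit_saturation(s)
  s_shuf <- s
  set.seed(1); idx <- sample(nrow(s$points))
  s_shuf$points <- s$points[idx, ]
  expect_equal(fit_saturation(s_shuf)$estimate, fit$estimate,
               tolerance = 1e-6)
  s_aff <- s
  s_aff$points$fnorm <- 2.5 * s$points$fnorm + 100
  fit_aff <- fit_saturation(s_aff)
  expect_equal(fit_aff$estimate, fit$estimate, tolerance = 1e-6)
  expect_equal(fit_aff$fnorm_unbound, 2.5 * fit$fnorm_unbound + 100,
               tolerance = 1e-3)
})

test_that("Kd recovery under default noise is accurate with calibrated CIs", {
  # scaled-down sweep of the full recovery study (details in the vignette)
  for (kd_true in c(0.5, 50)) {
    est <- vapply(1:20, function(s)
      fit_saturation(sat_series(kd_true, seed = s,
                                noise = trace_noise_model()))$estimate,
      numeric(1))
    expect_lt(abs(median(est) - kd_true) / kd_true, 0.15)
  }
  covered <- vapply(1:60, function(s) {
    fit <- fit_saturation(sat_series(5, seed = s,
                                     noise = trace_noise_model()))
    fit$ci95[1] <= 5 && 5 <= fit$ci95[2]
  }, logical(1))
  expect_gte(mean(covered), 0.85)
})

test_that("competition fit + ternary inversion recovers Ki from noiseless data", {
  fit <- fit_competition(comp_series(1.60))
  ki <- ki_from_ic50(fit$estimate, 7.65, 10, 0.25, l0 = 4000)
  expect_equal(ki, 1.60, tolerance = 0.02)
  # direct ternary fit is shape-exact
  expect_equal(fit_ki_direct(comp_series(1.60))$estimate, 1.60,
               tolerance = 1e-6)
  expect_equal(fit_ki_direct(comp_series(0.44))$estimate, 0.44,
               tolerance = 1e-6)
})

test_that("competition fit flags an IC50 beyond the titrated range", {
  fit <- fit_competition(comp_series(5e4))
  expect_true("EXTRAPOLATED_IC50" %in% fit$flags)
  s <- comp_series(1.60)
  s$points$fnorm <- rep(960, nrow(s$points))
  expect_error(fit_competition(s), "flat curve")
})

test_that("one-phase decay fitting recovers exact model data", {
  t <- c(0, 0.5, 1, 2, 3)
  fit <- fit_one_phase_decay(t, 100 * exp(-log(2) * t))
  expect_equal(fit$t_half, 1, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  fit2 <- fit_one_phase_decay(c(0, 1), c(100, 50))
  expect_equal(fit2$k, log(2), tolerance = 1e-9)
  expect_error(fit_one_phase_decay(c(0, 1, 2, 3), c(10, 20, 40, 80)),
               "not decaying")
  expect_error(fit_one_phase_decay(c(0.5, 1, 2), c(100, 50, 25)),
               "t = 0")
})

test_that("decay rate is recovered with negligible bias at default noise", {
  k_true <- log(2) / 0.42
  ks <- vapply(1:200, function(s) {
    cr <- simulate_degradation_course("PRE_IMMUNE", 4000, seed = s)
    fit_one_phase_decay(cr$times, percent_heroin(cr$concentrations, 4000))$k
  }, numeric(1))
  expect_lt(abs(median(ks) - k_true) / k_true, 0.02)
})

test_that("r-squared follows its definition", {
  expect_equal(goodness_of_fit(c(1, 2, 3), c(1, 2, 3)), 1)
  obs <- c(4, 7, 2, 9)
  expect_equal(goodness_of_fit(obs, rep(mean(obs), 4)), 0)
  expect_equal(goodness_of_fit(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_error(goodness_of_fit(c(2, 2, 2), c(1, 2, 3)), "zero variance")
  expect_error(goodness_of_fit(1:4, 1:3), "length")
})
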