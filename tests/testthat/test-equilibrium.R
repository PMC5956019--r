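test_that("binary bound fraction matches its analytic limits", {
  expect_equal(binary_bound_fraction(0, 0.25, 5), 0)
  # hyperbolic limit: trace tracer at A = Kd gives half occupancy
  expect_equal(binary_bound_fraction(5, 1e-9 * 5, 5), 0.5, tolerance = 1e-6)
  # stoichiometric limit: Kd -> 0 with equimolar ligand binds everything
  expect_equal(binary_bound_fraction(10, 10, 1e-12), 1, tolerance = 1e-6)
  expect_error(binary_bound_fraction(1, 0, 5), "degenerate")
  # stays within [0, 1] across a wide sweep
  f <- binary_bound_fraction(10^seq(-3, 6, by = 0.5), 0.25, 7.65)
  expect_true(all(f >= 0 & f <= 1))
  expect_true(all(diff(f) > 0))
})

test_that("ternary equilibrium reduces to the binary case and its limits", {
  kd <- 5; t0 <- 0.25; i0 <- 10
  st0 <- ternary_equilibrium(ternary_system(i0, t0, 0, kd, 1))
  expect_equal(st0$bound_tracer,
               binary_bound_fraction(i0, t0, kd) * t0, tolerance = 1e-9)
  # effectively non-binding competitor changes nothing
  st_inf <- ternary_equilibrium(ternary_system(i0, t0, 100, kd, 1e12))
  expect_equal(st_inf$bound_tracer, st0$bound_tracer, tolerance = 1e-6)
  # symmetric ligands bind equally
  st_sym <- ternary_equilibrium(ternary_system(i0, 3, 3, 2, 2))
  expect_equal(st_sym$bound_tracer, st_sym$bound_competitor,
               tolerance = 1e-9)
})

test_that("ternary solver agrees with the independent bisection oracle", {
  st <- ternary_equilibrium(ternary_system(10, 0.25, 100, 5, 1))
  expect_equal(st$bound_tracer,
               oracle_ternary_bound_tracer(10, 0.25, 100, 5, 1),
               tolerance = 1e-8)
  set.seed(42)
  for (i in 1:200) {
    i0 <- 10^runif(1, -1, 3); t0 <- 10^runif(1, -2, 1)
    l0 <- 10^runif(1, -2, 5)
    kd <- 10^runif(1, -2, 6); ki <- 10^runif(1, -2, 6)
    got <- ternary_equilibrium(ternary_system(i0, t0, l0, kd, ki))$bound_tracer
    want <- oracle_ternary_bound_tracer(i0, t0, l0, kd, ki)
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("ternary equilibrium conserves mass for every component", {
  set.seed(7)
  for (i in 1:1000) {
    i0 <- 10^runif(1, -2, 3); t0 <- 10^runif(1, -2, 2)
    l0 <- 10^runif(1, -2, 5)
    kd <- 10^runif(1, -2, 6); ki <- 10^runif(1, -2, 6)
    st <- ternary_equilibrium(ternary_system(i0, t0, l0, kd, ki))
    expect_true(all(unlist(st) >= -1e-12))
    expect_equal(st$bound_tracer + st$free_tracer, t0,
                 tolerance = 1e-9)
    expect_equal(st$bound_competitor + st$free_competitor, l0,
                 tolerance = 1e-9)
    expect_equal(st$free_sites + st$bound_tracer + st$bound_competitor, i0,
                 tolerance = 1e-9)
  }
})

test_that("bound tracer responds monotonically to the design knobs", {
  base <- function(l0 = 10, i0 = 10, ki = 2)
    ternary_equilibrium(ternary_system(i0, 0.25, l0, 5, ki))$bound_tracer
  l_grid <- c(0, 1, 10, 100, 1000)
  expect_true(all(diff(vapply(l_grid, function(l) base(l0 = l),
                              numeric(1))) < 0))
  i_grid <- c(1, 5, 10, 50)
  expect_true(all(diff(vapply(i_grid, function(i) base(i0 = i),
                              numeric(1))) > 0))
  ki_grid <- c(0.1, 1, 10, 100)  # weaker competitor -> more tracer bound
  expect_true(all(diff(vapply(ki_grid, function(k) base(ki = k),
                              numeric(1))) > 0))
})

test_that("IC50 matches Cheng-Prusoff when antibody depletion is negligible", {
  ic <- ic50_from_ki(2, kd = 5, i0 = 1e-6, t0 = 0.25)
  expect_equal(ic, cheng_prusoff_ic50(2, 5, 0.25), tolerance = 0.005)
  # linearity in the limit: doubling Ki doubles the IC50
  ic2 <- ic50_from_ki(4, kd = 5, i0 = 1e-6, t0 = 0.25)
  expect_equal(ic2 / ic, 2, tolerance = 0.005)
  # a barely-binding competitor needs an enormous IC50
  expect_gt(ic50_from_ki(1e9, kd = 5, i0 = 10, t0 = 0.25), 1e8)
})

test_that("ki_from_ic50 inverts ic50_from_ki", {
  ic <- ic50_from_ki(7.3, kd = 7.65, i0 = 10, t0 = 0.25)
  expect_equal(ki_from_ic50(ic, 7.65, 10, 0.25, l0 = 4000), 7.3,
               tolerance = 1e-6)
  # Cheng-Prusoff limit inversion
  expect_equal(ki_from_ic50(2.1, kd = 5, i0 = 1e-6, t0 = 0.25, l0 = 4000),
               2.0, tolerance = 0.005)
  # identity across four decades at the standard polyclonal design
  for (ki in 10^seq(-1, 4, by = 1)) {
    ic <- ic50_from_ki(ki, kd = 7.65, i0 = 10, t0 = 0.25)
    expect_equal(ki_from_ic50(ic, 7.65, 10, 0.25, l0 = 1e7), ki,
                 tolerance = 1e-6)
  }
  # monotone: larger measured IC50 implies weaker competitor
  kis <- vapply(c(8, 12, 20, 50, 200), function(ic)
    ki_from_ic50(ic, 4.58, 10, 0.25, l0 = 4000), numeric(1))
  expect_true(all(diff(kis) > 0))
  expect_error(ki_from_ic50(5000, 4.58, 10, 0.25, l0 = 4000),
               "not identifiable")
})

test_that("Mueller's equation inverts the binary depletion isotherm", {
  expect_equal(mueller_binding_sites(0, 5, 5), 0)
  expect_equal(mueller_binding_sites(0.5, 5, 5), 7.5)
  expect_error(mueller_binding_sites(1, 5, 5), "\\[0, 1\\)")
  b <- binary_bound_fraction(12, 5, 3)
  expect_equal(mueller_binding_sites(b, 5, 3), 12, tolerance = 1e-9)
  # round trip across random systems
  set.seed(11)
  for (i in 1:50) {
    ab <- 10^runif(1, -1, 3); t0 <- 10^runif(1, -1, 1)
    kd <- 10^runif(1, -2, 3)
    b <- binary_bound_fraction(ab, t0, kd)
    expect_equal(mueller_binding_sites(b, t0, kd), ab,
                 tolerance = 1e-9 * max(ab, 1))
  }
})

test_that("binding-site estimates average arithmetically", {
  expect_equal(average_binding_sites(10), 10)
  expect_equal(average_binding_sites(c(8, 12)), 10)
  expect_error(average_binding_sites(numeric(0)), "no binding-site")
  b <- binary_bound_fraction(12, 5, 3)
  est <- mueller_binding_sites(b, 5, 3)
  expect_equal(average_binding_sites(c(est, est)), 12, tolerance = 1e-9)
})
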