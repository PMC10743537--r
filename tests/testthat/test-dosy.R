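experiment1 <- function() {
  as_binding_experiment(
    read_diffusion_table(example_path("dosy_binding_compound1.csv")),
    c_ligand = 0.6, c_dna = 0.6)
}
experiment2 <- function() {
  as_binding_experiment(
    read_diffusion_table(example_path("dosy_binding_compound2.csv")),
    c_ligand = 0.6, c_dna = 0.6)
}

test_that("free_fraction reproduces the measured mixture and its limits", {
  expect_equal(free_fraction(0.93, 2.12, 0.74), 0.138, tolerance = 5e-3)
  expect_equal(free_fraction(2.12, 2.12, 0.74), 1)
  expect_equal(free_fraction(0.74, 2.12, 0.74), 0)
  expect_error(free_fraction(0.9, 0.8, 0.8), "unobservable")
  # clipped within noise, rejected beyond it
  expect_warning(mf <- free_fraction(0.72, 2.12, 0.74, noise = 0.05), "clipped")
  expect_equal(mf, 0)
  expect_error(free_fraction(0.30, 2.12, 0.74, noise = 0.05), "fast-exchange")
  # invariant under common rescaling of all three coefficients
  expect_equal(free_fraction(0.93, 2.12, 0.74),
               free_fraction(9.3, 21.2, 7.4))
})

test_that("complex concentration and binding constant are exact arithmetic", {
  expect_equal(complex_concentration(0.90, 0.60), 0.54)
  expect_equal(complex_concentration(0, 0.7), 0)
  expect_equal(complex_concentration(1, 0.7), 0.7)
  expect_equal(binding_constant(0.54, 0.60, 0.60), 150)
  expect_equal(binding_constant(0.51739, 0.60, 0.60), 76, tolerance = 5e-3)
  expect_equal(binding_constant(1e-9, 0.6, 0.6), 1e-9 / 0.36, tolerance = 1e-6)
  expect_error(binding_constant(0.6, 0.6, 0.8), "saturated")
})

test_that("solve_equilibrium matches a bisection oracle and its limits", {
  for (ka in c(1, 10, 76, 150, 500)) {
    for (cc in list(c(0.6, 0.6), c(0.1, 0.5), c(2, 1), c(0.3, 1.7))) {
      expect_equal(solve_equilibrium(ka, cc[1], cc[2]),
                   oracle_equilibrium(ka, cc[1], cc[2]), tolerance = 1e-9)
    }
  }
  expect_equal(solve_equilibrium(150, 0.60, 0.60), 0.54, tolerance = 1e-3)
  expect_equal(solve_equilibrium(0, 0.6, 0.6), 0)
  expect_equal(solve_equilibrium(1e9, 0.6, 0.4), 0.4, tolerance = 1e-4)
})

test_that("the DOSY chain reproduces both measured binding experiments", {
  b1 <- analyze_binding(experiment1())
  expect_equal(b1$mf_bound, 0.86, tolerance = 0.005)
  expect_equal(b1$ka, 76, tolerance = 0.01)
  b2 <- analyze_binding(experiment2())
  expect_equal(b2$mf_bound, 0.90, tolerance = 1e-9)
  expect_equal(b2$ka, 150, tolerance = 1e-9)
  expect_false(b1$no_binding || b2$no_binding)
  expect_match(paste(attr(b1, "assumptions"), collapse = " "), "1:1")
})

test_that("a ligand diffusing as when free reports no binding", {
  e <- experiment1()
  e$d_obs_ligand <- e$d_free_ligand
  b <- analyze_binding(e)
  expect_true(b$no_binding)
  expect_equal(b$ka, 0)
})

test_that("the free-ligand coefficient comes from the most dilute record", {
  e <- experiment1()
  expect_equal(e$d_free_ligand, 2.12)   # 0.05 mM record, not 0.78 mM
  expect_equal(e$sigma_d_free_ligand, 0.10)
})

test_that("the binding chain is monotone in the observed ligand coefficient", {
  e <- experiment1()
  kas <- vapply(seq(0.92, 0.80, by = -0.02), function(d) {
    e$d_obs_ligand <- d
    analyze_binding(e)$ka
  }, numeric(1))
  expect_true(all(diff(kas) > 0))
})

test_that("round-trip through the equilibrium recovers ka exactly", {
  for (ka in c(1, 10, 76, 150, 500)) {
    for (cc in list(c(0.6, 0.6), c(0.1, 0.5), c(2, 1))) {
      spec <- synthetic_spec(seed = 1, binding_truth_ka = ka,
                             d_complex = 0.70, d_noise_sd = 0)
      e <- simulate_dosy_experiment(spec, c_dna = cc[1], c_ligand = cc[2])
      b <- analyze_binding(e, d_complex = 0.70)
      expect_equal(b$ka, ka, tolerance = 1e-6)
    }
  }
})

test_that("delta-method ka uncertainty brackets the Monte-Carlo spread", {
  for (e in list(experiment1(), experiment2())) {
    b <- analyze_binding(e)
    mc <- ka_uncertainty_mc(e, n = 1e4, seed = 99)
    ratio <- mc$ka_sigma_robust / b$ka_sigma
    expect_gt(ratio, 0.5)
    expect_lt(ratio, 2)
    expect_gt(mc$n_valid, 9000)
  }
})

test_that("the DNA-side consistency check needs an independent complex coefficient", {
  # simulate with a complex slower than the free duplex, then check both
  # mass balances agree on [DNA.L]
  spec <- synthetic_spec(seed = 4, binding_truth_ka = 100,
                         d_complex = 0.70, d_noise_sd = 0)
  e <- simulate_dosy_experiment(spec, 0.6, 0.6)
  x_l <- analyze_binding(e, d_complex = 0.70)$complex_conc
  x_dna <- complex_conc_dna_side(e$d_obs_dna, e$d_free_dna, 0.70, 0.6)
  expect_equal(x_l, x_dna, tolerance = 1e-9)
  expect_error(complex_conc_dna_side(0.74, 0.75, 0.75, 0.6), "unobservable")
})

test_that("concentration trend check reads the dilution diffusion data", {
  r <- read_diffusion_table(example_path("diffusion_free_ligand.csv"))
  tr <- check_concentration_trend(r)
  expect_equal(nrow(tr), 2)
  expect_true(all(tr$monotone_decreasing))
  expect_true(all(tr$conclusion == "aggregation-consistent"))
})

test_that("trend check flags counterexamples and degenerate input", {
  up <- tibble::tibble(species_id = "x", conc = c(0.1, 0.5, 1),
                       d_coef = c(1.5, 1.8, 2.1), d_sigma = 0.01)
  expect_equal(check_concentration_trend(up)$conclusion, "trend violated")
  flat <- tibble::tibble(species_id = "x", conc = c(0.1, 0.5),
                         d_coef = c(2, 2), d_sigma = 0.05)
  expect_equal(check_concentration_trend(flat)$conclusion,
               "no significant trend")
  one <- flat[1, ]
  expect_error(check_concentration_trend(one), "fewer than 2")
})
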