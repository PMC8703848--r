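# independent oracle: the reduced-mobility formulation
#   K = L / (t_A E),  K0 = K (P/760)(273.15/T),
#   CCS = 3 z e / (16 N0) * sqrt(2 pi / (mu kb T)) / K0
# (distinct algebraic route from the package's direct evaluation)
oracle_ccs <- function(t_a_ms, e_vcm, l_cm, p_torr, t_k, mi_da,
                       mb_da = 28.0134, z = 1) {
  e <- 1.602176634e-19; kb <- 1.380649e-23
  N0 <- 2.6867811e25; da <- 1.66053907e-27
  K <- l_cm / (t_a_ms * 1e-3 * e_vcm) * 1e-4          # m^2 / (V s)
  K0 <- K * (p_torr / 760) * (273.15 / t_k)
  mu <- (mi_da * mb_da / (mi_da + mb_da)) * da
  3 * z * e / (16 * N0) * sqrt(2 * pi / (mu * kb * t_k)) / K0 * 1e20
}

ref_cond <- function(t_a = 20) {
  drift_conditions(t_a = t_a, e_field = 15, length = 78, pressure = 4,
                   temperature = 300, ion_mass = 300)
}

test_that("reduced-mass term: arithmetic, symmetry, limits, domain", {
  expect_equal(reduced_mass_term(28, 28), sqrt(2 / 28))
  expect_equal(reduced_mass_term(100, 28), 0.2138091, tolerance = 1e-6)
  expect_equal(reduced_mass_term(100, 28), reduced_mass_term(28, 100))
  expect_equal(reduced_mass_term(1e12, 28), sqrt(1 / 28), tolerance = 1e-6)
  # strictly decreasing in each argument
  expect_true(reduced_mass_term(120, 28) < reduced_mass_term(100, 28))
  expect_error(reduced_mass_term(-1, 28), "positive")
})

test_that("direct evaluation agrees with the mobility-route oracle to 6 sig figs", {
  grid <- expand.grid(t_a = c(12, 20, 35), p = c(2, 4, 760),
                      t_k = c(250, 300, 373), mi = c(150, 300, 800))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    cond <- drift_conditions(t_a = g$t_a, e_field = 15, length = 78,
                             pressure = g$p, temperature = g$t_k,
                             ion_mass = g$mi)
    expect_equal(ccs_from_drift(cond)$value,
                 oracle_ccs(g$t_a, 15, 78, g$p, g$t_k, g$mi),
                 tolerance = 1e-7)
  }
})

test_that("CCS is linear in t_A and E, inverse in L and P", {
  base <- ccs_from_drift(ref_cond())$value
  expect_equal(ccs_from_drift(ref_cond(t_a = 40))$value, 2 * base)
  half_e <- drift_conditions(t_a = 20, e_field = 7.5, length = 78,
                             pressure = 4, temperature = 300, ion_mass = 300)
  expect_equal(ccs_from_drift(half_e)$value, base / 2)
  # invariance under simultaneous doubling of L and t_A
  both <- drift_conditions(t_a = 40, e_field = 15, length = 156,
                           pressure = 4, temperature = 300, ion_mass = 300)
  expect_equal(ccs_from_drift(both)$value, base)
  double_p <- drift_conditions(t_a = 20, e_field = 15, length = 78,
                               pressure = 8, temperature = 300,
                               ion_mass = 300)
  expect_equal(ccs_from_drift(double_p)$value, base / 2)
})

test_that("drift_time_from_ccs is the exact inverse and monotone", {
  cond <- ref_cond()
  ccs <- ccs_from_drift(cond)
  t_back <- drift_time_from_ccs(ccs, cond)
  expect_equal(t_back, 20, tolerance = 1e-9)
  roundtrip <- ccs_from_drift(ref_cond(t_a = t_back))$value
  expect_equal(roundtrip / ccs$value, 1, tolerance = 1e-9)
  expect_gt(drift_time_from_ccs(ccs_value(250), cond),
            drift_time_from_ccs(ccs_value(150), cond))
})

test_that("SI unit input converges to the same CCS", {
  cond_si <- drift_conditions(t_a = 20e-3, e_field = 1500, length = 0.78,
                              pressure = 4 * 133.322368, temperature = 300,
                              ion_mass = 300, units = "si")
  expect_equal(ccs_from_drift(cond_si)$value,
               ccs_from_drift(ref_cond())$value, tolerance = 1e-9)
})

test_that("frozen regression value for the reference condition set", {
  # independently derived via the mobility route (see oracle_ccs)
  expect_equal(ccs_from_drift(ref_cond())$value, 169.4513584,
               tolerance = 1e-8)
})

test_that("invalid conditions are rejected", {
  expect_error(drift_conditions(t_a = 20, e_field = -1, length = 78,
                                pressure = 4, temperature = 300,
                                ion_mass = 300), "positive")
  expect_error(ccs_from_drift(drift_conditions(e_field = 15, length = 78,
                                               pressure = 4,
                                               temperature = 300,
                                               ion_mass = 300)),
               "arrival time")
  expect_error(ccs_value(-3), "positive")
})
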