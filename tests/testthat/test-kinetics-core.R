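# Closed-form tight-binding algebra against brute-force oracles.

test_that("kinetic_params validates positivity and kon/koff/Kd consistency", {
  expect_s3_class(kinetic_params(Km = 1, kcat = 0.05), "kinetic_params")
  expect_error(kinetic_params(Km = -1, kcat = 0.05), "positive")
  expect_error(kinetic_params(Km = 1, kcat = 0), "positive")
  # Kd = koff/kon must hold when all three are given
  expect_silent(kinetic_params(Km = 1, kcat = 0.05, kon = 0.057,
                               koff = 0.0068, Kd = 0.0068 / 0.057))
  expect_error(kinetic_params(Km = 1, kcat = 0.05, kon = 0.057,
                              koff = 0.0068, Kd = 0.2),
               "koff/kon")
  # Km >= Kd deliberately not enforced (substrate Km vs dead-end Kd)
  expect_silent(kinetic_params(Km = 1, kcat = 0.05, Kd = 0.12))
})

test_that("bound_complex matches examples and stays in range", {
  expect_identical(bound_complex(0, 0.5, 1), 0)
  expect_equal(bound_complex(1, 0.5, 1), 0.2192, tolerance = 1e-3)
  # frozen from the bisection oracle
  expect_equal(bound_complex(1, 0.5, 1), oracle_bound_complex(1, 0.5, 1),
               tolerance = 1e-12)
  # saturation: complex -> P_T as N_T -> Inf (0.499546 from the oracle)
  expect_equal(bound_complex(1100, 0.5, 1),
               oracle_bound_complex(1100, 0.5, 1), tolerance = 1e-9)
  expect_gt(bound_complex(1100, 0.5, 1), 0.999 * 0.5)
  expect_error(bound_complex(-1, 0.5, 1), ">= 0")
  expect_error(bound_complex(1, 0.5, 0), "Km > 0")
})

test_that("bound_complex agrees with bisection oracle across a log grid", {
  g <- 10^seq(-3, 6, by = 1.5)
  for (N_T in g) for (P_T in g) for (Km in g) {
    got <- bound_complex(N_T, P_T, Km)
    want <- oracle_bound_complex(N_T, P_T, Km)
    expect_equal(got, want, tolerance = 1e-9,
                 label = sprintf("NP(N_T=%g, P_T=%g, Km=%g)", N_T, P_T, Km))
    expect_lte(got, min(N_T, P_T) * (1 + 1e-12))
  }
})

test_that("morrison_velocity reproduces examples and the classic limit", {
  p <- kinetic_params(Km = 1, kcat = 0.03)
  expect_identical(morrison_velocity(0, 0.5, p), 0)
  expect_equal(morrison_velocity(1, 0.5, p),
               0.03 * oracle_bound_complex(1, 0.5, 1), tolerance = 1e-12)
  expect_equal(morrison_velocity(1, 0.5, p), 0.006576, tolerance = 1e-3)
  # near-Vmax plateau over the 50-1100 nM range
  v <- morrison_velocity(c(50, 1100), 0.5, p)
  expect_equal(v[2], 0.01499, tolerance = 1e-3)
  expect_true(all(v > 0.98 * 0.015))
  # strictly increasing in N_T
  vv <- morrison_velocity(10^seq(-2, 4, by = 0.25), 0.5, p)
  expect_true(all(diff(vv) > 0))
})

test_that("morrison_velocity converges to Michaelis-Menten when enzyme is dilute", {
  p <- kinetic_params(Km = 5, kcat = 0.1)
  for (N_T in c(0.5, 5, 50)) {
    P_T <- 0.009 * (p$Km + N_T)   # P_T < 0.01 (Km + N_T)
    v_tb <- morrison_velocity(N_T, P_T, p)
    v_mm <- p$kcat * P_T * N_T / (p$Km + N_T)
    expect_lt(abs(v_tb - v_mm) / v_mm, 0.01)
  }
})

test_that("competitive free concentrations solve the coupled relations", {
  # O_T = 0 closed form reduces to P_T/(1 + N_T/Km)
  fc <- free_concentrations_competitive(
    species_totals(N_T = 50, P_T = 0.25), Km = 1, KdO = 30)
  expect_equal(fc$P, 0.25 / 51, tolerance = 1e-12)
  expect_equal(fc$P, 0.004902, tolerance = 1e-3)
  # with competitor: matches fixed-point iteration of the three relations
  fc <- free_concentrations_competitive(
    species_totals(N_T = 50, P_T = 0.25, O_T = 30), Km = 1, KdO = 30)
  orc <- oracle_competitive(50, 0.25, 30, 1, 30)
  expect_equal(fc$P, orc$P, tolerance = 1e-10)
  expect_equal(fc$O, orc$O, tolerance = 1e-10)
  # competitor saturation: P -> 0
  fc_inf <- free_concentrations_competitive(
    species_totals(N_T = 50, P_T = 0.25, O_T = 1e9), Km = 1, KdO = 30)
  expect_lt(fc_inf$P, 1e-8)
  # monotone decreasing in O_T and N_T
  Ps_O <- sapply(c(0, 1, 10, 100, 1e3, 1e4), function(o)
    free_concentrations_competitive(
      species_totals(N_T = 50, P_T = 0.25, O_T = o), 1, 30)$P)
  expect_true(all(diff(Ps_O) < 0))
  Ps_N <- sapply(c(30, 50, 100, 300, 1000), function(n)
    free_concentrations_competitive(
      species_totals(N_T = n, P_T = 0.25, O_T = 10), 1, 30)$P)
  expect_true(all(diff(Ps_N) < 0))
})

test_that("competitive solver enforces its substrate-excess regime", {
  expect_error(
    free_concentrations_competitive(
      species_totals(N_T = 10, P_T = 0.25), Km = 1),
    "N_T/P_T")
})

test_that("tqssa_free_pair solves both relations simultaneously", {
  # sequestration regime: most pEndos free, enzyme nearly all bound
  fp <- tqssa_free_pair(1000, 250, 1)
  expect_equal(fp$N, 750, tolerance = 1e-3)
  expect_equal(fp$P, 1 * 250 / fp$N, tolerance = 2e-3)
  # relations hold exactly at the returned point
  expect_equal(fp$N, 1000 / (1 + fp$P / 1), tolerance = 1e-9)
  expect_equal(fp$P, 250 / (1 + fp$N / 1), tolerance = 1e-9)
  # trivial and excess-enzyme cases
  expect_equal(tqssa_free_pair(0, 250, 1), list(N = 0, P = 250))
  fp2 <- tqssa_free_pair(125, 250, 1)
  expect_equal(fp2$P, 125, tolerance = 2e-2)
  # complex identical to bound_complex
  expect_equal(1000 - fp$N, bound_complex(1000, 250, 1), tolerance = 1e-12)
})

test_that("competitive (O_T = 0) and tqssa solutions agree in the excess regime", {
  # the substrate-excess approximation [N] ~ N_T carries a relative
  # error in P bounded by P_T/N_T; assert that bound across the regime
  # and 0.1% agreement deep inside it
  for (ratio in c(100, 300, 1000, 5000)) {
    for (N_T in c(50, 500, 5000)) {
      P_T <- N_T / ratio
      fc <- free_concentrations_competitive(
        species_totals(N_T = N_T, P_T = P_T), Km = 2, KdO = 30)
      fp <- tqssa_free_pair(N_T, P_T, 2)
      rel <- abs(fc$P / fp$P - 1)
      expect_lt(rel, 1.1 / ratio)
      if (ratio >= 1000) expect_lt(rel, 1e-3)
      # tqssa solution matches the explicit binding equilibrium
      # (kcat = 0, Kd = Km) essentially exactly
      np_eq <- oracle_bound_complex(N_T, P_T, 2)
      expect_equal(fp$P, P_T - np_eq, tolerance = 1e-9)
    }
  }
})

test_that("unit helpers convert to canonical nM / s", {
  expect_equal(uM_to_nM(0.47), 470)
  expect_equal(nM_to_uM(85000), 85)
  expect_equal(per_min_to_per_s(0.020), 0.020 / 60)
})
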