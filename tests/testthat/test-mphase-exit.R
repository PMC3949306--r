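# M-phase-exit scenarios: tQSSA integration, mass-action cross-check,
# desequestration times, fractional velocities, validity diagnostics.

test_that("the three canonical scenarios reproduce their desequestration times", {
  t_a <- half_desequestration_time(simulate_tqssa(mphase_scenario("pp2a_only")))
  t_b <- half_desequestration_time(simulate_tqssa(mphase_scenario("with_ppx")))
  t_c <- half_desequestration_time(simulate_tqssa(mphase_scenario("dead_end")))
  expect_equal(t_a, 74, tolerance = 2 / 74)
  expect_equal(t_b, 38, tolerance = 2 / 38)
  expect_equal(t_c, 6200, tolerance = 0.10)
  # ordering: PPX accelerates modestly; a dead-end inhibitor stalls exit
  expect_lt(t_b, t_a)
  expect_gt(t_c, 20 * t_a)
})

test_that("half_desequestration_time handles edge cases", {
  tr <- kin_trajectory(data.frame(t = 0:10,
                                  free_P_fraction = seq(0.6, 1,
                                                        length.out = 11)))
  expect_equal(half_desequestration_time(tr), 0)
  short <- simulate_tqssa(mphase_scenario("dead_end"), horizon = 1000)
  expect_identical(half_desequestration_time(short), Inf)
})

test_that("trajectory fractions are monotone and bounded", {
  traj <- simulate_tqssa(mphase_scenario("with_ppx"))
  expect_true(all(diff(traj$phospho_fraction) <= 1e-12))
  expect_true(all(diff(traj$free_P_fraction) >= -1e-12))
  expect_true(all(traj$N_T >= 0 & traj$P >= 0 & traj$X >= 0))
})

test_that("pEndos consumption is zero-order while the enzyme is saturated", {
  traj <- simulate_tqssa(mphase_scenario("pp2a_only"), horizon = 600,
                         dt = 0.05)
  # window where N_T is between ~1.5 P_T and N_T0: all enzyme sequestered
  i <- which(traj$N_T < 950 & traj$N_T > 1.5 * 250)
  rate <- -diff(traj$N_T[i]) / diff(traj$t[i])
  expect_true(all(abs(rate / (0.05 * 250) - 1) < 0.01))
})

test_that("mass-action integration conserves totals to 1e-9", {
  for (sc in c("pp2a_only", "dead_end")) {
    cfg <- mphase_scenario(sc)
    ma <- simulate_mass_action(cfg, horizon = 200)
    expect_lt(max(abs(ma$N + ma$NP + ma$released - cfg$N_T0)) / cfg$N_T0,
              1e-9)
    expect_lt(max(abs(ma$P + ma$NP - cfg$P_T)) / cfg$P_T, 1e-9)
  }
})

test_that("tQSSA and mass-action trajectories agree beyond the transient", {
  for (sc in c("pp2a_only", "with_ppx", "dead_end")) {
    cfg <- mphase_scenario(sc)
    hor <- if (sc == "dead_end") 2e4 else 600
    tq <- simulate_tqssa(cfg, horizon = hor)
    ma <- simulate_mass_action(cfg, horizon = hor)
    i <- tq$t >= 1
    ma_pf <- stats::approx(ma$t, ma$phospho_fraction, tq$t[i])$y
    # sup-norm agreement of the fraction curves: "visually
    # indistinguishable"
    expect_lt(max(abs(ma_pf - tq$phospho_fraction[i])), 0.01,
              label = sprintf("sup-norm dev (%s)", sc))
    # relative agreement while the substrate is still detectable
    j <- i & tq$phospho_fraction >= 0.01
    ma_pf2 <- stats::approx(ma$t, ma$phospho_fraction, tq$t[j])$y
    expect_lt(max(abs(ma_pf2 / tq$phospho_fraction[j] - 1)), 0.02,
              label = sprintf("relative dev at detectable levels (%s)", sc))
  }
})

test_that("the initial instants differ by construction", {
  cfg <- mphase_scenario("pp2a_only")
  tq <- simulate_tqssa(cfg, horizon = 10, dt = 0.01)
  ma <- simulate_mass_action(cfg, horizon = 10, dt = 0.01)
  # tQSSA has the complex pre-formed at t = 0; mass action starts unbound
  expect_equal(ma$free_P_fraction[1], 1)
  expect_lt(tq$free_P_fraction[1], 0.01)
  # but they meet within a few transient times t_c (~0.02 s)
  k <- which(tq$t >= 0.5)[1]
  expect_equal(ma$free_P_fraction[k], tq$free_P_fraction[k],
               tolerance = 0.01)
})

test_that("Briggs-Haldane koff is required to be positive", {
  cfg <- scenario_config(N_T0 = 1000, P_T = 250, Km_P = 1, kcat_P = 0.05,
                         kon = 0.01)   # kon*Km < kcat
  expect_error(simulate_mass_action(cfg), "koff")
})

test_that("fractional velocities are normalized and switch with pEndos level", {
  cfg <- mphase_scenario("with_ppx")
  fv <- fractional_velocities(c(100, 300, 1000), cfg)
  expect_equal(fv$f_P + fv$f_X, rep(1, 3), tolerance = 1e-12)
  # below the PP2A-B55 pool, pEndos is protected from PPX
  expect_lt(fv$f_X[fv$N_T0 == 100], 0.01)
  # in large excess, PPX dominates raw flux
  expect_gt(fv$f_X[fv$N_T0 == 1000], 0.5)
  expect_error(fractional_velocities(100, mphase_scenario("pp2a_only")),
               "X_T")
})

test_that("validity diagnostics reproduce both epsilon readings and t_c", {
  val <- tqssa_validity(mphase_scenario("pp2a_only"))
  expect_equal(val$t_c, 1 / (0.057 * 1001), tolerance = 1e-12)
  expect_equal(round(val$t_c, 2), 0.02)
  expect_equal(val$epsilon, 0.05 * 250 / (0.057 * 1251^2),
               tolerance = 1e-12)
  expect_equal(val$epsilon, 1.4e-4, tolerance = 0.01)
  expect_equal(val$epsilon_per_nM, 5.6e-7, tolerance = 0.01)
  expect_true(val$valid)
  # instantaneous-binding limit
  fast <- mphase_scenario("pp2a_only")
  fast$kon <- 1e6
  val2 <- tqssa_validity(fast)
  expect_lt(val2$epsilon, 1e-10)
  expect_lt(val2$t_c, 1e-8)
})
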