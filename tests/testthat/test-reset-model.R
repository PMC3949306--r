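# Automatic-reset model: control closed form, inhibited simulation,
# lag definition, two-stage fitting, dose-response and IC50 -> Kd.

test_that("control closed form matches hand evaluation and its limits", {
  cfg <- fig8b_config(N_T0 = 0, deg_onset = 0)
  expect_equal(control_release_curve(cfg, 0), 0)
  # 0.52 * 0.47 * 0.25 nM/s for 600 s with kdeg = 0.020/min
  rate0 <- 0.52 * 0.47 * 0.25
  kd <- 0.020 / 60
  expect_equal(control_release_curve(cfg, 600),
               rate0 * (1 - exp(-kd * 600)) / kd, tolerance = 1e-12)
  expect_equal(control_release_curve(cfg, 600), 33.23, tolerance = 1e-3)
  # kdeg -> 0 limit is linear and bounds the decayed curve from above
  cfg0 <- fig8b_config(N_T0 = 0, deg_onset = 0, kdeg = 0)
  expect_equal(control_release_curve(cfg0, 600), rate0 * 600,
               tolerance = 1e-12)
  expect_equal(control_release_curve(cfg0, 600), 36.67, tolerance = 1e-3)
  expect_gt(control_release_curve(cfg0, 600),
            control_release_curve(cfg, 600))
})

test_that("simulate_reset with no inhibitor equals the closed form", {
  cfg <- fig8b_config(N_T0 = 0, deg_onset = 0)
  tg <- seq(0, 7200, by = 300)
  traj <- simulate_reset(cfg, tg)
  expect_equal(traj$released[-1], control_release_curve(cfg, tg[-1]),
               tolerance = 1e-8)
})

test_that("reset trajectories respect mass balance and curve ordering", {
  tg <- seq(0, 7200, by = 60)
  ctl <- simulate_reset(fig8b_config(N_T0 = 0, deg_onset = 0), tg)
  sub <- simulate_reset(fig8b_config(), tg)
  ded <- simulate_reset(fig8b_config(inhibitor_mode = "dead_end",
                                     Kd_dead = 0.12), tg)
  for (tr in list(ctl, sub, ded)) {
    expect_true(all(tr$released <= 470 + 1e-9))
    expect_true(all(diff(tr$N_T) <= 1e-9))
  }
  # dead-end <= substrate-mode <= control at every time point
  expect_true(all(ded$released <= sub$released + 1e-9))
  expect_true(all(sub$released <= ctl$released + 1e-9))
})

test_that("lag_time implements the 50%-of-control-rate definition", {
  tg <- seq(0, 7200, by = 10)
  ctl <- simulate_reset(fig8b_config(N_T0 = 0, deg_onset = 0), tg)
  expect_equal(lag_time(ctl, ctl), 0)
  inh <- simulate_reset(fig8b_config(), tg)
  lag <- lag_time(inh, ctl)
  expect_gt(lag / 60, 30)
  expect_lt(lag / 60, 40)
  # thiophosphorylated pEndos (dead-end, Kd 0.12 nM): no recovery in 2 h
  ded <- simulate_reset(fig8b_config(inhibitor_mode = "dead_end",
                                     Kd_dead = 0.12), tg)
  expect_identical(lag_time(ded, ctl), Inf)
})

test_that("two-stage reset fit recovers noiseless truth", {
  cfg <- fig8b_config()
  tc <- gen_reset_timecourses(cfg, noise = noise_model(cv = 0,
                                                       replicates = 1))
  fits <- fit_reset(tc$control, tc$inhibited, cfg)
  expect_equal(est_value(fits$control, "eff_C"), 0.52, tolerance = 1e-6)
  expect_equal(est_value(fits$control, "kdeg"), 0.020, tolerance = 1e-6)
  expect_equal(est_value(fits$inhibited, "Km"), 0.47, tolerance = 1e-4)
  expect_equal(est_value(fits$inhibited, "kcat"), 0.03, tolerance = 1e-4)
})

test_that("reset fit tolerates 5% fractional noise", {
  cfg <- fig8b_config()
  tc <- gen_reset_timecourses(cfg, noise = noise_model(cv = 0.05,
                                                       replicates = 3,
                                                       seed = 4))
  fits <- fit_reset(tc$control, tc$inhibited, cfg)
  # within the SE scale of the underlying experiment (+/- 0.14 nM)
  expect_lt(abs(est_value(fits$inhibited, "Km") - 0.47), 0.14)
})

test_that("tight-binding dose-response locates the IC50 on the fitted curve", {
  # Kd 0.12 nM assayed at P_T 0.125 nM against 5 uM substrate (Km 85 uM)
  Kd_app <- 0.12 * (1 + 5 / 85)
  P_T <- 0.125
  doses <- c(0, 10^seq(-2.5, 1, length.out = 9))
  act <- (P_T - bound_complex(doses, P_T, Kd_app)) / P_T
  res <- fit_dose_response(data.frame(conc = doses, activity = act),
                           P_T = P_T)
  # analytic IC50 for the Morrison curve: P_T/2 + Kd_app
  expect_equal(res$IC50, P_T / 2 + Kd_app, tolerance = 1e-4)
  expect_equal(res$IC50, 0.19, tolerance = 0.01)
  # zero-inhibitor plateau recovered
  expect_equal(coef(res$fit)[["top"]], 1, tolerance = 1e-6)
})

test_that("logistic dose-response returns the symmetric midpoint", {
  doses <- 10^seq(-2, 2, length.out = 9)
  act <- 1 / (1 + doses / 1)   # hill = 1, IC50 = 1, sampled at 1
  res <- fit_dose_response(data.frame(conc = doses, activity = act),
                           model = "logistic")
  expect_equal(res$IC50, 1, tolerance = 1e-6)
})

test_that("ic50_to_kd applies the tight-binding competitive correction", {
  expect_equal(ic50_to_kd(0.197, P_T = 0.125, S = 5, Km_S = 85),
               (0.197 - 0.0625) / (1 + 5 / 85), tolerance = 1e-12)
  expect_equal(ic50_to_kd(0.197, P_T = 0.125, S = 5, Km_S = 85), 0.127,
               tolerance = 1e-2)
  # classic limit: no substrate, vanishing enzyme
  expect_equal(ic50_to_kd(5, P_T = 1e-9, S = 0, Km_S = Inf), 5,
               tolerance = 1e-6)
  expect_error(ic50_to_kd(0.0625, P_T = 0.125), "titration")
})
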