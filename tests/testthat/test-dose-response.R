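# Kinetic and steady-state fitting and the confirmation rule.

test_that("global kinetic fit recovers noiseless parameters", {
  p <- kinetic_params(5e4, 0.08, 40)
  ds <- generate_dose_series(p, two_fold_series(50e-6), screen_protocol())
  fit <- fit_kinetic_1to1(ds)
  expect_true(fit$converged)
  expect_lt(abs(fit$kd_value - kd_from_rates(p)) / kd_from_rates(p), 1e-4)
  expect_lt(fit$residual_rms, 1e-8)
})

test_that("degenerate series are signalled, never silently fitted", {
  prot <- screen_protocol()
  zero <- lapply(1:4, function(i)
    sensorgram(prot$sample_times, rep(0, length(prot$sample_times)),
               cycle_id = i, role = "dose_point", concentration = 50e-6 / 2^i,
               t_inject = 10, t_stop = 60))
  fit <- fit_kinetic_1to1(zero)
  expect_false(fit$converged)
  expect_match(fit$message, "no signal")
  one <- generate_dose_series(clean_binder(), 25e-6, screen_protocol())
  expect_false(fit_kinetic_1to1(one)$converged)
})

test_that("noisy series recover KD within 10%", {
  p <- kinetic_params(5e4, 0.08, 40)  # KD 1.6 uM, Rmax 40 RU
  ds <- generate_dose_series(p, two_fold_series(50e-6), screen_protocol(),
                             noise_model(sigma = 0.3, seed = 2024))
  fit <- fit_kinetic_1to1(ds)
  expect_true(fit$converged)
  expect_lt(abs(fit$kd_value - kd_from_rates(p)) / kd_from_rates(p), 0.1)
})

test_that("global and local fits agree on shared-parameter data", {
  p <- kinetic_params(3e4, 0.05, 55)
  ds <- generate_dose_series(p, two_fold_series(40e-6), screen_protocol())
  fg <- fit_kinetic_1to1(ds, mode = "global")
  fl <- fit_kinetic_1to1(ds, mode = "local")
  expect_lt(abs(fg$kd_value - fl$kd_value) / fg$kd_value, 0.005)
  expect_lt(abs(fg$params$ka - fl$params$ka) / fg$params$ka, 0.005)
})

test_that("steady-state isotherm fit recovers KD", {
  p <- params_from_kd(82e-6, 300, rmax = 50)
  cc <- c(500, 250, 125, 62.5, 31.25, 15.62) * 1e-6
  lv <- data.frame(conc = cc, level = equilibrium_response(p, cc))
  fit <- fit_steady_state(lv)
  expect_true(fit$converged)
  expect_lt(abs(fit$kd_value - 82e-6) / 82e-6, 0.01)
  expect_false(fit$kd_poorly_determined)
  # concentrations far below KD leave the affinity unidentifiable
  cc2 <- c(1, 0.5, 0.25, 0.125) * 1e-6
  lv2 <- data.frame(conc = cc2, level = equilibrium_response(p, cc2))
  fit2 <- fit_steady_state(lv2)
  expect_true(fit2$kd_poorly_determined)
  expect_error(fit_steady_state(lv[1:2, ]), "at least 3")
})

test_that("steady-state and kinetic KD agree at long contact", {
  p <- kinetic_params(2e4, 0.03, 45)
  kobs_min <- p$ka * min(two_fold_series(50e-6)) + p$kd
  prot <- injection_protocol(contact_time = ceiling(5 / kobs_min) + 10,
                             dissociation_time = 60)
  ds <- generate_dose_series(p, two_fold_series(50e-6), prot)
  fk <- fit_kinetic_1to1(ds)
  lv <- data.frame(conc = vapply(ds, `[[`, numeric(1), "concentration"),
                   level = vapply(ds, function(s) binding_level(s)$level,
                                  numeric(1)))
  fs <- fit_steady_state(lv)
  expect_lt(abs(fk$kd_value - fs$kd_value) / fk$kd_value, 0.01)
})

test_that("the confirmation rule follows the three-part definition", {
  # six increasing levels, top %Rmax 30: confirmed
  lv <- data.frame(conc = two_fold_series(50e-6), level = c(30, 22, 14, 8, 4, 2))
  c1 <- confirm_hit(lv, percent_rmax_at_top = 30)
  expect_true(c1$confirmed)
  expect_equal(c1$n_concentration_dependent, 6)
  # flat levels: not confirmed
  flat <- data.frame(conc = two_fold_series(50e-6), level = rep(5, 6))
  expect_false(confirm_hit(flat, percent_rmax_at_top = 30)$confirmed)
  # concentration-dependent but weak (top %Rmax below 10): not pursued
  c3 <- confirm_hit(lv, percent_rmax_at_top = 8)
  expect_false(c3$confirmed)
  expect_equal(c3$n_concentration_dependent, 6)
  # noise tolerance: increases below one buffer sigma do not count
  wob <- data.frame(conc = two_fold_series(50e-6),
                    level = c(5.4, 5.2, 5.3, 5.1, 5.2, 5.0))
  expect_false(confirm_hit(wob, noise_sigma = 0.5,
                           percent_rmax_at_top = 30)$confirmed)
  # ill-behaviour above the top clean concentration is recorded
  qc <- c(TRUE, rep(FALSE, 5))  # aligned with rows (top concentration first)
  c5 <- confirm_hit(lv, qc = qc, percent_rmax_at_top = 30)
  expect_true(c5$confirmed)
  expect_equal(c5$illbehaved_above, 50e-6)
  expect_equal(c5$n_concentration_dependent, 5)
})

test_that("confirmed hits carry KD, LE and half-life", {
  p <- params_from_kd(53.4e-6, 600, rmax = 45)
  ds <- generate_dose_series(p, two_fold_series(50e-6), screen_protocol(),
                             analyte_id = "K")
  fit <- fit_kinetic_1to1(ds)
  frag <- data.frame(id = "K", mw = 280, heavy_atoms = 21)
  lv <- data.frame(conc = vapply(ds, `[[`, numeric(1), "concentration"),
                   level = vapply(ds, function(s) binding_level(s)$level,
                                  numeric(1)))
  conf <- confirm_hit(lv, fit = fit, fragment = frag,
                      surface = default_surface(), activity_factor = 1,
                      percent_rmax_at_top = 40)
  expect_true(conf$confirmed)
  expect_equal(round(conf$le, 2), 0.28)
  expect_equal(conf$t_half_min, 10, tolerance = 1e-3)
})

test_that("hit summaries reproduce published LE rows", {
  fitK <- structure(list(kd_value = 53.4e-6, converged = TRUE,
                         params = kinetic_params(1e3, 1e3 * 53.4e-6, 40),
                         fragment_id = "K"), class = "spr_fit")
  expect_equal(round(summarize_hit(fitK, data.frame(heavy_atoms = 21))$le, 2),
               0.28)
  fitL <- structure(list(kd_value = 70e-6, converged = TRUE,
                         params = kinetic_params(1e3, 1e3 * 70e-6, 40),
                         fragment_id = "L"), class = "spr_fit")
  expect_equal(round(summarize_hit(fitL, data.frame(heavy_atoms = 23))$le, 2),
               0.25)
  fit_ln2 <- structure(list(kd_value = 1e-6, converged = TRUE,
                            params = kinetic_params(log(2) * 1e6, log(2), 40),
                            fragment_id = "x"), class = "spr_fit")
  expect_equal(summarize_hit(fit_ln2, data.frame(heavy_atoms = 10))$t_half_min,
               1 / 60)
})
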