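# Background threshold, activity normalisation, %Rmax, QC and hit calling.

test_that("background threshold is mean + 3 sample SD", {
  st <- background_threshold(c(0, 0, 0, 4))
  expect_equal(st$buffer_mean, 1)
  expect_equal(st$buffer_sigma, 2)
  expect_equal(st$threshold, 7)
  # no spread: threshold equals the common level
  expect_equal(background_threshold(rep(3, 5))$threshold, 3)
  # homogeneity: scaling the levels scales the threshold
  st10 <- background_threshold(10 * c(0, 0, 0, 4))
  expect_equal(st10$threshold, 70)
  expect_error(background_threshold(1), "at least 2")
})

test_that("activity factors interpolate the probe series", {
  a <- activity_factors(c(50, 50, 50), c(1, 50, 100), 100)
  expect_true(all(a$factors == 1))
  b <- activity_factors(c(100, 85), c(1, 101), 101)
  expect_equal(b$factors[51], 0.925)
  expect_equal(b$factors[1], 1)
  # monotone decreasing probes give monotone factors, clamped to (0, 1]
  m <- activity_factors(c(100, 90, 70), c(1, 40, 80), 90)
  expect_true(all(diff(m$factors) <= 0))
  expect_true(all(m$factors > 0 & m$factors <= 1))
})

test_that("%Rmax normalises to MW, activity and background", {
  surf <- default_surface()
  st <- background_threshold(c(0.1, 0.3, 0.2, 0.2))
  expect_equal(percent_rmax(st$buffer_mean, 250, surf, 1, st), 0)
  rmax <- theoretical_rmax(250, surf)
  expect_equal(percent_rmax(rmax, 250, surf, 1), 100)
  # a binder with KD at the screen concentration sits near 50%
  p <- kinetic_params(2e3, 0.05, rmax)  # KD 25 uM
  lvl <- equilibrium_response(p, 25e-6)
  expect_equal(percent_rmax(lvl, 250, surf, 1), 50, tolerance = 1e-6)
  # invariance under a common response-unit rescaling
  surf_k <- surface_model(surf$protein_mw, 7 * surf$capture_level)
  expect_equal(percent_rmax(7 * lvl, 250, surf_k, 1),
               percent_rmax(lvl, 250, surf, 1))
})

test_that("QC flags trip on their artifact kind and only then", {
  s <- simulate_cycle(clean_binder(), 25e-6, screen_protocol())
  q0 <- qc_sensorgram(s, 40)
  expect_false(any(q0$flags))
  q1 <- qc_sensorgram(apply_artifact(s, artifact_spec("upward_drift", 0.2)), 40)
  expect_identical(names(which(q1$flags)), "upward_drift")
  q2 <- qc_sensorgram(apply_artifact(s, artifact_spec("carryover", 3)), 40)
  expect_identical(names(which(q2$flags)), "carryover")
  q3 <- qc_sensorgram(apply_artifact(s, artifact_spec("super_stoichiometry", 3)), 40)
  expect_true(q3$flags[["super_stoichiometry"]])
  q4 <- qc_sensorgram(
    apply_artifact(s, artifact_spec("slow_non11_dissociation", 0.3)), 40)
  expect_identical(names(which(q4$flags)), "non11_dissociation")
})

test_that("hit calling applies threshold, QC and promiscuity rules", {
  lib <- generate_library(60, seed = 13)
  surf <- default_surface()
  # plant: one clean target binder with KD 50 uM, one off-target-only binder
  target_id <- lib$id[10]
  prom_id <- lib$id[20]
  p50 <- kinetic_params(ka = 0.5 / 50e-6, kd = 0.5,
                        rmax = theoretical_rmax(lib$mw[10], surf))
  des <- screen_design(lib,
                       planted_binders = setNames(list(p50), target_id),
                       offtarget_binders = setNames("offtarget_CA", prom_id))
  scr <- generate_screen(des, surf, screen_protocol(),
                         noise_model(sigma = 0.3, seed = 21))
  an <- process_screen(scr, lib, surf)
  rec <- an$records
  # KD 50 uM at 25 uM: Req ~ rmax/3 >> 3 sigma, so it must be called
  expect_true(rec$is_hit[rec$fragment_id == target_id])
  expect_false(rec$promiscuous[rec$fragment_id == target_id])
  # the off-target-only binder is promiscuous and not in the clean hit list
  expect_true(rec$promiscuous[rec$fragment_id == prom_id])
  expect_false(prom_id %in% an$hits$fragment_id)
  expect_true(target_id %in% an$hits$fragment_id)
})

test_that("every strong planted binder is recovered (completeness)", {
  lib <- generate_library(120, seed = 31)
  surf <- default_surface()
  idx <- c(5, 30, 55, 80, 105)
  planted <- lapply(idx, function(i)
    kinetic_params(ka = 0.5 / 30e-6, kd = 0.5,
                   rmax = theoretical_rmax(lib$mw[i], surf)))
  names(planted) <- lib$id[idx]
  des <- screen_design(lib, planted_binders = planted)
  scr <- generate_screen(des, surf, screen_protocol(),
                         noise_model(sigma = 0.3, seed = 77))
  an <- process_screen(scr, lib, surf)
  # all planted binders have Req >> 2x threshold here
  req <- vapply(planted, equilibrium_response, numeric(1), 25e-6)
  expect_true(all(req >= 2 * an$summary$threshold))
  expect_true(all(names(planted) %in% an$hits$fragment_id))
})

test_that("pure-noise screens rarely yield hits", {
  lib <- generate_library(600, seed = 4)
  scr <- generate_screen(screen_design(lib), default_surface(),
                         screen_protocol(), noise_model(sigma = 0.3, seed = 12))
  an <- process_screen(scr, lib, default_surface())
  # expectation is 0.135%; allow the upper tail of Binomial(600, 0.00135)
  expect_lte(an$summary$n_hits, qbinom(0.999, 600, 0.00135))
})
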