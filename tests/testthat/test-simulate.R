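# Synthetic library, screen and dose-series generators.

test_that("library generation is deterministic and hits its profile", {
  expect_equal(nrow(generate_library(0)), 0)
  a <- generate_library(50, seed = 7)
  b <- generate_library(50, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, generate_library(50, seed = 8)))
  # library-scale draw: property means land within 3 sigma of the targets
  lib <- generate_library(5260, seed = 1)
  p <- library_profile()
  expect_lt(abs(mean(lib$mw) - p$mw_mean), 3 * p$mw_sd / sqrt(5260) + 1)
  expect_lt(abs(mean(lib$clogp) - p$clogp_mean),
            3 * p$clogp_sd / sqrt(5260) + 0.1)
  expect_lt(abs(mean(lib$hbd) - p$hbd_size * p$hbd_p),
            3 * sqrt(p$hbd_size * p$hbd_p * (1 - p$hbd_p) / 5260))
  expect_true(all(lib$heavy_atoms >= 1))
  expect_true(all(nchar(lib$fingerprint) == p$fp_bits / 4))
})

test_that("screens have the designed structure", {
  lib <- generate_library(40, seed = 3)
  surf <- default_surface()
  # no binders, no noise: every fragment trace on the target spot is zero
  des0 <- screen_design(lib)
  scr0 <- generate_screen(des0, surf, screen_protocol(),
                          noise_model(sigma = 0, seed = 1))
  frag_target <- scr0$meta$role == "fragment" & scr0$meta$spot == "target"
  expect_true(all(scr0$traces[, frag_target] == 0))
  # buffer blanks every 6 fragments, probes every 20 cycles
  roles <- scr0$meta$role[scr0$meta$spot == "target"]
  expect_equal(sum(roles == "buffer"), floor(40 / 6))
  expect_gte(sum(roles == "reference_ligand"), 2)

  # a strong planted binder reaches its activity-scaled theoretical Rmax
  strong <- kinetic_params(ka = 0.05 / 0.5e-6, kd = 0.05,
                           rmax = theoretical_rmax(lib$mw[4], surf))
  des1 <- screen_design(lib, planted_binders = setNames(list(strong), lib$id[4]))
  scr1 <- generate_screen(des1, surf, screen_protocol(),
                          noise_model(sigma = 0, seed = 1))
  cyc <- scr1$meta$cycle_id[scr1$meta$analyte_id == lib$id[4] &
                              scr1$meta$spot == "target"]
  s <- get_sensorgram(scr1, cyc, "target")
  fac <- scr1$meta$activity_factor[scr1$meta$cycle_id == cyc &
                                     scr1$meta$spot == "target"]
  expect_equal(binding_level(s)$level,
               equilibrium_response(strong, 25e-6) * fac, tolerance = 0.01)

  # reference-ligand probe levels decay by the configured activity loss
  probes <- which(scr1$meta$role == "reference_ligand" &
                    scr1$meta$spot == "target")
  lv <- vapply(probes, function(j)
    binding_level(get_sensorgram(scr1, scr1$meta$cycle_id[j], "target"))$level,
    numeric(1))
  drop <- 1 - lv[length(lv)] / lv[1]
  expect_equal(drop, 0.15, tolerance = 0.01)
})

test_that("screen generation is bit-identical under a fixed seed", {
  lib <- generate_library(25, seed = 2)
  des <- screen_design(lib)
  nm <- noise_model(sigma = 0.3, bulk_shift = 10, seed = 99)
  a <- generate_screen(des, default_surface(), screen_protocol(), nm)
  b <- generate_screen(des, default_surface(), screen_protocol(), nm)
  expect_identical(a$traces, b$traces)
  expect_identical(a$meta, b$meta)
})

test_that("dose series round-trip and edge cases", {
  expect_identical(generate_dose_series(clean_binder(), numeric(0)), list())
  concs <- two_fold_series(50e-6)
  ds <- generate_dose_series(clean_binder(), concs, screen_protocol())
  expect_length(ds, 6)
  plateaus <- vapply(ds, function(s) max(s$responses), numeric(1))
  expect_true(all(diff(plateaus) < 0))  # input order is decreasing conc
  fit <- fit_kinetic_1to1(ds)
  expect_lt(abs(fit$kd_value - kd_from_rates(clean_binder())) /
              kd_from_rates(clean_binder()), 1e-4)
})

test_that("noiseless dose series recover random kinetics to < 0.1%", {
  set.seed(41)
  for (i in 1:100) {
    ka <- 10^stats::runif(1, 3.3, 5.5)
    kd <- 10^stats::runif(1, -2.5, -0.8)
    rmax <- stats::runif(1, 15, 90)
    p <- kinetic_params(ka, kd, rmax)
    concs <- two_fold_series(4 * kd_from_rates(p))
    ds <- generate_dose_series(p, concs, screen_protocol())
    fit <- fit_kinetic_1to1(ds)
    expect_true(fit$converged)
    expect_lt(abs(fit$params$ka - ka) / ka, 1e-3)
    expect_lt(abs(fit$params$kd - kd) / kd, 1e-3)
    expect_lt(abs(fit$params$rmax - rmax) / rmax, 1e-3)
  }
})

test_that("artifacts modify exactly the intended trace segment", {
  s <- simulate_cycle(clean_binder(), 25e-6, screen_protocol())
  expect_identical(apply_artifact(s, artifact_spec("upward_drift", 0)), s)
  # super-stoichiometry x3 scales the plateau threefold
  s3 <- apply_artifact(s, artifact_spec("super_stoichiometry", 3))
  expect_equal(max(s3$responses), 3 * max(s$responses))
  # upward drift leaves the dissociation phase untouched
  sd_ <- apply_artifact(s, artifact_spec("upward_drift", 0.2))
  post <- s$times > s$t_stop
  expect_identical(sd_$responses[post], s$responses[post])
  expect_gt(max(sd_$responses - s$responses), 5)
  # carryover raises only the pre-injection baseline
  sc <- apply_artifact(s, artifact_spec("carryover", 3))
  pre <- s$times < s$t_inject
  expect_true(all(sc$responses[pre] == s$responses[pre] + 3))
  expect_identical(sc$responses[!pre], s$responses[!pre])
  # slow non-1:1 dissociation is continuous at injection stop and slower
  sn <- apply_artifact(s, artifact_spec("slow_non11_dissociation", 0.3))
  i_stop <- max(which(s$times <= s$t_stop))
  expect_equal(sn$responses[i_stop], s$responses[i_stop])
  expect_true(all(sn$responses[post] >= s$responses[post]))
})
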