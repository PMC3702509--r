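# Closed-form 1:1 model and its derived scalar quantities.

test_that("theoretical Rmax is the MW-scaled capture level", {
  surf <- default_surface()
  # identity case: analyte as heavy as the protein recovers the capture level
  expect_equal(theoretical_rmax(55000, surf), 16000)
  # hand arithmetic: 150/55000 * 16000
  expect_equal(theoretical_rmax(150, surf), 150 / 55000 * 16000)
  expect_equal(round(theoretical_rmax(150, surf), 1), 43.6)
  # halved activity halves the response
  expect_equal(theoretical_rmax(150, default_surface(activity = 0.5)), 21.8,
               tolerance = 1e-3)
  # exact linearity in analyte MW and capture level
  expect_equal(theoretical_rmax(300, surf), 2 * theoretical_rmax(150, surf))
  surf2 <- surface_model(55000, 32000)
  expect_equal(theoretical_rmax(150, surf2), 2 * theoretical_rmax(150, surf))
  expect_error(theoretical_rmax(-1, surf), "analyte_mw")
  expect_error(surface_model(-5, 16000), "protein_mw")
})

test_that("simulated cycles obey the 1:1 model limits", {
  p <- clean_binder()
  prot <- screen_protocol()
  # no analyte, no response
  expect_true(all(simulate_cycle(p, 0, prot)$responses == 0))
  # at C = KD and long contact, the plateau is Rmax/2
  long <- injection_protocol(contact_time = 5000, dissociation_time = 0)
  s <- simulate_cycle(p, kd_from_rates(p), long)
  expect_equal(max(s$responses), p$rmax / 2, tolerance = 1e-6)
  # response starts at zero and never exceeds Rmax
  s2 <- simulate_cycle(p, 1e-3, prot)
  expect_equal(s2$responses[1], 0)
  expect_true(all(s2$responses <= p$rmax + 1e-12))
})

test_that("closed form matches fourth-order numerical integration", {
  skip_if_not_installed("deSolve")
  p <- clean_binder()
  conc <- 25e-6
  prot <- injection_protocol(50, 60, sample_hz = 10)
  s <- simulate_cycle(p, conc, prot)
  # rk4 on a 0.01 s internal grid, compared on the 0.1 s sample grid
  fine <- seq(0, 50, 0.01)
  assoc <- deSolve::ode(c(R = 0), fine, method = "rk4", parms = NULL,
                        func = function(t, y, parms)
                          list(p$ka * conc * (p$rmax - y) - p$kd * y))
  at_grid <- assoc[, "R"][seq(1, length(fine), by = 10)]
  cf_assoc <- s$responses[s$times >= 10 & s$times <= 60]
  expect_lt(max(abs(at_grid - cf_assoc)), 1e-6)
  r_stop <- cf_assoc[length(cf_assoc)]
  fine_d <- seq(0, 60, 0.01)
  diss <- deSolve::ode(c(R = r_stop), fine_d, method = "rk4", parms = NULL,
                       func = function(t, y, parms) list(-p$kd * y))
  at_grid_d <- diss[, "R"][seq(1, length(fine_d), by = 10)]
  cf_diss <- s$responses[s$times >= 60]
  expect_lt(max(abs(at_grid_d - cf_diss)), 1e-6)
})

test_that("equilibrium response is the saturation isotherm", {
  p <- kinetic_params(ka = 285, kd = 3.99e-4, rmax = 72.3)
  kd_eq <- kd_from_rates(p)
  expect_equal(kd_eq, 1.4e-6, tolerance = 5e-3)
  expect_equal(equilibrium_response(p, kd_eq), p$rmax / 2)
  expect_equal(equilibrium_response(p, 1), p$rmax, tolerance = 1e-5)
  expect_equal(equilibrium_response(p, 0), 0)
  expect_equal(round(equilibrium_response(p, 62.5e-6), 1), 70.7)
  # monotone non-decreasing in concentration
  cc <- seq(0, 1e-4, length.out = 50)
  expect_true(all(diff(equilibrium_response(p, cc)) >= 0))
})

test_that("equilibrium response is the long-contact limit of a cycle", {
  p <- clean_binder()
  conc <- 5e-6
  kobs <- p$ka * conc + p$kd
  # ~30 association time constants leave < 1e-9 RU of the transient
  prot <- injection_protocol(contact_time = ceiling(30 / kobs),
                             dissociation_time = 0)
  s <- simulate_cycle(p, conc, prot)
  expect_lt(abs(max(s$responses) - equilibrium_response(p, conc)), 1e-9)
})

test_that("KD is kd/ka", {
  expect_equal(kd_from_rates(kinetic_params(1e5, 1e-2, 1)), 1e-7)
  expect_equal(kd_from_rates(kinetic_params(0.37, 0.37, 1)), 1)
})

test_that("ligand efficiency reproduces published fragment values", {
  # fragments A and M of the confirmed-hit table
  expect_equal(round(ligand_efficiency(18.3e-6, 13), 2), 0.50)
  expect_equal(round(ligand_efficiency(55e-6, 25), 2), 0.23)
  expect_warning(le1 <- ligand_efficiency(1, 10), "non-positive")
  expect_equal(le1, 0)
  # monotone decreasing in heavy atoms at fixed KD and in KD at fixed Nh
  nh <- 10:30
  expect_true(all(diff(ligand_efficiency(50e-6, nh)) < 0))
  kds <- c(1e-6, 1e-5, 1e-4, 1e-3)
  expect_true(all(diff(ligand_efficiency(kds, 15)) < 0))
})

test_that("dissociation half-life is ln2/kd", {
  expect_equal(half_life(log(2)), 1)
  expect_equal(round(half_life(3.99e-4) / 60, 2), 28.95)
  expect_equal(half_life(0.02), 2 * half_life(0.04))
  expect_error(half_life(0), "kd_rate")
})

test_that("single-concentration detection limit", {
  expect_equal(detection_limit_kd(25e-6, 40, 20), 25e-6)
  # effective Rmax / LOD of 6.2 at 25 uM: weakest detectable KD 0.13 mM
  expect_equal(detection_limit_kd(25e-6, 6.2, 1), 1.3e-4)
  expect_lt(detection_limit_kd(25e-6, 40, 40 - 1e-9), 1e-12)
  expect_error(detection_limit_kd(25e-6, 40, 40), class = "sprscreen_undetectable")
  expect_error(detection_limit_kd(25e-6, 40, 50), class = "sprscreen_undetectable")
})
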