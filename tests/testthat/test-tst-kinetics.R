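test_that("Eyring rates reproduce the prefactor and barrier attenuation", {
  expect_equal(eyring_rate(0), 6.2124e12, tolerance = 1e-4)
  expect_equal(eyring_rate(34.0), 6.87e6, tolerance = 1e-3)
  # linear in the reaction-path degeneracy
  for (dG in c(10, 34, 60))
    expect_equal(eyring_rate(dG, degeneracy = 2), 2 * eyring_rate(dG))
  expect_warning(eyring_rate(-5), "negative")
})

test_that("Eyring arithmetic agrees with a log-space evaluation up to 200 kJ/mol", {
  cst <- physical_constants()
  for (dG in seq(10, 200, by = 10)) {
    k_log <- exp(log(cst$k_B * 298.15 / cst$h) -
                   dG * 1000 / (cst$R * 298.15))
    expect_equal(eyring_rate(dG), k_log, tolerance = 1e-12)
  }
})

test_that("Eckart kappa approaches 1 in the classical and high-T limits", {
  expect_equal(eckart_kappa(eckart_barrier(30, 30, 1)), 1, tolerance = 1e-3)
  expect_equal(eckart_kappa(eckart_barrier(30, 30, 1000), temperature = 3000),
               1, tolerance = 0.05)
})

test_that("Eckart kappa matches the fine-grid trapezoidal oracle to 4 digits", {
  cases <- list(c(30, 30, 1500), c(20, 60, 1200), c(45, 15, 900))
  for (cs in cases) {
    k <- eckart_kappa(eckart_barrier(cs[1], cs[2], cs[3]))
    expect_equal(k, oracle_eckart_kappa(cs[1], cs[2], cs[3]),
                 tolerance = 1e-4)
  }
})

test_that("Eckart kappa is >= 1, decreasing in T, increasing in imag_freq", {
  for (Vf in c(15, 40)) for (Vr in c(25, 60)) for (nu in c(800, 1600)) {
    k <- eckart_kappa(eckart_barrier(Vf, Vr, nu))
    expect_gte(k, 1 - 1e-6)
  }
  b <- eckart_barrier(30, 30, 1500)
  ks <- vapply(c(280, 298.15, 320), function(Tk) eckart_kappa(b, Tk), 0)
  expect_true(all(diff(ks) < 0))
  ks <- vapply(c(800, 1200, 1600), function(nu)
    eckart_kappa(eckart_barrier(30, 30, nu)), 0)
  expect_true(all(diff(ks) > 0))
})

test_that("pathway dispatch: diffusion, plain TST, Eckart TST, Marcus", {
  w <- solvent("water")
  bl <- pathway("RAF", "3-C", "A", -30, barrierless = TRUE)
  r <- rate_for_pathway(bl, w)
  expect_identical(r$method, "DIFFUSION")
  expect_identical(r$k, 1.91e9)

  hat <- pathway("HAT", "1-OH", "A", -100, delta_G_act = 34.0)
  r <- rate_for_pathway(hat, w)
  expect_identical(r$method, "TST_PLAIN")
  expect_identical(r$kappa, 1)
  expect_equal(r$k, 6.87e6, tolerance = 1e-3)

  hat$imag_freq <- 1500
  hat$reverse_barrier <- 134
  r <- rate_for_pathway(hat, w)
  expect_identical(r$method, "TST_ECKART")
  expect_gt(r$kappa, 1)
  expect_equal(r$k, r$kappa * eyring_rate(34.0), tolerance = 1e-10)

  et <- pathway("ET", "mol", "A", -30, vertical_energy = 50)
  r <- rate_for_pathway(et, w)
  expect_identical(r$method, "MARCUS")
  expect_lte(r$k, 1.91e9)

  # reference rate constants take precedence when requested
  hat$k_ref <- 3.65e7
  expect_identical(rate_for_pathway(hat, w)$k, 3.65e7)
  expect_identical(rate_for_pathway(hat, w)$method, "REFERENCE")
  expect_false(rate_for_pathway(hat, w, use_reference = FALSE)$k == 3.65e7)

  bad <- pathway("HAT", "1-OH", "A", -50)
  expect_error(rate_for_pathway(bad, w), "missing delta_G_act")
})

test_that("temperature profiles are monotone for kappa = 1 and tunneling fades with T", {
  s <- solvent("water")
  p <- pathway("HAT", "1-OH", "A", -100, delta_G_act = 34.0)
  prof <- temperature_profile(p, s, c(280, 298.15, 320))
  expect_true(all(diff(prof$k) > 0))
  expect_equal(prof$k[2], eyring_rate(34.0), tolerance = 1e-12)

  b <- eckart_barrier(34, 80, 1400)
  expect_gt(eckart_kappa(b, 280), eckart_kappa(b, 320))
  expect_error(temperature_profile(p, s, numeric(0)), "empty")
})

test_that("overall rates are invariant to splitting a degenerate pathway", {
  s <- solvent("benzene")
  one <- mechanism_network("X", list(species_form("X", 0, 0, 1)), s,
                           pathway("HAT", "1-OH,3-OH,5-OH", "X", -100,
                                   delta_G_act = 34, degeneracy = 3))
  three <- mechanism_network("X", list(species_form("X", 0, 0, 1)), s,
                             do.call(rbind, lapply(1:3, function(i)
                               pathway("HAT", sprintf("%d-OH", 2 * i - 1),
                                       "X", -100, delta_G_act = 34,
                                       id = sprintf("hat%d", i)))))
  k1 <- overall_rate(pathway_rates(one), one)
  k3 <- overall_rate(pathway_rates(three), three)
  expect_equal(k1, k3, tolerance = 1e-12)
})
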