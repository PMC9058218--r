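test_that("Marcus activation energy: activationless point, lambda/4, inverted symmetry", {
  expect_equal(marcus_activation(-40, 40), 0)
  expect_equal(marcus_activation(0, 40), 10)
  expect_equal(marcus_activation(-80, 40), marcus_activation(0, 40))
  expect_error(marcus_activation(0, -1), "positive")
})

test_that("reorganization energy is the vertical/adiabatic gap", {
  expect_equal(reorganization_energy(50, -30), 80)
  expect_error(reorganization_energy(10, 10), "vertical energy below adiabatic")
  # composition contract
  act <- marcus_activation(-30, reorganization_energy(50, -30))
  expect_true(is.finite(act) && act >= 0)
})

test_that("Stokes-Einstein and Smoluchowski reproduce closed-form values", {
  w <- solvent("water")
  expect_equal(stokes_einstein_diffusivity(2e-10, w), 1.226e-9,
               tolerance = 1e-3)
  expect_equal(stokes_einstein_diffusivity(2e-10, w),
               2 * stokes_einstein_diffusivity(4e-10, w))
  thick <- solvent("custom", dielectric = 78, viscosity = 2 * w$viscosity)
  expect_equal(stokes_einstein_diffusivity(2e-10, thick),
               stokes_einstein_diffusivity(2e-10, w) / 2)

  expect_equal(smoluchowski_rate(2e-10, 2e-10, w), 7.42e9, tolerance = 1e-3)
  expect_equal(smoluchowski_rate(1e-10, 3e-10, w),
               smoluchowski_rate(3e-10, 1e-10, w))
  # k_D scales as T/eta at fixed radii
  expect_equal(smoluchowski_rate(2e-10, 2e-10, thick),
               smoluchowski_rate(2e-10, 2e-10, w) / 2, tolerance = 1e-12)
})

test_that("diffusion-corrected ET rates obey the Collins-Kimball limits", {
  k_D <- 8e9
  # activation-controlled limit
  slow <- et_rate(0, lambda = 160, k_D = k_D)
  expect_lt(attr(slow, "k_act") / k_D, 1e-3)
  expect_equal(as.numeric(slow), attr(slow, "k_act"), tolerance = 0.01)
  # k_act = k_D gives exactly k_D / 2
  k_act <- attr(et_rate(-10, lambda = 40, k_D = 1), "k_act")
  half <- et_rate(-10, lambda = 40, k_D = k_act)
  expect_equal(as.numeric(half), k_act / 2, tolerance = 1e-12)
  # always below both branches; harmonic form matches brute force
  for (dG in seq(-150, 20, by = 10)) {
    k <- et_rate(dG, lambda = 60, k_D = k_D)
    ka <- attr(k, "k_act")
    expect_lte(as.numeric(k), min(ka, k_D) * (1 + 1e-12))
    expect_equal(as.numeric(k), 1 / (1 / ka + 1 / k_D), tolerance = 1e-12)
  }
  # the crude clipping alternative
  expect_equal(as.numeric(et_rate(-60, 60, k_D, clip = "min")), k_D)
})

test_that("the Marcus inverted region appears past delta_G = -lambda", {
  lam <- 40
  k_D <- 8e9
  grid <- c(0, -40, -80, -120, -160)
  k <- vapply(grid, function(g) as.numeric(et_rate(g, lam, k_D)), 0)
  expect_equal(which.max(k), 2L)      # maximal at delta_G = -lambda
  expect_true(all(diff(k[2:5]) < 0))  # strictly decreasing beyond
  # fine sweep: monotone decrease everywhere past the activationless point
  fine <- seq(-lam, -200, by = -5)
  kf <- vapply(fine, function(g) as.numeric(et_rate(g, lam, k_D)), 0)
  expect_true(all(diff(kf) <= 0))
})
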