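test_that("scan classification separates descents from interior barriers", {
  r <- seq(350, 150, by = -5)
  desc <- scan_profile(r, -0.2 * (350 - r))
  expect_identical(as.character(classify_scan(desc)), "BARRIERLESS")

  e <- -0.2 * (350 - r) + 15 * exp(-(r - 250)^2 / 200)
  act <- classify_scan(scan_profile(r, e))
  expect_identical(as.character(act), "ACTIVATED")
  expect_equal(attr(act, "barrier"), max(e) - e[1], tolerance = 1e-12)

  prof3 <- scan_profile(c(300, 250, 200), c(0, 10, -5))
  expect_equal(attr(classify_scan(prof3), "barrier"), 10)
  expect_error(scan_profile(c(300, 250), c(0, 1)), "at least 3")
})

test_that("sub-tolerance jitter on a descent still classifies as barrierless", {
  set.seed(11)
  r <- seq(350, 150, by = -5)
  e <- -0.3 * (350 - r) + runif(length(r), -0.2, 0.2)
  # finite-difference oracle: no forward rise beyond the tolerance
  expect_true(all(diff(e) <= 0.5))
  expect_identical(as.character(classify_scan(scan_profile(r, e),
                                              noise_tol = 0.5)),
                   "BARRIERLESS")
})

test_that("classification is invariant to energy offsets and traversal direction", {
  set.seed(3)
  for (kind in c("BARRIERLESS", "ACTIVATED")) {
    p <- generate_scan(sample(1e6, 1), kind, noise_sd = 0.1)
    c0 <- as.character(classify_scan(p))
    shifted <- scan_profile(p$coordinate, p$energy + 123.4)
    reversed <- scan_profile(rev(p$coordinate), rev(p$energy))
    expect_identical(as.character(classify_scan(shifted)), c0)
    expect_identical(as.character(classify_scan(reversed)), c0)
  }
})

test_that("spin-crossing location on analytic lines, with symmetry and no-crossing cases", {
  r <- seq(350, 150, by = -5)
  a <- scan_profile(r, r - 200)
  b <- scan_profile(r, 300 - r)
  x <- find_spin_crossing(a, b)
  expect_equal(x$coordinate, 250)
  expect_equal(x$energy, 50)
  # symmetric in its arguments
  y <- find_spin_crossing(b, a)
  expect_equal(y$coordinate, x$coordinate)
  expect_equal(y$energy, x$energy)

  expect_null(find_spin_crossing(a, scan_profile(r, r - 200 + 10)))
  far <- scan_profile(seq(500, 400, by = -5), seq(500, 400, by = -5))
  expect_error(find_spin_crossing(a, far), "overlap")
})

test_that("crossing refinement agrees with a 0.01 pm brute-force oracle", {
  r <- seq(350, 150, by = -5)
  singlet <- scan_profile(r, -0.5 * (350 - r))
  triplet <- scan_profile(r, 20 - 0.002 * (r - 240)^2 - 0.4 * (350 - r))
  x <- find_spin_crossing(singlet, triplet)
  expect_false(is.null(x))
  expect_equal(x$coordinate, oracle_crossing(singlet, triplet),
               tolerance = 2.5 / x$coordinate)  # within half the 5 pm step
})

test_that("a barrierless scan feeds the diffusion rate constant downstream", {
  p <- generate_scan(5, "BARRIERLESS")
  expect_identical(as.character(classify_scan(p)), "BARRIERLESS")
  row <- rate_for_pathway(pathway("RAF", "3-C", "A", -30, barrierless = TRUE),
                          solvent("water"))
  expect_identical(row$method, "DIFFUSION")
  expect_identical(row$k, 1.91e9)
})
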