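test_that("network generation is deterministic: same seed, byte-identical files", {
  f1 <- tempfile(fileext = ".net")
  f2 <- tempfile(fileext = ".net")
  write_network(generate_network(seed = 1, n_sites = 6), f1)
  write_network(generate_network(seed = 1, n_sites = 6), f2)
  expect_identical(readLines(f1), readLines(f2))
  # and a different seed gives a different network
  f3 <- tempfile(fileext = ".net")
  write_network(generate_network(seed = 2, n_sites = 6), f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("the ring template yields 6 RAF and 3 HAT candidates for 6 sites", {
  net <- generate_network(seed = 3, n_sites = 6)
  tab <- table(net$pathways$mechanism)
  expect_equal(unname(tab[["RAF"]]), 6)
  expect_equal(unname(tab[["HAT"]]), 3)
  expect_equal(unname(tab[["SET"]]), 1)
  expect_equal(unname(tab[["ET"]]), 1)
  expect_length(validate_network(net), 0)
})

test_that("electron loss is thermodynamically prohibitive in non-polar networks", {
  n_total <- 0
  n_kept <- 0
  for (seed in 1:300) {
    net <- generate_network(seed, n_sites = 3, solvent_name = "benzene")
    s <- screen_pathways(net)
    n_total <- n_total + 1
    if (any(s$retained$composite %in% "SET_PT")) n_kept <- n_kept + 1
  }
  expect_lt(n_kept / n_total, 0.01)
})

test_that("generated scans close the loop with the classifier", {
  expect_identical(as.character(classify_scan(generate_scan(1, "BARRIERLESS"))),
                   "BARRIERLESS")
  act <- classify_scan(generate_scan(2, "ACTIVATED", bump_height = 20))
  expect_identical(as.character(act), "ACTIVATED")
  expect_equal(attr(act, "barrier"), 20, tolerance = 0.05)
})

test_that("crossing pairs record a ground truth the locator recovers", {
  pair <- generate_scan(4, "CROSSING_PAIR", grid_step = 2,
                        ground_truth = 236.2)
  x <- find_spin_crossing(pair$low, pair$high)
  expect_equal(x$coordinate, attr(pair, "ground_truth"), tolerance = 1 / 236.2)
})

test_that("per-pathway rates are recoverable from branching ratios and k_overall", {
  for (seed in c(11, 23, 57)) {
    net <- generate_network(seed, n_sites = 6)
    s <- screen_pathways(net)
    rt <- pathway_rates(net, s)
    k <- overall_rate(rt, net, weight_by_fraction = FALSE)
    g <- branching_ratios(rt, k)
    recovered <- g$gamma * k / 100
    consuming <- rt[rt$mechanism %in% c("HAT", "RAF", "SET", "ET"), ]
    expect_equal(recovered, consuming$k, tolerance = 1e-6)
  }
})

test_that("the whole pipeline is reproducible from the seed", {
  r1 <- run_pipeline(generate_network(seed = 9, n_sites = 5))
  r2 <- run_pipeline(generate_network(seed = 9, n_sites = 5))
  attr(r1, "manifest") <- attr(r2, "manifest") <- NULL  # timestamps differ
  expect_identical(r1, r2)
})
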