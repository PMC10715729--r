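test_that("tree simulation is seeded, sized and degenerates gracefully", {
  t1 <- simulate_tree(20, seed = 1)
  t2 <- simulate_tree(20, seed = 1)
  expect_identical(write_newick(t1), write_newick(t2))
  expect_equal(length(simulate_tree(2, seed = 2)$tip.label), 2)
  expect_error(simulate_tree(1, seed = 3), "n_taxa")
})

test_that("tree depth shrinks as the birth rate grows", {
  depth <- function(rate) {
    mean(vapply(1:20, function(s) {
      max(diag(ape::vcv.phylo(simulate_tree(20, rate, seed = 1000 + s))))
    }, numeric(1)))
  }
  expect_gt(depth(0.5), depth(2))
})

test_that("simulated traits carry the configured allometry", {
  tree <- simulate_tree(116, seed = 4)
  tt <- simulate_traits(tree, seed = 5)
  expect_true(all(tt$svl > 0))
  expect_true(all(tt$brain > 0))
  # zero-noise check: slope 1 on cubed SVL is recovered exactly
  cfg <- default_trait_config()
  cfg$Sigma <- cfg$Sigma * 0
  cfg$Sigma <- diag(1e-20, length(cfg$tissues))
  dimnames(cfg$Sigma) <- list(cfg$tissues, cfg$tissues)
  cfg$slopes[] <- 1
  t0 <- simulate_traits(tree, cfg, seed = 6)
  f <- fit_allometry(t0$fat, t0$svl, tree, species = t0$species, n_boot = 0)
  expect_equal(f$slope, 1, tolerance = 1e-4)
})

test_that("uncorrelated trait deviations stay uncorrelated on contrasts", {
  tree <- simulate_tree(200, seed = 7)
  cfg <- default_trait_config()
  cfg$Sigma <- diag(0.04, length(cfg$tissues))
  dimnames(cfg$Sigma) <- list(cfg$tissues, cfg$tissues)
  cfg$lambda[] <- 1
  cfg$slopes[] <- 0   # isolate the deviations from the size signal
  tt <- simulate_traits(tree, cfg, seed = 8)
  p1 <- ape::pic(log(setNames(tt$brain, tt$species)), tree)
  p2 <- ape::pic(log(setNames(tt$testes, tt$species)), tree)
  expect_lt(abs(cor(p1, p2)), 0.2)
})

test_that("configured shallow brain slope is recoverable at study scale", {
  covered <- 0
  for (s in 1:3) {
    tree <- simulate_tree(116, seed = 40 + s)
    tt <- simulate_traits(tree, seed = 50 + s)
    f <- fit_allometry(tt$brain, tt$svl, tree, species = tt$species,
                       n_boot = 50, seed = s)
    if (f$ci[1] <= 0.49 && f$ci[2] >= 0.49) covered <- covered + 1
  }
  expect_gte(covered, 2)
})

test_that("temperature series follow the configured seasonal geometry", {
  # constant warm series: never below threshold
  warm <- simulate_temperatures(mean_temp = 20, amplitude = 0, noise_sd = 0,
                                seed = 9)
  expect_equal(annual_brumation_days(warm, 10, year = 2013), 0)
  # noise-free sinusoid: crossing days from arcsine arithmetic
  ser <- simulate_temperatures(mean_temp = 12, amplitude = 12, noise_sd = 0,
                               seed = 10)
  thr <- 10
  nd <- 365
  # temp(d) = 12 + 12 sin(2 pi (d-1)/nd - pi/2) > thr
  frac_above <- 0.5 + asin((thr - 12) / 12) / pi
  expected_active <- round(nd * (1 - frac_above))
  got <- annual_brumation_days(ser, thr, year = 2013)
  expect_lt(abs((nd - got) - expected_active), 3)
  # determinism
  ser2 <- simulate_temperatures(mean_temp = 12, amplitude = 12,
                                noise_sd = 2, seed = 11)
  ser3 <- simulate_temperatures(mean_temp = 12, amplitude = 12,
                                noise_sd = 2, seed = 11)
  expect_identical(ser2, ser3)
})

test_that("noisier years reduce the repeatability of brumation estimates", {
  est_sd <- function(noise) {
    days <- vapply(1:6, function(s) {
      ser <- simulate_temperatures(mean_temp = 12, amplitude = 12,
                                   noise_sd = noise, years = 2013,
                                   seed = 60 + s)
      annual_brumation_days(ser, 10, year = 2013)
    }, numeric(1))
    sd(days)
  }
  expect_lt(est_sd(0.5), est_sd(4))
})

test_that("binary-pair simulation respects its generating model", {
  tree <- simulate_tree(40, seed = 12)
  # zero rates: all tips share the root state
  p0 <- simulate_binary_pair(tree, "independent", rep(0, 4), seed = 13)
  expect_equal(length(unique(p0$x)), 1)
  expect_equal(length(unique(p0$y)), 1)
  # independent evolution: association near zero across replicates
  phis <- vapply(1:60, function(s) {
    p <- simulate_binary_pair(tree, "independent", c(1, 1, 1, 1),
                              seed = 1000 + s)
    if (length(unique(p$x)) < 2 || length(unique(p$y)) < 2) return(NA_real_)
    cor(p$x, p$y)
  }, numeric(1))
  expect_lt(abs(mean(phis, na.rm = TRUE)), 0.12)
  expect_error(simulate_binary_pair(tree, "nope", 1:4, seed = 1), "arg")
})

test_that("study bundles mirror the design's nesting and serialize", {
  st <- simulate_study(seed = 3, n_taxa = 30, n_prepost = 12,
                       n_breeding = 10, n_field = 8, n_sites = 4)
  expect_length(st$tree$tip.label, 30)
  expect_equal(nrow(st$prepost), 12)
  expect_equal(nrow(st$breeding), 10)
  expect_equal(sum(st$thresholds$field_validated), 8)
  expect_length(st$temperatures, 4)
  dir <- withr::local_tempdir()
  paths <- write_study(st, dir)
  expect_true(all(file.exists(paths)))
  rt <- read_newick(paste(readLines(paths["tree"]), collapse = ""))
  expect_setequal(rt$tip.label, st$tree$tip.label)
})
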