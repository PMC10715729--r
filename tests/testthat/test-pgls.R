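test_that("r/t conversions invert each other and handle edge cases", {
  set.seed(1)
  for (rep in 1:50) {
    r <- runif(1, -0.99, 0.99)
    df <- sample(2:200, 1)
    expect_equal(r_from_t(t_from_r(r, df), df), r, tolerance = 1e-12)
  }
  expect_equal(r_from_t(0, 10), 0)
  expect_equal(r_from_t(0, 117), 0)
  expect_error(t_from_r(1, 10), "< 1")
  ci <- r_ci(0.5, 100)
  expect_lt(ci[1], 0.5)
  expect_gt(ci[2], 0.5)
})

test_that("fit_pgls equals OLS on a star phylogeny", {
  set.seed(2)
  star <- ape::stree(40, "star")
  star$edge.length <- rep(1, 40)
  star$tip.label <- sprintf("sp%02d", 1:40)
  d <- data.frame(species = star$tip.label, x = rnorm(40))
  d$y <- 1 + 0.8 * d$x + rnorm(40, 0, 0.5)
  f <- fit_pgls(y ~ x, d, star, n_boot = 0)
  ols <- lm(y ~ x, d)
  expect_equal(unname(f$coefficients), unname(coef(ols)), tolerance = 1e-6)
  expect_equal(f$df, 38)
})

test_that("a response copying the predictor gives standardized beta and r of 1", {
  set.seed(3)
  tree <- simulate_tree(30, seed = 3)
  d <- data.frame(species = tree$tip.label, x = rnorm(30))
  d$y <- d$x
  f <- fit_pgls(y ~ x, d, tree, n_boot = 0)
  expect_equal(unname(f$standardized_betas["x"]), 1, tolerance = 1e-8)
  expect_equal(unname(f$r["x"]), 1, tolerance = 1e-6)
})

test_that("profile likelihood at the optimum dominates the lambda grid", {
  set.seed(4)
  tree <- simulate_tree(60, seed = 4)
  tt <- simulate_traits(tree, seed = 5)
  d <- data.frame(species = tt$species, y = log(tt$brain),
                  x = log(tt$svl))
  f <- fit_pgls(y ~ x, d, tree, n_boot = 0)
  al <- align_tree_traits(tree, d, quiet = TRUE)
  V <- phylo_covariance(al$tree, taxa = al$traits$species)$V
  X <- cbind(1, al$traits$x)
  for (lam in seq(0, 1, by = 0.01)) {
    ll <- gls_fit(al$traits$y, X, apply_lambda(V, lam))$log_likelihood
    expect_lte(ll, f$log_likelihood + 1e-6)
  }
})

test_that("standardized betas are invariant to affine predictor rescaling", {
  tree <- simulate_tree(50, seed = 6)
  tt <- simulate_traits(tree, seed = 7)
  d <- data.frame(species = tt$species, y = log(tt$fat), x = log(tt$svl))
  d2 <- d
  d2$x <- 1000 * d$x - 77
  f1 <- fit_pgls(y ~ x, d, tree, n_boot = 0)
  f2 <- fit_pgls(y ~ x, d2, tree, n_boot = 0)
  expect_equal(f1$standardized_betas["x"], f2$standardized_betas["x"],
               tolerance = 1e-8)
  expect_equal(f1$t_statistics["x"], f2$t_statistics["x"], tolerance = 1e-8)
})

test_that("df bookkeeping matches n - p - 1", {
  tree <- simulate_tree(116, seed = 8)
  tt <- simulate_traits(tree, seed = 9)
  d <- data.frame(species = tt$species, y = log(tt$brain),
                  x1 = log(tt$svl), x2 = log(tt$fat))
  f1 <- fit_pgls(y ~ x1, d, tree, n_boot = 0)
  expect_equal(f1$df, 114)
  f2 <- fit_pgls(y ~ x1 + x2, d, tree, n_boot = 0)
  expect_equal(f2$df, 113)
})

test_that("lambda-ML recovers strong phylogenetic signal with covering CIs", {
  covered <- 0
  for (s in 1:5) {
    tree <- simulate_tree(150, seed = 100 + s)
    V <- ape::vcv.phylo(tree)
    set.seed(200 + s)
    L <- t(chol(V / max(diag(V))))
    d <- data.frame(species = tree$tip.label,
                    x = as.numeric(L %*% rnorm(150)))
    d$y <- 0.5 * d$x + 0.5 * as.numeric(L %*% rnorm(150))
    f <- fit_pgls(y ~ x, d, tree, n_boot = 40, seed = s)
    expect_gt(f$lambda_hat, 0.6)
    if (f$boot$lambda_ci[2] >= 0.99) covered <- covered + 1
  }
  expect_gte(covered, 4)
})

test_that("allometry classifies constructed power laws", {
  tree <- simulate_tree(60, seed = 10)
  set.seed(11)
  svl <- exp(rnorm(60, log(45), 0.4))
  # exact isometry: mass proportional to SVL^3
  iso <- fit_allometry(0.01 * svl^3, svl, tree, species = tree$tip.label,
                       n_boot = 20, seed = 1)
  expect_equal(iso$slope, 1, tolerance = 1e-8)
  expect_equal(iso$classification, "proportionate")
  # mass ~ SVL^1.5, i.e. exponent 0.5 on SVL^3, with mild noise
  sh <- fit_allometry(0.01 * svl^1.5 * exp(rnorm(60, 0, 0.05)), svl, tree,
                      species = tree$tip.label, n_boot = 40, seed = 2)
  expect_equal(sh$slope, 0.5, tolerance = 0.05)
  expect_equal(sh$classification, "shallower")
  st <- fit_allometry(0.01 * svl^4.5 * exp(rnorm(60, 0, 0.05)), svl, tree,
                      species = tree$tip.label, n_boot = 40, seed = 3)
  expect_equal(st$classification, "steeper")
  expect_error(fit_allometry(c(-1, svl[-1]), svl, tree,
                             species = tree$tip.label), "positive")
})

test_that("phylogenetic logistic regression matches glm on a star tree", {
  set.seed(12)
  star <- ape::stree(60, "star")
  star$edge.length <- rep(1, 60)
  star$tip.label <- sprintf("sp%02d", 1:60)
  d <- data.frame(species = star$tip.label, x = rnorm(60))
  d$y <- rbinom(60, 1, plogis(0.3 + 0.9 * d$x))
  f <- fit_phylo_logistic(y ~ x, d, star)
  g <- glm(y ~ x, binomial, d)
  expect_equal(unname(f$coefficients), unname(coef(g)), tolerance = 1e-4)
})

test_that("phylogenetic logistic regression is symmetric on a balanced toy", {
  star <- ape::stree(8, "star")
  star$edge.length <- rep(1, 8)
  star$tip.label <- paste0("s", 1:8)
  d <- data.frame(species = star$tip.label,
                  x = c(-2, -1, -0.5, -0.25, 0.25, 0.5, 1, 2),
                  y = c(0, 0, 1, 0, 1, 0, 1, 1))
  f <- fit_phylo_logistic(y ~ x, d, star)
  expect_equal(unname(f$coefficients["(Intercept)"]), 0, tolerance = 1e-6)
})

test_that("non-finite responses and constant responses are rejected", {
  tree <- simulate_tree(20, seed = 13)
  d <- data.frame(species = tree$tip.label, x = rnorm(20), y = rnorm(20))
  d$y[3] <- Inf
  expect_error(fit_pgls(y ~ x, d, tree, n_boot = 0), "non-finite")
  d$y <- 1
  expect_error(fit_phylo_logistic(y ~ x, d, tree), "variation")
})
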