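test_that("basis sets match textbook d-separation for simple DAGs", {
  chain <- path_model(c("Y <- X", "Z <- Y"))
  bs <- basis_set(chain)
  expect_length(bs, 1)
  expect_equal(bs[[1]]$x, "X")
  expect_equal(bs[[1]]$y, "Z")
  expect_equal(bs[[1]]$cond, "Y")

  saturated <- path_model(c("Y <- X", "Z <- X + Y"))
  expect_length(basis_set(saturated), 0)

  expect_error(path_model(c("Y <- X", "X <- Y")), "cyclic")
})

test_that("basis-set claims agree with the path-blocking oracle", {
  set.seed(1)
  for (rep in 1:50) {
    g <- oracle_random_dag(5, p = 0.4)
    m <- path_model(g$edges, nodes = g$nodes)
    for (cl in basis_set(m)) {
      expect_true(oracle_dsep(g$nodes, g$edges, cl$x, cl$y, cl$cond),
                  label = sprintf("claim %s _||_ %s | {%s} rep %d", cl$x,
                                  cl$y, paste(cl$cond, collapse = ","), rep))
    }
    # claims cover exactly the non-adjacent pairs
    adj <- nrow(unique(m$edges))
    expect_equal(length(basis_set(m)), choose(5, 2) - adj)
  }
})

test_that("basis sets are independent of node listing order", {
  edges <- data.frame(from = c("A", "B", "D"), to = c("B", "C", "C"))
  m1 <- path_model(edges, nodes = c("A", "B", "C", "D"))
  m2 <- path_model(edges[c(3, 1, 2), ], nodes = c("D", "C", "B", "A"))
  key <- function(m) {
    sort(vapply(basis_set(m), function(cl) {
      paste(cl$x, cl$y, paste(cl$cond, collapse = ","))
    }, character(1)))
  }
  expect_equal(key(m1), key(m2))
})

test_that("Fisher's C combines claim p-values correctly", {
  expect_equal(fishers_c(c(1, 1))$C, 0)
  f <- fishers_c(c(0.5, 0.5))
  expect_equal(f$C, 2.7726, tolerance = 1e-4)
  expect_equal(f$df, 4)
  for (k in c(1, 3, 7)) {
    expect_equal(fishers_c(rep(0.05, k))$C, k * 5.9915, tolerance = 1e-3)
  }
  expect_warning(out <- fishers_c(c(0.5, 0)), "clamped")
  expect_true(is.finite(out$C))
})

test_that("a saturated model has C = 0 and the closed-form CICc", {
  tree <- simulate_tree(50, seed = 2)
  set.seed(3)
  d <- data.frame(species = tree$tip.label, X = rnorm(50), Y = rnorm(50),
                  Z = rnorm(50))
  m <- path_model(c("Y <- X", "Z <- X + Y"))
  f <- fit_path_model(m, d, tree)
  expect_equal(f$C, 0)
  expect_equal(f$q, 3)  # 3 edges, 1 exogenous node, no free covariances
  expect_equal(f$CICc, 2 * 3 * 50 / (50 - 1 - 3), tolerance = 1e-10)
})

test_that("generative chain data favour the chain over a fork model", {
  wins <- 0
  for (s in 1:10) {
    tree <- simulate_tree(200, seed = 500 + s)
    V <- ape::vcv.phylo(tree)
    set.seed(600 + s)
    L <- t(chol(V / max(diag(V))))
    X <- as.numeric(L %*% rnorm(200))
    Y <- 0.8 * X + 0.4 * as.numeric(L %*% rnorm(200))
    Z <- 0.8 * Y + 0.4 * as.numeric(L %*% rnorm(200))
    d <- data.frame(species = tree$tip.label, X = X, Y = Y, Z = Z)
    chain <- path_model(c("Y <- X", "Z <- Y"), name = "chain")
    fork <- path_model(c("Y <- X", "Z <- X"), name = "fork")
    f_chain <- fit_path_model(chain, d, tree)
    f_fork <- fit_path_model(fork, d, tree)
    if (f_chain$p > 0.05 && f_fork$p < 0.05 &&
        f_chain$CICc < f_fork$CICc) {
      wins <- wins + 1
    }
  }
  expect_gte(wins, 8)
})

test_that("single-edge coefficients cover zero on independent data", {
  covered <- 0
  n_rep <- 40
  for (s in seq_len(n_rep)) {
    tree <- simulate_tree(60, seed = 700 + s)
    set.seed(800 + s)
    d <- data.frame(species = tree$tip.label, X = rnorm(60), Y = rnorm(60))
    f <- fit_path_model(path_model("Y <- X"), d, tree)
    e <- f$coefficients
    if (e$ci_low <= 0 && e$ci_high >= 0) covered <- covered + 1
  }
  expect_gte(covered, round(0.85 * n_rep))
})

test_that("adding the missing edge to a chain cannot increase C", {
  tree <- simulate_tree(80, seed = 4)
  set.seed(5)
  d <- data.frame(species = tree$tip.label, X = rnorm(80))
  d$Y <- 0.5 * d$X + rnorm(80)
  d$Z <- 0.5 * d$Y + rnorm(80)
  f1 <- fit_path_model(path_model(c("Y <- X", "Z <- Y")), d, tree)
  f2 <- fit_path_model(path_model(c("Y <- X", "Z <- X + Y")), d, tree)
  expect_lte(f2$C, f1$C)
})

test_that("model averaging respects the CICc band and symmetry", {
  mk <- function(cicc, beta, name) {
    structure(list(CICc = cicc, C = 0, df = 0, p = 1, q = 1, n = 50,
                   model = list(name = name),
                   coefficients = data.frame(from = "X", to = "Y",
                                             beta = beta, ci_low = beta - 1,
                                             ci_high = beta + 1)),
              class = "path_fit")
  }
  # single model: identity
  one <- average_models(list(mk(10, 0.5, "a")))
  expect_equal(one$edges$beta, 0.5)
  # symmetric pair: average zero
  two <- average_models(list(mk(10, 0.5, "a"), mk(10, -0.5, "b")))
  expect_equal(two$edges$beta, 0)
  # threshold arithmetic: CICc 10, 11, 14 retains the first two
  three <- average_models(list(mk(10, 1, "a"), mk(11, 2, "b"),
                               mk(14, 9, "c")))
  expect_setequal(three$retained, c("a", "b"))
  expect_equal(three$edges$beta, 1.5)
  # CICc-weighted variant down-weights the worse model
  w <- average_models(list(mk(10, 1, "a"), mk(11, 2, "b"), mk(14, 9, "c")),
                      weighted = TRUE)
  expect_lt(w$edges$beta, 1.5)
})

test_that("shipped candidate model sets parse into valid DAGs", {
  tis <- read_path_models(system.file("extdata", "path_models_tissue.txt",
                                      package = "brumate"))
  expect_length(tis, 28)
  cli <- read_path_models(system.file("extdata", "path_models_climate.txt",
                                      package = "brumate"))
  expect_length(cli, 8)
  for (m in c(tis, cli)) expect_s3_class(m, "path_model")
  # every tissue model can explain brain and testes variation
  for (m in tis) {
    expect_true(all(c("brain", "testes") %in% m$nodes))
  }
})
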