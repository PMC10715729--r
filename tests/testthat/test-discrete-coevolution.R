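test_that("residual binarization splits species around the allometric line", {
  tree <- simulate_tree(40, seed = 1)
  set.seed(2)
  svl <- exp(rnorm(40, log(45), 0.4))
  # exact power law: all residuals zero -> all-0 with a warning
  expect_warning(
    z <- binarize_residual(0.01 * svl^3, svl, tree,
                           species = tree$tip.label),
    "exactly zero")
  expect_true(all(z == 0))
  # constructed residuals: species pushed above/below the line
  shift <- rep(c(1, -1), 20) * 0.5
  x <- binarize_residual(0.01 * svl^3 * exp(shift), svl, tree,
                         species = tree$tip.label)
  expect_equal(unname(x[tree$tip.label]),
               as.integer(shift[match(tree$tip.label, tree$tip.label)] > 0))
  # mean split: values below the mean are coded 1 ("short")
  v <- c(a = 10, b = 20, c = 90)
  expect_equal(binarize_mean_split(v), c(a = 1L, b = 1L, c = 0L))
})

test_that("rate matrices have generator structure in all four models", {
  for (m in c("independent", "x_dep_on_y", "y_dep_on_x", "mutual")) {
    k <- switch(m, independent = 4, mutual = 8, 6)
    Q <- pagel_rate_matrix(m, seq_len(k) / 10)
    expect_equal(unname(rowSums(Q)), rep(0, 4), tolerance = 1e-12)
    off <- Q; diag(off) <- 0
    expect_true(all(off >= 0))
    # dual transitions are structurally impossible
    expect_equal(Q["00", "11"], 0)
    expect_equal(Q["11", "00"], 0)
    expect_equal(Q["01", "10"], 0)
    expect_equal(Q["10", "01"], 0)
  }
  expect_error(pagel_rate_matrix("independent", 1:3), "4 rates")
  expect_error(pagel_rate_matrix("mutual", rep(-1, 8)), "nonnegative")
})

test_that("independent-model likelihood factorizes over the two traits", {
  set.seed(3)
  for (rep in 1:50) {
    tree <- ape::rcoal(sample(6:15, 1))
    rates <- runif(4, 0.1, 2)
    x <- setNames(rbinom(length(tree$tip.label), 1, 0.5), tree$tip.label)
    y <- setNames(rbinom(length(tree$tip.label), 1, 0.5), tree$tip.label)
    joint <- pagel_likelihood(x, y, tree, "independent", rates)
    solo <- oracle_two_state_loglik(x, tree, rates[1], rates[2]) +
      oracle_two_state_loglik(y, tree, rates[3], rates[4])
    expect_equal(joint, solo, tolerance = 1e-8)
  }
})

test_that("two-taxon likelihood matches a direct matrix-exponential oracle", {
  tree <- read_newick("(A:0.7,B:0.7);")
  rates <- c(0.5, 0.9, 1.2, 0.3, 0.8, 0.2, 0.4, 1.1)
  Q <- pagel_rate_matrix("mutual", rates)
  # direct computation via series expansion of expm
  expm_series <- function(A, terms = 60) {
    E <- diag(4); term <- diag(4)
    for (k in 1:terms) {
      term <- term %*% A / k
      E <- E + term
    }
    E
  }
  P <- expm_series(Q * 0.7)
  sA <- 1 + 2 * 1 + 0  # x=1, y=0 -> state "10" = index 3
  sB <- 1 + 2 * 0 + 1  # x=0, y=1 -> state "01" = index 2
  oracle <- log(sum(0.25 * P[, sA] * P[, sB]))
  got <- pagel_likelihood(c(A = 1, B = 0), c(A = 0, B = 1), tree,
                          "mutual", rates)
  expect_equal(got, oracle, tolerance = 1e-8)
})

test_that("zero rates anchor the likelihood at the root frequencies", {
  tree <- read_newick("((A:1,B:1):1,C:2);")
  x <- c(A = 0, B = 0, C = 0)
  y <- c(A = 0, B = 0, C = 0)
  ll <- pagel_likelihood(x, y, tree, "independent", rep(0, 4))
  expect_equal(ll, log(0.25))
})

test_that("likelihood is invariant to relabeling both traits", {
  set.seed(4)
  tree <- ape::rcoal(12)
  x <- setNames(rbinom(12, 1, 0.5), tree$tip.label)
  y <- setNames(rbinom(12, 1, 0.5), tree$tip.label)
  rates <- runif(8, 0.1, 2)
  ll1 <- pagel_likelihood(x, y, tree, "mutual", rates)
  # flip both traits; permute rates accordingly: 0<->1 swaps the roles of
  # the gain/loss rates and of the conditioning states
  flipped <- rates[c(4, 3, 2, 1, 8, 7, 6, 5)]
  ll2 <- pagel_likelihood(1 - x, 1 - y, tree, "mutual", flipped)
  expect_equal(ll1, ll2, tolerance = 1e-10)
})

test_that("optimized log-likelihoods respect the model nesting", {
  tree <- simulate_tree(60, seed = 5)
  pair <- simulate_binary_pair(tree, "x_dep_on_y",
                               rates = c(0.2, 3, 3, 0.2, 1, 1), seed = 6)
  fd <- fit_directional(pair$x, pair$y, tree, n_start = 2, seed = 7)
  ll <- setNames(fd$table$logL, fd$table$model)
  expect_gte(ll["mutual"] + 1e-4, ll["x_dep_on_y"])
  expect_gte(ll["mutual"] + 1e-4, ll["y_dep_on_x"])
  expect_gte(ll["x_dep_on_y"] + 1e-4, ll["independent"])
  expect_gte(ll["y_dep_on_x"] + 1e-4, ll["independent"])
  expect_equal(sum(fd$table$w_AIC), 1, tolerance = 1e-12)
  expect_equal(fd$table$k[fd$table$model == "independent"], 4)
  expect_equal(fd$table$k[fd$table$model == "mutual"], 8)
})

test_that("directional fits require variation in both traits", {
  tree <- simulate_tree(10, seed = 8)
  x <- setNames(rep(1L, 10), tree$tip.label)
  y <- setNames(rbinom(10, 1, 0.5), tree$tip.label)
  expect_error(fit_directional(x, y, tree), "vary")
})
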