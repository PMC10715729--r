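# Joint states of the two binary traits, in fixed order:
# 1 = (0,0), 2 = (0,1), 3 = (1,0), 4 = (1,1); x is the first trait.
pagel_states <- c("00", "01", "10", "11")

#' Binarize a trait by the sign of its phylogenetic allometric residual
#'
#' Species with positive residuals from a lambda-ML PGLS of log(trait) on
#' log(size) are coded 1 ("relatively large"), negative residuals 0.
#' A residual of exactly zero is assigned 0 with a warning.
#'
#' @param trait,size Positive values per species.
#' @param tree Phylogeny.
#' @param species Species labels (default `names(trait)`).
#' @return Named integer vector of 0/1 codes.
#' @export
binarize_residual <- function(trait, size, tree, species = names(trait)) {
  if (any(trait <= 0) || any(size <= 0)) {
    stop("trait and size must be strictly positive")
  }
  dat <- data.frame(species = species, log_trait = log(trait),
                    log_size = log(size))
  al <- align_tree_traits(tree, dat, quiet = TRUE)
  fit <- fit_pgls(log_trait ~ log_size, dat, tree, n_boot = 0)
  res <- stats::setNames(fit$fit$residuals, al$traits$species)
  zero <- abs(res) < 1e-9 * max(1, max(abs(dat$log_trait)))
  if (any(zero)) {
    warning(sum(zero), " residual(s) exactly zero; assigned 0")
    res[zero] <- 0
  }
  stats::setNames(as.integer(res > 0), names(res))
}

#' Binarize by a mean split
#'
#' Values strictly below the mean are coded 1 (e.g. "short" breeding
#' seasons), the rest 0.
#'
#' @param values Numeric vector (named by species).
#' @return Integer 0/1 vector with the same names.
#' @export
binarize_mean_split <- function(values) {
  stats::setNames(as.integer(values < mean(values)), names(values))
}

#' Build the 4-state rate matrix for a Pagel model
#'
#' States are ordered (x,y) = 00, 01, 10, 11. Only one trait may change per
#' instant, so the two "dual transition" entries are structurally zero.
#' Rate vectors by model: `independent` has 4 rates
#' (x01, x10, y01, y10); `x_dep_on_y` lets the x rates depend on the
#' current y state (6 rates); `y_dep_on_x` mirrors that; `mutual` has all
#' 8 rates free.
#'
#' @param model One of `"independent"`, `"x_dep_on_y"`, `"y_dep_on_x"`,
#'   `"mutual"`.
#' @param rates Nonnegative rate vector of the model's length.
#' @return 4x4 generator matrix (rows sum to zero).
#' @export
pagel_rate_matrix <- function(model = c("independent", "x_dep_on_y",
                                        "y_dep_on_x", "mutual"), rates) {
  model <- match.arg(model)
  k <- pagel_n_rates(model)
  if (length(rates) != k) {
    stop("model '", model, "' needs ", k, " rates, got ", length(rates))
  }
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("rates must be finite and nonnegative")
  }
  r <- switch(model,
    independent = c(x01_y0 = rates[1], x01_y1 = rates[1],
                    x10_y0 = rates[2], x10_y1 = rates[2],
                    y01_x0 = rates[3], y01_x1 = rates[3],
                    y10_x0 = rates[4], y10_x1 = rates[4]),
    x_dep_on_y = c(x01_y0 = rates[1], x01_y1 = rates[2],
                   x10_y0 = rates[3], x10_y1 = rates[4],
                   y01_x0 = rates[5], y01_x1 = rates[5],
                   y10_x0 = rates[6], y10_x1 = rates[6]),
    y_dep_on_x = c(x01_y0 = rates[1], x01_y1 = rates[1],
                   x10_y0 = rates[2], x10_y1 = rates[2],
                   y01_x0 = rates[3], y01_x1 = rates[4],
                   y10_x0 = rates[5], y10_x1 = rates[6]),
    mutual = c(x01_y0 = rates[1], x01_y1 = rates[2],
               x10_y0 = rates[3], x10_y1 = rates[4],
               y01_x0 = rates[5], y01_x1 = rates[6],
               y10_x0 = rates[7], y10_x1 = rates[8])
  )
  Q <- matrix(0, 4, 4, dimnames = list(pagel_states, pagel_states))
  Q["00", "10"] <- r["x01_y0"]; Q["01", "11"] <- r["x01_y1"]
  Q["10", "00"] <- r["x10_y0"]; Q["11", "01"] <- r["x10_y1"]
  Q["00", "01"] <- r["y01_x0"]; Q["10", "11"] <- r["y01_x1"]
  Q["01", "00"] <- r["y10_x0"]; Q["11", "10"] <- r["y10_x1"]
  diag(Q) <- -rowSums(Q)
  Q
}

pagel_n_rates <- function(model) {
  switch(model, independent = 4L, x_dep_on_y = 6L, y_dep_on_x = 6L,
         mutual = 8L)
}

# matrix exponential by scaling and squaring with a Pade(6) approximant;
# adequate for the small generators used here
expm_ss <- function(A) {
  nrm <- max(rowSums(abs(A)))
  s <- max(0L, ceiling(log2(max(nrm, 1e-300))) + 1L)
  As <- A / 2^s
  n <- nrow(A)
  cN <- diag(n)
  cD <- diag(n)
  X <- diag(n)
  c_ <- 1
  for (k in 1:6) {
    c_ <- c_ * (6 - k + 1) / (k * (12 - k + 1))
    X <- X %*% As
    cN <- cN + c_ * X
    cD <- cD + (-1)^k * c_ * X
  }
  E <- solve(cD, cN)
  for (i in seq_len(s)) E <- E %*% E
  E
}

# transition probabilities for every edge; eigendecomposition when stable,
# scaling-and-squaring per unique branch length otherwise
edge_transition_probs <- function(Q, lens) {
  u <- unique(lens)
  P <- vector("list", length(u))
  eg <- tryCatch(eigen(Q), error = function(e) NULL)
  use_eig <- FALSE
  if (!is.null(eg)) {
    Uin <- tryCatch(solve(eg$vectors), error = function(e) NULL)
    if (!is.null(Uin)) {
      chk <- Re(eg$vectors %*% diag(exp(eg$values * u[1]), 4) %*% Uin)
      ref <- expm_ss(Q * u[1])
      use_eig <- max(abs(chk - ref)) < 1e-8
    }
  }
  for (i in seq_along(u)) {
    Pi <- if (use_eig) {
      Re(eg$vectors %*% diag(exp(eg$values * u[i]), 4) %*% Uin)
    } else {
      expm_ss(Q * u[i])
    }
    Pi[Pi < 0] <- 0
    P[[i]] <- Pi
  }
  P[match(lens, u)]
}

#' Likelihood of a Pagel correlated-evolution model
#'
#' Felsenstein pruning over the four joint states of two binary tip traits,
#' with per-branch transition probabilities from the matrix exponential of
#' the model's generator. Root state frequencies are flat (1/4 each) by
#' default; `root = "stationary"` uses the stationary distribution of the
#' generator.
#'
#' @param x,y Named 0/1 vectors over the tree's tips.
#' @param tree Phylogeny.
#' @param model Model label (see [pagel_rate_matrix()]).
#' @param rates Rate vector for the model.
#' @param root `"flat"` or `"stationary"`.
#' @return Log-likelihood (scalar).
#' @export
pagel_likelihood <- function(x, y, tree, model, rates, root = "flat") {
  Q <- pagel_rate_matrix(model, rates)
  pagel_loglik_Q(x, y, tree, Q, root)
}

pagel_loglik_Q <- function(x, y, tree, Q, root = "flat") {
  tips <- tree$tip.label
  x <- x[tips]; y <- y[tips]
  if (anyNA(x) || anyNA(y)) stop("x and y must cover every tip")
  ntip <- length(tips)
  state <- 1L + 2L * as.integer(x) + as.integer(y)
  nnode <- tree$Nnode
  part <- matrix(0, ntip + nnode, 4)
  part[cbind(seq_len(ntip), state)] <- 1
  part[(ntip + 1L):(ntip + nnode), ] <- 1
  tre <- ape::reorder.phylo(tree, "postorder")
  Ps <- edge_transition_probs(Q, tre$edge.length)
  scale_log <- 0
  for (e in seq_len(nrow(tre$edge))) {
    par <- tre$edge[e, 1]; child <- tre$edge[e, 2]
    contrib <- as.numeric(Ps[[e]] %*% part[child, ])
    part[par, ] <- part[par, ] * contrib
    m <- max(part[par, ])
    if (m > 0 && m < 1e-200) {
      part[par, ] <- part[par, ] / m
      scale_log <- scale_log + log(m)
    }
  }
  root_node <- ntip + 1L
  pi_root <- if (identical(root, "flat")) {
    rep(0.25, 4)
  } else {
    stationary_dist(Q)
  }
  lik <- sum(pi_root * part[root_node, ])
  if (lik <= 0) return(-Inf)
  log(lik) + scale_log
}

stationary_dist <- function(Q) {
  A <- rbind(t(Q), rep(1, 4))
  b <- c(rep(0, 4), 1)
  qrres <- qr.solve(A, b)
  pmax(qrres, 0) / sum(pmax(qrres, 0))
}

#' Fit one Pagel model by maximum likelihood
#'
#' Optimizes the log rates by bounded L-BFGS with `n_start` seeded restarts
#' around a parsimony-informed initial rate.
#'
#' @inheritParams pagel_likelihood
#' @param n_start Number of restarts.
#' @param seed Seed for the restart jitter.
#' @param extra_starts Optional list of additional rate vectors to start
#'   from (used to seed richer models from the optimum of a nested one).
#' @return List with `model`, `rates`, `logL`, `k`, `AIC`, `convergence`.
#' @export
fit_pagel <- function(x, y, tree, model, n_start = 3, seed = NULL,
                      root = "flat", extra_starts = NULL) {
  k <- pagel_n_rates(model)
  tl <- sum(tree$edge.length)
  init <- log(max(length(tree$tip.label) / (2 * tl), 1e-3))
  if (!is.null(seed)) set.seed(seed)
  nll <- function(lr) {
    v <- -pagel_likelihood(x, y, tree, model, exp(lr), root = root)
    # L-BFGS-B cannot digest non-finite objectives (possible when all mass
    # underflows at extreme rates); cap instead
    if (!is.finite(v)) 1e10 else v
  }
  starts <- c(list(rep(init, k)),
              lapply(extra_starts, function(r) log(pmax(r, 1e-8))),
              lapply(seq_len(max(0, n_start - 1)), function(s) {
                init + stats::rnorm(k, 0, 1.5)
              }))
  best <- NULL
  restarts <- 0L
  for (s in seq_along(starts)) {
    p0 <- starts[[s]]
    op <- tryCatch(
      stats::optim(p0, nll, method = "L-BFGS-B",
                   lower = rep(log(1e-8), k), upper = rep(log(1e3), k),
                   control = list(maxit = 300)),
      error = function(e) NULL
    )
    if (is.null(op)) next
    if (op$convergence != 0) restarts <- restarts + 1L
    if (is.null(best) || op$value < best$value) best <- op
  }
  if (is.null(best)) stop("optimizer failed for model ", model)
  logL <- -best$value
  list(model = model, rates = exp(best$par), logL = logL, k = k,
       AIC = -2 * logL + 2 * k,
       convergence = best$convergence, restarts = restarts)
}

#' Directional test of correlated evolution between two binary traits
#'
#' Fits the four Pagel ARD models -- independent (4 rates), x dependent on
#' y (6), y dependent on x (6), mutual dependence (8) -- and ranks them by
#' AIC with Akaike weights.
#'
#' @inheritParams fit_pagel
#' @return A `pagel_directional` object: list of fits plus a ranked
#'   summary table (`logL`, `k`, `AIC`, `delta_AIC`, `w_AIC`).
#' @export
fit_directional <- function(x, y, tree, n_start = 3, seed = NULL,
                            root = "flat") {
  if (length(unique(x[tree$tip.label])) < 2 ||
      length(unique(y[tree$tip.label])) < 2) {
    stop("both traits must vary across species")
  }
  # fit the nested model first and seed the richer ones from its optimum,
  # which keeps the log-likelihoods weakly ordered along the nesting
  f_ind <- fit_pagel(x, y, tree, "independent", n_start = n_start,
                     seed = if (is.null(seed)) NULL else seed + 1,
                     root = root)
  r <- f_ind$rates  # (x01, x10, y01, y10)
  f_xy <- fit_pagel(x, y, tree, "x_dep_on_y", n_start = n_start,
                    seed = if (is.null(seed)) NULL else seed + 2,
                    root = root,
                    extra_starts = list(c(r[1], r[1], r[2], r[2],
                                          r[3], r[4])))
  f_yx <- fit_pagel(x, y, tree, "y_dep_on_x", n_start = n_start,
                    seed = if (is.null(seed)) NULL else seed + 3,
                    root = root,
                    extra_starts = list(c(r[1], r[2], r[3], r[3],
                                          r[4], r[4])))
  rx <- f_xy$rates; ry <- f_yx$rates
  f_mu <- fit_pagel(x, y, tree, "mutual", n_start = n_start,
                    seed = if (is.null(seed)) NULL else seed + 4,
                    root = root,
                    extra_starts = list(
                      c(rx[1], rx[2], rx[3], rx[4], rx[5], rx[5],
                        rx[6], rx[6]),
                      c(ry[1], ry[1], ry[2], ry[2], ry[3], ry[4],
                        ry[5], ry[6])))
  fits <- list(independent = f_ind, x_dep_on_y = f_xy, y_dep_on_x = f_yx,
               mutual = f_mu)
  models <- names(fits)
  aic <- vapply(fits, `[[`, numeric(1), "AIC")
  delta <- aic - min(aic)
  w <- exp(-delta / 2) / sum(exp(-delta / 2))
  tab <- data.frame(
    model = models,
    logL = vapply(fits, `[[`, numeric(1), "logL"),
    k = vapply(fits, `[[`, numeric(1), "k"),
    AIC = aic, delta_AIC = delta, w_AIC = w
  )
  tab <- tab[order(tab$AIC), ]
  structure(list(fits = fits, table = tab), class = "pagel_directional")
}

#' @export
print.pagel_directional <- function(x, ...) {
  cat("Directional test of correlated evolution\n")
  print(transform(x$table, logL = round(logL, 3), AIC = round(AIC, 2),
                  delta_AIC = round(delta_AIC, 2), w_AIC = round(w_AIC, 3)),
        row.names = FALSE)
  invisible(x)
}
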