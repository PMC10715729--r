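#' Profile log-likelihood over Pagel's lambda
#'
#' Evaluates the ML log-likelihood of a GLS fit on a coarse grid of 21
#' lambda values in \[0, 1\] and refines the best grid point by bounded
#' golden-section/parabolic search ([stats::optimize()]) within its
#' bracketing interval.
#'
#' @param y Response vector.
#' @param X Design matrix.
#' @param V Brownian-motion phylogenetic covariance matrix (lambda = 1).
#' @return List with `lambda`, `logLik` and `fit` (the [gls_fit()] at the
#'   optimum).
#' @keywords internal
profile_lambda <- function(y, X, V) {
  ll <- function(lam) {
    gls_fit(y, X, apply_lambda(V, lam))$log_likelihood
  }
  grid <- seq(0, 1, length.out = 21)
  vals <- vapply(grid, ll, numeric(1))
  i <- which.max(vals)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  if (lo < hi) {
    opt <- stats::optimize(ll, interval = c(lo, hi), maximum = TRUE,
                           tol = 1e-6)
    lam <- opt$maximum
    val <- opt$objective
  } else {
    lam <- grid[i]
    val <- vals[i]
  }
  # never let the refinement fall below a grid point (incl. the bounds)
  if (vals[i] > val) {
    lam <- grid[i]
    val <- vals[i]
  }
  fit <- gls_fit(y, X, apply_lambda(V, lam))
  list(lambda = lam, logLik = val, fit = fit)
}

#' Phylogenetic generalized least squares with ML lambda
#'
#' Fits a PGLS regression in which the residual covariance is the
#' phylogenetic (Brownian) covariance with off-diagonals scaled by Pagel's
#' lambda, estimated by maximum likelihood on \[0, 1\]. Uncertainty in the
#' standardized coefficients and in lambda is quantified by a parametric
#' bootstrap: `n_boot` response vectors are simulated from the fitted
#' model and the full fit (including lambda) is repeated on each,
#' yielding percentile confidence intervals.
#'
#' Effect sizes `r` per predictor are obtained from the t statistics via
#' [r_from_t()]; with one focal predictor plus covariates this is the
#' partial correlation given the other terms.
#'
#' @param formula Model formula over columns of `data`.
#' @param data Data frame with a `species` column matching tip labels.
#' @param tree A `phylo` object; pruned to the data before fitting.
#' @param lambda `"ML"` (default) or a fixed value in \[0, 1\].
#' @param n_boot Number of parametric bootstrap replicates (0 disables).
#' @param seed Optional seed for the bootstrap.
#' @return A `pgls_fit` object.
#' @export
fit_pgls <- function(formula, data, tree, lambda = "ML", n_boot = 100,
                     seed = NULL) {
  al <- align_tree_traits(tree, data, quiet = TRUE)
  mf <- stats::model.frame(formula, al$traits)
  if (nrow(mf) < nrow(al$traits)) {
    stop("non-finite or missing trait values in rows: ",
         paste(setdiff(rownames(al$traits), rownames(mf)), collapse = ", "))
  }
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  if (!all(is.finite(y)) || !all(is.finite(X))) {
    bad <- rownames(mf)[!is.finite(y) | rowSums(!is.finite(X)) > 0]
    stop("non-finite trait values in rows: ", paste(bad, collapse = ", "))
  }
  n <- length(y)
  if (n < ncol(X) + 2) stop("fewer species than model parameters + 2")
  Cv <- phylo_covariance(al$tree, taxa = rownames(mf))
  V <- Cv$V

  fit_once <- function(yy) {
    if (identical(lambda, "ML")) {
      profile_lambda(yy, X, V)
    } else {
      f <- gls_fit(yy, X, apply_lambda(V, lambda))
      list(lambda = lambda, logLik = f$log_likelihood, fit = f)
    }
  }
  base <- fit_once(y)
  fit <- base$fit
  lam_hat <- base$lambda

  # standardized coefficients: beta_j * sd(x_j) / sd(y), plain sample SDs
  std_beta <- function(f, X, y) {
    b <- f$coefficients
    sy <- stats::sd(y)
    out <- b
    for (j in seq_along(b)) {
      nm <- names(b)[j]
      if (nm == "(Intercept)") {
        out[j] <- NA_real_
      } else {
        out[j] <- b[j] * stats::sd(X[, j]) / sy
      }
    }
    out
  }
  betas_std <- std_beta(fit, X, y)

  boot <- NULL
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    L <- chol(apply_lambda(V, lam_hat)$V)
    sig <- sqrt(fit$sigma2)
    bs_beta <- matrix(NA_real_, n_boot, length(fit$coefficients),
                      dimnames = list(NULL, names(fit$coefficients)))
    bs_raw <- bs_beta
    bs_lambda <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      ystar <- fit$fitted + sig * as.numeric(crossprod(L, stats::rnorm(n)))
      fb <- fit_once(ystar)
      bs_beta[b, ] <- std_beta(fb$fit, X, ystar)
      bs_raw[b, ] <- fb$fit$coefficients
      bs_lambda[b] <- fb$lambda
    }
    qs <- function(v) stats::quantile(v, c(0.025, 0.975), na.rm = TRUE,
                                      names = FALSE)
    boot <- list(
      beta_ci = t(apply(bs_beta, 2, qs)),
      raw_ci = t(apply(bs_raw, 2, qs)),
      lambda_ci = qs(bs_lambda),
      betas = bs_beta, raw = bs_raw, lambdas = bs_lambda
    )
  }

  tv <- fit$t_statistics
  r <- vapply(tv, function(t) r_from_t(t, fit$df), numeric(1))
  p <- 2 * stats::pt(abs(tv), fit$df, lower.tail = FALSE)

  structure(list(
    call = match.call(),
    fit = fit,
    coefficients = fit$coefficients,
    standardized_betas = betas_std,
    t_statistics = tv,
    p_values = p,
    r = r,
    df = fit$df,
    n = n,
    lambda_hat = lam_hat,
    log_likelihood = base$logLik,
    boot = boot,
    n_boot = n_boot,
    formula = formula
  ), class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("PGLS fit:", deparse(x$formula), "\n")
  cat("n =", x$n, " df =", x$df, " lambda =", round(x$lambda_hat, 3))
  if (!is.null(x$boot)) {
    cat(" [", paste(round(x$boot$lambda_ci, 3), collapse = ", "), "]")
  }
  cat("\n")
  tab <- cbind(Estimate = x$coefficients, std_beta = x$standardized_betas,
               t = x$t_statistics, r = x$r, p = x$p_values)
  print(round(tab, 4))
  invisible(x)
}

#' Effect-size conversions between r and t
#'
#' Standard conversion between a correlation-type effect size and the t
#' statistic on `df` degrees of freedom:
#' `t = r * sqrt(df) / sqrt(1 - r^2)`, inverted as
#' `r = t / sqrt(t^2 + df)`.
#'
#' @param t t statistic.
#' @param r Correlation in (-1, 1).
#' @param df Degrees of freedom (>= 1).
#' @return The converted value.
#' @export
r_from_t <- function(t, df) {
  stopifnot(df >= 1)
  ifelse(is.infinite(t), sign(t), t / sqrt(t^2 + df))
}

#' @rdname r_from_t
#' @export
t_from_r <- function(r, df) {
  stopifnot(df >= 1)
  if (any(abs(r) >= 1)) stop("|r| must be < 1")
  r * sqrt(df) / sqrt(1 - r^2)
}

#' @rdname r_from_t
#' @param conf Confidence level (default 0.95).
#' @export
r_ci <- function(r, df, conf = 0.95) {
  if (any(abs(r) >= 1)) stop("|r| must be < 1")
  if (df < 2) stop("df must be >= 2 for a Fisher-z interval")
  # Fisher z: effective n = df + 2 for a simple correlation, se = 1/sqrt(n-3)
  se <- 1 / sqrt(df - 1)
  z <- atanh(r)
  q <- stats::qnorm(1 - (1 - conf) / 2)
  tanh(c(z - q * se, z + q * se))
}

#' Phylogenetic allometric regression against cubed SVL
#'
#' PGLS of log tissue mass on log cubed snout-vent length, so that a slope
#' of 1 corresponds to isometry (mass proportional to length cubed). The
#' slope is classified against 1 using its bootstrap 95% CI: `steeper` if
#' the lower bound exceeds 1, `shallower` if the upper bound is below 1,
#' `proportionate` otherwise.
#'
#' @param mass Positive tissue masses (one per species).
#' @param svl Positive snout-vent lengths.
#' @param tree Phylogeny.
#' @param species Species labels matching tip labels; defaults to
#'   `names(mass)`.
#' @param cube Cube SVL before logging (default `TRUE`).
#' @param n_boot,seed Passed to [fit_pgls()].
#' @return An `allometry_fit` with `slope`, `ci` and `classification`.
#' @export
fit_allometry <- function(mass, svl, tree, species = names(mass),
                          cube = TRUE, n_boot = 100, seed = NULL) {
  if (any(mass <= 0) || any(svl <= 0)) {
    stop("masses and SVL must be strictly positive")
  }
  if (is.null(species)) stop("species labels required")
  size <- if (cube) svl^3 else svl
  dat <- data.frame(species = species, log_mass = log(mass),
                    log_size = log(size))
  fit <- fit_pgls(log_mass ~ log_size, dat, tree, n_boot = n_boot,
                  seed = seed)
  slope <- unname(fit$coefficients["log_size"])
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    ci <- fit$boot$raw_ci["log_size", ]
  }
  # tiny tolerance so that numerically exact isometry stays proportionate
  eps <- 1e-8
  classification <- if (!anyNA(ci) && ci[1] > 1 + eps) {
    "steeper"
  } else if (!anyNA(ci) && ci[2] < 1 - eps) {
    "shallower"
  } else {
    "proportionate"
  }
  structure(list(slope = slope, ci = ci, classification = classification,
                 pgls = fit), class = "allometry_fit")
}

#' @export
print.allometry_fit <- function(x, ...) {
  cat("Allometric slope:", round(x$slope, 3))
  if (!anyNA(x$ci)) {
    cat(" [", paste(round(x$ci, 3), collapse = ", "), "]")
  }
  cat(" ->", x$classification, "\n")
  invisible(x)
}
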