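#' Close a compositional vector (or matrix) to proportions
#'
#' Divides each part by the row total so that the parts sum to 1. Closure
#' is scale-invariant: `close_composition(k * x)` equals
#' `close_composition(x)` for any k > 0.
#'
#' @param parts Positive numeric vector, or matrix/data frame with one
#'   composition per row.
#' @return Object of the same shape with rows summing to 1.
#' @export
close_composition <- function(parts) {
  if (is.data.frame(parts)) parts <- as.matrix(parts)
  if (is.matrix(parts)) {
    bad <- which(parts <= 0, arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stop("nonpositive part: row ",
           paste(rownames(parts)[bad[1, 1]], colnames(parts)[bad[1, 2]],
                 sep = " / "))
    }
    sweep(parts, 1, rowSums(parts), "/")
  } else {
    if (any(parts <= 0)) {
      stop("nonpositive part: ",
           paste(names(parts)[parts <= 0], collapse = ", "))
    }
    parts / sum(parts)
  }
}

#' Centered log-ratio transform
#'
#' `clr(x)_i = log(x_i) - mean(log(x))`; components sum to zero and the
#' original part identities are preserved.
#'
#' @param x Closed composition (vector or row-wise matrix); zero parts are
#'   an error (no silent zero replacement is performed).
#' @return Numeric vector/matrix of clr coordinates.
#' @export
clr <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.matrix(x)) {
    if (any(x <= 0)) stop("zero or negative part in composition")
    lx <- log(x)
    lx - rowMeans(lx)
  } else {
    if (any(x <= 0)) stop("zero or negative part in composition")
    log(x) - mean(log(x))
  }
}

# Helmert-type orthonormal ilr basis (D x (D-1)); columns sum to 0
ilr_basis <- function(D) {
  Vb <- matrix(0, D, D - 1)
  for (j in seq_len(D - 1)) {
    Vb[seq_len(j), j] <- 1 / j
    Vb[j + 1, j] <- -1
    Vb[, j] <- Vb[, j] * sqrt(j / (j + 1))
  }
  Vb
}

#' Isometric log-ratio transform and its inverse
#'
#' Projects a D-part composition isometrically to D-1 unconstrained
#' coordinates using a fixed Helmert-type balance basis: `ilr(x) = V' clr(x)`
#' with V the D x (D-1) orthonormal basis, and
#' `ilr_inv(y) = close(exp(V y))`. The ilr map preserves Aitchison
#' distances; `ilr_inv(0)` is the barycentre (1/D per part), the null
#' expectation for back-transformed regression coefficients.
#'
#' @param x Closed composition (vector or row-wise matrix).
#' @param y ilr coordinates (length D-1 vector or matrix with D-1 columns).
#' @param D Number of parts for `ilr_inv` (default `length(y) + 1`).
#' @return Coordinates (ilr) or a closed composition (ilr_inv).
#' @export
ilr <- function(x) {
  z <- clr(x)
  if (is.matrix(z)) {
    z %*% ilr_basis(ncol(z))
  } else {
    as.numeric(crossprod(ilr_basis(length(z)), z))
  }
}

#' @rdname ilr
#' @export
ilr_inv <- function(y, D = NULL) {
  if (is.matrix(y)) {
    if (is.null(D)) D <- ncol(y) + 1L
    close_composition(exp(y %*% t(ilr_basis(D))))
  } else {
    if (is.null(D)) D <- length(y) + 1L
    close_composition(exp(as.numeric(ilr_basis(D) %*% y)))
  }
}

#' Multivariate phylogenetic regression of ilr coordinates
#'
#' Fits a multivariate GLS of the ilr-transformed composition on a single
#' predictor under a common Pagel's lambda (profiled by ML), computes
#' Pillai's trace from the hypothesis and error cross-product matrices of
#' the phylogeny-whitened data, and obtains a p-value by permuting the
#' whitened residuals of the intercept-only model. The predictor's ilr
#' coefficient vector is back-transformed to the simplex with [ilr_inv()]
#' for interpretation (each part would be 1/D if the predictor had no
#' effect).
#'
#' The effect size `xi2` is a permutation-corrected Pillai trace,
#' `(V - mean(V_perm)) / (1 - mean(V_perm))`, i.e. the observed association
#' rescaled against its chance expectation.
#'
#' @param ilr_response n x (D-1) matrix of ilr coordinates with species
#'   rownames.
#' @param predictor Named numeric vector (species names) or numeric vector
#'   aligned with the rows.
#' @param tree Phylogeny.
#' @param n_perm Number of permutations (default 999).
#' @param seed Seed for the permutations.
#' @return An `mv_pgls_fit` with `pillai`, `xi2`, `p_perm`, `p_approx`
#'   (F approximation), `lambda_hat`, `coef_ilr` and `coef_simplex`.
#' @export
fit_mv_pgls <- function(ilr_response, predictor, tree, n_perm = 999,
                        seed = NULL) {
  Y <- as.matrix(ilr_response)
  n <- nrow(Y)
  m <- ncol(Y)
  if (n <= m + 1) stop("insufficient data: need n > number of coordinates + 1")
  if (is.null(rownames(Y))) stop("ilr_response needs species rownames")
  if (!is.null(names(predictor))) {
    predictor <- predictor[rownames(Y)]
  }
  if (anyNA(predictor) || !all(is.finite(predictor))) {
    stop("predictor must be finite for every species")
  }
  names(predictor) <- rownames(Y)
  keep <- intersect(tree$tip.label, rownames(Y))
  tree <- ape::keep.tip(tree, keep)
  Y <- Y[tree$tip.label, , drop = FALSE]
  predictor <- predictor[tree$tip.label]
  n <- nrow(Y)
  V <- phylo_covariance(tree, taxa = rownames(Y))$V
  X <- cbind(`(Intercept)` = 1, predictor = as.numeric(predictor))

  mv_ll <- function(lam) {
    C <- apply_lambda(V, lam)$V
    L <- chol(C)
    Wy <- backsolve(L, Y, transpose = TRUE)
    Wx <- backsolve(L, X, transpose = TRUE)
    B <- qr.coef(qr(Wx), Wy)
    E <- Wy - Wx %*% B
    S <- crossprod(E) / n
    ld <- determinant(S, logarithm = TRUE)$modulus[1]
    -(n * m * log(2 * pi) + n * ld + m * 2 * sum(log(diag(L))) + n * m) / 2
  }
  grid <- seq(0, 1, length.out = 21)
  vals <- vapply(grid, mv_ll, numeric(1))
  i <- which.max(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(mv_ll, c(lo, hi), maximum = TRUE, tol = 1e-6)
  lam <- if (opt$objective >= vals[i]) opt$maximum else grid[i]

  C <- apply_lambda(V, lam)$V
  L <- chol(C)
  Wy <- backsolve(L, Y, transpose = TRUE)
  Wx <- backsolve(L, X, transpose = TRUE)
  qf <- qr(Wx)
  B <- qr.coef(qf, Wy)
  E_full <- Wy - Wx %*% B
  SSE <- crossprod(E_full)
  W0 <- Wx[, 1, drop = FALSE]
  q0 <- qr(W0)
  B0 <- qr.coef(q0, Wy)
  E_red <- Wy - W0 %*% B0
  SSH <- crossprod(E_red) - SSE

  pillai_of <- function(H, E) {
    sum(diag(H %*% solve(H + E)))
  }
  pillai <- pillai_of(SSH, SSE)

  # permutation of whitened reduced-model residuals
  if (!is.null(seed)) set.seed(seed)
  fitted0 <- W0 %*% B0
  perm_stats <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    Wy_star <- fitted0 + E_red[sample.int(n), , drop = FALSE]
    Bs <- qr.coef(qf, Wy_star)
    Es <- Wy_star - Wx %*% Bs
    SSEs <- crossprod(Es)
    B0s <- qr.coef(q0, Wy_star)
    E0s <- Wy_star - W0 %*% B0s
    SSHs <- crossprod(E0s) - SSEs
    perm_stats[b] <- pillai_of(SSHs, SSEs)
  }
  p_perm <- (1 + sum(perm_stats >= pillai)) / (n_perm + 1)
  xi2 <- (pillai - mean(perm_stats)) / (1 - mean(perm_stats))

  # F approximation for Pillai with s = 1 hypothesis df
  s <- 1
  df1 <- m
  df2 <- n - ncol(X) - m + 1
  Fstat <- (pillai / df1) / ((s - pillai) / df2)
  p_approx <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)

  coef_ilr <- B[2, ]  # predictor row (intercept first)
  coef_simplex <- ilr_inv(as.numeric(coef_ilr), D = m + 1)

  structure(list(
    pillai = pillai, xi2 = xi2, p_perm = p_perm,
    F = Fstat, p_approx = p_approx,
    lambda_hat = lam, n = n, n_perm = n_perm,
    coef_ilr = coef_ilr, coef_simplex = coef_simplex,
    perm_mean = mean(perm_stats)
  ), class = "mv_pgls_fit")
}

#' @export
print.mv_pgls_fit <- function(x, ...) {
  cat("Multivariate phylogenetic regression (n =", x$n, ")\n")
  cat("Pillai =", round(x$pillai, 3), " xi2 =", round(x$xi2, 3),
      " p(perm) =", signif(x$p_perm, 3),
      " lambda =", round(x$lambda_hat, 3), "\n")
  cat("Back-transformed coefficients:",
      paste(round(x$coef_simplex, 3), collapse = ", "), "\n")
  invisible(x)
}
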