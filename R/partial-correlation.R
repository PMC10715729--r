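#' Phylogenetic trait variance-covariance matrix
#'
#' Estimates the evolutionary rate (trait covariance) matrix by GLS about
#' the phylogenetic mean: with C the phylogenetic covariance (optionally
#' lambda-scaled) and `a` the GLS means,
#' `R = (X - 1a')' C^{-1} (X - 1a') / (n - 1)`. On a star phylogeny this
#' reduces to the ordinary sample covariance.
#'
#' @param traits Data frame or matrix of numeric trait columns with species
#'   as rownames (or a `species` column).
#' @param tree Phylogeny.
#' @param lam Pagel's lambda for the residual covariance; 1 (Brownian
#'   motion) by default.
#' @return List with `R` (trait covariance), `corr` (its correlation),
#'   `means` (phylogenetic GLS means) and `n`.
#' @export
phylo_trait_vcv <- function(traits, tree, lam = 1) {
  if (is.data.frame(traits) && "species" %in% names(traits)) {
    al <- align_tree_traits(tree, traits, quiet = TRUE)
    tree <- al$tree
    X <- as.matrix(al$traits[, setdiff(names(al$traits), "species"),
                             drop = FALSE])
    rownames(X) <- al$traits$species
  } else {
    X <- as.matrix(traits)
    if (is.null(rownames(X))) stop("traits need species rownames")
    keep <- intersect(tree$tip.label, rownames(X))
    tree <- ape::keep.tip(tree, keep)
    X <- X[tree$tip.label, , drop = FALSE]
  }
  n <- nrow(X)
  if (n < 3) stop("need at least 3 species")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant trait column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  }
  C <- apply_lambda(phylo_covariance(tree, taxa = rownames(X)), lam)$V
  L <- chol(C)
  one <- matrix(1, n, 1)
  Wx <- backsolve(L, X, transpose = TRUE)
  W1 <- backsolve(L, one, transpose = TRUE)
  a <- as.numeric(crossprod(W1, Wx) / sum(W1^2))
  D <- Wx - W1 %*% t(a)
  R <- crossprod(D) / (n - 1)
  dimnames(R) <- list(colnames(X), colnames(X))
  list(R = R, corr = stats::cov2cor(R),
       means = stats::setNames(a, colnames(X)), n = n)
}

#' Partial correlation from pairwise correlations
#'
#' First-order partial correlation of x and y controlling for z:
#' `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`.
#'
#' @param r_xy,r_xz,r_yz Pairwise correlations in (-1, 1).
#' @return The partial correlation.
#' @export
partial_r <- function(r_xy, r_xz, r_yz) {
  if (abs(r_xz) >= 1 || abs(r_yz) >= 1) {
    stop("control correlations must be strictly inside (-1, 1)")
  }
  (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
}

#' Pairwise phylogenetic partial correlations between tissues
#'
#' For each unordered pair of tissue columns, computes the phylogenetic
#' trait correlation matrix (with the control variable, lambda = 1) via
#' [phylo_trait_vcv()], derives the partial correlation controlling for
#' the control variable with [partial_r()], and converts it to a
#' t statistic and Fisher-z confidence interval. The t test uses
#' df = n - 3 (two focal variables plus one control, minus the mean).
#'
#' @param traits Data frame with `species`, tissue columns and the control
#'   column. Values are used as supplied (log-transform upstream).
#' @param tissues Character vector of tissue column names.
#' @param control Name of the control column (default `"log_svl"`).
#' @param tree Phylogeny.
#' @param lam Lambda for the trait covariance (1 = Brownian motion).
#' @return Data frame: pair, r (partial), t, df, p, ci_low, ci_high.
#' @export
all_pairwise_partials <- function(traits, tissues, control = "log_svl",
                                  tree, lam = 1) {
  if (!control %in% names(traits)) {
    stop("control column '", control, "' missing from trait table")
  }
  if (!all(tissues %in% names(traits))) {
    stop("missing tissue column(s): ",
         paste(setdiff(tissues, names(traits)), collapse = ", "))
  }
  pairs <- utils::combn(tissues, 2)
  out <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    x <- pairs[1, k]; y <- pairs[2, k]
    sub <- traits[, c("species", x, y, control)]
    pv <- phylo_trait_vcv(sub, tree, lam = lam)
    rc <- pv$corr
    r_p <- partial_r(rc[x, y], rc[x, control], rc[y, control])
    df <- pv$n - 3
    t <- t_from_r(r_p, df)
    ci <- r_ci(r_p, df)
    out[[k]] <- data.frame(
      x = x, y = y, control = control,
      r = r_p, t = t, df = df,
      p = 2 * stats::pt(abs(t), df, lower.tail = FALSE),
      ci_low = ci[1], ci_high = ci[2]
    )
  }
  do.call(rbind, out)
}
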