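#' Phylogenetically informed principal component analysis
#'
#' Eigendecomposition of the evolutionary trait covariance (or correlation)
#' matrix estimated by GLS about the phylogenetic mean under Brownian
#' motion (see [phylo_trait_vcv()]). Scores are the trait deviations from
#' the GLS phylogenetic mean projected on the eigenvectors; percent
#' variance per component comes from the eigenvalues. On a star phylogeny
#' the result coincides with an ordinary PCA of the centered data.
#'
#' Each loading column is sign-fixed so that its largest-magnitude entry is
#' positive, making the output deterministic.
#'
#' @param traits Data frame with `species` plus numeric trait columns
#'   (typically log species means), or a matrix with species rownames.
#' @param tree Phylogeny.
#' @param mode `"covariance"` (default) or `"correlation"`.
#' @param lam Lambda for the residual structure (1 = Brownian motion).
#' @return A `ppca_fit` with `eigenvalues`, `percent_variance`, `loadings`,
#'   `scores` and `mode`.
#' @export
fit_ppca <- function(traits, tree, mode = c("covariance", "correlation"),
                     lam = 1) {
  mode <- match.arg(mode)
  pv <- phylo_trait_vcv(traits, tree, lam = lam)
  if (is.data.frame(traits) && "species" %in% names(traits)) {
    al <- align_tree_traits(tree, traits, quiet = TRUE)
    X <- as.matrix(al$traits[, setdiff(names(al$traits), "species"),
                             drop = FALSE])
    rownames(X) <- al$traits$species
  } else {
    X <- as.matrix(traits)
    X <- X[intersect(tree$tip.label, rownames(X)), , drop = FALSE]
  }
  k <- ncol(X)
  if (nrow(X) < 3 || k < 2) stop("need >= 3 species and >= 2 traits")
  if (mode == "correlation" && nrow(X) < k) {
    warning("fewer species than traits in correlation mode")
  }
  M <- if (mode == "covariance") pv$R else pv$corr
  eg <- eigen(M, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  Vv <- eg$vectors
  # deterministic sign: largest-|loading| entry positive per column
  for (j in seq_len(ncol(Vv))) {
    i <- which.max(abs(Vv[, j]))
    if (Vv[i, j] < 0) Vv[, j] <- -Vv[, j]
  }
  cn <- paste0("PC", seq_len(k))
  dimnames(Vv) <- list(colnames(X), cn)
  centred <- sweep(X, 2, pv$means)
  if (mode == "correlation") {
    centred <- sweep(centred, 2, sqrt(diag(pv$R)), "/")
  }
  scores <- centred %*% Vv
  structure(list(
    eigenvalues = stats::setNames(ev, cn),
    percent_variance = stats::setNames(100 * ev / sum(ev), cn),
    loadings = Vv,
    scores = scores,
    mode = mode,
    trait_vcv = M
  ), class = "ppca_fit")
}

#' @export
print.ppca_fit <- function(x, ...) {
  cat("Phylogenetic PCA (", x$mode, " mode)\n", sep = "")
  print(round(rbind(eigenvalue = x$eigenvalues,
                    `% variance` = x$percent_variance), 3))
  invisible(x)
}
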