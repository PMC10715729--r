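#' Read a Newick tree
#'
#' Parses a Newick string into an `ape` phylogeny, with stricter validation
#' than [ape::read.tree()]: unbalanced parentheses are reported with their
#' character position and trees with missing branch lengths are rejected,
#' since every downstream covariance computation needs them.
#'
#' @param text A Newick string (or a length-1 character vector holding one).
#' @return An object of class `phylo`.
#' @export
read_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("malformed Newick: unmatched ')' at position ", i)
      }
    }
  }
  if (depth > 0L) {
    stop("malformed Newick: ", depth, " unclosed '(' by position ",
         length(chars))
  }
  if (!grepl(";", text, fixed = TRUE)) {
    stop("malformed Newick: no terminating ';' found at position ",
         length(chars))
  }
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("malformed Newick: ", conditionMessage(e))
  )
  if (is.null(tree)) stop("malformed Newick: parser returned no tree")
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths; branch lengths are required")
  }
  if (anyNA(tree$edge.length)) {
    stop("tree has missing branch lengths on ",
         sum(is.na(tree$edge.length)), " edge(s)")
  }
  if (any(tree$edge.length < 0)) {
    stop("tree has negative branch lengths")
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  }
  tree
}

#' Write a phylogeny to a Newick string
#'
#' @param tree A `phylo` object.
#' @return A Newick string.
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree)
}

#' Phylogenetic covariance matrix
#'
#' Entry (i, j) is the total branch length shared by the root-to-tip paths
#' of taxa i and j (the expected trait covariance under Brownian motion);
#' the diagonal holds root-to-tip distances. The returned object carries a
#' Pagel's lambda attribute, initialised to 1 (no rescaling).
#'
#' @param tree A `phylo` object with branch lengths.
#' @param taxa Optional character vector selecting and ordering the rows
#'   and columns; must be a subset of the tip labels.
#' @return A `phylo_vcv` object: list with elements `V` (matrix), `taxa`
#'   and `lambda`.
#' @export
phylo_covariance <- function(tree, taxa = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  term <- tree$edge[, 2] <= length(tree$tip.label)
  if (any(tree$edge.length[term] == 0)) {
    warning("tree has zero-length terminal branches; ",
            "lambda estimation can degenerate")
  }
  V <- ape::vcv.phylo(tree)
  if (!is.null(taxa)) {
    missing <- setdiff(taxa, rownames(V))
    if (length(missing) > 0) {
      stop("taxa not in tree: ", paste(missing, collapse = ", "))
    }
    V <- V[taxa, taxa, drop = FALSE]
  }
  new_phylo_vcv(V, lambda = 1)
}

new_phylo_vcv <- function(V, lambda = 1) {
  structure(list(V = V, taxa = rownames(V), lambda = lambda),
            class = "phylo_vcv")
}

#' @export
print.phylo_vcv <- function(x, ...) {
  cat("Phylogenetic covariance for", nrow(x$V), "taxa (lambda =",
      format(x$lambda), ")\n")
  invisible(x)
}

as_vcv_matrix <- function(C) {
  if (inherits(C, "phylo_vcv")) C$V else as.matrix(C)
}

#' Apply Pagel's lambda transform
#'
#' Multiplies all off-diagonal entries of a phylogenetic covariance matrix
#' by `lam`, leaving the diagonal unchanged. `lam = 1` returns the matrix
#' untouched (Brownian motion); `lam = 0` removes all shared history (star
#' phylogeny).
#'
#' @param C A `phylo_vcv` object or covariance matrix.
#' @param lam Scalar in \[0, 1\].
#' @return A `phylo_vcv` with the transformed matrix and `lambda = lam`.
#' @export
apply_lambda <- function(C, lam) {
  if (!is.numeric(lam) || length(lam) != 1L || is.na(lam) ||
      lam < 0 || lam > 1) {
    stop("lambda must be a single value in [0, 1]")
  }
  V <- as_vcv_matrix(C)
  d <- diag(V)
  V2 <- V * lam
  diag(V2) <- d
  out <- new_phylo_vcv(V2, lambda = lam)
  out$taxa <- if (inherits(C, "phylo_vcv")) C$taxa else rownames(V)
  out
}

#' Generalized least squares under a phylogenetic covariance
#'
#' Solves the GLS normal equations via a Cholesky factorisation of the
#' covariance (never an explicit inverse) and returns ML quantities: the
#' residual rate `sigma2` is the ML estimate RSS/n, and the log-likelihood
#' is the multivariate normal density at the fit. Standard errors use the
#' unbiased RSS/(n - p) scaling so that t = beta/SE follows the usual
#' t distribution on n - p degrees of freedom.
#'
#' @param y Numeric response vector.
#' @param X Design matrix (rows aligned with `y` and the taxa order of `C`).
#' @param C A `phylo_vcv` or covariance matrix.
#' @return A `gls_fit` object.
#' @export
gls_fit <- function(y, X, C) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- length(y)
  stopifnot(nrow(X) == n)
  V <- as_vcv_matrix(C)
  stopifnot(nrow(V) == n, ncol(V) == n)
  p <- ncol(X)
  L <- tryCatch(chol(V), error = function(e)
    stop("covariance not positive definite: ", conditionMessage(e)))
  # whiten: solve t(L) %*% z = y
  z <- backsolve(L, y, transpose = TRUE)
  W <- backsolve(L, X, transpose = TRUE)
  qw <- qr(W)
  if (qw$rank < p) stop("design matrix is rank-deficient")
  beta <- qr.coef(qw, z)
  res_w <- z - W %*% beta
  rss <- sum(res_w^2)
  df <- n - p
  sigma2_ml <- rss / n
  logdetV <- 2 * sum(log(diag(L)))
  ll <- if (sigma2_ml > 0) {
    -0.5 * (n * log(2 * pi) + n * log(sigma2_ml) + logdetV + n)
  } else {
    Inf
  }
  R <- qr.R(qw)
  XtViX_inv <- chol2inv(R)
  # undo any pivoting from the QR
  piv <- qw$pivot
  XtViX_inv <- XtViX_inv[order(piv), order(piv), drop = FALSE]
  se <- sqrt(pmax(diag(XtViX_inv), 0) * if (df > 0) rss / df else NaN)
  tval <- beta / se
  fitted <- as.numeric(X %*% beta)
  structure(list(
    coefficients = stats::setNames(as.numeric(beta), colnames(X)),
    standard_errors = stats::setNames(as.numeric(se), colnames(X)),
    t_statistics = stats::setNames(as.numeric(tval), colnames(X)),
    df = df,
    sigma2 = sigma2_ml,
    log_likelihood = ll,
    fitted = fitted,
    residuals = y - fitted,
    n = n,
    XtViX_inv = XtViX_inv,
    lambda = if (inherits(C, "phylo_vcv")) C$lambda else NA_real_
  ), class = "gls_fit")
}

#' @export
print.gls_fit <- function(x, ...) {
  cat("Generalized least-squares fit (n =", x$n, ", df =", x$df, ")\n")
  tab <- cbind(Estimate = x$coefficients, SE = x$standard_errors,
               t = x$t_statistics)
  print(round(tab, 4))
  cat("sigma2 (ML):", format(x$sigma2, digits = 4),
      " logLik:", format(x$log_likelihood, digits = 6), "\n")
  invisible(x)
}

#' @export
logLik.gls_fit <- function(object, ...) {
  structure(object$log_likelihood, df = length(object$coefficients) + 1,
            class = "logLik")
}

#' Align a trait table with a phylogeny
#'
#' Prunes the tree to the species present in the trait table and drops
#' trait rows absent from the tree, reporting both counts. Species matching
#' is exact and case-sensitive on the `species` column.
#'
#' @param tree A `phylo` object.
#' @param traits A data frame with a `species` column.
#' @param quiet Suppress the alignment message.
#' @return List with elements `tree` (pruned) and `traits` (reordered to
#'   match the tip labels of the pruned tree).
#' @export
align_tree_traits <- function(tree, traits, quiet = FALSE) {
  stopifnot(inherits(tree, "phylo"), is.data.frame(traits))
  if (!"species" %in% names(traits)) {
    stop("trait table must have a 'species' column")
  }
  if (anyDuplicated(traits$species)) {
    stop("duplicate species in trait table")
  }
  common <- intersect(tree$tip.label, traits$species)
  if (length(common) < 1) stop("no species shared between tree and traits")
  dropped_tips <- length(tree$tip.label) - length(common)
  dropped_rows <- nrow(traits) - length(common)
  if (!quiet && (dropped_tips > 0 || dropped_rows > 0)) {
    message("alignment: pruned ", dropped_tips, " tip(s); dropped ",
            dropped_rows, " trait row(s)")
  }
  tree2 <- if (dropped_tips > 0) ape::keep.tip(tree, common) else tree
  traits2 <- traits[match(tree2$tip.label, traits$species), , drop = FALSE]
  rownames(traits2) <- traits2$species
  list(tree = tree2, traits = traits2)
}
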