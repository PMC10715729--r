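#' Construct a directed acyclic path model
#'
#' @param edges Character vector of edge specifications, one per line in
#'   the form `"child <- parent1 + parent2"`, or a two-column data frame
#'   / matrix with columns `from`, `to`.
#' @param nodes Optional full node set (allows isolated nodes).
#' @param name Optional model label.
#' @return A `path_model` (nodes, edges data frame, name).
#' @export
path_model <- function(edges, nodes = NULL, name = NULL) {
  if (is.character(edges)) {
    ed <- do.call(rbind, lapply(edges, parse_edge_line))
  } else {
    ed <- as.data.frame(edges)
    names(ed) <- c("from", "to")
  }
  ed <- unique(ed)
  all_nodes <- union(nodes, union(ed$from, ed$to))
  ord <- topo_sort(all_nodes, ed)
  if (is.null(ord)) stop("graph is cyclic: not a valid path model")
  structure(list(nodes = all_nodes, edges = ed, order = ord, name = name),
            class = "path_model")
}

parse_edge_line <- function(line) {
  line <- trimws(line)
  parts <- strsplit(line, "<-", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("cannot parse edge line: ", line)
  child <- trimws(parts[1])
  parents <- trimws(strsplit(parts[2], "+", fixed = TRUE)[[1]])
  data.frame(from = parents, to = child)
}

# Kahn's algorithm; returns NULL on a cycle
topo_sort <- function(nodes, edges) {
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  for (v in edges$to) indeg[v] <- indeg[v] + 1L
  order <- character(0)
  avail <- sort(names(indeg)[indeg == 0L])  # alphabetical tie-break
  ed <- edges
  while (length(avail) > 0) {
    v <- avail[1]
    avail <- avail[-1]
    order <- c(order, v)
    out <- ed$to[ed$from == v]
    ed <- ed[ed$from != v, , drop = FALSE]
    for (w in out) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) avail <- sort(c(avail, w))
    }
  }
  if (length(order) != length(nodes)) NULL else order
}

parents_of <- function(model, v) {
  model$edges$from[model$edges$to == v]
}

#' @export
print.path_model <- function(x, ...) {
  cat("Path model", if (!is.null(x$name)) paste0("'", x$name, "'"),
      "with", length(x$nodes), "nodes and", nrow(x$edges), "edges\n")
  for (v in x$order) {
    pa <- parents_of(x, v)
    if (length(pa) > 0) cat(" ", v, "<-", paste(pa, collapse = " + "), "\n")
  }
  invisible(x)
}

#' d-separation basis set of a DAG
#'
#' One conditional-independence claim per non-adjacent pair of nodes (x, y):
#' x is independent of y given the union of the parents of x and of y.
#' Pairs are ordered canonically so that y never precedes x in the
#' topological order (with alphabetical tie-break), making the output
#' independent of how the nodes were listed; a saturated DAG yields an
#' empty set.
#'
#' @param model A `path_model`.
#' @return List of claims, each a list with `x`, `y` and `cond`.
#' @export
basis_set <- function(model) {
  stopifnot(inherits(model, "path_model"))
  ord <- model$order
  adj <- paste(model$edges$from, model$edges$to)
  claims <- list()
  nn <- length(ord)
  for (i in seq_len(nn - 1)) {
    for (j in (i + 1):nn) {
      x <- ord[i]; y <- ord[j]
      if (paste(x, y) %in% adj || paste(y, x) %in% adj) next
      cond <- sort(setdiff(union(parents_of(model, x),
                                 parents_of(model, y)), c(x, y)))
      claims[[length(claims) + 1]] <- list(x = x, y = y, cond = cond)
    }
  }
  claims
}

#' Fisher's C statistic
#'
#' Combines the p-values of the k conditional-independence claims of a path
#' model: `C = -2 sum(log p_i)`, chi-squared with `2k` degrees of freedom
#' under the model. p-values of exactly zero are clamped to 1e-300 with a
#' warning.
#'
#' @param p_values Numeric vector of claim p-values in (0, 1].
#' @return List with `C`, `df` and `p`.
#' @export
fishers_c <- function(p_values) {
  if (length(p_values) == 0) {
    return(list(C = 0, df = 0, p = 1))
  }
  if (any(p_values < 0 | p_values > 1)) stop("p-values must be in [0, 1]")
  if (any(p_values == 0)) {
    warning("p-value of 0 clamped to 1e-300")
    p_values[p_values == 0] <- 1e-300
  }
  C <- -2 * sum(log(p_values))
  df <- 2 * length(p_values)
  list(C = C, df = df, p = stats::pchisq(C, df, lower.tail = FALSE))
}

#' Fit a phylogenetic path model
#'
#' Tests every d-separation claim of the model by the t test of x's
#' coefficient in a lambda-ML PGLS of y on x plus the conditioning set,
#' combines them into Fisher's C, and computes the C-statistic information
#' criterion `CICc = C + 2 q n / (n - 1 - q)`. The parameter count q is the
#' number of edges plus the number of free covariances among exogenous
#' nodes (one per unordered pair of parentless vertices). Per-edge
#' standardized coefficients come from the PGLS of each child on its
#' parents, with normal-approximation 95% CIs on the standardized scale.
#'
#' If `size_control` is given, that column enters every claim regression
#' and every edge regression as a covariate (body size as a parent of all
#' nodes), without itself being subject to independence claims.
#'
#' @param model A `path_model`.
#' @param data Data frame with `species` and all node columns.
#' @param tree Phylogeny.
#' @param size_control Optional column name (e.g. `"log_svl"`).
#' @return A `path_fit`.
#' @export
fit_path_model <- function(model, data, tree, size_control = NULL) {
  stopifnot(inherits(model, "path_model"))
  missing_nodes <- setdiff(model$nodes, names(data))
  if (length(missing_nodes) > 0) {
    stop("nodes missing from data: ", paste(missing_nodes, collapse = ", "))
  }
  claims <- basis_set(model)
  n <- sum(data$species %in% tree$tip.label)
  claim_p <- numeric(length(claims))
  for (k in seq_along(claims)) {
    cl <- claims[[k]]
    rhs <- unique(c(cl$x, cl$cond, size_control))
    f <- stats::as.formula(paste(cl$y, "~", paste(rhs, collapse = " + ")))
    fit <- fit_pgls(f, data, tree, n_boot = 0)
    claim_p[k] <- fit$p_values[cl$x]
  }
  fc <- fishers_c(claim_p)
  n_exo <- sum(vapply(model$nodes,
                      function(v) length(parents_of(model, v)) == 0,
                      logical(1)))
  q <- nrow(model$edges) + choose(n_exo, 2)
  if (n <= q + 1) stop("CICc undefined: n <= q + 1")
  cicc <- fc$C + 2 * q * n / (n - 1 - q)

  # per-edge standardized coefficients
  edge_rows <- list()
  for (child in unique(model$edges$to)) {
    pa <- parents_of(model, child)
    rhs <- unique(c(pa, size_control))
    f <- stats::as.formula(paste(child, "~", paste(rhs, collapse = " + ")))
    fit <- fit_pgls(f, data, tree, n_boot = 0)
    for (p_ in pa) {
      b <- fit$standardized_betas[p_]
      # t is scale-invariant, so beta_std / t is the SE on that scale
      se <- b / fit$t_statistics[p_]
      edge_rows[[length(edge_rows) + 1]] <- data.frame(
        from = p_, to = child, beta = unname(b),
        ci_low = unname(b - 1.96 * abs(se)),
        ci_high = unname(b + 1.96 * abs(se))
      )
    }
  }
  edges <- do.call(rbind, edge_rows)
  structure(list(
    model = model, claims = claims, claim_p = claim_p,
    C = fc$C, df = fc$df, p = fc$p, q = q, n = n, CICc = cicc,
    coefficients = edges
  ), class = "path_fit")
}

#' @export
print.path_fit <- function(x, ...) {
  cat("Path fit", if (!is.null(x$model$name)) paste0("'", x$model$name, "'"),
      ": C =", round(x$C, 3), "df =", x$df, "p =", signif(x$p, 3),
      "q =", x$q, "CICc =", round(x$CICc, 2), "\n")
  print(transform(x$coefficients, beta = round(beta, 3),
                  ci_low = round(ci_low, 3), ci_high = round(ci_high, 3)))
  invisible(x)
}

#' Rank fitted path models by CICc
#'
#' @param fits List of `path_fit` objects.
#' @return Data frame with model, C, df, p, q, CICc, delta_CICc and
#'   CICc-based Akaike-type weights, ordered by CICc.
#' @export
rank_path_models <- function(fits) {
  tab <- data.frame(
    model = vapply(fits, function(f) {
      if (is.null(f$model$name)) "unnamed" else f$model$name
    }, character(1)),
    C = vapply(fits, `[[`, numeric(1), "C"),
    df = vapply(fits, `[[`, numeric(1), "df"),
    p = vapply(fits, `[[`, numeric(1), "p"),
    q = vapply(fits, `[[`, numeric(1), "q"),
    CICc = vapply(fits, `[[`, numeric(1), "CICc")
  )
  tab$delta_CICc <- tab$CICc - min(tab$CICc)
  w <- exp(-tab$delta_CICc / 2)
  tab$weight <- w / sum(w)
  tab[order(tab$CICc), ]
}

#' Average path models within a CICc band
#'
#' Retains fits with `CICc - min(CICc) <= delta` (the top model is always
#' retained) and averages the standardized edge coefficients. Averaging is
#' conditional by default: an edge is averaged over the retained models
#' that contain it. With `weighted = TRUE` the average uses CICc weights
#' `exp(-delta_i/2)` renormalized over the retained set.
#'
#' @param fits List of `path_fit` objects.
#' @param delta CICc band (default 2).
#' @param weighted Use CICc weights instead of an unweighted mean.
#' @return List with `edges` (averaged coefficient table) and `retained`
#'   (model names).
#' @export
average_models <- function(fits, delta = 2, weighted = FALSE) {
  stopifnot(length(fits) >= 1)
  cicc <- vapply(fits, `[[`, numeric(1), "CICc")
  keep <- which(cicc - min(cicc) <= delta)
  w_all <- exp(-(cicc - min(cicc)) / 2)
  rows <- list()
  for (i in keep) {
    e <- fits[[i]]$coefficients
    e$w <- if (weighted) w_all[i] else 1
    rows[[length(rows) + 1]] <- e
  }
  allr <- do.call(rbind, rows)
  key <- paste(allr$from, allr$to, sep = "->")
  agg <- lapply(split(allr, key), function(d) {
    data.frame(from = d$from[1], to = d$to[1],
               beta = sum(d$beta * d$w) / sum(d$w),
               ci_low = sum(d$ci_low * d$w) / sum(d$w),
               ci_high = sum(d$ci_high * d$w) / sum(d$w),
               n_models = nrow(d))
  })
  edges <- do.call(rbind, agg)
  rownames(edges) <- NULL
  retained <- vapply(fits[keep], function(f) {
    if (is.null(f$model$name)) "unnamed" else f$model$name
  }, character(1))
  list(edges = edges, retained = retained)
}

#' Read a candidate path-model set from a config file
#'
#' The plain-text format has one `model <name>` header per candidate
#' followed by its edge lines (`child <- parent1 + parent2`); blank lines
#' and `#` comments are ignored. Two reconstructed candidate sets matching
#' the study design ship with the package under `inst/extdata`
#' (`path_models_climate.txt`, 8 models; `path_models_tissue.txt`,
#' 28 models).
#'
#' @param path File path.
#' @param nodes Optional shared node set applied to every model.
#' @return Named list of `path_model` objects.
#' @export
read_path_models <- function(path, nodes = NULL) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  models <- list()
  cur_name <- NULL
  cur_edges <- character(0)
  flush <- function() {
    if (!is.null(cur_name)) {
      models[[cur_name]] <<- path_model(cur_edges, nodes = nodes,
                                        name = cur_name)
    }
  }
  for (ln in lines) {
    if (grepl("^model\\s+", ln)) {
      flush()
      cur_name <- sub("^model\\s+", "", ln)
      cur_edges <- character(0)
    } else {
      cur_edges <- c(cur_edges, ln)
    }
  }
  flush()
  models
}
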