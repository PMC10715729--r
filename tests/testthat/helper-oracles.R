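# Independent oracles used across the test suite. Each is a deliberately
# naive, literal implementation kept separate from the package internals.

# literal day-scan of the activity-period rule: first run of >= persistence
# days strictly above the start threshold opens the active period; the last
# day above the end threshold (scanning back from 31 Dec) closes it.
oracle_brumation_scan <- function(temps, thr_start, thr_end = thr_start,
                                  persistence = 5) {
  n <- length(temps)
  first <- NA_integer_
  for (i in seq_len(n - persistence + 1)) {
    ok <- TRUE
    for (j in i:(i + persistence - 1)) {
      if (!(temps[j] > thr_start)) { ok <- FALSE; break }
    }
    if (ok) { first <- i; break }
  }
  if (is.na(first)) return(n)
  last <- n
  while (last >= 1 && temps[last] <= thr_end) last <- last - 1
  if (last < first) return(n)
  n - (last - first + 1L)
}

# d-separation by explicit path blocking: enumerate every simple undirected
# path between x and y and test whether each is blocked given cond.
oracle_dsep <- function(nodes, edges, x, y, cond) {
  edge_key <- paste(edges$from, edges$to)
  descendants <- function(v) {
    out <- v
    frontier <- v
    while (length(frontier) > 0) {
      nxt <- setdiff(edges$to[edges$from %in% frontier], out)
      out <- c(out, nxt)
      frontier <- nxt
    }
    out
  }
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == y) {
      paths[[length(paths) + 1]] <<- path
      return(invisible())
    }
    nbrs <- union(edges$to[edges$from == v], edges$from[edges$to == v])
    for (w in setdiff(nbrs, path)) walk(c(path, w))
  }
  walk(x)
  for (p in paths) {
    blocked <- FALSE
    if (length(p) > 2) {
      for (i in 2:(length(p) - 1)) {
        a <- p[i - 1]; b <- p[i]; cc <- p[i + 1]
        collider <- paste(a, b) %in% edge_key && paste(cc, b) %in% edge_key
        if (collider) {
          if (!any(descendants(b) %in% cond)) { blocked <- TRUE; break }
        } else {
          if (b %in% cond) { blocked <- TRUE; break }
        }
      }
    }
    if (!blocked) return(FALSE)
  }
  TRUE
}

# random DAG on nodes n1..n, edges only from lower to higher index
oracle_random_dag <- function(n, p = 0.4) {
  nodes <- paste0("n", seq_len(n))
  from <- character(0); to <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (stats::runif(1) < p) {
        from <- c(from, nodes[i]); to <- c(to, nodes[j])
      }
    }
  }
  list(nodes = nodes, edges = data.frame(from = from, to = to))
}

# single-binary-trait pruning likelihood with the closed-form 2-state
# transition matrix (flat root)
oracle_two_state_loglik <- function(states, tree, q01, q10) {
  Pm <- function(t) {
    s <- q01 + q10
    if (s == 0) return(diag(2))
    e <- exp(-s * t)
    matrix(c(q10 + q01 * e, q01 - q01 * e,
             q10 - q10 * e, q01 + q10 * e), 2, 2, byrow = TRUE) / s
  }
  ntip <- length(tree$tip.label)
  part <- matrix(1, ntip + tree$Nnode, 2)
  part[seq_len(ntip), ] <- 0
  part[cbind(seq_len(ntip), states[tree$tip.label] + 1L)] <- 1
  tre <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(tre$edge))) {
    par <- tre$edge[e, 1]; ch <- tre$edge[e, 2]
    part[par, ] <- part[par, ] *
      as.numeric(Pm(tre$edge.length[e]) %*% part[ch, ])
  }
  log(sum(0.5 * part[ntip + 1L, ]))
}

# brute-force shared root-to-tip path length between two tips
oracle_shared_path <- function(tree, i, j) {
  root <- length(tree$tip.label) + 1L
  path_to_root <- function(tip) {
    edges <- integer(0)
    node <- tip
    while (node != root) {
      e <- which(tree$edge[, 2] == node)
      edges <- c(edges, e)
      node <- tree$edge[e, 1]
    }
    edges
  }
  shared <- intersect(path_to_root(i), path_to_root(j))
  sum(tree$edge.length[shared])
}

# simulate correlated Brownian traits on a tree (independent of the
# package's generator)
oracle_sim_bm <- function(tree, Sigma) {
  V <- ape::vcv.phylo(tree)
  n <- nrow(V)
  k <- nrow(Sigma)
  Z <- matrix(stats::rnorm(n * k), n, k)
  X <- t(chol(V)) %*% Z %*% chol(Sigma)
  rownames(X) <- rownames(V)
  X
}
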