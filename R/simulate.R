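#' Simulate a pure-birth phylogeny
#'
#' Yule tree with exactly `n_taxa` tips, reproducible under `seed`.
#'
#' @param n_taxa Number of tips (>= 2).
#' @param birth_rate Speciation rate.
#' @param seed Seed (required for reproducibility).
#' @return A `phylo` object with tip labels `sp001`, `sp002`, ...
#' @export
simulate_tree <- function(n_taxa, birth_rate = 1, seed) {
  if (n_taxa < 2) stop("n_taxa must be >= 2")
  set.seed(seed)
  tree <- ape::rphylo(n_taxa, birth = birth_rate, death = 0)
  tree$tip.label <- sprintf("sp%03d", seq_len(n_taxa))
  tree
}

#' Default trait-simulation configuration
#'
#' Tissue names, allometric slopes on cubed SVL, intercepts, between-tissue
#' evolutionary correlations, per-tissue phylogenetic signal (lambda) and
#' deviation scales. Slopes follow the allometric structure seen in anuran
#' tissue data: shallow brain scaling (0.49), steeper fat and limb-muscle
#' scaling, near-isometry elsewhere.
#'
#' @return A list configuration understood by [simulate_traits()].
#' @export
default_trait_config <- function() {
  tissues <- c("brain", "fat", "testes", "hindlimb", "digestive", "other")
  k <- length(tissues)
  Sigma <- diag(k) * 0.04
  dimnames(Sigma) <- list(tissues, tissues)
  # mild inter-tissue correlations in the residual (non-allometric) part
  Sigma["brain", "fat"] <- Sigma["fat", "brain"] <- -0.012
  Sigma["brain", "testes"] <- Sigma["testes", "brain"] <- -0.012
  Sigma["testes", "hindlimb"] <- Sigma["hindlimb", "testes"] <- -0.012
  Sigma["fat", "digestive"] <- Sigma["digestive", "fat"] <- 0.016
  list(
    tissues = tissues,
    slopes = c(brain = 0.49, fat = 1.10, testes = 1.00, hindlimb = 1.03,
               digestive = 1.00, other = 1.00),
    intercepts = c(brain = -4.4, fat = -3.2, testes = -4.8,
                   hindlimb = -2.2, digestive = -2.6, other = -0.35),
    Sigma = Sigma,
    lambda = c(brain = 0.9, fat = 0.5, testes = 0.8, hindlimb = 0.5,
               digestive = 0.7, other = 0.8),
    svl_log_mean = log(45),   # mm
    svl_log_sd = 0.45
  )
}

#' Simulate species trait data on a phylogeny
#'
#' Log SVL evolves as Brownian motion on the (ultrametric) tree; each log
#' tissue mass is `intercept + slope * log(SVL^3)` plus a correlated
#' deviation with per-tissue phylogenetic signal: the deviation is
#' `sqrt(lambda) * (BM component) + sqrt(1 - lambda) * (iid component)`,
#' both sharing the configured between-tissue covariance. Masses are
#' returned on the natural scale (grams), strictly positive by
#' construction.
#'
#' @param tree Phylogeny (ultrametric, e.g. from [simulate_tree()]).
#' @param config List as from [default_trait_config()].
#' @param seed Seed.
#' @return Data frame: `species`, `svl`, one mass column per tissue, and
#'   `body_mass` (sum of tissue masses).
#' @export
simulate_traits <- function(tree, config = default_trait_config(), seed) {
  set.seed(seed)
  n <- length(tree$tip.label)
  V <- ape::vcv.phylo(tree)
  h <- max(diag(V))
  Vu <- V / h  # unit-height scaling so lambda mixing preserves variance
  Lv <- chol(Vu)
  tissues <- config$tissues
  k <- length(tissues)
  Ls <- chol(config$Sigma)
  log_svl <- config$svl_log_mean +
    config$svl_log_sd * as.numeric(crossprod(Lv, stats::rnorm(n)))
  B <- crossprod(Lv, matrix(stats::rnorm(n * k), n, k)) %*% Ls
  Wn <- matrix(stats::rnorm(n * k), n, k) %*% Ls
  lam <- config$lambda[tissues]
  dev <- sweep(B, 2, sqrt(lam), "*") + sweep(Wn, 2, sqrt(1 - lam), "*")
  log_mass <- matrix(NA_real_, n, k, dimnames = list(rownames(V), tissues))
  for (j in seq_len(k)) {
    tj <- tissues[j]
    log_mass[, j] <- config$intercepts[tj] +
      config$slopes[tj] * 3 * log_svl + dev[, j]
  }
  out <- data.frame(species = rownames(V), svl = exp(log_svl),
                    exp(log_mass))
  out$body_mass <- rowSums(out[, tissues])
  rownames(out) <- NULL
  out[match(tree$tip.label, out$species), , drop = FALSE]
}

#' Simulate daily temperature series
#'
#' Daily mean temperature = annual mean + amplitude * sin(2 pi doy/n +
#' phase) + AR(1) noise. The default phase puts the coldest day at the
#' turn of the year (northern-hemisphere winter). With `noise_sd = 0` the
#' threshold-crossing days follow closed-form arcsine arithmetic, which the
#' tests exploit.
#'
#' @param site_id Site label.
#' @param years Integer vector of calendar years (default 2012-2016, the
#'   study window).
#' @param mean_temp Annual mean (deg C).
#' @param amplitude Seasonal amplitude (deg C).
#' @param noise_sd Marginal standard deviation of the AR(1) noise.
#' @param ar1 AR(1) coefficient (default 0.7; autocorrelated cold spells
#'   exercise the 5-day persistence rule realistically).
#' @param phase Phase shift (radians).
#' @param seed Seed.
#' @return Data frame `site`, `date`, `temp_c`.
#' @export
simulate_temperatures <- function(site_id = "site1", years = 2012:2016,
                                  mean_temp = 12, amplitude = 12,
                                  noise_sd = 2, ar1 = 0.7,
                                  phase = -pi / 2, seed) {
  set.seed(seed)
  out <- lapply(years, function(y) {
    nd <- days_in_year(y)
    doy <- seq_len(nd)
    base <- mean_temp + amplitude * sin(2 * pi * (doy - 1) / nd + phase)
    eps <- numeric(nd)
    if (noise_sd > 0) {
      innov_sd <- noise_sd * sqrt(1 - ar1^2)
      eps[1] <- stats::rnorm(1, 0, noise_sd)
      for (i in 2:nd) eps[i] <- ar1 * eps[i - 1] + stats::rnorm(1, 0, innov_sd)
    }
    data.frame(site = site_id,
               date = seq(as.Date(sprintf("%d-01-01", y)), by = "day",
                          length.out = nd),
               temp_c = base + eps)
  })
  do.call(rbind, out)
}

#' Simulate two binary traits under a Pagel model
#'
#' Simulates the joint 4-state continuous-time Markov chain from the root
#' (flat root state) to the tips and returns the two marginal 0/1 traits.
#'
#' @param tree Phylogeny.
#' @param model Model label (see [pagel_rate_matrix()]).
#' @param rates Rate vector for the model.
#' @param seed Seed.
#' @return List with named 0/1 vectors `x` and `y`.
#' @export
simulate_binary_pair <- function(tree, model, rates, seed) {
  Q <- pagel_rate_matrix(model, rates)
  set.seed(seed)
  ntip <- length(tree$tip.label)
  tre <- ape::reorder.phylo(tree, "postorder")
  edges <- tre$edge[rev(seq_len(nrow(tre$edge))), , drop = FALSE]  # preorder
  lens <- rev(tre$edge.length)
  Ps <- edge_transition_probs(Q, lens)
  state <- integer(ntip + tre$Nnode)
  state[ntip + 1L] <- sample.int(4, 1)
  for (e in seq_len(nrow(edges))) {
    par <- edges[e, 1]; child <- edges[e, 2]
    p <- Ps[[e]][state[par], ]
    state[child] <- sample.int(4, 1, prob = pmax(p, 0))
  }
  tip_state <- state[seq_len(ntip)]
  x <- as.integer(tip_state >= 3)          # states 10, 11
  y <- as.integer(tip_state %in% c(2, 4))  # states 01, 11
  list(x = stats::setNames(x, tre$tip.label),
       y = stats::setNames(y, tre$tip.label))
}

#' Simulate a full study dataset at the design's scale
#'
#' Bundles every input the pipeline consumes, mirroring the nesting of the
#' study design: 116 species with trait data, 50 of them with paired
#' pre-brumation measurements, 43 with breeding metadata, 30 flagged as
#' field-validated for their activity thresholds, and 5 years of daily
#' temperatures per site over a latitudinal gradient of sites.
#'
#' @param seed Seed driving every generator.
#' @param n_taxa,n_prepost,n_breeding,n_field Subset sizes.
#' @param years Calendar years for the temperature series.
#' @param n_sites Number of climate sites spread over the gradient.
#' @return A list: `tree`, `traits`, `prepost`, `breeding`, `thresholds`,
#'   `temperatures` (list of per-site series), `climate` (monthly normals),
#'   `sites` (per-species site assignment and geography).
#' @export
simulate_study <- function(seed = 1, n_taxa = 116, n_prepost = 50,
                           n_breeding = 43, n_field = 30,
                           years = 2012:2016, n_sites = 12) {
  tree <- simulate_tree(n_taxa, birth_rate = 1, seed = seed)
  traits <- simulate_traits(tree, seed = seed + 1)
  set.seed(seed + 2)
  sp <- tree$tip.label

  # geography: sites along a latitude/elevation gradient
  lat <- seq(18, 45, length.out = n_sites) + stats::rnorm(n_sites, 0, 0.5)
  elev <- stats::runif(n_sites, 200, 2500)
  site_mean <- 24 - 0.45 * lat - 0.004 * elev + stats::rnorm(n_sites, 0, 0.8)
  # keep annual means positive (subtropical/montane sites) so the
  # temperature CV stays well-defined
  site_mean <- pmax(site_mean, 2)
  site_amp <- 4 + 0.35 * lat + stats::rnorm(n_sites, 0, 0.8)
  site_of <- sample.int(n_sites, n_taxa, replace = TRUE)
  sites <- data.frame(site = sprintf("site%02d", seq_len(n_sites)),
                      latitude = lat, elevation = elev,
                      mean_temp = site_mean, amplitude = site_amp)

  temperatures <- lapply(seq_len(n_sites), function(i) {
    simulate_temperatures(sites$site[i], years = years,
                          mean_temp = site_mean[i], amplitude = site_amp[i],
                          noise_sd = 2, ar1 = 0.7, seed = seed + 10 + i)
  })
  names(temperatures) <- sites$site

  # monthly climate normals per site
  climate <- do.call(rbind, lapply(seq_len(n_sites), function(i) {
    doym <- cumsum(c(15, rep(30.4, 11)))
    tm <- site_mean[i] + site_amp[i] * sin(2 * pi * (doym - 1) / 365 - pi / 2)
    pr <- pmax(5, 80 + 60 * sin(2 * pi * (doym - 100) / 365) +
                 stats::rnorm(12, 0, 10) - 1.2 * lat[i])
    data.frame(site = sites$site[i], month = 1:12, temp_c = tm,
               precip_mm = pr)
  }))

  # activity thresholds: colder-adapted species where brumation is long
  thr <- 8 + 0.12 * (lat[site_of] - 30) + stats::rnorm(n_taxa, 0, 0.8)
  thresholds <- data.frame(
    species = sp, site = sites$site[site_of],
    entry_c = thr, emergence_c = thr + stats::rnorm(n_taxa, 0.3, 0.2),
    field_validated = sp %in% sample(sp, n_field)
  )

  # paired pre-brumation masses for a subset: fat depleted, testes regrown
  idx_pp <- sort(sample.int(n_taxa, n_prepost))
  pp <- traits[idx_pp, ]
  prepost <- data.frame(
    species = pp$species,
    fat_pre = pp$fat * exp(stats::rnorm(n_prepost, 0.69, 0.25)),
    fat_post = pp$fat,
    testes_pre = pp$testes * exp(stats::rnorm(n_prepost, -0.69, 0.25)),
    testes_post = pp$testes,
    brain_pre = pp$brain * exp(stats::rnorm(n_prepost, -0.05, 0.1)),
    brain_post = pp$brain
  )

  # breeding metadata: season shortens with latitude; aggregation more
  # likely when the season is short
  idx_br <- sort(sample.int(n_taxa, n_breeding))
  season <- pmax(7, 150 - 2.8 * lat[site_of[idx_br]] +
                   stats::rnorm(n_breeding, 0, 12))
  p_agg <- stats::plogis(2.2 - 0.06 * season)
  breeding <- data.frame(
    species = sp[idx_br],
    season_days = season,
    aggregation = stats::rbinom(n_breeding, 1, p_agg)
  )

  list(tree = tree, traits = traits, prepost = prepost,
       breeding = breeding, thresholds = thresholds,
       temperatures = temperatures, climate = climate,
       sites = sites, species_sites = data.frame(
         species = sp, site = sites$site[site_of],
         latitude = lat[site_of], elevation = elev[site_of]))
}

#' Write a simulated study to CSV/Newick files
#'
#' Emits the same plain-text formats the analysis functions consume:
#' `tree.nwk`, `traits.csv`, `prepost.csv`, `breeding.csv`,
#' `thresholds.csv`, `temperatures.csv` (long format), `climate.csv`,
#' `species_sites.csv`.
#'
#' @param study List from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    tree = file.path(dir, "tree.nwk"),
    traits = file.path(dir, "traits.csv"),
    prepost = file.path(dir, "prepost.csv"),
    breeding = file.path(dir, "breeding.csv"),
    thresholds = file.path(dir, "thresholds.csv"),
    temperatures = file.path(dir, "temperatures.csv"),
    climate = file.path(dir, "climate.csv"),
    species_sites = file.path(dir, "species_sites.csv")
  )
  writeLines(write_newick(study$tree), paths["tree"])
  utils::write.csv(study$traits, paths["traits"], row.names = FALSE)
  utils::write.csv(study$prepost, paths["prepost"], row.names = FALSE)
  utils::write.csv(study$breeding, paths["breeding"], row.names = FALSE)
  utils::write.csv(study$thresholds, paths["thresholds"], row.names = FALSE)
  utils::write.csv(do.call(rbind, study$temperatures),
                   paths["temperatures"], row.names = FALSE)
  utils::write.csv(study$climate, paths["climate"], row.names = FALSE)
  utils::write.csv(study$species_sites, paths["species_sites"],
                   row.names = FALSE)
  invisible(paths)
}
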