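#' Repeatability (intraclass correlation) of repeated measures
#'
#' Gaussian one-way random-effects repeatability
#' `R = sigma2_between / (sigma2_between + sigma2_within)`, with variance
#' components estimated by REML ([lme4::lmer()]) and a parametric-bootstrap
#' percentile confidence interval (simulate from the fitted model, refit).
#' Used for the year-to-year consistency of the species-specific brumation
#' estimates.
#'
#' @param values Numeric measurements.
#' @param groups Grouping factor (e.g. species) aligned with `values`.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Seed for the bootstrap.
#' @return A `repeatability_result` with `R`, `ci`, `n_groups`,
#'   `sigma2_between`, `sigma2_within`.
#' @export
repeatability <- function(values, groups, n_boot = 1000, seed = NULL) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (max(table(groups)) < 2) {
    stop("all groups are singletons: within-group variance undefined")
  }
  dat <- data.frame(v = as.numeric(values), g = groups)
  fit <- lme4::lmer(v ~ 1 + (1 | g), data = dat, REML = TRUE)
  comp <- function(f) {
    vc <- as.data.frame(lme4::VarCorr(f))
    sb <- vc$vcov[vc$grp == "g"]
    sw <- vc$vcov[vc$grp == "Residual"]
    c(sb = sb, sw = sw, R = sb / (sb + sw))
  }
  est <- comp(fit)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    sims <- stats::simulate(fit, nsim = n_boot)
    Rb <- vapply(seq_len(n_boot), function(b) {
      fb <- suppressMessages(suppressWarnings(lme4::refit(fit, sims[[b]])))
      unname(comp(fb)["R"])
    }, numeric(1))
    ci <- stats::quantile(Rb, c(0.025, 0.975), names = FALSE)
  }
  structure(list(R = unname(est["R"]), ci = ci,
                 n_groups = nlevels(groups),
                 sigma2_between = unname(est["sb"]),
                 sigma2_within = unname(est["sw"]),
                 n_boot = n_boot),
            class = "repeatability_result")
}

#' @export
print.repeatability_result <- function(x, ...) {
  cat("Repeatability R =", round(x$R, 3))
  if (!anyNA(x$ci)) cat(" [", paste(round(x$ci, 3), collapse = ", "), "]")
  cat(" over", x$n_groups, "groups\n")
  invisible(x)
}

#' Symmetric percent change between paired pre/post measurements
#'
#' Per species, `100 * log(post / pre)` (natural logarithm), which is
#' symmetric (halving and doubling have equal magnitude, opposite sign) and
#' additive across multiplicative stages. The group summary is the mean
#' with a t-interval over the species values; the back-transformed ratio
#' `exp(mean/100)` is reported alongside.
#'
#' @param pre,post Positive paired measurements.
#' @param conf Confidence level for the group mean (default 0.95).
#' @return A `percent_change` object with `delta` (per species), `mean`,
#'   `ci` and `ratio`.
#' @export
percent_change <- function(pre, post, conf = 0.95) {
  if (any(pre <= 0) || any(post <= 0)) {
    stop("pre and post masses must be strictly positive")
  }
  if (length(pre) != length(post)) stop("pre and post must be paired")
  delta <- 100 * log(post / pre)
  m <- mean(delta)
  n <- length(delta)
  ci <- c(NA_real_, NA_real_)
  if (n > 1 && stats::sd(delta) > 0) {
    se <- stats::sd(delta) / sqrt(n)
    q <- stats::qt(1 - (1 - conf) / 2, n - 1)
    ci <- c(m - q * se, m + q * se)
  } else if (n > 1) {
    ci <- c(m, m)
  }
  structure(list(delta = delta, mean = m, ci = ci,
                 ratio = exp(m / 100), n = n),
            class = "percent_change")
}

#' @export
print.percent_change <- function(x, ...) {
  cat("Mean change:", round(x$mean, 2), "log-points")
  if (!anyNA(x$ci)) cat(" [", paste(round(x$ci, 2), collapse = ", "), "]")
  cat(" (ratio ", round(x$ratio, 3), ", n = ", x$n, ")\n", sep = "")
  invisible(x)
}
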