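# Group comparison and effect sizes: Cohen's d, Cramer's V with
# interpretation bands, Monte-Carlo chi-squared on fixed margins,
# donor-level permutation tests, Bonferroni correction.

#' Effect-size interpretation band
#'
#' Bands follow the conventional cut-offs: Cohen's d (absolute value)
#' 0.2 / 0.5 / 0.8 and Cramer's V 0.1 / 0.3 / 0.5 for small / medium /
#' large; boundary values map to the larger band.
#'
#' @param value effect-size value.
#' @param kind `"cohens_d"` or `"cramers_v"`.
#' @return one of `"negligible"`, `"small"`, `"medium"`, `"large"`.
#' @export
effect_size_band <- function(value, kind = c("cohens_d", "cramers_v")) {
  kind <- match.arg(kind)
  cuts <- switch(kind, cohens_d = c(0.2, 0.5, 0.8),
                 cramers_v = c(0.1, 0.3, 0.5))
  v <- abs(value)
  c("negligible", "small", "medium", "large")[findInterval(v, cuts) + 1L]
}

#' Cohen's d
#'
#' `d = (mean(x) - mean(y)) / s_pooled` with the (n-1)-weighted pooled
#' standard deviation. Anti-symmetric in its arguments.
#'
#' @param x,y numeric samples (each n >= 2).
#' @return `effect_size`: `kind`, `value`, `band`.
#' @export
cohens_d <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stopf("both groups need n >= 2")
  sp2 <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
    (length(x) + length(y) - 2)
  if (sp2 <= 0) stopf("pooled SD is zero; Cohen's d undefined")
  d <- (mean(x) - mean(y)) / sqrt(sp2)
  structure(list(kind = "cohens_d", value = d,
                 band = effect_size_band(d, "cohens_d")),
            class = "effect_size")
}

#' Cramer's V
#'
#' `V = sqrt(chi2 / (n * (min(r, c) - 1)))` with the Pearson chi-squared
#' statistic (no continuity correction). Rows/columns with zero
#' marginals are dropped with a warning.
#'
#' @param tab r x c contingency table of counts (>= 2 rows and columns
#'   after dropping empty margins).
#' @return `effect_size`: `kind`, `value` in `[0, 1]`, `band`.
#' @export
cramers_v <- function(tab) {
  tab <- as.matrix(tab)
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) {
    warnf("dropping %d empty row(s)/column(s) from the table",
          sum(rs == 0) + sum(cs == 0))
    tab <- tab[rs > 0, cs > 0, drop = FALSE]
  }
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stopf("need >= 2 rows and columns with nonzero marginals")
  n <- sum(tab)
  if (n < 1) stopf("table total must be >= 1")
  chi2 <- suppressWarnings(
    unname(chisq.test(tab, correct = FALSE)$statistic))
  v <- sqrt(chi2 / (n * (min(dim(tab)) - 1)))
  structure(list(kind = "cramers_v", value = v,
                 band = effect_size_band(v, "cramers_v"),
                 chi2 = chi2, n = n),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("<effect_size> %s = %.4f (%s)\n", x$kind, x$value, x$band))
  invisible(x)
}

#' Monte-Carlo chi-squared test with fixed margins
#'
#' Simulates `n_sims` tables under independence conditional on the
#' observed margins (multivariate hypergeometric draws via
#' [stats::r2dtable()]), computes the Pearson chi-squared statistic of
#' each, and reports the add-one p-value
#' `p = (1 + #{chi2_sim >= chi2_obs}) / (n_sims + 1)` - never 0, with
#' floor `1 / (n_sims + 1)`.
#'
#' @param tab contingency table of counts.
#' @param n_sims number of simulated tables (>= 999).
#' @param seed RNG seed.
#' @return `perm_result`: observed statistic, p, `n_sims`, `seed`,
#'   `degenerate` flag.
#' @export
monte_carlo_chi2 <- function(tab, n_sims = 9999, seed = 1) {
  if (n_sims < 999) stopf("n_sims must be >= 999")
  tab <- as.matrix(tab)
  if (sum(tab > 0) <= 1L)
    return(structure(list(observed = 0, p = 1, n_sims = n_sims, seed = seed,
                          degenerate = TRUE), class = "perm_result"))
  rs <- rowSums(tab); cs <- colSums(tab)
  tab <- tab[rs > 0, cs > 0, drop = FALSE]
  rs <- rowSums(tab); cs <- colSums(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    return(structure(list(observed = 0, p = 1, n_sims = n_sims, seed = seed,
                          degenerate = TRUE), class = "perm_result"))
  ex <- outer(rs, cs) / sum(tab)
  chi2 <- function(m) sum((m - ex)^2 / ex)
  obs <- chi2(tab)
  set.seed(seed)
  sims <- r2dtable(n_sims, rs, cs)
  stat <- vapply(sims, chi2, 0)
  p <- (1 + sum(stat >= obs - 1e-12)) / (n_sims + 1)
  structure(list(observed = obs, p = p, n_sims = n_sims, seed = seed,
                 degenerate = FALSE), class = "perm_result")
}

#' Donor-level permutation test of a group difference
#'
#' The statistic is the difference of group means of per-donor values
#' (donor as the exchangeable unit, respecting the donor hierarchy
#' without covariate modelling); group labels are permuted over donors
#' and the two-sided add-one p-value reported,
#' `p = (1 + #{|T_perm| >= |T_obs|}) / (n_perm + 1)`.
#'
#' @param values per-donor statistic (one value per donor).
#' @param groups two-level group label per donor.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return `perm_result`: observed mean difference (first level minus
#'   second), p, `n_perm`, `seed`.
#' @export
donor_permutation_test <- function(values, groups, n_perm = 9999, seed = 1) {
  g <- factor(groups)
  if (nlevels(g) != 2L) stopf("exactly two groups required")
  nA <- sum(g == levels(g)[1]); nB <- sum(g == levels(g)[2])
  if (nA == 0L || nB == 0L) stopf("a group is empty")
  if (min(nA, nB) < 3L)
    warnf("fewer than 3 donors in a group; permutation p is coarse")
  v <- as.numeric(values)
  n <- length(v)
  tot <- sum(v)
  obs <- sum(v[g == levels(g)[1]]) / nA - sum(v[g == levels(g)[2]]) / nB
  set.seed(seed)
  stat <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    sA <- sum(v[sample.int(n, nA)])
    stat[b] <- sA / nA - (tot - sA) / nB
  }
  p <- (1 + sum(abs(stat) >= abs(obs) - 1e-12)) / (n_perm + 1)
  structure(list(observed = obs, p = p, n_perm = n_perm, seed = seed,
                 groups = levels(g)), class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("<perm_result> statistic = %.4f, p = %.4g (%d draws, seed %d)\n",
              x$observed, x$p, x$n_perm %||% x$n_sims, x$seed))
  invisible(x)
}

#' Bonferroni correction
#'
#' Adjusted p = min(1, m * p); decisions at `alpha` on the adjusted
#' values. Adjusted p is never below the raw p.
#'
#' @param p_values nonempty numeric vector of raw p-values.
#' @param alpha significance threshold (default 0.05).
#' @return data frame: `p_raw`, `p_adjusted`, `reject`.
#' @export
bonferroni <- function(p_values, alpha = 0.05) {
  if (!length(p_values)) stopf("p_values must be nonempty")
  adj <- pmin(1, length(p_values) * p_values)
  data.frame(p_raw = p_values, p_adjusted = adj, reject = adj < alpha)
}
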