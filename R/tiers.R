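# VDAC1-normalised OXPHOS expression ratios on beta cells, k-means
# tiering with elbow selection, ANOVA validation, donor tier profiles.

#' Compute VDAC1-normalised OXPHOS ratios
#'
#' One ratio record per insulin-threshold-positive cell of a
#' mitochondrial-panel cell table (OXPHOS quantification is restricted
#' to beta cells); the ratio is the marker mean intensity divided by the
#' VDAC1 mean intensity (mitochondrial-mass normalisation). Cells that
#' are not INS-positive, or whose VDAC1 signal is at or below the noise
#' floor, are excluded and logged with a reason in
#' `attr(result, "excluded")`.
#'
#' @param typed_cells mitochondrial-panel cell table carrying `pos_INS`
#'   (from [classify_cells()] with `channels = "INS"`).
#' @param marker `"NDUFB8"` or `"MTCO1"`.
#' @param vdac_floor VDAC1 noise floor; cells with `mean_VDAC1 <=
#'   vdac_floor` are excluded (default 0, excluding only zero signal).
#' @return `ratio_records` data frame: donor_id, islet_id, cell_id,
#'   marker, raw marker and VDAC1 intensities, and `ratio` (> 0).
#' @export
compute_ratios <- function(typed_cells, marker, vdac_floor = 0) {
  mcol <- paste0("mean_", marker)
  if (!"mean_VDAC1" %in% names(typed_cells))
    stopf("VDAC1 channel absent from cell table")
  if (!mcol %in% names(typed_cells))
    stopf("marker channel %s absent from cell table", marker)
  if (!"pos_INS" %in% names(typed_cells))
    stopf("cell table lacks pos_INS; run classify_cells() first")
  reason <- rep(NA_character_, nrow(typed_cells))
  reason[!typed_cells$pos_INS] <- "not INS-positive"
  reason[typed_cells$pos_INS & typed_cells$mean_VDAC1 <= vdac_floor] <-
    "VDAC1 at or below noise floor"
  keep <- is.na(reason)
  out <- data.frame(donor_id = typed_cells$donor_id[keep],
                    islet_id = typed_cells$islet_id[keep],
                    cell_id = typed_cells$cell_id[keep],
                    marker = marker,
                    marker_intensity = typed_cells[[mcol]][keep],
                    vdac1_intensity = typed_cells$mean_VDAC1[keep],
                    stringsAsFactors = FALSE)
  out$ratio <- out$marker_intensity / out$vdac1_intensity
  excluded <- data.frame(donor_id = typed_cells$donor_id[!keep],
                         islet_id = typed_cells$islet_id[!keep],
                         cell_id = typed_cells$cell_id[!keep],
                         reason = reason[!keep], stringsAsFactors = FALSE)
  structure(out, excluded = excluded,
            class = c("ratio_records", "data.frame"))
}

# k-means++ initial centres (D^2-weighted sampling) for an n x p matrix.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  if (k == 1L) return(centers)
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in 2:k) {
    pick <- if (all(d2 == 0)) sample.int(n, 1) else
      sample.int(n, 1, prob = d2)
    centers[j, ] <- x[pick, ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  centers
}

tier_names <- function(k) {
  if (k == 1L) "all"
  else if (k == 2L) c("low", "high")
  else if (k == 3L) c("low", "medium", "high")
  else sprintf("tier%02d", seq_len(k))
}

#' Fit expression tiers by k-means with elbow selection
#'
#' Runs k-means (k-means++ initialisation, `n_restarts` restarts, best
#' within-cluster sum of squares kept) for k = 1..`k_max` on the pooled
#' 1-D ratio values of all beta cells across all donors and islets. The
#' cluster count is chosen by the elbow rule - the k maximising the
#' discrete second difference of the WCSS curve over k = 2..k_max-1 - an
#' objective stand-in for a visual elbow plot, and tiers are named by
#' ascending centre (low / medium / high for k = 3). Optionally,
#' standardised covariates can be appended to the clustering feature
#' (non-default).
#'
#' @param ratios a [compute_ratios()] result (or numeric vector).
#' @param k_max largest k scanned (default 8).
#' @param n_restarts k-means restarts per k (default 10).
#' @param seed RNG seed; fitting is deterministic given the seed.
#' @param k fixed cluster count, bypassing elbow selection (`NULL` =
#'   elbow rule).
#' @param covariates optional numeric data frame (one row per cell)
#'   appended, standardised, to the clustering feature.
#' @return `tier_model`: marker, chosen `k`, ascending `centers`,
#'   `wcss_curve` (k = 1..k_max, non-increasing), per-cell `tier` factor,
#'   `seed`, `n_restarts`.
#' @export
fit_tiers <- function(ratios, k_max = 8, n_restarts = 10, seed = 1,
                      k = NULL, covariates = NULL) {
  r <- if (is.data.frame(ratios)) ratios$ratio else as.numeric(ratios)
  marker <- if (is.data.frame(ratios) && nrow(ratios))
    ratios$marker[1] else NA_character_
  x <- matrix(r, ncol = 1)
  if (!is.null(covariates)) {
    cv <- scale(as.matrix(covariates))
    x <- cbind(scale(x), cv)
  }
  k_scan <- max(k_max, k %||% 1L)
  if (length(unique(r)) < k_scan)
    stopf("need at least %d distinct ratio values (got %d)",
          k_scan, length(unique(r)))
  set.seed(seed)
  fits <- vector("list", k_scan)
  wcss <- numeric(k_scan)
  for (kk in seq_len(k_scan)) {
    if (kk == 1L) {
      # closed form: WCSS(1) is the total sum of squares about the mean
      ctr <- matrix(colMeans(x), 1)
      fits[[1L]] <- list(cluster = rep(1L, nrow(x)), centers = ctr,
                         tot.withinss = sum(sweep(x, 2, ctr)^2))
      wcss[1L] <- fits[[1L]]$tot.withinss
      next
    }
    best <- NULL
    for (rs in seq_len(max(1L, n_restarts))) {
      init <- kmeanspp_centers(x, kk)
      fit <- suppressWarnings(kmeans(x, centers = init, iter.max = 100,
                                     algorithm = "Lloyd"))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    fits[[kk]] <- best
    wcss[kk] <- best$tot.withinss
  }
  wcss <- cummin(wcss)   # guard tiny non-monotonicity from local optima
  k_sel <- if (!is.null(k)) as.integer(k) else elbow_k(wcss)
  fit <- fits[[k_sel]]
  centers_ratio <- tapply(r, fit$cluster, mean)  # centres on the ratio scale
  ord <- order(centers_ratio)
  rank_of <- integer(k_sel); rank_of[ord] <- seq_len(k_sel)
  tier <- factor(tier_names(k_sel)[rank_of[fit$cluster]],
                 levels = tier_names(k_sel))
  structure(list(marker = marker, k = k_sel,
                 centers = as.numeric(centers_ratio[ord]),
                 wcss_curve = wcss, tier = tier,
                 sizes = as.integer(table(tier)),
                 seed = seed, n_restarts = n_restarts,
                 used_covariates = !is.null(covariates)),
            class = "tier_model")
}

#' Elbow rule on the WCSS curve
#'
#' Selects the k maximising the discrete second difference of
#' `log(WCSS)` over k = 2..k_max-1, i.e. the point of maximum curvature
#' of the log-scale elbow profile. Working on the log scale makes the
#' rule sensitive to the *relative* flattening of successive drops: the
#' raw-scale second difference is dominated by the always-large k = 1 to
#' 2 drop and peaks at k = 2 even for perfectly separated three-cluster
#' data, so it cannot act as an objective elbow.
#'
#' @param wcss within-cluster sum of squares for k = 1..k_max.
#' @return selected k.
#' @export
elbow_k <- function(wcss) {
  k_max <- length(wcss)
  if (k_max < 3L) return(k_max)
  lw <- log(pmax(wcss, max(wcss) * 1e-12))
  ks <- 2:(k_max - 1L)
  d2 <- lw[ks - 1L] - 2 * lw[ks] + lw[ks + 1L]
  ks[which.max(d2)]
}

#' @export
print.tier_model <- function(x, ...) {
  cat(sprintf("<tier_model> marker=%s k=%d centers=(%s) n=%d\n",
              x$marker, x$k, paste(sprintf("%.3f", x$centers), collapse = ", "),
              length(x$tier)))
  invisible(x)
}

#' Validate tiers by one-way ANOVA
#'
#' One-way ANOVA of the ratio values by tier label, computed from the
#' definitional sums of squares. A zero within-tier sum of squares gives
#' an infinite F, flagged `degenerate`.
#'
#' @param model a [fit_tiers()] result (k >= 2).
#' @param ratios the ratios the model was fitted on.
#' @return list: `F`, `p`, `df1`, `df2`, `ss_between`, `ss_within`,
#'   `degenerate`.
#' @export
validate_tiers_anova <- function(model, ratios) {
  r <- if (is.data.frame(ratios)) ratios$ratio else as.numeric(ratios)
  g <- model$tier
  if (model$k < 2L) stopf("ANOVA validation needs k >= 2")
  if (any(table(g) == 0L)) stopf("empty tier; cannot run ANOVA")
  gm <- tapply(r, g, mean)
  n_g <- tapply(r, g, length)
  ss_between <- sum(n_g * (gm - mean(r))^2)
  ss_within <- sum((r - gm[g])^2)
  df1 <- model$k - 1L
  df2 <- length(r) - model$k
  if (ss_within <= .Machine$double.eps * sum(r^2)) {
    return(list(F = Inf, p = 0, df1 = df1, df2 = df2,
                ss_between = ss_between, ss_within = ss_within,
                degenerate = TRUE))
  }
  Fstat <- (ss_between / df1) / (ss_within / df2)
  list(F = Fstat, p = pf(Fstat, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2, ss_between = ss_between,
       ss_within = ss_within, degenerate = FALSE)
}

#' Donor-level tier profiles
#'
#' Per-donor tier cell counts and proportions of that donor's beta
#' cells (proportions sum to 1 per donor), plus group-level pooled
#' proportions when a cohort manifest (or donor->group table) is given.
#'
#' @param model a [fit_tiers()] result.
#' @param ratios the ratios the model was fitted on (provides donor ids).
#' @param manifest cohort manifest from [generate_cohort()], or a data
#'   frame with `donor_id` and `group` columns (`NULL` = no groups).
#' @return list: `donors` (donor_id, group, per-tier count and
#'   proportion columns), `groups` (pooled), `tier_levels`.
#' @export
donor_tier_profiles <- function(model, ratios, manifest = NULL) {
  stopifnot(is.data.frame(ratios))
  lv <- levels(model$tier)
  groups_tab <- if (is.null(manifest)) NULL else
    if (is.data.frame(manifest)) manifest else manifest$donors
  tab <- table(ratios$donor_id, model$tier)
  donors <- data.frame(donor_id = rownames(tab), stringsAsFactors = FALSE)
  if (!is.null(groups_tab)) {
    miss <- setdiff(donors$donor_id, groups_tab$donor_id)
    if (length(miss))
      stopf("donor(s) missing from manifest: %s", paste(miss, collapse = ", "))
    donors$group <- groups_tab$group[match(donors$donor_id,
                                           groups_tab$donor_id)]
  }
  for (l in lv) donors[[paste0("n_", l)]] <- as.integer(tab[, l])
  tot <- rowSums(tab)
  for (l in lv) donors[[paste0("prop_", l)]] <- tab[, l] / tot
  donors$n_cells <- as.integer(tot)
  groups <- NULL
  if (!is.null(groups_tab)) {
    gt <- rowsum(as.matrix(as.data.frame.matrix(tab)), donors$group)
    groups <- data.frame(group = rownames(gt), stringsAsFactors = FALSE)
    for (l in lv) groups[[paste0("n_", l)]] <- as.integer(gt[, l])
    gtot <- rowSums(gt)
    for (l in lv) groups[[paste0("prop_", l)]] <- gt[, l] / gtot
    groups$n_cells <- as.integer(gtot)
  }
  list(donors = donors, groups = groups, tier_levels = lv)
}
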