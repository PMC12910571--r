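# Donor-adaptive thresholding, cell typing, islet eligibility,
# composition and contact-architecture statistics with a jumbled-islet
# permutation null.

#' Donor-adaptive intensity thresholds
#'
#' For each donor, the positivity threshold of a channel is
#' `max(mean, median) + k * scale` of that donor's per-cell mean
#' intensities. The robust scale is, by default, 1.4826 times the median
#' absolute deviation of the sub-median (background) cells - a
#' background-noise estimate that stays finite-and-small for strongly
#' bimodal stains, where the full-distribution MAD would absorb the
#' between-mode gap (`scale_method = "mad"` restores the classical
#' full-distribution MAD). Thresholds are scale-equivariant: multiplying
#' all intensities by c multiplies the threshold by c.
#'
#' @param cell_table cell table with `mean_<channel>` columns.
#' @param channel channel name (e.g. `"INS"`).
#' @param k unitless multiplier of the robust scale (default 1).
#' @param scale_method `"lower_mad"` (default) or `"mad"`.
#' @return `threshold_spec` data frame: one row per donor with n_cells,
#'   mean, median, scale, k and the resulting threshold `value`
#'   (recomputable from the stored summaries; always `>= max(mean,
#'   median)`).
#' @export
compute_thresholds <- function(cell_table, channel, k = 1,
                               scale_method = c("lower_mad", "mad")) {
  scale_method <- match.arg(scale_method)
  col <- paste0("mean_", channel)
  if (!col %in% names(cell_table)) stopf("cell table lacks column %s", col)
  if (!nrow(cell_table)) stopf("empty cell table: no donors to threshold")
  out <- lapply(split(cell_table[[col]], cell_table$donor_id), function(x) {
    if (!length(x)) stopf("donor with no cells")
    if (length(x) < 20L)
      warnf("donor has only %d cells (< 20); threshold computed anyway",
            length(x))
    m <- mean(x); md <- median(x)
    sc <- switch(scale_method,
                 lower_mad = {
                   lo <- x[x <= md]
                   1.4826 * median(abs(lo - median(lo)))
                 },
                 mad = mad(x))
    c(n_cells = length(x), mean = m, median = md, scale = sc)
  })
  res <- data.frame(donor_id = names(out), channel = channel,
                    do.call(rbind, out), k = k, stringsAsFactors = FALSE)
  res$value <- pmax(res$mean, res$median) + k * res$scale
  rownames(res) <- NULL
  class(res) <- c("threshold_spec", "data.frame")
  res
}

threshold_lookup <- function(thresholds, donor, channel) {
  i <- which(thresholds$donor_id == donor & thresholds$channel == channel)
  if (!length(i))
    stopf("no threshold for donor '%s', channel '%s'", donor, channel)
  thresholds$value[i[1]]
}

#' Classify cells by marker positivity
#'
#' Positivity is strict: mean intensity > the donor's threshold. When
#' both INS and GCG thresholds are supplied, cells are typed as
#' `bihormonal` (INS+ and GCG+ within the same membrane-defined cell
#' boundary), `beta` (INS+ only), `alpha` (GCG+ only) or `other`;
#' otherwise only the per-channel positivity flags are added.
#'
#' @param cell_table cell table.
#' @param thresholds stacked `threshold_spec` rows covering every donor
#'   present, for every channel in `channels`.
#' @param channels channels to flag (default INS and GCG).
#' @return the cell table with `pos_<channel>` logical columns and (when
#'   INS and GCG are both flagged) a `cell_type` column.
#' @export
classify_cells <- function(cell_table, thresholds,
                           channels = c("INS", "GCG")) {
  out <- cell_table
  for (ch in channels) {
    col <- paste0("mean_", ch)
    if (!col %in% names(out)) stopf("cell table lacks column %s", col)
    thr <- vapply(out$donor_id, threshold_lookup, 0,
                  thresholds = thresholds, channel = ch)
    out[[paste0("pos_", ch)]] <- out[[col]] > thr
  }
  if (all(c("INS", "GCG") %in% channels)) {
    out$cell_type <- ifelse(out$pos_INS & out$pos_GCG, "bihormonal",
                            ifelse(out$pos_INS, "beta",
                                   ifelse(out$pos_GCG, "alpha", "other")))
  }
  out
}

#' Filter islets by insulin-positive cell count
#'
#' An islet is eligible iff it contains strictly more than `min_beta`
#' insulin-positive cells (beta plus bi-hormonal); an islet with exactly
#' `min_beta` is excluded.
#'
#' @param typed_cells output of [classify_cells()].
#' @param min_beta eligibility cut (default 10, strict `>`).
#' @return data frame of eligible (donor_id, islet_id) pairs.
#' @export
filter_eligible_islets <- function(typed_cells, min_beta = 10) {
  if (!nrow(typed_cells))
    return(data.frame(donor_id = character(), islet_id = integer()))
  key <- interaction(typed_cells$donor_id, typed_cells$islet_id, drop = TRUE)
  ins <- tapply(typed_cells$pos_INS, key, sum)
  keep <- names(ins)[ins > min_beta]
  if (!length(keep))
    return(data.frame(donor_id = character(), islet_id = integer()))
  parts <- strsplit(keep, ".", fixed = TRUE)
  data.frame(donor_id = vapply(parts, `[`, "", 1),
             islet_id = as.integer(vapply(parts, `[`, "", 2)),
             stringsAsFactors = FALSE)
}

#' Summarise islet composition
#'
#' Per-islet alpha/beta/bi-hormonal/other counts and the alpha:beta
#' ratio (`NA` with `ratio_undefined = TRUE` when the islet has no beta
#' cells); per-donor totals with the per-islet ratio list retained in
#' the islet table; overall totals, the aggregate alpha:beta ratio and
#' bi-hormonal prevalence (percent of all typed cells).
#'
#' @param typed_cells output of [classify_cells()]; apply
#'   [filter_eligible_islets()] first (or deliberately skip it).
#' @return list of class `composition_summary` with `islets`, `donors`,
#'   `overall`.
#' @export
summarise_composition <- function(typed_cells) {
  lv <- c("alpha", "beta", "bihormonal", "other")
  if (!nrow(typed_cells)) {
    islets <- data.frame(donor_id = character(), islet_id = integer(),
                         alpha_count = integer(), beta_count = integer(),
                         bihormonal_count = integer(), other_count = integer(),
                         total = integer(), alpha_beta_ratio = numeric(),
                         ratio_undefined = logical())
    donors <- islets[, c("donor_id", "alpha_count", "beta_count",
                         "bihormonal_count", "other_count", "total")]
    overall <- list(alpha_count = 0L, beta_count = 0L, bihormonal_count = 0L,
                    other_count = 0L, total = 0L,
                    alpha_beta_ratio = NA_real_,
                    bihormonal_prevalence_pct = NA_real_)
    return(structure(list(islets = islets, donors = donors, overall = overall),
                     class = "composition_summary"))
  }
  ty <- factor(typed_cells$cell_type, levels = lv)
  tab <- as.data.frame.matrix(
    table(interaction(typed_cells$donor_id, typed_cells$islet_id, drop = TRUE,
                      sep = "\r"), ty))
  keyp <- strsplit(rownames(tab), "\r", fixed = TRUE)
  islets <- data.frame(
    donor_id = vapply(keyp, `[`, "", 1),
    islet_id = as.integer(vapply(keyp, `[`, "", 2)),
    alpha_count = tab$alpha, beta_count = tab$beta,
    bihormonal_count = tab$bihormonal, other_count = tab$other,
    stringsAsFactors = FALSE)
  islets$total <- islets$alpha_count + islets$beta_count +
    islets$bihormonal_count + islets$other_count
  islets$ratio_undefined <- islets$beta_count == 0L
  islets$alpha_beta_ratio <- ifelse(islets$ratio_undefined, NA_real_,
                                    islets$alpha_count / islets$beta_count)
  islets <- islets[order(islets$donor_id, islets$islet_id), ]
  rownames(islets) <- NULL
  agg <- function(v, g) as.vector(rowsum(v, g))
  g <- factor(islets$donor_id)
  donors <- data.frame(
    donor_id = levels(g),
    alpha_count = agg(islets$alpha_count, g),
    beta_count = agg(islets$beta_count, g),
    bihormonal_count = agg(islets$bihormonal_count, g),
    other_count = agg(islets$other_count, g),
    total = agg(islets$total, g),
    n_islets = as.integer(table(g)),
    mean_islet_ratio = as.vector(tapply(islets$alpha_beta_ratio, g, mean,
                                        na.rm = TRUE)),
    stringsAsFactors = FALSE)
  donors$bihormonal_pct <- 100 * donors$bihormonal_count / donors$total
  overall <- list(
    alpha_count = sum(islets$alpha_count),
    beta_count = sum(islets$beta_count),
    bihormonal_count = sum(islets$bihormonal_count),
    other_count = sum(islets$other_count),
    total = sum(islets$total))
  overall$alpha_beta_ratio <- if (overall$beta_count > 0)
    overall$alpha_count / overall$beta_count else NA_real_
  overall$bihormonal_prevalence_pct <-
    100 * overall$bihormonal_count / overall$total
  structure(list(islets = islets, donors = donors, overall = overall),
            class = "composition_summary")
}

#' @export
print.composition_summary <- function(x, ...) {
  o <- x$overall
  cat(sprintf(paste0("<composition_summary> %d islets, %d cells ",
                     "(alpha %d, beta %d, bihormonal %d, other %d)\n",
                     "  aggregate alpha:beta ratio %.4f, bi-hormonal ",
                     "prevalence %.3f%%\n"),
              nrow(x$islets), o$total, o$alpha_count, o$beta_count,
              o$bihormonal_count, o$other_count,
              o$alpha_beta_ratio, o$bihormonal_prevalence_pct))
  invisible(x)
}

pair_type <- function(ta, tb) {
  core <- ta %in% c("alpha", "beta") & tb %in% c("alpha", "beta")
  out <- rep("other_pair", length(ta))
  out[core & ta == "alpha" & tb == "alpha"] <- "alpha_alpha"
  out[core & ta == "beta" & tb == "beta"] <- "beta_beta"
  out[core & ta != tb] <- "beta_alpha"
  out
}

pair_percentages <- function(counts) {
  tot <- sum(counts)
  if (tot == 0) return(setNames(rep(NA_real_, 3), names(counts)))
  100 * counts / tot
}

#' Contact-pair composition of islets
#'
#' Tallies alpha-alpha, beta-alpha and beta-beta contact pairs per islet,
#' per donor and overall, as percentages of the three-way pair total;
#' pairs involving bi-hormonal or other cells are counted separately
#' (`other_pair`) and excluded from the percentages. Cell-level
#' fractions (e.g. proportion of beta cells with at least one beta
#' neighbour) are also reported per donor.
#'
#' @param graph a [build_contact_graph()] result.
#' @param typed_cells typed cells covering the graph's nodes (same
#'   donor/image).
#' @return list of class `contact_profile` with `islets`, `donors`,
#'   `overall` and `cell_level` tables.
#' @export
contact_proportions <- function(graph, typed_cells) {
  ed <- graph$edges
  type_of <- setNames(typed_cells$cell_type, typed_cells$cell_id)
  ta <- type_of[as.character(ed$cell_a)]
  tb <- type_of[as.character(ed$cell_b)]
  pt <- pair_type(ta, tb)
  lv3 <- c("alpha_alpha", "beta_alpha", "beta_beta")
  per_islet <- lapply(split(seq_len(nrow(ed)), ed$islet_id), function(sel) {
    counts <- table(factor(pt[sel], levels = c(lv3, "other_pair")))
    pct <- pair_percentages(counts[lv3])
    data.frame(islet_id = ed$islet_id[sel[1]],
               alpha_alpha = counts[1], beta_alpha = counts[2],
               beta_beta = counts[3], other_pair = counts[4],
               pct_alpha_alpha = pct[1], pct_beta_alpha = pct[2],
               pct_beta_beta = pct[3])
  })
  islets <- if (length(per_islet)) do.call(rbind, per_islet) else
    data.frame(islet_id = integer(), alpha_alpha = integer(),
               beta_alpha = integer(), beta_beta = integer(),
               other_pair = integer(), pct_alpha_alpha = numeric(),
               pct_beta_alpha = numeric(), pct_beta_beta = numeric())
  rownames(islets) <- NULL
  counts_all <- table(factor(pt, levels = c(lv3, "other_pair")))
  overall <- as.list(c(counts_all,
                       setNames(pair_percentages(counts_all[lv3]),
                                paste0("pct_", lv3))))
  # donor-level: typed cells carry donor ids; edges are within-donor
  donor_of <- setNames(typed_cells$donor_id, typed_cells$cell_id)
  dnr <- donor_of[as.character(ed$cell_a)]
  per_donor <- lapply(split(seq_len(nrow(ed)), dnr), function(sel) {
    counts <- table(factor(pt[sel], levels = c(lv3, "other_pair")))
    pct <- pair_percentages(counts[lv3])
    data.frame(alpha_alpha = counts[1], beta_alpha = counts[2],
               beta_beta = counts[3], other_pair = counts[4],
               pct_alpha_alpha = pct[1], pct_beta_alpha = pct[2],
               pct_beta_beta = pct[3])
  })
  donors <- if (length(per_donor))
    cbind(data.frame(donor_id = names(per_donor), stringsAsFactors = FALSE),
          do.call(rbind, per_donor)) else
    data.frame(donor_id = character())
  rownames(donors) <- NULL
  # cell-level fractions
  nb <- rbind(data.frame(cell = ed$cell_a, nbr = ed$cell_b),
              data.frame(cell = ed$cell_b, nbr = ed$cell_a))
  nb$cell_type <- type_of[as.character(nb$cell)]
  nb$nbr_type <- type_of[as.character(nb$nbr)]
  nb$donor_id <- donor_of[as.character(nb$cell)]
  frac <- function(cells, focal, nbr_ty) {
    foc <- cells$cell_id[cells$cell_type == focal]
    if (!length(foc)) return(NA_real_)
    has <- unique(nb$cell[nb$cell_type == focal & nb$nbr_type == nbr_ty])
    mean(foc %in% has)
  }
  cl <- lapply(split(typed_cells, typed_cells$donor_id), function(cells)
    data.frame(frac_beta_with_beta = frac(cells, "beta", "beta"),
               frac_alpha_with_alpha = frac(cells, "alpha", "alpha"),
               frac_beta_with_alpha = frac(cells, "beta", "alpha"),
               frac_alpha_with_beta = frac(cells, "alpha", "beta")))
  cell_level <- cbind(data.frame(donor_id = names(cl),
                                 stringsAsFactors = FALSE),
                      do.call(rbind, cl))
  rownames(cell_level) <- NULL
  structure(list(islets = islets, donors = donors, overall = overall,
                 cell_level = cell_level), class = "contact_profile")
}

#' Jumbled-islet permutation null for contact architecture
#'
#' Holds the contact graph fixed and permutes the cell-type labels over
#' the nodes (`n_perm` draws), emulating a random mixture of cells - the
#' jumbled islet. For each pair type the expected percentage is the
#' permutation mean, and the two-sided p-value uses the add-one rule
#' `p = (1 + #{|perm - mean| >= |obs - mean|}) / (n_perm + 1)`, so p is
#' never 0. Degenerate islets (a single represented type) return p = 1
#' for all pair types.
#'
#' @param graph a [build_contact_graph()] result (typically one islet).
#' @param typed_cells typed cells covering the graph's nodes.
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed (reproducible).
#' @return list of class `jumbled_null`: observed and expected pair-type
#'   percentages, two-sided p per pair type, `n_perm`, `seed`.
#' @export
jumbled_null <- function(graph, typed_cells, n_perm = 999, seed = 1) {
  if (n_perm < 100) stopf("n_perm must be >= 100")
  lv3 <- c("alpha_alpha", "beta_alpha", "beta_beta")
  type_of <- setNames(typed_cells$cell_type, typed_cells$cell_id)
  nodes <- graph$nodes$cell_id
  types <- unname(type_of[as.character(nodes)])
  ed <- graph$edges
  ia <- match(ed$cell_a, nodes)
  ib <- match(ed$cell_b, nodes)
  # integer coding for speed: alpha = 1, beta = 2, other/bihormonal = 0;
  # pair sums 2/3/4 <-> alpha_alpha / beta_alpha / beta_beta
  code <- ifelse(is.na(types), 0L,
                 ifelse(types == "alpha", 1L, ifelse(types == "beta", 2L, 0L)))
  pct_of <- function(cv) {
    ca <- cv[ia]; cb <- cv[ib]
    s <- (ca + cb)[ca > 0L & cb > 0L]
    counts <- tabulate(s - 1L, 3L)
    pair_percentages(setNames(counts, lv3))
  }
  obs <- pct_of(code)
  if (length(unique(types[!is.na(types)])) <= 1L || !nrow(ed)) {
    return(structure(list(observed = obs, expected = obs,
                          p = setNames(rep(1, 3), lv3),
                          n_perm = n_perm, seed = seed),
                     class = "jumbled_null"))
  }
  set.seed(seed)
  perm <- matrix(NA_real_, n_perm, 3, dimnames = list(NULL, lv3))
  for (b in seq_len(n_perm)) perm[b, ] <- pct_of(sample(code))
  ok <- stats::complete.cases(perm)
  expected <- colMeans(perm[ok, , drop = FALSE])
  p <- setNames(rep(1, 3), lv3)
  for (j in seq_len(3)) {
    if (is.na(obs[j])) next
    dev_obs <- abs(obs[j] - expected[j])
    dev_perm <- abs(perm[ok, j] - expected[j])
    p[j] <- (1 + sum(dev_perm >= dev_obs - 1e-12)) / (sum(ok) + 1)
  }
  structure(list(observed = obs, expected = expected, p = p,
                 n_perm = n_perm, seed = seed),
            class = "jumbled_null")
}
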