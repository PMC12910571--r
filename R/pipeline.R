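# End-to-end orchestration: simulate -> segment -> quantify -> phenotype
# -> tiers -> compare, with config validation and a reproducibility
# manifest.

run_config_schema <- function() {
  list(
    seed = NULL, out_dir = NULL,
    sim = list(n_donors_per_group = NULL, group_effects = NULL,
               panels = NULL, image_shape = NULL, n_islets = NULL,
               cells_per_islet = NULL, arrangement = NULL),
    segmentation = list(smooth_sigma = NULL, threshold = NULL,
                        min_islet_area = NULL, close_radius = NULL,
                        split_touching = NULL),
    nuclei = list(sigmas = NULL, min_separation = NULL,
                  response_frac = NULL),
    cells = list(max_cell_radius = NULL, lambda = NULL),
    quant = list(contact_distance = NULL),
    phenotype = list(k = NULL, min_beta = NULL, n_perm = NULL,
                     scale_method = NULL),
    islet_sample = list(enabled = NULL, max_per_donor = NULL),
    tiers = list(k_max = NULL, n_restarts = NULL),
    compare = list(n_perm = NULL))
}

#' Build / validate a pipeline run configuration
#'
#' Every stage parameter has a default; unknown keys raise a validation
#' error naming the key. The configuration round-trips unchanged through
#' [write_run_config()] / [read_run_config()].
#'
#' @param ... named overrides of the default configuration, nested as in
#'   the schema (e.g. `phenotype = list(k = 1.5)`).
#' @return validated `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 17L, out_dir = "isletkit_run",
    sim = list(n_donors_per_group = 2L, group_effects = NULL,
               panels = c("composition", "NDUFB8", "MTCO1"),
               image_shape = c(320L, 320L), n_islets = 3L,
               cells_per_islet = c(50L, 70L), arrangement = "jumbled"),
    segmentation = list(smooth_sigma = 2, threshold = "otsu",
                        min_islet_area = 500, close_radius = 5,
                        split_touching = FALSE),
    nuclei = list(sigmas = c(1.4, 2.0, 2.8, 4.0), min_separation = 6,
                  response_frac = 0.15),
    cells = list(max_cell_radius = 15, lambda = 0.05),
    quant = list(contact_distance = 2),
    phenotype = list(k = 1, min_beta = 10, n_perm = 199,
                     scale_method = "lower_mad"),
    islet_sample = list(enabled = FALSE, max_per_donor = 20L),
    tiers = list(k_max = 8, n_restarts = 10),
    compare = list(n_perm = 9999))
  over <- list(...)
  cfg <- merge_config(cfg, over, run_config_schema(), path = "")
  class(cfg) <- "run_config"
  cfg
}

merge_config <- function(base, over, schema, path) {
  for (nm in names(over)) {
    full <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(schema))
      stopf("unknown configuration key: %s", full)
    if (is.list(schema[[nm]]) && length(schema[[nm]])) {
      if (!is.list(over[[nm]]))
        stopf("configuration key %s must be a list", full)
      base[[nm]] <- merge_config(base[[nm]], over[[nm]], schema[[nm]], full)
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' Seeded random selection of eligible islets
#'
#' Optionally emulates selecting up to a fixed number of eligible islets
#' per donor at random (off by default for synthetic data, where every
#' eligible islet is analysed).
#'
#' @param eligible data frame of (donor_id, islet_id) pairs.
#' @param max_per_donor cap per donor.
#' @param seed RNG seed.
#' @return subset of `eligible`.
#' @export
select_islets <- function(eligible, max_per_donor = 20L, seed = 1) {
  set.seed(seed)
  keep <- unlist(lapply(split(seq_len(nrow(eligible)), eligible$donor_id),
                        function(idx) {
                          if (length(idx) <= max_per_donor) idx
                          else sort(sample(idx, max_per_donor))
                        }))
  eligible[sort(keep), , drop = FALSE]
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full pipeline
#'
#' Simulates a two-group donor cohort, segments islets and cells on
#' every donor image, measures cells, phenotypes the composition panel
#' (thresholds, typing, eligibility, composition, contact architecture),
#' fits OXPHOS tiers on the mitochondrial panels, and runs donor-level
#' group comparisons. All stage outputs are written as CSV/JSON under
#' `config$out_dir`, and a manifest records the package version, config
#' hash, seeds, per-stage row counts and the MD5 of every output file;
#' re-running with the same config reproduces every file bit-identically.
#'
#' @param config a [run_config()].
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  written <- character()
  emit_csv <- function(x, name) {
    p <- file.path(out, name)
    write.csv(x, p, row.names = FALSE)
    written <<- c(written, p)
    p
  }
  counts <- list()

  sim <- config$sim
  scfg <- sim_config(image_shape = sim$image_shape, n_islets = sim$n_islets,
                     cells_per_islet = sim$cells_per_islet,
                     arrangement = sim$arrangement,
                     rng_seed = config$seed)
  raw_dir <- file.path(out, "raw")
  manifest <- stage("simulate",
                    generate_cohort(scfg, sim$n_donors_per_group,
                                    group_effects = sim$group_effects %||%
                                      cohort_group_effects(),
                                    out_dir = raw_dir, panels = sim$panels))

  ip <- do.call(islet_params, config$segmentation)
  np <- do.call(nuclei_params, config$nuclei)
  cp <- do.call(cell_params, config$cells)
  tables <- list()
  seg_report <- list()
  for (key in names(manifest$files)) {
    img <- read_image(manifest$files[[key]]$image)
    panel <- img$panel_id
    res <- stage(paste0("segment:", key), {
      masks <- segment_islets(img, ip)
      seeds <- if ("DAPI" %in% names(img$channels))
        detect_nuclei(img$channels$DAPI, masks$islet_label_map, np)
      else membrane_seeds(img$channels$ECAD, masks$islet_label_map,
                          spacing = np$min_separation + 3)
      cells <- segment_cells(img$channels$ECAD, seeds, masks, cp)
      list(masks = masks, seeds = seeds, cells = cells)
    })
    tab <- stage(paste0("quantify:", key),
                 measure_cells(res$cells, img))
    tables[[panel]] <- rbind(tables[[panel]], tab)
    seg_report[[key]] <- data.frame(
      image = key, panel = panel, n_islets = nrow(res$masks$stats),
      islet_area_px2 = sum(res$masks$stats$area),
      n_seeds = nrow(res$seeds), n_cells = nrow(tab),
      seeding = attr(res$seeds, "method") %||% "dapi_log")
    # contact graph per composition image, used by phenotyping below
    if (panel == "composition")
      attr(tables[["composition"]], paste0("graph_", key)) <-
        build_contact_graph(res$cells, config$quant$contact_distance)
  }
  emit_csv(do.call(rbind, seg_report), "segmentation_report.csv")

  # ---- phenotyping (composition panel)
  comp <- tables$composition
  pheno <- config$phenotype
  thr <- stage("thresholds", rbind(
    compute_thresholds(comp, "INS", k = pheno$k,
                       scale_method = pheno$scale_method),
    compute_thresholds(comp, "GCG", k = pheno$k,
                       scale_method = pheno$scale_method)))
  emit_csv(thr, "thresholds_composition.csv")
  typed <- stage("classify", classify_cells(comp, thr))
  # threshold validation report: per-donor positivity rates per channel
  pos_rates <- do.call(rbind, lapply(c("INS", "GCG"), function(ch)
    data.frame(donor_id = names(tapply(typed[[paste0("pos_", ch)]],
                                       typed$donor_id, mean)),
               channel = ch,
               positivity_rate = as.vector(tapply(typed[[paste0("pos_", ch)]],
                                                  typed$donor_id, mean)))))
  emit_csv(pos_rates, "positivity_rates_composition.csv")
  eligible <- filter_eligible_islets(typed, pheno$min_beta)
  if (isTRUE(config$islet_sample$enabled))
    eligible <- select_islets(eligible, config$islet_sample$max_per_donor,
                              seed = config$seed)
  typed_el <- typed[paste(typed$donor_id, typed$islet_id) %in%
                      paste(eligible$donor_id, eligible$islet_id), ]
  emit_csv(typed_el, "typed_cells_composition.csv")
  counts$typed_cells <- nrow(typed_el)
  comp_sum <- summarise_composition(typed_el)
  emit_csv(comp_sum$islets, "composition_islets.csv")
  emit_csv(comp_sum$donors, "composition_donors.csv")

  profiles <- list()
  nulls <- list()
  for (key in grep("_composition$", names(manifest$files), value = TRUE)) {
    g <- attr(tables$composition, paste0("graph_", key))
    if (is.null(g)) next
    did <- sub("_composition$", "", key)
    cells_d <- typed_el[typed_el$donor_id == did, ]
    if (!nrow(cells_d)) next
    keep_cells <- g$nodes$cell_id %in% cells_d$cell_id
    g$nodes <- g$nodes[keep_cells, , drop = FALSE]
    g$edges <- g$edges[g$edges$cell_a %in% g$nodes$cell_id &
                         g$edges$cell_b %in% g$nodes$cell_id, , drop = FALSE]
    profiles[[did]] <- contact_proportions(g, cells_d)
    per_islet <- lapply(split(g$nodes$cell_id, g$nodes$islet_id),
                        function(cid) {
      gi <- list(nodes = g$nodes[g$nodes$cell_id %in% cid, , drop = FALSE],
                 edges = g$edges[g$edges$cell_a %in% cid, , drop = FALSE])
      class(gi) <- "contact_graph"
      jn <- jumbled_null(gi, cells_d, n_perm = max(100, pheno$n_perm),
                         seed = config$seed)
      data.frame(donor_id = did, islet_id = gi$nodes$islet_id[1],
                 t(jn$observed), t(setNames(jn$expected,
                                            paste0("exp_", names(jn$expected)))),
                 t(setNames(jn$p, paste0("p_", names(jn$p)))))
    })
    nulls[[did]] <- do.call(rbind, per_islet)
  }
  contact_donors <- do.call(rbind, lapply(names(profiles), function(d)
    profiles[[d]]$donors))
  emit_csv(contact_donors, "contact_profile_donors.csv")
  emit_csv(do.call(rbind, nulls), "contact_jumbled_null.csv")

  # ---- OXPHOS tiers (mitochondrial panels)
  tier_results <- list()
  for (marker in intersect(c("NDUFB8", "MTCO1"), names(tables))) {
    mt <- tables[[marker]]
    thr_m <- stage(paste0("thresholds:", marker),
                   compute_thresholds(mt, "INS", k = pheno$k,
                                      scale_method = pheno$scale_method))
    typed_m <- classify_cells(mt, thr_m, channels = "INS")
    ratios <- stage(paste0("ratios:", marker),
                    compute_ratios(typed_m, marker))
    model <- stage(paste0("tiers:", marker),
                   fit_tiers(ratios, k_max = config$tiers$k_max,
                             n_restarts = config$tiers$n_restarts,
                             seed = config$seed))
    av <- if (model$k >= 2) validate_tiers_anova(model, ratios) else NULL
    prof <- donor_tier_profiles(model, ratios, manifest)
    emit_csv(cbind(ratios, tier = as.character(model$tier)),
             sprintf("tiers_%s_cells.csv", marker))
    emit_csv(data.frame(k = seq_along(model$wcss_curve),
                        wcss = model$wcss_curve),
             sprintf("tiers_%s_wcss.csv", marker))
    emit_csv(prof$donors, sprintf("tiers_%s_donors.csv", marker))
    tier_results[[marker]] <- list(model = model, profiles = prof,
                                   anova = av, ratios = ratios)
    counts[[paste0("ratios_", marker)]] <- nrow(ratios)
  }

  # ---- group comparison (donor as exchangeable unit)
  cmp_rows <- list()
  donors_groups <- manifest$donors
  ratio_by_donor <- comp_sum$donors$mean_islet_ratio[
    match(donors_groups$donor_id, comp_sum$donors$donor_id)]
  ok <- !is.na(ratio_by_donor)
  if (sum(ok) >= 4 && length(unique(donors_groups$group[ok])) == 2) {
    pt <- donor_permutation_test(ratio_by_donor[ok],
                                 donors_groups$group[ok],
                                 n_perm = config$compare$n_perm,
                                 seed = config$seed)
    gsplit <- split(ratio_by_donor[ok], donors_groups$group[ok])
    es <- cohens_d(gsplit[[1]], gsplit[[2]])
    cmp_rows$alpha_beta_ratio <- data.frame(
      metric = "alpha_beta_ratio", statistic = pt$observed, p = pt$p,
      effect = es$value, effect_kind = es$kind, band = es$band)
  }
  for (marker in names(tier_results)) {
    prof <- tier_results[[marker]]$profiles
    lowcol <- paste0("prop_", prof$tier_levels[1])
    pt <- donor_permutation_test(prof$donors[[lowcol]], prof$donors$group,
                                 n_perm = config$compare$n_perm,
                                 seed = config$seed)
    gt <- as.matrix(prof$groups[, paste0("n_", prof$tier_levels)])
    mc <- monte_carlo_chi2(gt, n_sims = config$compare$n_perm,
                           seed = config$seed)
    cv <- cramers_v(gt)
    cmp_rows[[paste0(marker, "_low_prop")]] <- data.frame(
      metric = paste0(marker, "_low_tier_prop"), statistic = pt$observed,
      p = pt$p, effect = cv$value, effect_kind = cv$kind, band = cv$band)
    cmp_rows[[paste0(marker, "_mc")]] <- data.frame(
      metric = paste0(marker, "_tier_table_mc_chi2"),
      statistic = mc$observed, p = mc$p, effect = cv$value,
      effect_kind = cv$kind, band = cv$band)
  }
  cmp <- do.call(rbind, cmp_rows)
  if (!is.null(cmp)) {
    cmp <- cbind(cmp, bonferroni(cmp$p)[, c("p_adjusted", "reject")])
    emit_csv(cmp, "group_comparison.csv")
  }

  # ---- manifest
  cfg_file <- file.path(out, "run_config.yaml")
  write_run_config(config, cfg_file)
  written <- c(written, cfg_file)
  run_manifest <- list(
    package_version = as.character(packageVersion("isletkit")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    counts = counts,
    files = lapply(setNames(written, basename(written)),
                   function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(run_manifest, file.path(out, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(run_manifest, list(tier_results = tier_results,
                                 composition = comp_sum,
                                 comparison = cmp)))
}

#' Export a tidy per-cell table for external mixed-model fitting
#'
#' The in-package inferential claim is the donor-level permutation test;
#' this export (donor, group, islet and cell ids, cell type, ratios,
#' optional donor covariates) is the documented hook for fitting a
#' hierarchical linear mixed model in an external statistics
#' environment.
#'
#' @param typed_cells typed composition-panel cells.
#' @param manifest cohort manifest (or donor_id/group data frame).
#' @param ratios optional [compute_ratios()] result merged on cell keys.
#' @param covariates optional per-donor data frame (keyed by donor_id)
#'   merged on donor.
#' @return tidy data frame, one row per cell.
#' @export
export_modelling_table <- function(typed_cells, manifest, ratios = NULL,
                                   covariates = NULL) {
  donors <- if (is.data.frame(manifest)) manifest else manifest$donors
  out <- typed_cells
  out$group <- donors$group[match(out$donor_id, donors$donor_id)]
  if (!is.null(ratios))
    out <- merge(out, ratios[, c("donor_id", "islet_id", "cell_id",
                                 "marker", "ratio")],
                 by = c("donor_id", "islet_id", "cell_id"), all.x = TRUE)
  if (!is.null(covariates))
    out <- merge(out, covariates, by = "donor_id", all.x = TRUE)
  out[order(out$donor_id, out$islet_id, out$cell_id), ]
}
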