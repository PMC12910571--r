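# Synthetic islet field generator: geometry, ground truth and rendering.

PANELS <- list(
  composition = c("DAPI", "ECAD", "INS", "GCG"),
  NDUFB8 = c("ECAD", "INS", "VDAC1", "NDUFB8"),
  MTCO1 = c("ECAD", "INS", "VDAC1", "MTCO1")
)

# Place n non-overlapping ellipses (bounding-circle separation) on the field.
place_islets <- function(shape, n, areas) {
  out <- vector("list", n)
  placed <- 0L
  tries <- 0L
  max_tries <- 400L * max(1L, n)
  while (placed < n && tries < max_tries) {
    tries <- tries + 1L
    A <- areas[placed + 1L]
    aspect <- runif(1, 0.6, 0.95)
    a <- sqrt(A / (pi * aspect))   # semi-major
    b <- a * aspect                # semi-minor
    theta <- runif(1, 0, pi)
    margin <- 4
    if (2 * (a + margin) >= min(shape)) break
    cr <- runif(1, a + margin, shape[1] - a - margin)
    cc <- runif(1, a + margin, shape[2] - a - margin)
    ok <- TRUE
    if (placed > 0L) {
      for (e in out[seq_len(placed)]) {
        if (sqrt((cr - e$cr)^2 + (cc - e$cc)^2) < a + e$a + 2 * margin) {
          ok <- FALSE; break
        }
      }
    }
    if (ok) {
      placed <- placed + 1L
      out[[placed]] <- list(cr = cr, cc = cc, a = a, b = b, theta = theta)
    }
  }
  if (placed < n)
    stopf(paste("image too small to place %d islets of the requested size:",
                "limiting parameters are image_shape and cells_per_islet",
                "(via islet area)"), n)
  out
}

# Normalised elliptical radius (<= 1 inside) of points relative to an ellipse.
ellipse_rho <- function(r, c, ell) {
  dr <- r - ell$cr; dc <- c - ell$cc
  u <- dr * cos(ell$theta) + dc * sin(ell$theta)
  v <- -dr * sin(ell$theta) + dc * cos(ell$theta)
  sqrt((u / ell$a)^2 + (v / ell$b)^2)
}

# Dart-throwing Poisson-disc sampling of n seeds inside an ellipse.
sample_seeds <- function(n, ell, r_min) {
  pts <- matrix(NA_real_, n, 2)
  got <- 0L
  tries <- 0L
  max_tries <- 200L * n
  while (got < n && tries < max_tries) {
    tries <- tries + 1L
    t <- runif(1, 0, 2 * pi); rad <- sqrt(runif(1)) * 0.97
    u <- rad * cos(t) * ell$a; v <- rad * sin(t) * ell$b
    r <- ell$cr + u * cos(ell$theta) - v * sin(ell$theta)
    c <- ell$cc + u * sin(ell$theta) + v * cos(ell$theta)
    if (got > 0L &&
        min((pts[seq_len(got), 1] - r)^2 + (pts[seq_len(got), 2] - c)^2) <
          r_min^2) next
    got <- got + 1L
    pts[got, ] <- c(r, c)
  }
  if (got < n)
    stopf(paste("could not place %d nucleus seeds at minimum seed spacing",
                "%.2f px inside the islet: limiting parameters are",
                "cells_per_islet and cell_radius"), n, r_min)
  pts
}

# Draw cell types for one islet per the configured frequencies/arrangement.
assign_types <- function(seeds, ell, cfg) {
  n <- nrow(seeds)
  tf <- cfg$type_frequencies[c("alpha", "beta", "other")]
  counts <- as.vector(stats::rmultinom(1, n, tf))
  if (cfg$arrangement == "jumbled") {
    types <- sample(rep(c("alpha", "beta", "other"), counts))
  } else {
    rho <- ellipse_rho(seeds[, 1], seeds[, 2], ell)
    ord <- order(rho, decreasing = TRUE)    # outermost first
    types <- character(n)
    types[ord[seq_len(counts[1])]] <- "alpha"
    inner <- rev(ord)                        # innermost first
    inner <- inner[!(inner %in% ord[seq_len(counts[1])])]
    types[inner[seq_len(counts[2])]] <- "beta"
    types[types == ""] <- "other"
  }
  bih <- runif(n) < cfg$bihormonal_rate
  types[bih] <- "bihormonal"
  types
}

# Per-cell true channel intensities. Marker channels are uniform over the
# cell region, so the painted value is the cell's true noise-free mean.
draw_intensities <- function(types, cfg) {
  n <- length(types)
  ip <- cfg$intensity_params
  chans <- names(ip)
  out <- matrix(NA_real_, n, length(chans), dimnames = list(NULL, chans))
  for (ch in chans) {
    for (ty in unique(types)) {
      idx <- types == ty
      p <- ip[[ch]][[ty]]
      out[idx, ch] <- rlnorm(sum(idx), p[1], p[2])
    }
  }
  # Bi-hormonal cells must be positive in both hormone channels by
  # construction: redraw INS and GCG strictly above the positive-population
  # mean exp(mu + sigma^2/2).
  bih <- types == "bihormonal"
  if (any(bih)) {
    for (ch in c("INS", "GCG")) {
      p <- ip[[ch]][["bihormonal"]]
      out[bih, ch] <- exp(p[1] + p[2]^2 / 2) * exp(abs(rnorm(sum(bih), 0, p[2])))
    }
  }
  out
}

# OXPHOS tier labels and true marker/VDAC1 ratios for one marker.
draw_tiers <- function(types, cfg, marker, weights = NULL) {
  tp <- cfg$ratio_tier_params[[marker]]
  w <- weights %||% tp$weights
  n <- length(types)
  tier <- rep(NA_integer_, n)
  ratio <- rep(NA_real_, n)
  ins_pos <- types %in% c("beta", "bihormonal")
  k <- length(w)
  comp <- sample.int(k, sum(ins_pos), replace = TRUE, prob = w)
  tier[ins_pos] <- comp
  ratio[ins_pos] <- rlnorm(sum(ins_pos), tp$meanlog[comp], tp$sdlog[comp])
  # alpha/other cells still carry mitochondria: ratio from the pooled mixture
  if (any(!ins_pos)) {
    comp2 <- sample.int(k, sum(!ins_pos), replace = TRUE, prob = w)
    ratio[!ins_pos] <- rlnorm(sum(!ins_pos), tp$meanlog[comp2], tp$sdlog[comp2])
  }
  list(tier = tier, ratio = ratio)
}

#' Generate one synthetic multi-channel islet image with ground truth
#'
#' Renders a field of non-overlapping elliptical islets, each tiled by a
#' nearest-seed partition of Poisson-disc nucleus seeds. Marker channels
#' paint each cell's true intensity uniformly over the cell region; the
#' membrane channel (ECAD) paints cell boundaries; DAPI paints nuclear
#' discs. The painted field is convolved with a Gaussian PSF and corrupted
#' with Poisson-Gaussian noise. Generation is deterministic given
#' `config$rng_seed`, `donor_id` and `panel`.
#'
#' @param config a [sim_config()].
#' @param donor_id donor identifier recorded in the outputs (also salts
#'   the random stream, so donors differ).
#' @param panel `"composition"` (DAPI/ECAD/INS/GCG), `"NDUFB8"` or
#'   `"MTCO1"` (ECAD/INS/VDAC1/marker).
#' @param tier_weights optional per-marker override of the tier mixture
#'   weights (used for group effects).
#'
#' @return list with `image` (a [multichannel_image()]) and `truth` (list
#'   of `cell_label_map`, `islet_label_map`, `truth_table`). The truth
#'   table has one row per cell: ids, seed position, area, true type,
#'   true noise-free mean intensity per marker channel, and the true
#'   OXPHOS tier (`tier_<marker>`, 1 = low) for insulin-positive cells.
#' @export
generate_islet_image <- function(config, donor_id, panel = "composition",
                                 tier_weights = NULL) {
  validate_sim_config(config)
  if (!panel %in% names(PANELS)) stopf("unknown panel '%s'", panel)
  set.seed(derive_seed(config$rng_seed, paste(donor_id, panel)))
  shape <- config$image_shape
  chans <- PANELS[[panel]]
  bg <- config$background

  cell_lab <- matrix(0L, shape[1], shape[2])
  islet_lab <- matrix(0L, shape[1], shape[2])
  canvases <- lapply(chans, function(ch) matrix(bg, shape[1], shape[2]))
  names(canvases) <- chans
  truth_rows <- list()

  if (config$n_islets > 0L) {
    rng <- seq(config$cells_per_islet[1], config$cells_per_islet[2])
    n_cells <- if (length(rng) == 1L) rep(rng, config$n_islets) else
      sample(rng, config$n_islets, replace = TRUE)
    areas <- n_cells * pi * config$cell_radius^2 * 1.15
    ells <- place_islets(shape, config$n_islets, areas)
    next_label <- 0L
    ecad_all <- numeric(0)
    for (ii in seq_len(config$n_islets)) {
      ell <- ells[[ii]]
      A <- areas[ii]
      r_min <- 0.75 * sqrt(A / n_cells[ii])
      seeds <- sample_seeds(n_cells[ii], ell, r_min)
      # pixels of the islet ellipse (bounding box scan)
      r0 <- max(1L, floor(ell$cr - ell$a)); r1 <- min(shape[1], ceiling(ell$cr + ell$a))
      c0 <- max(1L, floor(ell$cc - ell$a)); c1 <- min(shape[2], ceiling(ell$cc + ell$a))
      gr <- rep(r0:r1, times = c1 - c0 + 1L)
      gc <- rep(c0:c1, each = r1 - r0 + 1L)
      inside <- ellipse_rho(gr, gc, ell) <= 1
      pr <- gr[inside]; pc <- gc[inside]
      # nearest-seed (Voronoi) partition
      best <- rep(Inf, length(pr)); owner <- integer(length(pr))
      for (s in seq_len(nrow(seeds))) {
        d2 <- (pr - seeds[s, 1])^2 + (pc - seeds[s, 2])^2
        upd <- d2 < best
        best[upd] <- d2[upd]; owner[upd] <- s
      }
      labels <- next_label + seq_len(n_cells[ii])
      cell_lab[cbind(pr, pc)] <- labels[owner]
      islet_lab[cbind(pr, pc)] <- ii

      types <- assign_types(seeds, ell, config)
      intens <- draw_intensities(types, config)
      td_n <- draw_tiers(types, config, "NDUFB8",
                         tier_weights$NDUFB8 %||% NULL)
      td_m <- draw_tiers(types, config, "MTCO1",
                         tier_weights$MTCO1 %||% NULL)
      intens_full <- cbind(intens,
                           NDUFB8 = td_n$ratio * intens[, "VDAC1"],
                           MTCO1 = td_m$ratio * intens[, "VDAC1"])
      truth_rows[[ii]] <- data.frame(
        donor_id = donor_id, panel_id = panel, islet_id = ii,
        cell_id = labels, row = seeds[, 1], col = seeds[, 2],
        area = tabulate(owner, n_cells[ii]),
        true_type = types,
        true_INS = intens_full[, "INS"], true_GCG = intens_full[, "GCG"],
        true_VDAC1 = intens_full[, "VDAC1"],
        true_NDUFB8 = intens_full[, "NDUFB8"],
        true_MTCO1 = intens_full[, "MTCO1"],
        true_ratio_NDUFB8 = td_n$ratio, true_ratio_MTCO1 = td_m$ratio,
        tier_NDUFB8 = td_n$tier, tier_MTCO1 = td_m$tier,
        stringsAsFactors = FALSE)

      # paint marker channels uniformly over each cell region (DAPI and
      # ECAD have their own structured rendering below)
      for (ch in setdiff(intersect(chans, colnames(intens_full)),
                         c("DAPI", "ECAD"))) {
        vals <- intens_full[, ch]
        canvases[[ch]][cbind(pr, pc)] <- vals[owner]
      }
      if ("DAPI" %in% chans) {
        canvases$DAPI <- paint_discs(canvases$DAPI, seeds,
                                     config$nucleus_radius,
                                     intens[, "DAPI"])
      }
      ecad_all <- c(ecad_all, intens[, "ECAD"])
      next_label <- next_label + n_cells[ii]
    }
    if ("ECAD" %in% chans && next_label > 0L) {
      bnd <- boundary_pixels(cell_lab)
      canvases$ECAD[bnd] <- ecad_all[cell_lab[bnd]]
    }
  }

  for (ch in chans) {
    x <- gaussian_blur(canvases[[ch]], config$psf_sigma)
    if (config$noise$poisson_gain > 0)
      x <- matrix(rpois(length(x), pmax(x, 0) / config$noise$poisson_gain) *
                    config$noise$poisson_gain, nrow(x), ncol(x))
    if (config$noise$gaussian_sd > 0)
      x <- x + rnorm(length(x), 0, config$noise$gaussian_sd)
    canvases[[ch]] <- pmax(x, 0)
  }

  truth_table <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    empty_truth_table(donor_id, panel)
  img <- multichannel_image(canvases, donor_id = donor_id, panel_id = panel)
  list(image = img,
       truth = list(cell_label_map = cell_lab, islet_label_map = islet_lab,
                    truth_table = truth_table))
}

empty_truth_table <- function(donor_id, panel) {
  data.frame(donor_id = character(), panel_id = character(),
             islet_id = integer(), cell_id = integer(),
             row = numeric(), col = numeric(), area = integer(),
             true_type = character(), true_INS = numeric(),
             true_GCG = numeric(), true_VDAC1 = numeric(),
             true_NDUFB8 = numeric(), true_MTCO1 = numeric(),
             true_ratio_NDUFB8 = numeric(), true_ratio_MTCO1 = numeric(),
             tier_NDUFB8 = integer(), tier_MTCO1 = integer(),
             stringsAsFactors = FALSE)
}

# Logical index of pixels on a label boundary (4-neighbour different label,
# including the background).
boundary_pixels <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  b <- matrix(FALSE, nr, nc)
  b[-nr, ] <- b[-nr, ] | (lab[-nr, ] != lab[-1, ])
  b[-1, ] <- b[-1, ] | (lab[-1, ] != lab[-nr, ])
  b[, -nc] <- b[, -nc] | (lab[, -nc] != lab[, -1])
  b[, -1] <- b[, -1] | (lab[, -1] != lab[, -nc])
  b & lab > 0
}

#' Generate a two-group synthetic donor cohort on disk
#'
#' Writes per-donor multi-channel images (one per requested staining
#' panel), ground-truth label maps, truth tables, and a cohort manifest.
#' Per-group generative overrides emulate case/control contrasts in
#' composition, bi-hormonal rate and OXPHOS tier weights.
#'
#' @param config base [sim_config()] shared by all donors.
#' @param n_donors_per_group donors per group.
#' @param group_effects named list (one entry per group) of overrides;
#'   recognised fields: `type_frequencies`, `bihormonal_rate`,
#'   `tier_weights` (list per marker). See [cohort_group_effects()].
#' @param out_dir output directory (created if needed). `NULL` keeps
#'   everything in memory and writes nothing.
#' @param panels staining panels to render per donor.
#' @param donor_ids optional explicit donor ids (length
#'   `2 * n_donors_per_group`); must be unique.
#'
#' @return invisibly, the cohort manifest: donors table (donor_id,
#'   group), file paths (when written), and the per-donor truth tables.
#' @export
generate_cohort <- function(config, n_donors_per_group,
                            group_effects = NULL, out_dir = NULL,
                            panels = c("composition", "NDUFB8", "MTCO1"),
                            donor_ids = NULL) {
  validate_sim_config(config)
  groups <- names(group_effects) %||% c("A", "B")
  if (is.null(group_effects)) group_effects <- setNames(
    rep(list(list()), length(groups)), groups)
  for (g in groups) {
    unknown <- setdiff(names(group_effects[[g]]),
                       c("type_frequencies", "bihormonal_rate", "tier_weights"))
    if (length(unknown))
      stopf("group_effects for '%s' references unknown config fields: %s",
            g, paste(unknown, collapse = ", "))
  }
  donors <- data.frame(
    donor_id = donor_ids %||%
      unlist(lapply(groups, function(g)
        sprintf("%s%02d", g, seq_len(n_donors_per_group)))),
    group = rep(groups, each = n_donors_per_group),
    stringsAsFactors = FALSE)
  if (anyDuplicated(donors$donor_id))
    stopf("duplicate donor ids: %s",
          paste(unique(donors$donor_id[duplicated(donors$donor_id)]),
                collapse = ", "))

  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  files <- list()
  truths <- list()
  for (i in seq_len(nrow(donors))) {
    did <- donors$donor_id[i]
    eff <- group_effects[[donors$group[i]]]
    cfg_i <- config
    if (!is.null(eff$type_frequencies))
      cfg_i$type_frequencies <- eff$type_frequencies
    if (!is.null(eff$bihormonal_rate))
      cfg_i$bihormonal_rate <- eff$bihormonal_rate
    validate_sim_config(cfg_i)
    for (panel in panels) {
      gen <- generate_islet_image(cfg_i, did, panel,
                                  tier_weights = eff$tier_weights)
      key <- paste(did, panel, sep = "_")
      truths[[key]] <- gen$truth$truth_table
      if (!is.null(out_dir)) {
        img_path <- file.path(out_dir, paste0(key, ".tif"))
        write_image(gen$image, img_path)
        write_label_map(gen$truth$cell_label_map,
                        file.path(out_dir, paste0(key, "_cells.tif")))
        write_label_map(gen$truth$islet_label_map,
                        file.path(out_dir, paste0(key, "_islets.tif")))
        write.csv(gen$truth$truth_table,
                  file.path(out_dir, paste0(key, "_truth.csv")),
                  row.names = FALSE)
        files[[key]] <- list(image = img_path,
                             cells = paste0(key, "_cells.tif"),
                             islets = paste0(key, "_islets.tif"),
                             truth = paste0(key, "_truth.csv"))
      }
    }
  }
  manifest <- list(donors = donors, panels = panels,
                   groups = groups, files = files,
                   rng_seed = config$rng_seed)
  if (!is.null(out_dir)) {
    manifest_path <- file.path(out_dir, "cohort_manifest.json")
    jsonlite::write_json(list(donors = donors, panels = panels,
                              groups = groups, rng_seed = config$rng_seed,
                              files = files),
                         manifest_path, auto_unbox = TRUE, pretty = TRUE)
    manifest$path <- manifest_path
  }
  manifest$truth_tables <- truths
  invisible(manifest)
}
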