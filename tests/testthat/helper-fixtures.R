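# Shared fixtures and independent oracles, all built in code.

# Small, fast generator config; noise_free drops PSF and camera noise so
# rendered marker means equal the painted truth exactly.
tiny_cfg <- function(seed = 1L, n_islets = 1L, cells = c(50L, 60L),
                     shape = c(180L, 180L), noise_free = FALSE,
                     arrangement = "jumbled", ...) {
  noise <- if (noise_free) list(poisson_gain = 0, gaussian_sd = 0) else
    list(poisson_gain = 0.5, gaussian_sd = 2)
  sim_config(image_shape = shape, n_islets = n_islets,
             cells_per_islet = cells, arrangement = arrangement,
             noise = noise, psf_sigma = if (noise_free) 0 else 1,
             rng_seed = seed, ...)
}

truth_typed_cells <- function(gen) {
  tt <- gen$truth$truth_table
  data.frame(donor_id = tt$donor_id, islet_id = tt$islet_id,
             cell_id = tt$cell_id, cell_type = tt$true_type,
             stringsAsFactors = FALSE)
}

# Independent O(n^2) contact oracle: explicit pairwise Chebyshev minimum
# distance between the pixel sets of every label pair.
contact_oracle <- function(lab, d) {
  ids <- sort(unique(lab[lab > 0]))
  px <- lapply(ids, function(i) which(lab == i, arr.ind = TRUE))
  out <- NULL
  for (a in seq_along(ids)) for (b in seq_along(ids)) {
    if (b <= a) next
    A <- px[[a]]; B <- px[[b]]
    dmin <- Inf
    for (r in seq_len(nrow(A))) {
      cheb <- pmax(abs(B[, 1] - A[r, 1]), abs(B[, 2] - A[r, 2]))
      dmin <- min(dmin, min(cheb))
      if (dmin <= d) break
    }
    if (dmin <= d) out <- rbind(out, c(ids[a], ids[b]))
  }
  if (is.null(out)) matrix(integer(), 0, 2) else out
}

edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))

# Best-overlap mean Jaccard of a segmentation against a truth label map.
mean_cell_jaccard <- function(truth_lab, seg_lab) {
  ids <- sort(unique(truth_lab[truth_lab > 0]))
  js <- vapply(ids, function(ti) {
    tm <- truth_lab == ti
    cand <- seg_lab[tm]
    cand <- cand[cand > 0]
    if (!length(cand)) return(0)
    si <- as.integer(names(which.max(table(cand))))
    sum(tm & seg_lab == si) / sum(tm | seg_lab == si)
  }, 0)
  mean(js)
}

# Deterministic stratified sample from a two-mode Gaussian mixture
# (exact 50/50 split, quantile-spaced within modes).
bimodal_sample <- function(n_per_mode = 1000, m1 = 10, m2 = 100, s = 5) {
  q <- stats::qnorm(stats::ppoints(n_per_mode))
  c(m1 + s * q, m2 + s * q)
}

# Closed-form one-way ANOVA F for a list of groups (textbook sums of
# squares, independent of the package implementation).
anova_f_oracle <- function(groups) {
  all <- unlist(groups)
  gm <- mean(all)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df1 <- length(groups) - 1
  df2 <- length(all) - length(groups)
  (ssb / df1) / (ssw / df2)
}

# Draw from the generator's ratio tier mixture for one marker.
draw_tier_mixture <- function(n, marker = "NDUFB8", weights = NULL,
                              seed = 1) {
  tp <- default_tier_params()[[marker]]
  w <- if (is.null(weights)) tp$weights else weights / sum(weights)
  set.seed(seed)
  comp <- sample.int(length(w), n, TRUE, prob = w)
  list(ratio = stats::rlnorm(n, tp$meanlog[comp], tp$sdlog[comp]),
       component = comp)
}
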