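# Deterministic classical segmentation: islet masks, nucleus seeding,
# seeded cell delineation. Standard image operators (Gaussian smoothing,
# Otsu, morphology, hole filling, seeded region growing) come from
# EBImage; this module assembles them into the islet-specific pipeline.

#' Islet segmentation parameters
#'
#' @param smooth_sigma Gaussian smoothing sigma (px) before thresholding.
#' @param threshold `"otsu"` or a fixed numeric intensity threshold.
#' @param min_islet_area smallest retained islet (px^2).
#' @param close_radius radius of the morphological closing disc (px).
#' @param foreground_channels channels summed into the foreground signal;
#'   `NULL` = every channel except DAPI (hormone/marker plus membrane
#'   staining jointly delineate endocrine tissue).
#' @param split_touching if `TRUE`, a marker-controlled watershed on the
#'   smoothed foreground splits connected components that contain two or
#'   more strong intensity modes (islets in close proximity).
#' @param split_tolerance watershed mode-depth tolerance (intensity units).
#' @return parameter list.
#' @export
islet_params <- function(smooth_sigma = 2, threshold = "otsu",
                         min_islet_area = 500, close_radius = 5,
                         foreground_channels = NULL,
                         split_touching = FALSE, split_tolerance = 50) {
  list(smooth_sigma = smooth_sigma, threshold = threshold,
       min_islet_area = min_islet_area, close_radius = close_radius,
       foreground_channels = foreground_channels,
       split_touching = split_touching, split_tolerance = split_tolerance)
}

odd_brush <- function(r) EBImage::makeBrush(2L * as.integer(ceiling(r)) + 1L,
                                            shape = "disc")

#' Segment islet regions
#'
#' Foreground = sum of the configured channels, Gaussian-smoothed, then
#' globally thresholded (Otsu on the normalised image, or a fixed value),
#' morphologically closed, hole-filled and labelled as 8-connected
#' components; components below `min_islet_area` are dropped and labels
#' renumbered 1..N. An all-background image yields an empty mask set.
#'
#' @param image a [multichannel_image()].
#' @param params [islet_params()].
#' @return object of class `islet_masks`: `islet_label_map` plus a
#'   per-islet stats table (id, area, centroid, bounding box).
#' @export
segment_islets <- function(image, params = islet_params()) {
  chans <- names(image$channels)
  sel <- params$foreground_channels %||% setdiff(chans, "DAPI")
  missing <- setdiff(sel, chans)
  if (length(missing))
    stopf("foreground channel(s) absent: %s", paste(missing, collapse = ", "))
  fg <- Reduce(`+`, image$channels[sel])
  sm <- gaussian_blur(fg, params$smooth_sigma)
  if (identical(params$threshold, "otsu")) {
    rng <- range(sm)
    if (diff(rng) < 1e-12) {
      lab <- matrix(0L, nrow(sm), ncol(sm))
      return(new_islet_masks(lab))
    }
    thr_n <- EBImage::otsu(EBImage::Image((sm - rng[1]) / diff(rng)))
    thr <- rng[1] + thr_n * diff(rng)
  } else {
    thr <- params$threshold
  }
  bw <- sm > thr
  if (!any(bw)) return(new_islet_masks(matrix(0L, nrow(sm), ncol(sm))))
  bw <- as_mat(EBImage::closing(bw * 1, odd_brush(params$close_radius)))
  bw <- as_mat(EBImage::fillHull(bw))
  if (isTRUE(params$split_touching)) {
    ws <- as_mat(EBImage::watershed(EBImage::Image(sm * (bw > 0)),
                                    tolerance = params$split_tolerance,
                                    ext = 3))
    lab <- ws
  } else {
    lab <- label8(bw > 0)
  }
  # size filter + renumber
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0], max(lab))
    drop <- which(areas < params$min_islet_area)
    if (length(drop)) lab[lab %in% drop] <- 0L
    lab <- relabel_sequential(lab)
  }
  new_islet_masks(lab)
}

new_islet_masks <- function(lab) {
  n <- max(lab)
  if (n > 0) {
    idx <- which(lab > 0)
    lv <- lab[idx]
    rows <- (idx - 1L) %% nrow(lab) + 1L
    cols <- (idx - 1L) %/% nrow(lab) + 1L
    stats <- data.frame(
      islet_id = seq_len(n),
      area = tabulate(lv, n),
      centroid_row = as.vector(rowsum(rows, lv)) / tabulate(lv, n),
      centroid_col = as.vector(rowsum(cols, lv)) / tabulate(lv, n),
      bbox_r0 = as.vector(tapply(rows, lv, min)),
      bbox_r1 = as.vector(tapply(rows, lv, max)),
      bbox_c0 = as.vector(tapply(cols, lv, min)),
      bbox_c1 = as.vector(tapply(cols, lv, max)))
  } else {
    stats <- data.frame(islet_id = integer(), area = integer(),
                        centroid_row = numeric(), centroid_col = numeric(),
                        bbox_r0 = integer(), bbox_r1 = integer(),
                        bbox_c0 = integer(), bbox_c1 = integer())
  }
  structure(list(islet_label_map = lab, stats = stats),
            class = "islet_masks")
}

#' Nucleus detection parameters
#' @param sigmas Laplacian-of-Gaussian scales (px); nucleus radius ~
#'   sigma * sqrt(2).
#' @param min_separation minimum seed separation (px).
#' @param response_frac candidate threshold as a fraction of the maximum
#'   in-mask blob response (scale-invariant).
#' @return parameter list.
#' @export
nuclei_params <- function(sigmas = c(1.4, 2.0, 2.8, 4.0),
                          min_separation = 6, response_frac = 0.15) {
  list(sigmas = sigmas, min_separation = min_separation,
       response_frac = response_frac)
}

log_response <- function(x, sigma) {
  sm <- gaussian_blur(x, sigma)
  lap <- as_mat(EBImage::filter2(sm,
                                 matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3),
                                 boundary = "replicate"))
  -sigma^2 * lap   # bright blobs -> positive scale-normalised response
}

#' Detect nuclei as blob seeds
#'
#' Multiscale scale-normalised Laplacian-of-Gaussian blob detection with
#' greedy non-maximum suppression, restricted to the islet mask. Fully
#' deterministic; an empty result is allowed.
#'
#' @param dapi nuclear-channel matrix.
#' @param islet_mask matrix; nonzero = inside an islet (`NULL` = whole
#'   field).
#' @param params [nuclei_params()].
#' @return `seed_set`: data frame (row, col, score), one seed per
#'   detected nucleus, pairwise separation >= `min_separation`.
#' @export
detect_nuclei <- function(dapi, islet_mask = NULL, params = nuclei_params()) {
  if (is.null(islet_mask)) islet_mask <- matrix(1L, nrow(dapi), ncol(dapi))
  resp <- Reduce(pmax, lapply(params$sigmas, function(s) log_response(dapi, s)))
  resp[islet_mask == 0] <- -Inf
  mx <- max(resp)
  empty <- data.frame(row = integer(), col = integer(), score = numeric())
  if (!is.finite(mx) || mx <= 0) return(structure(empty, class = c("seed_set", "data.frame")))
  thr <- params$response_frac * mx
  # 3x3 local maxima
  dil <- as_mat(EBImage::dilate(pmax(resp, 0), EBImage::makeBrush(3, "box")))
  cand <- which(resp >= dil - 1e-12 & resp > thr)
  if (!length(cand)) return(structure(empty, class = c("seed_set", "data.frame")))
  rows <- (cand - 1L) %% nrow(resp) + 1L
  cols <- (cand - 1L) %/% nrow(resp) + 1L
  sc <- resp[cand]
  ord <- order(sc, decreasing = TRUE)
  rows <- rows[ord]; cols <- cols[ord]; sc <- sc[ord]
  keep <- logical(length(sc))
  for (i in seq_along(sc)) {
    if (i == 1L) { keep[1] <- TRUE; next }
    ki <- which(keep)
    if (min((rows[ki] - rows[i])^2 + (cols[ki] - cols[i])^2) >=
        params$min_separation^2) keep[i] <- TRUE
  }
  structure(data.frame(row = rows[keep], col = cols[keep], score = sc[keep]),
            class = c("seed_set", "data.frame"))
}

#' Fallback seeding from the membrane channel
#'
#' For panels without a nuclear stain, seeds are taken as regularly
#' spaced local maxima of the smoothed, inverted membrane channel (cell
#' interiors are membrane-dark). The result carries
#' `attr(, "method") == "membrane_fallback"` so downstream reports can
#' flag it.
#'
#' @param membrane membrane-channel matrix (e.g. ECAD).
#' @param islet_mask nonzero = inside an islet.
#' @param spacing minimum seed separation (px); of the order of the cell
#'   diameter.
#' @param smooth_sigma smoothing before maxima extraction.
#' @return a `seed_set` as in [detect_nuclei()].
#' @export
membrane_seeds <- function(membrane, islet_mask, spacing = 9,
                           smooth_sigma = 2) {
  inv <- max(membrane) - membrane
  sm <- gaussian_blur(inv, smooth_sigma)
  sm[islet_mask == 0] <- -Inf
  dil <- as_mat(EBImage::dilate(pmax(sm, 0), EBImage::makeBrush(3, "box")))
  cand <- which(sm >= dil - 1e-9 & is.finite(sm) & islet_mask > 0)
  empty <- data.frame(row = integer(), col = integer(), score = numeric())
  if (!length(cand))
    return(structure(empty, class = c("seed_set", "data.frame"),
                     method = "membrane_fallback"))
  rows <- (cand - 1L) %% nrow(sm) + 1L
  cols <- (cand - 1L) %/% nrow(sm) + 1L
  sc <- sm[cand]
  ord <- order(sc, decreasing = TRUE)
  rows <- rows[ord]; cols <- cols[ord]; sc <- sc[ord]
  keep <- logical(length(sc))
  for (i in seq_along(sc)) {
    if (i == 1L) { keep[1] <- TRUE; next }
    ki <- which(keep)
    if (min((rows[ki] - rows[i])^2 + (cols[ki] - cols[i])^2) >= spacing^2)
      keep[i] <- TRUE
  }
  structure(data.frame(row = rows[keep], col = cols[keep], score = sc[keep]),
            class = c("seed_set", "data.frame"), method = "membrane_fallback")
}

#' Cell segmentation parameters
#' @param max_cell_radius hard cap on cell radius (px); no cell pixel may
#'   lie farther than this from its seed.
#' @param lambda regularisation of the seeded region growing (trade-off
#'   between intensity and spatial distance, as in CellProfiler-style
#'   secondary-object propagation).
#' @return parameter list.
#' @export
cell_params <- function(max_cell_radius = 15, lambda = 0.05) {
  list(max_cell_radius = max_cell_radius, lambda = lambda)
}

#' Delineate cells by seeded region growing on the membrane channel
#'
#' Seeds (one per nucleus) grow within the islet mask under
#' intensity-aware propagation on the membrane image (region boundaries
#' settle on membrane ridges), clipped to a disc of `max_cell_radius`
#' around each seed; each surviving cell is the 8-connected component of
#' its region containing the seed. Seeds outside the islet mask are
#' skipped with a warning. Every cell pixel lies inside its parent islet
#' (asserted).
#'
#' @param membrane membrane-channel matrix.
#' @param seeds a `seed_set` ([detect_nuclei()] / [membrane_seeds()]).
#' @param islet_masks an [segment_islets()] result (or an integer islet
#'   label map).
#' @param params [cell_params()].
#' @return `cell_labels`: `cell_label_map` (0 = background) plus a
#'   `parents` table (cell_id, islet_id, seed row/col).
#' @export
segment_cells <- function(membrane, seeds, islet_masks,
                          params = cell_params()) {
  islet_lab <- if (inherits(islet_masks, "islet_masks"))
    islet_masks$islet_label_map else islet_masks
  nr <- nrow(membrane); nc <- ncol(membrane)
  empty <- structure(list(cell_label_map = matrix(0L, nr, nc),
                          parents = data.frame(cell_id = integer(),
                                               islet_id = integer(),
                                               row = integer(),
                                               col = integer())),
                     class = "cell_labels")
  if (!nrow(seeds)) return(empty)
  inside <- islet_lab[cbind(seeds$row, seeds$col)] > 0
  if (any(!inside))
    warnf("%d seed(s) outside the islet mask were skipped", sum(!inside))
  seeds <- seeds[inside, , drop = FALSE]
  if (!nrow(seeds)) return(empty)

  seed_map <- matrix(0L, nr, nc)
  seed_map[cbind(seeds$row, seeds$col)] <- seq_len(nrow(seeds))
  allowed <- matrix(0L, nr, nc)
  allowed <- paint_discs(allowed, cbind(seeds$row, seeds$col),
                         params$max_cell_radius, rep(1L, nrow(seeds)))
  allowed <- allowed * (islet_lab > 0)
  lab <- as_mat(EBImage::propagate(EBImage::Image(membrane / max(membrane, 1)),
                                   seeds = EBImage::Image(seed_map),
                                   mask = allowed > 0,
                                   lambda = params$lambda))
  lab <- matrix(as.integer(round(lab)), nr, nc)
  # hard radius cap + islet consistency
  idx <- which(lab > 0)
  if (length(idx)) {
    lv <- lab[idx]
    rows <- (idx - 1L) %% nr + 1L
    cols <- (idx - 1L) %/% nr + 1L
    d2 <- (rows - seeds$row[lv])^2 + (cols - seeds$col[lv])^2
    bad <- d2 > params$max_cell_radius^2 |
      islet_lab[idx] != islet_lab[cbind(seeds$row, seeds$col)][lv]
    lab[idx[bad]] <- 0L
  }
  # keep, for every cell, only the 8-connected component containing the seed
  idx <- which(lab > 0)
  lv <- lab[idx]
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  by_cell <- split(seq_along(idx), lv)
  for (cid_chr in names(by_cell)) {
    cid <- as.integer(cid_chr)
    sel <- by_cell[[cid_chr]]
    r0 <- min(rows[sel]); r1 <- max(rows[sel])
    c0 <- min(cols[sel]); c1 <- max(cols[sel])
    sub <- matrix(0L, r1 - r0 + 1L, c1 - c0 + 1L)
    sub[cbind(rows[sel] - r0 + 1L, cols[sel] - c0 + 1L)] <- 1L
    comp <- label8(sub)
    keep_comp <- comp[seeds$row[cid] - r0 + 1L, seeds$col[cid] - c0 + 1L]
    if (keep_comp == 0L) { # seed pixel itself trimmed; keep largest component
      keep_comp <- which.max(tabulate(comp[comp > 0]))
    }
    drop <- sel[comp[cbind(rows[sel] - r0 + 1L, cols[sel] - c0 + 1L)] !=
                  keep_comp]
    if (length(drop)) lab[idx[drop]] <- 0L
  }
  parents <- data.frame(cell_id = seq_len(nrow(seeds)),
                        islet_id = islet_lab[cbind(seeds$row, seeds$col)],
                        row = seeds$row, col = seeds$col)
  # nesting invariant, asserted on every run
  stopifnot(all(islet_lab[lab > 0] > 0))
  structure(list(cell_label_map = lab, parents = parents),
            class = "cell_labels")
}
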