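# Per-cell measurement and the cell-cell contact graph (the
# object-neighbour analogue of CellProfiler's MeasureObjectNeighbors).

#' Measure per-cell geometry and channel intensities
#'
#' One record per nonzero label: area (px^2), centroid (1-based row/col),
#' and the arithmetic mean of each channel's pixel intensities over the
#' cell label.
#'
#' @param cell_labels a `cell_labels` object from [segment_cells()], or a
#'   plain integer label matrix.
#' @param image a [multichannel_image()] sharing the label map's shape.
#' @param islet_label_map optional islet map used to assign `islet_id`
#'   when `cell_labels` is a plain matrix.
#' @return cell table data frame (see [write_cell_table()] for the
#'   column contract).
#' @export
measure_cells <- function(cell_labels, image, islet_label_map = NULL) {
  lab <- if (inherits(cell_labels, "cell_labels"))
    cell_labels$cell_label_map else cell_labels
  parents <- if (inherits(cell_labels, "cell_labels"))
    cell_labels$parents else NULL
  if (!all(dim(lab) == dim(image$channels[[1]])))
    stopf("label map shape %s does not match image shape %s",
          paste(dim(lab), collapse = "x"),
          paste(dim(image$channels[[1]]), collapse = "x"))
  idx <- which(lab > 0)
  chans <- names(image$channels)
  if (!length(idx)) {
    out <- data.frame(donor_id = character(), panel_id = character(),
                      islet_id = integer(), cell_id = integer(),
                      row = numeric(), col = numeric(), area = integer())
    for (ch in chans) out[[paste0("mean_", ch)]] <- numeric()
    return(out)
  }
  lv <- lab[idx]
  ids <- sort(unique(lv))
  counts <- tabulate(lv, max(lv))[ids]
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L
  f <- factor(lv, levels = ids)
  out <- data.frame(
    donor_id = image$donor_id, panel_id = image$panel_id,
    islet_id = NA_integer_, cell_id = ids,
    row = as.vector(rowsum(rows, f)) / counts,
    col = as.vector(rowsum(cols, f)) / counts,
    area = counts, stringsAsFactors = FALSE)
  for (ch in chans)
    out[[paste0("mean_", ch)]] <-
      as.vector(rowsum(image$channels[[ch]][idx], f)) / counts
  if (!is.null(parents)) {
    out$islet_id <- parents$islet_id[match(out$cell_id, parents$cell_id)]
  } else if (!is.null(islet_label_map)) {
    mode_islet <- tapply(islet_label_map[idx], f, function(v) {
      v <- v[v > 0]
      if (!length(v)) NA_integer_ else as.integer(names(which.max(table(v))))
    })
    out$islet_id <- as.integer(mode_islet)
  }
  out
}

#' Build the cell-cell contact graph
#'
#' Edge (i, j) iff the dilation of label i by the Chebyshev ball (square
#' structuring element) of radius `contact_distance` intersects label j -
#' equivalently, iff some pixel of i and some pixel of j are within
#' Chebyshev distance `contact_distance`. With `contact_distance = 1`,
#' 8-adjacent labels touch. The graph is simple and symmetric by
#' construction, and edges never join cells of different islets.
#'
#' @param cell_labels a `cell_labels` object or plain label matrix.
#' @param contact_distance dilation radius in px (>= 0); default 2
#'   (touching or nearly touching cells count as neighbours).
#' @param islet_ids optional vector mapping cell id -> islet id (taken
#'   from `cell_labels$parents` when available).
#' @return `contact_graph`: list with `edges` (islet_id, cell_a, cell_b;
#'   cell_a < cell_b) and `nodes` (cell_id, islet_id, degree).
#' @export
build_contact_graph <- function(cell_labels, contact_distance = 2,
                                islet_ids = NULL) {
  if (contact_distance < 0) stopf("contact_distance must be >= 0")
  lab <- if (inherits(cell_labels, "cell_labels"))
    cell_labels$cell_label_map else cell_labels
  if (is.null(islet_ids) && inherits(cell_labels, "cell_labels"))
    islet_ids <- setNames(cell_labels$parents$islet_id,
                          cell_labels$parents$cell_id)
  d <- as.integer(floor(contact_distance))
  nr <- nrow(lab); nc <- ncol(lab)
  ids <- sort(unique(lab[lab > 0]))
  pairs <- list()
  if (d >= 1L && length(ids) >= 2L) {
    offs <- expand.grid(di = -d:d, dj = 0:d)
    offs <- offs[offs$dj > 0 | (offs$dj == 0 & offs$di > 0), , drop = FALSE]
    for (k in seq_len(nrow(offs))) {
      di <- offs$di[k]; dj <- offs$dj[k]
      ri <- max(1L, 1L - di):min(nr, nr - di)
      cj <- max(1L, 1L - dj):min(nc, nc - dj)
      a <- lab[ri, cj, drop = FALSE]
      b <- lab[ri + di, cj + dj, drop = FALSE]
      sel <- a > 0 & b > 0 & a != b
      if (any(sel))
        pairs[[length(pairs) + 1L]] <- cbind(pmin(a[sel], b[sel]),
                                             pmax(a[sel], b[sel]))
    }
  }
  edges <- if (length(pairs)) unique(do.call(rbind, pairs)) else
    matrix(integer(), 0, 2)
  nodes <- data.frame(cell_id = ids,
                      islet_id = if (!is.null(islet_ids))
                        as.integer(islet_ids[as.character(ids)]) else
                          NA_integer_)
  ed <- data.frame(cell_a = as.integer(edges[, 1]),
                   cell_b = as.integer(edges[, 2]))
  if (!is.null(islet_ids)) {
    ia <- nodes$islet_id[match(ed$cell_a, nodes$cell_id)]
    ib <- nodes$islet_id[match(ed$cell_b, nodes$cell_id)]
    ed <- ed[!is.na(ia) & !is.na(ib) & ia == ib, , drop = FALSE]
    ed$islet_id <- nodes$islet_id[match(ed$cell_a, nodes$cell_id)]
  } else {
    ed$islet_id <- rep(NA_integer_, nrow(ed))
  }
  ed <- ed[order(ed$cell_a, ed$cell_b), c("islet_id", "cell_a", "cell_b")]
  rownames(ed) <- NULL
  deg <- table(factor(c(ed$cell_a, ed$cell_b), levels = ids))
  nodes$degree <- as.integer(deg)
  structure(list(edges = ed, nodes = nodes), class = "contact_graph")
}

#' @export
print.contact_graph <- function(x, ...) {
  cat(sprintf("<contact_graph> %d cells, %d contacts\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}
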