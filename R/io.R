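# Image, label-map, cell-table and config I/O with panel-contract
# validation. Conventions used throughout the package: 0-based pixel
# coordinates are never used -- everything is 1-based (row, col) with the
# origin at the top-left, all distances in pixel units.

#' Multi-channel image container
#'
#' Named 2-D nonnegative intensity channels of identical shape, plus the
#' identifiers the pipeline carries along (donor, panel).
#'
#' @param channels named list of numeric matrices, one per channel.
#' @param donor_id,panel_id identifiers recorded in downstream tables.
#' @param pixel_size microns per pixel (optional, informational).
#' @return object of class `mc_image`.
#' @export
multichannel_image <- function(channels, donor_id = NA_character_,
                               panel_id = NA_character_, pixel_size = NA_real_) {
  if (!length(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels))))
    stopf("channels must be a non-empty named list")
  shapes <- vapply(channels, function(m) paste(dim(m), collapse = "x"), "")
  if (length(unique(shapes)) != 1L)
    stopf("channel shape mismatch: %s",
          paste(unique(shapes), collapse = " vs "))
  if (any(vapply(channels, function(m) any(m < 0), logical(1))))
    stopf("channel intensities must be nonnegative")
  structure(list(channels = channels, donor_id = donor_id,
                 panel_id = panel_id, pixel_size = pixel_size),
            class = "mc_image")
}

#' @export
print.mc_image <- function(x, ...) {
  cat(sprintf("<mc_image> donor=%s panel=%s %s px, channels: %s\n",
              x$donor_id, x$panel_id,
              paste(dim(x$channels[[1]]), collapse = "x"),
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

required_channels <- function(panel) {
  switch(panel,
         composition = list(fixed = c("DAPI", "ECAD", "INS", "GCG"),
                            one_of = character()),
         mitochondrial = list(fixed = c("ECAD", "INS", "VDAC1"),
                              one_of = c("NDUFB8", "MTCO1")),
         NDUFB8 = list(fixed = c("ECAD", "INS", "VDAC1", "NDUFB8"),
                       one_of = character()),
         MTCO1 = list(fixed = c("ECAD", "INS", "VDAC1", "MTCO1"),
                      one_of = character()),
         stopf("unknown panel '%s'", panel))
}

#' Validate an image against a staining-panel contract
#'
#' The composition panel requires DAPI, ECAD, INS, GCG; the mitochondrial
#' panel requires ECAD, INS, VDAC1 and exactly one of NDUFB8 / MTCO1
#' (`panel = "NDUFB8"` / `"MTCO1"` pin the marker).
#'
#' @param image a [multichannel_image()].
#' @param panel panel name.
#' @return the image, invisibly; errors list any missing channel names.
#' @export
validate_panel <- function(image, panel) {
  req <- required_channels(panel)
  have <- names(image$channels)
  missing <- setdiff(req$fixed, have)
  if (length(req$one_of)) {
    hits <- intersect(req$one_of, have)
    if (length(hits) == 0L)
      missing <- c(missing, paste(req$one_of, collapse = " | "))
    if (length(hits) > 1L)
      stopf("panel '%s' allows exactly one of %s; image has %s", panel,
            paste(req$one_of, collapse = ", "), paste(hits, collapse = ", "))
  }
  if (length(missing))
    stopf("image does not satisfy panel '%s': missing channel(s) %s",
          panel, paste(missing, collapse = ", "))
  invisible(image)
}

#' Split a multi-channel image into single-channel images
#' @param image a [multichannel_image()].
#' @return named list of single-channel `mc_image` objects.
#' @export
split_channels <- function(image) {
  lapply(setNames(names(image$channels), names(image$channels)), function(ch)
    multichannel_image(image$channels[ch], image$donor_id, image$panel_id,
                       image$pixel_size))
}

#' Write / read a multi-channel image as multi-page 16-bit TIFF
#'
#' Intensities are floating point; on write they are scaled into the
#' 16-bit range by a recorded per-file scale factor, stored with the
#' channel names and identifiers in a JSON sidecar (`<path>.json`).
#' Round trips are lossless to the declared 16-bit precision
#' (`scale / 65535` absolute).
#'
#' @param image a [multichannel_image()].
#' @param path TIFF path; sidecar written to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  scale <- max(1e-12, max(vapply(image$channels, max, 0)))
  pages <- lapply(image$channels, function(m) m / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(channels = names(image$channels), donor_id = image$donor_id,
         panel_id = image$panel_id, pixel_size = image$pixel_size,
         scale = scale),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_image
#' @param panel panel contract to validate against (`NULL` skips).
#' @export
read_image <- function(path, panel = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  side <- paste0(path, ".json")
  if (!file.exists(side))
    stopf("missing channel-name sidecar: %s", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != length(meta$channels))
    stopf("page/channel count mismatch in %s: %d pages, %d channel names",
          path, length(pages), length(meta$channels))
  chans <- lapply(pages, function(p) {
    if (length(dim(p)) > 2) p <- p[, , 1]
    p * meta$scale
  })
  names(chans) <- meta$channels
  img <- multichannel_image(chans, donor_id = meta$donor_id %||% NA_character_,
                            panel_id = meta$panel_id %||% NA_character_,
                            pixel_size = meta$pixel_size %||% NA_real_)
  if (!is.null(panel)) validate_panel(img, panel)
  img
}

#' Write / read integer label maps as 16-bit TIFF
#'
#' Labels up to 65535 round-trip exactly. `read_label_map` refuses
#' images whose pixel values are not integers at 16-bit precision.
#'
#' @param lab integer matrix (0 = background).
#' @param path TIFF path.
#' @return `path` invisibly / the integer matrix.
#' @export
write_label_map <- function(lab, path) {
  if (any(lab != round(lab))) stopf("label map must be integer-valued")
  if (max(lab) > 65535L) stopf("labels exceed 16-bit range")
  tiff::writeTIFF(lab / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  x <- tiff::readTIFF(path)
  if (length(dim(x)) > 2) x <- x[, , 1]
  v <- x * 65535
  if (max(abs(v - round(v))) > 1e-6)
    stopf("non-integer label image: %s", path)
  matrix(as.integer(round(v)), nrow(x), ncol(x))
}

# Fixed, documented cell-table column order. Mean-intensity columns
# (mean_<CHANNEL>) follow in the order the channels appear in the image.
CELL_TABLE_KEYS <- c("donor_id", "panel_id", "islet_id", "cell_id",
                     "row", "col", "area")

#' Write / read per-cell measurement tables as CSV
#'
#' Column order is fixed: donor_id, panel_id, islet_id, cell_id, row,
#' col, area, then one `mean_<CHANNEL>` column per channel. Centroids are
#' 1-based (row, col) pixel coordinates, origin top-left; areas in px^2.
#' (donor_id, islet_id, cell_id) must be unique per row.
#'
#' @param tab cell table data frame.
#' @param path CSV path.
#' @return `path` invisibly / the data frame (0 rows for a header-only
#'   file).
#' @export
write_cell_table <- function(tab, path) {
  validate_cell_table(tab)
  keys <- intersect(CELL_TABLE_KEYS, names(tab))
  tab <- tab[, c(keys, setdiff(names(tab), keys)), drop = FALSE]
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  validate_cell_table(tab)
  tab
}

validate_cell_table <- function(tab) {
  missing <- setdiff(c("donor_id", "islet_id", "cell_id"), names(tab))
  if (length(missing))
    stopf("cell table lacks key column(s): %s", paste(missing, collapse = ", "))
  key <- paste(tab$donor_id, tab$islet_id, tab$cell_id)
  if (anyDuplicated(key))
    stopf("duplicate (donor_id, islet_id, cell_id) keys in cell table")
  if ("area" %in% names(tab) && nrow(tab) && any(tab$area < 1))
    stopf("cell areas must be >= 1 px^2")
  invisible(tab)
}
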