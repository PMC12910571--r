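# Islet masks, nucleus seeding, cell delineation.

test_that("a blank image yields zero islets, not an error", {
  img <- multichannel_image(list(DAPI = matrix(0, 60, 60),
                                 ECAD = matrix(0, 60, 60),
                                 INS = matrix(0, 60, 60),
                                 GCG = matrix(0, 60, 60)))
  masks <- segment_islets(img)
  expect_identical(nrow(masks$stats), 0L)
  expect_true(all(masks$islet_label_map == 0L))
})

test_that("a uniform bright ellipse is recovered with the analytic area", {
  a <- 40; b <- 25
  rows <- matrix(rep(1:160, 160), 160)
  cols <- t(rows)
  ins <- ifelse(((rows - 80) / a)^2 + ((cols - 80) / b)^2 <= 1, 200, 0)
  img <- multichannel_image(list(INS = ins, GCG = matrix(0, 160, 160),
                                 ECAD = matrix(0, 160, 160),
                                 DAPI = matrix(0, 160, 160)))
  masks <- segment_islets(img)
  expect_identical(nrow(masks$stats), 1L)
  expect_lt(abs(masks$stats$area - pi * a * b) / (pi * a * b), 0.05)
})

test_that("well-separated synthetic islets are recovered with Jaccard >= 0.9", {
  cfg <- tiny_cfg(seed = 11, n_islets = 3L, cells = c(50L, 70L),
                  shape = c(400L, 400L))
  gen <- generate_islet_image(cfg, "D1", "composition")
  masks <- segment_islets(gen$image)
  expect_identical(nrow(masks$stats), 3L)
  tl <- gen$truth$islet_label_map
  sl <- masks$islet_label_map
  for (ti in 1:3) {
    j <- max(vapply(seq_len(max(sl)), function(si) {
      sum(tl == ti & sl == si) / sum(tl == ti | sl == si)
    }, 0))
    expect_gte(j, 0.9)
  }
})

test_that("nucleus detection handles empty, single-blob and crowded fields", {
  # zero-intensity DAPI -> empty seed set
  s0 <- detect_nuclei(matrix(0, 50, 50))
  expect_identical(nrow(s0), 0L)
  # one Gaussian blob within the scale range -> one seed at the centre
  blob <- matrix(0, 51, 51); blob[26, 26] <- 1000
  blob <- isletkit:::gaussian_blur(blob, 2.2)
  s1 <- detect_nuclei(blob)
  expect_identical(nrow(s1), 1L)
  expect_lte(max(abs(c(s1$row, s1$col) - 26)), 1)
  # 50-nucleus islet at default noise: count within 2, localisation 3 px
  cfg <- tiny_cfg(seed = 19, cells = c(50L, 50L), shape = c(200L, 200L))
  gen <- generate_islet_image(cfg, "D1", "composition")
  seeds <- detect_nuclei(gen$image$channels$DAPI,
                         gen$truth$islet_label_map)
  expect_gte(nrow(seeds), 48)
  expect_lte(nrow(seeds), 52)
  tt <- gen$truth$truth_table
  dmin <- apply(sqrt(outer(seeds$row, tt$row, "-")^2 +
                       outer(seeds$col, tt$col, "-")^2), 1, min)
  expect_gte(mean(dmin <= 3), 0.95)
})

test_that("membrane fallback seeding covers panels without a nuclear stain", {
  cfg <- tiny_cfg(seed = 23, cells = c(50L, 50L), shape = c(200L, 200L))
  gen <- generate_islet_image(cfg, "D1", "NDUFB8")
  seeds <- membrane_seeds(gen$image$channels$ECAD,
                          gen$truth$islet_label_map, spacing = 8)
  expect_identical(attr(seeds, "method"), "membrane_fallback")
  expect_gt(nrow(seeds), 35)
  cells <- segment_cells(gen$image$channels$ECAD, seeds,
                         gen$truth$islet_label_map)
  expect_gt(nrow(cells$parents), 35)
})

test_that("one seed in a uniform disc grows to the radius cap", {
  rows <- matrix(rep(1:81, 81), 81); cols <- t(rows)
  mask <- ((rows - 41)^2 + (cols - 41)^2 <= 35^2) * 1L
  membrane <- matrix(1, 81, 81)
  seeds <- structure(data.frame(row = 41L, col = 41L, score = 1),
                     class = c("seed_set", "data.frame"))
  cells <- segment_cells(membrane, seeds, mask,
                         cell_params(max_cell_radius = 15))
  expect_identical(sort(unique(as.vector(cells$cell_label_map))), c(0L, 1L))
  area <- sum(cells$cell_label_map == 1L)
  expect_lt(abs(area - pi * 15^2) / (pi * 15^2), 0.1)
  expect_lte(area, pi * 15^2 * 1.1)
})

test_that("two seeds split a two-cell islet along the membrane ridge", {
  # vertical membrane ridge at column 31 inside a 2-cell rectangle islet
  nr <- 40; nc <- 61
  mask <- matrix(0L, nr, nc); mask[6:35, 6:56] <- 1L
  membrane <- matrix(1, nr, nc); membrane[, 31] <- 300
  membrane <- isletkit:::gaussian_blur(membrane, 1)
  seeds <- structure(data.frame(row = c(20L, 20L), col = c(18L, 44L),
                                score = 1),
                     class = c("seed_set", "data.frame"))
  cells <- segment_cells(membrane, seeds, mask,
                         cell_params(max_cell_radius = 20))
  lab <- cells$cell_label_map
  expect_identical(sort(unique(lab[lab > 0])), c(1L, 2L))
  # the label boundary must hug the ridge midline (col 31) for >= 90%
  bnd <- which(lab[, -nc] > 0 & lab[, -1] > 0 & lab[, -nc] != lab[, -1],
               arr.ind = TRUE)
  expect_gt(nrow(bnd), 10)
  expect_gte(mean(abs(bnd[, 2] + 0.5 - 31) <= 2), 0.9)
})

test_that("noise-free cell segmentation reaches Jaccard >= 0.85 and nests", {
  cfg <- tiny_cfg(seed = 31, n_islets = 2L, cells = c(50L, 60L),
                  shape = c(300L, 300L), noise_free = TRUE)
  gen <- generate_islet_image(cfg, "D1", "composition")
  masks <- segment_islets(gen$image)
  seeds <- detect_nuclei(gen$image$channels$DAPI, masks$islet_label_map)
  cells <- segment_cells(gen$image$channels$ECAD, seeds, masks)
  expect_gte(mean_cell_jaccard(gen$truth$cell_label_map,
                               cells$cell_label_map), 0.85)
  # nesting: every cell pixel inside its parent islet
  expect_true(all(masks$islet_label_map[cells$cell_label_map > 0] > 0))
  # determinism: identical inputs give identical label maps
  cells2 <- segment_cells(gen$image$channels$ECAD, seeds, masks)
  expect_identical(cells$cell_label_map, cells2$cell_label_map)
})

test_that("segmentation quality degrades monotonically with noise", {
  js <- vapply(c(0, 25, 70), function(sg) {
    cfg <- tiny_cfg(seed = 37, n_islets = 1L, cells = c(55L, 55L),
                    shape = c(200L, 200L))
    cfg$noise$gaussian_sd <- sg
    gen <- generate_islet_image(cfg, "D1", "composition")
    masks <- segment_islets(gen$image)
    seeds <- detect_nuclei(gen$image$channels$DAPI, masks$islet_label_map)
    cells <- segment_cells(gen$image$channels$ECAD, seeds, masks)
    mean_cell_jaccard(gen$truth$cell_label_map, cells$cell_label_map)
  }, 0)
  expect_true(all(diff(js) <= 0),
              info = paste("jaccards:", paste(round(js, 3), collapse = " ")))
})

test_that("seeds outside the islet mask are skipped with a warning", {
  mask <- matrix(0L, 40, 40); mask[10:30, 10:30] <- 1L
  seeds <- structure(data.frame(row = c(20L, 2L), col = c(20L, 2L),
                                score = 1),
                     class = c("seed_set", "data.frame"))
  expect_warning(cells <- segment_cells(matrix(1, 40, 40), seeds, mask),
                 "outside the islet mask")
  expect_identical(nrow(cells$parents), 1L)
})
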