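# Donor-adaptive thresholds, typing, eligibility, composition and
# contact architecture.

cells_df <- function(donor, ins, gcg, islet = 1L) {
  data.frame(donor_id = donor, panel_id = "composition", islet_id = islet,
             cell_id = seq_along(ins), row = 1, col = 1, area = 10L,
             mean_INS = ins, mean_GCG = gcg, stringsAsFactors = FALSE)
}

test_that("constant intensities give threshold = c and no positives", {
  tab <- cells_df("D1", ins = rep(7, 25), gcg = rep(3, 25))
  thr <- compute_thresholds(tab, "INS")
  expect_identical(thr$value, 7)
  ty <- classify_cells(tab, rbind(thr, compute_thresholds(tab, "GCG")))
  expect_false(any(ty$pos_INS))   # strict '>' positivity
  expect_true(all(ty$cell_type == "other"))
})

test_that("bimodal thresholds separate the modes", {
  x <- bimodal_sample(1000, m1 = 10, m2 = 100, s = 5)
  tab <- cells_df("D1", ins = x, gcg = rep(1, length(x)))
  thr <- compute_thresholds(tab, "INS", k = 2)
  expect_gt(thr$value, 30)
  expect_lt(thr$value, 90)
  # classification error at that threshold is at most 1%
  truth_hi <- rep(c(FALSE, TRUE), each = 1000)
  called_hi <- x > thr$value
  expect_lte(mean(called_hi != truth_hi), 0.01)
})

test_that("thresholds are scale-equivariant", {
  set.seed(8)
  x <- rlnorm(500, 3, 0.6)
  t1 <- compute_thresholds(cells_df("D1", x, x), "INS", k = 1.5)
  t2 <- compute_thresholds(cells_df("D1", 2 * x, x), "INS", k = 1.5)
  expect_equal(t2$value, 2 * t1$value, tolerance = 1e-12)
  expect_equal(t2$scale, 2 * t1$scale, tolerance = 1e-12)
  expect_equal(pmax(t2$mean, t2$median), 2 * pmax(t1$mean, t1$median),
               tolerance = 1e-12)
  # value never below the location anchor
  expect_gte(t1$value, max(t1$mean, t1$median))
})

test_that("thresholds warn below 20 cells and error on empty input", {
  expect_warning(compute_thresholds(cells_df("D1", 1:5, 1:5), "INS"),
                 "< 20")
  expect_error(compute_thresholds(cells_df("D1", 1, 1)[0, ], "INS"),
               "empty")
})

test_that("classification follows the positivity contract", {
  tab <- rbind(cells_df("D1", ins = c(rep(10, 30), 200, 200, 200),
                        gcg = c(rep(10, 30), 5, 300, 5)))
  thr <- rbind(compute_thresholds(tab, "INS"),
               compute_thresholds(tab, "GCG"))
  t_ins <- thr$value[thr$channel == "INS"]
  t_gcg <- thr$value[thr$channel == "GCG"]
  probe <- cells_df("D1",
                    ins = c(t_ins + 1e-6, t_ins + 1, t_ins - 1e-6),
                    gcg = c(t_gcg - 1e-6, t_gcg + 1, t_gcg + 1e-6))
  ty <- classify_cells(probe, thr)
  expect_identical(ty$cell_type, c("beta", "bihormonal", "alpha"))
  expect_error(classify_cells(cells_df("D9", 1, 1), thr), "D9")
})

test_that("classification is invariant under joint monotone rescaling", {
  set.seed(12)
  tab <- cells_df("D1", ins = rlnorm(300, 4, 1), gcg = rlnorm(300, 3, 1))
  thr <- rbind(compute_thresholds(tab, "INS"), compute_thresholds(tab, "GCG"))
  ty1 <- classify_cells(tab, thr)
  tab2 <- tab
  tab2$mean_INS <- tab$mean_INS * 5
  tab2$mean_GCG <- tab$mean_GCG * 5
  thr2 <- rbind(compute_thresholds(tab2, "INS"),
                compute_thresholds(tab2, "GCG"))
  ty2 <- classify_cells(tab2, thr2)
  expect_identical(ty1$cell_type, ty2$cell_type)
})

test_that("type calls reach 95% accuracy on a default-SNR cohort", {
  acc_n <- 0; acc_ok <- 0
  for (d in c("D1", "D2")) {
    gen <- generate_islet_image(tiny_cfg(seed = 61, n_islets = 2L,
                                         cells = c(60L, 80L),
                                         shape = c(300L, 300L)),
                                d, "composition")
    m <- measure_cells(gen$truth$cell_label_map, gen$image,
                       gen$truth$islet_label_map)
    thr <- rbind(compute_thresholds(m, "INS"), compute_thresholds(m, "GCG"))
    ty <- classify_cells(m, thr)
    truth <- gen$truth$truth_table$true_type[
      match(m$cell_id, gen$truth$truth_table$cell_id)]
    acc_n <- acc_n + length(truth)
    acc_ok <- acc_ok + sum(ty$cell_type == truth)
  }
  expect_gte(acc_ok / acc_n, 0.95)
})

test_that("islet eligibility uses a strict > 10 insulin-positive cut", {
  mk <- function(islet, n_pos, n_neg) data.frame(
    donor_id = "D1", islet_id = islet, cell_id = seq_len(n_pos + n_neg),
    pos_INS = rep(c(TRUE, FALSE), c(n_pos, n_neg)))
  cells <- rbind(mk(1L, 10L, 5L), mk(2L, 11L, 5L), mk(3L, 0L, 8L))
  el <- filter_eligible_islets(cells, min_beta = 10)
  expect_identical(el$islet_id, 2L)
  expect_identical(nrow(filter_eligible_islets(cells[0, ])), 0L)
})

test_that("composition summaries reproduce hand-computed quantities", {
  mk <- function(donor, islet, types) data.frame(
    donor_id = donor, islet_id = islet,
    cell_id = seq_along(types), cell_type = types,
    stringsAsFactors = FALSE)
  # islet with 4 alpha and 8 beta -> ratio 0.5
  s1 <- summarise_composition(mk("D1", 1L, rep(c("alpha", "beta"), c(4, 8))))
  expect_identical(s1$islets$alpha_beta_ratio, 0.5)
  # no beta cells -> undefined ratio, flagged
  s2 <- summarise_composition(mk("D1", 1L, rep("alpha", 5)))
  expect_true(s2$islets$ratio_undefined)
  expect_true(is.na(s2$islets$alpha_beta_ratio))
  # printed cohort totals: alpha 10,232 / beta 7,964 -> aggregate 1.2848...
  s3 <- summarise_composition(mk("T2D", 1L,
                                 rep(c("alpha", "beta"), c(10232, 7964))))
  expect_equal(s3$overall$alpha_beta_ratio, 10232 / 7964, tolerance = 1e-12)
  expect_equal(round(s3$overall$alpha_beta_ratio, 4), 1.2848)
  # 169 bi-hormonal among 35,733 cells -> prevalence 0.473%
  s4 <- summarise_composition(
    mk("ALL", 1L, rep(c("alpha", "beta", "bihormonal"),
                      c(16197, 19367, 169))))
  expect_identical(s4$overall$total, 35733L)
  expect_equal(round(s4$overall$bihormonal_prevalence_pct, 3), 0.473)
})

test_that("contact-pair proportions match hand enumeration", {
  ty <- data.frame(donor_id = "D1", islet_id = 1L, cell_id = 1:7,
                   cell_type = c("alpha", "alpha", "alpha",
                                 "beta", "beta", "beta", "beta"))
  # two all-beta cells and one edge -> 100% beta-beta
  g_bb <- structure(list(
    edges = data.frame(islet_id = 1L, cell_a = 4L, cell_b = 5L),
    nodes = data.frame(cell_id = 4:5, islet_id = 1L, degree = 1L)),
    class = "contact_graph")
  cp <- contact_proportions(g_bb, ty[ty$cell_id %in% 4:5, ])
  expect_equal(unname(cp$overall$pct_beta_beta), 100)
  # triangle alpha-beta-beta -> pairs {ab, ab, bb}
  g_tri <- structure(list(
    edges = data.frame(islet_id = 1L, cell_a = c(1L, 1L, 4L),
                       cell_b = c(4L, 5L, 5L)),
    nodes = data.frame(cell_id = c(1L, 4L, 5L), islet_id = 1L,
                       degree = 2L)),
    class = "contact_graph")
  cp2 <- contact_proportions(g_tri, ty[ty$cell_id %in% c(1, 4, 5), ])
  expect_equal(unname(cp2$overall$pct_beta_alpha), 200 / 3, tolerance = 1e-9)
  expect_equal(unname(cp2$overall$pct_beta_beta), 100 / 3, tolerance = 1e-9)
  # workflow-schematic islet: 3 alpha + 4 beta with a drawn contact list
  edges <- data.frame(islet_id = 1L,
                      cell_a = c(1L, 1L, 2L, 2L, 3L, 4L, 5L, 6L, 4L),
                      cell_b = c(2L, 4L, 3L, 5L, 6L, 5L, 6L, 7L, 7L))
  g_fig <- structure(list(edges = edges,
                          nodes = data.frame(cell_id = 1:7, islet_id = 1L,
                                             degree = 2L)),
                     class = "contact_graph")
  cp3 <- contact_proportions(g_fig, ty)
  # hand enumeration: aa = {12,23}, ab = {14,25,36}, bb = {45,56,67,47}
  expect_equal(unname(cp3$overall$alpha_alpha), 2)
  expect_equal(unname(cp3$overall$beta_alpha), 3)
  expect_equal(unname(cp3$overall$beta_beta), 4)
  expect_equal(unname(cp3$overall$pct_beta_beta), 400 / 9, tolerance = 1e-9)
  # percentages over the three-way total always sum to 100
  expect_equal(unname(cp3$overall$pct_alpha_alpha +
                        cp3$overall$pct_beta_alpha +
                        cp3$overall$pct_beta_beta), 100, tolerance = 1e-6)
  # cell-level fractions: all four beta cells have a beta neighbour
  expect_equal(cp3$cell_level$frac_beta_with_beta, 1)
  expect_equal(cp3$cell_level$frac_alpha_with_alpha, 1)
})

test_that("bihormonal and other cells are excluded from pair percentages", {
  ty <- data.frame(donor_id = "D1", islet_id = 1L, cell_id = 1:3,
                   cell_type = c("beta", "bihormonal", "beta"))
  g <- structure(list(
    edges = data.frame(islet_id = 1L, cell_a = c(1L, 2L), cell_b = c(2L, 3L)),
    nodes = data.frame(cell_id = 1:3, islet_id = 1L, degree = c(1L, 2L, 1L))),
    class = "contact_graph")
  cp <- contact_proportions(g, ty)
  expect_equal(unname(cp$overall$other_pair), 2)
  expect_true(is.na(cp$overall$pct_beta_beta))  # no typed pairs at all
})

test_that("jumbled null is degenerate for single-type islets", {
  ty <- data.frame(donor_id = "D1", islet_id = 1L, cell_id = 1:4,
                   cell_type = "beta")
  g <- build_contact_graph(matrix(c(0L, 1L, 2L, 0L, 3L, 4L, 0L, 0L, 0L),
                                  3, 3), 1)
  jn <- jumbled_null(g, ty, n_perm = 199, seed = 4)
  expect_equal(unname(jn$p), rep(1, 3))
  expect_equal(unname(jn$observed["beta_beta"]), 100)
  expect_equal(jn$observed, jn$expected)
  expect_error(jumbled_null(g, ty, n_perm = 50), ">= 100")
})

test_that("jumbled null is reproducible and detects mantle-core structure", {
  # a detectable alpha mantle needs >= 2 cell layers, hence ~140-cell islets
  hits <- 0
  for (i in 1:10) {
    cfg <- tiny_cfg(seed = 400 + i, cells = c(140L, 140L),
                    shape = c(322L, 322L), noise_free = TRUE,
                    arrangement = "mantle_core")
    gen <- generate_islet_image(cfg, "M", "composition")
    g <- build_contact_graph(gen$truth$cell_label_map, 2)
    cells <- truth_typed_cells(gen)
    jn <- jumbled_null(g, cells, n_perm = 999, seed = 900 + i)
    if (i == 1) {
      jn2 <- jumbled_null(g, cells, n_perm = 999, seed = 900 + i)
      expect_identical(jn2$p, jn$p)
    }
    if (jn$observed["alpha_alpha"] > jn$expected["alpha_alpha"] &&
        jn$p["alpha_alpha"] < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("jumbled pair percentages converge to the product form", {
  cfg <- tiny_cfg(seed = 71, cells = c(500L, 500L), shape = c(420L, 420L),
                  noise_free = TRUE, bihormonal_rate = 0)
  gen <- generate_islet_image(cfg, "BIG", "composition")
  g <- build_contact_graph(gen$truth$cell_label_map, 2)
  cells <- truth_typed_cells(gen)
  cp <- contact_proportions(g, cells)
  # product-form expectation at the islet's realised type fractions
  p_a <- mean(cells$cell_type == "alpha")
  p_b <- mean(cells$cell_type == "beta")
  exp_bb <- 100 * p_b^2 / (p_a + p_b)^2
  exp_aa <- 100 * p_a^2 / (p_a + p_b)^2
  expect_lt(abs(cp$overall$pct_beta_beta - exp_bb), 2)
  expect_lt(abs(cp$overall$pct_alpha_alpha - exp_aa), 2)
})

test_that("classified bi-hormonal prevalence is unbiased over seeds", {
  rate <- 0.00473
  n_tot <- 0; n_bih <- 0
  for (i in 1:20) {
    gen <- generate_islet_image(tiny_cfg(seed = 700 + i, n_islets = 1L,
                                         cells = c(90L, 90L),
                                         shape = c(200L, 200L)),
                                "U", "composition")
    m <- measure_cells(gen$truth$cell_label_map, gen$image,
                       gen$truth$islet_label_map)
    thr <- rbind(compute_thresholds(m, "INS"), compute_thresholds(m, "GCG"))
    ty <- classify_cells(m, thr)
    n_tot <- n_tot + nrow(ty)
    n_bih <- n_bih + sum(ty$cell_type == "bihormonal")
  }
  se <- sqrt(rate * (1 - rate) / n_tot)
  expect_lt(abs(n_bih / n_tot - rate), 2 * se + 1e-9)
})
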