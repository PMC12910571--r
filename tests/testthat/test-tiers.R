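# OXPHOS ratios, k-means tiering with elbow selection, ANOVA validation,
# donor profiles.

mito_cells <- function(donor, ins_pos, marker, vdac, islet = 1L) {
  data.frame(donor_id = donor, panel_id = "NDUFB8", islet_id = islet,
             cell_id = seq_along(marker), row = 1, col = 1, area = 10L,
             mean_INS = ifelse(ins_pos, 100, 1), mean_NDUFB8 = marker,
             mean_VDAC1 = vdac, pos_INS = ins_pos,
             stringsAsFactors = FALSE)
}

test_that("ratios divide marker by VDAC1 on INS-positive cells only", {
  tab <- mito_cells("D1", ins_pos = c(TRUE, TRUE, FALSE, TRUE),
                    marker = c(2, 6, 4, 3), vdac = c(1, 3, 2, 0))
  rat <- compute_ratios(tab, "NDUFB8")
  expect_identical(rat$ratio, c(2, 2))
  excl <- attr(rat, "excluded")
  expect_identical(nrow(excl), 2L)
  expect_setequal(excl$reason,
                  c("not INS-positive", "VDAC1 at or below noise floor"))
  expect_error(compute_ratios(tab[, setdiff(names(tab), "mean_VDAC1")],
                              "NDUFB8"), "VDAC1")
})

test_that("noise-free panel ratios equal the configured truth exactly", {
  gen <- generate_islet_image(tiny_cfg(seed = 43, cells = c(60L, 60L),
                                       shape = c(200L, 200L),
                                       noise_free = TRUE), "D1", "MTCO1")
  m <- measure_cells(gen$truth$cell_label_map, gen$image,
                     gen$truth$islet_label_map)
  ty <- classify_cells(m, compute_thresholds(m, "INS"), channels = "INS")
  rat <- compute_ratios(ty, "MTCO1")
  tt <- gen$truth$truth_table
  expect_equal(rat$ratio,
               tt$true_ratio_MTCO1[match(rat$cell_id, tt$cell_id)],
               tolerance = 1e-10)
})

test_that("k = 1 WCSS equals the total sum of squares about the mean", {
  set.seed(6)
  r <- rlnorm(300, 0, 0.5)
  fit <- fit_tiers(r, k = 1, seed = 2)
  expect_equal(fit$wcss_curve[1], sum((r - mean(r))^2), tolerance = 1e-9)
  expect_identical(fit$k, 1L)
})

test_that("elbow selects k = 3 with >= 95% assignment accuracy at defaults", {
  mx <- draw_tier_mixture(2000, "NDUFB8", seed = 5)
  fit <- fit_tiers(mx$ratio, seed = 17)
  expect_identical(fit$k, 3L)
  expect_identical(levels(fit$tier), c("low", "medium", "high"))
  expect_gte(mean(as.integer(fit$tier) == mx$component), 0.95)
  # centres strictly ascending, close to the configured component means
  expect_true(all(diff(fit$centers) > 0))
  mx2 <- draw_tier_mixture(2000, "MTCO1", seed = 5)
  fit2 <- fit_tiers(mx2$ratio, seed = 17)
  expect_identical(fit2$k, 3L)
  expect_gte(mean(as.integer(fit2$tier) == mx2$component), 0.95)
})

test_that("fitting is deterministic given the seed", {
  mx <- draw_tier_mixture(800, "NDUFB8", seed = 9)
  f1 <- fit_tiers(mx$ratio, seed = 99)
  f2 <- fit_tiers(mx$ratio, seed = 99)
  expect_identical(f1$centers, f2$centers)
  expect_identical(f1$tier, f2$tier)
  expect_error(fit_tiers(rep(c(1, 2, 3), 10), k_max = 8), "distinct")
})

test_that("WCSS curves are non-increasing across datasets", {
  for (seed in 1:4) {
    set.seed(seed)
    r <- rlnorm(400, 0, 0.7)
    fit <- fit_tiers(r, seed = seed)
    expect_true(all(diff(fit$wcss_curve) <= 1e-9))
  }
})

test_that("ANOVA validation matches the closed-form oracle", {
  # degenerate: {1,1,1} vs {2,2,2} -> SSB 1.5, SSW 0, infinite F
  r <- c(1, 1, 1, 2, 2, 2)
  model <- list(k = 2L, tier = factor(rep(c("low", "high"), each = 3),
                                      levels = c("low", "high")))
  class(model) <- "tier_model"
  av <- validate_tiers_anova(model, r)
  expect_true(av$degenerate)
  expect_identical(av$F, Inf)
  expect_equal(av$ss_between, 1.5)
  # hand-sized example: 3 groups of 3 against the textbook formula and lm
  g <- list(c(1.1, 2.0, 1.4), c(3.2, 2.8, 3.9), c(6.0, 5.5, 7.1))
  model2 <- list(k = 3L,
                 tier = factor(rep(c("low", "medium", "high"), each = 3),
                               levels = c("low", "medium", "high")))
  class(model2) <- "tier_model"
  av2 <- validate_tiers_anova(model2, unlist(g))
  expect_equal(av2$F, anova_f_oracle(g), tolerance = 1e-12)
  lmf <- anova(lm(y ~ grp, data.frame(y = unlist(g),
                                      grp = rep(letters[1:3], each = 3))))
  expect_equal(av2$F, lmf$`F value`[1], tolerance = 1e-9)
  expect_equal(av2$p, lmf$`Pr(>F)`[1], tolerance = 1e-9)
  # separated k-means tiers validate at p < 0.001
  mx <- draw_tier_mixture(1000, "NDUFB8", seed = 3)
  fit <- fit_tiers(mx$ratio, seed = 7)
  expect_lt(validate_tiers_anova(fit, mx$ratio)$p, 0.001)
  expect_error(validate_tiers_anova(list(k = 1L), 1:5), "k >= 2")
})

test_that("donor tier profiles normalise per donor and recover weights", {
  # a donor with all cells in the low tier -> profile (1, 0, 0)
  rat <- data.frame(donor_id = rep(c("A1", "A2"), c(10, 30)),
                    islet_id = 1L, cell_id = 1:40, marker = "NDUFB8",
                    ratio = c(rep(0.9, 10), rep(c(0.9, 1.4, 2.3), 10)))
  model <- fit_tiers(rat$ratio + seq_len(40) * 1e-6, k = 3, seed = 1)
  model$tier <- factor(c(rep("low", 10), rep(c("low", "medium", "high"), 10)),
                       levels = c("low", "medium", "high"))
  prof <- donor_tier_profiles(model, rat,
                              data.frame(donor_id = c("A1", "A2"),
                                         group = "A"))
  a1 <- prof$donors[prof$donors$donor_id == "A1", ]
  expect_equal(c(a1$prop_low, a1$prop_medium, a1$prop_high), c(1, 0, 0))
  sums <- rowSums(prof$donors[, paste0("prop_", prof$tier_levels)])
  expect_equal(sums, rep(1, 2), tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(donor_tier_profiles(model, rat,
                                   data.frame(donor_id = "A1", group = "A")),
               "missing from manifest")

  # group-specific weights recovered within 3 binomial SE (pooled fit)
  w_a <- c(0.46, 0.48, 0.06); w_b <- c(0.70, 0.28, 0.02)
  mx_a <- draw_tier_mixture(1500, "NDUFB8", weights = w_a, seed = 21)
  mx_b <- draw_tier_mixture(1500, "NDUFB8", weights = w_b, seed = 22)
  rat2 <- data.frame(donor_id = rep(c("A1", "B1"), each = 1500),
                     islet_id = 1L, cell_id = 1:3000, marker = "NDUFB8",
                     ratio = c(mx_a$ratio, mx_b$ratio))
  fit <- fit_tiers(rat2, seed = 4)
  expect_identical(fit$k, 3L)
  prof2 <- donor_tier_profiles(fit, rat2,
                               data.frame(donor_id = c("A1", "B1"),
                                          group = c("A", "B")))
  props <- as.matrix(prof2$groups[, paste0("prop_", levels(fit$tier))])
  for (j in 1:3) {
    se_a <- sqrt(w_a[j] * (1 - w_a[j]) / 1500)
    se_b <- sqrt(w_b[j] * (1 - w_b[j]) / 1500)
    expect_lt(abs(props[prof2$groups$group == "A", j] - w_a[j]), 3 * se_a)
    expect_lt(abs(props[prof2$groups$group == "B", j] - w_b[j]), 3 * se_b)
  }
})

test_that("tier names follow ascending centres regardless of fit order", {
  set.seed(11)
  r <- c(rlnorm(200, log(5), 0.05), rlnorm(200, log(1), 0.05),
         rlnorm(200, log(0.2), 0.05))
  fit <- fit_tiers(r, k = 3, seed = 31)
  expect_true(all(diff(fit$centers) > 0))
  by_tier <- tapply(r, fit$tier, mean)
  expect_true(by_tier[["low"]] < by_tier[["medium"]])
  expect_true(by_tier[["medium"]] < by_tier[["high"]])
})
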