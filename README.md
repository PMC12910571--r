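# isletkit

Single-cell image analysis of pancreatic islets: composition, contact
architecture, and beta-cell mitochondrial (OXPHOS) protein expression
from multi-channel immunofluorescence.

## What it is for

In type 2 diabetes, islets lose beta-cell mass (the alpha:beta cell
ratio rises), their architecture shifts (fewer beta–beta and more
alpha–alpha cell contacts), rare bi-hormonal INS⁺GCG⁺ cells become more
frequent, and beta-cell mitochondrial oxidative-phosphorylation
proteins re-balance — complex I (NDUFB8) falls while complex IV (MTCO1)
rises once expression is normalised to mitochondrial mass (VDAC1).
`isletkit` is for imaging groups who want to quantify these phenotypes
at single-cell resolution from stained tissue sections, with every
stage of the pipeline testable against synthetic ground truth.

The pipeline, stage by stage:

1. **Islet masks** — smoothed sum of marker channels → Otsu threshold →
   closing, hole-filling, 8-connected components, size filter.
2. **Nucleus seeds** — multiscale Laplacian-of-Gaussian blob detection
   on DAPI with non-maximum suppression (membrane-derived fallback for
   panels without a nuclear stain).
3. **Cells** — seeded region growing on the E-cadherin membrane channel,
   clipped to the islet and a hard radius cap.
4. **Measurement** — per-cell area, centroid, and mean intensity per
   channel; cell–cell contact graph (Chebyshev dilation, default 2 px).
5. **Phenotyping** — donor-adaptive thresholds
   `t = max(mean, median) + k·s` with a robust background scale `s`;
   types alpha / beta / bi-hormonal / other; islet eligibility
   (strictly > 10 insulin-positive cells); per-islet alpha:beta ratios;
   contact-pair percentages against a *jumbled-islet* permutation null.
6. **OXPHOS tiers** — per-cell marker/VDAC1 ratios on
   insulin-positive cells, k-means over k = 1..8 with k-means++
   restarts, cluster count by the maximum curvature of the log-WCSS
   elbow curve, tiers named low/medium/high by ascending centre, ANOVA
   validation, per-donor tier profiles.
7. **Group statistics** — donor-level permutation tests (donor as the
   exchangeable unit), Monte-Carlo chi-squared with fixed margins,
   Bonferroni correction, Cohen's d and Cramér's V with the
   conventional interpretation bands (0.2/0.5/0.8 and 0.1/0.3/0.5).

A synthetic islet generator (`sim_config()`, `generate_islet_image()`,
`generate_cohort()`) renders elliptical islets of touching Voronoi
cells with nuclei, membranes, cell-type-dependent lognormal marker
intensities, a three-component mixture of OXPHOS expression tiers,
Gaussian PSF blur and Poisson–Gaussian noise — and emits the label maps
and per-cell truth tables that make every stage's accuracy measurable.

## Worked example

```r
library(isletkit)

cfg   <- sim_config(image_shape = c(400L, 400L), n_islets = 3L,
                    cells_per_islet = c(50L, 70L), rng_seed = 11L)
gen   <- generate_islet_image(cfg, donor_id = "D1", panel = "composition")
masks <- segment_islets(gen$image)
seeds <- detect_nuclei(gen$image$channels$DAPI, masks$islet_label_map)
cells <- segment_cells(gen$image$channels$ECAD, seeds, masks)
tab   <- measure_cells(cells, gen$image)

thr   <- rbind(compute_thresholds(tab, "INS"),
               compute_thresholds(tab, "GCG"))
typed <- classify_cells(tab, thr)
summarise_composition(typed)
#> <composition_summary> 3 islets, 174 cells (alpha 58, beta 78, bihormonal 0, other 38)
#>   aggregate alpha:beta ratio 0.7436, bi-hormonal prevalence 0.000%

graph <- build_contact_graph(cells, contact_distance = 2)
graph
#> <contact_graph> 174 cells, 473 contacts
jn <- jumbled_null(graph, typed, n_perm = 999, seed = 1)
round(rbind(observed = jn$observed, expected = jn$expected, p = jn$p), 3)
#>          alpha_alpha beta_alpha beta_beta
#> observed      17.406     50.171    32.423
#> expected      17.975     49.362    32.664
#> p              0.782      0.780     0.916
```

The 174 cells of the three simulated islets are found (one seed per
nucleus), typed from their donor-specific thresholds, and summarised:
this donor's aggregate alpha:beta ratio is 0.74, and — because the
field was generated with the `jumbled` arrangement — the observed
contact-pair percentages sit on their permutation-null expectations
(all p ≈ 1). A `mantle_core` field would instead show alpha–alpha
enrichment with small p.

For an end-to-end run (two-group cohort → segmentation → phenotyping →
tiers → donor-level comparison, with a reproducibility manifest):

```r
run_pipeline(run_config(seed = 17L, out_dir = "isletkit_run"))
```

or, from a shell, `Rscript inst/cli/isletkit.R run-all --out-dir run
--seed 17`.

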