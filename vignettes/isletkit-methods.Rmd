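---
title: "isletkit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{isletkit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isletkit)
```

## The analysis problem

Pancreatic islets are micro-organs whose endocrine composition and
architecture change in type 2 diabetes: the alpha:beta cell ratio rises,
beta–beta cell contacts thin out, rare bi-hormonal (insulin- and
glucagon-co-expressing) cells become more frequent, and the mitochondrial
oxidative-phosphorylation (OXPHOS) machinery of beta cells shifts —
complex I (NDUFB8) down, complex IV (MTCO1) up — once expression is
normalised to mitochondrial mass (VDAC1). Quantifying any of this from
multi-channel immunofluorescence requires a single-cell pipeline:
delineate islets, seed and segment individual cells, measure per-cell
marker intensities, call cell types with donor-adaptive thresholds, and
compare donor groups at the right hierarchical level.

`isletkit` implements that pipeline end to end, together with a
synthetic islet image generator that emits exhaustive ground truth, so
that every stage has an oracle and every statistical procedure has a
calibration suite.

## Pipeline stages and their assumptions

**Islet masks.** The foreground signal is the sum of all non-nuclear
channels (hormones, mitochondrial markers and membrane staining jointly
cover endocrine tissue). It is Gaussian-smoothed (`smooth_sigma`, default
2 px), thresholded (Otsu on the normalised image by default, or a fixed
value), morphologically closed (disc radius 5 px), hole-filled and
labelled as 8-connected components; components under `min_islet_area`
(default 500 px², the scale of a ~13-cell fragment at 20x confocal
resolution) are discarded. An optional watershed on the smoothed
foreground (`split_touching`) separates islets in close proximity when a
single component carries two or more strong intensity modes; it is off
by default because the generator places islets with clear margins.

**Nucleus seeds.** Multiscale scale-normalised Laplacian-of-Gaussian
blob detection (`sigmas` 1.4–4.0 px, matching nuclear radii of roughly
2–6 px), greedy non-maximum suppression with `min_separation` 6 px, and
a candidate threshold expressed as a fraction (0.15) of the maximum
in-mask response, which makes detection invariant to global intensity
scaling and returns an empty set on blank input. The mitochondrial
panels carry no nuclear stain, so there seeds come from regularly
spaced local maxima of the smoothed, inverted membrane channel
(`membrane_seeds()`); results carry a `membrane_fallback` flag because
interior seeding from membrane topology is less accurate than nuclear
seeding.

**Cells.** Seeded region growing (`EBImage::propagate`) on the membrane
channel — the same propagation metric CellProfiler uses for secondary
objects — within the islet mask, with `lambda = 0.05` balancing
intensity against spatial distance so that region boundaries settle on
membrane ridges. Two hard guarantees are enforced after propagation: no
cell pixel lies farther than `max_cell_radius` (15 px) from its seed,
and each cell is the single 8-connected component containing its seed.
Every cell pixel lies inside its parent islet; this nesting invariant is
asserted on every run.

**Measurement.** Per-cell area, centroid (1-based row/col pixel
coordinates, origin top-left) and the arithmetic mean of every channel
over the cell label. Means are the only intensity statistic used
downstream, matching mean-based expression ratios; medians were
deliberately not added until a use case appears.

**Contact graph.** Two cells are neighbours iff their pixel sets come
within Chebyshev distance `contact_distance` (default 2 px: touching or
nearly touching). The Chebyshev ball was chosen over the Euclidean disc
so that 8-adjacent cells — which visibly touch on a raster — count as
contacts at distance 1. The implementation compares shifted label
images over all offsets in the ball; the test suite checks it against a
brute-force pairwise-distance oracle on every fixture up to 30 cells.

## Donor-adaptive thresholds

Marker positivity is donor-specific: the threshold for a channel is

\[
t = \max(\bar{x}, \tilde{x}) + k \cdot s,
\]

where \(\bar{x}\) and \(\tilde{x}\) are the mean and median of the
donor's per-cell mean intensities, \(k\) (default 1) is config-exposed,
and \(s\) is a robust scale. The scale is estimated from the sub-median
cells: \(s = 1.4826 \cdot \mathrm{median}(|x_{lo} - \tilde{x}_{lo}|)\)
for \(x_{lo} = \{x : x \le \tilde{x}\}\). This "background-half" scale
is the deliberate design choice: for a strongly bimodal stain the full
distribution's MAD absorbs the gap between the negative and positive
modes (for 50/50 modes at 10 and 100 the full MAD is ≈ 45, placing the
threshold far above the positive mode), whereas the sub-median scale
measures the spread of the background population the threshold is meant
to sit above. The classical full-distribution MAD remains available via
`scale_method = "mad"`. Thresholds are scale-equivariant (doubling all
intensities doubles the threshold) and positivity is strict (`>`), which
makes the degenerate constant-intensity donor well-defined: threshold
equals the constant and no cell is positive.

One structural caveat is worth stating: because the threshold anchors at
`max(mean, median)`, it assumes the marker-positive population is a
minority of the donor's cells in that channel (otherwise the median
climbs into the positive mode). This holds for hormone channels at
realistic islet compositions, and the per-donor positivity-rate report
emitted by the pipeline is the place to check it on real data.

Cell types follow the positivity flags: `bihormonal` = INS⁺ and GCG⁺
within the same membrane-defined boundary, `beta` = INS⁺ only, `alpha`
= GCG⁺ only, `other` otherwise. Bi-hormonal cells count toward the
insulin-positive islet-eligibility tally (they are insulin-positive
cells) but form their own class, excluded from both numerator and
denominator of the alpha:beta ratio; the four counts are always
reported separately, so either accounting convention can be
reconstructed. Islet eligibility is strictly more than `min_beta`
(default 10) insulin-positive cells — an islet with exactly 10 is
excluded.

## Contact architecture and the jumbled-islet null

The primary architecture statistic is the pair-level distribution of
alpha–alpha, beta–alpha and beta–beta contacts (percentages over those
three pair types; pairs involving bi-hormonal or `other` cells are
tallied separately). Cell-level fractions — e.g. the proportion of beta
cells with at least one beta neighbour — are also emitted, because the
two statistics answer subtly different questions and published analyses
phrase findings both ways.

The null model for architecture is the *jumbled islet*: hold the
contact graph fixed and permute the type labels over the cells. The
expected pair-type percentage is the permutation mean and the two-sided
p-value uses the add-one rule
\(p = (1 + \#\{|T_b - \bar{T}| \ge |T_{obs} - \bar{T}|\})/(B + 1)\),
so p is never 0 and is reproducible given the seed. Degenerate islets
(one represented type) return p = 1. Under jumbled generation the
pair-type percentages converge to the product form
\(p_{bb} = \pi_b^2 / (\pi_a + \pi_b)^2\) evaluated at the islet's
realised type fractions, which the tests verify at 500-cell islets
within 2 percentage points.

A geometric subtlety discovered while validating this statistic: a
*thin* alpha mantle does not raise the alpha–alpha pair percentage. On
a one-cell-thick rim each alpha touches only ~2 other alphas along a
one-dimensional ring, while a random mixture at alpha fraction 0.40
gives each alpha ~2.4 alpha neighbours in a two-dimensional
neighbourhood — so single-layer mantles are anti-enriched at the pair
level. The enrichment the permutation test is meant to detect appears
once the mantle is at least two cell layers thick, which at the default
composition means islets of roughly 140 cells and above; the
mantle-core property test therefore runs at that size.

## OXPHOS expression tiers

OXPHOS quantification is restricted to insulin-threshold-positive cells
of the mitochondrial panels, and each cell's marker mean is divided by
its VDAC1 mean — a per-mitochondrion expression proxy that removes
variation in organelle mass. Cells with VDAC1 at or below the noise
floor (default 0) are excluded and logged with a reason.

The pooled 1-D ratio values of all beta cells across all donors and
islets are clustered by k-means for k = 1..`k_max` (default 8), with
k-means++ initialisation and `n_restarts` (default 10) restarts per k,
keeping the best within-cluster sum of squares (WCSS). Clustering on
the ratio alone is the default; an optional `covariates` argument
appends standardised donor covariates to the feature vector for users
who want the covariate-augmented variant, but no claim is made that it
improves the tiers and it is not the default.

The cluster count is selected by an objective elbow rule: the k
maximising the discrete second difference of **log** WCSS over
k = 2..k_max−1, i.e. the point of maximum curvature of the log-scale
elbow profile. The log scale matters: the raw-scale second difference
is dominated by the always-large k = 1→2 drop and peaks at k = 2 even
for perfectly separated, equidistant three-cluster data (for three
tight clusters at spacing c the raw second differences are c²n/3 at
k = 2 versus c²n/6 at k = 3), so it cannot function as an elbow
detector. Tiers are named by ascending centre (`low`, `medium`, `high`
for k = 3); naming depends only on the sorted centres, never on
k-means' internal cluster indices. WCSS is non-increasing in k by
construction (a `cummin` guards the rare local-optimum wobble) and
k = 1 is computed in closed form as the total sum of squares.

Tier validity is checked by one-way ANOVA of ratio by tier from
definitional sums of squares; a zero within-tier sum of squares yields
an infinite F flagged `degenerate`. Donor profiles are per-tier
proportions of each donor's beta cells (summing to 1 per donor), with
group-level pooled proportions alongside.

## Group statistics

The donor is the exchangeable unit. The in-package inferential claim
for any per-donor metric (mean per-islet alpha:beta ratio, tier
proportions) is a permutation test of the difference of group means,
permuting donor group labels, with the two-sided add-one p-value. This
respects the donor hierarchy without covariate modelling; it does not
re-implement covariate-adjusted hierarchical mixed models, which are
better fitted in a dedicated modelling environment —
`export_modelling_table()` emits the tidy per-cell table (donor, group,
islet and cell ids, types, ratios, optional covariates) for exactly
that purpose.

Supporting procedures: Pearson chi-squared via Monte-Carlo simulation
under fixed margins (`stats::r2dtable` draws, add-one p, floor
1/(n_sims+1)); Bonferroni correction (adjusted p = min(1, m·p));
Cohen's d with (n−1)-weighted pooled SD; Cramér's V =
√(χ²/(n·(min(r,c)−1))). Effect-size bands use the conventional
cut-offs — d: 0.2/0.5/0.8, V: 0.1/0.3/0.5 for small/medium/large, on
|d| — with boundary values mapping to the larger band.

## What the generator emulates, and what it does not

The synthetic generator renders elliptical islets tiled by a
nearest-seed (Voronoi) partition of Poisson-disc-sampled nucleus seeds:
contiguous, mutually touching, membrane-delimited cells, as in
epithelium-like islet tissue. Marker channels paint each cell's true
intensity uniformly over its region (so the painted value *is* the
noise-free per-cell mean, giving exact oracles); membranes are painted
on region boundaries, nuclei as discs; the field is blurred with a
Gaussian PSF (default σ = 1 px) and corrupted with Poisson shot noise
(gain 0.5) plus Gaussian read noise (σ = 2).

Default study conditions, fixed once:

* **Composition** — alpha 0.40, beta 0.45, other 0.15. Published aged
  human cohorts show near alpha/beta parity, and delta/PP cells
  motivate a nonzero `other` class; keeping each hormone's positive
  fraction below one half also keeps the threshold anchor in the
  background mode (see above).
* **Bi-hormonal rate** — 0.00473 (0.473%), the printed cohort
  prevalence scale; the two-group cohort defaults split it 70.7/29.3
  between the diabetic-like and control-like groups.
* **Tier mixtures** — component centres at the printed cluster means
  (NDUFB8/VDAC1: 0.907/1.42/2.30; MTCO1/VDAC1: 7.03/7.74/10.8) with
  within-component spreads (sdlog 0.08 and 0.012) narrow enough that
  the three components are well separated — a deliberate idealisation
  that gives the generator *recoverable* tier ground truth. The
  per-group weight overrides are the printed group proportions
  (e.g. NDUFB8 low tier 46.0% vs 68.4%).
* **Intensities** — no published intensity distributions exist, so the
  lognormal levels (positive markers ≈ 300 units, sdlog 0.2; negative
  ≈ 20, sdlog 0.4; VDAC1 ≈ 150) are free parameters chosen to give a
  clean working point, not estimates of any donor's data.

The generator deliberately omits: 3-D structure and optical sectioning,
autofluorescence, exocrine texture, uneven illumination, staining
batch effects, segmentation-hostile cell shapes, and overlap between
tier components. Passing tests therefore demonstrate correctness of
the *algorithms* under a controlled model of islet imagery — they do
not certify performance on real tissue, where thresholds and
segmentation quality must be inspected through the per-donor
positivity-rate and segmentation reports the pipeline writes.

## Numerical choices and degenerate inputs

* Images are stored as 16-bit multi-page TIFF with a recorded per-file
  scale factor (JSON sidecar carries channel names and identifiers);
  round trips are lossless to scale/65535. Label maps are 16-bit and
  exact up to 65,535 labels; non-integer label images are refused.
* Permutation and Monte-Carlo p-values all use the add-one rule and a
  1e-12 comparison slack so ties in floating point never flip a count.
* k-means ties across restarts resolve to the first-best WCSS;
  determinism is guaranteed by seeding the whole scan once.
* Empty inputs: a blank image yields zero islets (not an error); an
  empty seed set yields an empty cell map; empty cell tables write
  header-only CSVs that read back as zero rows.
* Donors with fewer than 20 cells threshold with a warning; an empty
  donor is an error. Fewer than 3 donors per group warns that the
  permutation p is coarse (with 2 vs 2 donors the smallest two-sided p
  is 1/3).
* The demo problem sizes — 300–560 px fields, 2–5 islets of 50–140
  cells, 500-replicate calibration suites at 999 permutations — were
  chosen so the whole test suite and the acceptance script each run in
  a few minutes on a single CPU while keeping every binomial
  tolerance (3 SE) meaningful.

## Known limitations

* The threshold rule assumes minority-positive channels per donor (see
  above); donors whose insulin-positive fraction exceeds ~50% need a
  lower `k` or a fixed threshold, and the positivity-rate report makes
  such donors visible.
* Mitochondrial-panel seeding from the membrane channel is a
  flagged approximation; nuclear seeding is strictly better when a
  nuclear channel exists.
* Panels are analysed separately (as acquired); the package never
  registers panels to each other, so NDUFB8/MTCO1 co-expression within
  single cells is out of reach by design.
* The donor-level permutation test trades covariate adjustment for
  exactness; age/BMI/sex adjustment requires the exported modelling
  table and an external mixed-model fit.
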