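---
title: "Methods: multifaceted diversity along river gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multifaceted diversity along river gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ripdiv)
```

This vignette documents the statistical model behind each stage of the
`ripdiv` pipeline, the assumptions and tunable parameters, the design
choices made where the methodology was genuinely open, and what the
synthetic-data generator does and does not emulate.

## The data model

The pipeline consumes five objects, bundled by `rip_dataset()`: a
site × species abundance matrix (non-negative counts), a species trait
table with declared column types (continuous, ordinal, categorical), a
rooted phylogeny with branch lengths whose tips are the species, a site
table with elevation (m a.s.l.), river identity, river direction, and
up to nine environmental predictors (`rip_env_vars`), and a
conservation-status map assigning each species a weight in {1, 4, 8}.
Species name spaces are reconciled by exact string match after
whitespace trimming; species missing from any component are dropped
with a warning. No fuzzy matching is attempted, to avoid silent
misjoins. Before analysis, species detected at fewer than three sites
are removed (`filter_low_occurrence()`, threshold configurable):
occurrence-based metrics are unstable for species seen once or twice,
and presence means abundance > 0 — no detection-probability model is
attempted.

## Taxonomic diversity

Richness is the count of species with positive abundance. Shannon
diversity is computed in **log base 2** by default. The base is
genuinely a convention; base 2 is chosen because, for assemblages of up
to ~15 species per site, it yields values spanning 0–3.9, the range
over which field studies of this design typically report H′, whereas
natural log saturates near 2.7. The base is an argument throughout.

## Functional richness

FRic is built in three steps.

1. **Gower dissimilarity** over the mixed trait table: continuous
   traits contribute range-scaled absolute differences, categorical
   traits a 0/1 mismatch, ordinal traits range-scaled rank differences;
   contributions are averaged over the traits non-missing for both
   species. A zero-range trait contributes 0 with a warning.
2. **Principal coordinates.** Gower matrices over mixed traits are
   usually non-Euclidean; when the most negative eigenvalue exceeds
   1e-8 of the leading one, the Cailliez additive-constant correction
   is applied before embedding, and recorded in the returned object.
   Up to `m_max = 4` positive-eigenvalue axes are retained.
3. **Convex-hull volume.** A site's FRic is the hull volume of its
   species' coordinates on the first `m_eff` axes, divided by the hull
   volume of the entire pool, so FRic ∈ [0, 1] and the pool itself
   scores 1. The hull volume is computed exactly: shoelace area in two
   dimensions and recursive facet decomposition in three and four
   (every supporting hyperplane's facet polytope is measured in an
   orthonormal basis of the hyperplane and combined with its distance
   to the centroid). Point sets of community size (≤ ~60 species,
   ≤ 4 axes) are well within its reach.

`m_eff` defaults to the smaller of the retained axis count and
(minimum richness over sites with at least two species) − 1, the usual
convention of distance-based FD software; sites with fewer than
`m_eff + 1` species, or with affinely degenerate coordinates, are
undefined (`NA`) and listed rather than silently dropped.

Two caveats are deliberate. FRic is computed on **presence only**: a
hull volume is abundance-invariant by definition, so describing it as
abundance-weighted would be misleading even when the surrounding
workflow weights other quantities by abundance. And the raw
(unstandardized) volumes are also returned, since the [0, 1]
standardization ties values to the particular pool analysed.

## Phylogenetic diversity

Faith's PD is the summed branch length of the minimal subtree spanning
a site's species. The path to the root is **included by default**
(the common default of comparative-ecology software; `include_root =
FALSE` restricts to the subtree below the species' MRCA, making
single-species sites score 0). Empty sites score 0 with a warning.
The implementation walks parent pointers on the `phylo` edge table and
is checked in the tests against an independent brute-force union of
root-to-tip edge sets and against `picante::pd()`.

## Null models and standardized effect sizes

Raw FRic and PD are strongly coupled to richness, so departures from
chance are measured as `ses = (obs − mean_null)/sd_null` over
richness-constrained randomizations. The null scheme: per site,
draw the same number of species uniformly (without replacement) from
the regional pool — all species in the matrix — and assign the site's
observed positive abundances to them in random order. Per-site
richness and the per-site abundance multiset are preserved **exactly**;
species occurrence frequencies are *not* constrained. This is the
"richness" null of the comparative-ecology tradition; frequency-
preserving swap algorithms are a different null hypothesis and are out
of scope. 1000 replicates is the default; tests use fewer. Sites with
undefined observed metrics or zero null SD yield `NA` with a warning.
`richness_decoupling_check()` reports the Pearson correlation of each
SES column with richness and whether |r| < 0.10 — a diagnostic, never
an enforcement.

## Phylogenetic signal

Blomberg's K compares the observed ratio of trait variance around the
GLS phylogenetic mean (MSE0) to the phylogenetically corrected MSE,
against that ratio's Brownian-motion expectation on the same tree:
K = 1 under BM, exactly 1 on an equal-branch star tree (an identity the
tests assert to 1e-8). Significance uses the original formulation's
randomization: trait values are permuted across tips and the
phylogenetic MSE compared, with the add-one-smoothed p-value
`(1 + #{MSE_perm ≤ MSE_obs})/(n_perm + 1)`. V is inverted by Cholesky
factorization, with a tiny ridge (1e-10 · tr(V)/n) only if numerically
singular. Ordinal and categorical traits are encoded to their integer
level codes before testing — a declared simplification: a one-axis
score cannot fully represent unordered categories, so K for such traits
should be read qualitatively.

## Conservation value

`CVI = Σ log₁₀(aᵢ + 1) · eᵢ` over the species present, with weights 1,
4, 8 by protection class. Log base 10 is the default: with it a site
holding a single unthreatened individual scores log₁₀(2) ≈ 0.301, the
natural floor for surveys reporting CVI minima near 0.3; the base is
configurable. CVI is additive across species and monotone in both
abundance and protection class (property-tested).

## Gradient smooths

Diversity–elevation shapes are fitted as Gaussian additive mixed
models: a penalized cubic regression spline on elevation with basis
dimension `k = 5` plus random intercepts for river identity and river
direction, all estimated in a single penalized least-squares problem
with smoothing parameters by REML (GCV fallback on failure), via
`mgcv`. `k = 5` reflects the design: with ~10 sites per river and ~60
total, larger bases cannot be supported; it is an argument. The
population-level curve (random effects excluded) is evaluated on a
1-metre grid; `peak_location()` takes its argmax, breaking ties to the
lowest elevation, and classifies a boundary argmax as "monotone", an
internal one as "interior" (hump-shaped). The CVI–elevation curve uses
a plain Gaussian polynomial GLM (degree 2 default) for comparability
with how such curves are usually displayed.

The random effects are deliberately estimated as shrunken intercepts
*inside* the penalized fit — one coherent estimator — rather than as a
two-stage mixed-model hybrid. "River direction" is treated as an
opaque categorical label; with few rivers it is nearly confounded with
river identity, which the shrinkage handles gracefully.

## Environmental-driver inference

Predictors are screened by variance inflation: VIFⱼ = 1/(1 − R²ⱼ) from
regressing predictor j on the others, iteratively removing the single
worst predictor while any VIF ≥ 4. The filter's post-condition (no
retained VIF ≥ 4) is sweep-tested. The threshold-4 "remove-while-high"
reading is the only one under which a nine-variable predictor set of
this kind survives screening, and matches universal practice.

Every subset of the retained, z-standardized predictors (including the
intercept-only model) is then fitted as a Gaussian linear mixed model
with a random intercept for river identity, by maximum likelihood.
The implementation profiles the likelihood: with V(θ) = σ²(I + θZZ′),
a single eigendecomposition of ZZ′ turns every subset into a weighted
least-squares fit plus a one-dimensional optimization in θ, which makes
the 2^9 = 512-model enumeration (and its replication in simulation
tests) fast and dependency-free; it is verified against
`lme4::lmer(REML = FALSE)` to 1e-5 in the tests. Only the river
intercept is included as a random effect — with six rivers, river
direction is confounded with river identity at the grouping level.

Models are ranked by AICc = −2ℓ + 2k + 2k(k+1)/(n−k−1) (k counts fixed
effects plus the two variances), with Akaike weights over the full
candidate set. The ΔAICc ≤ 2 set is averaged with renormalized
weights: **full (zero-substitution) averaging** by default — a
predictor absent from a model contributes 0, shrinking the averaged
coefficient — with conditional averaging available by flag.
Unconditional standard errors combine within-model variance and
between-model spread, `SE = Σ wᵢ √(seᵢ² + (bᵢ − b̄)²)`; p-values use
the normal approximation; relative importance is the summed weight of
top-set models containing the predictor.

## The synthetic-data generator

`generate_study()` emulates the study design the pipeline assumes, and
its defaults are the fixed reference conditions used throughout the
tests:

* **Design**: 6 rivers × 10 sites, elevations evenly spaced over
  481–912 m; river direction alternates between two labels.
* **Phylogeny**: pure-birth (Yule) tree with 47 tips via
  `ape::rphylo` — the simplest process producing ultrametric trees of
  the needed shape; the speciation rate is a knob.
* **Traits**: six columns. Three are Brownian-motion draws (tip values
  multivariate normal with covariance `bm_rate · V`); the other three
  discretize further latent BM traits into ordinal/categorical levels,
  so every trait carries phylogenetic signal, as trait sets of real
  assemblages typically do.
* **Environment**: forest cover rises with elevation while shrub/herb
  covers decline; habitat-heterogeneity variables (land-cover patches,
  vegetation-height SD) and channel sinuosity are mid-peaked along the
  gradient; channel width and gravel-bar area shrink gently upstream.
  Noise levels are set so that all nine predictors pass the VIF < 4
  screen — i.e. the generator reproduces a design in which the full
  predictor set is usable, the situation the driver-inference stage is
  built for.
* **Communities**: species niche optima are normal around the 700-m
  richness peak (SD 0.35 × gradient span); occupancy is
  `max_occupancy = 0.22` times a Gaussian elevation response
  (`niche_breadth = 170` m), multiplied by a centred log-linear term in
  four "true" drivers (Forest, H_SD, Lnum, Sinuosity; 0.2 per SD each)
  and capped at 1; abundances are zero-truncated Poisson (rate 2).
  These values were calibrated once so that realized richness has a
  mid-gradient hump near 700 m with site richness mostly in the 1–20
  range around a mean near 7–8 — the regime of breeding-bird point
  counts on submontane rivers — and then frozen.
* **Conservation status**: weights 1/4/8 drawn with probabilities
  0.80/0.15/0.05; most real assemblages are dominated by unthreatened
  species with a small protected minority.
* **Seeding**: one master seed; each component draws from a derived
  sub-stream, so changing one component's draw count does not disturb
  the others, and the same seed reproduces every output byte-for-byte.

What the generator does **not** emulate: real species identities or
trait values, detection error, temporal turnover, spatial
autocorrelation beyond the river-level intercept, and abundance–
occupancy relationships richer than the truncated-Poisson draw.
Passing tests therefore demonstrate that the pipeline recovers known
structure under its own assumptions — not that those assumptions hold
for any particular field system.

## Problem sizes and numerical choices

The test suite and the acceptance script run at deliberately chosen
sizes: null models at 199–499 replicates (1000 remains the analysis
default), permutation tests at 199–499, BM calibration at 200
replicates on 64-tip trees, peak-recovery at 20 seeds, and
driver-recovery at 50 replicates of the full 512-model enumeration.
These sizes give stable Monte-Carlo summaries for the properties
checked while keeping a full run in the minutes range on one CPU.

Other numerical conventions: hull facet tests use a relative tolerance
of 1e-9; the Cailliez correction triggers at a relative negative
eigenvalue of 1e-8; peak searches use a 1-m grid with ties to the
lowest elevation; empty sites yield S = 0, H′ = 0, PD = 0 and
undefined FRic, always with warnings rather than silent drops.

## Known limitations

* FRic beyond four axes is not supported (exact facet enumeration
  grows combinatorially); four axes is also where trait spaces of
  ~6 traits stop being interpretable.
* The permutation encoding of categorical traits for K is a one-axis
  summary; a multivariate signal statistic is out of scope.
* The driver models assume Gaussian errors for what are often counts;
  with richness means near 7 this is serviceable, but a Poisson GLMM
  variant would be the natural extension.
* The null model does not preserve species occurrence frequencies;
  conclusions about trait/phylogenetic clustering are relative to the
  uniform-pool null only.
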