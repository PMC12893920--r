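---
title: "Methods: pseudospace axis construction and axis-variable gene analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pseudospace axis construction and axis-variable gene analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# Scope

`organaxis` implements the computational spine of a rostrocaudal
("pseudospace") analysis of a tubular organ — the kind of analysis used
to study the regionalization of the developing reproductive tract
(Müllerian and Wolffian ducts and their derivatives): a normalized axis
coordinate built from anatomical landmark annotations in spatial
transcriptomics, transfer of that coordinate onto dissociated single
cells, spline-based detection of axis-variable genes, signature scoring
with an ordered trend test, cross-species neighbourhood matching through
an orthologue space, and integration-QC statistics. Every step is
exercised end-to-end on a synthetic tubular-organ generator with known
ground truth, so the package's tests are parameter-recovery experiments
rather than golden-file comparisons.

Upstream processing (read alignment, ambient-RNA removal, doublet
calling, batch-correction embeddings, deconvolution) is out of scope;
embeddings and abundances are accepted as inputs where relevant.

# The synthetic organ

`generate_tube_organ()` places units on a quadratic Bézier centerline —
deliberately curved so that straight-line (chord) distance between
units is not proportional to arc-length, which is exactly the regime
where axis-construction choices matter — with Gaussian lateral jitter
(sd = 5% of tube length, the scale of a thick epithelial band around a
duct). The true axis of a unit is its normalized arc-length position
`s` in [0, 1]. The 2% of units nearest each endpoint carry the
`rostral_tip` / `caudal_tip` landmark labels, mirroring annotated
landmark *regions* (such as fimbriae or a duct junction) rather than
single points.

Expression follows a negative binomial with
`log2 mu(s) = log2(base_mean) + amplitude * f(s)` and variance
`mu + mu^2 * dispersion` (so dispersion 0 is the Poisson limit). The
pattern functions are `1 - s` (rostral-decreasing), `s`
(caudal-increasing) and a Gaussian bump centred at `s = 0.5` with
sd 0.15 (middle-peaked) — the three qualitative classes observed for
regionalized genes in tubular organs. Defaults: `base_mean` log-uniform
in [1, 50] (spot-level counts for moderately expressed genes),
gradient `amplitude` uniform in [1, 2] log2-fold, `dispersion = 0.5`
(a typical per-gene overdispersion for droplet and spot data),
per-unit size factors log-normal(0, 0.3) so library-size offsets are
never a no-op. Dissociated cells are drawn from the same model at
uniform axis positions; an ISS-like reference is the same organ
restricted to a gene panel. ISS counts and spot counts are treated as
the same NB family at different unit granularity; the generator does
not model panel-specific noise (probe efficiency, segmentation error).

What passing on these data does *not* show: robustness to
batch-confounded axes, to zero-inflation beyond NB, to segmentation
artefacts, or to landmark mislabelling; the generator is deliberately
clean in those respects.

# Axis construction

For each unit, `assign_axis()` computes the distance `d_R` to the
nearest rostral-landmark unit and `d_C` to the nearest caudal-landmark
unit and assigns `s = d_R / (d_R + d_C)` — a normalized relative
distance that is 0 on the rostral landmark, 1 on the caudal landmark,
and invariant to any rigid transform of the whole section.

Distances are geodesic by default: shortest paths on a spatial
adjacency graph (symmetric k-nearest-neighbour graph, k = 10, edges
longer than 3x the median nearest-neighbour spacing removed). A
Delaunay triangulation would serve the same purpose; the kNN graph was
chosen because it needs no geometry engine and behaves identically at
tissue densities. In a curved organ the Euclidean ratio is not
monotone in arc-length (points far along the tube can be close in
space), which is why geodesic is the default; `method = "euclidean"`
remains available and is the fallback if the graph cannot be connected.
Stray graph components (isolated jittered units) are first re-attached
by their single shortest connecting edge, so one outlying unit does not
force the whole tissue onto the fallback.

Multi-section data are stitched with user-supplied affine transforms
(`stitch_sections()`); the package validates and applies them but does
not estimate them — image-based alignment is interactive and happens
elsewhere. `rescale_axis()` applies a piecewise-linear monotone map
through user anchors (with (0,0) and (1,1) implicit) so axes from
different samples of the same organ can be put on a consistent scale,
and `bin_axis()` uses 20 equal-width bins by default — enough to
resolve gradients at spot-level unit counts while keeping tens of units
per bin.

# Axis imputation onto dissociated cells

`impute_axis_knn()` restricts reference and query to shared genes,
normalizes both to log[CPM/100 + 1], scales per gene with the
*reference* statistics and projects both into the reference's top 30
principal components. Each query cell receives the unweighted mean axis
value of its k = 50 nearest reference units (inverse-distance weighting
is available but changes little). Projecting the query into the
reference space avoids a batch-dominated joint embedding without
implementing integration. k = 50 balances locality against neighbour
noise at reference sizes of a few thousand units; neighbour ties are
broken by reference index for reproducibility. Confidence is
`1 - sd(neighbour values) / (axis range / 2)`: 1 when the neighbours
agree, near 0 when they span the organ. Label transfer uses the same
space with majority voting; transfers with a majority fraction below
0.8 are flagged low-confidence but retained, so downstream summaries
can apply the 0.8 rule without losing cells.

# Axis-variable genes

`fit_gene_axis_model()` regresses a gene's counts on a spline in the
axis coordinate: negative binomial with log link, linear predictor =
intercept + spline basis + `log(size_factor)` offset, treating the
spatial axis exactly as a pseudotime association model would. The
basis is a natural cubic spline with `spline_df = 5` basis functions
and internal knots at axis quantiles (so sparse axis regions do not
destabilize the fit). The natural (linear-beyond-boundary) constraint
matters: the amplitude statistic below is the max-min of the fitted
curve, and an unconstrained cubic B-spline's edge variance inflates
that statistic by ~20% on noisy genes, while the natural basis keeps
amplitude recovery unbiased (a planted 1-log2-fold gradient is
recovered at ~1.1 on average) without affecting calibration.
`spline_df = 1` reduces to a linear basis, which is how the fit is
cross-checked against a generic NB-GLM in the tests.

Dispersion is estimated once per gene by moment matching — the value
solving `sum((y - mu)^2 / (mu + phi mu^2)) = n - p` on the full fit,
floored at 1e-8 — then held fixed for both the full and the
intercept-only null fit. No empirical-Bayes shrinkage is applied. The
association statistic is `2 (loglik_full - loglik_null)`, clipped at 0,
referred to a chi-square with `spline_df` degrees of freedom; fixing
the dispersion across both fits is what keeps the null distribution
calibrated (measured type-I error 0.047-0.059 at alpha = 0.05 over
2,000 null genes with dispersion 0.5 and 500 units).

`detect_spatially_variable_genes()` tests every gene detected in at
least 1% of units (a floor that prevents degenerate fits) and flags
genes with raw p < 0.001 **and** fitted log2 amplitude > 0.5 — the
stringent pass criterion uses the raw p-value, with
Benjamini-Hochberg q-values reported alongside for transparency. Two
conventions deserve note because the threshold could be read several
ways: the fold change of a smooth curve is defined as the max-min of
the fitted log2 profile across the axis (the amplitude convention of
pseudotime fold-change arguments, not an endpoint contrast), and the
0.5 threshold is interpreted in log2, the customary base for
fold-change cutoffs in this literature; both are arguments, not
constants. All-zero genes return a flat model with p = 1 rather than
an error; fits not converged within 100 IRLS iterations are flagged
and excluded from the q-value computation. Pattern classes are read
off the fitted curve: flat if amplitude <= 0.5, else
rostral / middle / caudal by which third of the axis holds the fitted
maximum. Binned min-max profiles (mean normalized expression per axis
bin, row-scaled to [0, 1], constant rows all-zero by convention) are
the heatmap-ready summary; empty bins are NA unless fitted values are
requested.

# Signature scoring and the ordered trend test

`score_signature()` is the average normalized expression of a gene set
minus the average of an expression-matched control pool: genes are cut
into 25 equal-size bins on dataset-mean expression and 50 controls per
signature gene are sampled (without replacement, excluding signature
genes) from the matching bin. 25/50 mirror the common scoring
convention for matched control pools; both are arguments. Control
candidates are sorted before sampling so the score is invariant to
gene order given the seed.

`jonckheere_test()` tests a monotone trend of scores across ordered
groups (e.g. rostral, mid, caudal regions of an adult organ). The JT
statistic is the sum over ordered group pairs of Mann-Whitney counts,
ties counted 0.5 (the standard tie convention). Significance comes
from shuffling group labels 2,000 times with the add-one estimator
`(1 + #as-or-more-extreme) / (n_perm + 1)`, which cannot return 0 and
stays valid at any n_perm; the default alternative is `decreasing`,
matching the rostral-signature use case. `exact_jonckheere_p()`
enumerates the complete permutation null for small instances (at most
1e5 assignments) and uses the identical tie convention, so permutation
and enumeration are directly comparable — the suite requires agreement
within 3 binomial standard errors on 19/20 random small instances.

`target_set_enrichment()` applies the same scoring idea to drug target
sets: per-cell score = mean normalized expression of the targets,
Wilcoxon rank-sum of the focus cell type against all other cells,
BH-adjusted p < 0.01, log2 fold change of mean scores > 2, and at
least 10% of focus cells expressing >= 1 target. The "rank score" used
for ordering is the standardized rank-sum statistic, not an additional
cutoff — the filtering contract names it without defining a threshold,
so it orders rather than gates.

# Cross-species neighbourhood matching

The shared feature space is built exactly as stated for orthologue
comparisons: one-to-one orthologue pairs expressed in at least 10
cells in both species, top 4,000 highly variable genes per species
(normalized dispersion, z-scored within 20 mean-expression bins),
intersected. Neighbourhoods are sampled Milo-style: 10% of cells as
index cells, each neighbourhood = index cell + its 30 nearest
neighbours in the per-dataset embedding (a 30-PC embedding on the
shared features by default; a user-supplied batch-corrected embedding
can replace it).

Matching operates on neighbourhood expression profiles — mean
log-normalized expression over members on the shared features,
standardized per gene with statistics pooled across both datasets —
because profile space is the only space common to two independently
embedded datasets without re-implementing integration. Each
neighbourhood takes its 30 nearest counterparts in both directions and
the retained pairs are those present in both directions (mutual
nearest pairs). Majority labels per side (lexicographic tie-break,
ties flagged) aggregate into the harmonized label-combination table.

# Integration QC

Per-cluster Shannon entropy of label composition is reported in bits
(base 2); the base is cosmetic for the two rules actually applied —
donor-specific clusters are exactly those with donor entropy 0, and
cluster annotation assigns the modal label iff its fraction is >= 0.40
(inclusive; modal ties are unresolved). TF-IDF markers follow the
quickMarkers convention: tf = in-cluster detection rate, idf = ln of
inverse global detection rate, so scores depend only on the
detected/not-detected pattern. Cell-type-by-region enrichment is a
z-score of per-region mean abundance across regions with sample sd
(ddof = 1); zero-variance cell types get all-zero rows rather than
NaN.

# Determinism and problem sizes

Every generator and every stochastic step (control sampling,
permutations, index-cell sampling) takes an explicit seed and restores
the caller's RNG state, so workflows are pure functions of their
configuration; `run_workflow()` fans one seed out to per-stage seeds by
fixed offsets and records parameters and output checksums in a
manifest. The test suite and the analysis scripts run at desk scale —
2,000 spots x 500 genes for the organ, 2,000 dissociated cells,
2,000 null genes at 500 units for calibration, 3,000 cells per species
for matching — sizes at which the Monte-Carlo error of each recovery
statistic is comfortably inside the asserted bands.

# Known limitations

* The axis is 2-D and single-path; branching organs or 3-D sections
  need a different geodesic structure.
* The NB spline model does not model zero-inflation or smooth
  dispersion over the axis; strongly zero-inflated panels will look
  overdispersed and lose power.
* Mutual-nearest neighbourhood matching assumes the shared orthologue
  space preserves population geometry; a species-wide shift on many
  genes is absorbed by the pooled standardization, but population-
  specific divergence is not.
* The signature score's control pool matches mean expression only, not
  dropout rate; scores on very sparse data inherit the usual caveats of
  matched-control scoring.
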