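# organaxis

Landmark-based organ axis construction and axis-variable gene analysis
for spatial transcriptomics.

## What this is for

Tubular organs — the developing reproductive tract's Müllerian and
Wolffian ducts are the motivating case — are patterned along their
rostrocaudal axis: gene expression changes smoothly from one anatomical
end (e.g. the fallopian fimbriae) to the other (e.g. the
vagina–vaginal-plate junction). Spatial transcriptomics makes that
axis measurable, but only after a chain of bespoke computational steps
that `organaxis` implements as a tested R package for computational
biologists working with spatial + single-cell data:

1. **Axis construction** — every spatial unit u gets a normalized
   pseudospace coordinate from annotated landmark regions,

   $$s(u) = \frac{d_R(u)}{d_R(u) + d_C(u)} \in [0, 1],$$

   where $d_R, d_C$ are (by default geodesic, graph-based) distances to
   the nearest rostral / caudal landmark unit; multi-section samples
   are first stitched with affine transforms, and axes are rescaled
   across samples with monotone piecewise-linear anchor maps.
2. **Axis imputation** — dissociated scRNA-seq cells, which have no
   coordinates, inherit the axis by k-nearest-neighbour transfer
   (k = 50) from an ISS-like panel-limited spatial reference in a
   reference-fit PCA space; categorical labels transfer the same way
   with a 0.8 majority-fraction confidence rule.
3. **Axis-variable genes** — per gene, counts are modelled as
   $y_u \sim \mathrm{NB}(\mu_u, \phi)$ with
   $\log \mu_u = \beta_0 + f(s_u) + \log(\text{size factor}_u)$, f a
   natural cubic spline (df = 5), $\phi$ a fixed moment estimate; the
   likelihood-ratio statistic against the intercept-only null is
   referred to $\chi^2_{df}$, and genes pass with p < 0.001 and fitted
   log2 amplitude (max − min of the fitted curve) > 0.5.
4. **Signature trends** — gene-set scores against expression-matched
   control pools, tested across ordered regions with a permutation
   Jonckheere–Terpstra test (2,000 permutations; an exact enumeration
   oracle is included), plus the drug target-set variant with rank-sum
   enrichment filters (adjusted p < 0.01, log2 FC > 2, ≥ 10%
   target-expressing cells).
5. **Cross-species matching** — kNN-graph neighbourhoods per species,
   matched through the intersection of top-4,000 orthologue HVGs by
   mutual nearest pairs (k = 30 both directions), with majority-vote
   label harmonization.
6. **Integration QC** — per-cluster Shannon label entropy, ≥ 40%
   majority-vote annotation, TF-IDF cluster markers and cell-type ×
   region z-score enrichment.

A seeded synthetic tubular-organ generator (`generate_tube_organ()`,
`generate_dissociated()`, `split_into_sections()`,
`generate_species_pair()`) provides every input modality with known
ground truth, so the whole pipeline runs — and is tested as a
parameter-recovery problem — without any external download.

## Worked example

```r
library(organaxis)

sim  <- generate_tube_organ(n_units = 800, n_genes = 200,
                            frac_gradient = 0.2, seed = 1)
axis <- assign_axis(sim$spatial, method = "geodesic")
cor(axis$value, sim$truth$true_axis, method = "spearman")
#> [1] 0.997

svg <- detect_spatially_variable_genes(sim$spatial, axis)
head(svg[, c("gene_id", "lrt_stat", "p_value", "log2_amplitude",
             "pattern", "pass")], 5)
#>     gene_id lrt_stat      p_value log2_amplitude pattern pass
#> 1 gene_0012 325.4895 3.299666e-68       1.648363  middle TRUE
#> 2 gene_0009 266.6581 1.460712e-55       1.862860  middle TRUE
#> 3 gene_0003 264.0380 5.334809e-55       1.699288  middle TRUE
#> 4 gene_0039 254.2825 6.624770e-53       1.631539  middle TRUE
#> 5 gene_0032 246.9054 2.535384e-51       1.917106  caudal TRUE
sum(svg$pass)
#> [1] 41

sig <- score_signature(sim$spatial,
                       head(svg$gene_id[svg$pattern == "rostral"], 10),
                       seed = 2)
region <- cut(axis$value, c(0, 1/3, 2/3, 1), include.lowest = TRUE,
              labels = c("rostral", "middle", "caudal"))
jonckheere_test(sig$score, region, alternative = "decreasing", seed = 3)
#> <trend_test> JT = 32796, p = 0.0004998 (decreasing, 2000 permutations)
```

The axis coordinate tracks the generator's arc-length truth (Spearman
0.997); 41 of 200 genes — the planted gradient genes plus a single
borderline case — pass the stringent criteria, with pattern classes
matching what was planted; and the score of a rostral-decreasing
signature falls monotonically across the three regions (permutation
p ≈ 5 × 10⁻⁴, the floor for 2,000 permutations).

## The analysis, step by step

`analysis/` contains numbered drivers that run the full study on
simulated data and write their tables under `results/`:

| script | does | key outputs |
|---|---|---|
| `01_simulate_data.R` | all synthetic modalities + ground truth | `results/data/` |
| `02_axis_construction.R` | stitch sections, build + bin the axis | `axis.csv` |
| `03_impute_axis.R` | panel reference → per-cell axis | `imputed_axis.csv` |
| `04_axis_variable_genes.R` | NB-spline axis-variable gene scan | `svg_results.tsv`, `profiles.tsv` |
| `05_signature_trend.R` | signature score + Jonckheere trend | `trend_test.tsv` |
| `06_cross_species.R` | orthologue HVG space, mutual matching | `matches.tsv`, `combinations.tsv` |
| `07_integration_qc.R` | entropy, majority vote, TF-IDF, z map | `cluster_stats.tsv`, ... |

Run them in order (`Rscript analysis/01_simulate_data.R`, ...); each
prints what it found. `run_workflow()` packages the same chains behind
a single YAML config with a run manifest.

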