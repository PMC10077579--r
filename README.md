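# domdiv — molecular diversity of dissolved organic matter from FT-ICR MS

Dissolved organic matter (DOM) is one of the most molecularly complex
mixtures on Earth. Ultrahigh-resolution mass spectrometry (FT-ICR MS)
resolves thousands of exact masses per sample, each assignable to a unique
CHNOSP molecular formula — which makes a DOM extract analysable like an
ecological community whose "species" are molecular formulas. `domdiv` is
an R package for that analysis, written for aquatic biogeochemists and
environmental chemists working with calibrated negative-ion peak lists
(for example from lake, river or marine SPE-DOM surveys).

The pipeline covers:

* **Formula assignment** — exhaustive CHNOSP enumeration for singly
  charged [M−H]⁻ ions within a ppm tolerance, chemical plausibility
  filters (integer DBE ≥ 0, H/C ∈ [0.3, 2.5], O/C ≤ 1, O ≥ 4P,
  DBE − O ≤ 10) and a deterministic heteroatom-parsimony tie-break.
* **Molecular indices** — DBE; DBE_AI = 1 + C − O/2 − S − (N+P+H)/2;
  AI_mod = DBE_AI / (C − O/2 − N − S − P) (clamped at 0); NOSC; the
  degradation index I_Deg; the standard four compound categories with
  O-rich/O-poor subdivision.
* **Alpha-diversity** — richness D_R, Gini–Simpson D_A = 1 − Σ pᵢ², and
  Rao quadratic entropy D_F = Σᵢ Σⱼ pᵢ pⱼ |xᵢ − xⱼ| for six chemical
  properties.
* **Beta-diversity** — Jensen–Shannon divergence (base-2 logs, bounded in
  [0, 1]) of presence-based DBE_AI distributions binned on the 0.5 grid,
  and Bray–Curtis dissimilarity of normalised intensities.
* **Community analysis** — average-linkage clustering with
  silhouette-chosen k, NMDS, post-hoc environmental vector fitting,
  indicator-formula analysis (IndVal = specificity × fidelity, permutation
  tests, Benjamini–Hochberg adjustment), and Mantel tests of
  distance decay against great-circle and z-scored environmental
  distances.
* **A synthetic lake-survey generator** — peak lists plus environment
  tables with exact ground truth (planted lake types, cluster-exclusive
  marker formulas, an EC-driven richness gradient, and coordinates
  independent of composition), so the whole pipeline is testable without
  field data.

Standard steps run through the field's standard packages (vegan, cluster,
geosphere, ape); the formula/index/diversity layer and the generator are
implemented and tested here.

## Worked example

Assign formulas to a three-peak list and inspect the indices:

```r
library(domdiv)
pl <- peaklist(
  mz = c(167.034983, 179.034996, 187.097581),
  intensity = c(2.1e7, 1.4e7, 0.8e7),
  sample_id = "lake_A"
)
asg <- assign_sample(pl)
asg$assignments[, c("mz", "formula", "error_ppm", "intensity")]
#>         mz       formula    error_ppm intensity
#> 1 167.0350  C8H8O4N0S0P0 -0.004403654   2.1e+07
#> 2 179.0350  C9H8O4N0S0P0 -0.076315411   1.4e+07
#> 3 187.0976 C9H16O4N0S0P0  0.007974276   8.0e+06

formula_indices(parse_formula(asg$assignments$formula))[
  , c("formula", "dbe", "dbe_ai", "ai_mod", "nosc", "category")]
#>         formula dbe dbe_ai    ai_mod       nosc           category
#> 1  C8H8O4N0S0P0   5      3 0.5000000  0.0000000 highly_unsaturated
#> 2  C9H8O4N0S0P0   6      4 0.5714286  0.0000000           aromatic
#> 3 C9H16O4N0S0P0   2      0 0.0000000 -0.8888889        unsaturated
```

All three peaks resolve to a unique formula with sub-0.1 ppm error;
vanillic acid (C8H8O4) sits exactly on the aromatic threshold
(AI_mod = 0.5, classified highly unsaturated), its C9 homologue crosses it.

A small synthetic survey, end to end:

```r
sv <- generate_survey(survey_config(
  n_lakes = 8,
  pool_sizes = c(fresh = 150, highly_unsaturated = 200, aromatic = 120),
  seed = 1
))
asg_all <- lapply(sv$peaklists, assign_sample)
head(alpha_diversity(asg_all)[, c("sample_id", "D_R", "D_A", "D_F_NOSC")], 4)
#>   sample_id D_R       D_A  D_F_NOSC
#> 1       L01 324 0.9907705 0.5088765
#> 2       L02 345 0.9921691 0.5182561
#> 3       L03 215 0.9881734 0.5640930
#> 4       L04 182 0.9866470 0.4926344
```

Richness (D_R) falls from the dilute proglacial lakes (L01, L02) to the
saline ones, D_A stays near its ceiling (no formula dominates the
intensity distribution), and D_F(NOSC) says two random molecules differ by
about 0.5 units of carbon oxidation state. The survey reproduces the
distance-decay contrast the generator plants — composition tracks the
environment, not geography:

```r
m  <- normalize_intensities(assemble_formula_matrix(asg_all))
bc <- bray_curtis_matrix(m)
mantel_test(bc, env_distance(sv$env),    n_perm = 999, seed = 1)
#> Mantel vs environment: r_M = 0.692, p = 0.001
mantel_test(bc, haversine_matrix(sv$env), n_perm = 999, seed = 1)
#> Mantel vs space:       r_M = 0.262, p = 0.106
```

The methods vignette (`vignettes/dom-molecular-diversity.Rmd`) documents
the models, parameter defaults, the generator's mechanisms, and known
limitations.

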