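---
title: "Molecular diversity of DOM from FT-ICR MS peak lists: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular diversity of DOM from FT-ICR MS peak lists: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domdiv)
```

## The analysis in one paragraph

Ultrahigh-resolution mass spectrometry (FT-ICR MS) resolves thousands of
exact masses in a single dissolved organic matter (DOM) extract, each
assignable to a unique CHNOSP molecular formula. `domdiv` treats those
formulas as the "species" of a molecular community: per-sample peak lists
become a samples x formulas intensity matrix, alpha-diversity summarises
how many and how evenly formulas occur within a sample, beta-diversity
quantifies compositional differences between samples, and community-ecology
machinery (clustering, ordination, indicator analysis, Mantel tests)
relates those differences to the environment. A synthetic lake-survey
generator with known ground truth closes the loop: every stage of the
pipeline can be validated end-to-end without access to field data.

## Formula assignment

Peaks are singly charged, even-electron [M-H]⁻ ions, so a measured m/z is
converted to a neutral mass by adding one proton mass (1.00727646 Da).
Candidates are enumerated exhaustively inside configurable element ranges
(defaults C 1–60, H 1–122, N 0–4, O 0–40, S 0–2, P 0–1, community-standard
DOM settings) within a mass tolerance of 0.5 ppm, then filtered by
chemical plausibility:

* integer DBE ≥ 0 (even-electron neutral molecule),
* H/C in [0.3, 2.5] and O/C ≤ 1 (the occupied region of van Krevelen space),
* O ≥ 4P (phosphorus occurs as phosphate in DOM), and
* DBE − O ≤ 10 (natural SPE-DOM carries enough oxygen to account for its
  unsaturation).

The last two rules matter more than they may look. Element swaps such as
−N₄ −O₆ +C₁₀ +H +P change the exact mass by only 0.197 mDa, which falls
inside a 0.5 ppm window above roughly 400 Da; without the phosphate and
oxygen-deficit rules such near-isobaric candidates would systematically
displace genuine N-rich formulas. Remaining ties are broken
deterministically: candidates without phosphorus first (P-bearing
assignments conventionally require isotopologue confirmation), then fewest
heteroatoms (N+S+P), then smallest |mass error|, then canonical formula
order. Assignment is therefore a pure function of the peak list and the
configuration.

## Molecular indices

For a neutral formula CcHhNnOoSsPp the package computes

* DBE = 1 + c − h/2 + n/2 + p/2, rings plus double bonds;
* DBE_AI = 1 + c − o/2 − s − (n + p + h)/2, the unsaturation of the
  molecular core after discounting heteroatom-attributable double bonds —
  its values fall on a 0.5 grid, which is what makes it convenient to bin;
* AI_mod = DBE_AI / (c − o/2 − n − s − p), clamped to 0 when either the
  numerator or the denominator is ≤ 0; values above 0.5 flag aromatic
  structures. Values above 1 are possible for exotic cores and are not
  clipped;
* NOSC = 4 − (4c + h − 3n − 2o + 5p − 2s)/c, the nominal oxidation state
  of carbon (checked against glucose = 0 and methane = −4).

Compound categories follow the standard four-way partition — saturated
(DBE = 0), aromatic (AI_mod > 0.5), unsaturated (H/C ≥ 1.5), highly
unsaturated (the remainder) — evaluated in that order so the classes are
mutually exclusive; each is subdivided into O-rich (O/C ≥ 0.5) and O-poor.

The degradation index I_Deg is an intensity ratio over ten reference CHO
formulas, five enriched in altered DOM (the numerator) and five associated
with fresh material. The shipped reference set
(`inst/extdata/ideg_formulas.csv`) is a transcription of the ten formulas
conventionally used for this index; because the defining publication is
not bundled with the package, the set is deliberately configuration, not
code — any disjoint pair of formula sets can be supplied.

## Alpha- and beta-diversity

Within a sample, with relative intensities $p_i$ over distinct formulas:

* richness $D_R$ — the number of distinct formulas;
* Gini–Simpson $D_A = 1 - \sum_i p_i^2$ — the probability that two
  randomly drawn molecules differ in formula;
* Rao quadratic entropy $D_F = \sum_i \sum_j p_i p_j |x_i - x_j|$ — the
  expected difference between two molecules in a chemical property $x$
  (carbon number, H/C, N/C, AI_mod, DBE, NOSC are reported by default).
  The implementation sorts and uses prefix sums ($O(n \log n)$); tests
  pin it to the naive double sum.

Between samples the package computes two complementary dissimilarities:

* the Jensen–Shannon divergence of binned DBE_AI distributions. Each
  sample's distinct formulas are binned on the global 0.5 grid
  (presence counts, not intensities — so the measure is robust to
  intensity calibration); JSd uses base-2 logarithms, hence is bounded in
  [0, 1], symmetric, and 0 only for identical distributions. Bins are
  aligned on the union of supports and empty bins contribute nothing
  (0·log 0 = 0). An intensity-weighted variant exists but is off by
  default.
* Bray–Curtis dissimilarity of row-normalised intensities, the standard
  currency for cross-study comparison, computed with `vegan::vegdist`.

## Community analysis

Average-linkage hierarchical clustering runs on the JSd matrix; the number
of clusters is chosen by maximising the mean silhouette width computed
from the original distance matrix (not from ordination coordinates), over
k = 2 … min(10, n−1), ties resolved towards the smallest k. NMDS
(`vegan::metaMDS`) provides the two-dimensional view, and environmental
variables are fitted post hoc with `vegan::envfit` (least-squares vectors,
permutation p-values).

Indicator formulas use the classical IndVal: specificity
$A_{ic}$ = mean abundance of formula *i* in cluster *c* divided by the sum
of its cluster means (group-size-unweighted), fidelity $B_{ic}$ = fraction
of the cluster's samples containing the formula, and
$\mathrm{IndVal}_i = \max_c A_{ic} B_{ic}$. Abundance means normalised
intensity: the index's "relative average abundance" reads most naturally
as intensity-based, and presence/absence is recoverable by binarising the
matrix first. Significance comes from permuting cluster labels
(statistic = the max over clusters), with the additive-smoothing estimator
$p = (1 + \#\{ \mathrm{perm} \ge \mathrm{obs} \})/(n_\mathrm{perm} + 1)$
so p-values are never zero, and Benjamini–Hochberg adjustment across
formulas.

Distance decay is tested with the Mantel statistic (Pearson correlation of
corresponding distance entries, via `vegan::mantel`) against two
predictors: great-circle distance (haversine, Earth radius 6371.0088 km)
and the Euclidean distance of z-scored environmental variables (EC, pH,
water temperature, DIN by default). EC is log10-transformed before
z-scoring because conductivity spans four orders of magnitude across lake
types. The permutation test is one-sided ("greater"): the scientific
hypothesis is that compositional dissimilarity *increases* with distance,
so only positive correlations count as evidence.

## The synthetic lake survey

The generator is phenomenological: it does not integrate photochemical
kinetics, it plants the *statistical signatures* of three mechanisms as
inclusion-probability modifiers on a shared regional formula pool, so that
ground truth stays exact.

The pool (defaults: 2700 "fresh" H/C ≥ 1.5, N-bearing formulas; 3100
highly unsaturated; 1500 aromatic; ~7300 total, a scale comparable to real
surveys) is drawn by rejection inside the assignment module's plausibility
space, so every planted formula survives its own pipeline. Mechanisms:

* **Evapo-concentration / photodegradation.** A lake's inclusion
  probability for a formula is
  `base_rate × exp(−degradation_strength · z · max(AI_mod, 0))`, capped at
  1, where z is the z-scored log10 EC (saturating at `z_saturation` = 2:
  once the photodegradable stock is gone, further concentration removes
  little). Defaults `base_rate` = 0.35 and `degradation_strength` = 1.4
  place the four lake types at distinct positions along the aromatic-
  retention axis while keeping per-lake richness in the low thousands.
  An additional pH penalty (0.6 per pH unit above 7) acts on O-rich
  aromatics.
* **N-enrichment in proglacial lakes.** The fresh class is up-weighted
  (×1.8), and the lowest-DBE_AI fifth of the fresh class — the most
  aliphatic, protein-like material — occurs only in proglacial lakes
  (inclusion 0.95 there, 0 elsewhere). These are the planted
  proglacial-exclusive indicators.
* **Sulfurization in hypersaline lakes.** A fixed 8% of the pool, drawn
  from the high-DBE_AI, O-bearing end (quinone-like cores react readily
  with sulfide), appears in hypersaline lakes as the one-O-for-one-S
  analog (inclusion 0.95 — sulfide-rich brines both form and preserve
  these products) and nowhere else. The S-analogs are the planted
  hypersaline-exclusive indicators.

Environment tables draw EC lognormally per lake type (medians 0.01, 0.08,
2 and 40 S m⁻¹ for proglacial, freshwater, saline, hypersaline; the
hypersaline median sits above the >22 S m⁻¹ convention), pH in the
neutral-to-basic band (7.1–8.9), DIN elevated in hypersaline lakes, DOC
increasing with EC, and coordinates uniform over a ~50 km coastal window
*independently of everything else* — so space carries no compositional
signal by construction. Intensities are lognormal (meanlog 16, sdlog 1);
the ten I_Deg reference formulas are present in every lake with intensity
ratios that put I_Deg near 0.15, the fresh-DOM regime. Observed m/z values
are [M-H]⁻ masses with Gaussian jitter (sd 0.2 ppm) truncated at ±2 sd —
calibrated peak lists have bounded residual errors, and unbounded tails
would make a fraction of planted peaks unassignable at any tolerance.

What the generator does *not* emulate: isotopologue peaks, intensity
nonlinearity and ionisation suppression, isomers behind a formula,
replicate-level technical noise structure, and any real spatial
autocorrelation of the environment. Passing the end-to-end tests therefore
demonstrates that the pipeline recovers planted structure of realistic
size and shape — not that it would recover every structure present in
field data.

## Numerical choices and degenerate inputs

* Peak lists reject non-positive intensities and m/z duplicates within
  0.1 mDa rather than merging them; ingestion sorts by m/z.
* Blank subtraction keeps a matched peak only if sample ≥ 5 × blank
  intensity (0.5 ppm matching); both knobs are arguments.
* Normalisation refuses zero-sum rows and is idempotent; matrix columns
  are ordered by exact mass with an element-count tie-break so output is
  bit-stable.
* JSd clamps tiny negative rounding residues to 0 and its inputs must sum
  to 1 within 1e-6.
* All-equal distance matrices cluster with a warning and the smallest k.
* Permutation seeds are explicit arguments everywhere; given (input,
  seed), clustering, NMDS, IndVal and Mantel results are reproducible.
* Problem sizes in the shipped tests: the default 40-lake survey with a
  ~7300-formula pool for end-to-end recovery; 500 replicates × 999
  permutations for the null calibration of Mantel and envfit; 600 uniform
  draws for the assignment round-trip. These sizes give stable statistics
  while keeping a full test run in a few minutes.

## Known limitations

* Formula-level diversity underestimates true molecular diversity: every
  formula hides an unknown number of isomers.
* The default I_Deg reference set should be checked against the original
  source before quantitative cross-study comparison of I_Deg values.
* The blank-filter rule and assignment caps are conventional defaults,
  not instrument-calibrated values; both are fully configurable.
* IndVal's permutation test is run with the classical unweighted group
  means; strongly unbalanced cluster sizes may favour small clusters.

## A worked micro-example

```{r example}
sv <- generate_survey(survey_config(
  n_lakes = 8,
  pool_sizes = c(fresh = 150, highly_unsaturated = 200, aromatic = 120),
  seed = 1
))
asg <- lapply(sv$peaklists, assign_sample)
alpha_diversity(asg)[, c("sample_id", "D_R", "D_A", "D_F_NOSC")]
d <- jsd_matrix(asg)
round(as.matrix(d)[1:4, 1:4], 4)
```
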