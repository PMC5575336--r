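---
title: "From amplicon tables to nitrogen-cycle function: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From amplicon tables to nitrogen-cycle function: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`nitroguild` links the taxonomic composition of a soil prokaryotic
community to its nitrogen-cycle potential. This vignette documents the
models behind each stage, the tunable parameters and their defaults,
the numerical choices, and what the synthetic-data tests do and do not
demonstrate about real data.

## 1. Absolute abundance scaling

Amplicon counts are compositional: only the relative profile within a
sample is informative, and correlations computed on relative data can
be artifacts of the closure constraint. We therefore scale relative
abundances to absolute SSU gene copy numbers before any co-occurrence
work. With `Q_d(j)` the qPCR copy number of domain *d* (bacteria,
archaea, fungi) in sample *j* (copies·ngDNA⁻¹),

$$A_{ij} = \frac{rel_{ij}}{\sum_{i' \in d(i)} rel_{i'j}} \; Q_{d(i)}(j).$$

The within-domain renormalization reflects that a bacterial 16S qPCR
assay measures bacterial copies only. A `pooled` mode (raw relative
abundance times the summed copy numbers) is available for tables where
domain-specific assays were not run. Note the units: these are gene
*copies*, not cells — no per-genome SSU copy-number correction is
applied, because the downstream quantities (guild ratios, network
scores) are ratios or rank statistics for which the correction largely
cancels, and reliable per-taxon copy numbers are not generally
available.

qPCR quantification itself is modeled by the standard curve
`Ct = slope·log10(copies) + intercept` with amplification efficiency
`(10^(-1/slope) − 1)·100 %`. Published efficiencies sometimes disagree
with this formula at the stated slopes (e.g. "93–95 %" reported for
slopes −3.34 to −3.53, where the formula gives 99–92 %); we implement
the standard formula and note the discrepancy rather than reconcile it.

## 2. Functional guild quantification

Genus-level annotation tables (one genus, one or more marker genes)
drive guild assignment; an OTU inherits the genes of its genus. The
fixed vocabulary maps genes to pathways: nitrate reduction (napA,
narG), denitrification (nirK, nirS, norB, nosZ), DNRA (nrfA), N₂
fixation (nifH), ammonia oxidation (amoA). Design choices:

* **Genus rank only.** No fallback to family: fidelity over coverage.
  The mass of unannotated OTUs is reported so the user can judge
  coverage.
* **Membership counting.** A pathway's abundance is the summed
  absolute abundance of OTUs carrying *at least one* of its genes; an
  organism is not counted twice for carrying both nirK and nosZ. This
  matches the organism-level notion "microorganisms capable of X".
  Consequently adding a second denitrification gene to an
  already-denitrifying genus changes nothing (a tested invariant).
* **norB stays in denitrification** even though nor genes alone do not
  complete the pathway; the printed vocabulary is kept as is.
* **Ratios on group means.** The denitrification:DNRA ratio is the
  ratio of group-mean abundances (per-sample ratios are attached for
  dispersion), because the headline community-level contrast is a
  property of the group profile, not the mean of noisy per-sample
  ratios.

## 3. The co-occurrence ensemble

### Measures and candidates

Five association measures are scored over all OTU pairs on the
absolute table: Spearman and Pearson correlation on raw rows;
Bray–Curtis dissimilarity `Σ|x−y|/Σ(x+y)`; symmetrized
Kullback–Leibler divergence on Laplace-smoothed profiles
`p_i = (x_i+1)/(Σx+n)`; and mutual information on
equal-frequency-discretized rows with `B = ⌊√n⌋` bins (robust at the
16–31 samples typical of such studies; ties in the discretization are
broken by sample index so the binning is deterministic under
bootstrap). Per measure, the `top_n` highest and `bottom_n` lowest
scoring pairs become candidates (defaults 1000/1000, the reference
configuration); all pairs tied with the cutoff are included so the
selection is order-independent. The candidate set is the union across
measures, each candidate tagged with its proposers.

### Permutation null and p-value

For each candidate edge, one row's sample order is shuffled `n_perm`
(default 100) times; a single shared shuffle per iteration scores all
five measures, so the joint null preserves the strong cross-measure
dependence. Because inputs are absolute abundances, no compositional
renormalization (ReBoot-style) is applied during permutation. The
p-value is the add-one estimator `(1+k)/(n_perm+1)` with *k* the
number of null scores at least as extreme as the observed one,
extremeness being the absolute deviation from the null median. This
rule is calibrated (uniform under the null) for signed correlations
and one-sided dissimilarity measures alike, attains its floor 1/101
for a strong edge, and returns 1 when the observed score equals every
null score. A naive "one-sided in the direction of the observation"
rule looks similar but halves every null p-value (mean 0.25) and
destroys calibration — a property the test suite checks explicitly.

### Stability

CoNet-style workflows filter "unstable" edges using a bootstrap; the
exact criterion is not published. We resample samples with replacement
`n_boot` (default 100) times (a draw with fewer than three distinct
samples is redrawn, with capped retries) and call a measure stable
when its central `1−α` bootstrap interval is **disjoint** from its
central `1−α` permutation-null interval (α = 0.05 by default; edges
are re-checked at α = 0.01 for robustness, and tightening α can only
shrink the network — a tested invariant). An edge is stable when a
strict majority of measures is stable. We considered the weaker rule
"null median outside the bootstrap interval": it admits null pairs
with sample |r| ≈ 0.5 under every measure at n = 30, and since a
100-permutation p-value cannot resolve below 1/101, no downstream
correction can remove them — on planted-block benchmarks precision
stalls near 0.73. The disjointness rule separates at |r| ≈ 0.55,
keeping ρ = 0.9 blocks (per-edge sensitivity 0.998) while passing
fewer than 5 in 10 000 null pairs; it is also the more literal reading
of "bootstrap distribution overlapping the null". The median rule
remains available (`stability_test = "median"`).

### Merging dependent evidence

The five measures are highly dependent, so their p-values cannot be
combined as if independent. Two merging routes are implemented:

* `merge_method = "empirical"` (default): Fisher's statistic
  `X = Σ −2 log p` is evaluated against the edge's own joint
  permutation null — the observed score vector and its 100 null
  vectors form 101 exchangeable candidates, each converted to
  p-values against the pooled score set, and the merged p is the tail
  rank of the observed X. This is exact under exchangeability: merged
  null p-values are discrete-uniform by construction, which the
  calibration suite verifies (Kolmogorov distance < 0.02 against
  uniform on 10 000 simulated null edges; that check runs at
  `n_perm = 400` because a 100-permutation grid has step 1/101 ≈ 0.01
  and would nearly saturate the bound by discreteness alone).
* `merge_method = "brown"`: Brown's method — `X ~ c·χ²(f)` with
  `c = Var(X)/(2E[X])`, `f = 2E[X]²/Var(X)`, `E[X] = 2k`,
  `Var(X) = 4k + 2Σ cov`, covariances of the `−2 log p` terms
  estimated from the edge's permutation p-series (Fisher fallback if
  estimation is degenerate). At zero covariance this is exactly
  Fisher; with duplicated, perfectly dependent p-values it returns
  the single p. At 100 permutations the χ² tail approximation leaves
  visible miscalibration (Kolmogorov distance ≈ 0.03), which is why
  it is not the default.

Benjamini–Hochberg correction is applied over the stable edges (the
workflow order: unstable edges are removed first, then evidence is
merged and corrected), and edges with `q ≤ 0.05` are retained.
Isolated candidates disappear with their edges. Edge sign: correlation
measures vote by the sign of their score; dissimilarity measures vote
co-presence when the observed score is below the null median; mutual
information is unsigned and abstains; ties default to co-presence.

## 4. Keystones

Degree, Brandes betweenness (normalized by `(n−1)(n−2)/2`) and
closeness as the reciprocal mean shortest-path length to reachable
nodes, computed within connected components (the NetworkAnalyzer
convention; isolated nodes get 0). Published keystone tables are
degree-sorted but the exact selection rule is never stated; we rank by
degree, breaking ties by higher closeness (more central), then lower
betweenness (embedded in a cohesive neighborhood rather than bridging),
then OTU id for determinism, and return the top *k* (default 7, the
count reported per forest stand in the motivating study).

## 5. Soil stoichiometry

* **Biomass:** `Cmic = (DOC_fum − DOC_nonfum)/k_EC` with `k_EC = 0.38`;
  `Nmic` with `k_EN = 0.54`. Negative extract differences (measurement
  noise) are floored at zero with a warning rather than propagated
  into ratios.
* **Net rates:** `(c_21 − c_7)/336 h` for NH₄⁺ (ammonification) and
  NO₃⁻ (nitrification); the 14-day interval between the day-7 and
  day-21 extractions is the denominator. Rates may be negative (net
  immobilization).
* **Specific respiration:** respiration/Cmic, reported ×1000 (nmol C
  per µmol-biomass-C scale of the reference tables).
* **CUE model:** the source methodology cites a stoichiometric CUE
  calculation without printing the equation. We adopt the saturating
  model `CUE = CUE_max·S/(S + K)` with `S = B/L`, `B = Cmic/Nmic`,
  `L` the substrate C:N, `CUE_max = 0.6`, `K = 0.5` — at the spruce
  group means (B = 11.0, L = 30.7) it gives 0.2505 against the printed
  0.24, within averaging error. `NUE = min(1, CUE·L/B)` (equal to CUE
  when substrate matches biomass stoichiometry) and the critical C:N
  ratio `B/CUE` (45.8 at the printed CUE, against the printed 46.0)
  are inferences of the same kind and are labelled as model-based in
  the documentation. All constants are arguments.
* **Substrate C:N:** default DOC/DN of the soil leachate, which makes
  the NUE back-calculation self-consistent; the mineral-N variant
  DOC/(NO₃⁻+NH₄⁺) from the reference table's footnote is available as
  `substrate = "doc_mineral"`. The two disagree in the source; we
  surface both rather than pick silently.
* Everything is computed **per sample** and only then summarized as
  group mean (SD); mean-of-ratios is never silently replaced by
  ratio-of-means (the two differ visibly for enzyme ratios, e.g. a
  group-mean BG/NAG of 3.3 versus 2.5 from the ratio of means).

## 6. The synthetic-data generator

`generate_community()` draws per-sample OTU abundances with log-normal
marginals (meanlog 0, sdlog 1 — heavy-tailed, as amplicon abundance
distributions are) coupled by a Gaussian copula: members of a planted
block share a latent factor giving within-block correlation ρ, blocks
are mutually independent, everything else is independent. Counts are
multinomial draws of fixed depth from the per-sample relative
abundances — sequencing-effort noise, but no PCR error, chimeras or
overdispersion beyond multinomial. Guild genes are planted genus-wise
on the highest-abundance OTUs (pathways disjoint) until each target
fraction of total absolute abundance is reached; the overshoot is at
most one OTU's share and the realized fraction is recorded, so
recovery tests compare against the realized, not the nominal, truth.
qPCR totals are the per-domain column sums of the absolute table —
the generator's qPCR is noise-free, so absolute-scaling round-trips
are exact by construction.

`generate_incubation()` inverts the biomass and rate formulas
(fumigated = non-fumigated + truth × efficiency factor; day-21 =
day-7 + rate × 336 h) with multiplicative Gaussian noise on every
measured quantity. Defaults describe a realistic organic forest-floor
sample: extractable DOC baseline 50 µmol g⁻¹, TN 10 µmol g⁻¹, Cmic
300 and Nmic 40 µmol g⁻¹, net ammonification 0.25 and nitrification
0.05 nmol g⁻¹ h⁻¹, spruce-like leachate chemistry, 5 % relative
measurement noise.

**What passing tests show — and what they don't.** Recovery of planted
blocks (recall ≥ 0.7, precision ≥ 0.8 at q ≤ 0.05 over ten seeds, at
60 OTUs × 30 samples with three ρ = 0.9 blocks) demonstrates that the
inference chain is correct and calibrated under its own assumptions:
monotone copula dependence, independent samples, noise-free qPCR. Real
communities violate all three in degree — compositional distortion
enters through real qPCR error, samples are spatially autocorrelated,
and associations need not be monotone — so these figures are upper
bounds on field performance, not predictions of it.

## 7. Numerical choices and degenerate inputs

* Permutation/bootstrap loops run in compiled code; all randomness
  flows through R's RNG, so a single `set.seed()` (or the `seed`
  argument every stochastic function takes) makes runs byte-identical,
  a property the test suite asserts on whole pipeline outputs.
* Constant rows make correlations undefined: such pairs are skipped
  and counted, never silently zeroed.
* Chao1 uses the bias-corrected form `S + F1(F1−1)/(2(F2+1))`, defined
  when doubletons are absent; singletons are defined on the
  whole-table total (one sequence in the entire dataset).
* Rarefaction subsamples without replacement and drops samples below
  the target depth with a warning; it never upsamples.
* p-values of exactly 0 passed to `merge_brown()` are clamped to the
  machine minimum with a warning; the add-one permutation estimator
  cannot produce them internally.
* Test-suite problem sizes (60 × 30 recovery benchmark, 10 000-edge
  calibration at 400 permutations, 10×10 oracle tables, graphs up to
  n = 50) were chosen as the smallest sizes at which each property is
  non-trivially exercised.

## 8. Known limitations

* Genus-level annotation misses strain-level gene variation in both
  directions; the unannotated fraction is reported but not imputed.
* The stability and merging rules are operational interpretations of
  a partially specified workflow; the alternatives are kept as
  options and the defaults are the ones that pass calibration.
* Taxonomy-aware candidate pruning (parent–child exclusion) is not
  implemented; lineage-correlated OTU pairs are not filtered.
* No time-series or compositional-equilibrium estimators (SparCC,
  SPIEC-EASI); the package targets the absolute-abundance route.
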