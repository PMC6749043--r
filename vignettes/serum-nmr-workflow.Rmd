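---
title: "Serum 1H-NMR metabolic profiling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serum 1H-NMR metabolic profiling: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`nmrmetab` implements a complete serum ^1^H-NMR metabolomics workflow for
the spontaneously hypertensive rat (SHR) model and its Wistar-Kyoto (WKY)
control: a synthetic-spectrum generator parameterized from published
biomarker tables, spectral preprocessing, supervised multivariate
modelling with honest validation, univariate biomarker selection, and
pathway screening. This vignette explains the underlying models, the
parameters that matter, and the design decisions taken where the
methodology left genuine freedom.

## The synthetic cohort generator

No raw spectra are deposited for this study design, so the package ships a
forward model that renders cohorts with known ground truth. Each
metabolite is a sum of Lorentzian multiplets at its tabulated chemical
shifts; a sample's spectrum is

$$ I(\delta) \;=\; d \Big( \sum_m c_m \sum_r a_{mr}\, L_{mr}(\delta) \;+\;
b(\delta) \Big) \;+\; \varepsilon(\delta), $$

where $c_m$ is the metabolite concentration, $a_{mr}$ the relative area of
resonance $r$, $L_{mr}$ a unit-area Lorentzian multiplet, $b$ a slow
sinusoidal macromolecule baseline, $\varepsilon$ i.i.d. Gaussian noise,
and $d$ the per-sample dilution factor. Two modelling points deserve
emphasis:

* **The dilution factor multiplies the whole sample, baseline included.**
  Physically the broad macromolecule background is part of the serum and
  dilutes with it; only the instrumental noise sits outside $d$. This also
  makes the generator coherent with probabilistic quotient normalization:
  with an additive, undiluted baseline the median feature-wise quotient
  cannot track dilution even in principle, and in early experiments it
  absorbed roughly 10% of the group effect instead.
* **The baseline envelope is cohort-fixed.** Its phase is drawn once per
  cohort and samples vary only in amplitude (5% CV by default), mirroring
  the reproducible macromolecule background of one acquisition series. A
  per-sample random baseline shape would spread the quotients of
  baseline-dominated bins so widely that the PQN median slides into the
  peak bins and inherits their group effects.

Multiplet conventions, chosen once because only multiplicity codes are
tabulated: s = 1 line, d = 2 equal lines, t = 1:2:1, q = 1:3:3:1,
dd = 4 equal lines (couplings $J$ and $0.4J$), m and br = one Lorentzian
broadened to three times the base linewidth. $J$ is fixed at 7 Hz and
converted to ppm at the 599.808 MHz observation frequency.

Defaults, per `cohort_design()`: 10 samples per group (the study's cohort
size), grid 0.5-9.0 ppm with 16384 points, linewidth 0.002 ppm HWHM
(about 1.2 Hz, a typical shimmed serum line), biological CV 10% per
metabolite (log-normal around the group mean, so the group mean equals
the injected target exactly), dilution log-SD 0.1, noise SD 0.3 intensity
units against singlet peak heights near $1/(\pi w) \approx 160$ per unit
concentration, baseline amplitude 2 (a few percent of a typical peak).
The per-sample dispersion and SNR of the real spectra are not reported
anywhere; these values are stated choices, not inferences.

Group means follow the fold-change (FC) columns of the transcribed
biomarker tables, and contrasts chain: the treatment group's mean is the
disease group's mean times the treatment FC. Base levels are mostly 1.0,
with glucose, lipoprotein and lipid signals raised and trace aromatics
lowered, roughly as in serum.

### What the generator does not emulate

Free-induction decay and phasing artifacts, water-suppression residuals
beyond the excluded band, peak-position jitter (pH/ionic-strength shift
drift), ridge-like baseline distortions, and correlated biological
variation between metabolites. Passing recovery tests on these cohorts
therefore demonstrates the pipeline's statistical machinery, not
robustness to misreferenced or badly phased real spectra.

## Preprocessing

1. **Exclusion** of 4.33-5.50 ppm (residual water and affected signals).
2. **Adaptive binning** at a target mean width of 0.015 ppm. The binning
   variant is deliberately simple: uniform seed boundaries within each
   retained segment, each interior boundary moved to the lowest point of
   the cohort-mean spectrum within +/-40% of the target width (ties break
   toward the seed, so flat spectra bin uniformly), then bins narrower
   than 25% of the target merge into their narrower neighbour. Minima
   placement keeps peaks intact inside single bins; cells are trapezoidal
   integrals, so a row's bins sum exactly to its retained total integral.
3. **PQN**: rows are scaled to the cohort's median total integral, then
   divided by the median feature-wise quotient against the median spectrum
   (all samples by default; a named control group optionally). Quotients
   use only features whose reference value exceeds 1% of the reference's
   median positive value, keeping near-zero noise features out of the
   median. PQN is exactly idempotent on pure-dilution data and idempotent
   to within a fraction of a percent otherwise (the second pass's
   quotients are all ~1).
4. **Pareto scaling**: each column is mean-centred and divided by the
   square root of its standard deviation, so the post-scaling variance
   equals the pre-scaling SD — large peaks are damped without the noise
   amplification of unit-variance scaling. Constant columns become zeros
   with a warning rather than being dropped, keeping feature indices
   stable.

A caveat worth knowing: when a large fraction of the total spectral mass
changes between groups (as in these cohorts, where most tabulated
metabolites carry effects), the PQN quotient retains a small group
component and fold-change estimates are mildly shrunk toward 1. With the
cohort-fixed baseline this residual bias is about 1-5% here; it is a
property of quotient normalization itself, not of the implementation.

## Multivariate modelling

PCA is the standard SVD on the scaled matrix. OPLS-DA follows the
orthogonal-projection scheme for a single response: class membership is
coded -1/+1 (second factor level positive), $y$-orthogonal components are
extracted from X and removed, and one predictive PLS component is fitted
on the filtered X. With zero orthogonal components the fit reduces exactly
to one-component PLS1, which the test suite verifies against a brute-force
NIPALS oracle. The predictive weight vector is signed so the second-listed
class has a positive mean score.

* **Q²** uses repeated (default 7) stratified twofold cross-validation.
  Orthogonal and predictive components are re-estimated inside every
  training fold — the held-out half contributes nothing to the filter, so
  there is no information leak. PRESS is evaluated on held-out coded
  responses against the training-fold mean, pooled over both folds and
  averaged over repeats. The repeat count is a stated choice; only
  "repeated twofold" is prescribed.
* **The permutation test** refits under randomly permuted labels and
  scores each permutation with the same cross-validated Q². The p-value
  uses the add-one estimator $(1 + \#\{Q^2_{perm} \ge Q^2_{obs}\})/(n+1)$,
  whose floor $1/(n+1)$ avoids claiming $p = 0$. Under exchangeable nulls
  the p-values are uniform (checked by a KS test over 200 replicates).
* **VIP** is computed over the predictive component only (discriminant
  reading): with a unit-norm weight vector, $VIP_j = \sqrt{p}\,|w_j|$ and
  the mean squared VIP is exactly 1. A total-model variant weighting
  orthogonal components by explained X-variance is available via
  `compute_vip(type = "total")`. For metabolite-level selection, VIP is
  evaluated on the bin-level model and read off per metabolite as the
  maximum VIP among bins overlapping its integration window
  (`metabolite_vip()`): scoring peaks keeps the VIP > 1 convention
  meaningful, because with hundreds of bins the mean squared VIP of 1
  sits among baseline bins. Computing VIP on the ~30 metabolite integrals
  instead lets one dominant effect absorb the weight norm and pushes most
  genuine effects below 1 (measured sensitivity drops from ~0.86 to
  ~0.33).

## Biomarker selection

Metabolite integrals are taken over +/-0.012 ppm around each metabolite's
marker resonance. The shipped library marks one integration shift per
metabolite, defaulting to the first tabulated shift but overridden where
that shift collides with another metabolite's resonance (glutamine 2.45,
methionine 2.64, lactate 4.11, betaine 3.91, myo-inositol 3.63, creatine
3.93, histidine 7.07); overlapping windows are flagged, and windows inside
the excluded region are errors.

Per contrast, each metabolite gets a Student (equal-variance) t-test with
Benjamini-Hochberg correction across the metabolite set, a group-mean
fold change (case over reference), and its peak VIP. Selection uses
**raw p < 0.05 and VIP > 1**: the printed tables this package transcribes
contain p-values up to 0.047 that were counted as significant, which is
consistent with raw-p thresholds even though BH correction is reported
alongside; both values are always carried.

The **potential-biomarker rule**: metabolites selected in both the disease
and treatment contrasts *and* whose fold changes cross 1 in opposite
directions, $(FC_{disease}-1)(FC_{treatment}-1) < 0$. Plain two-way
significance alone leaves four additional same-direction metabolites
(isoleucine, lysine, pyruvate, N,N-dimethylglycine); the reversal
criterion reproduces the published 13-metabolite set exactly and encodes
the pharmacological reading — the treatment pushes the disturbed level
back past the reference. The plain intersection is returned alongside for
transparency. Name matching is case-insensitive with an alias map
(LDL/VLDL = VLDL/LDL).

## Pathway screening

Enrichment is the hypergeometric upper tail per pathway, BH-corrected
across pathways, over a background defaulting to the union of pathway
nodes and the mapped biomarkers. Topology impact is the sum of relative
betweenness centralities (normalized by $(n-1)(n-2)/2$) of matched nodes
divided by the pathway total; pathways with impact strictly above 0.1 are
screened as targets. When every node has zero betweenness (two-node
graphs), the matched fraction substitutes so a full match still scores 1.

The packaged pathway graphs are small hand-curated reaction adjacencies
(KEGG compound identifiers as labels, 4-16 nodes) for the ten pathways
relevant to these biomarkers plus five decoys; they reproduce the
computation, not any database snapshot, so screened-pathway counts are
not comparable to results obtained against a full KEGG library. The
metabolite-protein map is likewise a curated stand-in
(`metabolite_protein_map_synthetic.csv`) restricted to ten
hypertension-related enzymes, with edges justified by enzyme-substrate
relationships (e.g. tyrosine to tyrosine hydroxylase and tyrosinase;
methionine and serine to the transsulfuration enzymes CBS and CTH).
DDC's substrates (L-DOPA, 5-HTP) are not among the profiled serum
metabolites, so DDC carries no edge.

## Numerical choices and degenerate inputs

* Ties in boundary placement resolve toward the uniform seed; flat
  spectra therefore bin uniformly.
* Rows with non-positive total integral abort PQN with the sample named;
  zero-variance features scale to zero with a warning and map to
  covariance/correlation (0, 0) in loadings plots.
* Fold changes require positive group means and error otherwise rather
  than silently offsetting.
* All stochastic steps (cohort generation, CV splits, permutations) take
  explicit seeds and restore the session RNG state afterwards; one
  pipeline seed derives per-stage seeds by stage-name hashing, so
  enabling or disabling a stage does not shift the others' streams.

## Problem sizes in the test suite

The test and validation suites run on deliberately compact problems
chosen to exercise every code path: cohorts of 5-10 samples per group on
4096-16384-point grids, 20 random 12x30 matrices for the PLS1 oracle, 200
replicate datasets at 99 permutations for the p-value calibration, and
10-20 replicate cohorts for fold-change recovery and selection
sensitivity. Each was picked as the smallest size at which the property
under test is statistically unambiguous.

## Known limitations

* Two-class OPLS-DA only; multi-class questions are handled pairwise.
* No peak alignment: the generator holds chemical shifts fixed, and real
  spectra with shift drift would need alignment upstream.
* Quotient normalization under pervasive effects retains a small group
  component (see above); fold changes near the selection boundary should
  be read with that in mind.
* The pathway library is illustrative; impact values depend strongly on
  the granularity of the curated graphs.
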