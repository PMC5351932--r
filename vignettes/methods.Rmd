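---
title: "Cross-brain-region methylome association: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-brain-region methylome association: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(crossmeth)
```

# Scope

`crossmeth` implements an end-to-end analysis of array-based DNA methylation
across multiple brain regions and donor cohorts: quality control and
normalization of beta values, probe-wise epigenome-wide association (EWAS)
against a case/control diagnosis or a polygenic risk score (PRS),
inverse-variance fixed-effects meta-analysis across cohorts, a cross-region
linear mixed model, detection of differentially methylated regions (DMRs)
by autocorrelation-corrected Stouffer–Liptak combination with Šidák
correction, a permutation-based family-wise-error (FWER) threshold,
genotype QC / LD pruning / PRS scoring, methylation-QTL (mQTL) scanning,
and Fisher's-exact enrichment of association signal inside GWAS-nominated
genomic regions. Because raw post-mortem brain array data of this design
are not publicly deposited, the package ships a first-class synthetic-data
generator that emulates the study design and provides a ground-truth ledger
against which every stage is validated.

# The data model

A **beta value** is a methylation proportion in $[0,1]$ per probe and
sample; user-facing effect sizes are reported as percentages
(coefficient × 100). The `beta_matrix` container carries optional
same-shape detection-p and beadcount layers used only by QC. Coordinates
are 1-based throughout, and region intervals are inclusive of the first
and last probe position. Missing values are explicit `NA` tokens in every
file format, never zeros.

# Quality control and normalization

Filters follow standard array practice, with the boundary semantics the
thresholds imply implemented literally:

* a **sample** is removed when *more than* 1% of its probes have detection
  $p > 0.01$ (strict inequality);
* a **probe** is removed when detection $p > 0.05$ in *at least* 1% of
  samples, or its beadcount is below 3 in *at least* 5% of samples
  (inclusive boundaries);
* probes flagged as genotyping controls, sex-chromosomal,
  cross-hybridizing or SNP-proximal are excluded;
* the order is samples → probes → flagged probes → normalization. The
  filters are idempotent, and the QC report reconciles exactly with the
  matrix shapes.

Normalization is **between-sample quantile normalization stratified by
Infinium probe type** on beta values: within each type, every sample's
values are replaced by the rank-matched mean-of-sorted reference
distribution (via `limma::normalizeQuantiles`). Intensity-level
normalization methods additionally equalize type-specific backgrounds from
raw channel intensities; raw intensities are outside this package's data
model, so the type-stratified beta-level alignment is the implemented
contract. One consequence is checked and worked around explicitly: after
full quantile normalization all samples share a distribution per type, so
per-sample *global* mean methylation is constant by construction — the
global-mean group comparison therefore runs on the filtered,
*unnormalized* betas.

The sex check reduces the usual multidimensional-scaling inspection to a
deterministic 1-D rule: mean methylation over sex-chromosome probes is
split by two-means clustering (centers initialized at the extremes,
threshold at the midpoint of the cluster means), the cluster-to-sex
mapping that minimizes disagreement is taken, and mismatching samples are
reported but never removed.

# Probe-wise association and diagnostics

Each probe is fitted by ordinary least squares of beta on the exposure
(diagnosis coded control = 0 / case = 1, so positive estimates mean
hypermethylation in cases; or the PRS) plus covariates — age, sex and the
estimated neuronal proportion, the latter dropped for cerebellum, where
NeuN-based deconvolution is not meaningful. Inference is a two-sided $t$
test on the exposure coefficient; complete cases are used per probe, with
dropped-sample counts retained; rank-deficient designs yield flagged rows
rather than errors. Betas (not M-values) are the regression outcome.
Internally probes sharing a missingness pattern are solved in one QR-based
batch, which is what makes the 5,000-permutation FWER procedure and the
20,000-probe pipeline practical on one CPU.

Inflation is summarized by
$\lambda = \chi^2_{1}(1 - \mathrm{median}(p)) / \chi^2_{1}(0.5)$ together
with observed-vs-expected $-\log_{10} p$ pairs for QQ plots. The PC
sensitivity analysis refits the EWAS with the top-$k$ methylation PCs
appended ($k = 1..10$) and reports the correlation of exposure estimates
with the PC-free model. PC scores use a deterministic sign convention
(largest-magnitude loading positive) so runs are bitwise reproducible.

# Meta-analysis and the cross-region model

Cohorts are pooled by **fixed-effects inverse-variance** weighting:
$\hat\theta = \sum w_i \theta_i / \sum w_i$, $w_i = 1/se_i^2$,
$se = (\sum w_i)^{-1/2}$, Wald $z$, with Cochran's $Q$ reported as a
diagnostic only. With two cohorts the between-study variance cannot be
estimated usefully, which is why no random-effects variant is offered.
A group-summary flavour pools per-cohort mean differences of
**covariate-adjusted betas**; "adjusted" is implemented as the observed
value minus the fitted covariate contribution of the full
(exposure + covariates) model, centred to preserve the overall mean. The
naive alternative — residualize on covariates only, then re-add raw group
means — double-counts the group contrast whenever covariates are
unbalanced, and is deliberately not used.

The cross-region model is a linear mixed model per probe: fixed effects
for exposure, sex, age, neuronal proportion and cohort; random intercepts
for donor and for brain region; REML variance components (via `lme4`);
Wald $z$ on the exposure. Cerebellum is excluded by default because its
global methylation profile is an outlier relative to the other regions.
Region enters as a random intercept even though it has only three levels —
a fidelity choice that mirrors the published model rather than a
statistically optimal one. With zero variance components the fit collapses
to pooled OLS (tested), and donor correlation widens the exposure standard
error relative to naive OLS (tested against a known-covariance
construction).

# Region detection

The DMR stack follows the canonical spatially-correlated-p-value pipeline:

1. **ACF estimation**: Pearson correlation of $z = \Phi^{-1}(1-p)$ over
   same-chromosome probe pairs, binned by distance (half-open 50-bp bins
   to 300 bp); bins with under 50 pairs, and negative estimates, are
   truncated to 0, so the combination step never deflates variance.
2. **Smoothing**: each probe's p is replaced by the Stouffer–Liptak
   combination $C = \sum z_i / \sqrt{\mathbf{1}^\top \Sigma \mathbf{1}}$
   of all probes within ±300 bp, with $\Sigma$ from the ACF step function
   (the bin estimate within a bin, 0 beyond the last bin, no
   interpolation). Smoothing can be switched off, in which case seeding
   uses raw p.
3. **Seeding**: maximal runs of probes with smoothed $p < 10^{-3}$ whose
   consecutive members are at most 300 bp apart; runs with fewer than 2
   probes are discarded.
4. **Scoring**: Stouffer–Liptak over the *raw* member p-values with
   $\Sigma$ from the ACF at member distances.
5. **Šidák correction**: $p_{\text{šidák}} = 1 - (1-p)^{n_a/n_r}$ with
   $n_a$ the genome-wide number of probes tested in the EWAS and $n_r$
   the region's probe count, computed in log space (`-expm1(k*log1p(-p))`)
   for numerical stability at small p. $p = 1$ is clamped to
   $1 - 10^{-16}$ before the z-transform.

**Calibration, honestly stated.** At the validation scale used in the
acceptance suite (50 null seeds), the number of Šidák-significant regions
stays within binomial noise of 5% of regions tested. A higher-precision
simulation (600 null seeds, ≈200 selected regions) estimates the
per-selected-region error rate at ≈9%: selection through the smoothed seed
threshold biases the combined p of candidate regions downward, and the
$n_a/n_r$ correction only approximately accounts for the implicit scan.
This degree of anticonservatism is a known property of this family of
region callers and is the main reason region calls should be read together
with the per-probe FWER threshold rather than in isolation.

# Permutation FWER threshold

Diagnosis labels are permuted **at the donor level** — all of a donor's
samples move together — preserving the case:control donor counts; the
configured EWAS is re-run per permutation and the minimum p recorded; the
threshold is the $\lceil \alpha n \rceil$-th smallest minimum (lower
empirical order statistic). Donor-level permutation prevents leakage when
several regions of the same donor are present; the published analogue
permuted sample labels in a single-tissue external dataset of 675
individuals, and its constant, $1.66 \times 10^{-7}$, is exposed as
`reference_fwer_threshold()` — a citable default that is reproducible only
with that external dataset, not from this package's simulations. On
independent null probes the procedure's threshold matches the analytic
minimum-of-uniforms quantile $1 - 0.95^{1/m}$ within Monte-Carlo error,
and applying it to fresh null datasets yields a family-wise error of
5% ± 2% (both checked in the acceptance suite).

# Genetics

* **Hardy–Weinberg**: the Levene–Haldane exact conditional test, matching
  what PLINK computes, implemented in log space and verified against full
  enumeration for totals up to 200. Monomorphic sites return p = 1.
* **Genotype QC order**: samples with >5% missing dosages, then SNPs with
  >1% missingness, HWE $p < 10^{-3}$ (on hard calls at threshold 0.1) or
  MAF < 5%.
* **LD pruning**: greedy in position order; the later SNP of any pair
  within 1500 bp with $r^2 > 0.20$ is dropped, and the postcondition is
  re-verified exhaustively before returning.
* **PRS**: $\sum (\text{dosage} \times \text{weight})$ over matched SNPs,
  with allele flips ($2-d$) when the score file's effect allele is the
  map's other allele; both PLINK scoring conventions (sum and mean) are
  provided, default sum. The case/control comparison is a two-sided
  two-sample $t$ test at the donor level.
* **mQTL**: additive regression of beta on dosage with the EWAS covariate
  set (a configurable choice — the source analysis does not list its mQTL
  covariates), batched per SNP over all probes; reported at the
  genome-wide $3.69 \times 10^{-13}$ and relaxed $10^{-10}$ thresholds.
  LD-pruned SNPs are scanned by default.
* **Enrichment**: Fisher's exact test (two-sided, summing hypergeometric
  probabilities no larger than the observed table's) of nominal DMPs
  ($p < 10^{-3}$) inside 1-based inclusive GWAS intervals, judged at the
  Bonferroni-corrected $1.25 \times 10^{-2}$.

# The synthetic-data generator

`simulate_beta` generates
$\beta = \mathrm{logit}^{-1}(\text{baseline} + \text{covariate terms} +
\text{effects} + \text{noise})$ with:

* **spatial noise**: a stationary Gaussian process with exponential kernel
  $\exp(-d/\varphi)$ on the logit scale per chromosome, default
  $\varphi = 200$ bp and SD 0.3. The 1-D exponential kernel is Markov, so
  the process is sampled *exactly* as a gap-dependent AR(1) recursion in
  $O(n)$ — no covariance factorization.
* **covariate structure**: per-probe loadings on age, sex, latent neuronal
  proportion and cohort drawn from zero-mean normals, so every probe has
  its own covariate signature and cohort batch shifts let the
  meta-analysis be tested under heterogeneity.
* **effects**: beta-scale deltas converted to logit shifts at each probe's
  baseline so the noise-free group difference equals the requested delta;
  the generator refuses effects that push the expected beta outside
  $[0.02, 0.98]$. Targets may be the diagnosis, the standardized true PRS,
  or a SNP dosage (per-allele).
* **cell-type reference probes**: a reserved probe subset is generated as
  a noisy neuron/glia mixture driven by each sample's latent neuronal
  proportion, and the matching reference profiles are emitted so the
  two-class projection estimator can be validated against the latent
  truth (RMSE < 0.05 at 50 reference probes with profile noise SD 0.02).
* **genotypes**: donor-level Hardy–Weinberg draws with MAF uniform on
  (0.05, 0.5], replicated across a donor's samples; mQTL SNPs are placed
  adjacent to their target probes; the PRS construct shifts case allele
  frequencies proportionally to weight × allele variance so the true score
  separates cases from controls by a chosen number of SDs (default 0.8).

The design generator emulates the two-brain-bank, four-region,
88-donor / 262-sample shape: donors split ≈60/40 across cohorts,
hippocampus restricted to one cohort, per-region missingness
(PFC 0.14, STR 0.07, HC 0.49, CER 0.12), ages from a truncated
N(60, 15²) ≥ 18, and a ~3:1 male:female ratio.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: probe-type chemistry biases beyond a
scalar attenuation option, bimodal genome-wide beta distributions (the
baseline is uniform on (0.1, 0.9)), batch structure beyond additive cohort
shifts, smoking and medication exposure, 5-hydroxymethylcytosine, and any
form of cellular heterogeneity beyond a single neuronal fraction.

# Validation experiments: operating points and power

The recovery experiments fix their conditions once, from power arithmetic
done before running them:

* **Spiked DMP/DMR** (Δβ = 0.05, logit noise SD 0.3, n = 40/group): the
  spiked probes are pinned to **baseline beta 0.2**. The beta-scale noise
  SD near baseline $p_0$ is ≈ $0.3\,p_0(1-p_0)$, giving
  $t \approx 0.05 / (0.048\sqrt{2/40}) \approx 4.7$ at $p_0 = 0.2$
  (per-seed top-10 power ≈ 95–98% among 1,000 probes) versus $t \approx 3$
  at $p_0 = 0.5$, where the top-10 criterion would not be attainable at
  90% power. The DMR experiment spikes 5 consecutive probes; neighbour
  smoothing is what lifts per-probe p ≈ 10⁻⁴–10⁻³ over the 10⁻³ seed
  threshold.
* **mQTL** (0.05/allele, MAF 0.3, n = 70): detection at the relaxed
  $10^{-10}$ threshold requires $t \gtrsim 7$; at logit noise 0.3 the
  implied $t \approx 3.6$, so the experiment runs in the strong-cis regime
  (logit noise 0.1, the SNP explaining ≈60% of probe variance,
  $t \approx 11$) — the magnitude of effect that thresholds this stringent
  are designed to find at n ≈ 70.
* **Null calibration** uses 10,000 independent probes (φ = 0) and 60
  samples; λ stays in [0.9, 1.1] across 10 seeds and the p-value
  distribution passes a Kolmogorov–Smirnov uniformity check at p > 0.01.
* **FWER calibration** uses 1,000 independent probes, 60 samples, 500
  permutations, and 500 fresh null replicates.
* The **end-to-end run** uses 20,000 probes over 4 chromosomes, 57 donors
  (≈160 samples), 100 SNPs and 200 permutations, and completes in about a
  minute per run on one CPU; the acceptance suite runs it twice and
  compares file hashes.

# Numerical and degenerate-input choices

* p-values from $t$ and normal tests are floored at the smallest positive
  double, keeping them in (0, 1] as the association-table contract
  requires.
* `welch_from_summary` with both SDs zero returns p = 1 when the means are
  equal and p = 0 (flagged degenerate) otherwise.
* The epigenetic-clock transform inverts exactly: ages map through
  $\log(a+1) - \log(A+1)$ below the adult anchor $A = 20$ and
  $(a-A)/(1+A)$ above; the round trip is identity to $10^{-9}$ over
  [0, 100] years. Acceleration defaults to the residual of predicted on
  chronological age (the difference is available by flag), an open choice
  the source text does not pin down.
* Two spec-level boundary readings are implemented exactly as quoted and
  tested: "more than 1%" (strict) for the sample filter versus "at least
  1%" (inclusive) for the probe filter.
* Probe filters are computed after sample removal; the source narrative
  does not state the order, so the choice is recorded here rather than
  attributed.

# Known limitations

* The Šidák-corrected region p-values are modestly anticonservative under
  selection (≈9% at a nominal 5%; see *Region detection*).
* The beta-level quantile normalization is a stand-in for intensity-level
  normalization; it enforces distribution alignment but cannot correct
  channel-specific background.
* The cross-region mixed model estimates a region variance component from
  three levels; its absolute value is unreliable even though the exposure
  inference is well behaved (Wald z, no small-sample df correction).
* The permutation FWER threshold from a 1,000-probe simulation is not
  comparable to the 450K-scale reference constant; thresholds shrink with
  probe count (tested), which is why the reference constant ships
  separately.
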