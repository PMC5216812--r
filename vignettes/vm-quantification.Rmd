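---
title: "Quantifying vasculogenic mimicry and DSG2 cohort statistics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying vasculogenic mimicry and DSG2 cohort statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vmquant)
```

# Scope and model

Vasculogenic mimicry (VM) is the formation of basement-membrane-lined,
perfusable channel networks by tumor cells rather than endothelium. On
PAS/CD31 co-stained sections, VM is the branching PAS-positive network that
lacks CD31 staining; conventional vessels are PAS-positive *and*
CD31-positive and must be subtracted. `vmquant` provides

* a per-image VM quantification pipeline (`quantify_vm()`),
* the bulk RNA-seq cohort workflow around a stratification gene, DSG2 by
  default (`run_cohort_pipeline()`),
* from-scratch survival and categorical statistics (`km_estimate()`,
  `logrank_test()`, `fisher_exact_2x2()`, `benjamini_hochberg()`),
* seeded ground-truthed synthetic generators (`generate_vm_image()`,
  `generate_expression_cohort()`) that every claim in the test suite is
  validated against.

# The imaging model

## Tubeness

A bright tube of cross-sectional scale $w$ against a darker background has,
at the matched Gaussian analysis scale $\sigma$, a strongly negative second
derivative across the tube and a near-zero one along it. We use the
Sato-style bright-line measure

$$ T(\mathbf{x}) \;=\; \max_{\sigma \in S} \; \sigma^2 \, \max\{0, -\lambda_2(\mathbf{x};\sigma)\}, $$

where $\lambda_2$ is the larger-magnitude eigenvalue of the Hessian of the
$\sigma$-smoothed image and $\sigma^2$ is the usual scale normalization.
Default $S = \{2, 3, 4, 6\}$ px, spanning tube widths from capillary-thin to
several pixels; the set is configurable because the appropriate scales
depend on magnification.

**Discretization contract.** The derivative kernels are *discrete central
differences of the sampled Gaussian*, so on interior pixels the Hessian
equals the central finite-difference Hessian of the smoothed raster exactly
(to machine precision) — a property the test suite asserts at `1e-3`
relative tolerance against an independently coded oracle. The price is the
standard $\tfrac{1}{4}(w^2+\sigma^2)^{-1}$ discretization bias relative to
the continuum response $\sigma^2 w/(w^2+\sigma^2)^{3/2}$ for a unit Gaussian
ridge: about 3% at $w=\sigma=2$, below 1% for $w^2+\sigma^2 \ge 25$. The
closed-form checks therefore run at moderate scales, and the small-scale
bias is pinned by its own test. An implementation using analytic derivative
kernels would flip the trade (closed form exact, finite-difference
equivalence violated at the percent level); we chose the variant whose
contract is exact, machine-checkable equality.

## Tissue detection

`detect_tissue()` smooths the summed channels ($\sigma = 8$ px), estimates
pixel noise from the high-frequency residual (1.4826·MAD), and calls tissue
where the smoothed intensity exceeds half its 90th percentile, followed by
morphological closing and hole filling. An image whose 90th-percentile
smoothed intensity fails to clear 1.5× the pixel-noise estimate raises
`"no tissue detected"`; the margin comes from the fact that a field of pure
zero-clipped noise smooths to roughly its own pixel standard deviation.
**Limitation:** the in-tissue background stain level must exceed ~1.5× the
pixel noise; very faint tissue is reported as absent. An explicit
`tissue_mask` on the image bypasses all of this.

## Segmentation thresholds

Four policies are available and the one used is recorded in every
`vmq_network_mask`:

| policy | rule | use |
|---|---|---|
| `background` (PAS default) | median + $k$·MAD of in-tissue response, $k = 7$ | robust when the network is a small minority of pixels |
| `robust_otsu` (CD31 default) | Otsu restricted to pixels above median + 6·MAD | finds the amplitude valley despite extreme class imbalance |
| `quantile` | keep the top $q$ fraction ($q = 0.05$) | reproducible fixed-area baseline |
| `otsu` / `fixed` | classical Otsu; user value | dense scenes; externally calibrated thresholds |

The pipeline default deviates deliberately from a fixed-quantile policy: a
quantile threshold pins the segmented area at $q$ *by construction*, so the
resulting score cannot track how much network is actually present (measured
Spearman correlation with truth across a synthetic density sweep was
strongly *negative*). Classical Otsu fails in the opposite direction: with
<1% vessel pixels its between-class criterion is maximized by splitting the
background mode. The `background` policy's $k = 7$ was calibrated once, for
area-unbiasedness of the segmented network against generator truth across a
density sweep (seeds 101–110), and then frozen; it is a detection constant
of the estimator, not a per-dataset tuning knob.

Before filtering, `quantify_vm()` replaces out-of-tissue pixels with the
median in-tissue intensity. Without this, the tissue boundary — a large
intensity step — responds as a ridge and inflates the in-tissue background
MAD, which suppressed real networks noticeably on small fields of view.

**Limitation:** the background policy assumes the network is a minority of
tissue. In synthetic experiments recovery degrades once true network
coverage exceeds roughly 15% of tissue area; such extensive networks are
better quantified with the `otsu` policy or a `fixed` threshold.

## Subtraction, score, categories

`subtract_vessels()` removes the CD31 mask dilated by 2 px (8-connected
square dilation) from the PAS mask; the dilation absorbs chromatic and
registration offset between the stains and makes the score conservative
(vm_score is non-increasing in the dilation radius — a tested invariant).
`compute_vm_score()` reports $100\,|{\rm VM} \wedge {\rm tissue}|/|{\rm
tissue}|$, i.e. percent of tissue area: the only normalization consistent
with a "<10% of area" category definition; raw pixel areas are recoverable
from the masks. Categories: *PAS-neg* — empty network mask; *PAS-low* —
area fraction < 0.10 **or** all components are simple arcs (operationalized
as: the pruned Zhang–Suen skeleton contains no pixel with ≥3 skeleton
neighbours); *PAS-high* — otherwise. Group comparison of scores uses the
pooled-variance unpaired Student t-test (the conventional "unpaired
t-test"); Welch is available via `var_equal = FALSE`.

# The expression model

## Contamination filter

DSG2 is expressed by keratinocytes, so bulk melanoma samples contaminated
with normal skin would confound any DSG2 analysis. The filter removes a
sample iff all three of IVL, KRT14, BNC exceed 5 CPM, or any two exceed
20 CPM — strict inequalities, read literally. The rule is idempotent and
depends only on the three marker rows (both tested). Note that the rule
presumes realistic sequencing depth: at a 200k-read library a single stray
marker read is already 6 CPM, so very shallow libraries can trip the
all-three clause by chance; at the 1e6+ depths the rule was designed for,
5 CPM corresponds to several reads and the planted-recovery tests are exact.

## Stratification

`stratify_by_expression_range()` supports the value-range rule (cuts at
min + f·range and max − f·range, default f = 0.10) and the empirical
quantile rule (f and 1−f quantiles). Boundary values are assigned to `mid`;
samples strictly below/above the cuts are `low`/`high`. Range mode is the
default. A property worth knowing: under multiplicative count noise
(NB dispersion ~0.1 means ~32% CV for well-expressed genes) the realized
expression *maximum* is an outlier-dominated statistic, so range-mode
extreme groups can be very small (single digits out of hundreds of
samples). That is a faithful consequence of the rule, not a bug; analyses
that need balanced extreme groups should use quantile mode, and the
power-dependent tests in this package do so explicitly.

## Differential expression

`nb_exact_de_test()` is a deliberate, documented substitute for an edgeR
analysis — simple enough to verify from first principles:

1. counts are scaled to the geometric-mean library size and rounded
   ("pseudo-counts");
2. one common dispersion $\hat\varphi = \max\{0, \sum(v-m)/\sum m^2\}$
   pooled over genes and groups (method of moments on within-group mean $m$
   and variance $v$); the floor at 0 degenerates the model to Poisson;
3. per gene, an exact conditional test: given the total $s = s_1 + s_2$,
   the group-1 sum follows a negative hypergeometric law (binomial when
   $\varphi = 0$), and the two-sided p sums the point probabilities not
   exceeding the observed one (beyond $2\times10^5$ total counts a
   moment-matched normal approximation to the same conditional law is
   used);
4. Benjamini–Hochberg adjustment; flags at fold ≥ 2 and FDR < 0.005, with a
   0.5-count prior inside the log2 fold change.

Results will not bit-match an edgeR run (no TMM, no quantile-adjusted
pseudo-counts, no tagwise shrinkage); sensitivity ≥ 0.9 at planted
log2FC = 3 (n = 40/group, dispersion 0.1) and null false-positive control
at FDR < 0.005 are the tested guarantees.

## Survival and categorical statistics

All estimators are implemented from first principles (base R distribution
functions are used as numerical primitives only):

* **Kaplan–Meier**: product-limit with deaths before censorings at tied
  times; the median is the first time the curve reaches ≤ 0.5, undefined
  (NA) if never reached.
* **Log-rank**: Mantel–Haenszel chi-square with the hypergeometric variance
  at each distinct event time, no continuity correction; p from the
  $\chi^2_1$ upper tail. The hazard ratio is reported as the O/E ratio
  $(O_a/E_a)/(O_b/E_b)$, matching a "rate of death" reading; it is mildly
  attenuated toward 1 for large effects with long follow-up (50-simulation
  mean ≈ 2.4 at true HR 2.6 with 20% censoring — inside the stated
  acceptance band, and the reason a Cox estimate can differ).
* **Fisher's exact (2×2)**: two-sided p as the sum of hypergeometric point
  probabilities ≤ the observed table's (the dominant convention; the
  doubling convention would give different values), computed by exact
  enumeration over the support. Property-tested against a brute-force
  enumeration oracle and `stats::fisher.test`.
* **BH**: step-up adjusted values with monotonicity enforcement, order
  preserved; rejections at level q equal the classical step-up rule's.
* **Concordance**: counts matched primary/metastasis status pairs; the
  bundled 8-patient table yields 6/8 with patients 3 and 5 discordant.

The overall-survival convention for clinical tables: time is
`days_to_death` for deceased patients, else days to last follow-up with
`event = 0`; records with negative or missing times are dropped with a
logged warning in the pipeline report.

# The synthetic world

## Images

`vm_image_spec()` fixes the stated test world once: 192-px square field;
tissue disc covering 70% of it at background level 200; a branching network
grown as a random recursive walk (segment length 12–24 px, branch
probability 0.35, angular jitter 0.35 rad) rendered with Gaussian
cross-section (sd 2 px) at amplitude 600; a vessel network half the
network's segment count, of which `vessel_overlap_fraction` (default 0.3)
are co-staining copies of network segments; additive Gaussian noise with
sd 120 — SNR 5, the hardest condition the recovery criteria quote. The
default 20 network segments yield a true VM area of ~4–6% of tissue,
matching the few-percent score scale reported for patient melanomas. Truth
masks are the pixels at or above half the rendered tube amplitude (FWHM),
and `true_vm_area_fraction` is recomputable from the returned masks — an
identity the tests assert.

What the generator does **not** emulate: colorimetric-to-fluorescent
conversion or stain unmixing (inputs are assumed already split into PAS
fluorescence and CD31 channels), intensity inhomogeneity across the slide,
autofluorescence texture, nuclei, or real vascular morphogenesis (the tree
is a test substrate, not a biological model). A green recovery test
therefore establishes that the ridge-detection/subtraction/scoring chain is
correct and calibrated on tube-like structures in stationary noise — not
that the score is accurate on any particular scanner's output.

## Cohorts

`cohort_spec()` defaults mirror the cohort arithmetic the analysis targets:
473 samples, 46 of them with planted keratinocyte contamination (all three
markers drawn log-uniformly in 50–500 CPM with a shared per-sample severity
— "tightly correlated" — vs 0.2 CPM clean), 2000 genes with lognormal
baseline abundances normalized to a 1e6 expected CPM budget, NB dispersion
0.1, 1e6-read libraries, a DSG2 gradient spanning 1–400 CPM (uniform by
default, trimodal optional), 100 DE genes at log2FC 2, and exponential
survival with baseline hazard 1e-4/day, hazard ratio 2.6 for the high
stratum, independent exponential censoring at 2.5e-5/day and a 30-year
administrative horizon.

The planted strata are the *eventual* strata: the stratification rule is
applied to the realized DSG2 CPM of the clean samples — exactly what a
downstream analysis computes — and DE counts are then redrawn for the high
stratum (iterated up to three times so membership and planted counts
agree). This makes planted-group recovery exact by construction in both
modes and keeps the DE and survival plants attached to the groups the
pipeline will actually find. The alternative (truth from noise-free
expected values) is not recoverable under realistic dispersion and was
rejected; see the range-mode caveat above.

# Numerical and degenerate-input choices

* Reflective (symmetric) boundary for all Gaussian filtering; tests
  evaluate interior pixels.
* Masks are binary pixel sets (a pixel is in or out); coordinates are
  row-major with the origin at the top-left.
* Dilation/erosion use the 8-connected (square) structuring element;
  `dilation_px` counts iterations.
* An empty in-tissue tubeness support yields an empty network mask (a valid
  PAS-negative image), not an error; an empty tissue mask is an error.
* `fisher_exact_2x2` compares point probabilities with a `1 + 1e-7`
  relative tolerance to absorb floating-point ties in the enumeration.
* Exact Mann–Whitney enumeration is used when both groups have ≤ 8
  observations (the largest case enumerates 12 870 labelings); otherwise
  the normal approximation with tie correction and no continuity
  correction. All-tied inputs give statistic 0, p 1.
* RNG: every generator seeds a local RNG state and restores the caller's
  (`.Random.seed` is untouched — tested).

# Known limitations

* No whole-slide (pyramidal) images, no stain deconvolution, no
  nucleus/cell segmentation, no microvessel-density scoring.
* Image I/O is a minimal uncompressed 16-bit grayscale multi-page TIFF
  subset (the deployment environment has no R TIFF/PNG bindings); analysis
  functions accept in-memory matrices from any source.
* The DE engine is a verified substitute, not an edgeR reimplementation;
  real-data gene lists will differ from an edgeR analysis.
* Estimated VM scores are calibrated for sparse networks (≲15% of tissue)
  at SNR ≥ 5; denser networks need the alternative threshold policies.
* The O/E hazard ratio attenuates large effects; a partial-likelihood (Cox)
  estimate would sit closer to the true hazard ratio in heavy-event data.
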