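# vmquant

Quantification of vasculogenic mimicry (VM) in PAS/CD31 histology and the
companion DSG2 bulk RNA-seq cohort statistics.

## The problem

Aggressive tumors such as melanoma can build perfusable channel networks out
of tumor cells themselves — *vasculogenic mimicry* — instead of relying only
on endothelium-lined vessels. On sections co-stained with Periodic Acid-Schiff
(PAS, which marks the basement membrane lining both VM channels and real
vessels and also fluoresces) and anti-CD31 (endothelium only), VM appears as
branching PAS⁺ networks that lack CD31. Historically VM has been scored by
eye; `vmquant` implements a quantitative score:

1. **Tubeness ridge detection.** The PAS fluorescence channel is filtered
   with the multiscale Hessian bright-line ("tubeness") measure
   `T(x) = max_σ σ² · max(0, −λ₂(x; σ))`, where λ₂ is the larger-magnitude
   eigenvalue of the Gaussian-scale-σ Hessian. Default scales: σ ∈ {2, 3, 4, 6} px.
2. **Network segmentation.** The in-tissue response is thresholded
   (robust background policy by default: median + 7·MAD) and components
   smaller than 20 px are dropped.
3. **CD31 subtraction.** The CD31⁺ endothelial network is segmented from the
   (smoothed) CD31 channel and removed from the PAS network after a 2 px
   dilation that absorbs stain registration offset.
4. **Scoring.** `vm_score = 100 · |PAS⁺CD31⁻ ∧ tissue| / |tissue|` (percent
   of tissue area), plus a PAS pattern category: *PAS-neg* (no network),
   *PAS-low* (<10% of area, or disconnected arcs only), *PAS-high*
   (extensive branching networks).

The expression side reproduces the cohort workflow used around the
desmosomal cadherin DSG2 in melanoma:

- counts-per-million (CPM) normalization;
- a **keratinocyte contamination filter**: a sample is excluded when all
  three skin markers (IVL, KRT14, BNC) exceed 5 CPM, or any two exceed
  20 CPM (this removes tumor samples carrying normal skin);
- **expression-range stratification**: cut points at the top and bottom 10%
  of the DSG2 expression range (value-range by default, empirical quantiles
  as an alternative);
- Kaplan–Meier curves, the Mantel–Haenszel **log-rank test** with the O/E
  hazard ratio `(O_a/E_a)/(O_b/E_b)`;
- an exact negative-binomial **differential-expression test** (common
  method-of-moments dispersion, exact conditional test on group sums,
  Benjamini–Hochberg FDR) with the thresholds ">2-fold, FDR < 0.005";
- **Fisher's exact test** (two-sided, by hypergeometric enumeration),
  Mann–Whitney and Kruskal–Wallis rank tests.

Seeded synthetic-data generators (ground-truthed two-channel images;
negative-binomial cohorts with planted contamination, DSG2 strata, DE genes
and exponential survival) make every stage testable against known truth.

## Worked example

```r
library(vmquant)

# --- image side: a ground-truthed synthetic field of view ---
gt <- generate_vm_image(vm_image_spec(seed = 4))
quantify_vm(gt$image)
#> <vmq_vm> vm_score = 5.832% of tissue, PAS area fraction = 0.0682, category = PAS-low
100 * gt$true_vm_area_fraction   # ground truth the score estimates
#> [1] 5.717714

# --- cohort side: filter -> stratify -> survival -> DE ---
ch  <- generate_expression_cohort(cohort_spec(seed = 4, strat_mode = "quantile"))
rep <- run_cohort_pipeline(ch$counts, ch$clinical, vmq_config(strat_mode = "quantile"))
rep
#> <vmq_run_report>
#>   samples: 473 total, 427 kept, 46 removed by contamination filter
#>   stratification (DSG2): cuts [35.39, 394.6], low/mid/high = 43/341/43
#>   survival: median days [high: 2268.588, low: NR], HR (O/E) 3.554, log-rank p = 1.479e-06
#>   DE: 101 overexpressed / 0 underexpressed
```

The synthetic cohort plants 46 contaminated samples among 473 (all 46 — and
only those — are removed), a 2.6-fold death-rate increase for the DSG2-high
stratum (the single-seed O/E estimate above is 3.55; the 50-seed mean at
n = 1000/group is ≈ 2.4), and 100 DE genes (the 101st call is one false
positive at FDR < 0.005 across 1 900 null genes).

```r
# --- in-study fixtures ---
fx <- load_paper_fixtures()
fisher_exact_2x2(fx$stage_contingency)$p_two_sided  # DSG2+ by stage
#> [1] 0.2937921                                     # printed as p = 0.294
concordance_summary(fx)
#> $n_concordant [1] 6   $n_total [1] 8   $discordant_patient_ids [1] 3 5
```

## Command line

```sh
Rscript inst/cli/vmquant simulate-image  --seed 1 --out out/img
Rscript inst/cli/vmquant vm-score --pas pas.tiff --cd31 cd31.tiff --out report.json
Rscript inst/cli/vmquant simulate-cohort --seed 1 --out out/cohort
Rscript inst/cli/vmquant filter-samples  --counts out/cohort/counts.tsv
Rscript inst/cli/vmquant fisher --table 18,28,6,19
```

Exit codes: 0 success, 2 input error, 3 stage failure.

## Limitations

Documented in the methods vignette (`vignettes/vm-quantification.Rmd`):
no whole-slide/pyramidal input, no stain deconvolution (channels must
already be split), network area must be a minority of tissue (recovery
degrades above ~15% coverage), tissue background must exceed ~1.5× pixel
noise for automatic tissue detection, and the DE engine is a documented
substitute for edgeR, not a bit-compatible reimplementation.
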