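# Seeded generator of synthetic bulk RNA-seq cohorts with planted ground
# truth: negative-binomial counts, a keratinocyte-contaminated sample subset
# (correlated high IVL/KRT14/BNC), a heterogeneous DSG2 expression gradient,
# planted DE genes between the eventual DSG2-high/low strata, and exponential
# survival with a DSG2-group-dependent hazard plus independent censoring.

#' Specification of a synthetic expression cohort
#'
#' Defaults mirror the arithmetic of the melanoma TCGA cohort the analysis
#' emulates: 473 samples of which 46 carry keratinocyte contamination,
#' stratification gene DSG2 with cut points at the top and bottom 10% of its
#' expression range, a 2.6-fold death-rate increase for the high stratum.
#' Magnitudes without a stated value (library size, dispersion, marker CPM
#' ranges, hazards) are fixed once as realistic bulk RNA-seq conditions; see
#' the methods vignette.
#'
#' @param n_samples,n_genes cohort dimensions.
#' @param n_contaminated number of planted keratinocyte-contaminated samples.
#' @param marker_gene_ids the three keratinocyte marker gene ids.
#' @param contaminated_marker_cpm_range CPM interval the contaminated
#'   samples' marker expression is drawn from; its lower end must exceed
#'   `clean_marker_cpm_max` or the planted truth would be ill-defined.
#' @param clean_marker_cpm_max mean marker CPM of clean samples.
#' @param dsg2_gene_id stratification gene id.
#' @param dsg2_range CPM interval spanned by the stratification gene.
#' @param dsg2_pattern `"uniform"` spreads expected DSG2 CPM uniformly over
#'   `dsg2_range`; `"trimodal"` plants three well-separated modes.
#' @param strat_mode stratification rule (`"range"` or `"quantile"`) used to
#'   define the planted strata; must match the mode the downstream analysis
#'   will use for the planted truth to be recoverable.
#' @param n_de_genes number of genes differentially expressed (high vs low
#'   stratum) at `de_log2fc`.
#' @param de_log2fc planted log2 fold-change of the DE genes.
#' @param nb_dispersion common negative-binomial dispersion
#'   (`variance = mu + dispersion * mu^2`).
#' @param library_size_mean mean sequencing library size (counts per sample).
#' @param true_hazard_ratio death-rate multiplier of the high stratum.
#' @param baseline_hazard_per_day exponential death hazard of non-high samples.
#' @param censoring_rate_per_day independent exponential censoring hazard
#'   (0 = none).
#' @param horizon_days administrative censoring cutoff.
#' @param strat_fraction range fraction defining the planted low/high strata.
#' @param seed integer RNG seed.
#' @return object of class `vmq_cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 473L, n_genes = 2000L,
                        n_contaminated = 46L,
                        marker_gene_ids = c("IVL", "KRT14", "BNC"),
                        contaminated_marker_cpm_range = c(50, 500),
                        clean_marker_cpm_max = 2,
                        dsg2_gene_id = "DSG2", dsg2_range = c(1, 400),
                        dsg2_pattern = c("uniform", "trimodal"),
                        n_de_genes = 100L, de_log2fc = 2,
                        nb_dispersion = 0.1, library_size_mean = 1e6,
                        true_hazard_ratio = 2.6,
                        baseline_hazard_per_day = 1e-4,
                        censoring_rate_per_day = 2.5e-5,
                        horizon_days = 10950,
                        strat_fraction = 0.10,
                        strat_mode = c("range", "quantile"), seed = 1L) {
  assert_scalar_num(n_samples, "n_samples", min = 6)
  assert_scalar_num(n_genes, "n_genes", min = 10)
  assert_scalar_num(n_contaminated, "n_contaminated", min = 0, max = n_samples)
  if (length(marker_gene_ids) != 3L || anyDuplicated(marker_gene_ids)) {
    abort("marker_gene_ids must be three distinct identifiers")
  }
  if (length(contaminated_marker_cpm_range) != 2L ||
      diff(contaminated_marker_cpm_range) < 0) {
    abort("contaminated_marker_cpm_range must be an increasing interval")
  }
  assert_scalar_num(clean_marker_cpm_max, "clean_marker_cpm_max", min = 0)
  if (contaminated_marker_cpm_range[1L] <= clean_marker_cpm_max) {
    abort("contaminated marker CPM range [%g, %g] overlaps the clean ceiling %g: planted truth would be ill-defined",
          contaminated_marker_cpm_range[1L], contaminated_marker_cpm_range[2L],
          clean_marker_cpm_max)
  }
  if (length(dsg2_range) != 2L || diff(dsg2_range) <= 0 || dsg2_range[1L] < 0) {
    abort("dsg2_range must be an increasing non-negative interval")
  }
  dsg2_pattern <- match.arg(dsg2_pattern)
  strat_mode <- match.arg(strat_mode)
  assert_scalar_num(n_de_genes, "n_de_genes", min = 0, max = n_genes - 4)
  assert_scalar_num(de_log2fc, "de_log2fc")
  assert_scalar_num(nb_dispersion, "nb_dispersion", min = 0)
  assert_scalar_num(library_size_mean, "library_size_mean", min = 1e3)
  assert_scalar_num(true_hazard_ratio, "true_hazard_ratio", min = 1e-9)
  assert_scalar_num(baseline_hazard_per_day, "baseline_hazard_per_day",
                    min = 1e-12)
  assert_scalar_num(censoring_rate_per_day, "censoring_rate_per_day", min = 0)
  assert_scalar_num(horizon_days, "horizon_days", min = 1)
  assert_scalar_num(strat_fraction, "strat_fraction", min = 1e-6, max = 0.499)
  assert_scalar_num(seed, "seed")
  structure(
    list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
         n_contaminated = as.integer(n_contaminated),
         marker_gene_ids = as.character(marker_gene_ids),
         contaminated_marker_cpm_range = as.numeric(contaminated_marker_cpm_range),
         clean_marker_cpm_max = clean_marker_cpm_max,
         dsg2_gene_id = dsg2_gene_id, dsg2_range = as.numeric(dsg2_range),
         dsg2_pattern = dsg2_pattern, n_de_genes = as.integer(n_de_genes),
         de_log2fc = de_log2fc, nb_dispersion = nb_dispersion,
         library_size_mean = library_size_mean,
         true_hazard_ratio = true_hazard_ratio,
         baseline_hazard_per_day = baseline_hazard_per_day,
         censoring_rate_per_day = censoring_rate_per_day,
         horizon_days = horizon_days, strat_fraction = strat_fraction,
         strat_mode = strat_mode, seed = as.integer(seed)),
    class = "vmq_cohort_spec"
  )
}

# counts ~ NB(mu, dispersion); dispersion 0 degenerates to Poisson
rcounts <- function(n, mu, dispersion) {
  if (dispersion <= 0) return(stats::rpois(n, mu))
  stats::rnbinom(n, size = 1 / dispersion, mu = mu)
}

#' Generate a synthetic expression cohort with planted truth
#'
#' Counts are negative binomial around expected CPM profiles: a lognormal
#' baseline for regular genes, low marker expression in clean samples with
#' elevated, tightly correlated marker CPM in the contaminated subset, and a
#' heterogeneous DSG2 profile.  The planted strata are the *eventual* strata:
#' the stratification rule (`strat_mode`, `strat_fraction`) applied to the
#' realized DSG2 CPM of the clean samples - exactly what a downstream
#' analysis of the generated matrix computes - and DE genes are then planted
#' by redrawing their counts at a `2^de_log2fc`-shifted mean in the high
#' stratum (iterated so that stratum membership and planted counts are
#' mutually consistent).  Survival follows the planted strata.
#'
#' @param spec a [cohort_spec()].
#' @return object of class `vmq_cohort`: `counts` (genes x samples integer
#'   matrix with gene/sample dimnames), `clinical` (data.frame with columns
#'   `sample_id`, `days`, `event`, `stage`, `dsg2_cnv_amplified`) and `truth`
#'   (contaminated sample ids, DE gene ids, planted group per sample, the
#'   cut points, true hazard ratio, expected per-sample DSG2 CPM).
#' @export
generate_expression_cohort <- function(spec) {
  stopifnot(inherits(spec, "vmq_cohort_spec"))
  ns <- spec$n_samples
  ng <- spec$n_genes
  with_seed(spec$seed, {
    sample_ids <- sprintf("S%04d", seq_len(ns))
    special <- c(spec$marker_gene_ids, spec$dsg2_gene_id)
    n_regular <- ng - length(special)
    gene_ids <- c(special, sprintf("G%05d", seq_len(n_regular)))

    # expected DSG2 CPM per sample: heterogeneous gradient or three modes
    rng <- spec$dsg2_range
    span <- diff(rng)
    f <- spec$strat_fraction
    dsg2_cpm <- switch(spec$dsg2_pattern,
      uniform = stats::runif(ns, rng[1L], rng[2L]),
      trimodal = {
        n_low <- max(2L, round(f * ns))
        n_high <- max(2L, round(f * ns))
        c(stats::runif(n_low, rng[1L], rng[1L] + 0.02 * span),
          stats::runif(ns - n_low - n_high, rng[1L] + 0.40 * span,
                       rng[1L] + 0.60 * span),
          stats::runif(n_high, rng[2L] - 0.02 * span, rng[2L]))[
            sample.int(ns)]
      }
    )

    # baseline expected CPM; DE genes are kept at moderate abundance so the
    # planted shift perturbs library sizes by ~1% at most
    base_cpm <- stats::rlnorm(n_regular, meanlog = log(100), sdlog = 1.3)
    de_ids <- character(0)
    if (spec$n_de_genes > 0L) {
      base_cpm[seq_len(spec$n_de_genes)] <-
        stats::rlnorm(spec$n_de_genes, meanlog = log(30), sdlog = 0.6)
      de_ids <- sprintf("G%05d", seq_len(spec$n_de_genes))
    }
    # normalize so expected CPM sums to ~1e6 per sample: special genes keep
    # their stated absolute CPM, regular genes absorb the remainder
    marker_cpm <- matrix(spec$clean_marker_cpm_max * 0.1, 3L, ns)
    contam <- integer(0)
    if (spec$n_contaminated > 0L) {
      contam <- sort(sample.int(ns, spec$n_contaminated))
      lo <- spec$contaminated_marker_cpm_range[1L]
      hi_c <- spec$contaminated_marker_cpm_range[2L]
      severity <- stats::runif(spec$n_contaminated) # shared by the 3 markers
      base <- lo * (hi_c / lo)^severity
      for (m in 1:3) {
        val <- base * exp(stats::rnorm(spec$n_contaminated, 0, 0.1))
        marker_cpm[m, contam] <- pmin(pmax(val, lo), hi_c)
      }
    }
    contaminated_ids <- sample_ids[contam]
    special_total <- colSums(marker_cpm) + dsg2_cpm
    if (any(special_total >= 1e6)) {
      abort("marker/DSG2 CPM levels exceed the per-sample CPM budget")
    }
    base_cpm <- base_cpm * (1e6 - mean(special_total)) / sum(base_cpm)
    cpm_expect <- rbind(marker_cpm, matrix(dsg2_cpm, 1L, ns),
                        matrix(rep(base_cpm, ns), n_regular, ns))
    dimnames(cpm_expect) <- list(gene_ids, sample_ids)

    lib_sizes <- stats::rlnorm(ns, meanlog = log(spec$library_size_mean),
                               sdlog = 0.1)
    mu <- sweep(cpm_expect / 1e6, 2L, lib_sizes, `*`)
    counts <- matrix(rcounts(length(mu), mu, spec$nb_dispersion), ng, ns,
                     dimnames = dimnames(mu))

    # planted strata = stratification rule on realized DSG2 CPM of the clean
    # samples; DE planting changes library sums slightly, so iterate until
    # membership and planted counts agree (the last recomputation defines
    # the stored truth either way)
    clean <- setdiff(seq_len(ns), contam)
    de_rows <- match(de_ids, gene_ids)
    base_de_counts <- counts[de_rows, , drop = FALSE]
    assign_groups <- function(counts) {
      cpm_dsg2 <- counts[spec$dsg2_gene_id, ] / colSums(counts) * 1e6
      x <- cpm_dsg2[clean]
      if (spec$strat_mode == "range") {
        r <- range(x)
        cuts <- c(r[1L] + f * diff(r), r[2L] - f * diff(r))
      } else {
        cuts <- stats::quantile(x, c(f, 1 - f), names = FALSE)
      }
      list(group = ifelse(cpm_dsg2 < cuts[1L], "low",
                          ifelse(cpm_dsg2 > cuts[2L], "high", "mid")),
           cuts = cuts)
    }
    gr <- assign_groups(counts)
    if (length(de_rows) > 0L) {
      for (iter in 1:3) {
        hi <- which(gr$group == "high")
        counts[de_rows, ] <- base_de_counts
        if (length(hi)) {
          mu_hi <- mu[de_rows, hi, drop = FALSE] * 2^spec$de_log2fc
          counts[de_rows, hi] <- rcounts(length(mu_hi), mu_hi,
                                         spec$nb_dispersion)
        }
        gr2 <- assign_groups(counts)
        converged <- identical(gr2$group, gr$group)
        gr <- gr2
        if (converged) break
      }
    }
    group <- stats::setNames(gr$group, sample_ids)

    # clinical covariates: stage, CNV amplification enriched at high DSG2
    stage <- sample(c("I", "II", "III", "IV"), ns, replace = TRUE,
                    prob = c(0.2, 0.3, 0.3, 0.2))
    amp_p <- stats::plogis(-2.5 + 2 * (rank(dsg2_cpm) / ns))
    dsg2_cnv_amplified <- stats::runif(ns) < amp_p

    # overall survival: exponential death hazard with group-dependent rate,
    # independent exponential censoring, administrative horizon
    hazard <- spec$baseline_hazard_per_day *
      ifelse(group == "high", spec$true_hazard_ratio, 1)
    t_death <- stats::rexp(ns, hazard)
    t_cens <- if (spec$censoring_rate_per_day > 0) {
      stats::rexp(ns, spec$censoring_rate_per_day)
    } else {
      rep(Inf, ns)
    }
    t_cens <- pmin(t_cens, spec$horizon_days)
    days <- pmin(t_death, t_cens)
    event <- as.integer(t_death <= t_cens)

    clinical <- data.frame(
      sample_id = sample_ids, days = days, event = event, stage = stage,
      dsg2_cnv_amplified = dsg2_cnv_amplified, stringsAsFactors = FALSE
    )
    truth <- list(
      contaminated_sample_ids = contaminated_ids, de_gene_ids = de_ids,
      group_of_sample = group, true_hazard_ratio = spec$true_hazard_ratio,
      dsg2_expected_cpm = stats::setNames(dsg2_cpm, sample_ids),
      library_sizes = stats::setNames(lib_sizes, sample_ids),
      low_cut = gr$cuts[1L], high_cut = gr$cuts[2L]
    )
    structure(list(counts = counts, clinical = clinical, truth = truth,
                   spec = spec),
              class = "vmq_cohort")
  })
}

#' @export
print.vmq_cohort <- function(x, ...) {
  cat(sprintf("<vmq_cohort> %d genes x %d samples, %d contaminated, %d DE genes, true HR %.2f (seed %d)\n",
              nrow(x$counts), ncol(x$counts),
              length(x$truth$contaminated_sample_ids),
              length(x$truth$de_gene_ids), x$truth$true_hazard_ratio,
              x$spec$seed))
  invisible(x)
}
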