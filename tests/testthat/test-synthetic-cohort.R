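# Synthetic cohort generator: determinism, planted contamination, NB
# marginals, null survival calibration.

test_that("generation is deterministic and leaves the global RNG alone", {
  sp <- cohort_spec(n_samples = 40, n_genes = 50, n_contaminated = 4,
                    n_de_genes = 5, seed = 9)
  a <- generate_expression_cohort(sp)
  b <- generate_expression_cohort(sp)
  expect_identical(a$counts, b$counts)
  expect_identical(a$clinical, b$clinical)
  set.seed(21)
  before <- .Random.seed
  invisible(generate_expression_cohort(sp))
  expect_identical(before, .Random.seed)
})

test_that("planted contaminated samples are exactly the ones the filter removes", {
  ch <- generate_expression_cohort(cohort_spec(seed = 2))
  expect_identical(ncol(ch$counts), 473L)
  rep <- keratinocyte_contamination_filter(compute_cpm(ch$counts))
  expect_setequal(rep$removed_sample_ids, ch$truth$contaminated_sample_ids)
  expect_length(rep$kept_sample_ids, 427L)
})

test_that("n_contaminated = 0 plants nothing and the filter removes nothing", {
  ch <- generate_expression_cohort(cohort_spec(
    n_samples = 60, n_genes = 80, n_contaminated = 0, n_de_genes = 10,
    seed = 3
  ))
  expect_length(ch$truth$contaminated_sample_ids, 0L)
  rep <- keratinocyte_contamination_filter(compute_cpm(ch$counts))
  expect_length(rep$removed_sample_ids, 0L)
})

test_that("a contaminated CPM range overlapping the clean ceiling is rejected", {
  expect_error(
    cohort_spec(contaminated_marker_cpm_range = c(1, 500),
                clean_marker_cpm_max = 2),
    "ill-defined"
  )
})

test_that("count marginals match the negative-binomial moments", {
  # scaled-up cohort; variance checked through library-size-adjusted counts
  sp <- cohort_spec(n_samples = 4000, n_genes = 12, n_contaminated = 0,
                    n_de_genes = 0, nb_dispersion = 0.1, seed = 4)
  ch <- generate_expression_cohort(sp)
  libs <- ch$truth$library_sizes
  for (g in c("G00003", "G00005")) {
    z <- ch$counts[g, ] / libs # per-sample rate, expectation = cpm/1e6
    m <- mean(z)
    pred_var <- m * mean(1 / libs) + sp$nb_dispersion * m^2
    expect_lt(abs(stats::var(z) - pred_var) / pred_var, 0.05)
  }
})

test_that("groups planted are the eventual strata of the generated matrix", {
  for (mode in c("range", "quantile")) {
    ch <- generate_expression_cohort(cohort_spec(
      n_samples = 150, n_genes = 120, n_contaminated = 10,
      strat_mode = mode, seed = 7
    ))
    cpm <- compute_cpm(ch$counts)
    kept <- setdiff(colnames(cpm), ch$truth$contaminated_sample_ids)
    st <- stratify_by_expression_range(cpm[, kept], "DSG2", mode = mode)
    expect_identical(st$group_of_sample, ch$truth$group_of_sample[kept])
  }
})

test_that("null hazard ratio gives calibrated log-rank p-values", {
  # 200 replicate generator seeds at true HR = 1; quantile strata for stable
  # group sizes; small cohorts keep this cheap
  ps <- vapply(1:200, function(seed) {
    ch <- generate_expression_cohort(cohort_spec(
      n_samples = 80, n_genes = 20, n_contaminated = 0, n_de_genes = 0,
      true_hazard_ratio = 1, strat_mode = "quantile", strat_fraction = 0.3,
      seed = seed
    ))
    grp <- ch$truth$group_of_sample
    sel <- grp %in% c("high", "low")
    cl <- ch$clinical[sel, ]
    logrank_test(cl$days, cl$event, grp[sel])$p_value
  }, numeric(1))
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.03)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
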