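# End-to-end orchestration: validated configuration, the cohort pipeline
# (contamination filter -> stratification -> survival -> DE), the image batch
# pipeline, and the self-contained acceptance suite of in-study worked
# examples.

vmq_default_config <- function() {
  list(
    # image stage
    scales_px = c(2, 3, 4, 6),
    threshold_policy = "background",
    cd31_threshold_policy = "robust_otsu",
    threshold_q = 0.05,
    threshold_k = 7,
    threshold_value = NULL,
    min_component_px = 20L,
    dilation_px = 2L,
    # expression stage
    marker_gene_ids = c("IVL", "KRT14", "BNC"),
    t_all = 5,
    t_two = 20,
    strat_gene = "DSG2",
    strat_fraction = 0.10,
    strat_mode = "range",
    de_fdr = 0.005,
    de_min_fold = 2,
    values_are_cpm = FALSE,
    # survival stage
    hr_method = "oe",
    # misc
    seed = 1L
  )
}

#' Pipeline configuration
#'
#' Builds the effective configuration from the documented defaults; unknown
#' keys are rejected and numeric keys are range-checked.
#'
#' @param ... overrides of the default keys (see [vmq_default_config] source
#'   or the methods vignette for the full key list).
#' @return named list of class `vmq_config`.
#' @export
vmq_config <- function(...) {
  cfg <- vmq_default_config()
  over <- list(...)
  if (length(over) == 1L && is.null(names(over)) && is.list(over[[1L]])) {
    over <- over[[1L]]
  }
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    abort("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  if (any(cfg$scales_px < 0.5)) abort("scales_px must all be >= 0.5")
  pols <- c("quantile", "otsu", "background", "robust_otsu", "fixed")
  if (!cfg$threshold_policy %in% pols) {
    abort("threshold_policy must be one of %s", paste(pols, collapse = "/"))
  }
  if (!cfg$cd31_threshold_policy %in% pols) {
    abort("cd31_threshold_policy must be one of %s", paste(pols, collapse = "/"))
  }
  assert_scalar_num(cfg$threshold_q, "threshold_q", min = 1e-6, max = 0.999)
  assert_scalar_num(cfg$threshold_k, "threshold_k", min = 0)
  assert_scalar_num(cfg$min_component_px, "min_component_px", min = 0)
  assert_scalar_num(cfg$dilation_px, "dilation_px", min = 0)
  assert_scalar_num(cfg$t_all, "t_all", min = 0)
  assert_scalar_num(cfg$t_two, "t_two", min = 0)
  assert_scalar_num(cfg$strat_fraction, "strat_fraction",
                    min = 1e-9, max = 0.5 - 1e-9)
  if (!cfg$strat_mode %in% c("range", "quantile")) {
    abort("strat_mode must be range or quantile")
  }
  assert_scalar_num(cfg$de_fdr, "de_fdr", min = 0, max = 1)
  assert_scalar_num(cfg$de_min_fold, "de_min_fold", min = 1)
  if (!cfg$hr_method %in% c("oe")) abort("hr_method must be 'oe'")
  structure(cfg, class = c("vmq_config", "list"))
}

stage <- function(report, name, expr) {
  t0 <- proc.time()[["elapsed"]]
  value <- tryCatch(expr, error = function(e) {
    abort("stage '%s' failed: %s", name, conditionMessage(e))
  })
  report$timings[[name]] <- proc.time()[["elapsed"]] - t0
  report$stages[[name]] <- value
  report
}

#' Run the cohort analysis pipeline
#'
#' Executes, in order: CPM normalization, the keratinocyte contamination
#' filter, stratification of the kept samples on the configured gene,
#' Kaplan-Meier / log-rank survival comparison of the high vs low strata, and
#' the NB exact DE test (high vs low).  Deterministic given inputs and
#' config.
#'
#' @param counts genes x samples count matrix (or CPM when
#'   `values_are_cpm = TRUE` in the config).
#' @param clinical data.frame with columns `sample_id`, `days`, `event` (and
#'   optionally `stage`, `dsg2_cnv_amplified`).
#' @param config a [vmq_config()].
#' @param out_dir optional directory for artifact files (JSON summary plus
#'   per-stage CSV/TSV tables).
#' @return object of class `vmq_run_report` with the effective config, per
#'   stage outputs, timings, warnings and a flat `summary` list.
#' @export
run_cohort_pipeline <- function(counts, clinical, config = vmq_config(),
                                out_dir = NULL) {
  stopifnot(inherits(config, "vmq_config"))
  report <- structure(
    list(config = config, stages = list(), timings = list(), warnings = character(0)),
    class = "vmq_run_report"
  )
  check_count_matrix(counts)
  if (!config$strat_gene %in% rownames(counts)) {
    abort("stage 'stratify' failed: gene '%s' absent from matrix",
          config$strat_gene)
  }
  report <- stage(report, "cpm", {
    if (isTRUE(config$values_are_cpm)) counts else compute_cpm(counts)
  })
  cpm <- report$stages$cpm
  report <- stage(report, "filter", keratinocyte_contamination_filter(
    cpm, markers = config$marker_gene_ids, t_all = config$t_all,
    t_two = config$t_two
  ))
  kept <- report$stages$filter$kept_sample_ids
  report <- stage(report, "stratify", stratify_by_expression_range(
    cpm[, kept, drop = FALSE], gene_id = config$strat_gene,
    fraction = config$strat_fraction, mode = config$strat_mode
  ))
  groups <- report$stages$stratify$group_of_sample
  report <- stage(report, "survival", {
    extreme <- names(groups)[groups %in% c("high", "low")]
    cl <- clinical[match(extreme, clinical$sample_id), , drop = FALSE]
    missing <- extreme[is.na(cl$sample_id)]
    if (length(missing)) {
      abort("clinical records missing for sample(s): %s",
            paste(utils::head(missing, 5L), collapse = ", "))
    }
    bad <- !is.finite(cl$days) | cl$days < 0
    if (any(bad)) {
      report$warnings <- c(report$warnings, sprintf(
        "dropped %d record(s) with missing/negative survival time", sum(bad)))
      cl <- cl[!bad, , drop = FALSE]
    }
    grp <- groups[cl$sample_id]
    lr <- logrank_test(cl$days, cl$event, grp)
    list(
      logrank = lr,
      km = lapply(split(seq_len(nrow(cl)), grp), function(idx) {
        km_estimate(cl$days[idx], cl$event[idx])
      })
    )
  })
  report <- stage(report, "de", nb_exact_de_test(
    counts[, kept, drop = FALSE], groups, fdr = config$de_fdr,
    min_fold = config$de_min_fold
  ))
  strat <- report$stages$stratify
  surv <- report$stages$survival
  de <- report$stages$de
  report$summary <- list(
    n_samples = ncol(counts),
    n_kept = length(kept),
    n_removed = length(report$stages$filter$removed_sample_ids),
    strat_gene = strat$gene_id,
    low_cut = strat$low_cut, high_cut = strat$high_cut,
    group_sizes = as.list(table(strat$group_of_sample)),
    median_days = lapply(surv$km, function(k) k$median_days),
    hazard_ratio_oe = surv$logrank$hazard_ratio_oe,
    logrank_chi_square = surv$logrank$chi_square,
    logrank_p = surv$logrank$p_value,
    n_overexpressed = sum(de$table$is_overexpressed),
    n_underexpressed = sum(de$table$is_underexpressed)
  )
  if (!is.null(out_dir)) write_cohort_artifacts(report, out_dir)
  report
}

write_cohort_artifacts <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  filt <- report$stages$filter
  utils::write.csv(
    data.frame(sample_id = c(filt$kept_sample_ids, filt$removed_sample_ids),
               removed = rep(c(FALSE, TRUE),
                             c(length(filt$kept_sample_ids),
                               length(filt$removed_sample_ids)))),
    file.path(out_dir, "filter_report.csv"), row.names = FALSE)
  strat <- report$stages$stratify
  utils::write.csv(
    data.frame(sample_id = names(strat$group_of_sample),
               group = unname(strat$group_of_sample)),
    file.path(out_dir, "stratification.csv"), row.names = FALSE)
  utils::write.csv(report$stages$de$table,
                   file.path(out_dir, "de_results.csv"), row.names = FALSE)
  for (g in names(report$stages$survival$km)) {
    k <- report$stages$survival$km[[g]]
    utils::write.csv(
      data.frame(time_days = k$event_times, survival_prob = k$survival_prob,
                 n_at_risk = k$n_at_risk, n_events = k$n_events),
      file.path(out_dir, sprintf("km_%s.csv", g)), row.names = FALSE)
  }
  jsonlite::write_json(
    c(report$summary,
      list(config = unclass(report$config), warnings = report$warnings)),
    file.path(out_dir, "run_summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  invisible(out_dir)
}

#' @export
print.vmq_run_report <- function(x, ...) {
  s <- x$summary
  cat("<vmq_run_report>\n")
  if (!is.null(s$n_samples)) {
    cat(sprintf("  samples: %d total, %d kept, %d removed by contamination filter\n",
                s$n_samples, s$n_kept, s$n_removed))
    cat(sprintf("  stratification (%s): cuts [%.4g, %.4g], low/mid/high = %s/%s/%s\n",
                s$strat_gene, s$low_cut, s$high_cut,
                s$group_sizes$low, s$group_sizes$mid, s$group_sizes$high))
    meds <- vapply(s$median_days, function(m) {
      if (is.na(m)) "NR" else format(m)
    }, character(1))
    cat(sprintf("  survival: median days [%s], HR (O/E) %.3f, log-rank p = %.4g\n",
                paste(sprintf("%s: %s", names(meds), meds), collapse = ", "),
                s$hazard_ratio_oe, s$logrank_p))
    cat(sprintf("  DE: %d overexpressed / %d underexpressed\n",
                s$n_overexpressed, s$n_underexpressed))
  }
  if (!is.null(s$n_images)) {
    cat(sprintf("  images: %d quantified; mean vm_score %.3f\n",
                s$n_images, s$mean_vm_score))
    if (!is.null(s$group_p)) {
      cat(sprintf("  group comparison: means %s, t-test p = %.4g\n",
                  paste(sprintf("%s: %.3f", names(s$group_means),
                                s$group_means), collapse = ", "),
                  s$group_p))
    }
  }
  if (length(x$warnings)) {
    cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  }
  invisible(x)
}

#' Run the image batch pipeline
#'
#' Quantifies VM for each image and, when two-level group labels are
#' supplied, compares the scores between groups with the unpaired t-test.
#'
#' @param images list of [two_channel_image()] objects (or `vmq_ground_truth`
#'   objects, whose `$image` is used).
#' @param config a [vmq_config()].
#' @param labels optional group label per image.
#' @param out_dir optional artifact directory (JSON summary + per-image CSV).
#' @return object of class `vmq_run_report`.
#' @export
run_image_pipeline <- function(images, config = vmq_config(), labels = NULL,
                               out_dir = NULL) {
  stopifnot(inherits(config, "vmq_config"))
  if (length(images) == 0L) abort("empty image batch")
  images <- lapply(images, function(im) {
    if (inherits(im, "vmq_ground_truth")) im$image else im
  })
  report <- structure(
    list(config = config, stages = list(), timings = list(),
         warnings = character(0)),
    class = "vmq_run_report"
  )
  report <- stage(report, "quantify", lapply(images, quantify_vm, config = config))
  quants <- report$stages$quantify
  scores <- vapply(quants, `[[`, numeric(1), "vm_score")
  categories <- vapply(quants, `[[`, character(1), "category")
  cmp <- NULL
  if (!is.null(labels)) {
    report <- stage(report, "compare", compare_vm_by_group(scores, labels))
    cmp <- report$stages$compare
  }
  report$summary <- list(
    n_images = length(images),
    vm_scores = scores,
    categories = categories,
    mean_vm_score = mean(scores),
    group_means = if (!is.null(cmp)) as.list(cmp$means) else NULL,
    group_p = if (!is.null(cmp)) cmp$p_value else NULL
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(
      data.frame(image = seq_along(scores), vm_score = scores,
                 category = categories,
                 label = if (is.null(labels)) NA else as.character(labels)),
      file.path(out_dir, "vm_scores.csv"), row.names = FALSE)
    jsonlite::write_json(
      c(report$summary[c("n_images", "mean_vm_score", "group_means", "group_p")],
        list(vm_scores = unname(scores), categories = unname(categories),
             config = unclass(report$config))),
      file.path(out_dir, "image_summary.json"),
      auto_unbox = TRUE, digits = NA, null = "null"
    )
  }
  report
}

#' Run the in-study worked-example acceptance suite
#'
#' Recomputes the worked examples with stated expected values (matched-cohort
#' concordance, the reconstructed DSG2-by-stage Fisher test, and small
#' closed-form statistics checks) and reports each as pass/fail; failures are
#' reported, never thrown.
#'
#' @param use_fixtures when `FALSE` the fixture-based targets are marked
#'   `skipped` instead of being run.
#' @return data.frame with columns `target`, `expected`, `computed`,
#'   `status`.
#' @export
run_acceptance_suite <- function(use_fixtures = TRUE) {
  rows <- list()
  add <- function(target, expected, computed, status) {
    rows[[length(rows) + 1L]] <<- data.frame(
      target = target, expected = expected, computed = computed,
      status = status, stringsAsFactors = FALSE
    )
  }
  safely <- function(target, expected_str, fun, check) {
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      add(target, expected_str, conditionMessage(res), "fail")
    } else {
      add(target, expected_str, res$computed,
          if (isTRUE(res$ok)) "pass" else "fail")
    }
  }
  if (use_fixtures) {
    safely("table1_concordance", "6/8, discordant 3 and 5", function() {
      cs <- concordance_summary(load_paper_fixtures())
      list(computed = sprintf("%d/%d, discordant %s", cs$n_concordant,
                              cs$n_total,
                              paste(cs$discordant_patient_ids, collapse = " and ")),
           ok = cs$n_concordant == 6L && cs$n_total == 8L &&
             setequal(cs$discordant_patient_ids, c(3L, 5L)))
    })
    safely("stage_fisher_p", "0.294", function() {
      f <- fisher_exact_2x2(load_paper_fixtures()$stage_contingency)
      list(computed = sprintf("%.3f", f$p_two_sided),
           ok = abs(round(f$p_two_sided, 3) - 0.294) < 1e-9)
    })
  } else {
    add("table1_concordance", "6/8, discordant 3 and 5", "", "skipped")
    add("stage_fisher_p", "0.294", "", "skipped")
  }
  safely("km_hand_example", "S = .75/.50/.25/0, median 2", function() {
    km <- km_estimate(c(1, 2, 3, 4), c(1, 1, 1, 1))
    list(computed = paste(format(km$survival_prob), collapse = "/"),
         ok = isTRUE(all.equal(km$survival_prob, c(0.75, 0.5, 0.25, 0))) &&
           km$median_days == 2)
  })
  safely("mw_exact_example", "U = 0, p = 0.1", function() {
    rt <- rank_group_tests(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
    list(computed = sprintf("U = %g, p = %g", rt$statistic, rt$p_value),
         ok = rt$statistic == 0 && isTRUE(all.equal(rt$p_value, 0.1)))
  })
  safely("bh_hand_example", "all adjusted to 0.04", function() {
    adj <- benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04))
    list(computed = paste(format(adj), collapse = ", "),
         ok = isTRUE(all.equal(adj, rep(0.04, 4))))
  })
  do.call(rbind, rows)
}
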