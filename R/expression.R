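# Bulk RNA-seq cohort computations: counts-per-million normalization, the
# keratinocyte-contamination sample filter (IVL/KRT14/BNC marker rule),
# expression-range stratification, rank-based group tests, and a
# negative-binomial exact differential-expression test (a documented
# substitute for edgeR's common-dispersion exact test).

check_count_matrix <- function(counts, name = "counts") {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    abort("`%s` must be a numeric genes x samples matrix", name)
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`%s` needs gene rownames and sample colnames", name)
  }
  if (anyDuplicated(rownames(counts))) abort("duplicate gene ids in `%s`", name)
  if (anyDuplicated(colnames(counts))) abort("duplicate sample ids in `%s`", name)
  if (any(!is.finite(counts)) || min(counts) < 0) {
    abort("`%s` must be finite and >= 0", name)
  }
  invisible(counts)
}

#' Counts-per-million normalization
#'
#' `cpm[g, s] = counts[g, s] / colsum(s) * 1e6`; every column of the result
#' sums to one million.
#'
#' @param counts numeric genes x samples matrix with gene rownames and sample
#'   colnames; every column sum must be positive.
#' @return CPM matrix with the same dimnames.
#' @export
compute_cpm <- function(counts) {
  check_count_matrix(counts)
  libs <- colSums(counts)
  zero <- libs <= 0
  if (any(zero)) {
    abort("zero library size for sample(s): %s",
          paste(colnames(counts)[zero], collapse = ", "))
  }
  sweep(counts, 2L, libs, `/`) * 1e6
}

#' Keratinocyte contamination filter
#'
#' Flags bulk tumor samples contaminated with normal skin: a sample is
#' removed iff all three keratinocyte marker genes exceed `t_all` CPM, or at
#' least two of them exceed `t_two` CPM (strict inequalities).
#'
#' @param cpm CPM matrix (see [compute_cpm()]).
#' @param markers the three marker gene ids (default IVL, KRT14, BNC).
#' @param t_all CPM threshold all three markers must exceed (default 5).
#' @param t_two CPM threshold any two markers must exceed (default 20).
#' @return object of class `vmq_filter_report`: `kept_sample_ids`,
#'   `removed_sample_ids`, `per_sample_marker_cpm` (3 x samples matrix) and
#'   the `rule` applied.
#' @export
keratinocyte_contamination_filter <- function(cpm,
                                              markers = c("IVL", "KRT14", "BNC"),
                                              t_all = 5, t_two = 20) {
  check_count_matrix(cpm, "cpm")
  if (length(markers) != 3L) abort("exactly three marker genes required")
  missing <- setdiff(markers, rownames(cpm))
  if (length(missing)) {
    abort("marker gene(s) missing from matrix: %s",
          paste(missing, collapse = ", "))
  }
  m <- cpm[markers, , drop = FALSE]
  all_over <- colSums(m > t_all) == 3L
  two_over <- colSums(m > t_two) >= 2L
  removed <- all_over | two_over
  structure(
    list(kept_sample_ids = colnames(cpm)[!removed],
         removed_sample_ids = colnames(cpm)[removed],
         per_sample_marker_cpm = m,
         rule = list(markers = markers, t_all = t_all, t_two = t_two)),
    class = "vmq_filter_report"
  )
}

#' @export
print.vmq_filter_report <- function(x, ...) {
  cat(sprintf("<vmq_filter_report> kept %d / removed %d of %d samples (markers %s; all three > %g CPM or any two > %g CPM)\n",
              length(x$kept_sample_ids), length(x$removed_sample_ids),
              length(x$kept_sample_ids) + length(x$removed_sample_ids),
              paste(x$rule$markers, collapse = "/"), x$rule$t_all, x$rule$t_two))
  invisible(x)
}

#' Stratify samples by the expression range of one gene
#'
#' `mode = "range"` (default) places the cut points at
#' `min + fraction * (max - min)` and `max - fraction * (max - min)` of the
#' gene's expression *range*; `mode = "quantile"` uses the `fraction` and
#' `1 - fraction` empirical quantiles instead.  Samples strictly below the
#' low cut are `low`, strictly above the high cut `high`, all others
#' (boundaries included) `mid`.
#'
#' @param cpm CPM matrix.
#' @param gene_id gene to stratify on (default `"DSG2"`).
#' @param fraction cut fraction in `(0, 0.5)` (default 0.10, the top and
#'   bottom 10%).
#' @param mode `"range"` or `"quantile"`.
#' @return object of class `vmq_stratification`: `gene_id`, `low_cut`,
#'   `high_cut`, `mode`, `fraction` and `group_of_sample` (named character
#'   vector with values low/mid/high).
#' @export
stratify_by_expression_range <- function(cpm, gene_id = "DSG2",
                                         fraction = 0.10,
                                         mode = c("range", "quantile")) {
  check_count_matrix(cpm, "cpm")
  mode <- match.arg(mode)
  assert_scalar_num(fraction, "fraction", min = 1e-9, max = 0.5 - 1e-9)
  if (!gene_id %in% rownames(cpm)) {
    abort("stratification gene '%s' not present in the matrix", gene_id)
  }
  x <- cpm[gene_id, ]
  if (length(unique(x)) < 3L) {
    abort("expression of '%s' is (nearly) constant: range stratification degenerate",
          gene_id)
  }
  if (mode == "range") {
    r <- range(x)
    low_cut <- r[1L] + fraction * diff(r)
    high_cut <- r[2L] - fraction * diff(r)
  } else {
    low_cut <- stats::quantile(x, fraction, names = FALSE)
    high_cut <- stats::quantile(x, 1 - fraction, names = FALSE)
  }
  group <- ifelse(x < low_cut, "low", ifelse(x > high_cut, "high", "mid"))
  structure(
    list(gene_id = gene_id, low_cut = low_cut, high_cut = high_cut,
         mode = mode, fraction = fraction,
         group_of_sample = stats::setNames(group, colnames(cpm))),
    class = "vmq_stratification"
  )
}

#' @export
print.vmq_stratification <- function(x, ...) {
  n <- table(factor(x$group_of_sample, c("low", "mid", "high")))
  cat(sprintf("<vmq_stratification> %s, %s mode, fraction %.2f: cuts [%.4g, %.4g]; low %d / mid %d / high %d\n",
              x$gene_id, x$mode, x$fraction, x$low_cut, x$high_cut,
              n[["low"]], n[["mid"]], n[["high"]]))
  invisible(x)
}

# Exact NB conditional two-sided p for group sums s1 (n1 samples) vs s2 (n2
# samples) sharing dispersion phi.  Conditional on s = s1 + s2 the group-1
# sum follows a negative hypergeometric law (binomial when phi = 0); the
# two-sided p sums the point probabilities <= that of the observed split.
# Beyond `exact_limit` total counts a moment-matched normal approximation to
# the same conditional law is used.
nb_exact_pvalue <- function(s1, n1, s2, n2, phi, exact_limit = 2e5) {
  s <- s1 + s2
  if (s == 0) return(1)
  if (s > exact_limit) {
    if (phi <= 0) {
      p1 <- n1 / (n1 + n2)
      mu <- s * p1
      v <- s * p1 * (1 - p1)
    } else {
      a1 <- n1 / phi; a2 <- n2 / phi; a <- a1 + a2
      mu <- s * a1 / a
      v <- s * (a1 * a2 / a^2) * (a + s) / (a + 1)
    }
    z <- (abs(s1 - mu) - 0.5) / sqrt(v)
    return(min(1, 2 * stats::pnorm(-max(z, 0))))
  }
  x <- 0:s
  if (phi <= 0) {
    lp <- stats::dbinom(x, s, n1 / (n1 + n2), log = TRUE)
  } else {
    a1 <- n1 / phi; a2 <- n2 / phi
    lp <- lgamma(x + a1) - lgamma(x + 1) + lgamma(s - x + a2) - lgamma(s - x + 1)
    lp <- lp - logsumexp(lp)
  }
  obs <- lp[s1 + 1]
  min(1, sum(exp(lp[lp <= obs + 1e-8])))
}

# Pooled method-of-moments common dispersion from within-group residuals:
# solve sum(v - m) = phi * sum(m^2) over genes and groups, floored at 0.
mom_common_dispersion <- function(pseudo, idx_by_group) {
  num <- 0; den <- 0
  for (idx in idx_by_group) {
    m <- rowMeans(pseudo[, idx, drop = FALSE])
    v <- apply(pseudo[, idx, drop = FALSE], 1L, stats::var)
    num <- num + sum(v - m)
    den <- den + sum(m^2)
  }
  if (den <= 0) return(0)
  max(0, num / den)
}

#' Negative-binomial exact differential-expression test
#'
#' Substitute DE engine with a fixed, documented contract: counts are
#' library-size-equalised to the geometric-mean library (rounded
#' pseudo-counts), a single common dispersion is estimated by method of
#' moments from within-group residuals (floored at 0, which degenerates to a
#' Poisson/binomial conditional test), each gene is tested with an exact NB
#' conditional test on the group sums, and p-values are Benjamini-Hochberg
#' adjusted.  Genes are flagged over/underexpressed (high vs low) at the
#' thresholds `|log2FC| > log2(min_fold)` and `FDR < fdr`.
#'
#' @param counts genes x samples count matrix.
#' @param groups named vector (names = sample ids) or vector aligned with
#'   `colnames(counts)`, with values `"high"`/`"low"`; other samples are
#'   ignored.  Each group needs at least two samples.
#' @param fdr FDR threshold for the flags (default 0.005).
#' @param min_fold fold-change threshold for the flags (default 2).
#' @param fc_prior prior count added to per-sample group means before the
#'   log2 fold-change (default 0.5, avoids division by zero).
#' @return object of class `vmq_de_result`: a `table` data.frame (gene_id,
#'   log2_fold_change, p_value, fdr_adjusted_p, is_overexpressed,
#'   is_underexpressed) plus the estimated `dispersion` and the thresholds.
#' @export
nb_exact_de_test <- function(counts, groups, fdr = 0.005, min_fold = 2,
                             fc_prior = 0.5) {
  check_count_matrix(counts)
  if (!is.null(names(groups))) {
    groups <- groups[intersect(colnames(counts), names(groups))]
  } else {
    if (length(groups) != ncol(counts)) {
      abort("unnamed `groups` must align with colnames(counts)")
    }
    names(groups) <- colnames(counts)
  }
  groups <- groups[groups %in% c("high", "low")]
  hi_ids <- names(groups)[groups == "high"]
  lo_ids <- names(groups)[groups == "low"]
  if (length(hi_ids) < 2L || length(lo_ids) < 2L) {
    abort("each group needs >= 2 samples (high: %d, low: %d)",
          length(hi_ids), length(lo_ids))
  }
  sub <- counts[, c(hi_ids, lo_ids), drop = FALSE]
  libs <- colSums(sub)
  if (any(libs <= 0)) abort("zero library size in DE input")
  nstar <- exp(mean(log(libs)))
  pseudo <- round(sweep(sub, 2L, nstar / libs, `*`))
  n1 <- length(hi_ids); n2 <- length(lo_ids)
  idx1 <- seq_len(n1); idx2 <- n1 + seq_len(n2)
  phi <- mom_common_dispersion(pseudo, list(idx1, idx2))
  s1 <- rowSums(pseudo[, idx1, drop = FALSE])
  s2 <- rowSums(pseudo[, idx2, drop = FALSE])
  pvals <- vapply(seq_len(nrow(pseudo)), function(g) {
    nb_exact_pvalue(s1[g], n1, s2[g], n2, phi)
  }, numeric(1))
  log2fc <- log2((s1 / n1 + fc_prior) / (s2 / n2 + fc_prior))
  padj <- benjamini_hochberg(pvals)
  over <- log2fc > log2(min_fold) & padj < fdr
  under <- log2fc < -log2(min_fold) & padj < fdr
  tab <- data.frame(
    gene_id = rownames(sub), log2_fold_change = log2fc, p_value = pvals,
    fdr_adjusted_p = padj, is_overexpressed = over, is_underexpressed = under,
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(
    list(table = tab, dispersion = phi,
         thresholds = list(fdr = fdr, min_fold = min_fold,
                           fc_prior = fc_prior),
         n_high = n1, n_low = n2),
    class = "vmq_de_result"
  )
}

#' @export
print.vmq_de_result <- function(x, ...) {
  cat(sprintf("<vmq_de_result> %d genes, %d high vs %d low samples, common dispersion %.4g: %d overexpressed / %d underexpressed (> %g-fold, FDR < %g)\n",
              nrow(x$table), x$n_high, x$n_low, x$dispersion,
              sum(x$table$is_overexpressed), sum(x$table$is_underexpressed),
              x$thresholds$min_fold, x$thresholds$fdr))
  invisible(x)
}

#' Rank-based group comparison (Mann-Whitney / Kruskal-Wallis)
#'
#' Two groups: two-sided Mann-Whitney U test, by exact enumeration of all
#' label assignments when both groups have at most 8 observations, otherwise
#' by the normal approximation with tie correction (no continuity
#' correction).  Three or more groups: Kruskal-Wallis chi-square test with
#' tie correction.
#'
#' @param values numeric observations.
#' @param labels group label per observation; at least two non-empty groups.
#' @return list with `method`, `statistic` (U or H), `p_value` and `groups`.
#' @export
rank_group_tests <- function(values, labels) {
  if (length(values) != length(labels)) {
    abort("values and labels differ in length")
  }
  if (any(!is.finite(values))) abort("values must be finite")
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) < 2L) abort("at least two groups required")
  n <- length(values)
  r <- rank(values)
  if (length(lev) == 2L) {
    n1 <- sum(labels == lev[1L]); n2 <- n - n1
    u <- sum(r[labels == lev[1L]]) - n1 * (n1 + 1) / 2
    if (n1 <= 8L && n2 <= 8L) {
      combos <- utils::combn(n, n1)
      u_all <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
      d_obs <- abs(u - n1 * n2 / 2)
      p <- mean(abs(u_all - n1 * n2 / 2) >= d_obs - 1e-9)
      method <- "mann-whitney (exact)"
    } else {
      ties <- table(r)
      tie_term <- sum(ties^3 - ties) / (n * (n - 1))
      v <- n1 * n2 / 12 * ((n + 1) - tie_term)
      if (v <= 0) {
        p <- 1
      } else {
        z <- (u - n1 * n2 / 2) / sqrt(v)
        p <- 2 * stats::pnorm(-abs(z))
      }
      method <- "mann-whitney (normal approximation)"
    }
    return(list(method = method, statistic = u, p_value = min(1, p),
                groups = lev))
  }
  k <- length(lev)
  h <- 12 / (n * (n + 1)) *
    sum(vapply(lev, function(g) {
      idx <- labels == g
      sum(idx) * mean(r[idx])^2
    }, numeric(1))) - 3 * (n + 1)
  ties <- table(r)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr <= 0) {
    h <- 0
    p <- 1
  } else {
    h <- h / corr
    p <- stats::pchisq(h, df = k - 1, lower.tail = FALSE)
  }
  list(method = "kruskal-wallis", statistic = h, p_value = p, groups = lev)
}
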