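# From-scratch survival and categorical statistics: Kaplan-Meier
# product-limit estimator, Mantel-Haenszel log-rank test with O/E hazard
# ratio, exact two-sided Fisher test by hypergeometric enumeration,
# Benjamini-Hochberg step-up FDR adjustment, and the matched-cohort
# concordance summary.

check_survival_input <- function(time_days, event) {
  if (length(time_days) != length(event)) {
    abort("time_days and event differ in length")
  }
  if (length(time_days) == 0L) abort("no survival records")
  if (any(!is.finite(time_days)) || any(time_days < 0)) {
    abort("negative or non-finite survival time")
  }
  event <- as.logical(event)
  if (any(is.na(event))) abort("event indicator must be TRUE/FALSE (or 0/1)")
  event
}

#' Kaplan-Meier product-limit estimator
#'
#' At tied times, deaths precede censorings.  The median is the smallest
#' event time at which the survival curve reaches 0.5 or below (`NA` if the
#' curve never does).
#'
#' @param time_days non-negative follow-up times in days.
#' @param event event indicator (`TRUE`/1 = death observed, `FALSE`/0 =
#'   censored).
#' @return object of class `vmq_km`: `event_times`, `survival_prob`,
#'   `n_at_risk`, `n_events` (per distinct event time) and `median_days`.
#' @export
km_estimate <- function(time_days, event) {
  event <- check_survival_input(time_days, event)
  n <- length(time_days)
  times <- sort(unique(time_days[event]))
  if (length(times) == 0L) {
    return(structure(
      list(event_times = numeric(0), survival_prob = numeric(0),
           n_at_risk = integer(0), n_events = integer(0),
           median_days = NA_real_, n = n),
      class = "vmq_km"
    ))
  }
  n_at_risk <- vapply(times, function(t) sum(time_days >= t), integer(1))
  n_events <- vapply(times, function(t) sum(time_days == t & event),
                     integer(1))
  surv <- cumprod(1 - n_events / n_at_risk)
  med_idx <- which(surv <= 0.5)
  median_days <- if (length(med_idx)) times[med_idx[1L]] else NA_real_
  structure(
    list(event_times = times, survival_prob = surv, n_at_risk = n_at_risk,
         n_events = n_events, median_days = median_days, n = n),
    class = "vmq_km"
  )
}

#' @export
print.vmq_km <- function(x, ...) {
  cat(sprintf("<vmq_km> %d records, %d event times, median %s days\n",
              x$n, length(x$event_times),
              if (is.na(x$median_days)) "not reached" else
                format(x$median_days)))
  invisible(x)
}

#' Two-group log-rank test with O/E hazard ratio
#'
#' Standard Mantel-Haenszel log-rank chi-square (1 df) with the
#' hypergeometric variance at each distinct event time and no continuity
#' correction.  The hazard ratio is reported as the observed/expected ratio
#' `(O_a/E_a) / (O_b/E_b)` for the first group (alphabetical order) relative
#' to the second.
#'
#' @inheritParams km_estimate
#' @param group two-level group label per record.
#' @return object of class `vmq_logrank`: `chi_square`, `p_value`,
#'   `observed_a`, `expected_a`, `observed_b`, `expected_b`,
#'   `hazard_ratio_oe`, `groups`.
#' @export
logrank_test <- function(time_days, event, group) {
  event <- check_survival_input(time_days, event)
  group <- as.character(group)
  if (length(group) != length(time_days)) {
    abort("group and time_days differ in length")
  }
  lev <- sort(unique(group))
  if (length(lev) != 2L) abort("exactly two groups required, got %d", length(lev))
  if (!any(event)) abort("log-rank undefined: zero events")
  is_a <- group == lev[1L]
  times <- sort(unique(time_days[event]))
  o_a <- 0; e_a <- 0; v <- 0
  for (t in times) {
    at_risk <- time_days >= t
    n_t <- sum(at_risk)
    n_a <- sum(at_risk & is_a)
    d_t <- sum(time_days == t & event)
    d_a <- sum(time_days == t & event & is_a)
    o_a <- o_a + d_a
    e_a <- e_a + d_t * n_a / n_t
    if (n_t > 1L) {
      v <- v + d_t * (n_a / n_t) * (1 - n_a / n_t) * (n_t - d_t) / (n_t - 1)
    }
  }
  o_tot <- sum(event)
  o_b <- o_tot - o_a
  e_b <- o_tot - e_a
  chi <- if (v > 0) (o_a - e_a)^2 / v else 0
  p <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
  hr <- if (e_a > 0 && e_b > 0 && o_b > 0) (o_a / e_a) / (o_b / e_b) else NA_real_
  structure(
    list(chi_square = chi, p_value = p, observed_a = o_a, expected_a = e_a,
         observed_b = o_b, expected_b = e_b, hazard_ratio_oe = hr,
         groups = lev),
    class = "vmq_logrank"
  )
}

#' @export
print.vmq_logrank <- function(x, ...) {
  cat(sprintf("<vmq_logrank> %s vs %s: O/E %.0f/%.2f vs %.0f/%.2f, HR (O/E) %.3f, chi-square %.3f, p = %.4g\n",
              x$groups[1L], x$groups[2L], x$observed_a, x$expected_a,
              x$observed_b, x$expected_b, x$hazard_ratio_oe, x$chi_square,
              x$p_value))
  invisible(x)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p by exact enumeration: the sum of hypergeometric point
#' probabilities over all tables with the observed margins whose probability
#' does not exceed that of the observed table (the dominant two-sided
#' convention).  The odds ratio is the sample cross-product ratio, `NA` when
#' undefined.
#'
#' @param tab 2x2 matrix of non-negative integer counts, or a length-4 vector
#'   `c(a, b, c, d)` filled row-wise.
#' @return list with `odds_ratio`, `p_two_sided` and the table.
#' @export
fisher_exact_2x2 <- function(tab) {
  if (is.vector(tab) && length(tab) == 4L) {
    tab <- matrix(tab, 2L, 2L, byrow = TRUE)
  }
  if (!is.matrix(tab) || !all(dim(tab) == 2L)) abort("a 2x2 table is required")
  if (any(!is.finite(tab)) || any(tab < 0) || any(tab != round(tab))) {
    abort("table entries must be non-negative integers")
  }
  a <- tab[1L, 1L]; b <- tab[1L, 2L]; cc <- tab[2L, 1L]; d <- tab[2L, 2L]
  r1 <- a + b; r2 <- cc + d; c1 <- a + cc
  n <- r1 + r2
  if (n == 0L) abort("empty table")
  lo <- max(0L, c1 - r2); hi <- min(r1, c1)
  x <- lo:hi
  probs <- stats::dhyper(x, r1, r2, c1)
  p_obs <- probs[a - lo + 1L]
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  or <- if (b > 0 && cc > 0) (a * d) / (b * cc) else NA_real_
  list(odds_ratio = or, p_two_sided = p, table = tab)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values with monotonicity enforcement; the input order
#' is preserved.  Rejecting `adjusted <= q` reproduces the classical BH
#' step-up rule at level `q`.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
benjamini_hochberg <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  m <- length(p_values)
  o <- order(p_values)
  adj <- p_values[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Concordance of DSG2 status between matched primary and metastatic tumors
#'
#' Counts patients whose primary and metastasis DSG2 statuses agree and lists
#' the discordant patients.
#'
#' @param fixtures a [load_paper_fixtures()] object, or any data.frame with
#'   columns `patient_id`, `primary_status`, `metastasis_status` using the
#'   symbols `"+"` / `"-"`.
#' @return list with `n_concordant`, `n_total`, `discordant_patient_ids`.
#' @export
concordance_summary <- function(fixtures) {
  tab <- if (inherits(fixtures, "vmq_fixtures")) {
    fixtures$matched_cohort_table
  } else {
    fixtures
  }
  if (!is.data.frame(tab) ||
      !all(c("patient_id", "primary_status", "metastasis_status") %in%
             names(tab))) {
    abort("a matched cohort table with patient_id/primary_status/metastasis_status is required")
  }
  if (nrow(tab) == 0L) abort("empty matched cohort table")
  ok <- c("+", "-")
  bad <- !(tab$primary_status %in% ok) | !(tab$metastasis_status %in% ok)
  if (any(bad)) {
    abort("malformed status symbol for patient(s): %s",
          paste(tab$patient_id[bad], collapse = ", "))
  }
  agree <- tab$primary_status == tab$metastasis_status
  list(n_concordant = sum(agree), n_total = nrow(tab),
       discordant_patient_ids = tab$patient_id[!agree])
}
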