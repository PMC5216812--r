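# Survival and categorical statistics: KM, log-rank, Fisher, BH,
# concordance.  The survival package serves as an independent oracle only.

test_that("KM estimator handles censoring-only and hand-computed cases", {
  allc <- km_estimate(c(3, 7, 9), c(0, 0, 0))
  expect_length(allc$event_times, 0L)
  expect_true(is.na(allc$median_days))

  km <- km_estimate(c(1, 2, 3, 4), rep(1, 4))
  expect_equal(km$survival_prob, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$median_days, 2)
  expect_equal(km$n_at_risk, c(4L, 3L, 2L, 1L))

  expect_error(km_estimate(c(1, -2), c(1, 1)), "negative")
})

test_that("KM equals the empirical survival function without censoring and
           recovers the exponential median", {
  set.seed(31)
  t <- rexp(400, 0.01)
  km <- km_estimate(t, rep(1, 400))
  emp <- vapply(km$event_times, function(u) mean(t > u), numeric(1))
  expect_equal(km$survival_prob, emp, tolerance = 1e-12)

  set.seed(32)
  big <- km_estimate(rexp(5000, log(2) / 100), rep(1, 5000))
  expect_lt(abs(big$median_days - 100), 5)
})

test_that("KM ties: deaths precede censorings at equal times", {
  # at t=2: 3 at risk, 1 death -> S(2) = 2/3; the censored record at 2 is
  # still at risk for the death
  km <- km_estimate(c(1, 2, 2, 4), c(1, 1, 0, 1))
  expect_equal(km$survival_prob, c(3 / 4, 3 / 4 * 2 / 3, 0))
})

test_that("log-rank of a group against its copy is null", {
  t <- c(5, 9, 13, 20, 31)
  ev <- c(1, 0, 1, 1, 0)
  lr <- logrank_test(c(t, t), c(ev, ev), rep(c("a", "b"), each = 5))
  expect_equal(lr$chi_square, 0)
  expect_equal(lr$p_value, 1)
  expect_equal(lr$hazard_ratio_oe, 1)
})

test_that("label swap inverts the O/E hazard ratio and preserves p", {
  d <- simulate_survival(80, 2, seed = 5)
  a <- logrank_test(d$time, d$event, d$group)
  swapped <- ifelse(d$group == "high", "low", "high")
  # alphabetical group order makes 'high' group_a in both runs
  b <- logrank_test(d$time, d$event, swapped)
  expect_equal(a$hazard_ratio_oe, 1 / b$hazard_ratio_oe, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  expect_error(logrank_test(c(1, 2), c(0, 0), c("a", "b")), "zero events")
})

test_that("log-rank chi-square matches survival::survdiff", {
  skip_if_not_installed("survival")
  for (seed in 1:5) {
    d <- simulate_survival(60, c(1, 1.5, 2.6, 0.5, 1)[seed], seed = seed)
    got <- logrank_test(d$time, d$event, d$group)
    ref <- survival::survdiff(
      survival::Surv(d$time, d$event) ~ d$group)
    expect_equal(got$chi_square, unname(ref$chisq), tolerance = 1e-8)
    expect_equal(c(got$observed_a, got$observed_b), unname(ref$obs))
    expect_equal(c(got$expected_a, got$expected_b), unname(ref$exp),
                 tolerance = 1e-8)
  }
})

test_that("log-rank p-values under permuted labels are uniform", {
  set.seed(77)
  t <- rexp(60, 0.01)
  ev <- runif(60) < 0.8
  ps <- vapply(1:500, function(s) {
    set.seed(s)
    logrank_test(t, ev, sample(rep(c("a", "b"), 30)))$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("Fisher exact: forced enumerations and error handling", {
  expect_equal(fisher_exact_2x2(c(1, 0, 0, 1))$p_two_sided, 1)
  expect_equal(fisher_exact_2x2(c(3, 1, 1, 3))$p_two_sided, 34 / 70)
  f <- fisher_exact_2x2(matrix(c(18, 28, 6, 19), 2, byrow = TRUE))
  expect_equal(round(f$p_two_sided, 3), 0.294)
  expect_true(is.na(fisher_exact_2x2(c(2, 0, 1, 3))$odds_ratio))
  expect_error(fisher_exact_2x2(c(-1, 2, 3, 4)), "non-negative")
})

test_that("Fisher p equals brute-force enumeration on random tables", {
  set.seed(19)
  for (i in 1:200) {
    tab <- matrix(rpois(4, 4), 2)
    if (sum(tab) == 0 || sum(tab) > 40) next
    got <- fisher_exact_2x2(tab)$p_two_sided
    want <- fisher_bruteforce(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("Fisher matches stats::fisher.test two-sided p", {
  set.seed(23)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 6), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab)$p_two_sided,
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("BH adjustment: hand cases and equivalence with p.adjust", {
  expect_equal(benjamini_hochberg(0.037), 0.037)
  expect_equal(benjamini_hochberg(rep(0.02, 5)), rep(0.02, 5))
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(benjamini_hochberg(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(41)
  for (i in 1:100) {
    p <- runif(sample(1:50, 1))
    expect_equal(benjamini_hochberg(p), stats::p.adjust(p, "BH"),
                 tolerance = 1e-12)
  }
})

test_that("BH rejections reproduce the classical step-up rule", {
  set.seed(42)
  p <- c(runif(40), runif(10, 0, 1e-4))
  q <- 0.05
  adj <- benjamini_hochberg(p)
  m <- length(p)
  ord <- order(p)
  k <- max(c(0, which(p[ord] <= q * seq_len(m) / m)))
  stepup <- ord[seq_len(k)]
  expect_setequal(which(adj <= q), stepup)
})

test_that("concordance summary counts matched statuses", {
  cs <- concordance_summary(load_paper_fixtures())
  expect_identical(cs$n_concordant, 6L)
  expect_identical(cs$n_total, 8L)
  expect_setequal(cs$discordant_patient_ids, c(3L, 5L))

  allpos <- data.frame(patient_id = 1:3, primary_status = "+",
                       metastasis_status = "+")
  expect_identical(concordance_summary(allpos)$n_concordant, 3L)

  expect_error(concordance_summary(allpos[0, ]), "empty")
  bad <- data.frame(patient_id = 1, primary_status = "pos",
                    metastasis_status = "+")
  expect_error(concordance_summary(bad), "malformed")
})
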