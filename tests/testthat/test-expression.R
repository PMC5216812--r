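# Expression module: CPM, contamination filter, stratification, NB exact DE
# test and rank tests.

mk_counts <- function(m, genes = NULL, samples = NULL) {
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  m
}

test_that("compute_cpm arithmetic and invariants", {
  one <- mk_counts(matrix(c(1, 1, 2), 3))
  expect_equal(unname(compute_cpm(one)[, 1]), c(250000, 250000, 500000))

  set.seed(1)
  m <- mk_counts(matrix(rpois(60, 40), 10))
  cpm <- compute_cpm(m)
  expect_equal(unname(colSums(cpm)), rep(1e6, 6), tolerance = 1e-9)
  # scale invariance: proportional columns give identical CPM columns
  m2 <- m
  m2[, 2] <- m[, 1] * 7
  cpm2 <- compute_cpm(m2)
  expect_equal(cpm2[, 1], cpm2[, 2], ignore_attr = TRUE)

  bad <- mk_counts(cbind(c(1, 2), c(0, 0)))
  expect_error(compute_cpm(bad), "s2")
})

test_that("contamination filter applies the marker rule with strict inequalities", {
  base <- matrix(1, 4, 4)
  rownames(base) <- c("IVL", "KRT14", "BNC", "other")
  colnames(base) <- c("all_over", "two_high", "one_high", "boundary")
  base[1:3, "all_over"] <- c(6, 7, 5.5)
  base[1:3, "two_high"] <- c(25, 21, 0)
  base[1:3, "one_high"] <- c(25, 10, 0)
  base[1:3, "boundary"] <- c(5, 5, 5)
  rep <- keratinocyte_contamination_filter(base)
  expect_setequal(rep$removed_sample_ids, c("all_over", "two_high"))
  expect_setequal(rep$kept_sample_ids, c("one_high", "boundary"))

  # idempotence: filtering the kept set removes nothing
  rep2 <- keratinocyte_contamination_filter(
    base[, rep$kept_sample_ids, drop = FALSE])
  expect_length(rep2$removed_sample_ids, 0L)

  # decision depends only on the marker rows
  perturbed <- base
  perturbed["other", ] <- c(1e6, 0, 42, 7)
  rep3 <- keratinocyte_contamination_filter(perturbed)
  expect_identical(rep3$removed_sample_ids, rep$removed_sample_ids)

  expect_error(keratinocyte_contamination_filter(base[-1, , drop = FALSE]),
               "IVL")
})

test_that("range stratification arithmetic and boundary handling", {
  vals <- matrix(0:100, 1, dimnames = list("DSG2", sprintf("s%d", 0:100)))
  st <- stratify_by_expression_range(vals, "DSG2", 0.10)
  expect_equal(st$low_cut, 10)
  expect_equal(st$high_cut, 90)
  g <- st$group_of_sample
  expect_true(all(g[paste0("s", 0:9)] == "low"))
  expect_identical(unname(g["s10"]), "mid") # boundary value goes to mid
  expect_identical(unname(g["s90"]), "mid")
  expect_true(all(g[paste0("s", 91:100)] == "high"))
  expect_identical(sum(g == "low") + sum(g == "mid") + sum(g == "high"), 101L)
})

test_that("quantile stratification yields ~fraction-sized extreme groups", {
  set.seed(4)
  vals <- matrix(sample(seq(1, 1000, length.out = 100)), 1,
                 dimnames = list("DSG2", sprintf("s%d", 1:100)))
  st <- stratify_by_expression_range(vals, "DSG2", 0.10, mode = "quantile")
  g <- st$group_of_sample
  expect_true(sum(g == "low") %in% 9:11)
  expect_true(sum(g == "high") %in% 9:11)

  const <- matrix(5, 1, 10, dimnames = list("DSG2", sprintf("s%d", 1:10)))
  expect_error(stratify_by_expression_range(const, "DSG2"), "constant")
  expect_error(stratify_by_expression_range(vals, "NOPE"), "NOPE")
})

test_that("DE test flags extreme separation and respects symmetry", {
  m <- mk_counts(rbind(c(0, 0, 0, 50, 60, 55),
                       rep(100, 6),
                       c(90, 110, 95, 100, 105, 98)))
  groups <- stats::setNames(rep(c("low", "high"), each = 3), colnames(m))
  de <- nb_exact_de_test(m, groups)
  expect_true(de$table$is_overexpressed[1])
  expect_gt(de$table$log2_fold_change[1], 1)
  expect_lt(de$table$fdr_adjusted_p[1], 0.005)

  flipped <- stats::setNames(rep(c("high", "low"), each = 3), colnames(m))
  de2 <- nb_exact_de_test(m, flipped)
  expect_equal(de2$table$log2_fold_change, -de$table$log2_fold_change,
               tolerance = 1e-9)
  expect_identical(de2$table$is_underexpressed, de$table$is_overexpressed)
  expect_equal(de2$table$p_value, de$table$p_value, tolerance = 1e-9)

  expect_error(nb_exact_de_test(m, stats::setNames(
    c("high", "low", "low", "low", "low", "low"), colnames(m))), ">= 2")
})

test_that("DE null calibration: false discoveries stay below the FDR target", {
  # homogeneous cohorts with permuted labels; expected FDR<0.005 calls per
  # reasoning over replicates <= 0.005 * n_genes
  n_genes <- 500
  calls <- vapply(1:40, function(rep) {
    set.seed(rep)
    mu <- rep(stats::rlnorm(n_genes, log(30), 1), 12)
    m <- mk_counts(matrix(stats::rnbinom(n_genes * 12, mu = mu, size = 10),
                          n_genes, 12))
    groups <- stats::setNames(sample(rep(c("high", "low"), each = 6)),
                              colnames(m))
    de <- nb_exact_de_test(m, groups)
    sum(de$table$fdr_adjusted_p < 0.005)
  }, numeric(1))
  expect_lte(mean(calls), 0.005 * n_genes)
})

test_that("Mann-Whitney exact enumeration matches hand results", {
  rt <- rank_group_tests(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_identical(rt$method, "mann-whitney (exact)")
  expect_equal(rt$statistic, 0)
  expect_equal(rt$p_value, 0.1) # 2 of the 20 labelings are as extreme

  sym <- rank_group_tests(c(1, 4, 2, 5, 3, 6),
                          rep(c("a", "b"), times = 3))
  expect_lte(sym$p_value, 1)
})

test_that("rank tests agree with the base R oracles in approximation mode", {
  set.seed(3)
  x <- rnorm(30); y <- rnorm(25, 0.5)
  got <- rank_group_tests(c(x, y), rep(c("a", "b"), c(30, 25)))
  want <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(got$p_value, want$p.value, tolerance = 1e-12)
  expect_equal(unname(got$statistic), unname(want$statistic))

  z <- sample(1:4, 20, TRUE) # heavy ties
  xt <- sample(1:4, 18, TRUE)
  gt <- rank_group_tests(c(z, xt), rep(c("a", "b"), c(20, 18)))
  wt <- stats::wilcox.test(z, xt, exact = FALSE, correct = FALSE)
  expect_equal(gt$p_value, wt$p.value, tolerance = 1e-12)

  k <- rank_group_tests(c(x, y, z), rep(c("a", "b", "c"), c(30, 25, 20)))
  kw <- stats::kruskal.test(list(x, y, z))
  expect_equal(k$statistic, unname(kw$statistic), tolerance = 1e-12)
  expect_equal(k$p_value, kw$p.value, tolerance = 1e-12)
})

test_that("degenerate rank-test inputs", {
  const <- rank_group_tests(rep(7, 9), rep(c("a", "b", "c"), each = 3))
  expect_equal(const$statistic, 0)
  expect_equal(const$p_value, 1)
  expect_error(rank_group_tests(1:4, rep("a", 4)), "two groups")
})

test_that("null rank-test p-values are uniform", {
  ps <- vapply(1:200, function(s) {
    set.seed(s)
    v <- rnorm(40)
    rank_group_tests(v, sample(rep(c("a", "b"), 20)))$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})
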