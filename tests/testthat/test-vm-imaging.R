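# VM imaging: Hessian/tubeness numerics, tissue detection, segmentation,
# vessel subtraction, scoring, categorization and the group comparison.

test_that("hessian of flat and quadratic rasters is exact", {
  flat <- matrix(5, 48, 48)
  ev <- hessian_eigenvalues(flat, 2)
  expect_equal(max(abs(ev$l1)), 0)
  expect_equal(max(abs(ev$l2)), 0)

  n <- 64
  xs <- matrix(rep(seq_len(n), each = n), n, n)
  quad <- (xs - n / 2)^2 + (t(xs) - n / 2)^2
  for (sigma in c(2, 3)) {
    ev <- hessian_eigenvalues(quad, sigma)
    int <- 20:44
    expect_equal(ev$l1[int, int], matrix(2, 25, 25), tolerance = 1e-10)
    expect_equal(ev$l2[int, int], matrix(2, 25, 25), tolerance = 1e-10)
  }
  expect_error(hessian_eigenvalues(matrix(c(1, NA, 3, 4), 2), 2), "non-finite")
  expect_error(hessian_eigenvalues(flat, 0.3), "sigma")
})

test_that("eigenvalues are magnitude-sorted", {
  set.seed(5)
  ev <- hessian_eigenvalues(matrix(rnorm(900), 30), 2)
  expect_true(all(abs(ev$l1) <= abs(ev$l2) + 1e-12))
})

test_that("tubeness equals the finite-difference oracle on random rasters", {
  set.seed(11)
  for (rep in 1:3) {
    r <- matrix(rnorm(64 * 64), 64, 64)
    sigma <- c(2, 3, 4)[rep]
    got <- tubeness(r, scales_px = sigma)$response
    want <- fd_tubeness_oracle(r, sigma)
    int <- 20:45
    denom <- pmax(abs(want[int, int]), 1e-9)
    expect_lt(max(abs(got[int, int] - want[int, int]) / denom), 1e-3)
  }
})

test_that("tubeness matches the Gaussian-ridge closed form", {
  # continuum closed form sigma^2 * w / (w^2 + sigma^2)^(3/2); the discrete
  # operator carries a ~1/(4(w^2+sigma^2)) bias, so the 1% check runs at
  # moderate scales and the small-scale case documents the known bias
  for (ws in list(c(3, 4), c(4, 6))) {
    w <- ws[1]; sigma <- ws[2]
    r <- ridge_raster(121, w)
    crest <- tubeness(r, scales_px = sigma)$response[61, 61]
    closed <- sigma^2 * w / (w^2 + sigma^2)^1.5
    expect_lt(rel_err(crest, closed), 0.01)
  }
  crest <- tubeness(ridge_raster(81, 2), scales_px = 2)$response[41, 41]
  closed <- 2^2 * 2 / (2^2 + 2^2)^1.5
  expect_lt(rel_err(crest, closed), 0.05)
})

test_that("tubeness polarity and rectification", {
  dark_line <- 1 - ridge_raster(81, 2)
  tb <- tubeness(dark_line, scales_px = 3)
  expect_equal(tb$response[41, 41], 0) # dark line: l2 > 0, rectified away
  set.seed(2)
  tb2 <- tubeness(matrix(rnorm(400), 20), scales_px = c(2, 3))
  expect_gte(min(tb2$response), 0)
  expect_error(tubeness(dark_line, numeric(0)), "non-empty")
})

test_that("tubeness of a ridge is invariant under 90-degree rotation", {
  r <- ridge_raster(81, 2)
  a <- tubeness(r, scales_px = c(2, 3))$response
  b <- tubeness(t(r), scales_px = c(2, 3))$response # ridge now vertical
  expect_lt(max(abs(t(b) - a)) / max(a), 0.02)
})

test_that("detect_tissue honours explicit masks and recovers discs", {
  gt <- generate_vm_image(vm_image_spec(seed = 8, tissue_fraction = 0.5))
  explicit <- two_channel_image(gt$image$pas, gt$image$cd31,
                                tissue_mask = gt$true_tissue_mask)
  expect_identical(detect_tissue(explicit), gt$true_tissue_mask)

  est <- detect_tissue(gt$image)
  expect_lt(rel_err(sum(est), sum(gt$true_tissue_mask)), 0.05)

  full <- generate_vm_image(vm_image_spec(seed = 8, tissue_fraction = 1))
  expect_gte(mean(detect_tissue(full$image)), 0.99)

  set.seed(99)
  blank <- two_channel_image(matrix(pmax(rnorm(96 * 96, 0, 50), 0), 96),
                             matrix(pmax(rnorm(96 * 96, 0, 50), 0), 96))
  expect_error(detect_tissue(blank), "no tissue")
  zero <- two_channel_image(matrix(0, 96, 96), matrix(0, 96, 96))
  expect_error(detect_tissue(zero), "no tissue")
})

test_that("segment_networks trivial and dominance cases", {
  tis <- matrix(TRUE, 48, 48)
  zero <- structure(list(response = matrix(0, 48, 48), scales_px = 2,
                         per_scale = NULL), class = "vmq_tubeness")
  nm <- segment_networks(zero, tis)
  expect_false(any(nm$mask))
  expect_identical(nm$n_components, 0L)

  gt <- generate_vm_image(vm_image_spec(seed = 2))
  tis2 <- gt$true_tissue_mask
  fld <- tubeness(gt$image$pas)
  big <- segment_networks(fld, tis2, min_component_px = 1e6)
  expect_false(any(big$mask))
  nm2 <- segment_networks(fld, tis2)
  expect_true(all(nm2$mask[!tis2] == FALSE))
  expect_identical(nm2$threshold_policy, "background")
  # every surviving component respects the size floor
  cc <- vmquant:::label_components(nm2$mask)
  if (length(cc$sizes)) expect_gte(min(cc$sizes), nm2$min_component_px)
})

test_that("default segmentation recovers the planted network (Jaccard)", {
  gt <- generate_vm_image(vm_image_spec(seed = 2))
  q <- quantify_vm(gt$image)
  jac <- sum(q$pas_network_mask & gt$true_network_mask) /
    sum(q$pas_network_mask | gt$true_network_mask)
  expect_gte(jac, 0.6)
})

test_that("cd31 segmentation recovers vessel area within 20%", {
  areas <- vapply(1:5, function(seed) {
    gt <- generate_vm_image(vm_image_spec(seed = seed))
    q <- quantify_vm(gt$image)
    sum(q$cd31_network_mask) / sum(gt$true_vessel_mask)
  }, numeric(1))
  expect_lt(abs(median(areas) - 1), 0.2)
  zero <- segment_cd31(matrix(0, 64, 64), matrix(TRUE, 64, 64))
  expect_false(any(zero$mask))
})

test_that("subtract_vessels matches brute-force pixel arithmetic", {
  a <- matrix(FALSE, 16, 16); a[4:12, 4:6] <- TRUE
  b <- matrix(FALSE, 16, 16); b[10:14, 5:9] <- TRUE
  k <- sum(a & b)
  expect_identical(sum(subtract_vessels(a, b, 0)), sum(a) - k)
  disj <- matrix(FALSE, 16, 16); disj[1:2, 14:16] <- TRUE
  expect_identical(subtract_vessels(a, disj, 0), a)
  expect_false(any(subtract_vessels(a, a | b, 0)))
  expect_error(subtract_vessels(a, b, -1), "dilation")
})

test_that("vm score bounds, trivial values and errors", {
  tis <- matrix(TRUE, 32, 32)
  expect_identical(compute_vm_score(matrix(FALSE, 32, 32), tis), 0)
  expect_identical(compute_vm_score(tis, tis), 100)
  expect_error(compute_vm_score(tis, matrix(FALSE, 32, 32)), "empty tissue")
})

test_that("vm score is monotone in dilation and zero under full co-staining", {
  gt <- generate_vm_image(vm_image_spec(seed = 6))
  q <- quantify_vm(gt$image)
  tis <- q$tissue_mask
  scores <- vapply(0:4, function(d) {
    compute_vm_score(
      subtract_vessels(q$pas_network_mask, q$cd31_network_mask, d), tis)
  }, numeric(1))
  expect_true(all(diff(scores) <= 1e-12))
  # CD31 == PAS channel: every detected network co-stains
  co <- two_channel_image(gt$image$pas, gt$image$pas)
  q2 <- quantify_vm(co)
  expect_lt(q2$vm_score, 0.5)
})

test_that("PAS categories follow the area and branching rules", {
  tis <- matrix(TRUE, 64, 64)
  empty <- list(pas_network_mask = matrix(FALSE, 64, 64),
                pas_area_fraction = 0)
  expect_identical(classify_pas_category(empty), "PAS-neg")

  # straight tube covering ~15% of tissue: disconnected arc only
  tube <- matrix(FALSE, 64, 64); tube[28:37, 3:62] <- TRUE
  straight <- list(pas_network_mask = tube,
                   pas_area_fraction = sum(tube) / sum(tis))
  expect_gt(straight$pas_area_fraction, 0.10)
  expect_identical(classify_pas_category(straight), "PAS-low")

  # branched cross of the same area class
  cross <- matrix(FALSE, 64, 64)
  cross[28:37, 3:62] <- TRUE; cross[3:62, 28:37] <- TRUE
  branched <- list(pas_network_mask = cross,
                   pas_area_fraction = sum(cross) / sum(tis))
  expect_identical(classify_pas_category(branched), "PAS-high")

  # sub-10% area is PAS-low even when branched
  small <- list(pas_network_mask = cross, pas_area_fraction = 0.05)
  expect_identical(classify_pas_category(small), "PAS-low")
})

test_that("group comparison reproduces the pooled t-test exactly", {
  same <- compare_vm_by_group(c(1, 2, 3, 1, 2, 3),
                              rep(c("a", "b"), each = 3))
  expect_equal(same$mean_difference, 0)
  expect_equal(same$p_value, 1)

  const <- compare_vm_by_group(c(0, 0, 0, 0, 1, 1, 1, 1),
                               rep(c("neg", "pos"), each = 4))
  expect_equal(unname(const$means), c(0, 1))

  set.seed(9)
  x <- rnorm(1000, 3.24, 1.2)
  y <- rnorm(1000, 1.42, 0.8)
  got <- compare_vm_by_group(c(x, y), rep(c("a", "b"), each = 1000))
  n1 <- n2 <- 1000
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  tref <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  expect_lt(abs(got$t_statistic - tref), 1e-10)
  expect_equal(got$p_value,
               t.test(x, y, var.equal = TRUE)$p.value, tolerance = 1e-12)

  expect_error(compare_vm_by_group(c(1, 2, 3), c("a", "a", "b")), ">= 2")
})
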