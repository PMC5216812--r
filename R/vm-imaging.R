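# Quantification of vasculogenic mimicry (VM) from two-channel histology:
# multiscale Hessian "tubeness" ridge detection on the PAS fluorescence
# channel, network segmentation, subtraction of the CD31-positive endothelial
# network, and scoring of the residual PAS+CD31- network area as a percentage
# of tissue.

#' Two-channel PAS/CD31 histology image
#'
#' Container for one field of view: a PAS fluorescence raster (basement
#' membrane, which outlines both VM channels and conventional vessels) and a
#' CD31 immunostain raster (endothelium only).  Rasters are numeric matrices
#' with row-major top-left origin; intensities must be finite and
#' non-negative.
#'
#' @param pas,cd31 numeric matrices of identical dimension.
#' @param pixel_size_um optional pixel edge length in micrometres.
#' @param tissue_mask optional logical matrix marking tissue pixels; when
#'   present, [detect_tissue()] returns it unchanged.
#' @return An object of class `vmq_image`.
#' @export
two_channel_image <- function(pas, cd31, pixel_size_um = NULL,
                              tissue_mask = NULL) {
  assert_matrix_finite(pas, "pas")
  assert_matrix_finite(cd31, "cd31")
  if (!identical(dim(pas), dim(cd31))) {
    abort("pas (%dx%d) and cd31 (%dx%d) differ in shape",
          nrow(pas), ncol(pas), nrow(cd31), ncol(cd31))
  }
  if (min(pas) < 0 || min(cd31) < 0) abort("channel intensities must be >= 0")
  if (!is.null(pixel_size_um)) {
    assert_scalar_num(pixel_size_um, "pixel_size_um", min = 1e-9)
  }
  if (!is.null(tissue_mask)) {
    tissue_mask <- as_binary_mask(tissue_mask, "tissue_mask")
    if (!identical(dim(tissue_mask), dim(pas))) {
      abort("tissue_mask shape differs from channels")
    }
  }
  structure(
    list(pas = pas, cd31 = cd31, pixel_size_um = pixel_size_um,
         tissue_mask = tissue_mask),
    class = "vmq_image"
  )
}

#' @export
print.vmq_image <- function(x, ...) {
  cat(sprintf("<vmq_image> %d x %d px, PAS range [%.3g, %.3g], CD31 range [%.3g, %.3g]%s\n",
              nrow(x$pas), ncol(x$pas), min(x$pas), max(x$pas),
              min(x$cd31), max(x$cd31),
              if (is.null(x$tissue_mask)) "" else ", tissue mask attached"))
  invisible(x)
}

#' Hessian eigenvalues of a Gaussian-smoothed raster
#'
#' Computes the 2x2 Hessian at every pixel from Gaussian-derivative
#' convolutions at scale `sigma` (reflective boundary).  The derivative
#' kernels are discrete central differences of the sampled Gaussian, so on
#' interior pixels the result equals the central finite-difference Hessian of
#' the Gaussian-smoothed raster exactly.  Eigenvalues are returned sorted by
#' magnitude per pixel.
#'
#' @param raster numeric matrix with finite entries.
#' @param sigma Gaussian scale in pixels, `>= 0.5`.
#' @return list with matrices `l1`, `l2` where `|l1| <= |l2|` pointwise.
#' @export
hessian_eigenvalues <- function(raster, sigma) {
  assert_matrix_finite(raster, "raster")
  assert_scalar_num(sigma, "sigma", min = 0.5)
  g0 <- gaussian_kernel(sigma, 0L)
  g1 <- gaussian_kernel(sigma, 1L)
  g2 <- gaussian_kernel(sigma, 2L)
  hrr <- conv_sep(raster, g2, g0)
  hcc <- conv_sep(raster, g0, g2)
  hrc <- conv_sep(raster, g1, g1)
  tr <- hrr + hcc
  disc <- sqrt((hrr - hcc)^2 + 4 * hrc^2)
  ea <- (tr + disc) / 2
  eb <- (tr - disc) / 2
  swap <- abs(ea) > abs(eb)
  l1 <- ifelse(swap, eb, ea)
  l2 <- ifelse(swap, ea, eb)
  list(l1 = matrix(l1, nrow(raster)), l2 = matrix(l2, nrow(raster)))
}

#' Multiscale tubeness (bright ridge) response
#'
#' Sato-style bright-line measure: at each scale sigma the response is
#' `sigma^2 * |l2|` where `l2`, the larger-magnitude Hessian eigenvalue, is
#' negative (bright ridge on dark background), else 0; the `sigma^2` factor
#' normalizes across scales.  The field response is the pointwise maximum
#' over scales.
#'
#' @param channel numeric matrix (one image channel).
#' @param scales_px positive Gaussian scales in pixels (default `c(2,3,4,6)`).
#' @param keep_per_scale keep the per-scale response stack?
#' @return object of class `vmq_tubeness` with elements `response`,
#'   `scales_px` and optionally `per_scale`.
#' @export
tubeness <- function(channel, scales_px = c(2, 3, 4, 6),
                     keep_per_scale = FALSE) {
  assert_matrix_finite(channel, "channel")
  if (length(scales_px) < 1L) abort("scales_px must be non-empty")
  if (any(!is.finite(scales_px)) || any(scales_px < 0.5)) {
    abort("all scales must be finite and >= 0.5 px")
  }
  per <- lapply(scales_px, function(s) {
    ev <- hessian_eigenvalues(channel, s)
    resp <- -ev$l2
    resp[resp < 0] <- 0
    s^2 * resp
  })
  response <- Reduce(pmax, per)
  structure(
    list(response = response, scales_px = scales_px,
         per_scale = if (keep_per_scale) per else NULL),
    class = "vmq_tubeness"
  )
}

#' Detect the tissue region of an image
#'
#' If the image carries an explicit tissue mask it is returned unchanged.
#' Otherwise the summed channels are Gaussian-smoothed and thresholded at
#' half the 90th-percentile smoothed intensity (tissue carries a positive
#' background stain level; the exterior is empty), followed by morphological
#' closing and hole filling.  An image whose smoothed intensity never rises
#' above its own noise floor raises "no tissue detected".
#'
#' @param image a [two_channel_image()].
#' @param smooth_sigma smoothing scale in pixels.
#' @param close_radius closing radius in pixels.
#' @return logical matrix.
#' @export
detect_tissue <- function(image, smooth_sigma = 8, close_radius = 3L) {
  stopifnot(inherits(image, "vmq_image"))
  if (!is.null(image$tissue_mask)) return(image$tissue_mask)
  combined <- image$pas + image$cd31
  sm <- gaussian_smooth(combined, smooth_sigma)
  # pixel-level noise estimate from the high-frequency residual; tissue must
  # carry a background stain level above it, while a field of pure (clipped)
  # noise smooths to well below its own pixel noise
  noise <- stats::mad(combined - sm)
  q90 <- stats::quantile(sm, 0.90, names = FALSE)
  # clipped pure noise smooths to ~its own pixel sd; real tissue background
  # must clear it with margin (documented limitation: background > ~1.5x
  # pixel noise)
  if (q90 <= 1.5 * noise || q90 <= 0) abort("no tissue detected")
  mask <- sm > q90 / 2
  mask <- fill_holes(binary_close(mask, close_radius))
  if (!any(mask)) abort("no tissue detected")
  mask
}

resolve_threshold <- function(values, threshold_policy, threshold_q,
                              threshold_value, threshold_k = 10) {
  switch(threshold_policy,
    quantile = stats::quantile(values, 1 - threshold_q, names = FALSE),
    otsu = otsu_threshold(values),
    # robust background model: foreground must clear the background level by
    # k robust standard deviations; stable under heavy class imbalance where
    # Otsu's criterion degenerates
    background = stats::median(values) + threshold_k * stats::mad(values),
    # Otsu restricted to candidate pixels well above background: finds the
    # amplitude valley even when foreground is a tiny fraction of pixels
    robust_otsu = {
      cand <- values[values > stats::median(values) + 6 * stats::mad(values)]
      if (length(cand) < 50L) Inf else otsu_threshold(cand)
    },
    fixed = {
      if (is.null(threshold_value)) {
        abort("threshold_policy 'fixed' requires threshold_value")
      }
      threshold_value
    },
    abort("unknown threshold_policy '%s'", threshold_policy)
  )
}

new_network_mask <- function(mask, threshold_used, threshold_policy,
                             min_component_px, cc) {
  structure(
    list(mask = mask, threshold_used = threshold_used,
         threshold_policy = threshold_policy,
         min_component_px = as.integer(min_component_px),
         n_components = length(cc$sizes),
         largest_component_px = if (length(cc$sizes)) max(cc$sizes) else 0L),
    class = "vmq_network_mask"
  )
}

#' @export
print.vmq_network_mask <- function(x, ...) {
  cat(sprintf("<vmq_network_mask> %d component(s), %d px total (largest %d), threshold %.4g [%s], min component %d px\n",
              x$n_components, sum(x$mask), x$largest_component_px,
              x$threshold_used, x$threshold_policy, x$min_component_px))
  invisible(x)
}

#' Segment the PAS network from a tubeness field
#'
#' Thresholds the in-tissue tubeness response and removes connected
#' components smaller than `min_component_px`; the policy and threshold used
#' are recorded in the output.  Policies: `"background"` (default; median +
#' `threshold_k` * MAD of the in-tissue response - robust to the heavy class
#' imbalance typical of sparse networks), `"quantile"` (keep the top
#' `threshold_q` fraction), `"otsu"`, `"robust_otsu"` (Otsu restricted to
#' pixels above the background floor) and `"fixed"`.  An empty result is a
#' valid PAS-negative outcome, not an error.
#'
#' @param field a [tubeness()] result.
#' @param tissue logical tissue mask of the same shape.
#' @param threshold_policy thresholding policy, see Description.
#' @param threshold_q top fraction of in-tissue response kept under the
#'   quantile policy.
#' @param threshold_value threshold for the fixed policy.
#' @param threshold_k background-clearance multiplier for the background
#'   policy.
#' @param min_component_px minimum component area in pixels.
#' @return object of class `vmq_network_mask`.
#' @export
segment_networks <- function(field, tissue,
                             threshold_policy = c("background", "quantile",
                                                  "otsu", "robust_otsu",
                                                  "fixed"),
                             threshold_q = 0.05, threshold_value = NULL,
                             min_component_px = 20L, threshold_k = 10) {
  stopifnot(inherits(field, "vmq_tubeness"))
  tissue <- as_binary_mask(tissue, "tissue")
  if (!identical(dim(field$response), dim(tissue))) {
    abort("tubeness field and tissue mask differ in shape")
  }
  threshold_policy <- match.arg(threshold_policy)
  vals <- field$response[tissue]
  if (length(vals) == 0L || all(vals <= 0)) {
    # no in-tissue support: valid PAS-negative image
    empty <- matrix(FALSE, nrow(tissue), ncol(tissue))
    return(new_network_mask(empty, Inf, threshold_policy, min_component_px,
                            list(sizes = integer(0))))
  }
  thr <- resolve_threshold(vals, threshold_policy, threshold_q,
                           threshold_value, threshold_k)
  mask <- field$response >= thr & tissue
  res <- remove_small_components(mask, min_component_px)
  new_network_mask(res$mask, thr, threshold_policy, min_component_px, res$cc)
}

#' Segment the CD31-positive (endothelial) network
#'
#' As [segment_networks()] but applied to the CD31 channel directly: vessels
#' are solid-stained, so no tubeness prefilter is used by default
#' (`use_tubeness = TRUE` enables one).  A light Gaussian smoothing
#' (`smooth_sigma`, default 2 px, roughly the vessel half-width) acts as a
#' matched filter so that pixel noise does not drag an automatic threshold
#' into the background intensity bulk.
#'
#' @param cd31 numeric matrix (CD31 channel).
#' @param tissue logical tissue mask.
#' @param use_tubeness apply a tubeness prefilter before thresholding?
#' @param scales_px scales for the optional prefilter.
#' @param smooth_sigma Gaussian presmoothing scale in pixels (0 = none);
#'   ignored when `use_tubeness` is set.
#' @inheritParams segment_networks
#' @return object of class `vmq_network_mask`.
#' @export
segment_cd31 <- function(cd31, tissue,
                         threshold_policy = c("robust_otsu", "background",
                                              "otsu", "quantile", "fixed"),
                         threshold_q = 0.05, threshold_value = NULL,
                         min_component_px = 20L, use_tubeness = FALSE,
                         scales_px = c(2, 3, 4, 6), smooth_sigma = 2,
                         threshold_k = 10) {
  assert_matrix_finite(cd31, "cd31")
  tissue <- as_binary_mask(tissue, "tissue")
  if (!identical(dim(cd31), dim(tissue))) {
    abort("cd31 and tissue mask differ in shape")
  }
  threshold_policy <- match.arg(threshold_policy)
  resp <- if (use_tubeness) {
    tubeness(cd31, scales_px)$response
  } else if (smooth_sigma > 0) {
    gaussian_smooth(cd31, smooth_sigma)
  } else {
    cd31
  }
  vals <- resp[tissue]
  if (length(vals) == 0L || max(vals) <= min(vals)) {
    empty <- matrix(FALSE, nrow(tissue), ncol(tissue))
    return(new_network_mask(empty, Inf, threshold_policy, min_component_px,
                            list(sizes = integer(0))))
  }
  thr <- resolve_threshold(vals, threshold_policy, threshold_q,
                           threshold_value, threshold_k)
  mask <- resp >= thr & tissue
  res <- remove_small_components(mask, min_component_px)
  new_network_mask(res$mask, thr, threshold_policy, min_component_px, res$cc)
}

#' Subtract the vessel network from the PAS network
#'
#' Removes from the PAS mask every pixel covered by the CD31 mask dilated by
#' `dilation_px` (8-connected square dilation); the dilation absorbs
#' registration offset between the two stains.
#'
#' @param pas_mask,cd31_mask logical matrices or `vmq_network_mask` objects.
#' @param dilation_px non-negative integer dilation radius.
#' @return logical matrix of PAS+CD31- pixels.
#' @export
subtract_vessels <- function(pas_mask, cd31_mask, dilation_px = 2L) {
  pas_mask <- as_binary_mask(pas_mask, "pas_mask")
  cd31_mask <- as_binary_mask(cd31_mask, "cd31_mask")
  if (!identical(dim(pas_mask), dim(cd31_mask))) {
    abort("pas_mask and cd31_mask differ in shape")
  }
  if (dilation_px < 0) abort("dilation_px must be >= 0")
  pas_mask & !binary_dilate(cd31_mask, dilation_px)
}

#' VM area score
#'
#' `100 * |vm_mask & tissue| / |tissue|`: the percentage of tissue area
#' occupied by PAS+CD31- network.
#'
#' @param vm_mask logical matrix (subtracted network).
#' @param tissue logical tissue mask with at least one pixel.
#' @return numeric scalar in `[0, 100]`.
#' @export
compute_vm_score <- function(vm_mask, tissue) {
  vm_mask <- as_binary_mask(vm_mask, "vm_mask")
  tissue <- as_binary_mask(tissue, "tissue")
  if (!identical(dim(vm_mask), dim(tissue))) {
    abort("vm_mask and tissue differ in shape")
  }
  nt <- sum(tissue)
  if (nt == 0L) abort("empty tissue mask")
  100 * sum(vm_mask & tissue) / nt
}

#' Classify the PAS network pattern of a quantified image
#'
#' Categories: `PAS-neg` when no PAS network was segmented; `PAS-low` when
#' the PAS network covers under 10% of the tissue area *or* consists only of
#' disconnected arcs (no skeleton branch point in any component); `PAS-high`
#' otherwise (extensive branching networks).
#'
#' @param q a `vmq_vm` quantification from [quantify_vm()], or a list with
#'   elements `pas_network_mask` (logical matrix) and `pas_area_fraction`.
#' @return one of `"PAS-neg"`, `"PAS-low"`, `"PAS-high"`.
#' @export
classify_pas_category <- function(q) {
  mask <- as_binary_mask(q$pas_network_mask, "pas_network_mask")
  frac <- q$pas_area_fraction
  assert_scalar_num(frac, "pas_area_fraction", min = 0, max = 1)
  if (!any(mask)) return("PAS-neg")
  if (frac < 0.10 || !has_branching_component(mask)) return("PAS-low")
  "PAS-high"
}

# Replace out-of-tissue pixels with the median in-tissue intensity so the
# tissue boundary (a large intensity step) does not itself respond as a
# ridge and inflate the in-tissue background statistics.
fill_background <- function(channel, tissue) {
  channel[!tissue] <- stats::median(channel[tissue])
  channel
}

#' Full VM quantification of one image
#'
#' Runs the complete per-image procedure: tissue detection, suppression of
#' the tissue-edge step (out-of-tissue pixels are filled with the median
#' in-tissue intensity before filtering), tubeness ridge detection on the
#' PAS channel, network segmentation, CD31 segmentation and subtraction,
#' area scoring and PAS categorization.
#'
#' @param image a [two_channel_image()].
#' @param config a [vmq_config()] (image-stage keys are used).
#' @return object of class `vmq_vm`: masks, `vm_score` (percent of tissue),
#'   `pas_area_fraction`, `category`, and the thresholds used.
#' @export
quantify_vm <- function(image, config = vmq_config()) {
  stopifnot(inherits(image, "vmq_image"))
  tissue <- detect_tissue(image)
  field <- tubeness(fill_background(image$pas, tissue), config$scales_px)
  pas_net <- segment_networks(field, tissue,
                              threshold_policy = config$threshold_policy,
                              threshold_q = config$threshold_q,
                              threshold_value = config$threshold_value,
                              threshold_k = config$threshold_k,
                              min_component_px = config$min_component_px)
  cd31_net <- segment_cd31(fill_background(image$cd31, tissue), tissue,
                           threshold_policy = config$cd31_threshold_policy,
                           threshold_q = config$threshold_q,
                           threshold_value = config$threshold_value,
                           threshold_k = config$threshold_k,
                           min_component_px = config$min_component_px)
  vm_mask <- subtract_vessels(pas_net, cd31_net, config$dilation_px)
  vm_score <- compute_vm_score(vm_mask, tissue)
  pas_area_fraction <- sum(pas_net$mask & tissue) / sum(tissue)
  out <- structure(
    list(pas_network_mask = pas_net$mask, cd31_network_mask = cd31_net$mask,
         vm_mask = vm_mask, tissue_mask = tissue, vm_score = vm_score,
         pas_area_fraction = pas_area_fraction,
         thresholds = list(pas = pas_net$threshold_used,
                           pas_policy = pas_net$threshold_policy,
                           cd31 = cd31_net$threshold_used,
                           cd31_policy = cd31_net$threshold_policy,
                           dilation_px = config$dilation_px,
                           min_component_px = config$min_component_px,
                           scales_px = config$scales_px)),
    class = "vmq_vm"
  )
  out$category <- classify_pas_category(out)
  out
}

#' @export
print.vmq_vm <- function(x, ...) {
  cat(sprintf("<vmq_vm> vm_score = %.3f%% of tissue, PAS area fraction = %.4f, category = %s\n",
              x$vm_score, x$pas_area_fraction, x$category))
  invisible(x)
}

#' Compare VM scores between two groups (unpaired t-test)
#'
#' Group means plus a two-sided unpaired Student t-test (pooled variance by
#' default, matching the conventional "unpaired t-test"; `var_equal = FALSE`
#' gives Welch).
#'
#' @param scores numeric VM scores.
#' @param groups group label per score; exactly two levels, each with at
#'   least two observations.
#' @param var_equal pool the variances?
#' @return list with per-group means, `t_statistic`, `df` and `p_value`.
#' @export
compare_vm_by_group <- function(scores, groups, var_equal = TRUE) {
  if (length(scores) != length(groups)) {
    abort("scores and groups differ in length")
  }
  if (any(!is.finite(scores))) abort("scores must be finite")
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  if (length(lev) != 2L) abort("exactly two groups required, got %d", length(lev))
  x <- scores[groups == lev[1L]]
  y <- scores[groups == lev[2L]]
  if (length(x) < 2L || length(y) < 2L) {
    abort("each group needs >= 2 observations")
  }
  n1 <- length(x); n2 <- length(y)
  m1 <- mean(x); m2 <- mean(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- se^4 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- if (se > 0) (m1 - m2) / se else 0
  p <- if (se > 0) 2 * stats::pt(-abs(tstat), df) else 1
  means <- stats::setNames(c(m1, m2), lev)
  list(groups = lev, means = means, mean_difference = m1 - m2,
       t_statistic = tstat, df = df, p_value = p)
}
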