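# Seeded generator of ground-truthed two-channel histology scenes: a bright
# branching PAS+ tubular network and a partially overlapping CD31+ vessel
# network rendered over a noisy tissue background.  Used as the validation
# substrate for the VM quantification pipeline.

#' Specification of a synthetic VM image
#'
#' The defaults describe the stated test world: a 192 px square field, a
#' branching network of 20 tube segments of Gaussian cross-section (sd 2 px)
#' - VM area of a few percent of tissue, the scale reported for patient
#' melanomas - tissue background level 200, network/vessel amplitude 600 and
#' additive Gaussian noise sd 120 (SNR 5), with 30% of the vessel network
#' co-staining the PAS network, on a tissue disc covering 70% of the field.
#'
#' @param width_px,height_px image size in pixels (`>= 64`).
#' @param n_branches number of network tube segments (0 = no network).
#' @param tube_width_px Gaussian cross-section sd of a tube, in pixels (`>= 1`).
#' @param network_intensity,vessel_intensity peak amplitude of the PAS network
#'   and CD31 vessel tubes.
#' @param background_level in-tissue background intensity on both channels.
#' @param noise_sd additive Gaussian noise sd (applied per channel).
#' @param vessel_overlap_fraction fraction of vessel segments that coincide
#'   with PAS network segments (in `[0, 1]`; 1 makes the vessel network equal
#'   the PAS network).
#' @param tissue_fraction fraction of the field covered by the tissue disc,
#'   in `(0, 1]` (values `>= 0.99` give full-field tissue).
#' @param seed integer RNG seed; the generator is a pure function of the spec.
#' @return object of class `vmq_image_spec`.
#' @export
vm_image_spec <- function(width_px = 192L, height_px = 192L, n_branches = 20L,
                          tube_width_px = 2, network_intensity = 600,
                          vessel_intensity = 600, background_level = 200,
                          noise_sd = 120, vessel_overlap_fraction = 0.3,
                          tissue_fraction = 0.7, seed = 1L) {
  assert_scalar_num(width_px, "width_px", min = 64)
  assert_scalar_num(height_px, "height_px", min = 64)
  assert_scalar_num(n_branches, "n_branches", min = 0)
  assert_scalar_num(tube_width_px, "tube_width_px", min = 1)
  assert_scalar_num(network_intensity, "network_intensity", min = 0)
  assert_scalar_num(vessel_intensity, "vessel_intensity", min = 0)
  assert_scalar_num(background_level, "background_level", min = 0)
  assert_scalar_num(noise_sd, "noise_sd", min = 0)
  assert_scalar_num(vessel_overlap_fraction, "vessel_overlap_fraction",
                    min = 0, max = 1)
  assert_scalar_num(tissue_fraction, "tissue_fraction", min = 1e-9, max = 1)
  assert_scalar_num(seed, "seed")
  structure(
    list(width_px = as.integer(width_px), height_px = as.integer(height_px),
         n_branches = as.integer(n_branches), tube_width_px = tube_width_px,
         network_intensity = network_intensity,
         vessel_intensity = vessel_intensity,
         background_level = background_level, noise_sd = noise_sd,
         vessel_overlap_fraction = vessel_overlap_fraction,
         tissue_fraction = tissue_fraction, seed = as.integer(seed)),
    class = "vmq_image_spec"
  )
}

# Tissue disc mask of the requested area fraction (clipped to the field;
# fractions >= 0.99 give the full field).
tissue_disc <- function(w, h, fraction) {
  if (fraction >= 0.99) return(matrix(TRUE, h, w))
  r <- sqrt(fraction * w * h / pi)
  cx <- (w + 1) / 2
  cy <- (h + 1) / 2
  xs <- matrix(seq_len(w), h, w, byrow = TRUE)
  ys <- matrix(seq_len(h), h, w)
  (xs - cx)^2 + (ys - cy)^2 <= r^2
}

# Random recursive branching walk inside the tissue disc.  Returns a matrix
# of segments (x0, y0, x1, y1); segment length and branch-angle jitter are
# internal configuration (test substrate, not a vascular growth model).
grow_tree <- function(n_segments, w, h, tissue) {
  if (n_segments == 0L) return(matrix(numeric(0), 0L, 4L))
  inside <- function(x, y) {
    xi <- round(x); yi <- round(y)
    xi >= 3 && xi <= w - 2 && yi >= 3 && yi <= h - 2 && tissue[yi, xi]
  }
  sample_root <- function() {
    repeat {
      x <- stats::runif(1, 4, w - 3)
      y <- stats::runif(1, 4, h - 3)
      if (inside(x, y)) return(c(x, y))
    }
  }
  n_roots <- max(1L, round(n_segments / 25))
  tips <- vector("list", n_roots)
  for (i in seq_len(n_roots)) {
    p <- sample_root()
    tips[[i]] <- c(p, stats::runif(1, 0, 2 * pi))
  }
  segs <- matrix(NA_real_, n_segments, 4L)
  k <- 0L
  while (k < n_segments && length(tips) > 0L) {
    i <- sample.int(length(tips), 1L)
    tip <- tips[[i]]
    tips[[i]] <- NULL
    len <- stats::runif(1, 12, 24)
    ang <- tip[3L] + stats::rnorm(1, 0, 0.35)
    x1 <- tip[1L] + len * cos(ang)
    y1 <- tip[2L] + len * sin(ang)
    if (!inside(x1, y1)) {
      # tip leaves the tissue: terminate it; reseed if the queue dried up
      if (length(tips) == 0L) {
        p <- sample_root()
        tips[[1L]] <- c(p, stats::runif(1, 0, 2 * pi))
      }
      next
    }
    k <- k + 1L
    segs[k, ] <- c(tip[1L], tip[2L], x1, y1)
    if (stats::runif(1) < 0.35) {
      spread <- stats::runif(1, 0.4, 0.8)
      tips[[length(tips) + 1L]] <- c(x1, y1, ang + spread)
      tips[[length(tips) + 1L]] <- c(x1, y1, ang - spread)
    } else {
      tips[[length(tips) + 1L]] <- c(x1, y1, ang)
    }
  }
  segs[seq_len(k), , drop = FALSE]
}

# Render tube segments as a unit-amplitude field with Gaussian cross-section
# of sd `w` px: centreline samples every 0.25 px are accumulated into a stamp
# raster and blurred; the normalization restores crest amplitude ~1.
render_tubes <- function(segs, width, height, w) {
  field <- matrix(0, height, width)
  if (nrow(segs) == 0L) return(field)
  step <- 0.25
  pts_x <- numeric(0); pts_y <- numeric(0)
  for (i in seq_len(nrow(segs))) {
    len <- sqrt((segs[i, 3] - segs[i, 1])^2 + (segs[i, 4] - segs[i, 2])^2)
    n <- max(2L, ceiling(len / step))
    tt <- seq(0, 1, length.out = n)
    pts_x <- c(pts_x, segs[i, 1] + tt * (segs[i, 3] - segs[i, 1]))
    pts_y <- c(pts_y, segs[i, 2] + tt * (segs[i, 4] - segs[i, 2]))
  }
  xi <- pmin(pmax(round(pts_x), 1), width)
  yi <- pmin(pmax(round(pts_y), 1), height)
  lin <- (xi - 1L) * height + yi
  stamp <- matrix(tabulate(lin, nbins = width * height), height, width)
  blurred <- gaussian_smooth(stamp, w)
  blurred * step * sqrt(2 * pi) * w
}

#' Generate a ground-truthed synthetic VM image
#'
#' Renders a branching PAS+ network and a vessel (CD31+) network, a fraction
#' of whose segments coincide with network segments, over a noisy tissue
#' background.  Ground-truth masks (pixels within the rendered tube at or
#' above half peak amplitude) and the true VM area fraction
#' `|network & !vessel & tissue| / |tissue|` are returned alongside the
#' image.  Identical specs (including seed) give bit-identical output.
#'
#' @param spec a [vm_image_spec()].
#' @return object of class `vmq_ground_truth`: `image` (a `vmq_image` without
#'   attached tissue mask), `true_network_mask`, `true_vessel_mask`,
#'   `true_tissue_mask`, `true_vm_area_fraction`.
#' @export
generate_vm_image <- function(spec) {
  stopifnot(inherits(spec, "vmq_image_spec"))
  w <- spec$width_px; h <- spec$height_px
  tissue <- tissue_disc(w, h, spec$tissue_fraction)
  if (!any(tissue)) abort("degenerate spec: zero tissue")
  with_seed(spec$seed, {
    net_segs <- grow_tree(spec$n_branches, w, h, tissue)
    n_vessel <- max(2L, round(spec$n_branches / 2))
    vessel_own <- grow_tree(n_vessel, w, h, tissue)
    vof <- spec$vessel_overlap_fraction
    if (vof >= 1 && nrow(net_segs) > 0L) {
      # full co-staining: the vessel network covers every network pixel
      vessel_segs <- net_segs
    } else {
      k <- min(round(vof * n_vessel), nrow(net_segs))
      shared <- if (k > 0L) {
        net_segs[sample.int(nrow(net_segs), k), , drop = FALSE]
      } else {
        matrix(numeric(0), 0L, 4L)
      }
      own <- vessel_own[seq_len(max(0L, n_vessel - k)), , drop = FALSE]
      vessel_segs <- rbind(shared, own)
    }
    net_render <- render_tubes(net_segs, w, h, spec$tube_width_px)
    ves_render <- render_tubes(vessel_segs, w, h, spec$tube_width_px)
    net_mask <- net_render >= 0.5 & tissue
    ves_mask <- ves_render >= 0.5 & tissue
    pas <- spec$background_level * tissue +
      spec$network_intensity * net_render * tissue +
      stats::rnorm(w * h, 0, spec$noise_sd)
    cd31 <- spec$background_level * tissue +
      spec$vessel_intensity * ves_render * tissue +
      stats::rnorm(w * h, 0, spec$noise_sd)
    pas <- matrix(pmax(pas, 0), h, w)
    cd31 <- matrix(pmax(cd31, 0), h, w)
    frac <- sum(net_mask & !ves_mask & tissue) / sum(tissue)
    structure(
      list(image = two_channel_image(pas, cd31),
           true_network_mask = net_mask, true_vessel_mask = ves_mask,
           true_tissue_mask = tissue, true_vm_area_fraction = frac,
           spec = spec),
      class = "vmq_ground_truth"
    )
  })
}

#' @export
print.vmq_ground_truth <- function(x, ...) {
  cat(sprintf("<vmq_ground_truth> %d x %d px, true VM area fraction %.4f (seed %d)\n",
              x$spec$height_px, x$spec$width_px, x$true_vm_area_fraction,
              x$spec$seed))
  invisible(x)
}
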