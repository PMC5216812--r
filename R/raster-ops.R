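# Low-level raster primitives: separable Gaussian (derivative) filtering with
# reflective boundaries, binary morphology on the 8-neighbourhood, connected
# components, Otsu thresholding and Zhang-Suen skeletonization.  Rasters are
# numeric matrices, row-major viewing: rows = y (top-left origin), cols = x.

# 1-D convolution of every column of `x` with kernel `k` (odd length),
# symmetric (reflective) boundary handling.
conv_cols <- function(x, k) {
  h <- (length(k) - 1L) %/% 2L
  if (h == 0L) return(x * k)
  n <- nrow(x)
  if (h > n - 1L) abort("kernel half-width %d exceeds image extent %d", h, n)
  xp <- rbind(x[h:1, , drop = FALSE], x, x[n:(n - h + 1L), , drop = FALSE])
  y <- stats::filter(xp, k, method = "convolution", sides = 2)
  y <- as.matrix(y)[(h + 1L):(h + n), , drop = FALSE]
  dimnames(y) <- NULL
  y
}

# Separable convolution: `krow` along rows (i.e. down columns, the y axis),
# `kcol` along columns (the x axis).
conv_sep <- function(x, krow, kcol) {
  y <- conv_cols(x, krow)
  t(conv_cols(t(y), kcol))
}

# Sampled Gaussian kernel and its first/second derivatives at scale `sigma`
# (pixels).  order 0 is normalized to unit sum.  Derivative kernels are the
# *discrete central differences* of the sampled kernel, so that by
# associativity of convolution the derivative of an image equals the central
# finite difference of its Gaussian-smoothed version exactly (away from the
# boundary) - the contract the tubeness oracle checks.  The price is the
# usual O(1/sigma^2) discretization bias relative to continuum derivatives.
gaussian_kernel <- function(sigma, order = 0L) {
  stopifnot(sigma > 0)
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  t <- seq.int(-r, r)
  g <- exp(-t^2 / (2 * sigma^2))
  g <- g / sum(g)
  if (order == 0L) return(g)
  gp <- c(0, 0, g, 0, 0) # guard zeros; support grows to 2r+3
  n <- length(gp)
  switch(as.character(order),
    "1" = (gp[3:n] - gp[1:(n - 2)]) / 2,
    "2" = gp[3:n] - 2 * gp[2:(n - 1)] + gp[1:(n - 2)],
    abort("unsupported derivative order %s", order)
  )
}

gaussian_smooth <- function(x, sigma) {
  g <- gaussian_kernel(sigma, 0L)
  conv_sep(x, g, g)
}

# Shift a matrix by (dr, dc), filling vacated cells with `fill`.
mshift <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr); cs <- seq_len(nc)
  r_src <- rs - dr; c_src <- cs - dc
  rok <- r_src >= 1L & r_src <= nr
  cok <- c_src >= 1L & c_src <= nc
  out[rs[rok], cs[cok]] <- m[r_src[rok], c_src[cok], drop = FALSE]
  out
}

NEIGH8 <- cbind(
  dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
  dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
)

# One binary dilation step with the 3x3 (8-connected) structuring element.
dilate3 <- function(mask) {
  out <- mask
  for (i in seq_len(nrow(NEIGH8))) {
    out <- out | mshift(mask, NEIGH8[i, 1L], NEIGH8[i, 2L], FALSE)
  }
  out
}

binary_dilate <- function(mask, radius) {
  mask <- as_binary_mask(mask)
  if (radius < 0) abort("dilation radius must be >= 0")
  radius <- as.integer(radius)
  for (i in seq_len(radius)) mask <- dilate3(mask)
  mask
}

binary_erode <- function(mask, radius) {
  !binary_dilate(!as_binary_mask(mask), radius)
}

binary_close <- function(mask, radius) {
  binary_erode(binary_dilate(mask, radius), radius)
}

# Fill holes: background components not reachable from the image border
# become foreground.  Geodesic propagation of a border seed over background.
fill_holes <- function(mask) {
  mask <- as_binary_mask(mask)
  bg <- !mask
  reach <- matrix(FALSE, nrow(mask), ncol(mask))
  reach[1L, ] <- bg[1L, ]; reach[nrow(mask), ] <- bg[nrow(mask), ]
  reach[, 1L] <- bg[, 1L]; reach[, ncol(mask)] <- bg[, ncol(mask)]
  repeat {
    grown <- dilate3(reach) & bg
    if (sum(grown) == sum(reach)) break
    reach <- grown
  }
  mask | (bg & !reach)
}

# 8-connected component labelling.  Returns an integer matrix (0 =
# background) plus component pixel counts, ordered by label.
label_components <- function(mask) {
  mask <- as_binary_mask(mask)
  idx <- which(mask)
  labels <- matrix(0L, nrow(mask), ncol(mask))
  if (length(idx) == 0L) {
    return(list(labels = labels, sizes = integer(0)))
  }
  node <- integer(length(mask))
  node[idx] <- seq_along(idx)
  nr <- nrow(mask)
  nc <- ncol(mask)
  edges <- list()
  # forward shifts only; each undirected adjacency counted once
  shifts <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))
  for (s in shifts) {
    nb <- mshift(mask, s[1L], s[2L], FALSE) # TRUE where the (-s) neighbour is fg
    both <- which(mask & nb)
    if (length(both)) {
      src <- both - s[1L] - s[2L] * nr
      edges[[length(edges) + 1L]] <- cbind(node[src], node[both])
    }
  }
  if (length(edges)) {
    el <- do.call(rbind, edges)
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  } else {
    g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  }
  comp <- igraph::components(g)
  labels[idx] <- comp$membership
  list(labels = labels, sizes = as.integer(comp$csize))
}

# Drop connected components smaller than min_px pixels.
remove_small_components <- function(mask, min_px) {
  cc <- label_components(mask)
  if (length(cc$sizes) == 0L || min_px <= 1L) {
    return(list(mask = as_binary_mask(mask), cc = cc))
  }
  keep <- which(cc$sizes >= min_px)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  out[cc$labels %in% keep] <- TRUE
  list(mask = out, cc = label_components(out))
}

# Otsu's threshold on a numeric vector (histogram with `nbins` bins).
# Returns a value t such that `x >= t` is the bright class.
otsu_threshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) abort("otsu: no finite values")
  lo <- min(x); hi <- max(x)
  if (hi <= lo) return(lo)
  br <- seq(lo, hi, length.out = nbins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins)
  w <- cumsum(h)
  mids <- (br[-1L] + br[-(nbins + 1L)]) / 2
  m <- cumsum(h * mids)
  n <- w[nbins]; mt <- m[nbins]
  w1 <- w[-nbins]; m1 <- m[-nbins]
  w2 <- n - w1
  valid <- w1 > 0 & w2 > 0
  between <- rep(-Inf, nbins - 1L)
  between[valid] <- (mt * w1[valid] - n * m1[valid])^2 /
    (w1[valid] * w2[valid])
  k <- which.max(between)
  br[k + 1L]
}

# Zhang-Suen thinning to an 8-connected, one-pixel-wide skeleton.
skeletonize <- function(mask) {
  p <- as_binary_mask(mask)
  nbrs <- function(m) {
    list(
      p2 = mshift(m, -1L, 0L, FALSE), p3 = mshift(m, -1L, 1L, FALSE),
      p4 = mshift(m, 0L, 1L, FALSE),  p5 = mshift(m, 1L, 1L, FALSE),
      p6 = mshift(m, 1L, 0L, FALSE),  p7 = mshift(m, 1L, -1L, FALSE),
      p8 = mshift(m, 0L, -1L, FALSE), p9 = mshift(m, -1L, -1L, FALSE)
    )
  }
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      nb <- nbrs(p)
      b <- Reduce(`+`, nb)
      ring <- with(nb, cbind(
        as.vector(p2), as.vector(p3), as.vector(p4), as.vector(p5),
        as.vector(p6), as.vector(p7), as.vector(p8), as.vector(p9),
        as.vector(p2)
      ))
      a <- matrix(rowSums(ring[, 1:8, drop = FALSE] == 0 &
                            ring[, 2:9, drop = FALSE] == 1), nrow(p), ncol(p))
      if (step == 1L) {
        cond <- with(nb, !(p2 & p4 & p6) & !(p4 & p6 & p8))
      } else {
        cond <- with(nb, !(p2 & p4 & p8) & !(p2 & p6 & p8))
      }
      del <- p & b >= 2 & b <= 6 & a == 1 & cond
      if (any(del)) {
        p <- p & !del
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  p
}

# Remove `n` layers of skeleton end-points (spur pruning).
prune_skeleton <- function(skel, n = 2L) {
  for (i in seq_len(n)) {
    deg <- neighbor_count(skel)
    ends <- skel & deg <= 1L
    if (!any(ends)) break
    skel <- skel & !ends
  }
  skel
}

neighbor_count <- function(mask) {
  mask <- as_binary_mask(mask)
  cnt <- matrix(0L, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(NEIGH8))) {
    cnt <- cnt + mshift(mask, NEIGH8[i, 1L], NEIGH8[i, 2L], FALSE)
  }
  cnt
}

# TRUE if any connected component of `mask` branches: its pruned skeleton
# contains a pixel with 3+ skeleton neighbours.  Components that are simple
# open arcs (every pixel has <= 2 neighbours) do not count.
has_branching_component <- function(mask) {
  mask <- as_binary_mask(mask)
  if (!any(mask)) return(FALSE)
  skel <- prune_skeleton(skeletonize(mask), 2L)
  if (!any(skel)) return(FALSE)
  any(skel & neighbor_count(skel) >= 3L)
}
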