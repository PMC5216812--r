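# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# any pre-existing global .Random.seed afterwards.  All generators route
# their randomness through this so that no caller-visible RNG state leaks.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# stop() without the call, with sprintf-style formatting
abort <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

assert_scalar_num <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort("`%s` must be a single finite number", name)
  }
  if (x < min || x > max) {
    abort("`%s` = %g out of range [%g, %g]", name, x, min, max)
  }
  invisible(x)
}

assert_matrix_finite <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort("`%s` must be a numeric matrix", name)
  }
  if (any(!is.finite(x))) {
    abort("`%s` contains non-finite values", name)
  }
  invisible(x)
}

as_binary_mask <- function(x, name = "mask") {
  if (inherits(x, "vmq_network_mask")) x <- x$mask
  if (is.matrix(x) && is.numeric(x)) x <- x > 0
  if (!is.matrix(x) || !is.logical(x)) {
    abort("`%s` must be a logical matrix (or a vmq_network_mask)", name)
  }
  x
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
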