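# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
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
  })
  set.seed(as.integer(seed))
  force(code)
}

abort_if <- function(cond, ...) {
  if (isTRUE(cond)) stop(..., call. = FALSE)
  invisible(NULL)
}

# Arc length of a closed polygon given an n x 2 vertex matrix.
closed_polygon_length <- function(pts) {
  stopifnot(is.matrix(pts), ncol(pts) == 2, nrow(pts) >= 2)
  d <- diff(rbind(pts, pts[1, , drop = FALSE]))
  sum(sqrt(rowSums(d^2)))
}

# Circular moving average of the rows of an n x 2 matrix (periodic contour).
smooth_closed_contour <- function(pts, window) {
  stopifnot(window >= 1)
  if (window == 1 || nrow(pts) <= window) return(pts)
  k <- rep(1 / window, window)
  apply(pts, 2, function(v) {
    as.numeric(stats::filter(v, k, method = "convolution",
                             sides = 2, circular = TRUE))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
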