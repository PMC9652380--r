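# Shared internal helpers: seed derivation, input checks, distance utilities.

#' Derive a child seed from a master seed
#'
#' Every stochastic operation in the package draws its own seed
#' deterministically from a single master seed so that a whole pipeline run
#' is reproducible from one integer. Seeds stay below `.Machine$integer.max`.
#'
#' @param master Integer master seed.
#' @param offset Non-negative integer offset distinguishing consumers.
#' @return An integer seed.
#' @export
derive_seed <- function(master, offset = 0L) {
  master <- as.double(master)
  offset <- as.double(offset)
  as.integer((master * 48271 + offset * 10007 + 12345) %% 2147483647)
}

with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

stop_if_not <- function(cond, msg, call. = FALSE) {
  if (!isTRUE(cond)) stop(msg, call. = call.)
}

# Pairwise Euclidean distance matrix (dense); wraps stats::dist once so the
# conversion cost is paid in one place.
dense_dist <- function(x) {
  as.matrix(dist(as.matrix(x)))
}

# Indices (columns) of the k nearest neighbours per row, self excluded,
# plus the matching distances. Ties broken by index order for determinism.
knn_from_dist <- function(dm, k) {
  n <- nrow(dm)
  stop_if_not(k < n, "k must be smaller than the number of rows")
  idx <- matrix(0L, n, k)
  d <- matrix(0, n, k)
  for (i in seq_len(n)) {
    ord <- order(dm[i, ], seq_len(n))
    ord <- ord[ord != i][seq_len(k)]
    idx[i, ] <- ord
    d[i, ] <- dm[i, ord]
  }
  list(idx = idx, dist = d)
}

# Min-max scaling to [0, 1]; a constant vector maps to 0.5 (uninformative).
minmax_scale <- function(x) {
  r <- range(x, na.rm = TRUE)
  if (!is.finite(r[1]) || r[2] - r[1] < .Machine$double.eps) {
    return(rep(0.5, length(x)))
  }
  (x - r[1]) / (r[2] - r[1])
}
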