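# Clustering-tendency testing: Hopkins statistic and its shuffle null.

#' Hopkins clustering-tendency statistic
#'
#' Samples `n_sample` real points and the same number of uniform points in
#' the data's bounding box, and compares nearest-neighbour distances:
#' \deqn{H = \frac{\sum_i u_i}{\sum_i u_i + \sum_i w_i}}
#' where \eqn{u_i} is the distance of a uniform point to its nearest real
#' point and \eqn{w_i} the distance of a sampled real point to its nearest
#' other real point. Under this convention spatially random data gives
#' H close to 0.5 and clustered data approaches 1.
#'
#' @param x Numeric matrix (>= 10 rows).
#' @param sample_frac Fraction of rows to sample (default 0.1; at least 5
#'   points are always used).
#' @param seed Integer seed.
#' @return List with `H`, `n_sampled` and `seed` (class `hopkins_result`).
#' @export
hopkins <- function(x, sample_frac = 0.1, seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  stop_if_not(n >= 10, "need at least 10 rows")
  if (all(apply(x, 2, function(v) diff(range(v)) == 0))) {
    stop("all rows identical: Hopkins statistic undefined", call. = FALSE)
  }
  m <- max(5L, round(sample_frac * n))
  stop_if_not(m < n, "sample size must be smaller than n")
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  res <- with_seed(seed, {
    sel <- sample(n, m)
    u_pts <- matrix(runif(m * ncol(x), rep(lo, each = m), rep(hi, each = m)),
                    nrow = m)
    w <- vapply(sel, function(i) {
      d2 <- colSums((t(x[-i, , drop = FALSE]) - x[i, ])^2)
      sqrt(min(d2))
    }, numeric(1))
    u <- vapply(seq_len(m), function(i) {
      d2 <- colSums((t(x) - u_pts[i, ])^2)
      sqrt(min(d2))
    }, numeric(1))
    sum(u) / (sum(u) + sum(w))
  })
  structure(list(H = res, n_sampled = m, seed = as.integer(seed)),
            class = "hopkins_result")
}

#' Shuffle null for the Hopkins statistic
#'
#' Permutes all cell values of the matrix (destroying row structure while
#' preserving the value multiset) and recomputes the Hopkins statistic per
#' shuffle, summarizing the resulting null distribution.
#'
#' @param x Numeric matrix.
#' @param n_shuffles Number of shuffles (>= 2; default 20).
#' @param sample_frac Passed to [hopkins()].
#' @param seed Integer seed; shuffle `i` uses a seed derived from it.
#' @return List with `mean`, `se`, and the per-shuffle `values`.
#' @export
shuffle_null <- function(x, n_shuffles = 20, sample_frac = 0.1, seed = 1L) {
  stop_if_not(n_shuffles >= 2, "n_shuffles must be >= 2")
  x <- as.matrix(x)
  values <- vapply(seq_len(n_shuffles), function(i) {
    xs <- with_seed(derive_seed(seed, i), {
      matrix(sample(as.vector(x)), nrow = nrow(x))
    })
    hopkins(xs, sample_frac = sample_frac,
            seed = derive_seed(seed, n_shuffles + i))$H
  }, numeric(1))
  list(mean = mean(values), se = sd(values) / sqrt(n_shuffles),
       values = values)
}
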