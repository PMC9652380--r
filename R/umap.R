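# Seeded 2-D neighborhood-preserving embeddings and their ensemble. The
# embedder follows the uniform-manifold family: a fuzzy k-nearest-neighbour
# graph with smooth locally-adaptive bandwidths, symmetrized by fuzzy union,
# optimized into 2-D by stochastic gradient descent with negative sampling.
# The construction of the graph is deterministic; only the layout stage is
# stochastic, and it is fully reproducible from an integer seed.

# Locally adaptive connectivity radii (rho) and bandwidths (sigma) solving
# sum_j exp(-(d_ij - rho_i)/sigma_i) = log2(k) by bisection.
smooth_knn <- function(knn_dist, local_connectivity = 0.7, n_iter = 64,
                       tol = 1e-5) {
  k <- ncol(knn_dist)
  target <- log2(k)
  n <- nrow(knn_dist)
  rho <- numeric(n)
  sigma <- numeric(n)
  for (i in seq_len(n)) {
    d <- knn_dist[i, ]
    nz <- d[d > 0]
    if (length(nz) > 0) {
      lc_int <- floor(local_connectivity)
      lc_frac <- local_connectivity - lc_int
      if (lc_int >= length(nz)) {
        rho[i] <- max(nz)
      } else if (lc_int > 0) {
        rho[i] <- nz[lc_int] + lc_frac * (nz[lc_int + 1] - nz[lc_int])
      } else {
        rho[i] <- lc_frac * nz[1]
      }
    }
    lo <- 0
    hi <- Inf
    mid <- 1
    for (it in seq_len(n_iter)) {
      val <- sum(exp(-pmax(d - rho[i], 0) / mid))
      if (abs(val - target) < tol) break
      if (val > target) {
        hi <- mid
        mid <- (lo + hi) / 2
      } else {
        lo <- mid
        mid <- if (is.finite(hi)) (lo + hi) / 2 else mid * 2
      }
    }
    sigma[i] <- max(mid, 1e-10)
  }
  list(rho = rho, sigma = sigma)
}

# Curve parameters (a, b) of 1/(1 + a d^(2b)) fitted by least squares to the
# piecewise target: 1 for d <= min_dist, exp(-(d - min_dist)/spread) beyond.
ab_params <- function(min_dist, spread = 1) {
  d <- seq(0, spread * 3, length.out = 300)
  target <- ifelse(d <= min_dist, 1, exp(-(d - min_dist) / spread))
  obj <- function(p) {
    a <- exp(p[1]); b <- exp(p[2])
    sum((1 / (1 + a * d^(2 * b)) - target)^2)
  }
  opt <- optim(c(log(1.6), log(0.9)), obj, method = "Nelder-Mead")
  c(a = exp(opt$par[1]), b = exp(opt$par[2]))
}

# Symmetrized fuzzy graph as an edge list (0-based endpoints) with
# epochs-per-sample weights, built once per input matrix and shared by all
# ensemble replicates.
fuzzy_graph <- function(dm, n_neighbors, local_connectivity, n_epochs) {
  n <- nrow(dm)
  nn <- knn_from_dist(dm, n_neighbors)
  sk <- smooth_knn(nn$dist, local_connectivity = local_connectivity)
  w <- exp(-pmax(nn$dist - sk$rho, 0) / sk$sigma)
  A <- Matrix::sparseMatrix(
    i = rep(seq_len(n), n_neighbors),
    j = as.vector(nn$idx),
    x = as.vector(w),
    dims = c(n, n)
  )
  G <- A + Matrix::t(A) - A * Matrix::t(A)   # fuzzy set union
  tr <- Matrix::summary(Matrix::triu(G, k = 1))
  keep <- tr$x >= max(tr$x) / n_epochs
  tr <- tr[keep, , drop = FALSE]
  list(head = tr$i - 1L, tail = tr$j - 1L,
       epochs_per_sample = max(tr$x) / tr$x)
}

# Deterministic initial coordinates: top-2 principal components rescaled to
# [-10, 10], plus a small seeded jitter that differentiates replicates.
init_coords <- function(x, seed, jitter_sd = 0.1) {
  pc <- prcomp(x, center = TRUE, scale. = FALSE)$x
  if (ncol(pc) < 2) pc <- cbind(pc, 0)
  co <- pc[, 1:2, drop = FALSE]
  co <- co / max(abs(co), 1e-12) * 10
  with_seed(seed, co + matrix(rnorm(length(co), 0, jitter_sd), nrow(co), 2))
}

#' Default minimum-distance parameter
#'
#' The embedding's minimum spread is tied to the number of observations:
#' `min_dist = 1 / sqrt(n)`.
#'
#' @param n Number of rows to be embedded.
#' @return Numeric scalar.
#' @export
default_min_dist <- function(n) 1 / sqrt(n)

#' Single seeded 2-D embedding
#'
#' @param x Numeric matrix (observations x features).
#' @param n_neighbors Neighbourhood size (default 5).
#' @param min_dist Minimum spread; defaults to [default_min_dist()].
#' @param local_connectivity Fraction of the first-neighbour distance
#'   guaranteed to be locally connected (default 0.7).
#' @param n_epochs SGD epochs (default 200).
#' @param seed Integer seed controlling the stochastic layout.
#' @param graph Optional precomputed fuzzy graph (internal reuse).
#' @param dm Optional precomputed dense distance matrix.
#' @return n x 2 coordinate matrix.
#' @export
umap_embed <- function(x, n_neighbors = 5, min_dist = NULL,
                       local_connectivity = 0.7, n_epochs = 200, seed = 1L,
                       graph = NULL, dm = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  stop_if_not(n >= n_neighbors + 1, "need at least n_neighbors + 1 rows")
  if (is.null(min_dist)) min_dist <- default_min_dist(n)
  if (is.null(graph)) {
    if (is.null(dm)) dm <- dense_dist(x)
    graph <- fuzzy_graph(dm, n_neighbors, local_connectivity, n_epochs)
  }
  ab <- ab_params(min_dist)
  init <- init_coords(x, seed)
  emb <- .umap_optimize_layout(init, graph$head, graph$tail,
                               graph$epochs_per_sample,
                               a = ab[["a"]], b = ab[["b"]], gamma = 1,
                               initial_alpha = 1,
                               negative_sample_rate = 5L,
                               n_epochs = as.integer(n_epochs),
                               seed = as.double(seed))
  colnames(emb) <- c("dim1", "dim2")
  emb
}

#' Ensemble of seeded 2-D embeddings
#'
#' Fits `n_models` independent 2-D embeddings of the same input, each with
#' its own seed, and stacks their coordinates horizontally into an
#' observations x (2 * n_models) feature matrix for density-based scanning.
#' The fuzzy graph is built once and shared; replicates differ only in
#' their stochastic layout.
#'
#' @param x Numeric matrix.
#' @param n_models Number of replicate embeddings; the scanned grid is
#'   normally 5, 10 or 20 (a different value triggers a warning only).
#' @param n_neighbors,min_dist,local_connectivity,n_epochs Passed to
#'   [umap_embed()].
#' @param seeds Integer vector of length `n_models`; defaults to
#'   `master_seed + 0:(n_models - 1)` (consecutive seeds from one master).
#' @param master_seed Master seed used when `seeds` is `NULL`.
#' @return An `ensemble_embedding`: list with `features` (the stacked
#'   matrix), `models` (list of n x 2 matrices), `seeds`, `n_neighbors`,
#'   `min_dist`.
#' @export
umap_ensemble <- function(x, n_models = 5, n_neighbors = 5, min_dist = NULL,
                          local_connectivity = 0.7, n_epochs = 200,
                          seeds = NULL, master_seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (!n_models %in% c(5, 10, 20)) {
    warning("n_models outside the usual grid {5, 10, 20}")
  }
  if (is.null(seeds)) seeds <- as.integer(master_seed) + seq_len(n_models) - 1L
  stop_if_not(length(seeds) == n_models, "need one seed per model")
  if (is.null(min_dist)) min_dist <- default_min_dist(n)

  dm <- dense_dist(x)
  graph <- fuzzy_graph(dm, n_neighbors, local_connectivity, n_epochs)
  models <- lapply(seeds, function(s) {
    umap_embed(x, n_neighbors = n_neighbors, min_dist = min_dist,
               local_connectivity = local_connectivity, n_epochs = n_epochs,
               seed = s, graph = graph, dm = dm)
  })
  features <- do.call(cbind, models)
  colnames(features) <- paste0("m", rep(seq_len(n_models), each = 2),
                               "_d", rep(1:2, n_models))
  stopifnot(all(is.finite(features)))
  structure(list(features = features, models = models,
                 seeds = as.integer(seeds), n_models = n_models,
                 n_neighbors = n_neighbors, min_dist = min_dist),
            class = "ensemble_embedding")
}

#' Trustworthiness of an embedding
#'
#' Rank-based measure penalizing points that are k-neighbours in the
#' embedding but not in the original space; in `[0, 1]`, 1 = perfect.
#'
#' @param x Original data matrix.
#' @param y Embedding (same row count).
#' @param k Neighbourhood size.
#' @return Numeric scalar.
#' @export
trustworthiness <- function(x, y, k = 5) {
  tc_measure(dense_dist(x), dense_dist(y), k)
}

#' Continuity of an embedding
#'
#' The converse of [trustworthiness()]: penalizes original-space
#' k-neighbours that are lost in the embedding.
#'
#' @inheritParams trustworthiness
#' @return Numeric scalar.
#' @export
continuity <- function(x, y, k = 5) {
  tc_measure(dense_dist(y), dense_dist(x), k)
}

# Shared rank penalty: for neighbours under dm_b missing from the k-NN under
# dm_a... specifically penalizes points in the k-NN of dm_a but ranked > k
# under dm_b (so tc_measure(dx, dy, k) with dm_a = embedding gives
# trustworthiness).
tc_measure <- function(dm_true, dm_emb, k) {
  n <- nrow(dm_true)
  stop_if_not(k < n, "k must be smaller than n")
  penalty <- 0
  for (i in seq_len(n)) {
    rank_true <- rank(dm_true[i, -i], ties.method = "first")
    emb_ord <- order(dm_emb[i, -i])[seq_len(k)]
    r <- rank_true[emb_ord]
    penalty <- penalty + sum(pmax(r - k, 0))
  }
  1 - 2 / (n * k * (2 * n - 3 * k - 1)) * penalty
}

#' Ensemble embedding diagnostics
#'
#' Summarizes an embedding ensemble by (i) per-dimension replicate
#' stability: the mean over model pairs of the absolute Pearson correlation
#' after testing both dimension pairings and both sign flips and keeping the
#' best alignment; (ii) mean trustworthiness and continuity of the
#' individual models against the input; and (iii) structure retention, their
#' product. All values lie in `[0, 1]`; retention near 1 indicates the
#' reduction preserved the original neighbourhood structure.
#'
#' @param x Input matrix the ensemble was fitted to.
#' @param ens An `ensemble_embedding`.
#' @param k Neighbourhood size for trustworthiness/continuity (default 5).
#' @return List with `stability` (per embedding dimension),
#'   `trustworthiness`, `continuity`, `retention` (class
#'   `embedding_diagnostics`).
#' @export
embedding_diagnostics <- function(x, ens, k = 5) {
  models <- ens$models
  m <- length(models)
  stab <- c(dim1 = NA_real_, dim2 = NA_real_)
  if (m >= 2) {
    acc <- matrix(0, 0, 2)
    for (a in seq_len(m - 1)) {
      for (b in seq((a + 1), m)) {
        ya <- models[[a]]
        yb <- models[[b]]
        same <- c(align_cor(ya[, 1], yb[, 1]), align_cor(ya[, 2], yb[, 2]))
        swap <- c(align_cor(ya[, 1], yb[, 2]), align_cor(ya[, 2], yb[, 1]))
        acc <- rbind(acc, if (mean(swap, na.rm = TRUE) >
                              mean(same, na.rm = TRUE)) swap else same)
      }
    }
    stab <- c(dim1 = mean(acc[, 1], na.rm = TRUE),
              dim2 = mean(acc[, 2], na.rm = TRUE))
  }
  dm_x <- dense_dist(x)
  tc <- vapply(models, function(y) {
    dm_y <- dense_dist(y)
    c(t = tc_measure(dm_x, dm_y, k), c = tc_measure(dm_y, dm_x, k))
  }, numeric(2))
  tt <- mean(tc["t", ])
  cc <- mean(tc["c", ])
  structure(list(stability = stab, trustworthiness = tt, continuity = cc,
                 retention = tt * cc, k = k),
            class = "embedding_diagnostics")
}

# |Pearson r| between two coordinate vectors; NA when either is constant.
align_cor <- function(u, v) {
  if (sd(u) == 0 || sd(v) == 0) return(NA_real_)
  abs(cor(u, v))
}
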