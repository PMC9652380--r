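# Density-based scanning of the embedding ensemble: radius estimation from
# the k-nearest-neighbour distance curve, the density clustering itself, the
# epsilon sweep, and silhouette-guided model selection.

#' Density-based clustering (DBSCAN)
#'
#' Classic density clustering: points with at least `min_pts` neighbours
#' (self included) within radius `eps` are core points; clusters grow by
#' expanding density-reachable neighbourhoods; unreached points are noise
#' (label `-1`). Border points join the first cluster that reaches them,
#' with expansion order fixed by row order for determinism.
#'
#' @param features Numeric matrix, or `NULL` when `dm` is supplied.
#' @param eps Neighbourhood radius (> 0), in the feature space's units.
#' @param min_pts Minimum neighbourhood size for a core point (default 5).
#' @param dm Optional precomputed dense distance matrix.
#' @return A `dbscan_model`: list with `eps`, `min_pts`, `labels` (`-1` =
#'   noise), `n_clusters`, `n_noise`, `silhouette` (summaries over non-noise
#'   points; `NA` when fewer than 2 clusters), and `rejected` (median
#'   silhouette < 0).
#' @export
dbscan_fit <- function(features = NULL, eps, min_pts = 5, dm = NULL) {
  stop_if_not(eps > 0, "eps must be positive")
  if (is.null(dm)) dm <- dense_dist(features)
  n <- nrow(dm)
  adj <- lapply(seq_len(n), function(i) which(dm[i, ] <= eps))
  core <- vapply(adj, length, integer(1)) >= min_pts
  labels <- rep(-1L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != -1L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- i
    pos <- 1L
    while (pos <= length(queue)) {
      p <- queue[pos]
      pos <- pos + 1L
      nb <- adj[[p]]
      newpts <- nb[labels[nb] == -1L]
      labels[newpts] <- cl
      queue <- c(queue, newpts[core[newpts]])
    }
  }
  model <- list(eps = eps, min_pts = min_pts, labels = labels,
                n_clusters = cl, n_noise = sum(labels == -1L))
  keep <- labels != -1L
  if (cl >= 2 && sum(keep) >= 3) {
    model$silhouette <- silhouette_summary(dm[keep, keep, drop = FALSE],
                                           labels[keep])
  } else {
    model$silhouette <- c(median = NA_real_, mean = NA_real_,
                          p75 = NA_real_, max = NA_real_)
  }
  model$rejected <- isTRUE(model$silhouette[["median"]] < 0)
  class(model) <- "dbscan_model"
  model
}

#' @export
print.dbscan_model <- function(x, ...) {
  cat(sprintf("DBSCAN model: eps = %.4g, minPts = %d, %d cluster(s), %d noise point(s)\n",
              x$eps, x$min_pts, x$n_clusters, x$n_noise))
  if (is.finite(x$silhouette[["median"]])) {
    cat(sprintf("  silhouette median %.3f, p75 %.3f, max %.3f%s\n",
                x$silhouette[["median"]], x$silhouette[["p75"]],
                x$silhouette[["max"]],
                if (x$rejected) " [rejected]" else ""))
  }
  invisible(x)
}

#' Estimate the scan radius from the k-NN distance elbow
#'
#' Sorts the distances to each point's k-th nearest neighbour in ascending
#' order and locates the elbow automatically as the point of maximum
#' perpendicular distance from the chord joining the curve's endpoints. The
#' full curve and chosen index are returned for audit.
#'
#' @param features Numeric matrix, or `NULL` with `dm` supplied.
#' @param k Neighbour rank to use (default 5, matching `min_pts`).
#' @param dm Optional precomputed distance matrix.
#' @return List with `eps`, `curve` (sorted k-NN distances) and `index`.
#' @export
knn_elbow_eps <- function(features = NULL, k = 5, dm = NULL) {
  if (is.null(dm)) dm <- dense_dist(features)
  n <- nrow(dm)
  stop_if_not(k < n, "k must be smaller than n")
  kdist <- vapply(seq_len(n), function(i) {
    sort(dm[i, -i], partial = k)[k]
  }, numeric(1))
  curve <- sort(kdist)
  if (diff(range(curve)) < .Machine$double.eps) {
    warning("all k-NN distances equal; eps set to that distance")
    return(list(eps = curve[1], curve = curve, index = n))
  }
  # Maximum perpendicular distance from the chord between the endpoints.
  t <- seq_len(n)
  chord <- c(n - 1, curve[n] - curve[1])
  chord <- chord / sqrt(sum(chord^2))
  relx <- t - 1
  rely <- curve - curve[1]
  perp <- abs(relx * chord[2] - rely * chord[1])
  idx <- which.max(perp)
  if (idx %in% c(1L, n)) {
    warning("elbow detected at an endpoint of the k-NN distance curve")
  }
  list(eps = curve[idx], curve = curve, index = idx)
}

#' Fit DBSCAN models over the stepwise epsilon sweep
#'
#' Fits one model at the base radius and one at each inflated radius
#' `eps0 + eps0 * j` for `j = 1..j_max` (six models with the default
#' `j_max = 5`); at the largest radius compact data typically collapses to a
#' single cluster.
#'
#' @param features Numeric matrix.
#' @param eps0 Base radius (e.g. from [knn_elbow_eps()]).
#' @param min_pts Minimum neighbourhood size (default 5).
#' @param j_max Number of inflation steps (default 5).
#' @param dm Optional precomputed distance matrix.
#' @return List of `dbscan_model`s, one per grid radius; the grid is in
#'   `attr(, "eps_grid")`.
#' @export
dbscan_scan <- function(features = NULL, eps0, min_pts = 5, j_max = 5,
                        dm = NULL) {
  stop_if_not(eps0 > 0, "eps0 must be positive")
  if (is.null(dm)) dm <- dense_dist(features)
  grid <- c(eps0, eps0 + eps0 * seq_len(j_max))
  models <- lapply(grid, function(e) dbscan_fit(eps = e, min_pts = min_pts,
                                                dm = dm))
  attr(models, "eps_grid") <- grid
  models
}

#' Select the best density-scan model
#'
#' Discards rejected models (negative median silhouette), then scores the
#' remainder by the sum of five min-max-scaled components: median, 75th
#' percentile and maximum silhouette, the number of classified points, and
#' the negated noise count -- balancing cluster quality against information
#' retention. Undefined silhouette summaries (single-cluster models) enter
#' as 0, the value of an indifferent partition. The highest summed score
#' wins; exact ties go to the model classifying more points.
#'
#' @param models List of `dbscan_model`s (possibly pooled across ensembles
#'   and radii).
#' @return The chosen `dbscan_model`, with the score table in
#'   `attr(, "score_table")`.
#' @export
select_dbscan_model <- function(models) {
  rejected <- vapply(models, function(m) isTRUE(m$rejected), logical(1))
  candidates <- models[!rejected]
  if (length(candidates) == 0) {
    stop("all density-scan models were rejected (negative median ",
         "silhouette); adjust eps or min_pts", call. = FALSE)
  }
  n_total <- length(candidates[[1]]$labels)
  grab <- function(m, what) {
    v <- m$silhouette[[what]]
    if (is.finite(v)) v else 0
  }
  tab <- data.frame(
    eps = vapply(candidates, `[[`, numeric(1), "eps"),
    n_clusters = vapply(candidates, `[[`, numeric(1), "n_clusters"),
    sil_median = vapply(candidates, grab, numeric(1), "median"),
    sil_p75 = vapply(candidates, grab, numeric(1), "p75"),
    sil_max = vapply(candidates, grab, numeric(1), "max"),
    n_classified = vapply(candidates, function(m) n_total - m$n_noise,
                          numeric(1)),
    n_noise = vapply(candidates, `[[`, numeric(1), "n_noise")
  )
  score_mat <- cbind(
    minmax_scale(tab$sil_median),
    minmax_scale(tab$sil_p75),
    minmax_scale(tab$sil_max),
    minmax_scale(tab$n_classified),
    minmax_scale(-tab$n_noise)
  )
  tab$score <- rowSums(score_mat)
  best <- order(-tab$score, -tab$n_classified)[1]
  chosen <- candidates[[best]]
  attr(chosen, "score_table") <- tab
  chosen
}
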