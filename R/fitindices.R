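# Internal cluster-quality machinery shared by the global-correlation scan
# and the meta-locus refinement: vectorized silhouette widths and a
# five-index fit panel, each index oriented so larger means better.

#' Per-point silhouette widths
#'
#' Vectorized silhouette computation from a dense distance matrix: for each
#' point, cohesion `a` is the mean distance to its own cluster (excluding
#' itself) and separation `b` the smallest mean distance to another cluster;
#' `s = (b - a) / max(a, b)`. Points in singleton clusters get `s = 0`.
#'
#' @param dm Dense symmetric distance matrix.
#' @param labels Integer/character cluster labels (no noise handling here).
#' @return Numeric vector of silhouette widths.
#' @export
silhouette_widths <- function(dm, labels) {
  labels <- as.integer(factor(labels))
  n <- length(labels)
  stop_if_not(nrow(dm) == n, "labels must align with the distance matrix")
  k <- max(labels)
  if (k < 2) stop("silhouette requires at least 2 clusters", call. = FALSE)
  ind <- matrix(0, n, k)
  ind[cbind(seq_len(n), labels)] <- 1
  sizes <- colSums(ind)
  sums <- dm %*% ind                      # n x k: summed distance to cluster
  own <- sums[cbind(seq_len(n), labels)]
  a <- ifelse(sizes[labels] > 1, own / (sizes[labels] - 1), 0)
  means <- sweep(sums, 2, sizes, "/")
  means[cbind(seq_len(n), labels)] <- Inf  # exclude own cluster from b
  b <- apply(means, 1, min)
  s <- (b - a) / pmax(a, b)
  s[sizes[labels] == 1] <- 0
  s[!is.finite(s)] <- 0
  unname(s)
}

# Summary statistics of the silhouette distribution used for density-scan
# model evaluation.
silhouette_summary <- function(dm, labels) {
  s <- silhouette_widths(dm, labels)
  c(median = median(s), mean = mean(s),
    p75 = unname(quantile(s, 0.75)), max = max(s))
}

#' Cluster fit-index panel
#'
#' Computes five cluster-quality indices from a distance matrix and a hard
#' partition, all oriented so that larger values indicate better fit:
#' average silhouette width, Calinski-Harabasz, the Dunn index, Pearson
#' gamma (correlation between dissimilarity and the different-cluster
#' indicator), and the negated distance-based Davies-Bouldin index. Every
#' index in the panel is non-monotone in the number of clusters, so
#' rank-based selection across a k grid is not biased toward either end.
#'
#' @param dm Dense symmetric distance matrix.
#' @param labels Cluster labels.
#' @return Named numeric vector of five indices.
#' @export
cluster_fit_indices <- function(dm, labels) {
  labels <- as.integer(factor(labels))
  n <- length(labels)
  k <- max(labels)
  dm2 <- dm^2

  ind <- matrix(0, n, k)
  ind[cbind(seq_len(n), labels)] <- 1
  sizes <- colSums(ind)

  tss <- sum(dm2) / (2 * n)
  wss_c <- diag(t(ind) %*% dm2 %*% ind) / (2 * sizes)
  wss <- sum(wss_c)
  bss <- max(tss - wss, 0)

  ch <- if (k > 1 && wss > 0) (bss / (k - 1)) / (wss / (n - k)) else NA_real_

  # Dunn: minimum between-cluster distance over maximum cluster diameter.
  min_between <- Inf
  max_diam <- 0
  for (a in seq_len(k)) {
    ia <- labels == a
    da <- dm[ia, ia, drop = FALSE]
    if (sum(ia) > 1) max_diam <- max(max_diam, max(da))
    if (a < k) {
      for (b in seq((a + 1), k)) {
        ib <- labels == b
        min_between <- min(min_between, min(dm[ia, ib, drop = FALSE]))
      }
    }
  }
  dunn <- if (k > 1 && max_diam > 0) min_between / max_diam else NA_real_

  lower <- lower.tri(dm)
  dvec <- dm[lower]
  diff_cluster <- outer(labels, labels, "!=")[lower]
  pg <- if (stats::var(dvec) > 0 && stats::var(as.numeric(diff_cluster)) > 0) {
    cor(dvec, as.numeric(diff_cluster))
  } else NA_real_

  asw <- if (k > 1) mean(silhouette_widths(dm, labels)) else NA_real_

  # Distance-based Davies-Bouldin: scatter = mean within-cluster
  # dissimilarity, separation = mean between-cluster dissimilarity.
  db <- NA_real_
  if (k > 1) {
    scatter <- vapply(seq_len(k), function(c) {
      i <- labels == c
      if (sum(i) < 2) return(0)
      sub <- dm[i, i, drop = FALSE]
      mean(sub[lower.tri(sub)])
    }, numeric(1))
    worst <- vapply(seq_len(k), function(a) {
      others <- setdiff(seq_len(k), a)
      max(vapply(others, function(b) {
        (scatter[a] + scatter[b]) /
          mean(dm[labels == a, labels == b, drop = FALSE])
      }, numeric(1)))
    }, numeric(1))
    db <- mean(worst)
  }

  c(avg_silwidth = asw,
    calinski_harabasz = ch,
    dunn = dunn,
    pearson_gamma = pg,
    neg_davies_bouldin = -db)
}

#' Min-max scale a table of fit indices across candidate solutions
#'
#' Each index (column) is scaled to `[0, 1]` across the candidate solutions
#' (rows); indices are already oriented larger-is-better, so no sign flip is
#' needed. A constant column scales to 0.5 everywhere; `NA` cells stay `NA`
#' and are ignored in summed scores.
#'
#' @param idx_table Solutions x indices numeric matrix.
#' @return Matrix of the same shape with values in `[0, 1]`, plus a
#'   `summed` attribute with the per-solution score sums.
#' @export
scale_fit_indices <- function(idx_table) {
  scaled <- apply(idx_table, 2, function(col) {
    out <- rep(NA_real_, length(col))
    ok <- is.finite(col)
    if (any(ok)) out[ok] <- minmax_scale(col[ok])
    out
  })
  scaled <- matrix(scaled, nrow = nrow(idx_table),
                   dimnames = dimnames(idx_table))
  attr(scaled, "summed") <- rowSums(scaled, na.rm = TRUE)
  scaled
}
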