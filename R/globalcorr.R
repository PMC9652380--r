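# Stage-1 analysis of the global trait x trait genetic-correlation matrix:
# principal components with trait loadings, and the multi-method cluster
# scan with scaled-sum fit-statistic selection.

#' Read and validate a global genetic-correlation matrix
#'
#' TSV with row and column headers; rows are cognitive traits, columns
#' psychopathological traits, cells global genetic correlations. The matrix
#' must be complete; values slightly outside `[-1, 1]` are tolerated with a
#' warning (estimation noise), larger excursions are rejected.
#'
#' @param path TSV path.
#' @return Numeric matrix.
#' @export
read_rg_matrix <- function(path) {
  m <- as.matrix(read.delim(path, sep = "\t", row.names = 1,
                            check.names = FALSE))
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("genetic-correlation matrix has missing cells",
                     call. = FALSE)
  if (any(abs(m) > 1.5)) stop("implausible correlation values (|r| > 1.5)",
                              call. = FALSE)
  if (any(abs(m) > 1)) {
    warning("correlation values outside [-1, 1]; retained unclipped")
  }
  m
}

#' @rdname read_rg_matrix
#' @param m Numeric matrix.
#' @export
write_rg_matrix <- function(m, path) {
  write.table(cbind(trait = rownames(m), as.data.frame(m)), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Principal components of a correlation matrix with trait loadings
#'
#' Extracts principal components across the psychopathology profiles (one
#' observation per column trait, one variable per row trait) and estimates
#' the loading of each row trait on each component as the bivariate Pearson
#' correlation between that trait's correlation profile and the component
#' score vector. A constant profile yields an undefined (NA) loading.
#'
#' @param m Rows x columns correlation matrix.
#' @param n_pc Number of components to return (default 2).
#' @return List with `scores` (columns x n_pc), `loadings` (rows x n_pc),
#'   `var_explained` (fraction per component).
#' @export
pca_with_loadings <- function(m, n_pc = 2) {
  stop_if_not(nrow(m) >= 2 && ncol(m) >= 2, "need at least a 2 x 2 matrix")
  pr <- prcomp(t(m), center = TRUE, scale. = FALSE)
  n_pc <- min(n_pc, ncol(pr$x))
  scores <- pr$x[, seq_len(n_pc), drop = FALSE]
  loadings <- matrix(NA_real_, nrow(m), n_pc,
                     dimnames = list(rownames(m), colnames(scores)))
  for (i in seq_len(nrow(m))) {
    profile <- m[i, ]
    if (sd(profile) == 0) {
      warning("constant profile for row ", i, "; loading undefined")
      next
    }
    loadings[i, ] <- cor(profile, scores)[1, ]
  }
  var_explained <- pr$sdev^2 / sum(pr$sdev^2)
  list(scores = scores, loadings = loadings,
       var_explained = var_explained[seq_len(n_pc)])
}

run_partition_method <- function(method, d, x, k, seed) {
  switch(
    method,
    kmeans = with_seed(seed, kmeans(x, centers = k, nstart = 10)$cluster),
    pam = cluster::pam(d, k = k, cluster.only = TRUE),
    agglomerative = cutree(hclust(d, method = "ward.D2"), k = k),
    diana = cutree(stats::as.hclust(cluster::diana(d)), k = k),
    stop("unknown clustering method: ", method, call. = FALSE)
  )
}

#' Multi-method cluster scan of trait profiles
#'
#' Clusters the column traits on the Euclidean dissimilarity of their
#' correlation profiles, with every requested method at each k starting
#' from `k_min`. k grows until any method produces a singleton cluster; the
#' previous k is `k_max` and the scan keeps solutions for k in
#' `[k_min, k_max]`. Every solution gets the five-index fit panel, each
#' index is min-max scaled across solutions, and the per-solution scaled
#' scores are summed; the highest sum is the provisional choice.
#'
#' @param m Rows x columns correlation matrix (columns are clustered).
#' @param k_min Smallest k (default 2).
#' @param methods Subset of `c("kmeans", "pam", "agglomerative", "diana")`.
#' @param seed Integer seed (k-means starts).
#' @return A `cluster_scan_result`: list with `solutions` (per method x k:
#'   labels and indices), `fit_table`, `scaled`, `summed`, `k_max`,
#'   `chosen` (method, k, labels).
#' @export
cluster_scan <- function(m, k_min = 2,
                         methods = c("kmeans", "pam", "agglomerative", "diana"),
                         seed = 1L) {
  stop_if_not(length(methods) >= 1, "methods must be nonempty")
  x <- t(m)
  n <- nrow(x)
  stop_if_not(n >= k_min + 1, "fewer observations than k_min + 1")
  d <- dist(x)
  dm <- as.matrix(d)

  solutions <- list()
  k_max <- NULL
  k <- k_min
  while (k <= n - 1) {
    labs <- lapply(methods, run_partition_method, d = d, x = x, k = k,
                   seed = derive_seed(seed, k))
    names(labs) <- methods
    singleton <- any(vapply(labs, function(l) min(table(l)) == 1, logical(1)))
    if (singleton) {
      if (k == k_min) {
        # keep the smallest solutions so the scan is never empty
        warning("a singleton cluster appears already at k_min; ",
                "k_max set to k_min")
        for (mth in methods) {
          solutions[[paste(mth, k, sep = "_k")]] <-
            list(method = mth, k = k, labels = labs[[mth]])
        }
        k_max <- k_min
      } else {
        k_max <- k - 1
      }
      break
    }
    for (mth in methods) {
      solutions[[paste(mth, k, sep = "_k")]] <-
        list(method = mth, k = k, labels = labs[[mth]])
    }
    k <- k + 1
  }
  if (is.null(k_max)) k_max <- k - 1
  stop_if_not(k_max >= k_min, "a singleton appeared already at k_min")
  solutions <- Filter(function(s) s$k <= k_max, solutions)

  fit_table <- t(vapply(solutions,
                        function(s) cluster_fit_indices(dm, s$labels),
                        numeric(5)))
  scaled <- scale_fit_indices(fit_table)
  summed <- attr(scaled, "summed")
  best <- which.max(summed)
  structure(list(solutions = solutions, fit_table = fit_table,
                 scaled = scaled, summed = summed,
                 k_min = k_min, k_max = k_max,
                 chosen = solutions[[best]],
                 dist = d, x = x, seed = as.integer(seed)),
            class = "cluster_scan_result")
}

#' @export
print.cluster_scan_result <- function(x, ...) {
  cat(sprintf("Cluster scan over k in [%d, %d], %d solution(s)\n",
              x$k_min, x$k_max, length(x$solutions)))
  cat(sprintf("  provisional choice: %s, k = %d (summed score %.3f)\n",
              x$chosen$method, x$chosen$k, max(x$summed)))
  invisible(x)
}

# Mean bootstrap Jaccard stability of one solution: resample observations
# with replacement, re-cluster, match each original cluster to its best
# Jaccard partner among the bootstrap clusters.
bootstrap_stability <- function(scan, solution, reps = 100, seed = 1L) {
  x <- scan$x
  n <- nrow(x)
  orig <- solution$labels
  vals <- vapply(seq_len(reps), function(r) {
    idx <- with_seed(derive_seed(seed, r), sample(n, n, replace = TRUE))
    xb <- x[idx, , drop = FALSE]
    db <- dist(xb)
    lb <- tryCatch(
      run_partition_method(solution$method, db, xb, solution$k,
                           derive_seed(seed, reps + r)),
      error = function(e) NULL
    )
    if (is.null(lb)) return(NA_real_)
    jac <- vapply(sort(unique(orig)), function(cl) {
      members <- which(orig == cl)
      in_boot <- idx %in% members
      if (!any(in_boot)) return(NA_real_)
      max(vapply(sort(unique(lb)), function(bcl) {
        a <- in_boot
        b <- lb == bcl
        sum(a & b) / sum(a | b)
      }, numeric(1)))
    }, numeric(1))
    mean(jac, na.rm = TRUE)
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

#' Select the final cluster solution with bootstrap stability
#'
#' The solution with the highest summed scaled fit score wins; near-ties
#' (within `tol`) are broken by mean bootstrap Jaccard stability
#' (resampling observations, re-clustering, greedy cluster matching).
#'
#' @param scan A `cluster_scan_result`.
#' @param bootstrap_reps Bootstrap replicates (default 100).
#' @param tol Score window treated as a tie (default 1e-6).
#' @param seed Integer seed.
#' @return List with `method`, `k`, `labels`, `stability` (when computed),
#'   and the candidate table.
#' @export
select_solution <- function(scan, bootstrap_reps = 100, tol = 1e-6,
                            seed = 1L) {
  stop_if_not(length(scan$solutions) >= 1, "empty scan")
  summed <- scan$summed
  top <- max(summed)
  tied <- which(summed >= top - tol)
  if (length(tied) == 1) {
    sol <- scan$solutions[[tied]]
    return(list(method = sol$method, k = sol$k, labels = sol$labels,
                stability = NULL, summed_score = unname(summed[tied])))
  }
  stab <- vapply(tied, function(i) {
    bootstrap_stability(scan, scan$solutions[[i]], reps = bootstrap_reps,
                        seed = derive_seed(seed, i))
  }, numeric(1))
  pick <- tied[which.max(stab)]
  sol <- scan$solutions[[pick]]
  list(method = sol$method, k = sol$k, labels = sol$labels,
       stability = setNames(stab, names(scan$solutions)[tied]),
       summed_score = unname(summed[pick]))
}
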