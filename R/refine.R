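# Hierarchical refinement of the density-scan solution into the final
# meta-locus assignment, and per-meta-locus summarization.

#' Hierarchically refine a density-scan clustering
#'
#' Recovers global cluster patterns from the localized density solution:
#' the ensemble features are augmented with a one-hot encoding of the
#' density-cluster memberships (noise rows all-zero, weighted by
#' `onehot_weight`), classified points are clustered agglomeratively (Ward
#' linkage, Euclidean distance), and candidate solutions at each `k` are
#' compared on the five-index fit panel. Each index ranks the candidate
#' solutions; the chosen `k` is the solution with the most indices ranked in
#' its top 3, ties broken by the larger summed min-max-scaled score. Noise
#' points keep label `-1` (unclassified).
#'
#' @param features Observations x features matrix (the stacked ensemble).
#' @param dbscan_labels Labels from the selected density model (`-1` noise).
#' @param k_candidates Candidate cluster counts (default `c(5, 10, 15, 25, 30)`).
#' @param onehot_weight Weight of the one-hot membership block (default 1).
#' @return A `metalocus_assignment`: list with `labels` (full-length, `-1`
#'   unclassified), `k`, `fit_table` (indices x candidates), `ranks`,
#'   `top3_counts`, and provenance fields.
#' @export
hierarchical_refine <- function(features, dbscan_labels,
                                k_candidates = c(5, 10, 15, 25, 30),
                                onehot_weight = 1) {
  features <- as.matrix(features)
  n <- nrow(features)
  stop_if_not(length(dbscan_labels) == n,
              "dbscan_labels must align with features")
  classified <- which(dbscan_labels != -1L)
  stop_if_not(length(classified) >= 3, "too few classified points to refine")

  cl_ids <- sort(unique(dbscan_labels[dbscan_labels != -1L]))
  onehot <- matrix(0, n, length(cl_ids))
  for (j in seq_along(cl_ids)) onehot[dbscan_labels == cl_ids[j], j] <- 1
  aug <- cbind(features, onehot_weight * onehot)

  keep <- k_candidates < length(classified)
  if (!all(keep)) {
    warning("skipping k candidate(s) >= number of classified points: ",
            paste(k_candidates[!keep], collapse = ", "))
  }
  k_candidates <- k_candidates[keep]
  stop_if_not(length(k_candidates) >= 1, "no usable k candidates")

  dm <- dense_dist(aug[classified, , drop = FALSE])
  hc <- hclust(as.dist(dm), method = "ward.D2")
  solutions <- lapply(k_candidates, function(k) cutree(hc, k = k))
  idx_table <- t(vapply(solutions, function(lab) cluster_fit_indices(dm, lab),
                        numeric(5)))
  rownames(idx_table) <- paste0("k", k_candidates)

  # Rank candidates per index (rank 1 = best); most indices in top 3 wins.
  ranks <- apply(idx_table, 2, function(col) rank(-col, ties.method = "min",
                                                  na.last = "keep"))
  ranks <- matrix(ranks, nrow = length(k_candidates),
                  dimnames = dimnames(idx_table))
  top3 <- rowSums(ranks <= 3, na.rm = TRUE)
  scaled <- scale_fit_indices(idx_table)
  summed <- attr(scaled, "summed")
  best <- order(-top3, -summed)[1]

  labels <- rep(-1L, n)
  labels[classified] <- as.integer(solutions[[best]])
  structure(list(labels = labels, k = k_candidates[best],
                 k_candidates = k_candidates,
                 fit_table = idx_table, ranks = ranks, top3_counts = top3,
                 summed_scores = summed,
                 dbscan_labels = dbscan_labels,
                 onehot_weight = onehot_weight),
            class = "metalocus_assignment")
}

#' @export
print.metalocus_assignment <- function(x, ...) {
  k_used <- length(setdiff(unique(x$labels), -1L))
  cat(sprintf("Meta-locus assignment: %d meta-loci (chosen k = %d), %d unclassified of %d segments\n",
              k_used, x$k, sum(x$labels == -1L), length(x$labels)))
  invisible(x)
}

#' Summarize meta-loci
#'
#' Per-meta-locus descriptive statistics -- segment count, total length in
#' MB (1 MB = 1e6 bp), summed local heritability and its fraction of the
#' trait total, and per-partner-trait z-score quartiles -- plus cohort-level
#' statistics over meta-loci.
#'
#' @param assign A `metalocus_assignment` (labels aligned to `segmap` rows).
#' @param segmap A `segment_map`.
#' @param data Optional `local_rg` for heritability and z summaries.
#' @param trait Trait whose heritability is apportioned (required with
#'   `data`).
#' @return A `metalocus_summary`: list with `per_locus` (data.frame),
#'   `cohort` (see [metalocus_cohort_stats()]), and `z_quartiles` (list per
#'   meta-locus, when `data` is given).
#' @export
summarize_metaloci <- function(assign, segmap, data = NULL, trait = NULL) {
  labels <- if (inherits(assign, "metalocus_assignment")) assign$labels else assign
  stop_if_not(length(labels) == nrow(segmap),
              "labels must align with the segment map")
  ids <- sort(setdiff(unique(labels), -1L))
  stop_if_not(length(ids) >= 1, "no classified meta-loci to summarize")

  h2_total <- NULL
  h2_by_seg <- NULL
  if (!is.null(data)) {
    stop_if_not(!is.null(trait), "trait required when data is given")
    h2_total <- sum_heritability(data, trait)$h2
    rows <- data$h2[data$h2$trait == trait, ]
    h2_by_seg <- setNames(rows$h2, rows$segment_id)
  }

  per <- lapply(ids, function(ml) {
    sel <- labels == ml
    if (!any(sel)) return(NULL)
    segs <- segmap[sel, , drop = FALSE]
    out <- data.frame(
      metalocus = ml,
      n_segments = nrow(segs),
      length_mb = sum(segs$end - segs$start + 1) / 1e6
    )
    if (!is.null(h2_by_seg)) {
      h2s <- sum(h2_by_seg[as.character(segs$segment_id)], na.rm = TRUE)
      out$h2 <- h2s
      out$h2_fraction <- h2s / h2_total
    }
    out
  })
  per <- do.call(rbind, per)

  zq <- NULL
  if (!is.null(data)) {
    zq <- lapply(ids, function(ml) {
      seg_ids <- segmap$segment_id[labels == ml]
      pr <- data$pairs[data$pairs$segment_id %in% seg_ids, ]
      if (nrow(pr) == 0) return(NULL)
      do.call(rbind, lapply(split(pr$z, pr$trait_b), function(z) {
        quantile(z, c(0.25, 0.5, 0.75))
      }))
    })
    names(zq) <- ids
  }
  structure(list(per_locus = per,
                 cohort = metalocus_cohort_stats(per),
                 z_quartiles = zq),
            class = "metalocus_summary")
}

#' Cohort-level meta-locus statistics
#'
#' Given a per-meta-locus table with `n_segments` and `length_mb` columns
#' (for instance one produced by [summarize_metaloci()], or a published
#' descriptive table fed in directly), computes the cohort descriptives:
#' median and maximum length, minimum and maximum segment count, and the
#' number of meta-loci.
#'
#' @param per_locus data.frame with columns `n_segments` and `length_mb`.
#' @return List with `n_metaloci`, `median_length_mb`, `min_length_mb`,
#'   `max_length_mb`, `min_segments`, `max_segments`.
#' @export
metalocus_cohort_stats <- function(per_locus) {
  stop_if_not(all(c("n_segments", "length_mb") %in% names(per_locus)),
              "per_locus needs n_segments and length_mb columns")
  stop_if_not(all(per_locus$length_mb > 0), "lengths must be positive")
  list(n_metaloci = nrow(per_locus),
       median_length_mb = median(per_locus$length_mb),
       min_length_mb = min(per_locus$length_mb),
       max_length_mb = max(per_locus$length_mb),
       min_segments = min(per_locus$n_segments),
       max_segments = max(per_locus$n_segments))
}

#' Reference meta-locus descriptive tables
#'
#' Published per-meta-locus descriptive statistics for the CTP (15 meta-loci)
#' and NCF (10 meta-loci) analyses: LD-segment counts, heritability share and
#' total length in MB. These serve as desk-check inputs for
#' [metalocus_cohort_stats()] and as a realistic reference cohort.
#'
#' @param trait `"CTP"` or `"NCF"`.
#' @return data.frame with columns `metalocus`, `n_segments`, `h2`,
#'   `length_mb`.
#' @export
reference_metaloci <- function(trait = c("CTP", "NCF")) {
  trait <- match.arg(trait)
  if (trait == "CTP") {
    data.frame(
      metalocus = 1:15,
      n_segments = c(96, 165, 125, 43, 148, 68, 168, 105, 46, 91, 132, 82,
                     99, 100, 101),
      h2 = c(0.0079, 0.0149, 0.0091, 0.0036, 0.0132, 0.0051, 0.0136, 0.0114,
             0.0051, 0.0071, 0.0221, 0.0078, 0.0085, 0.0122, 0.0137),
      length_mb = c(103.73, 187.30, 129.75, 44.87, 197.22, 80.64, 197.24,
                    127.26, 80.64, 98.62, 176.15, 98.69, 111.18, 132.29,
                    123.75)
    )
  } else {
    data.frame(
      metalocus = 1:10,
      n_segments = c(125, 208, 135, 123, 113, 105, 210, 143, 167, 77),
      h2 = c(0.0271, 0.0303, 0.0205, 0.0158, 0.0168, 0.0146, 0.0199, 0.0189,
             0.0187, 0.0124),
      length_mb = c(196.85, 243.30, 164.43, 138.01, 135.20, 128.79, 231.07,
                    157.57, 201.30, 93.58)
    )
  }
}

#' Export meta-loci as BED files
#'
#' Writes one BED file per meta-locus (segments it contains) for karyotype
#' rendering, plus a combined assignment TSV.
#'
#' @param assign A `metalocus_assignment`.
#' @param segmap A `segment_map` aligned with the assignment.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Character vector of written paths, invisibly.
#' @export
export_metaloci_bed <- function(assign, segmap, dir, prefix = "metalocus") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labels <- assign$labels
  paths <- character(0)
  tsv <- file.path(dir, paste0(prefix, "_assignment.tsv"))
  write.table(
    data.frame(segment_id = segmap$segment_id, chr = segmap$chrom,
               start = segmap$start, end = segmap$end,
               metalocus_label = labels),
    tsv, sep = "\t", quote = FALSE, row.names = FALSE
  )
  paths <- c(paths, tsv)
  for (ml in sort(setdiff(unique(labels), -1L))) {
    p <- file.path(dir, sprintf("%s_%02d.bed", prefix, ml))
    write_segments_bed(segmap[labels == ml, , drop = FALSE], p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
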