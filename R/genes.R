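# Gene prioritization: percentile filters over multi-method evidence, rank
# averaging across transcriptome annotations, union with credible genes,
# heterogeneity (HEIDI-style) adjustment, meta-locus assignment,
# inverse-rank scoring and druggability annotation.

#' Default gene-evidence column manifest
#'
#' Declares, rather than guesses, the direction and role of each evidence
#' column: `p_cols` are gene-based association p-values (smaller = better),
#' `score_cols` priority scores (larger = better), `twas_cols` transcriptome
#' association p-values averaged by rank across annotation sources,
#' `heidi_col` a heterogeneity p-value, `credible_col` a logical
#' fine-mapping credible-set flag.
#'
#' @return Named list manifest.
#' @export
default_evidence_manifest <- function() {
  list(p_cols = "magma_p",
       score_cols = "pops_score",
       twas_cols = c("twas_brain_p", "twas_cortex_p"),
       heidi_col = "heidi_p",
       credible_col = "credible")
}

#' Read / write gene evidence tables
#'
#' Plain TSV with a header; the column manifest travels as a JSON sidecar
#' (`<path>.manifest.json`) so column direction is declared, not inferred.
#'
#' @param path TSV path.
#' @param manifest Manifest list; on read, defaults to the sidecar or
#'   [default_evidence_manifest()].
#' @return `read_gene_evidence`: a `gene_evidence` data.frame.
#' @export
read_gene_evidence <- function(path, manifest = NULL) {
  ev <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (is.null(manifest)) {
    sidecar <- paste0(path, ".manifest.json")
    manifest <- if (file.exists(sidecar)) {
      jsonlite::read_json(sidecar, simplifyVector = TRUE)
    } else {
      default_evidence_manifest()
    }
  }
  if ("credible" %in% names(ev)) ev$credible <- as.logical(ev$credible)
  class(ev) <- c("gene_evidence", "data.frame")
  attr(ev, "manifest") <- manifest
  ev
}

#' @rdname read_gene_evidence
#' @param ev A `gene_evidence` data.frame.
#' @export
write_gene_evidence <- function(ev, path) {
  write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- attr(ev, "manifest")
  if (!is.null(manifest)) {
    jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

# Competition ranks with deterministic tie-breaking (input order), rank 1 =
# best. `decreasing = TRUE` means larger values are better.
rank_best_first <- function(x, decreasing = FALSE) {
  ord <- order(if (decreasing) -x else x, seq_along(x))
  r <- integer(length(x))
  r[ord] <- seq_along(x)
  r
}

#' Prioritize genes by multi-method percentile filters
#'
#' Per evidence method, genes at or better than the `pct_cutoff` rank
#' survive (rank `<= ceiling(N * pct_cutoff)`); transcriptome methods use
#' the mean rank across their annotation columns. Genes whose heterogeneity
#' p-value falls below `heidi_p` have their transcriptome support removed
#' (heterogeneity implies the expression-mediation signal is likely driven
#' by linkage). The final list is the union of per-method survivors with
#' credible-flagged genes; genes with no support anywhere are removed.
#'
#' @param ev A `gene_evidence` data.frame with a manifest attribute.
#' @param pct_cutoff Percentile cutoff in (0, 1]; default 0.5.
#' @param heidi_p Heterogeneity significance threshold; default 0.05.
#' @return Filtered `gene_evidence`, with a logical support matrix in
#'   `attr(, "support")`.
#' @export
prioritize_genes <- function(ev, pct_cutoff = 0.5, heidi_p = 0.05) {
  stop_if_not(nrow(ev) >= 1, "empty evidence table")
  manifest <- attr(ev, "manifest")
  if (is.null(manifest)) manifest <- default_evidence_manifest()
  methods_present <- c(manifest$p_cols, manifest$score_cols,
                       if (length(manifest$twas_cols)) "twas")
  stop_if_not(length(methods_present) >= 1,
              "no evidence columns declared in the manifest")

  n <- nrow(ev)
  cut <- ceiling(n * pct_cutoff)
  support <- matrix(FALSE, n, 0)

  for (col in manifest$p_cols) {
    support <- cbind(support, rank_best_first(ev[[col]]) <= cut)
    colnames(support)[ncol(support)] <- col
  }
  for (col in manifest$score_cols) {
    support <- cbind(support,
                     rank_best_first(ev[[col]], decreasing = TRUE) <= cut)
    colnames(support)[ncol(support)] <- col
  }
  if (length(manifest$twas_cols)) {
    twas_ranks <- vapply(manifest$twas_cols,
                         function(col) rank_best_first(ev[[col]]),
                         integer(n))
    mean_rank <- rowMeans(twas_ranks)
    twas_ok <- rank_best_first(mean_rank) <= cut
    if (!is.null(manifest$heidi_col) && manifest$heidi_col %in% names(ev)) {
      flagged <- ev[[manifest$heidi_col]] < heidi_p
      twas_ok[flagged] <- FALSE
    }
    support <- cbind(support, twas = twas_ok)
  }
  credible <- if (!is.null(manifest$credible_col) &&
                  manifest$credible_col %in% names(ev)) {
    isTRUE_vec(ev[[manifest$credible_col]])
  } else {
    rep(FALSE, n)
  }
  support <- cbind(support, credible = credible)
  keep <- rowSums(support) > 0
  out <- ev[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gene_evidence", "data.frame")
  attr(out, "manifest") <- manifest
  attr(out, "support") <- support[keep, , drop = FALSE]
  out
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Assign genes to meta-loci by genomic position
#'
#' Each gene inherits the meta-locus label of the segment containing its
#' midpoint; genes in unclassified segments, in segments absent from the
#' assignment (e.g. MHC-excluded), or outside every segment get label `-1`.
#'
#' @param ev A `gene_evidence` data.frame with `chrom`, `start`, `end`.
#' @param assign A `metalocus_assignment` (aligned to `segmap` rows) or a
#'   bare label vector.
#' @param segmap A `segment_map`.
#' @return `ev` with a `metalocus` column; the count of genes outside any
#'   segment is in `attr(, "n_unlocated")` (warned about when > 0).
#' @export
assign_genes_to_metaloci <- function(ev, assign, segmap) {
  labels <- if (inherits(assign, "metalocus_assignment")) assign$labels else assign
  stop_if_not(length(labels) == nrow(segmap),
              "assignment labels must align with segmap")
  mid <- floor((ev$start + ev$end) / 2)
  seg <- locate_in_segments(segmap, ev$chrom, mid)
  ml <- rep(-1L, nrow(ev))
  located <- !is.na(seg)
  ml[located] <- labels[match(seg[located], segmap$segment_id)]
  ml[is.na(ml)] <- -1L
  n_unlocated <- sum(!located)
  if (n_unlocated > 0) {
    warning(n_unlocated, " gene(s) fall outside every segment; labelled -1")
  }
  ev$metalocus <- ml
  attr(ev, "n_unlocated") <- n_unlocated
  ev
}

#' Inverse-rank score
#'
#' Maps a unidirectional gene ranking onto `[0, 1)`:
#' `score = 1 - rank / N`, with rank 1 the best gene and the worst-ranked
#' gene scoring exactly 0. Computed within the gene universe passed in
#' (typically per meta-locus). Ties are broken by stable input order; a
#' single-gene universe scores 0 with a warning.
#'
#' @param ev A `gene_evidence` data.frame (or any data.frame).
#' @param by Column to rank on.
#' @param decreasing `TRUE` (default) when larger `by` is better.
#' @return `ev` with an added `irs` column.
#' @export
inverse_rank_score <- function(ev, by = "pops_score", decreasing = TRUE) {
  stop_if_not(by %in% names(ev), paste("no column", by))
  n <- nrow(ev)
  stop_if_not(n >= 1, "empty table")
  if (n == 1) {
    warning("single-gene universe: inverse-rank score is 0")
  }
  if (anyDuplicated(ev[[by]])) {
    message("ties in ", by, " broken by input order")
  }
  r <- rank_best_first(ev[[by]], decreasing = decreasing)
  ev$irs <- 1 - r / n
  ev
}

#' Annotate genes with druggability tiers
#'
#' Left join on gene symbol against a two-column tier table; genes without
#' an entry get tier `"none"`. Duplicate symbols in the tier table keep
#' their first row, with a warning.
#'
#' @param ev A `gene_evidence` data.frame with a `gene` column.
#' @param tier_table data.frame with columns `gene` and `tier`, or a TSV
#'   path to one.
#' @return `ev` with an added `druggability_tier` column (same row count).
#' @export
annotate_druggability <- function(ev, tier_table) {
  if (is.character(tier_table)) {
    tier_table <- read.delim(tier_table, sep = "\t", stringsAsFactors = FALSE)
  }
  stop_if_not(all(c("gene", "tier") %in% names(tier_table)),
              "tier table needs gene and tier columns")
  if (anyDuplicated(tier_table$gene)) {
    warning("duplicate symbols in tier table; keeping first occurrence")
    tier_table <- tier_table[!duplicated(tier_table$gene), , drop = FALSE]
  }
  idx <- match(ev$gene, tier_table$gene)
  ev$druggability_tier <- ifelse(is.na(idx), "none", tier_table$tier[idx])
  ev
}
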