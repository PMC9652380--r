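# Gene-set analysis per meta-locus: preranked running-sum enrichment with a
# permutation null and leading-edge driver extraction, hypergeometric
# over-representation, and the multi-method consensus rule.

#' Read and write GMT gene-set collections
#'
#' @param path GMT file path (tab-separated: set name, description, members).
#' @return `read_gmt`: named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @param description Description field (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# Running-sum enrichment score from hit positions in a ranking.
# `scores_sorted` are the (non-negative) gene scores in ranking order,
# `pos` the sorted positions of the set's genes. Hits add score / sum(hit
# scores); misses subtract 1 / (N - n_hits). Returns the signed maximum
# deviation and the peak position.
es_from_positions <- function(scores_sorted, pos) {
  n <- length(scores_sorted)
  m <- length(pos)
  if (m == n) {
    # Every step is a hit: the walk climbs monotonically to 1.
    return(list(es = 1, peak = n))
  }
  hit_scores <- scores_sorted[pos]
  nr <- sum(hit_scores)
  miss_dec <- 1 / (n - m)
  if (nr <= 0) {
    # All-zero hit scores: hits contribute nothing, the walk only decreases.
    dev <- -(pos - seq_len(m)) * miss_dec
    i <- which.min(dev)
    return(list(es = dev[i], peak = pos[i]))
  }
  cum_hit <- cumsum(hit_scores) / nr
  after <- cum_hit - (pos - seq_len(m)) * miss_dec          # just after hit i
  before <- c(0, cum_hit[-m]) - (pos - seq_len(m)) * miss_dec  # just before
  lowest <- min(before, -(n - m) * miss_dec + cum_hit[m])
  hi <- max(after)
  if (hi >= abs(lowest)) {
    list(es = hi, peak = pos[which.max(after)])
  } else {
    list(es = lowest, peak = NA_integer_)
  }
}

#' Preranked gene-set enrichment with a permutation null
#'
#' Genes are ordered by decreasing score (non-negative inverse-rank scores).
#' Walking down the list, hitting a set member increases a running sum by
#' its score divided by the summed in-set scores and a miss decreases it by
#' `1 / (N - N_hits)`; the enrichment score (ES) is the signed maximum
#' deviation from zero. The null permutes the gene-score assignment
#' `n_perm` times; NES divides ES by the mean same-sign null ES; the p-value
#' is the same-sign null exceedance; FDR follows the pooled null-NES
#' estimate across sets. Leading-edge driver genes are the in-set genes at
#' or before the peak of the running sum.
#'
#' @param scores Named non-negative numeric vector (gene universe).
#' @param sets Named list of character vectors.
#' @param n_perm Number of permutations (default 1000).
#' @param min_size,max_size Set-size bounds after intersection with the
#'   universe (defaults 15 and 500); out-of-bounds sets are skipped.
#' @param seed Integer seed.
#' @return An `enrichment_result` data.frame: `set`, `size`, `ES`, `NES`,
#'   `pval`, `qval` and a `leading_edge` list-column.
#' @export
gsea_preranked <- function(scores, sets, n_perm = 1000, min_size = 15,
                           max_size = 500, seed = 1L) {
  stop_if_not(all(scores >= 0), "scores must be non-negative")
  stop_if_not(length(sets) >= 1, "sets must be nonempty")
  ord <- order(-scores, seq_along(scores))
  genes_sorted <- names(scores)[ord]
  scores_sorted <- unname(scores[ord])
  n <- length(scores)

  sizes <- integer(0)
  kept <- list()
  for (nm in names(sets)) {
    members <- intersect(sets[[nm]], genes_sorted)
    if (length(members) == 0) {
      message("set ", nm, " has no genes in the universe; skipped")
      next
    }
    if (length(members) < min_size || length(members) > max_size) {
      next
    }
    kept[[nm]] <- members
    sizes[nm] <- length(members)
  }
  if (length(kept) == 0) {
    stop("no gene set within the size bounds after intersection",
         call. = FALSE)
  }

  obs <- lapply(kept, function(members) {
    pos <- sort(match(members, genes_sorted))
    es <- es_from_positions(scores_sorted, pos)
    le <- if (is.finite(es$es) && es$es > 0 && !is.na(es$peak)) {
      genes_sorted[pos[pos <= es$peak]]
    } else {
      character(0)
    }
    list(es = es$es, leading_edge = le)
  })
  es_obs <- vapply(obs, `[[`, numeric(1), "es")

  # Null: permuting the gene-score assignment is equivalent to drawing the
  # set's positions uniformly at random within the fixed ranking.
  null_es <- with_seed(seed, {
    lapply(unique(sizes), function(m) {
      vapply(seq_len(n_perm), function(p) {
        es_from_positions(scores_sorted, sort(sample.int(n, m)))$es
      }, numeric(1))
    })
  })
  names(null_es) <- as.character(unique(sizes))

  norm_of <- function(null) {
    pos_mean <- mean(null[null > 0])
    neg_mean <- mean(abs(null[null < 0]))
    c(pos = if (is.finite(pos_mean)) pos_mean else NA_real_,
      neg = if (is.finite(neg_mean)) neg_mean else NA_real_)
  }

  nes <- pval <- numeric(length(kept))
  null_nes_pool <- numeric(0)
  nes_null_by_set <- vector("list", length(kept))
  for (i in seq_along(kept)) {
    null <- null_es[[as.character(sizes[i])]]
    nf <- norm_of(null)
    e <- es_obs[i]
    if (e >= 0) {
      nes[i] <- e / nf[["pos"]]
      pval[i] <- (1 + sum(null >= e)) / (1 + sum(null >= 0))
    } else {
      nes[i] <- e / nf[["neg"]]
      pval[i] <- (1 + sum(null <= e)) / (1 + sum(null < 0))
    }
    nn <- ifelse(null >= 0, null / nf[["pos"]], null / nf[["neg"]])
    nes_null_by_set[[i]] <- nn[is.finite(nn)]
  }
  null_nes_pool <- unlist(nes_null_by_set)

  qval <- vapply(seq_along(kept), function(i) {
    target <- nes[i]
    if (!is.finite(target)) return(NA_real_)
    if (target >= 0) {
      num <- mean(null_nes_pool >= target)
      den <- mean(nes >= target)
    } else {
      num <- mean(null_nes_pool <= target)
      den <- mean(nes <= target)
    }
    if (den == 0) return(NA_real_)
    min(1, num / den)
  }, numeric(1))

  out <- data.frame(set = names(kept), size = unname(sizes),
                    ES = unname(es_obs), NES = nes, pval = pval, qval = qval,
                    stringsAsFactors = FALSE)
  out$leading_edge <- I(lapply(obs, `[[`, "leading_edge"))
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  attr(out, "n_perm") <- n_perm
  out
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of the overlap between a selected gene
#' list and each gene set, against a background universe, with
#' Benjamini-Hochberg FDR across the tested sets. Sets overlapping the list
#' in fewer than `min_overlap` genes, or outside the size bounds, are not
#' tested.
#'
#' @param gene_list Selected genes (must be a subset of `universe`).
#' @param universe Background gene universe.
#' @param sets Named list of character vectors.
#' @param min_overlap Minimum overlap to test a set (default 3).
#' @param min_size,max_size Set-size bounds within the universe (defaults 5
#'   and 2000).
#' @return data.frame with `set`, `size`, `overlap`, `pval`, `qval`.
#' @export
hypergeometric_ora <- function(gene_list, universe, sets, min_overlap = 3,
                               min_size = 5, max_size = 2000) {
  stop_if_not(length(universe) >= 1, "empty universe")
  stop_if_not(all(gene_list %in% universe),
              "gene_list must be a subset of the universe")
  n_univ <- length(universe)
  n_list <- length(gene_list)
  rows <- lapply(names(sets), function(nm) {
    inset <- intersect(sets[[nm]], universe)
    k <- length(inset)
    if (k < min_size || k > max_size) return(NULL)
    ov <- length(intersect(inset, gene_list))
    if (ov < min_overlap) return(NULL)
    p <- phyper(ov - 1, k, n_univ - k, n_list, lower.tail = FALSE)
    data.frame(set = nm, size = k, overlap = ov, pval = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(set = character(), size = integer(),
                      overlap = integer(), pval = numeric(),
                      qval = numeric())
    return(out)
  }
  out$qval <- p.adjust(out$pval, method = "BH")
  rownames(out) <- NULL
  out
}

#' Consensus gene sets across enrichment methods
#'
#' A set reaches consensus when it is significant in the preranked
#' enrichment (primary evidence, `qval < gsea_q`) and supported by at least
#' one over-representation result (secondary evidence, `qval` below that
#' result's own threshold; a reduced-redundancy collection typically uses a
#' relaxed 0.1). Leading-edge genes from the primary analysis are attached
#' as drivers.
#'
#' @param gsea An `enrichment_result`.
#' @param ora_results List of ORA data.frames (from [hypergeometric_ora()]).
#' @param gsea_q Primary significance threshold (default 0.05).
#' @param ora_q Secondary thresholds, recycled across `ora_results`
#'   (default 0.05).
#' @return Consensus subset of `gsea` with a `supported_by` column naming
#'   the agreeing secondary methods.
#' @export
consensus_sets <- function(gsea, ora_results, gsea_q = 0.05, ora_q = 0.05) {
  if (!is.list(ora_results) || is.data.frame(ora_results)) {
    ora_results <- list(ora_results)
  }
  if (is.null(names(ora_results))) {
    names(ora_results) <- paste0("ora", seq_along(ora_results))
  }
  ora_q <- rep_len(ora_q, length(ora_results))
  primary <- !is.na(gsea$qval) & gsea$qval < gsea_q
  support <- vapply(seq_along(ora_results), function(i) {
    tab <- ora_results[[i]]
    ok <- tab$set[!is.na(tab$qval) & tab$qval < ora_q[i]]
    gsea$set %in% ok
  }, logical(nrow(gsea)))
  support <- matrix(support, nrow = nrow(gsea))
  keep <- primary & rowSums(support) > 0
  out <- gsea[keep, , drop = FALSE]
  out$supported_by <- apply(support[keep, , drop = FALSE], 1, function(r) {
    paste(names(ora_results)[r], collapse = ",")
  })
  rownames(out) <- NULL
  out
}

#' Extract driver genes from a consensus table
#'
#' The union of leading-edge genes over the (consensus) sets, preserving
#' first-seen order.
#'
#' @param consensus An `enrichment_result`-like data.frame with a
#'   `leading_edge` list-column.
#' @return Character vector of driver genes.
#' @export
driver_genes <- function(consensus) {
  unique(unlist(consensus$leading_edge))
}
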