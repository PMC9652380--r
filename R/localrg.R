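# Local genetic correlation datasets: per-segment, per-trait heritability
# and per-trait-pair covariance / correlation z-scores, in the style of a
# rho-HESS output, plus the segment-level aggregation statistics built on it.

#' Construct a local genetic correlation dataset
#'
#' @param map data.frame with `segment_id`, `chrom`, `start`, `end`.
#' @param h2 data.frame with `segment_id`, `trait`, `h2` (local heritability
#'   per segment; unitless, non-negative).
#' @param pairs data.frame with `segment_id`, `trait_a`, `trait_b`, `cov`
#'   (local genetic covariance) and `z` (local correlation z-score).
#' @return A `local_rg` object.
#' @export
local_rg <- function(map, h2, pairs) {
  stop_if_not(all(h2$h2 >= 0, na.rm = TRUE), "local h2 must be non-negative")
  stop_if_not(all(is.finite(pairs$z)), "z-scores must be finite")
  stop_if_not(all(pairs$segment_id %in% map$segment_id),
              "pair rows reference unknown segment ids")
  stop_if_not(!anyDuplicated(pairs[, c("segment_id", "trait_a", "trait_b")]),
              "one row per (segment, trait pair) expected")
  structure(list(map = map, h2 = h2, pairs = pairs,
                 traits = sort(unique(c(h2$trait, pairs$trait_a, pairs$trait_b)))),
            class = "local_rg")
}

#' @export
print.local_rg <- function(x, ...) {
  cat("Local genetic correlation dataset\n")
  cat("  segments:   ", nrow(x$map), "\n")
  cat("  traits:     ", length(x$traits), "\n")
  cat("  trait pairs:", nrow(unique(x$pairs[, c("trait_a", "trait_b")])), "\n")
  invisible(x)
}

#' Write a local genetic correlation dataset as TSV
#'
#' One flat tab-separated file with columns `segment_id, chr, start, end,
#' trait, h2, partner_trait, cov, z`. Heritability-only rows carry `"."` in
#' the pair columns; pair rows carry the heritability of `trait` in that
#' segment. Missing values are written as `"."`.
#'
#' @param x A `local_rg` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_local_rg <- function(x, path) {
  coord <- x$map[match(x$h2$segment_id, x$map$segment_id), c("chrom", "start", "end")]
  h2_rows <- data.frame(
    segment_id = x$h2$segment_id, chr = coord$chrom,
    start = coord$start, end = coord$end,
    trait = x$h2$trait, h2 = x$h2$h2,
    partner_trait = ".", cov = ".", z = ".",
    stringsAsFactors = FALSE
  )
  key <- paste(x$pairs$segment_id, x$pairs$trait_a)
  h2_lookup <- setNames(x$h2$h2, paste(x$h2$segment_id, x$h2$trait))
  coord_p <- x$map[match(x$pairs$segment_id, x$map$segment_id), c("chrom", "start", "end")]
  pair_rows <- data.frame(
    segment_id = x$pairs$segment_id, chr = coord_p$chrom,
    start = coord_p$start, end = coord_p$end,
    trait = x$pairs$trait_a, h2 = unname(h2_lookup[key]),
    partner_trait = x$pairs$trait_b,
    cov = x$pairs$cov, z = x$pairs$z,
    stringsAsFactors = FALSE
  )
  out <- rbind(h2_rows, pair_rows)
  out <- out[order(out$segment_id, out$trait, out$partner_trait), ]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = ".")
  invisible(path)
}

#' Read a local genetic correlation dataset from TSV
#'
#' Expects the dialect written by [write_local_rg()]: tab-separated with a
#' header and `"."` for missing. Pair rows whose `z` is missing are dropped
#' with a message reporting the count.
#'
#' @param path Input TSV path.
#' @return A `local_rg` object.
#' @export
read_local_rg <- function(path) {
  stop_if_not(file.exists(path), paste("file not found:", path))
  raw <- read.delim(path, sep = "\t", na.strings = ".",
                    stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("segment_id", "chr", "start", "end", "trait", "h2",
                "partner_trait", "cov", "z")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("local rg file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0) {
    warning("empty local rg file: returning an empty dataset")
    empty_map <- data.frame(segment_id = integer(), chrom = character(),
                            start = numeric(), end = numeric())
    return(structure(list(map = empty_map,
                          h2 = data.frame(segment_id = integer(),
                                          trait = character(), h2 = numeric()),
                          pairs = data.frame(segment_id = integer(),
                                             trait_a = character(),
                                             trait_b = character(),
                                             cov = numeric(), z = numeric()),
                          traits = character()),
                     class = "local_rg"))
  }
  map <- unique(data.frame(segment_id = raw$segment_id, chrom = raw$chr,
                           start = raw$start, end = raw$end,
                           stringsAsFactors = FALSE))
  map <- map[order(map$segment_id), ]
  rownames(map) <- NULL
  h2 <- unique(raw[!is.na(raw$h2), c("segment_id", "trait", "h2")])
  rownames(h2) <- NULL
  pr <- raw[!is.na(raw$partner_trait), , drop = FALSE]
  n_missing_z <- sum(is.na(pr$z))
  if (n_missing_z > 0) {
    message("dropping ", n_missing_z, " pair row(s) with missing z")
    pr <- pr[!is.na(pr$z), , drop = FALSE]
  }
  pairs <- data.frame(segment_id = pr$segment_id, trait_a = pr$trait,
                      trait_b = pr$partner_trait,
                      cov = as.numeric(pr$cov), z = as.numeric(pr$z),
                      stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  local_rg(map, h2, pairs)
}

#' Summed heritability across LD-independent segments
#'
#' Total heritability of a trait is the sum of its local heritabilities over
#' all segments in the dataset; when per-segment variances are available the
#' standard error is the square root of their sum.
#'
#' @param data A `local_rg` object.
#' @param trait Trait name.
#' @return List with `h2` (total) and `se` (`NULL` when no variances).
#' @export
sum_heritability <- function(data, trait) {
  rows <- data$h2[data$h2$trait == trait, , drop = FALSE]
  if (nrow(rows) == 0) stop("unknown trait: ", trait, call. = FALSE)
  se <- if ("var" %in% names(rows) && all(!is.na(rows$var))) sqrt(sum(rows$var)) else NULL
  list(h2 = sum(rows$h2), se = se)
}

#' Global genetic correlation aggregated from local covariances
#'
#' Sums the local genetic covariances across segments and normalizes by the
#' summed heritabilities of the two traits:
#' \deqn{r_g = \frac{\sum_j \mathrm{Cov}_j}{\sqrt{\sum_j h^2_{ja} \cdot \sum_j h^2_{jb}}}}
#' The sign of the covariance sum is preserved. On noisy input \eqn{|r_g|}
#' can exceed 1; it is reported unclipped with a warning.
#'
#' @param data A `local_rg` object.
#' @param trait_a,trait_b Trait names. The pair may be stored in either
#'   orientation; a trait paired with itself uses its h2 rows as covariance.
#' @return Signed global genetic correlation (numeric scalar).
#' @export
global_rg_from_local <- function(data, trait_a, trait_b) {
  h2a <- sum_heritability(data, trait_a)$h2
  h2b <- sum_heritability(data, trait_b)$h2
  denom <- sqrt(h2a * h2b)
  if (!is.finite(denom) || denom <= 0) {
    stop("zero total heritability: global rg undefined", call. = FALSE)
  }
  if (identical(trait_a, trait_b)) {
    covsum <- h2a  # cov of a trait with itself is its heritability
  } else {
    sel <- (data$pairs$trait_a == trait_a & data$pairs$trait_b == trait_b) |
      (data$pairs$trait_a == trait_b & data$pairs$trait_b == trait_a)
    if (!any(sel)) stop("no pair rows for (", trait_a, ", ", trait_b, ")", call. = FALSE)
    covsum <- sum(data$pairs$cov[sel])
  }
  rg <- covsum / denom
  if (abs(rg) > 1) {
    warning("aggregated |rg| exceeds 1 (", signif(rg, 4),
            "); reported unclipped")
  }
  rg
}

#' Flag segments with strong local genetic correlations
#'
#' Flags (segment, trait pair) rows whose |z| exceeds the threshold. The
#' default threshold of 4 corrects for multiple testing across ~2353
#' LD-independent segments.
#'
#' @param data A `local_rg` object.
#' @param threshold Positive z-score threshold (default 4).
#' @return A `flag_table`: data.frame of flagged rows with per-trait-pair
#'   counts in `attr(, "counts")` and the threshold in `attr(, "threshold")`.
#' @export
flag_strong_segments <- function(data, threshold = 4) {
  stop_if_not(threshold > 0, "threshold must be positive")
  flagged <- data$pairs[abs(data$pairs$z) > threshold, , drop = FALSE]
  rownames(flagged) <- NULL
  pair_key <- paste(flagged$trait_a, flagged$trait_b, sep = " x ")
  counts <- if (nrow(flagged)) table(pair_key) else table(character())
  structure(flagged, class = c("flag_table", "data.frame"),
            counts = counts, threshold = threshold)
}

#' Exclude segments overlapping the MHC window
#'
#' Removes every segment whose coordinates intersect the MHC window, from a
#' `local_rg` dataset (default) or from a bare `segment_map`.
#'
#' @param data A `local_rg` object, or `NULL` to filter `segmap` alone.
#' @param segmap A `segment_map`; defaults to the dataset's own map.
#' @param mhc_window Window to exclude.
#' @return Filtered object of the same class, with the number of removed
#'   segments in `attr(, "n_removed")`.
#' @export
exclude_mhc <- function(data = NULL, segmap = NULL,
                        mhc_window = default_mhc_window()) {
  if (is.null(segmap)) {
    stop_if_not(inherits(data, "local_rg"), "segmap required")
    segmap <- data$map
  }
  in_mhc <- segmap$chrom == mhc_window$chrom &
    segmap$start <= mhc_window$end & segmap$end >= mhc_window$start
  drop_ids <- segmap$segment_id[in_mhc]
  if (is.null(data)) {
    out <- segmap[!in_mhc, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "n_removed") <- length(drop_ids)
    return(out)
  }
  out <- data
  out$map <- data$map[!data$map$segment_id %in% drop_ids, , drop = FALSE]
  out$h2 <- data$h2[!data$h2$segment_id %in% drop_ids, , drop = FALSE]
  out$pairs <- data$pairs[!data$pairs$segment_id %in% drop_ids, , drop = FALSE]
  rownames(out$map) <- rownames(out$h2) <- rownames(out$pairs) <- NULL
  attr(out, "n_removed") <- length(drop_ids)
  out
}

#' Wide z-score matrix from a local genetic correlation dataset
#'
#' Arranges the per-segment correlation z-scores of one cognitive dimension
#' against every partner trait into a segments x traits matrix, the input
#' shape for clustering-tendency testing and embedding.
#'
#' @param data A `local_rg` object.
#' @param trait Cognitive dimension whose pair rows are used.
#' @return Numeric matrix, rownames = segment ids, colnames = partner traits.
#' @export
localrg_z_matrix <- function(data, trait) {
  pr <- data$pairs[data$pairs$trait_a == trait, , drop = FALSE]
  if (nrow(pr) == 0) stop("no pair rows with trait_a == ", trait, call. = FALSE)
  segs <- sort(unique(pr$segment_id))
  partners <- sort(unique(pr$trait_b))
  z <- matrix(NA_real_, length(segs), length(partners),
              dimnames = list(segs, partners))
  z[cbind(match(pr$segment_id, segs), match(pr$trait_b, partners))] <- pr$z
  z
}
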