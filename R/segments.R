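# Segment maps: ordered LD-independent genomic segments with coordinates and
# MHC flags. Coordinates are 1-based inclusive internally (hg19); BED export
# is 0-based half-open.

#' hg19 autosome lengths
#'
#' Reference lengths (bp) of the 22 human autosomes on the hg19/GRCh37
#' build. Chromosome X is excluded: the LD-independent segmentation that the
#' meta-locus analysis operates on covers the autosomes only.
#'
#' @return Named numeric vector of chromosome lengths, names `"chr1"`..`"chr22"`.
#' @export
hg19_autosome_lengths <- function() {
  setNames(
    c(249250621, 243199373, 198022430, 191154276, 180915260, 171115067,
      159138663, 146364022, 141213431, 135534747, 135006516, 133851895,
      115169878, 107349540, 102531392, 90354753, 81195210, 78077248,
      59128983, 63025520, 48129895, 51304566),
    paste0("chr", 1:22)
  )
}

#' Default MHC window
#'
#' The extended major histocompatibility complex region on chromosome 6
#' (hg19, 25-35 Mb), excluded from meta-locus clustering because of its
#' atypically long-range LD.
#'
#' @return List with `chrom`, `start`, `end` (1-based, bp).
#' @export
default_mhc_window <- function() {
  list(chrom = "chr6", start = 25e6, end = 35e6)
}

#' Simulate an ordered map of LD-independent segments
#'
#' Allocates `n_segments` segments to chromosomes proportionally to length
#' (largest-remainder rounding) and tiles each chromosome with contiguous,
#' non-overlapping segments whose widths are drawn from a normalized
#' exponential so every segment has positive width. Segments overlapping the
#' MHC window are flagged.
#'
#' @param n_segments Number of segments (>= 1).
#' @param genome_lengths Named vector of per-chromosome lengths in bp.
#' @param seed Integer seed.
#' @param mhc_window MHC window as returned by [default_mhc_window()].
#' @return A `segment_map`: data.frame with columns `segment_id`, `chrom`,
#'   `start`, `end`, `mhc`, ordered by chromosome then position.
#' @export
simulate_segment_map <- function(n_segments,
                                 genome_lengths = hg19_autosome_lengths(),
                                 seed = 1L,
                                 mhc_window = default_mhc_window()) {
  stop_if_not(n_segments >= 1, "n_segments must be >= 1")
  stop_if_not(all(genome_lengths > 0), "genome_lengths must be positive")
  stop_if_not(length(genome_lengths) >= 1 && !is.null(names(genome_lengths)),
              "genome_lengths must be a named vector")

  # Largest-remainder allocation proportional to chromosome length; every
  # chromosome keeps at least one segment when n_segments allows.
  share <- n_segments * genome_lengths / sum(genome_lengths)
  alloc <- floor(share)
  rem <- n_segments - sum(alloc)
  if (rem > 0) {
    ord <- order(share - alloc, genome_lengths, decreasing = TRUE)
    alloc[ord[seq_len(rem)]] <- alloc[ord[seq_len(rem)]] + 1
  }

  out <- with_seed(seed, {
    rows <- lapply(names(genome_lengths), function(ch) {
      k <- alloc[[ch]]
      if (k == 0) return(NULL)
      w <- rexp(k)
      bounds <- round(cumsum(w) / sum(w) * genome_lengths[[ch]])
      bounds <- pmax(bounds, seq_len(k))  # guarantee start < end everywhere
      bounds[k] <- genome_lengths[[ch]]
      start <- c(1, head(bounds, -1) + 1)
      data.frame(chrom = ch, start = start, end = bounds,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  out$segment_id <- seq_len(nrow(out))
  out$mhc <- out$chrom == mhc_window$chrom &
    out$start <= mhc_window$end & out$end >= mhc_window$start
  out <- out[, c("segment_id", "chrom", "start", "end", "mhc")]
  class(out) <- c("segment_map", "data.frame")
  attr(out, "mhc_window") <- mhc_window
  out
}

#' Convert a segment map to a GRanges object
#'
#' @param segmap A `segment_map`.
#' @return A [GenomicRanges::GRanges] with the segment ids as names and an
#'   `mhc` metadata column.
#' @export
segments_as_granges <- function(segmap) {
  gr <- GenomicRanges::GRanges(
    seqnames = segmap$chrom,
    ranges = IRanges::IRanges(start = segmap$start, end = segmap$end),
    mhc = segmap$mhc
  )
  names(gr) <- as.character(segmap$segment_id)
  gr
}

#' Write a segment map as BED
#'
#' @param segmap A `segment_map`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_segments_bed <- function(segmap, path) {
  rtracklayer::export.bed(segments_as_granges(segmap), path)
  invisible(path)
}

#' Read a segment map from BED
#'
#' @param path BED file path.
#' @param mhc_window MHC window used to re-derive the MHC flags.
#' @return A `segment_map`.
#' @export
read_segments_bed <- function(path, mhc_window = default_mhc_window()) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(
    segment_id = if (!is.null(gr$name)) as.integer(gr$name) else seq_along(gr),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$segment_id), , drop = FALSE]
  rownames(out) <- NULL
  out$mhc <- out$chrom == mhc_window$chrom &
    out$start <= mhc_window$end & out$end >= mhc_window$start
  class(out) <- c("segment_map", "data.frame")
  attr(out, "mhc_window") <- mhc_window
  out
}

# Segment id containing each genomic midpoint (NA when outside every
# segment). Used for gene-to-meta-locus assignment.
locate_in_segments <- function(segmap, chrom, pos) {
  res <- rep(NA_integer_, length(pos))
  for (ch in unique(chrom)) {
    seg <- segmap[segmap$chrom == ch, , drop = FALSE]
    if (nrow(seg) == 0) next
    sel <- which(chrom == ch)
    i <- findInterval(pos[sel], seg$start)
    ok <- i >= 1 & i <= nrow(seg)
    ok[ok] <- pos[sel][ok] <= seg$end[i[ok]]
    res[sel[ok]] <- seg$segment_id[i[ok]]
  }
  res
}
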