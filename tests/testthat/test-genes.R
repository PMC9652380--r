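make_evidence <- function(n = 10, seed = 31) {
  withr::with_seed(seed, {
    ev <- data.frame(
      gene = sprintf("G%03d", seq_len(n)),
      chrom = "chr1",
      start = seq(1e6, by = 1e6, length.out = n),
      end = seq(1e6, by = 1e6, length.out = n) + 1e4,
      magma_p = runif(n),
      pops_score = rnorm(n),
      twas_brain_p = runif(n),
      twas_cortex_p = runif(n),
      heidi_p = runif(n, 0.2, 1),
      credible = FALSE
    )
    class(ev) <- c("gene_evidence", "data.frame")
    attr(ev, "manifest") <- default_evidence_manifest()
    ev
  })
}

test_that("percentile filtering keeps the better half per method", {
  ev <- make_evidence(10)
  attr(ev, "manifest") <- list(p_cols = "magma_p", score_cols = character(),
                               twas_cols = character(), heidi_col = NULL,
                               credible_col = NULL)
  out <- prioritize_genes(ev, pct_cutoff = 0.5)
  expect_equal(nrow(out), 5)
  expect_true(all(out$magma_p <= sort(ev$magma_p)[5]))
  expect_error(prioritize_genes(ev[0, ]), "empty")
})

test_that("credible genes are retained regardless of filters", {
  ev <- make_evidence(20, seed = 32)
  worst <- which.max(ev$magma_p)
  ev$magma_p[worst] <- 1
  ev$pops_score[worst] <- min(ev$pops_score) - 10
  ev$twas_brain_p[worst] <- 1
  ev$twas_cortex_p[worst] <- 1
  ev$credible[worst] <- TRUE
  out <- prioritize_genes(ev, pct_cutoff = 0.25)
  expect_true(ev$gene[worst] %in% out$gene)
  support <- attr(out, "support")
  expect_true(support[out$gene == ev$gene[worst], "credible"])
})

test_that("heterogeneity-flagged genes lose their transcriptome support", {
  ev <- make_evidence(20, seed = 33)
  attr(ev, "manifest") <- list(p_cols = character(), score_cols = character(),
                               twas_cols = c("twas_brain_p", "twas_cortex_p"),
                               heidi_col = "heidi_p", credible_col = NULL)
  best <- which.min(ev$twas_brain_p + ev$twas_cortex_p)
  ev$heidi_p[best] <- 0.001
  out <- prioritize_genes(ev, pct_cutoff = 0.5)
  expect_false(ev$gene[best] %in% out$gene)
})

test_that("relaxing the percentile cutoff never drops a retained gene", {
  ev <- make_evidence(50, seed = 34)
  tight <- prioritize_genes(ev, pct_cutoff = 0.3)
  loose <- prioritize_genes(ev, pct_cutoff = 0.6)
  expect_true(all(tight$gene %in% loose$gene))
})

test_that("planted driver genes overwhelmingly survive prioritization", {
  rates <- vapply(1:10, function(s) {
    sim <- planted_sim(n_segments = 150, k_true = 4, n_traits = 4,
                       seed = 700 + s)
    ge <- simulate_gene_evidence(sim$segmap, sim$labels, 800,
                                 driver_clusters = c(1, 2),
                                 seed = 800 + s)
    mid <- floor((ge$evidence$start + ge$evidence$end) / 2)
    seg <- metaloci:::locate_in_segments(sim$segmap, ge$evidence$chrom, mid)
    lab <- sim$labels[match(seg, sim$segmap$segment_id)]
    drivers <- ge$evidence$gene[lab %in% c(1, 2)]
    kept <- prioritize_genes(ge$evidence)$gene
    mean(drivers %in% kept)
  }, numeric(1))
  expect_gte(median(rates), 0.9)
})

test_that("gene-to-meta-locus assignment matches an interval-overlap oracle", {
  sim <- planted_sim(n_segments = 200, k_true = 3, n_traits = 3, seed = 35)
  ge <- simulate_gene_evidence(sim$segmap, sim$labels, 1000, seed = 36)
  ev <- assign_genes_to_metaloci(ge$evidence, sim$labels, sim$segmap)
  mid <- floor((ev$start + ev$end) / 2)
  oracle <- vapply(seq_len(nrow(ev)), function(i) {
    hit <- which(sim$segmap$chrom == ev$chrom[i] &
                   sim$segmap$start <= mid[i] & sim$segmap$end >= mid[i])
    if (length(hit) == 0) return(-1L)
    as.integer(sim$labels[hit])
  }, integer(1))
  expect_equal(ev$metalocus, oracle)

  # a gene outside every segment gets -1 with a warning
  out_gene <- ev[1, ]
  out_gene$chrom <- "chrX"
  out_gene$start <- 1
  out_gene$end <- 10
  expect_warning(res <- assign_genes_to_metaloci(out_gene, sim$labels,
                                                 sim$segmap), "outside")
  expect_equal(res$metalocus, -1L)
})

test_that("meta-locus gene universes are mutually exclusive", {
  sim <- planted_sim(n_segments = 150, k_true = 3, n_traits = 3, seed = 37)
  ge <- simulate_gene_evidence(sim$segmap, sim$labels, 600, seed = 38)
  ev <- assign_genes_to_metaloci(ge$evidence, sim$labels, sim$segmap)
  split_genes <- split(ev$gene, ev$metalocus)
  all_pairs <- combn(names(split_genes), 2)
  for (j in seq_len(ncol(all_pairs))) {
    expect_equal(length(intersect(split_genes[[all_pairs[1, j]]],
                                  split_genes[[all_pairs[2, j]]])), 0)
  }
})

test_that("inverse-rank scores follow the 1 - rank/N transform", {
  ev <- data.frame(gene = letters[1:4], pops_score = c(4, 3, 2, 1))
  out <- inverse_rank_score(ev)
  expect_equal(out$irs, c(0.75, 0.5, 0.25, 0))

  # order isomorphism and bounds on a larger random instance
  ev2 <- make_evidence(40, seed = 39)
  out2 <- inverse_rank_score(ev2)
  expect_equal(order(-out2$irs), order(-ev2$pops_score))
  expect_true(all(out2$irs >= 0 & out2$irs <= 1 - 1 / 40))
  expect_equal(min(out2$irs), 0)

  expect_warning(one <- inverse_rank_score(data.frame(gene = "a",
                                                      pops_score = 1)),
                 "single-gene")
  expect_equal(one$irs, 0)
})

test_that("druggability annotation is a row-preserving left join", {
  ev <- make_evidence(6, seed = 40)
  tiers <- data.frame(gene = c("G001", "G003", "G003"),
                      tier = c("Tier 1", "Tier 2", "Tier 3"))
  expect_warning(out <- annotate_druggability(ev, tiers), "duplicate")
  expect_equal(nrow(out), 6)
  expect_equal(out$druggability_tier[out$gene == "G001"], "Tier 1")
  expect_equal(out$druggability_tier[out$gene == "G003"], "Tier 2")
  expect_equal(out$druggability_tier[out$gene == "G002"], "none")
})
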