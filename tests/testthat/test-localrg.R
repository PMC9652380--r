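test_that("local-rg TSV writer round-trips with the reader", {
  sim <- planted_sim(n_segments = 40, k_true = 2, n_traits = 3, seed = 21)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_local_rg(sim$data, path)
  back <- read_local_rg(path)
  expect_equal(back$traits, sim$data$traits)
  ord <- function(df) df[do.call(order, df), ]
  for (part in c("h2", "pairs")) {
    a <- ord(sim$data[[part]])
    b <- ord(back[[part]])
    rownames(a) <- rownames(b) <- NULL
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("reader rejects malformed files and tolerates empty ones", {
  sim <- planted_sim(n_segments = 10, k_true = 2, n_traits = 2, seed = 22)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_local_rg(sim$data, path)
  tab <- read.delim(path)
  tab$cov <- NULL
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_local_rg(path), "cov")

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(c("segment_id", "chr", "start", "end", "trait", "h2",
                     "partner_trait", "cov", "z"), collapse = "\t"), empty)
  expect_warning(out <- read_local_rg(empty), "empty")
  expect_equal(nrow(out$pairs), 0)

  expect_error(read_local_rg("/nonexistent/file.tsv"), "not found")
})

test_that("summed heritability is additive and matches plain arithmetic", {
  map <- data.frame(segment_id = 1:3, chrom = "chr1",
                    start = c(1, 11, 21) * 1e6, end = c(10, 20, 30) * 1e6)
  h2 <- data.frame(segment_id = 1:3, trait = "CTP",
                   h2 = c(0.01, 0.02, 0.03))
  pairs <- data.frame(segment_id = 1:3, trait_a = "CTP", trait_b = "SCZ",
                      cov = 0, z = 0)
  d <- local_rg(map, h2, pairs)
  expect_equal(sum_heritability(d, "CTP")$h2, 0.06)
  expect_error(sum_heritability(d, "nope"), "unknown trait")

  # additivity under dataset partition
  sim <- planted_sim(n_segments = 60, k_true = 2, n_traits = 2, seed = 23)
  full <- sum_heritability(sim$data, "CTP")$h2
  first <- sim$data
  ids <- sim$data$map$segment_id
  half <- ids[1:30]
  first$h2 <- first$h2[first$h2$segment_id %in% half, ]
  second <- sim$data
  second$h2 <- second$h2[!second$h2$segment_id %in% half, ]
  expect_equal(sum_heritability(first, "CTP")$h2 +
                 sum_heritability(second, "CTP")$h2, full)
})

test_that("aggregated global rg matches identities and a brute-force oracle", {
  sim <- planted_sim(n_segments = 8, k_true = 2, n_traits = 2, seed = 24)
  d <- sim$data
  expect_equal(global_rg_from_local(d, "CTP", "CTP"), 1.0)

  tb <- d$traits[d$traits != "CTP"][1]
  # brute-force oracle: explicit sums on the tiny instance
  pr <- d$pairs[d$pairs$trait_b == tb, ]
  h2a <- d$h2[d$h2$trait == "CTP", ]
  h2b <- d$h2[d$h2$trait == tb, ]
  oracle <- sum(pr$cov) / sqrt(sum(h2a$h2) * sum(h2b$h2))
  expect_equal(global_rg_from_local(d, "CTP", tb), oracle)

  zero <- d
  zero$pairs$cov <- 0
  expect_equal(global_rg_from_local(zero, "CTP", tb), 0)
})

test_that("planted global rg is recovered from simulated local covariances", {
  vals <- vapply(1:20, function(s) {
    withr::with_seed(600 + s, {
      n <- 500
      h2a <- rgamma(n, 4, 4 / 1e-4)
      h2b <- rgamma(n, 4, 4 / 1e-4)
      covs <- 0.5 * sqrt(h2a * h2b) + rnorm(n, 0, 2e-5)
      map <- data.frame(segment_id = 1:n, chrom = "chr1",
                        start = seq(1, by = 2e5, length.out = n),
                        end = seq(1e5, by = 2e5, length.out = n))
      d <- local_rg(map,
                    data.frame(segment_id = rep(1:n, 2),
                               trait = rep(c("A", "B"), each = n),
                               h2 = c(h2a, h2b)),
                    data.frame(segment_id = 1:n, trait_a = "A",
                               trait_b = "B", cov = covs,
                               z = covs / 2e-5))
      global_rg_from_local(d, "A", "B")
    })
  }, numeric(1))
  expect_true(all(abs(vals - 0.5) < 0.05))
})

test_that("strong-segment flagging respects the threshold and is monotone", {
  map <- data.frame(segment_id = 1:3, chrom = "chr1",
                    start = c(1, 2, 3) * 1e6, end = c(1.5, 2.5, 3.5) * 1e6)
  h2 <- data.frame(segment_id = 1:3, trait = "CTP", h2 = 1e-4)
  pairs <- data.frame(segment_id = 1:3, trait_a = "CTP", trait_b = "SCZ",
                      cov = 1e-5, z = c(3.9, 4.1, -5.0))
  d <- local_rg(map, h2, pairs)
  fl <- flag_strong_segments(d)
  expect_equal(nrow(fl), 2)
  expect_equal(attr(fl, "threshold"), 4)
  expect_true(all(abs(fl$z) > 4))
  expect_equal(unname(attr(fl, "counts")[["CTP x SCZ"]]), 2)

  # counts monotone non-increasing in threshold
  sim <- planted_sim(n_segments = 100, k_true = 3, n_traits = 4, seed = 25)
  counts <- vapply(c(0.5, 1, 2, 3, 4),
                   function(th) nrow(flag_strong_segments(sim$data, th)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(flag_strong_segments(sim$data, -1), "positive")
})

test_that("MHC exclusion filters a local-rg dataset consistently", {
  sim <- planted_sim(n_segments = 400, k_true = 2, n_traits = 2, seed = 26)
  out <- exclude_mhc(sim$data, sim$segmap)
  removed <- attr(out, "n_removed")
  expect_gt(removed, 0)
  expect_equal(nrow(out$map), 400 - removed)
  expect_equal(sum(sim$segmap$mhc), removed)
  expect_false(any(out$map$segment_id %in%
                     sim$segmap$segment_id[sim$segmap$mhc]))
  expect_equal(length(unique(out$pairs$segment_id)), 400 - removed)
})
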