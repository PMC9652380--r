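test_that("GMT files round-trip", {
  sets <- list(alpha = c("G1", "G2", "G3"), beta = c("G2", "G4"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_equal(back, sets)
})

test_that("the running-sum enrichment score matches the exhaustive oracle", {
  withr::with_seed(51, {
    for (rep in 1:10) {
      n <- 20
      scores <- sort(runif(n), decreasing = TRUE)
      names(scores) <- sprintf("G%02d", 1:n)
      m <- sample(3:8, 1)
      pos <- sort(sample(n, m))
      es_fast <- metaloci:::es_from_positions(unname(scores), pos)$es
      es_slow <- oracle_es(unname(scores), pos)
      expect_equal(es_fast, es_slow, tolerance = 1e-12)
    }
  })
})

test_that("the enrichment engine agrees with the standard implementation", {
  withr::with_seed(52, {
    n <- 200
    scores <- setNames(sort(runif(n), decreasing = TRUE),
                       sprintf("G%03d", 1:n))
    sets <- list(top = names(scores)[c(1:12, 30:34)],
                 spread = sample(names(scores), 20),
                 low = names(scores)[170:190])
  })
  mine <- gsea_preranked(scores, sets, n_perm = 200, min_size = 5,
                         max_size = 100, seed = 53)
  ref <- suppressWarnings(
    fgsea::fgseaSimple(sets, scores, nperm = 10, gseaParam = 1,
                       minSize = 5, maxSize = 100)
  )
  for (nm in mine$set) {
    expect_equal(mine$ES[mine$set == nm], ref$ES[ref$pathway == nm],
                 tolerance = 1e-10)
  }
})

test_that("a set covering the whole universe scores exactly 1", {
  scores <- setNames(seq(1, 0.1, length.out = 10), letters[1:10])
  res <- gsea_preranked(scores, list(all = letters[1:10]), n_perm = 10,
                        min_size = 1, max_size = 10, seed = 1)
  expect_equal(res$ES, 1)
})

test_that("top-ranked sets enrich strongly and carry their drivers", {
  withr::with_seed(54, {
    n <- 300
    scores <- setNames(sort(rbeta(n, 1, 1), decreasing = TRUE),
                       sprintf("G%03d", 1:n))
    sets <- c(list(planted = names(scores)[1:25]),
              lapply(1:10, function(i) sample(names(scores), 25)))
    names(sets)[-1] <- paste0("null", 1:10)
  })
  res <- gsea_preranked(scores, sets, n_perm = 500, seed = 55)
  planted <- res[res$set == "planted", ]
  expect_gt(planted$ES, 0.5)
  expect_lt(planted$pval, 0.01)
  expect_true(all(planted$leading_edge[[1]] %in% names(scores)[1:25]))
  expect_gt(length(planted$leading_edge[[1]]), 10)
})

test_that("hypergeometric over-representation matches the closed-form tail sum", {
  universe <- sprintf("G%04d", 1:1000)
  gene_list <- universe[1:50]
  set10 <- c(universe[1:5], universe[900:904])  # overlap 5 of size 10
  res <- hypergeometric_ora(gene_list, universe, list(s = set10))
  expect_equal(res$pval, oracle_hyper_p(5, 10, 50, 1000), tolerance = 1e-12)
  expect_equal(res$overlap, 5)

  # list = universe makes every overlap certain
  res_all <- hypergeometric_ora(universe, universe, list(s = set10))
  expect_equal(res_all$pval, 1)

  # overlaps below the minimum are not tested
  tiny <- list(t = c(universe[1:2], universe[500:520]))
  res_tiny <- hypergeometric_ora(gene_list, universe, tiny, min_overlap = 3)
  expect_equal(nrow(res_tiny), 0)

  expect_error(hypergeometric_ora("G1", character(), list(s = "G1")),
               "empty universe")
})

test_that("consensus requires primary significance plus secondary support", {
  gsea <- data.frame(set = c("a", "b", "c"), size = 20,
                     ES = c(0.8, 0.7, 0.6), NES = c(2, 1.8, 1.5),
                     pval = c(0.001, 0.001, 0.2),
                     qval = c(0.01, 0.01, 0.3))
  gsea$leading_edge <- I(list(c("G1", "G2"), c("G3"), c("G4")))
  ora_hit <- data.frame(set = "a", size = 20, overlap = 5, pval = 0.001,
                        qval = 0.01)
  cons <- consensus_sets(gsea, list(ora = ora_hit))
  expect_equal(cons$set, "a")        # b: GSEA only; c: not significant
  expect_equal(driver_genes(cons), c("G1", "G2"))

  # relaxed secondary threshold admits reduced-redundancy support
  ora_weak <- data.frame(set = "b", size = 20, overlap = 4, pval = 0.02,
                         qval = 0.08)
  cons2 <- consensus_sets(gsea, list(std = ora_hit, nored = ora_weak),
                          ora_q = c(0.05, 0.1))
  expect_equal(sort(cons2$set), c("a", "b"))
})
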