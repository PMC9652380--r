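test_that("planted z profiles are recovered from the simulated matrices", {
  # mean within-cluster profile should correlate > 0.95 with the truth
  cors <- unlist(lapply(1:20, function(s) {
    sim <- planted_sim(n_segments = 300, k_true = 3, n_traits = 6,
                       noise_sd = 0.3, seed = 900 + s)
    z <- localrg_z_matrix(sim$data, "CTP")
    vapply(seq_len(3), function(k) {
      prof <- colMeans(z[sim$labels == k, , drop = FALSE])
      cor(prof, sim$planted$trait_profiles[k, ])
    }, numeric(1))
  }))
  expect_gt(mean(cors), 0.95)
})

test_that("the zero-noise limit reproduces cluster profiles exactly", {
  segmap <- tiny_segmap(60)
  traits <- c("a", "b", "c")
  prof <- random_trait_profiles(2, traits, seed = 31)
  planted <- planted_structure(2, prof, noise_sd = 1e-12,
                               frac_noise_segments = 0)
  sim <- simulate_local_rg(segmap, planted, traits, seed = 32)
  z <- localrg_z_matrix(sim$data, "CTP")
  for (k in 1:2) {
    rows <- z[sim$labels == k, , drop = FALSE]
    expect_equal(unname(rows),
                 matrix(prof[k, ], nrow(rows), 3, byrow = TRUE),
                 tolerance = 1e-6)
  }
  # planted labels recoverable by nearest-profile assignment
  nearest <- apply(z, 1, function(r) {
    which.min(colSums((t(prof) - r)^2))
  })
  expect_equal(unname(nearest), sim$labels)
})

test_that("pure-noise matrices look spatially random to the Hopkins test", {
  hs <- vapply(1:10, function(s) {
    segmap <- simulate_segment_map(300, seed = 40 + s)
    planted <- planted_structure(2, matrix(0, 2, 4), noise_sd = 1,
                                 frac_noise_segments = 0.999)
    sim <- simulate_local_rg(segmap, planted, letters[1:4], seed = 50 + s)
    hopkins(localrg_z_matrix(sim$data, "CTP"), seed = 60 + s)$H
  }, numeric(1))
  expect_lt(abs(mean(hs) - 0.5), 0.15)
})

test_that("covariance sign always agrees with the z-score sign", {
  sim <- planted_sim(n_segments = 200, k_true = 3, n_traits = 5,
                     frac_noise = 0.1, seed = 33)
  expect_true(all(sign(sim$data$pairs$cov) == sign(sim$data$pairs$z)))
  expect_true(all(sim$data$h2$h2 > 0))
})

test_that("all generators are deterministic under a fixed seed", {
  a <- planted_sim(n_segments = 80, seed = 34)
  b <- planted_sim(n_segments = 80, seed = 34)
  expect_identical(a$data$pairs, b$data$pairs)
  expect_identical(a$labels, b$labels)

  ev1 <- simulate_gene_evidence(a$segmap, a$labels, 200, seed = 35)
  ev2 <- simulate_gene_evidence(a$segmap, a$labels, 200, seed = 35)
  expect_identical(ev1$evidence, ev2$evidence)
  expect_identical(ev1$sets, ev2$sets)

  dg <- list(ml1 = c("G1", "G2"), ml2 = c("G3"))
  tr <- c(ml1 = "prenatal", ml2 = "adulthood")
  ex1 <- simulate_expression(dg, tr, n_donors = 5, seed = 36)
  ex2 <- simulate_expression(dg, tr, n_donors = 5, seed = 36)
  expect_identical(ex1, ex2)
})

test_that("gene evidence correlates with driver-cluster membership", {
  sim <- planted_sim(n_segments = 200, k_true = 4, n_traits = 4, seed = 37)
  ge <- simulate_gene_evidence(sim$segmap, sim$labels, 1000,
                               driver_clusters = c(1, 2), seed = 38)
  mid <- floor((ge$evidence$start + ge$evidence$end) / 2)
  seg <- metaloci:::locate_in_segments(sim$segmap, ge$evidence$chrom, mid)
  lab <- sim$labels[match(seg, sim$segmap$segment_id)]
  in_driver <- lab %in% c(1, 2)
  expect_gt(mean(ge$effects[in_driver]), mean(ge$effects[!in_driver]) + 1)
  expect_lt(mean(ge$evidence$magma_p[in_driver]),
            mean(ge$evidence$magma_p[!in_driver]))
})

test_that("a null effect makes method rankings exchangeable", {
  sim <- planted_sim(n_segments = 100, k_true = 2, n_traits = 3, seed = 39)
  ge <- simulate_gene_evidence(sim$segmap, sim$labels, 500,
                               effect_sd = 0, effect_boost = 0, seed = 40)
  tau <- cor(rank(ge$evidence$magma_p), rank(-ge$evidence$pops_score),
             method = "kendall")
  expect_lt(abs(tau), 0.1)
})

test_that("expression trajectories plant the promised slopes and intercepts", {
  dg <- list(m1 = sprintf("G%d", 1:5), m2 = sprintf("H%d", 1:5),
             m3 = sprintf("K%d", 1:5))
  tr <- c(m1 = "prenatal", m2 = "adulthood", m3 = "flat")
  ex <- simulate_expression(dg, tr, n_donors = 40, donor_sd = 0,
                            resid_sd = 1e-12, seed = 41)
  for (ml in names(dg)) {
    sub <- ex[ex$gene %in% dg[[ml]], ]
    slope <- coef(lm(expression ~ age_weeks + gene, data = sub))[["age_weeks"]]
    expected <- c(prenatal = -0.003, adulthood = 0.003, flat = 0)[[tr[[ml]]]]
    expect_equal(slope, expected, tolerance = 1e-6)
  }
  expect_error(simulate_expression(dg, c(m1 = "sometime", m2 = "flat",
                                         m3 = "flat"), n_donors = 5),
               "invalid trajectory")
  expect_error(simulate_expression(dg, tr, n_donors = 2), ">= 3")

  # donor random intercepts create between-donor variance at matched ages
  ex2 <- simulate_expression(dg["m3"], tr["m3"], n_donors = 30,
                             donor_sd = 2, resid_sd = 0.1, seed = 42)
  donor_means <- tapply(ex2$expression, ex2$donor, mean)
  expect_gt(stats::var(donor_means), 0.5)
})

test_that("the iris fixture is the canonical 150 x 4 three-species table", {
  ir <- load_iris_fixture()
  expect_equal(nrow(ir$x), 150)
  expect_equal(ncol(ir$x), 4)
  expect_equal(unname(table(ir$species)), c(50L, 50L, 50L),
               ignore_attr = TRUE)
})
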