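make_rg_matrix <- function(n_cog = 8, n_psy = 6, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(runif(n_cog * n_psy, -0.6, 0.6), n_cog, n_psy)
    dimnames(m) <- list(paste0("cog", seq_len(n_cog)),
                        paste0("psy", seq_len(n_psy)))
    m
  })
}

# Column traits in tight groups, so small-k partitions have no singletons.
grouped_rg_matrix <- function(n_cog = 8, groups = 3, per_group = 3,
                              seed = 1) {
  withr::with_seed(seed, {
    centers <- matrix(runif(n_cog * groups, -0.6, 0.6), n_cog, groups)
    m <- centers[, rep(seq_len(groups), each = per_group)] +
      matrix(rnorm(n_cog * groups * per_group, 0, 0.03), n_cog)
    dimnames(m) <- list(paste0("cog", seq_len(n_cog)),
                        paste0("psy", seq_len(groups * per_group)))
    m
  })
}

test_that("rg matrix IO validates completeness and range", {
  m <- make_rg_matrix()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_rg_matrix(m, path)
  back <- read_rg_matrix(path)
  expect_equal(back, m, tolerance = 1e-12)

  m2 <- m
  m2[1, 1] <- 1.2
  write_rg_matrix(m2, path)
  expect_warning(read_rg_matrix(path), "outside")
  m2[1, 1] <- 3
  write_rg_matrix(m2, path)
  expect_error(read_rg_matrix(path), "implausible")
})

test_that("principal-component loadings follow the correlation definition", {
  m <- make_rg_matrix(seed = 2)
  m[2, ] <- m[1, ]  # two identical cognitive profiles
  res <- pca_with_loadings(m)
  expect_equal(res$loadings[1, ], res$loadings[2, ], tolerance = 1e-12)
  # loadings are literally Pearson correlations with the score vectors
  expect_equal(res$loadings[1, 1], cor(m[1, ], res$scores[, 1]))

  # rank-1 structure concentrates variance on PC1
  u <- seq(-1, 1, length.out = 8)
  v <- seq(0.2, 0.8, length.out = 6)
  r1 <- outer(u, v)
  dimnames(r1) <- dimnames(make_rg_matrix())
  res1 <- pca_with_loadings(r1)
  expect_gt(res1$var_explained[1], 0.999)

  const <- make_rg_matrix(seed = 3)
  const[4, ] <- 0.3
  expect_warning(resc <- pca_with_loadings(const), "constant")
  expect_true(all(is.na(resc$loadings[4, ])))
})

test_that("a planted two-factor matrix puts the seed traits on top", {
  hits <- vapply(1:20, function(s) {
    withr::with_seed(400 + s, {
      # a dominant factor (as the most pleiotropic trait) and a weaker
      # orthogonal one, each echoed by noisy derivative traits
      n_psy <- 17
      f1 <- rnorm(n_psy)
      f2 <- rnorm(n_psy)
      f2 <- f2 - f1 * sum(f1 * f2) / sum(f1^2)  # orthogonalize
      f1 <- f1 / sd(f1)
      f2 <- 0.6 * f2 / sd(f2)
      rows <- list(seed1 = f1, seed2 = f2)
      for (i in 1:4) {
        rows[[paste0("mixa", i)]] <- runif(1, 0.5, 0.9) * f1 +
          rnorm(n_psy, 0, 0.3)
      }
      for (i in 1:2) {
        rows[[paste0("mixb", i)]] <- runif(1, 0.5, 0.9) * f2 +
          rnorm(n_psy, 0, 0.3)
      }
      m <- do.call(rbind, rows)
      colnames(m) <- paste0("psy", 1:n_psy)
      res <- pca_with_loadings(m)
      top1 <- rownames(m)[which.max(abs(res$loadings[, 1]))]
      top2 <- rownames(m)[which.max(abs(res$loadings[, 2]))]
      top1 == "seed1" && top2 == "seed2"
    })
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("the cluster scan stops at singletons and finds planted pairs", {
  # four column-traits in two tight pairs
  base <- matrix(rnorm(40), 10, 4)
  m <- cbind(base[, 1], base[, 1] + 0.01, base[, 3], base[, 3] + 0.01)
  m <- m + withr::with_seed(9, matrix(rnorm(40, 0, 0.005), 10, 4))
  dimnames(m) <- list(paste0("cog", 1:10), paste0("psy", 1:4))
  scan <- cluster_scan(m, k_min = 2, seed = 5)
  expect_equal(scan$chosen$k, 2)
  pair_labels <- unname(scan$chosen$labels)
  expect_equal(pair_labels[1], pair_labels[2])
  expect_equal(pair_labels[3], pair_labels[4])
  expect_false(pair_labels[1] == pair_labels[3])

  # an outlier column gets isolated early, capping k_max low
  m2 <- grouped_rg_matrix(groups = 2, per_group = 4, seed = 6)
  m2[, 8] <- m2[, 8] + 3
  scan2 <- suppressWarnings(cluster_scan(m2, k_min = 2, seed = 7))
  expect_lte(scan2$k_max, 3)

  expect_error(cluster_scan(make_rg_matrix(n_psy = 2), k_min = 2), "fewer")
})

test_that("scan results are invariant to input permutation up to relabeling", {
  m <- grouped_rg_matrix(groups = 3, per_group = 3, seed = 8)
  scan <- cluster_scan(m, seed = 9)
  perm <- withr::with_seed(10, sample(ncol(m)))
  scan_p <- cluster_scan(m[, perm], seed = 9)
  expect_equal(scan$k_max, scan_p$k_max)
  sol <- scan$solutions[["pam_k2"]]$labels
  sol_p <- scan_p$solutions[["pam_k2"]]$labels[order(perm)]
  expect_equal(ari(sol, sol_p), 1)
})

test_that("scaled fit indices are invariant to affine transforms of raw indices", {
  raw <- matrix(c(1, 3, 2, 10, 30, 20, -1, -3, -2), ncol = 3)
  colnames(raw) <- c("a", "b", "c")
  s1 <- scale_fit_indices(raw)
  s2 <- scale_fit_indices(raw * 7 + 100)
  expect_equal(unclass(s1)[, ], unclass(s2)[, ], tolerance = 1e-12)
})

test_that("solution selection prefers stability only to break ties", {
  m <- grouped_rg_matrix(n_cog = 6, groups = 3, per_group = 3, seed = 11)
  scan <- cluster_scan(m, seed = 12)
  sel <- select_solution(scan, bootstrap_reps = 20, seed = 13)
  expect_equal(sel$summed_score, max(scan$summed))
  expect_true(sel$k >= scan$k_min && sel$k <= scan$k_max)

  # forced tie: stability decides
  scan2 <- scan
  scan2$summed[] <- 1
  sel2 <- select_solution(scan2, bootstrap_reps = 20, seed = 14)
  expect_false(is.null(sel2$stability))
  expect_equal(unname(sel2$summed_score), 1)
})
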