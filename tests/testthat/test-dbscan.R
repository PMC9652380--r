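make_blobs3 <- function(n_per = 20, seed = 1) {
  withr::with_seed(seed, {
    centers <- matrix(c(0, 0, 10, 0, 0, 10), ncol = 2, byrow = TRUE)
    do.call(rbind, lapply(1:3, function(k) {
      sweep(matrix(rnorm(2 * n_per, 0, 0.3), ncol = 2), 2, centers[k, ], "+")
    }))
  })
}

test_that("density clustering recovers separated blobs and flags noise", {
  x <- make_blobs3(seed = 2)
  m <- dbscan_fit(x, eps = 2, min_pts = 5)
  expect_equal(m$n_clusters, 3)
  expect_equal(m$n_noise, 0)
  expect_equal(ari(m$labels, rep(1:3, each = 20)), 1)

  # an isolated point becomes noise
  x2 <- rbind(x, c(50, 50))
  m2 <- dbscan_fit(x2, eps = 2, min_pts = 5)
  expect_equal(m2$labels[61], -1L)
  expect_equal(m2$n_noise, 1)
})

test_that("silhouette summaries agree with a brute-force oracle", {
  x <- make_blobs3(n_per = 20, seed = 3)
  m <- dbscan_fit(x, eps = 2, min_pts = 5)
  dm <- as.matrix(dist(x))
  s_pkg <- silhouette_widths(dm, m$labels)
  s_oracle <- oracle_silhouette(dm, m$labels)
  expect_equal(s_pkg, s_oracle, tolerance = 1e-12)
  expect_equal(m$silhouette[["median"]], median(s_oracle))
  expect_equal(m$silhouette[["p75"]],
               unname(quantile(s_oracle, 0.75)))
  expect_equal(m$silhouette[["max"]], max(s_oracle))

  # and with the field-standard implementation as a second oracle
  s_cluster <- cluster::silhouette(m$labels, dist(x))[, "sil_width"]
  expect_equal(unname(s_pkg), unname(s_cluster), tolerance = 1e-12)
})

test_that("the k-NN elbow lands between intra- and inter-blob scales", {
  x <- two_blobs(n_per = 30, gap = 10, sd = 0.03, seed = 4)
  el <- knn_elbow_eps(x, k = 5)
  expect_gt(el$eps, 0.001)
  expect_lt(el$eps, 10)
  expect_equal(length(el$curve), nrow(x))

  # uniform grid: eps close to the grid spacing
  grid <- as.matrix(expand.grid(x = seq(0, 9), y = seq(0, 9)))
  elg <- knn_elbow_eps(grid, k = 5)
  expect_lt(abs(elg$eps - sqrt(2)), 0.5)

  # all-equal distances short-circuit with a warning
  four <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1), ncol = 2, byrow = TRUE)
  expect_warning(el_eq <- knn_elbow_eps(four, k = 3), "equal")
  expect_equal(el_eq$eps, sqrt(2))
})

test_that("the epsilon sweep follows the stepwise inflation rule", {
  x <- make_blobs3(seed = 5)
  models <- dbscan_scan(x, eps0 = 0.2, min_pts = 5, j_max = 5)
  expect_equal(attr(models, "eps_grid"), c(0.2, 0.4, 0.6, 0.8, 1.0, 1.2))
  expect_equal(length(models), 6)

  # at a radius spanning the whole cloud, everything is one cluster
  big <- dbscan_fit(x, eps = 100, min_pts = 5)
  expect_equal(big$n_clusters, 1)
  expect_equal(big$n_noise, 0)
})

test_that("model selection rejects negative-median models and breaks ties on noise", {
  mk <- function(median_s, n_noise, n = 60, eps = 1) {
    structure(list(eps = eps, min_pts = 5,
                   labels = c(rep(1:2, length.out = n - n_noise),
                              rep(-1L, n_noise)),
                   n_clusters = 2, n_noise = n_noise,
                   silhouette = c(median = median_s, mean = median_s,
                                  p75 = median_s + 0.1,
                                  max = median_s + 0.2),
                   rejected = median_s < 0),
              class = "dbscan_model")
  }
  chosen <- select_dbscan_model(list(mk(-0.1, 0), mk(0.4, 10), mk(0.4, 2)))
  expect_equal(chosen$n_noise, 2)
  tab <- attr(chosen, "score_table")
  expect_equal(nrow(tab), 2)  # rejected model excluded

  expect_error(select_dbscan_model(list(mk(-0.2, 0), mk(-0.3, 5))),
               "rejected")
})

test_that("planted clusters survive the full scan-and-select path at small scale", {
  x <- make_blobs3(n_per = 25, seed = 6)
  el <- knn_elbow_eps(x, k = 5)
  models <- dbscan_scan(x, eps0 = el$eps, min_pts = 5)
  chosen <- select_dbscan_model(models)
  keep <- chosen$labels != -1
  expect_gte(ari(chosen$labels[keep], rep(1:3, each = 25)[keep]), 0.95)
})
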