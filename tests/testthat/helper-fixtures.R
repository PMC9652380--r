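# Shared fixtures and independent oracles, built in code at test time.

# Small deterministic segment map for unit tests.
tiny_segmap <- function(n = 50, seed = 101) {
  simulate_segment_map(n, seed = seed)
}

# Planted local-rg simulation at a configurable scale.
planted_sim <- function(n_segments = 300, k_true = 3, n_traits = 6,
                        noise_sd = 0.3, frac_noise = 0, profile_sd = 2,
                        seed = 1) {
  segmap <- simulate_segment_map(n_segments, seed = seed)
  traits <- sprintf("t%02d", seq_len(n_traits))
  planted <- planted_structure(
    k_true,
    random_trait_profiles(k_true, traits, profile_sd, seed = seed + 1),
    noise_sd = noise_sd, frac_noise_segments = frac_noise
  )
  sim <- simulate_local_rg(segmap, planted, traits, seed = seed + 2)
  list(segmap = segmap, planted = planted, traits = traits,
       data = sim$data, labels = sim$labels)
}

# Chance-corrected agreement between two partitions (closed form), used as
# an oracle-free metric; cross-checked against mclust in one test.
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(as.vector(tab))
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}

# Brute-force silhouette oracle, O(n^2) from first principles.
oracle_silhouette <- function(dm, labels) {
  n <- length(labels)
  vapply(seq_len(n), function(i) {
    own <- which(labels == labels[i])
    own <- setdiff(own, i)
    if (length(own) == 0) return(0)
    a <- mean(dm[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl) {
      mean(dm[i, labels == cl])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
}

# Exhaustive running-sum enrichment oracle: walks every position.
oracle_es <- function(scores_sorted, hit_positions) {
  n <- length(scores_sorted)
  hits <- seq_len(n) %in% hit_positions
  nr <- sum(scores_sorted[hits])
  miss_dec <- 1 / (n - sum(hits))
  run <- 0
  best <- 0
  for (t in seq_len(n)) {
    run <- if (hits[t]) run + scores_sorted[t] / nr else run - miss_dec
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# Closed-form upper-tail hypergeometric oracle.
oracle_hyper_p <- function(overlap, set_size, list_size, universe_size) {
  upper <- min(set_size, list_size)
  sum(vapply(overlap:upper, function(x) {
    choose(set_size, x) * choose(universe_size - set_size, list_size - x) /
      choose(universe_size, list_size)
  }, numeric(1)))
}

# Two well-separated Gaussian blobs in 2-D.
two_blobs <- function(n_per = 100, gap = 10, sd = 0.5, seed = 1) {
  withr::with_seed(seed, {
    rbind(matrix(rnorm(2 * n_per, 0, sd), ncol = 2),
          matrix(rnorm(2 * n_per, gap, sd), ncol = 2))
  })
}
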