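# Synthetic-data generators with planted ground truth. These emulate every
# input the pipeline consumes -- local genetic correlation tables, gene
# evidence, gene sets and longitudinal expression -- so that all downstream
# stages are testable without external downloads.

#' Planted latent cluster structure
#'
#' Describes the ground truth used by [simulate_local_rg()]: `k_true` latent
#' segment clusters, each with a trait-specific mean z-score profile, plus a
#' fraction of unassigned noise segments.
#'
#' @param k_true Number of latent clusters (>= 1).
#' @param trait_profiles `k_true` x n_traits matrix of per-cluster mean
#'   z-scores (columns named by trait, identical ordering across clusters).
#' @param noise_sd Within-cluster z standard deviation (> 0).
#' @param frac_noise_segments Fraction of segments belonging to no cluster,
#'   in `[0, 1)`.
#' @return A `planted_structure` object.
#' @export
planted_structure <- function(k_true, trait_profiles, noise_sd = 0.5,
                              frac_noise_segments = 0.05) {
  trait_profiles <- as.matrix(trait_profiles)
  stop_if_not(k_true >= 1, "k_true must be >= 1")
  stop_if_not(nrow(trait_profiles) == k_true,
              "trait_profiles must have k_true rows")
  stop_if_not(noise_sd > 0, "noise_sd must be > 0")
  stop_if_not(frac_noise_segments >= 0 && frac_noise_segments < 1,
              "frac_noise_segments must be in [0, 1)")
  structure(list(k_true = k_true, trait_profiles = trait_profiles,
                 noise_sd = noise_sd,
                 frac_noise_segments = frac_noise_segments),
            class = "planted_structure")
}

#' Draw well-separated cluster profiles
#'
#' Convenience constructor for planted mean z profiles: each cluster/trait
#' mean is drawn from Normal(0, `profile_sd`^2). With the default spread the
#' between-cluster profile distance is large relative to the default
#' within-cluster noise, emulating the strongly clustered structure local
#' genetic correlations exhibit.
#'
#' @param k Number of clusters.
#' @param traits Character vector of trait names.
#' @param profile_sd Spread of cluster means on the z scale (default 2).
#' @param seed Integer seed.
#' @return `k` x `length(traits)` matrix of means.
#' @export
random_trait_profiles <- function(k, traits, profile_sd = 2, seed = 1L) {
  with_seed(seed, {
    matrix(rnorm(k * length(traits), 0, profile_sd), nrow = k,
           dimnames = list(NULL, traits))
  })
}

#' Simulate a local genetic correlation dataset with planted clusters
#'
#' Each non-noise segment draws its z-score vector as the cluster mean plus
#' Normal(0, `noise_sd`) noise per trait; noise segments draw z ~ Normal(0, 1)
#' and carry label `-1` (the density-scan noise convention). Per-segment,
#' per-trait heritabilities are positive draws with mean `h2_scale`, and the
#' local covariance is derived as `cov = tanh(z / z_scale) * sqrt(h2_a h2_b)`
#' so the implied local correlation always agrees in sign with z.
#'
#' @param segmap A `segment_map`.
#' @param planted A `planted_structure` whose profile columns match `traits`.
#' @param traits Partner trait names (nonempty).
#' @param trait Name of the cognitive dimension paired with every partner
#'   trait (default `"CTP"`).
#' @param h2_scale Mean per-segment heritability (default `1e-4`, the order
#'   observed for highly polygenic cognitive phenotypes).
#' @param z_scale Scale of the z-to-correlation link (default 10).
#' @param seed Integer seed.
#' @return List with `data` (a `local_rg`) and `labels` (integer vector per
#'   segment; `-1` = noise).
#' @export
simulate_local_rg <- function(segmap, planted, traits, trait = "CTP",
                              h2_scale = 1e-4, z_scale = 10, seed = 1L) {
  stop_if_not(length(traits) >= 1, "traits must be nonempty")
  if (ncol(planted$trait_profiles) != length(traits)) {
    stop("trait_profiles dimension does not match traits", call. = FALSE)
  }
  n <- nrow(segmap)
  k <- planted$k_true
  with_seed(seed, {
    labels <- sample(rep_len(seq_len(k), n))
    n_noise <- round(planted$frac_noise_segments * n)
    if (n_noise > 0) labels[sample(n, n_noise)] <- -1L

    z <- matrix(rnorm(n * length(traits)), n, length(traits))
    keep <- labels != -1L
    z[keep, ] <- planted$trait_profiles[labels[keep], , drop = FALSE] +
      matrix(rnorm(sum(keep) * length(traits), 0, planted$noise_sd),
             sum(keep), length(traits))
    colnames(z) <- traits

    # Positive heritabilities with mean h2_scale (gamma, shape 4).
    all_traits <- c(trait, traits)
    h2_mat <- matrix(rgamma(n * length(all_traits), shape = 4,
                            rate = 4 / h2_scale),
                     n, length(all_traits), dimnames = list(NULL, all_traits))

    h2 <- data.frame(
      segment_id = rep(segmap$segment_id, length(all_traits)),
      trait = rep(all_traits, each = n),
      h2 = as.vector(h2_mat),
      stringsAsFactors = FALSE
    )
    r <- tanh(z / z_scale)
    covar <- r * sqrt(h2_mat[, trait] * h2_mat[, traits, drop = FALSE])
    pairs <- data.frame(
      segment_id = rep(segmap$segment_id, length(traits)),
      trait_a = trait,
      trait_b = rep(traits, each = n),
      cov = as.vector(covar),
      z = as.vector(z),
      stringsAsFactors = FALSE
    )
    list(data = local_rg(segmap[, c("segment_id", "chrom", "start", "end")],
                         h2, pairs),
         labels = labels)
  })
}

#' Simulate multi-method gene evidence and gene sets
#'
#' Places genes uniformly within the mapped segments and generates per-gene
#' evidence columns that emulate the outputs gene prioritization consumes: a
#' gene-based association p-value, a polygenic priority score, two
#' transcriptome association p-values, a credible-set flag and a
#' heterogeneity p-value. All evidence columns are noisy monotone functions
#' of one latent effect, which is boosted for genes falling in designated
#' driver clusters, and the planted enriched gene sets oversample
#' high-effect genes.
#'
#' @param segmap A `segment_map`.
#' @param labels Integer segment labels aligned to `segmap` (`-1` = noise).
#' @param n_genes Number of genes (>= 1).
#' @param enriched_sets List describing the planted collection:
#'   `n_enriched`, `size`, `n_null`, `null_size_range`.
#' @param driver_clusters Cluster labels whose genes get the effect boost
#'   (default: all non-noise labels).
#' @param effect_boost Latent-effect mean shift for driver-cluster genes.
#' @param effect_sd Standard deviation of the latent effect (0 gives fully
#'   exchangeable method ranks).
#' @param noise_sd Per-method observation noise.
#' @param seed Integer seed.
#' @return List with `evidence` (a `gene_evidence` data.frame), `sets`
#'   (named list of gene id vectors; planted sets prefixed `"enriched_"`)
#'   and `effects` (the latent per-gene effect).
#' @export
simulate_gene_evidence <- function(segmap, labels, n_genes,
                                   enriched_sets = list(n_enriched = 1,
                                                        size = 50,
                                                        n_null = 30,
                                                        null_size_range = c(20, 100)),
                                   driver_clusters = NULL,
                                   effect_boost = 2, effect_sd = 1,
                                   noise_sd = 0.5, seed = 1L) {
  stop_if_not(n_genes >= 1, "n_genes must be >= 1")
  stop_if_not(nrow(segmap) >= 1, "empty segment map")
  stop_if_not(length(labels) == nrow(segmap), "labels must align with segmap")
  if (is.null(driver_clusters)) driver_clusters <- setdiff(unique(labels), -1L)

  with_seed(seed, {
    widths <- segmap$end - segmap$start + 1
    seg_idx <- sample(nrow(segmap), n_genes, replace = TRUE,
                      prob = widths / sum(widths))
    gstart <- segmap$start[seg_idx] +
      floor(runif(n_genes) * pmax(widths[seg_idx] - 10000, 1))
    gend <- pmin(gstart + 9999, segmap$end[seg_idx])
    in_driver <- labels[seg_idx] %in% driver_clusters

    effect <- rnorm(n_genes, 0, effect_sd) + ifelse(in_driver, effect_boost, 0)
    obs <- function() effect + rnorm(n_genes, 0, noise_sd)
    evidence <- data.frame(
      gene = sprintf("G%05d", seq_len(n_genes)),
      chrom = segmap$chrom[seg_idx],
      start = gstart,
      end = gend,
      magma_p = pnorm(obs(), lower.tail = FALSE),
      pops_score = obs(),
      twas_brain_p = pnorm(obs(), lower.tail = FALSE),
      twas_cortex_p = pnorm(obs(), lower.tail = FALSE),
      heidi_p = runif(n_genes),
      credible = rbinom(n_genes, 1, pnorm(effect - 2)) == 1,
      stringsAsFactors = FALSE
    )
    class(evidence) <- c("gene_evidence", "data.frame")
    attr(evidence, "manifest") <- default_evidence_manifest()

    w <- exp(pmin(effect, 10))
    sets <- list()
    ne <- enriched_sets$n_enriched %||% 1
    size <- enriched_sets$size %||% 50
    for (s in seq_len(ne)) {
      sets[[sprintf("enriched_%02d", s)]] <-
        evidence$gene[sample(n_genes, min(size, n_genes), prob = w)]
    }
    nn <- enriched_sets$n_null %||% 0
    rng <- enriched_sets$null_size_range %||% c(20, 100)
    for (s in seq_len(nn)) {
      sz <- sample(seq(rng[1], rng[2]), 1)
      sets[[sprintf("null_%02d", s)]] <- evidence$gene[sample(n_genes, min(sz, n_genes))]
    }
    list(evidence = evidence, sets = sets, effects = effect)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate longitudinal expression for driver genes
#'
#' Generates a long-format developmental expression table: one donor per
#' sample with a random intercept, ages in developmental weeks, and a linear
#' trajectory per meta-locus -- negative slope for `"prenatal"`, positive
#' for `"adulthood"`, zero for `"flat"`.
#'
#' @param driver_genes Named list: meta-locus -> character vector of genes.
#' @param trajectory Named character vector (same names), values in
#'   `c("prenatal", "adulthood", "flat")`.
#' @param n_donors Number of donors (>= 3).
#' @param n_regions Brain regions sampled per donor (default 4); each donor
#'   contributes one sample per region at its age, as in a developmental
#'   transcriptome atlas.
#' @param age_range_weeks Age support in weeks, within `[8, 2117]`.
#' @param slope_mag Absolute expression change per week (default 0.003).
#' @param baseline_mean,baseline_sd Gene baseline distribution.
#' @param donor_sd Donor random-intercept SD.
#' @param resid_sd Residual SD.
#' @param seed Integer seed.
#' @return An `expression_dataset` data.frame with columns `donor`,
#'   `age_weeks`, `sex`, `region`, `gene`, `expression`; the latent donor
#'   intercepts are in `attr(, "donor_effects")`.
#' @export
simulate_expression <- function(driver_genes, trajectory, n_donors = 30,
                                n_regions = 4,
                                age_range_weeks = c(8, 2117),
                                slope_mag = 0.003,
                                baseline_mean = 5, baseline_sd = 1,
                                donor_sd = 1, resid_sd = 1, seed = 1L) {
  stop_if_not(n_donors >= 3, "n_donors must be >= 3")
  stop_if_not(age_range_weeks[1] >= 8 && age_range_weeks[2] <= 2117,
              "age range must lie within [8, 2117] weeks")
  bad <- setdiff(unname(trajectory), c("prenatal", "adulthood", "flat"))
  if (length(bad)) {
    stop("invalid trajectory label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  stop_if_not(all(names(driver_genes) %in% names(trajectory)),
              "every meta-locus needs a trajectory label")

  slope_of <- c(prenatal = -slope_mag, adulthood = slope_mag, flat = 0)
  with_seed(seed, {
    donors <- sprintf("D%03d", seq_len(n_donors))
    ages <- round(runif(n_donors, age_range_weeks[1], age_range_weeks[2]))
    sex <- sample(c("M", "F"), n_donors, replace = TRUE)
    u <- rnorm(n_donors, 0, donor_sd)

    regions <- sprintf("region%02d", seq_len(n_regions))
    n_samp <- n_donors * n_regions
    rows <- lapply(names(driver_genes), function(ml) {
      genes <- driver_genes[[ml]]
      base <- rnorm(length(genes), baseline_mean, baseline_sd)
      slope <- slope_of[[trajectory[[ml]]]]
      donor_part <- rep(u + slope * ages, n_regions)
      expr <- outer(donor_part, base, "+") +
        matrix(rnorm(n_samp * length(genes), 0, resid_sd),
               n_samp, length(genes))
      data.frame(
        donor = rep(rep(donors, n_regions), length(genes)),
        age_weeks = rep(rep(ages, n_regions), length(genes)),
        sex = rep(rep(sex, n_regions), length(genes)),
        region = rep(rep(regions, each = n_donors), length(genes)),
        gene = rep(genes, each = n_samp),
        expression = as.vector(expr),
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, rows)
    class(out) <- c("expression_dataset", "data.frame")
    attr(out, "donor_effects") <- setNames(u, donors)
    out
  })
}

#' The Iris calibration fixture
#'
#' The canonical 150-flower, 4-feature table with three species of 50, used
#' as the ground-truth dataset for calibrating the embedding + density-scan
#' clustering pipeline. Served from the copy shipped with R.
#'
#' @return List with `x` (150 x 4 numeric matrix) and `species` (factor of
#'   length 150).
#' @export
load_iris_fixture <- function() {
  data <- datasets::iris
  list(x = as.matrix(data[, 1:4]), species = data$Species)
}
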