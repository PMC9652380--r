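# End-to-end orchestration: a single config drives synthetic-data
# generation (or file inputs), the three analysis stages, and provenance.

#' Run the core meta-locus discovery procedure on a feature matrix
#'
#' The Stage-2 engine: fits an ensemble of seeded 2-D embeddings of the
#' z-score matrix, estimates the density-scan radius from the k-NN elbow,
#' sweeps the radius grid, selects the best density model by the summed
#' silhouette/retention score, and refines it hierarchically into the final
#' meta-locus assignment.
#'
#' @param z Observations x traits matrix (e.g. from [localrg_z_matrix()]).
#' @param n_models Ensemble size (default 5).
#' @param n_neighbors Embedding neighbourhood size (default 5).
#' @param min_dist Embedding minimum spread; default `1/sqrt(nrow(z))`.
#' @param min_pts Density-scan minimum neighbourhood size (default 5).
#' @param j_max Radius sweep steps (default 5).
#' @param k_candidates Refinement cluster counts (default
#'   `c(5, 10, 15, 25, 30)`).
#' @param n_epochs Embedding optimization epochs (default 200).
#' @param master_seed Master seed; the ensemble uses consecutive seeds
#'   derived from it.
#' @param diagnostics Also compute embedding diagnostics (slower).
#' @return A `metalocus_run`: list with `assignment`
#'   (`metalocus_assignment`), `dbscan` (chosen model), `elbow`, `ensemble`
#'   and optionally `diagnostics`.
#' @export
run_metalocus_pipeline <- function(z, n_models = 5, n_neighbors = 5,
                                   min_dist = NULL, min_pts = 5, j_max = 5,
                                   k_candidates = c(5, 10, 15, 25, 30),
                                   n_epochs = 200, master_seed = 1L,
                                   diagnostics = FALSE) {
  z <- as.matrix(z)
  ens <- umap_ensemble(z, n_models = n_models, n_neighbors = n_neighbors,
                       min_dist = min_dist, n_epochs = n_epochs,
                       master_seed = master_seed)
  dmf <- dense_dist(ens$features)
  elbow <- knn_elbow_eps(dm = dmf, k = min_pts)
  models <- dbscan_scan(eps0 = elbow$eps, min_pts = min_pts, j_max = j_max,
                        dm = dmf)
  chosen <- select_dbscan_model(models)
  assignment <- hierarchical_refine(ens$features, chosen$labels,
                                    k_candidates = k_candidates)
  out <- list(assignment = assignment, dbscan = chosen, elbow = elbow,
              ensemble = ens,
              eps_grid = attr(models, "eps_grid"),
              master_seed = as.integer(master_seed))
  if (diagnostics) out$diagnostics <- embedding_diagnostics(z, ens)
  structure(out, class = "metalocus_run")
}

#' @export
print.metalocus_run <- function(x, ...) {
  print(x$assignment)
  cat(sprintf("  density model: eps = %.4g (%d grid radii), %d cluster(s)\n",
              x$dbscan$eps, length(x$eps_grid), x$dbscan$n_clusters))
  invisible(x)
}

#' Build a pipeline configuration
#'
#' All tunables of the pipeline in one serializable list. Either pass file
#' inputs (`localrg`, `segments`, `rg_matrix`, ...) or leave the synthetic
#' block enabled, in which case every input is generated from the master
#' seed.
#'
#' @param out_dir Output directory.
#' @param master_seed Master seed; every stochastic step derives from it.
#' @param stages Character subset of `c("stage1", "stage2", "stage3")`.
#' @param rg_matrix Optional TSV path for the Stage-1 matrix.
#' @param localrg,segments Optional input paths (local-rg TSV, BED).
#' @param trait Cognitive dimension analyzed (default `"CTP"`).
#' @param exclude_mhc Drop MHC-overlapping segments before clustering.
#' @param synthetic Synthetic-generation block (see Details in the
#'   vignette): `n_segments`, `k_true`, `n_traits`, `noise_sd`,
#'   `frac_noise`, `profile_sd`, `h2_scale`, `n_genes`.
#' @param n_models,min_pts,j_max,k_candidates,n_epochs Stage-2 tunables.
#' @param pct_cutoff,n_perm,alpha Stage-3 tunables.
#' @return A validated `pipeline_config` list.
#' @export
metaloci_config <- function(out_dir = "metaloci_out", master_seed = 1L,
                            stages = c("stage2", "stage3"),
                            rg_matrix = NULL, localrg = NULL, segments = NULL,
                            trait = "CTP", exclude_mhc = TRUE,
                            synthetic = list(n_segments = 500, k_true = 5,
                                             n_traits = 17, noise_sd = 0.5,
                                             frac_noise = 0.05,
                                             profile_sd = 2,
                                             h2_scale = 1e-4,
                                             n_genes = 2000),
                            n_models = 5, min_pts = 5, j_max = 5,
                            k_candidates = c(5, 10, 15, 25, 30),
                            n_epochs = 200,
                            pct_cutoff = 0.5, n_perm = 1000, alpha = 0.05) {
  cfg <- list(out_dir = out_dir, master_seed = as.integer(master_seed),
              stages = stages, rg_matrix = rg_matrix, localrg = localrg,
              segments = segments, trait = trait, exclude_mhc = exclude_mhc,
              synthetic = synthetic, n_models = n_models, min_pts = min_pts,
              j_max = j_max, k_candidates = k_candidates,
              n_epochs = n_epochs, pct_cutoff = pct_cutoff, n_perm = n_perm,
              alpha = alpha)
  stop_if_not(all(stages %in% c("stage1", "stage2", "stage3")),
              "unknown stage name")
  stop_if_not(cfg$master_seed >= 0, "master_seed must be non-negative")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(metaloci_config, raw)
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline from a configuration
#'
#' Executes the enabled stages in order -- Stage 1 (global-correlation
#' clustering), Stage 2 (meta-locus discovery), Stage 3 (gene
#' prioritization, enrichment, expression trajectories) -- writing a results
#' bundle under `cfg$out_dir`. Every output carries the config hash in the
#' provenance JSON; a rerun with the same config reproduces the bundle.
#'
#' @param cfg A `pipeline_config` (or path to a YAML config).
#' @return Invisibly, a list of stage results plus `provenance`.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_config(cfg)
  stop_if_not(inherits(cfg, "pipeline_config"), "invalid config")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg)
  results <- list()
  provenance <- list(config_hash = hash, master_seed = cfg$master_seed,
                     stages = cfg$stages)

  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      writeLines(paste0("FAILED ", name, ": ", conditionMessage(e)),
                 file.path(cfg$out_dir, "FAILED"))
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  if ("stage1" %in% cfg$stages && !is.null(cfg$rg_matrix)) {
    results$stage1 <- run_stage("stage1", function() {
      m <- read_rg_matrix(cfg$rg_matrix)
      pca <- pca_with_loadings(m)
      scan <- cluster_scan(m, seed = derive_seed(cfg$master_seed, 11))
      sel <- select_solution(scan, seed = derive_seed(cfg$master_seed, 12))
      write.table(
        data.frame(trait = names(sel$labels), cluster = sel$labels),
        file.path(cfg$out_dir, "stage1_clusters.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE
      )
      list(pca = pca, scan = scan, selected = sel)
    })
  }

  truth <- NULL
  if ("stage2" %in% cfg$stages) {
    results$stage2 <- run_stage("stage2", function() {
      if (!is.null(cfg$localrg)) {
        data <- read_local_rg(cfg$localrg)
        segmap <- if (!is.null(cfg$segments)) read_segments_bed(cfg$segments)
                  else {
                    sm <- data$map
                    sm$mhc <- rep(FALSE, nrow(sm))
                    class(sm) <- c("segment_map", "data.frame")
                    sm
                  }
      } else {
        syn <- cfg$synthetic
        segmap <- simulate_segment_map(syn$n_segments,
                                       seed = derive_seed(cfg$master_seed, 21))
        traits <- sprintf("trait%02d", seq_len(syn$n_traits))
        planted <- planted_structure(
          syn$k_true,
          random_trait_profiles(syn$k_true, traits, syn$profile_sd,
                                seed = derive_seed(cfg$master_seed, 22)),
          noise_sd = syn$noise_sd, frac_noise_segments = syn$frac_noise
        )
        sim <- simulate_local_rg(segmap, planted, traits, trait = cfg$trait,
                                 h2_scale = syn$h2_scale,
                                 seed = derive_seed(cfg$master_seed, 23))
        data <- sim$data
        truth <<- sim$labels
        write_local_rg(data, file.path(cfg$out_dir, "localrg_synthetic.tsv"))
      }
      if (cfg$exclude_mhc) {
        keep <- !segmap$mhc
        if (!is.null(truth)) truth <<- truth[keep]
        data <- exclude_mhc(data, segmap)
        segmap <- segmap[keep, , drop = FALSE]
      }
      z <- localrg_z_matrix(data, cfg$trait)
      segmap <- segmap[match(as.integer(rownames(z)), segmap$segment_id), ,
                       drop = FALSE]
      tendency <- hopkins(z, seed = derive_seed(cfg$master_seed, 24))
      null <- shuffle_null(z, seed = derive_seed(cfg$master_seed, 25))
      run <- run_metalocus_pipeline(
        z, n_models = cfg$n_models, min_pts = cfg$min_pts,
        j_max = cfg$j_max, k_candidates = cfg$k_candidates,
        n_epochs = cfg$n_epochs,
        master_seed = derive_seed(cfg$master_seed, 26)
      )
      summary <- summarize_metaloci(run$assignment, segmap, data, cfg$trait)
      export_metaloci_bed(run$assignment, segmap, cfg$out_dir)
      write.table(summary$per_locus,
                  file.path(cfg$out_dir, "metalocus_summary.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      list(data = data, segmap = segmap, z = z, tendency = tendency,
           shuffle = null, run = run, summary = summary, truth = truth)
    })
  }

  if ("stage3" %in% cfg$stages && !is.null(results$stage2)) {
    results$stage3 <- run_stage("stage3", function() {
      s2 <- results$stage2
      labels_by_seg <- s2$run$assignment$labels
      syn <- cfg$synthetic
      sim_ev <- simulate_gene_evidence(
        s2$segmap, labels_by_seg, n_genes = syn$n_genes,
        seed = derive_seed(cfg$master_seed, 31)
      )
      ev <- prioritize_genes(sim_ev$evidence, pct_cutoff = cfg$pct_cutoff)
      ev <- assign_genes_to_metaloci(ev, s2$run$assignment, s2$segmap)
      per_ml <- split(seq_len(nrow(ev)), ev$metalocus)
      per_ml <- per_ml[names(per_ml) != "-1"]
      enr <- lapply(names(per_ml), function(ml) {
        sub <- inverse_rank_score(ev[per_ml[[ml]], , drop = FALSE])
        scores <- setNames(sub$irs, sub$gene)
        gs <- tryCatch(
          gsea_preranked(scores, sim_ev$sets, n_perm = cfg$n_perm,
                         seed = derive_seed(cfg$master_seed, 32 + as.integer(ml))),
          error = function(e) NULL
        )
        if (is.null(gs)) return(NULL)
        ora <- hypergeometric_ora(sub$gene[sub$irs >= 0.5], sub$gene,
                                  sim_ev$sets)
        cons <- consensus_sets(gs, list(ora = ora))
        list(metalocus = ml, gsea = gs, ora = ora, consensus = cons,
             drivers = driver_genes(cons))
      })
      enr <- Filter(Negate(is.null), enr)
      names(enr) <- vapply(enr, `[[`, character(1), "metalocus")

      drivers <- lapply(enr, `[[`, "drivers")
      drivers <- drivers[vapply(drivers, length, integer(1)) > 0]
      temporal <- NULL
      if (length(drivers) >= 1) {
        traj <- setNames(rep(c("prenatal", "adulthood"),
                             length.out = length(drivers)), names(drivers))
        expr <- simulate_expression(drivers, traj,
                                    seed = derive_seed(cfg$master_seed, 41))
        agg <- aggregate_driver_expression(expr, drivers)
        temporal <- lapply(names(drivers), function(ml) {
          fit <- fit_lmm(agg[agg$metalocus == ml, , drop = FALSE],
                         formula = "weeks_only")
          list(metalocus = ml, weeks_coef = fit$coefficients[
            fit$coefficients$term == "weeks", ],
            classification = classify_trajectory(fit, alpha = cfg$alpha))
        })
        names(temporal) <- names(drivers)
      }
      list(evidence = ev, enrichment = enr, temporal = temporal)
    })
  }

  provenance$n_metaloci <- if (!is.null(results$stage2)) {
    length(setdiff(unique(results$stage2$run$assignment$labels), -1L))
  } else NULL
  jsonlite::write_json(provenance,
                       file.path(cfg$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  results$provenance <- provenance
  invisible(results)
}
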