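# End-to-end orchestration: configuration, the synthetic study, provenance.

#' Build a pipeline run configuration
#'
#' Collects every stage parameter and seed in one validated list. In
#' `"synthetic"` mode (the default) all inputs are generated by the synthgen
#' functions; `"real"` mode requires paths to a PET volume directory, an
#' atlas volume, and precomputed subject matrices, and validates their
#' existence before any compute.
#'
#' @param mode `"synthetic"` or `"real"`.
#' @param granularity parcellation granularity; one of 100, 200, 300, 400.
#' @param seed master seed; per-stage seeds are derived from it.
#' @param n_molecules,n_axes,noise_sd synthetic panel parameters.
#' @param threshold_pct,alpha,n_components gradient parameters.
#' @param null_method `"vgm"` or `"spin"`; `n_null` surrogate count.
#' @param gamma_grid resolution grid for clustering; `n_reps` runs per
#'   resolution.
#' @param n_subjects subjects per synthetic FC/SC/MPC stack.
#' @param pet_dir,atlas_path,matrix_dir real-mode input locations.
#' @return a validated `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "real"),
                       granularity = 100L,
                       seed = 1L,
                       n_molecules = 19L,
                       n_axes = 3L,
                       noise_sd = 0.1,
                       threshold_pct = 90,
                       alpha = 0.5,
                       n_components = 10L,
                       null_method = c("vgm", "spin"),
                       n_null = 1000L,
                       gamma_grid = gamma_grid_subcortical(),
                       n_reps = 50L,
                       n_subjects = 20L,
                       pet_dir = NULL, atlas_path = NULL, matrix_dir = NULL) {
  cfg <- list(mode = match.arg(mode), granularity = as.integer(granularity),
              seed = as.integer(seed), n_molecules = n_molecules,
              n_axes = n_axes, noise_sd = noise_sd,
              threshold_pct = threshold_pct, alpha = alpha,
              n_components = n_components,
              null_method = match.arg(null_method), n_null = n_null,
              gamma_grid = gamma_grid, n_reps = n_reps,
              n_subjects = n_subjects, pet_dir = pet_dir,
              atlas_path = atlas_path, matrix_dir = matrix_dir)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

#' Validate a run configuration
#' @param cfg a `run_config` (or plain list).
#' @return the config, invisibly; errors on any violation.
#' @export
validate_run_config <- function(cfg) {
  if (!cfg$granularity %in% c(100L, 200L, 300L, 400L)) {
    stop_invalid("granularity must be one of 100, 200, 300, 400 (got %s)",
                 cfg$granularity)
  }
  if (cfg$mode == "real") {
    for (fld in c("pet_dir", "atlas_path", "matrix_dir")) {
      if (is.null(cfg[[fld]]) || !file.exists(cfg[[fld]])) {
        stop_invalid("real mode requires an existing %s", fld)
      }
    }
  }
  if (cfg$n_null < 1) stop_invalid("n_null must be >= 1")
  if (!length(cfg$gamma_grid)) stop_invalid("empty gamma grid")
  invisible(cfg)
}

config_fingerprint <- function(cfg) {
  txt <- jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE,
                          digits = NA, null = "null")
  # small deterministic content hash (djb2)
  h <- 5381
  for (v in utf8ToInt(as.character(txt))) h <- (h * 33 + v) %% 2^31
  sprintf("%08x", h)
}

#' Run the full receptome pipeline
#'
#' Executes panel assembly, z-scoring, receptome construction, gradient
#' decomposition, surrogate-based gradient-fingerprint correlations, network
#' alignment, community detection with modular stability, and FC/SC/MPC
#' coupling with class comparison, writing every artifact as TSV + JSON
#' sidecar plus a machine-readable `report.json` capturing all statistics,
#' the config, its fingerprint, and derived stage seeds. Deterministic under
#' a fixed config seed.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing).
#' @return the report list, invisibly; artifacts in `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  validate_run_config(config)
  if (config$mode == "real") {
    stop_invalid(paste("real-mode execution requires external imaging data;",
                       "assemble the panel with parcellate_volume() /",
                       "assemble_panel() and call the stage functions",
                       "directly"))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- list(geometry = derive_seed(config$seed, 1),
                panel = derive_seed(config$seed, 2),
                nulls = derive_seed(config$seed, 3),
                communities = derive_seed(config$seed, 4),
                stacks = derive_seed(config$seed, 5),
                classes = derive_seed(config$seed, 6))

  geom <- make_sphere_geometry(config$granularity, seed = seeds$geometry)
  sim <- simulate_density_panel(geom, n_molecules = config$n_molecules,
                                n_axes = config$n_axes,
                                noise_sd = config$noise_sd,
                                seed = seeds$panel)
  panel <- zscore_panel(sim$panel, "joint")
  rc <- build_receptome(panel)
  write_matrix(panel, file.path(out_dir, "panel.tsv"))
  write_matrix(rc, file.path(out_dir, "receptome.tsv"))

  gs <- compute_gradients(rc, threshold_pct = config$threshold_pct,
                          alpha = config$alpha,
                          n_components = config$n_components)
  utils::write.table(cbind(region = rownames(gs$components),
                           as.data.frame(gs$components)),
                     file.path(out_dir, "gradients.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  g1 <- gs$components[, 1]
  nulls <- if (config$null_method == "spin") {
    spin_surrogates(g1, geom, n_null = config$n_null, seed = seeds$nulls)
  } else {
    vgm_surrogates(g1, geom$dist, n_null = config$n_null,
                   seed = seeds$nulls)
  }
  fp <- correlate_fingerprints_with_gradient(panel, g1, nulls)

  # synthetic cytoarchitectural classes: quartiles of the first planted axis
  ax <- sim$truth$planted_axes[, 1]
  classes <- cut(ax, breaks = stats::quantile(ax, probs = seq(0, 1, 0.25)),
                 labels = c("idiotypic", "unimodal", "heteromodal",
                            "paralimbic"),
                 include.lowest = TRUE)
  align <- network_alignment_test(g1, classes, nulls)

  ens <- partition_ensemble(rc, gamma_grid = config$gamma_grid,
                            n_reps = config$n_reps,
                            seed = seeds$communities)
  consensus <- lapply(ens$per_gamma, `[[`, "consensus")
  stability <- lapply(levels(classes), function(cl) {
    ms <- modular_stability(consensus, classes == cl)
    ms$class <- cl
    ms
  })
  stability <- do.call(rbind, stability)

  stacks <- list(
    FC = simulate_subject_stack(geom, config$n_subjects, "FC",
                                seed = derive_seed(seeds$stacks, 1)),
    SC = simulate_subject_stack(geom, config$n_subjects, "SC",
                                seed = derive_seed(seeds$stacks, 2)),
    MPC = simulate_subject_stack(geom, config$n_subjects, "MPC",
                                 seed = derive_seed(seeds$stacks, 3)))
  cons <- list(FC = consensus_fc(stacks$FC),
               SC = consensus_sc(stacks$SC, geom$dist),
               MPC = consensus_mpc_from_stack(stacks$MPC))
  coup <- lapply(cons, function(m) row_coupling(rc, m))
  comp <- lapply(coup, function(v) {
    tryCatch(class_comparison(v, classes), error = function(e) NULL)
  })

  report <- list(
    config = unclass(config),
    config_fingerprint = config_fingerprint(unclass(config)),
    seeds = seeds,
    package_version = as.character(utils::packageVersion("receptome")),
    variance_fraction = gs$variance_fraction,
    fingerprint_correlations = fp,
    network_alignment = align,
    modular_stability = stability,
    coupling_mean = lapply(coup, function(v) mean(v, na.rm = TRUE)),
    class_comparison = lapply(comp, function(x) {
      if (is.null(x)) NULL else list(h = x$h, p_global = x$p_global)
    })
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns",
                       null = "null", force = TRUE)
  invisible(report)
}

# MPC subject matrices are already on the covariance scale; consensus is the
# plain entrywise average.
consensus_mpc_from_stack <- function(stack) {
  check_stack(stack)
  acc <- Reduce(`+`, lapply(stack, as.matrix)) / length(stack)
  diag(acc) <- 0
  similarity_matrix((acc + t(acc)) / 2,
                    row_ids = rownames(as.matrix(stack[[1]])), kind = "MPC")
}
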