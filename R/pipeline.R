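#' Configuration for a full analysis run
#'
#' Defaults reproduce the study settings where stated: 48-point sliding
#' windows, SIMPROF at alpha = 0.01 with 999 permutations; the remaining
#' settings (E range 1-10, tau = Tp = 1, the theta grid) are the package's
#' documented defaults.
#'
#' @param community_file,species_file Input paths (NULL to simulate instead).
#' @param sim A [simulation_config()] used when no input files are given.
#' @param w Window length.
#' @param E_range Candidate embedding dimensions.
#' @param tau,Tp Delay and prediction horizon.
#' @param theta_grid Nonlinearity grid (must include 0).
#' @param alpha SIMPROF significance level.
#' @param alpha_theta Level for the nonlinearity calls.
#' @param n_perm SIMPROF permutations.
#' @param seed Seed for all stochastic stages.
#' @param out_dir Output directory (created if needed).
#' @param do_theta Run the per-window regularized S-map scan (the slowest
#'   stage); set FALSE for a quick look at determinism and classification.
#' @param verbose Emit timestamped stage logs.
#' @return List of class `run_config`.
#' @export
run_config <- function(community_file = NULL, species_file = NULL,
                       sim = simulation_config(), w = 48, E_range = 1:10,
                       tau = 1L, Tp = 1L, theta_grid = default_theta_grid(),
                       alpha = 0.01, alpha_theta = 0.05, n_perm = 999,
                       seed = 1L, out_dir = "results/run", do_theta = TRUE,
                       verbose = TRUE) {
  structure(list(community_file = community_file,
                 species_file = species_file, sim = sim, w = w,
                 E_range = E_range, tau = tau, Tp = Tp,
                 theta_grid = theta_grid, alpha = alpha,
                 alpha_theta = alpha_theta, n_perm = n_perm, seed = seed,
                 out_dir = out_dir, do_theta = do_theta, verbose = verbose),
            class = "run_config")
}

stage <- function(name, cfg, expr) {
  log_stage(name, "start", verbose = cfg$verbose)
  tryCatch(expr, error = function(e) {
    stop("pipeline failed at stage '", name, "': ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full indicator-dynamics analysis
#'
#' End to end: read (or simulate) the community and species tables, compute
#' the ten indicator time series, build a mutual prediction matrix per
#' indicator, summarize determinism and nonlinearity, classify indicators by
#' Ward + SIMPROF on the matrix distances, and write the complete artifact
#' bundle (indicator table, one matrix file per indicator, summary JSON,
#' distance table, Newick dendrogram, cluster table, resolved config YAML)
#' into `cfg$out_dir`.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with all intermediate objects: `community`,
#'   `species`, `indicators`, `matrices`, `diagnostics`, `classification`.
#' @export
run_pipeline <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(cfg$community_file)) {
    community <- stage("read_community", cfg, read_community(cfg$community_file))
    species <- stage("read_species", cfg, {
      if (is.null(cfg$species_file)) stop("species file not given")
      read_species(cfg$species_file)
    })
  } else {
    simres <- stage("simulate", cfg, community_sim(cfg$sim))
    community <- simres$community
    species <- simres$species
    write_community(community, file.path(cfg$out_dir, "community.csv"))
    write_species(species, file.path(cfg$out_dir, "species.csv"))
  }

  ind <- stage("indicators", cfg, indicator_time_series(community, species))
  write_indicators(ind, file.path(cfg$out_dir, "indicators.csv"))

  series <- ind[indicator_names()]
  if (anyNA(series)) {
    bad <- which(rowSums(is.na(series)) > 0)
    stop("pipeline failed at stage 'windowing': indicator series have ",
         "missing values at surveys ", paste(bad, collapse = ", "),
         "; every sliding window must be complete. Drop or impute these ",
         "surveys, or restrict the series, before re-running.", call. = FALSE)
  }

  matrices <- stage("mutual_prediction", cfg, {
    lapply(stats::setNames(indicator_names(), indicator_names()), function(nm) {
      log_stage("mutual_prediction", "indicator ", nm, verbose = cfg$verbose)
      mutual_prediction_matrix(series[[nm]], cfg$w, name = nm,
                               E_range = cfg$E_range, tau = cfg$tau,
                               Tp = cfg$Tp)
    })
  })
  for (nm in names(matrices)) {
    write_mutual(matrices[[nm]],
                 file.path(cfg$out_dir, paste0("mutual_", nm, ".csv")),
                 dates = ind$date)
  }

  diagnostics <- if (cfg$do_theta) {
    stage("determinism_nonlinearity", cfg,
          determinism_nonlinearity(matrices, series,
                                   theta_grid = cfg$theta_grid,
                                   alpha = cfg$alpha_theta))
  } else {
    list(determinism = vapply(matrices, determinism_fraction, numeric(1)),
         theta = NULL, test = NULL)
  }

  classification <- stage("classification", cfg,
                          classify_indicators(matrices, alpha = cfg$alpha,
                                              n_perm = cfg$n_perm,
                                              seed = cfg$seed))
  write_dendrogram(classification$hclust,
                   file.path(cfg$out_dir, "dendrogram.nwk"))
  write_cluster_table(classification,
                      file.path(cfg$out_dir, "clusters.csv"))
  dm <- as.matrix(classification$dist)
  utils::write.table(cbind(indicator = rownames(dm), as.data.frame(dm)),
                     file.path(cfg$out_dir, "distances.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)

  summary <- list(
    E_star = lapply(matrices, function(m) as.integer(m$E)),
    determinism = as.list(diagnostics$determinism),
    theta_median = if (!is.null(diagnostics$theta))
      as.list(apply(diagnostics$theta, 2, stats::median)) else NULL,
    nonlinearity_significant = if (!is.null(diagnostics$test))
      as.list(stats::setNames(diagnostics$test$significant,
                              diagnostics$test$indicator)) else NULL,
    n_clusters = classification$n_clusters,
    clusters = as.list(classification$clusters))
  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  resolved <- unclass(cfg)
  resolved$sim <- unclass(resolved$sim)
  yaml::write_yaml(resolved, file.path(cfg$out_dir, "config.yaml"))
  log_stage("done", "bundle written to ", cfg$out_dir, verbose = cfg$verbose)

  invisible(list(community = community, species = species, indicators = ind,
                 matrices = matrices, diagnostics = diagnostics,
                 classification = classification))
}
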