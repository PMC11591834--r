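# End-to-end orchestration: preprocess -> PLV -> thresholded networks ->
# graph metrics -> paired statistics, for every participant, band and
# condition of a study, with CSV/JSON reporting.

#' Build a pipeline configuration
#'
#' @param data_dir directory holding the recordings and `manifest.csv` (as
#'   written by [generate_study()]).
#' @param out_dir output directory for report files.
#' @param montage_path optional montage CSV/JSON; default montage otherwise.
#' @param bands band names to analyze (subset of [band_specs()] names).
#' @param threshold_mode `"grid"` (absolute thresholds from `grid`) or
#'   `"sparsity"` (per-participant top-`sparsity` networks).
#' @param grid numeric thresholds for grid mode.
#' @param sparsity edge fraction for sparsity mode.
#' @param distance_mode edge length convention, see [shortest_paths()].
#' @param plv_pooling PLV estimator mode, see [plv_matrix()].
#' @param analytic where the analytic signal is computed, see
#'   [preprocess_phases()].
#' @param car apply common average referencing.
#' @param notch powerline notch in Hz (`NA` disables).
#' @param q FDR level for the edge map.
#' @param tail tail for the threshold-grid comparisons.
#' @param node_metric_threshold threshold at which node difference maps are
#'   computed; must be a grid member. `NULL` (default) takes the middle of
#'   the grid.
#' @param seed seed recorded in the run manifest.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(data_dir, out_dir,
                            montage_path = NULL,
                            bands = c("alpha", "theta", "delta"),
                            threshold_mode = c("grid", "sparsity"),
                            grid = threshold_grid(),
                            sparsity = 0.2,
                            distance_mode = "one_minus_w",
                            plv_pooling = "epoch",
                            analytic = "epoch",
                            car = TRUE,
                            notch = 50,
                            q = 0.05,
                            tail = "two",
                            node_metric_threshold = NULL,
                            seed = 1) {
  threshold_mode <- match.arg(threshold_mode)
  stopifnot(all(bands %in% band_specs()$name))
  if (is.null(node_metric_threshold)) {
    node_metric_threshold <- grid[ceiling(length(grid) / 2)]
  }
  if (threshold_mode == "grid" &&
      !any(abs(grid - node_metric_threshold) < 1e-9)) {
    stop("pipeline_config: node_metric_threshold must be a grid member")
  }
  structure(list(data_dir = data_dir, out_dir = out_dir,
                 montage_path = montage_path, bands = bands,
                 threshold_mode = threshold_mode, grid = grid,
                 sparsity = sparsity, distance_mode = distance_mode,
                 plv_pooling = plv_pooling, analytic = analytic,
                 car = car, notch = notch,
                 q = q, tail = tail,
                 node_metric_threshold = node_metric_threshold,
                 seed = seed),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as JSON
#'
#' @param path JSON file path.
#' @return `read_pipeline_config`: a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, obj)
}

#' @rdname read_pipeline_config
#' @param config a [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Stages, per participant/condition: preprocessing
#' ([preprocess_recording()]) per band, PLV matrices ([plv_matrix()]),
#' thresholded graphs ([build_graph()]) and metrics
#' ([metrics_for_graph()]); then group statistics: edge-wise FDR map
#' ([compare_edges()]), threshold-grid metric comparison
#' ([compare_global_across_thresholds()]) and per-channel node difference
#' maps ([node_difference_map()]). Writes, under `out_dir`:
#' `table1_plv_summary.csv`, `table_metrics_by_threshold_<band>.csv`,
#' `edges_significant_<band>.csv`, `node_diff_<metric>_<band>.csv`,
#' `run_manifest.json` and `run.log`.
#'
#' @param config a [pipeline_config()] or path to its JSON file.
#' @return invisibly, a list with all in-memory results (`plv`, `metrics`,
#'   `edge_maps`, `threshold_table`, `node_maps`, `plv_summary`, `log`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage: %s] %s", what, conditionMessage(e)),
           call. = FALSE)
    })
  }

  montage <- if (!is.null(config$montage_path)) {
    read_montage(config$montage_path)
  } else {
    default_montage()
  }
  manifest <- stage("input",
                    read_manifest(file.path(config$data_dir,
                                            "manifest.csv")))
  participants <- sort(unique(manifest$participant))
  say("pipeline: %d participants, bands %s, %s thresholds",
      length(participants), paste(config$bands, collapse = "/"),
      config$threshold_mode)

  # stage 1-2: preprocessing + PLV per participant/condition/band
  plv <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    raw <- stage("read", read_recording(row$abs_path))
    pp <- stage("preprocess",
                multi_band_phases(raw, config$bands,
                                  analytic = config$analytic,
                                  car = config$car, notch = config$notch))
    if (length(pp$rejected)) {
      say("  %s/%s: rejected %d epochs (%s)", row$participant,
          row$condition, length(pp$rejected),
          paste(pp$rejected, collapse = ","))
    }
    for (band in config$bands) {
      pm <- stage("connectivity",
                  plv_matrix(pp$phases[[band]],
                             pooling = config$plv_pooling,
                             band = band, condition = row$condition,
                             participant = row$participant))
      plv[[sprintf("%s.%s.%s", row$participant, row$condition, band)]] <- pm
    }
  }

  # stage 3-4: graphs + metrics on the threshold grid
  thresholds <- if (config$threshold_mode == "grid") config$grid else NA
  metrics <- list()
  for (pm in plv) {
    t_list <- if (config$threshold_mode == "grid") thresholds else
      NA_real_
    for (Ti in t_list) {
      g <- stage("network", if (config$threshold_mode == "grid") {
        build_graph(pm, threshold = Ti, montage = montage)
      } else {
        build_graph(pm, sparsity = config$sparsity, montage = montage)
      })
      mt <- stage("metrics", metrics_for_graph(g, config$distance_mode))
      metrics[[length(metrics) + 1]] <- mt
    }
  }

  # stage 5: statistics
  get_cond <- function(band, cond) {
    lapply(participants, function(p) {
      plv[[sprintf("%s.%s.%s", p, cond, band)]]
    })
  }
  edge_maps <- list()
  plv_summary <- list()
  for (band in config$bands) {
    em <- stage("stats",
                compare_edges(get_cond(band, "comfort"),
                              get_cond(band, "fatigue"), q = config$q))
    edge_maps[[band]] <- em
    plv_summary[[band]] <- cbind(band = band, em$summary)
    utils::write.csv(em$edges[em$edges$significant, ],
                     file.path(config$out_dir,
                               sprintf("edges_significant_%s.csv", band)),
                     row.names = FALSE)
  }
  plv_summary <- do.call(rbind, plv_summary)
  utils::write.csv(plv_summary,
                   file.path(config$out_dir, "table1_plv_summary.csv"),
                   row.names = FALSE)

  threshold_table <- NULL
  node_maps <- list()
  if (config$threshold_mode == "grid") {
    threshold_table <- stage("stats",
      compare_global_across_thresholds(metrics, grid = config$grid,
                                       tail = config$tail))
    for (band in config$bands) {
      utils::write.csv(
        threshold_table[threshold_table$band == band, ],
        file.path(config$out_dir,
                  sprintf("table_metrics_by_threshold_%s.csv", band)),
        row.names = FALSE)
      for (metric in c("bc", "ne", "cc")) {
        nm <- stage("stats",
                    node_difference_map(metrics, metric, band,
                                        config$node_metric_threshold))
        node_maps[[sprintf("%s.%s", metric, band)]] <- nm
        utils::write.csv(nm$channels,
                         file.path(config$out_dir,
                                   sprintf("node_diff_%s_%s.csv", metric,
                                           band)),
                         row.names = FALSE)
      }
    }
  }

  run_manifest <- list(
    package_version = as.character(utils::packageVersion("plvnet")),
    r_version = R.version.string,
    seed = config$seed,
    config = unclass(config),
    n_participants = length(participants),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(run_manifest,
                       file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(log_lines, file.path(config$out_dir, "run.log"))

  invisible(list(plv = plv, metrics = metrics, edge_maps = edge_maps,
                 threshold_table = threshold_table, node_maps = node_maps,
                 plv_summary = plv_summary, log = log_lines))
}
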