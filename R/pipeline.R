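#' Configuration of an end-to-end pipeline run
#'
#' @param seed Master seed; every random draw in the run derives from it.
#' @param n_participants Number of simulated participants.
#' @param truth List with `dynamics` and `maxima` ground truths.
#' @param pairs Indicator pairs to analyse.
#' @param scr_threshold SCR amplitude threshold (microsiemens), recorded for
#'   trace-level inputs.
#' @param transform A [transform_spec()].
#' @param max_parents Maximum factor parents per indicator node.
#' @param p_grid Tweedie power grid used by the network search.
#' @param outdir Output directory (created if missing); `NULL` to skip
#'   writing artefacts.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, n_participants = 27,
                       truth = list(dynamics = default_ground_truth("dynamics"),
                                    maxima = default_ground_truth("maxima")),
                       pairs = c("dynamics", "maxima"),
                       scr_threshold = 0.05,
                       transform = transform_spec(),
                       max_parents = 3,
                       p_grid = seq(1.1, 1.9, by = 0.1),
                       outdir = NULL) {
  structure(list(seed = as.integer(seed), n_participants = n_participants,
                 truth = truth, pairs = pairs, scr_threshold = scr_threshold,
                 transform = transform, max_parents = max_parents,
                 p_grid = p_grid, outdir = outdir),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Chains all stages on synthetic data: build the 32-run fractional design,
#' simulate the per-trial indicator table, apply the skewness corrections
#' and per-participant normalisation, run the exhaustive network search for
#' each indicator pair, and cluster the condition-cell means of each best
#' network. Fully deterministic given `config$seed`. When `config$outdir`
#' is set, writes the indicator tables (CSV), the top of each ranking
#' (CSV), and a machine-readable summary (JSON) that records the seed.
#'
#' @param config A [run_config()].
#' @return A list: `design`, `indicators_raw`, `indicators` (transformed),
#'   `searches` (per pair), `clusters` (per pair), `summary`.
#' @export
run_pipeline <- function(config = run_config()) {
  design <- build_fractional_design()
  bal <- check_balance(design, order = 3)
  if (nrow(bal) > 0) stop("design stage: balance check failed")

  raw <- simulate_indicator_table(design, config$n_participants,
                                  config$truth, config$seed)
  tab <- apply_transforms(raw, config$transform)
  model_data <- tab[!tab$is_collision, ]

  searches <- clusters <- list()
  for (pair in config$pairs) {
    searches[[pair]] <- search_networks(model_data, pair,
                                        max_parents = config$max_parents,
                                        p_grid = config$p_grid)
    clusters[[pair]] <- cluster_best_network(searches[[pair]], model_data)
  }

  summary <- list(
    seed = config$seed,
    n_participants = config$n_participants,
    n_records = nrow(model_data),
    n_structures = vapply(searches, function(s) nrow(s$ranking), numeric(1)),
    best = lapply(searches, function(s) s$best),
    best_partition_blocks = lapply(clusters, function(cl) {
      if (is.null(cl)) NULL else as.list(cl$best$block_means)
    })
  )

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    write_indicator_csv(raw, file.path(config$outdir, "indicators_raw.csv"))
    write_indicator_csv(tab, file.path(config$outdir, "indicators_transformed.csv"))
    for (pair in config$pairs) {
      utils::write.csv(utils::head(searches[[pair]]$ranking, 20),
                       file.path(config$outdir, paste0("ranking_", pair, ".csv")),
                       row.names = FALSE)
    }
    jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(design = design, indicators_raw = raw, indicators = tab,
       searches = searches, clusters = clusters, summary = summary)
}

#' Write / read an indicator table as CSV
#'
#' Plain comma-separated UTF-8 with a header row and `.` decimal separator.
#' Factor levels are written as their labels and read back to -1/+1 codes.
#'
#' @param table Indicator table (coded factor columns).
#' @param path File path.
#' @return `write_indicator_csv` returns `path` invisibly;
#'   `read_indicator_csv` returns the coded table.
#' @export
write_indicator_csv <- function(table, path) {
  utils::write.csv(design_to_labels(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_indicator_csv
#' @export
read_indicator_csv <- function(path) {
  labels_to_design(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write / read a trial plan as CSV
#' @param plan A `trial_plan`.
#' @param path File path.
#' @export
write_trial_plan_csv <- function(plan, path) {
  utils::write.csv(design_to_labels(plan), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_plan_csv
#' @export
read_trial_plan_csv <- function(path) {
  out <- labels_to_design(utils::read.csv(path, stringsAsFactors = FALSE))
  class(out) <- c("trial_plan", "data.frame")
  out
}
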