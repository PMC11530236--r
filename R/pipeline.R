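#' Pipeline configuration
#'
#' @param mode `"simulate"` (generate a synthetic cohort) or `"load"` (read
#'   the three study CSVs).
#' @param generator a [generator_config()] (simulate mode).
#' @param paths named list/vector with `rats`, `sessions`, `irritability`
#'   CSV paths (load mode).
#' @param out_dir output directory for the report bundle.
#' @param seed integer seed; mandatory, so runs are reproducible (no
#'   wall-clock seeding).
#' @param pr_session progressive-ratio session feeding the Motivation
#'   Index (default 2, the first post-LgA session).
#' @param include_irritability_in_pca include the irritability index in the
#'   PCA (default `TRUE`).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "load"),
                            generator = generator_config(),
                            paths = NULL,
                            out_dir,
                            seed,
                            pr_session = 2,
                            include_irritability_in_pca = TRUE) {
  mode <- match.arg(mode)
  if (missing(out_dir) || missing(seed)) {
    abort_addix("out_dir and seed are required", "addix_config_error")
  }
  if (mode == "load" &&
      !all(c("rats", "sessions", "irritability") %in% names(paths))) {
    abort_addix("load mode needs paths$rats, paths$sessions, paths$irritability",
                "addix_config_error")
  }
  if (mode == "simulate") validate_generator_config(generator)
  structure(list(
    mode = mode, generator = generator, paths = paths, out_dir = out_dir,
    seed = as.integer(seed), pr_session = pr_session,
    include_irritability_in_pca = include_irritability_in_pca
  ), class = "pipeline_config")
}

config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL  # hash identifies the analysis, not its destination
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE,
                              digits = NA, null = "null", force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full phenotyping pipeline
#'
#' simulate/load -> per-rat behavioral metrics -> cohort-by-sex Z-score
#' indices and Addiction Index -> resilient/vulnerable and severity
#' classification -> effect-size/correlation/PCA battery. Writes
#' `rats.csv`, `sessions.csv`, `irritability.csv` (and `truth.csv` when
#' simulating), `behavior_summary.csv`, `index_table.csv`,
#' `stats_report.csv`, `pca_result.csv` and `manifest.json` to
#' `config$out_dir`. Re-running with the same config and seed reproduces
#' the bundle byte for byte (the manifest carries no timestamps).
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with `summaries`, `indices`, `stats`,
#'   `manifest` and the input `tables`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    abort_addix("config must be a pipeline_config()", "addix_config_error")
  }
  stages <- character()
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      abort_addix(sprintf("stage '%s' failed: %s", name,
                          conditionMessage(e)), "addix_stage_error")
    })
    stages <<- c(stages, name)
    res
  }

  tables <- if (config$mode == "simulate") {
    stage("simulate", simulate_cohort(config$generator, seed = config$seed))
  } else {
    stage("load", read_study_tables(config$paths[["rats"]],
                                    config$paths[["sessions"]],
                                    config$paths[["irritability"]]))
  }

  n_excluded <- sum(tables$rats$excluded)
  summaries <- stage("metrics", behavior_summaries(tables,
                                                   pr_session = config$pr_session))
  indices <- stage("indices", build_indices(summaries))
  stats <- stage("stats", stats_battery(
    summaries, indices,
    include_irritability_in_pca = config$include_irritability_in_pca
  ))

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_study_tables(tables, config$out_dir)
  readr::write_csv(summaries, file.path(config$out_dir, "behavior_summary.csv"),
                   progress = FALSE)
  readr::write_csv(indices, file.path(config$out_dir, "index_table.csv"),
                   progress = FALSE)
  readr::write_csv(stats$tests, file.path(config$out_dir, "stats_report.csv"),
                   progress = FALSE)
  pca_tab <- tibble::as_tibble(stats$pca$loadings, rownames = "variable")
  pca_tab <- dplyr::bind_rows(
    pca_tab,
    tibble::tibble(variable = "explained_fraction",
                   !!!stats::setNames(as.list(stats$pca$explained_fraction),
                                      colnames(stats$pca$loadings)))
  )
  readr::write_csv(pca_tab, file.path(config$out_dir, "pca_result.csv"),
                   progress = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("addix")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    mode = config$mode,
    config_md5 = config_hash(config),
    stages_completed = stages,
    counts = list(
      rats_total = nrow(tables$rats),
      rats_excluded_patency = n_excluded,
      rats_cocaine = sum(tables$rats$group == "cocaine" & !tables$rats$excluded),
      rats_naive = sum(tables$rats$group == "naive" & !tables$rats$excluded),
      sessions = nrow(tables$sessions),
      rats_with_addiction_index = sum(!is.na(indices$addiction_index)),
      rats_missing_addiction_index = sum(is.na(indices$addiction_index)),
      severity = as.list(table(indices$severity)),
      vulnerability = as.list(table(indices$vulnerability))
    )
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(tables = tables, summaries = summaries, indices = indices,
                 stats = stats, manifest = manifest))
}
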