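#' Pipeline configuration
#'
#' Declarative configuration for [run_pipeline()]: the synthetic study
#' design (or a path to an existing sector table), the coarse and fine
#' sector resolutions, the consistency FDR threshold, the candidate models
#' and the optimizer budget. Validated up front so a bad configuration
#' fails before any stage runs.
#'
#' @param out_dir output directory (created if missing).
#' @param design a [study_design()] describing the simulated study, or
#'   `NULL` when `sector_table` is given.
#' @param sector_table optional path to a canonical sector-table CSV used
#'   instead of simulation (its grids are used for the fitting stage).
#' @param k_coarse sector divisions per axis for the consistency stage.
#' @param k_fine sector divisions per axis for model fitting.
#' @param q FDR threshold of the consistency stage.
#' @param models candidate models to compare.
#' @param control an [stn_control()] for the fitting stage.
#' @param fwhm_mm smoothing kernel FWHM recorded for volume-based imports.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, design = study_design(),
                            sector_table = NULL,
                            k_coarse = 3L, k_fine = 10L, q = 0.05,
                            models = MODEL_IDS, control = stn_control(),
                            fwhm_mm = 0.3) {
  if (is.null(design) && is.null(sector_table)) {
    stop("supply a study design or a sector table", call. = FALSE)
  }
  if (!is.null(design)) stopifnot(inherits(design, "study_design"))
  if (!is.null(sector_table) && !file.exists(sector_table)) {
    stop("sector table does not exist: ", sector_table, call. = FALSE)
  }
  bad <- setdiff(models, MODEL_IDS)
  if (length(bad) > 0L) {
    stop("unknown model id(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)", call. = FALSE)
  if (k_coarse < 1L || k_fine < 1L) stop("k values must be positive", call. = FALSE)
  stopifnot(inherits(control, "stn_control"))
  structure(list(out_dir = out_dir, design = design,
                 sector_table = sector_table,
                 k_coarse = as.integer(k_coarse),
                 k_fine = as.integer(k_fine), q = q, models = models,
                 control = control, fwhm_mm = fwhm_mm),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages on a simulated (or imported) study:
#' simulate sector grids at the coarse and fine resolutions, apply outlier
#' exclusion to the fine grids, run the across-specimen consistency
#' analysis per marker on the coarse grids, fit and compare the four
#' models per (specimen, marker) on the fine grids, and tally model
#' preferences. All stage outputs are written under `out_dir` together
#' with a manifest (configuration, seeds, output checksums); the same
#' configuration and seed reproduce the outputs bit-identically.
#'
#' @param config a [pipeline_config()].
#' @param verbose print one line per stage.
#' @return List with `preferences`, `tally`, `aggregates`, `consistency`,
#'   and `manifest` (also written as files in `out_dir`).
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message("[stngrad] ", sprintf(...))
  paths <- character(0)
  out_file <- function(name) {
    p <- file.path(config$out_dir, name)
    paths[[name]] <<- p
    p
  }

  if (!is.null(config$design)) {
    say("simulate: %d specimens x %d markers", config$design$n_specimens,
        length(config$design$markers))
    fine_design <- config$design
    fine_design$grid_shape <- rep(config$k_fine, 3L)
    fine <- generate_study(fine_design)
    # the consistency stage sees the same field at coarse resolution
    coarse_grids <- lapply(fine$grids, coarsen_grid, k = config$k_coarse)
    write_sector_table(fine$grids, out_file("sectors_fine.csv"))
    write_sector_table(coarse_grids, out_file("sectors_coarse.csv"))
    write_truth(fine$truth, out_file("truth.json"))
    fine_grids <- fine$grids
  } else {
    say("import: %s", config$sector_table)
    fine_grids <- read_sector_table(config$sector_table)
    coarse_grids <- NULL
  }

  say("outlier exclusion on %d fine grids", length(fine_grids))
  fine_grids <- lapply(fine_grids, exclude_outliers)
  write_sector_table(fine_grids, out_file("sectors_fine_included.csv"))
  excluded <- sum(vapply(fine_grids, function(g) sum(!g$included), 0L))

  consistency <- NULL
  if (!is.null(coarse_grids)) {
    say("consistency analysis at k = %d", config$k_coarse)
    markers <- unique(vapply(coarse_grids, attr, "", "marker"))
    consistency <- do.call(rbind, lapply(markers, function(mk) {
      gs <- coarse_grids[vapply(coarse_grids, attr, "", "marker") == mk]
      as.data.frame(consistency_test(gs, q = config$q))
    }))
    utils::write.csv(consistency, out_file("consistency.csv"),
                     row.names = FALSE)
  }

  say("fitting models %s on %d grids",
      paste(config$models, collapse = ""), length(fine_grids))
  prefs <- select_study(fine_grids, models = config$models,
                        control = config$control, exclude = FALSE)
  utils::write.csv(as.data.frame(prefs), out_file("preferences.csv"),
                   row.names = FALSE)

  tally <- tally_preferences(prefs)
  aggregates <- aggregate_preferences(prefs)
  jsonlite::write_json(list(tally_percent = as.list(tally),
                            overall_winner = aggregates$overall,
                            excluded_sectors = excluded),
                       out_file("tally.json"), auto_unbox = TRUE,
                       digits = NA)

  manifest <- list(
    package_version = as.character(utils::packageVersion("stngrad")),
    seed = if (!is.null(config$design)) config$design$seed else NA,
    k_coarse = config$k_coarse, k_fine = config$k_fine,
    q = config$q, models = config$models,
    fwhm_mm = config$fwhm_mm,
    control = unclass(config$control),
    outputs = as.list(tools::md5sum(unlist(paths))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done: %s", config$out_dir)
  list(preferences = prefs, tally = tally, aggregates = aggregates,
       consistency = consistency, manifest = manifest)
}
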