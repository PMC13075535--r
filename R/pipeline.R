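#' Default pipeline configuration
#'
#' A plain list collecting every tunable of the full analysis, so a run is
#' reproducible from its config and seed alone. Fields: `design` (L9
#' design matrix), `filter` ([filter_spec()]), `detection`
#' (`min_duration_samples`, `threshold_k`), `weights` (`w1`, `w2`),
#' `windows_only`, `seed`, and `source` — either `"fixture"` (use the
#' bundled run-by-muscle MVC table) or `"suite"` (a named list of
#' recordings under `suite`, e.g. from [generate_run_suite()]).
#'
#' @return the default config list.
#' @export
default_run_config <- function() {
  list(source = "fixture",
       suite = NULL,
       design = build_l9(),
       filter = filter_spec(),
       detection = list(min_duration_samples = 25, threshold_k = 3),
       weights = list(w1 = 0.7, w2 = 0.3),
       windows_only = FALSE,
       seed = 1L)
}

#' Run the full ergonomic analysis
#'
#' Orchestrates the complete chain: MVC responses (from synthetic/loaded
#' recordings through the signal chain, or from the bundled study table),
#' then main effects, interaction grids, quadratic fits, per-muscle
#' optima, the overall recommendation and the muscle-coordination matrix.
#' The result carries a manifest (config echo and seed) so every output
#' is traceable.
#'
#' @param config a config list as from [default_run_config()]; fields not
#'   supplied fall back to the defaults.
#' @param out optional output directory; when given, the report tables
#'   are written as CSV plus a JSON report.
#' @return list `mvc, features, main_effects, interaction_grids, fits,
#'   optima, overall, coordination, manifest`.
#' @examples
#' rep <- run_full_analysis()
#' rep$overall
#' @export
run_full_analysis <- function(config = list(), out = NULL) {
  cfg <- utils::modifyList(default_run_config(), config)
  design <- cfg$design
  if (!identical(sort(design$run_id), sort(paste0("E", 1:9)))) {
    stop("config design must cover runs E1-E9", call. = FALSE)
  }
  if (cfg$weights$w1 < 0 || cfg$weights$w2 < 0) {
    stop("MVC weights must be non-negative", call. = FALSE)
  }
  if (identical(cfg$source, "fixture")) {
    responses <- study_mvc_matrix()
    features <- study_table("emg_features")
  } else if (identical(cfg$source, "suite")) {
    if (is.null(cfg$suite)) stop("config$suite missing", call. = FALSE)
    missing <- setdiff(design$run_id, names(cfg$suite))
    if (length(missing)) {
      stop("suite missing run(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    tab <- compute_mvc_table(cfg$suite, cfg$filter,
                             w1 = cfg$weights$w1, w2 = cfg$weights$w2,
                             windows_only = isTRUE(cfg$windows_only),
                             min_duration_samples =
                               cfg$detection$min_duration_samples,
                             threshold_k = cfg$detection$threshold_k)
    responses <- tab$mvc
    features <- tab$features
  } else {
    stop("config$source must be 'fixture' or 'suite'", call. = FALSE)
  }

  factors <- setdiff(names(design), "run_id")
  pairs <- utils::combn(factors, 2, simplify = FALSE)
  effects <- main_effects(design, responses)
  grids <- setNames(lapply(pairs, function(p) {
    interaction_grid(design, responses, p)
  }), vapply(pairs, paste, "", collapse = ":"))
  fits <- fit_quadratic_all(design, responses)
  optima <- optimal_levels(effects)
  overall <- overall_recommendation(optima)

  report <- list(mvc = responses,
                 features = features,
                 main_effects = effects,
                 interaction_grids = grids,
                 fits = fits,
                 optima = optima,
                 overall = overall,
                 coordination = coordination_matrix(responses),
                 manifest = list(
                   package_version = as.character(
                     utils::packageVersion("ergolever")),
                   source = cfg$source,
                   filter = unclass(cfg$filter),
                   detection = cfg$detection,
                   weights = cfg$weights,
                   windows_only = isTRUE(cfg$windows_only),
                   seed = cfg$seed))
  if (!is.null(out)) write_report(report, out)
  report
}

# serialize the report bundle: per-table CSVs plus one JSON document
write_report <- function(report, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write.csv(data.frame(run_id = rownames(report$mvc), report$mvc),
            file.path(out, "mvc_table.csv"), row.names = FALSE)
  write.csv(report$main_effects, file.path(out, "main_effects.csv"),
            row.names = FALSE)
  write.csv(report$fits, file.path(out, "quadratic_fits.csv"),
            row.names = FALSE)
  write.csv(report$optima, file.path(out, "optimal_levels.csv"),
            row.names = FALSE)
  write.csv(report$overall, file.path(out, "overall_recommendation.csv"),
            row.names = FALSE)
  json <- report
  json$mvc <- as.data.frame(report$mvc)
  json$coordination <- as.data.frame(report$coordination)
  json$interaction_grids <- lapply(report$interaction_grids,
                                   function(g) lapply(g, as.data.frame))
  jsonlite::write_json(json, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}

#' Internal-consistency check of the bundled study tables
#'
#' Recomputes every derivable cell of the bundled tables and reports the
#' maximum absolute deviation from the stored values: the weighted MVC
#' from each amplitude/RMS pair, the main-effect table from the MVC
#' matrix and the design, the per-muscle optima from the main effects,
#' and the overall recommendation from the optima.
#'
#' @param features optionally, an `"emg_features"`-shaped data.frame to
#'   validate instead of the bundled one (used for negative controls).
#' @return data.frame `check, n_cells, max_abs_deviation`.
#' @examples
#' validate_fixtures()
#' @export
validate_fixtures <- function(features = study_table("emg_features")) {
  design <- build_l9()

  # MVC column from amplitude/RMS; printed values keep 2-3 decimals
  mvc_dev <- abs(mvc(features$amplitude, features$rms) - features$mvc)

  mvc_mat <- study_mvc_matrix()
  me <- main_effects(design, mvc_mat)
  ref_me <- study_table("main_effects")
  key <- paste(ref_me$factor, ref_me$level, ref_me$muscle)
  comp <- setNames(me$mean_mvc, paste(me$factor, me$level, me$muscle))
  me_dev <- abs(comp[key] - ref_me$mean_mvc)

  opt <- optimal_levels(main_effects(design, mvc_mat))
  ref_opt <- study_table("optimal_levels")
  opt <- opt[match(ref_opt$muscle, opt$muscle), ]
  opt_dev <- abs(as.matrix(opt[DOE_FACTORS]) - as.matrix(ref_opt[DOE_FACTORS]))

  ov <- overall_recommendation(opt)
  ref_ov <- study_table("overall")
  ov_dev <- abs(ov$optimal_setting[match(ref_ov$factor, ov$factor)] -
                  ref_ov$optimal_setting)

  data.frame(
    check = c("mvc_from_features", "main_effects_from_mvc",
              "optima_from_main_effects", "overall_from_optima"),
    n_cells = c(length(mvc_dev), length(me_dev),
                length(opt_dev), length(ov_dev)),
    max_abs_deviation = c(max(mvc_dev), max(me_dev),
                          max(opt_dev), max(ov_dev)))
}
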