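#' Bundled reference tables from the wheelchair ergonomic pilot study
#'
#' The package ships the study's summary tables as plain-text fixtures so
#' the design-of-experiments and usability stages can be exercised (and
#' cross-checked) independently of raw signal processing:
#'
#' * `"anthropometry"` — per-feature mean, SD and printed 5th/95th
#'   percentile bounds for the 20-participant anthropometric survey (cm,
#'   except age and weight).
#' * `"design"` — the L9 design: run IDs E1-E9 with numeric factor levels
#'   (torso angle in degrees, lever distance in mm, lever orientation in
#'   degrees).
#' * `"task_times"` — simulated-course completion times (seconds), 9 tasks
#'   by 9 participants.
#' * `"emg_features"` — per run and muscle: participant-averaged envelope
#'   amplitude, RMS, and the reported weighted MVC statistic.
#' * `"quadratic"` — reported quadratic-fit coefficients, residual standard
#'   error and R-squared (percent) per muscle and factor.
#' * `"main_effects"` — reported per-factor, per-level, per-muscle mean MVC.
#' * `"optimal_levels"` — reported per-muscle optimal factor settings.
#' * `"overall"` — reported overall (muscle-averaged) recommendation.
#' * `"clearance_standards"` — reach/clearance bounds (mm) from IS-7454,
#'   CPWD, CCD and ISO accessibility guidelines.
#' * `"vas_reference"` — reported mean (SD) visual-analog-scale ratings per
#'   attribute.
#'
#' @param name fixture name, one of the strings listed above.
#' @return a `data.frame`, except `"clearance_standards"` which is the
#'   parsed JSON list (`units`, `sources`, `rows`).
#' @examples
#' head(study_table("emg_features"))
#' study_table("overall")
#' @export
study_table <- function(name = c("anthropometry", "design", "task_times",
                                 "emg_features", "quadratic", "main_effects",
                                 "optimal_levels", "overall",
                                 "clearance_standards", "vas_reference")) {
  name <- match.arg(name)
  file <- switch(name,
    anthropometry       = "table1_anthropometry.csv",
    clearance_standards = "table2_clearance_standards.json",
    design              = "table5_design.csv",
    task_times          = "table6_task_times.csv",
    emg_features        = "table7_emg_features.csv",
    quadratic           = "table8_quadratic.csv",
    main_effects        = "table9_main_effects.csv",
    optimal_levels      = "table10_optimal_levels.csv",
    overall             = "table11_overall.csv",
    vas_reference       = "vas_reference_summary.csv")
  path <- system.file("extdata", file, package = "ergolever", mustWork = TRUE)
  if (grepl("[.]json$", file)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    read.csv(path, stringsAsFactors = FALSE)
  }
}

#' Reported MVC values as a run-by-muscle matrix
#'
#' Convenience accessor: reshapes the `"emg_features"` fixture into the
#' 9 x 4 response matrix consumed by the DOE stage.
#'
#' @param value which column to spread: the reported `"mvc"` statistic
#'   (default), the envelope `"amplitude"`, or the `"rms"`.
#' @return numeric matrix, rows E1-E9, columns BBL/TBL/BRD/PDT.
#' @examples
#' study_mvc_matrix()["E1", "BBL"]
#' @export
study_mvc_matrix <- function(value = c("mvc", "amplitude", "rms")) {
  value <- match.arg(value)
  tab <- study_table("emg_features")
  runs <- paste0("E", 1:9)
  out <- matrix(NA_real_, length(runs), length(EMG_CHANNELS),
                dimnames = list(runs, EMG_CHANNELS))
  for (i in seq_len(nrow(tab))) {
    out[tab$run_id[i], tab$muscle[i]] <- tab[[value]][i]
  }
  out
}
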