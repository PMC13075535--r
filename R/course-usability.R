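# round half away from zero (R's round() is half-even); reported task
# times use 1-decimal half-up rounding
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Per-task completion-time summary for the simulated course
#'
#' Arithmetic mean, sample SD (n - 1 denominator) and standard error
#' (`SD / sqrt(n)`) of each task's completion times across participants,
#' with reported values rounded half-up to 1 decimal second.
#'
#' @param table data.frame in the bundled `"task_times"` layout: a `task`
#'   column plus one numeric column per participant.
#' @return data.frame `task, n, mean, sd, se, mean_reported, se_reported`.
#' @examples
#' tt <- task_time_summary(study_table("task_times"))
#' tt[tt$task == "R", "mean_reported"]  # 14.8
#' @export
task_time_summary <- function(table) {
  if (!"task" %in% names(table)) {
    stop("`table` must have a `task` column", call. = FALSE)
  }
  pcols <- setdiff(names(table), "task")
  out <- NULL
  for (i in seq_len(nrow(table))) {
    x <- as.numeric(table[i, pcols])
    if (anyNA(x)) {
      stop("missing time for task ", table$task[i], ", participant ",
           pcols[which(is.na(x))[1]], call. = FALSE)
    }
    if (length(x) < 2) stop("need >= 2 participants per task", call. = FALSE)
    if (any(x <= 0)) {
      stop("non-positive time for task ", table$task[i], call. = FALSE)
    }
    out <- rbind(out, data.frame(task = table$task[i], n = length(x),
                                 mean = mean(x), sd = sd(x),
                                 se = sd(x) / sqrt(length(x))))
  }
  out$mean_reported <- round_half_up(out$mean, 1)
  out$se_reported <- round_half_up(out$se, 1)
  out
}

LIKERT_MAP <- c("strongly favorable" = 4L,
                "moderately favorable" = 3L,
                "moderately unfavorable" = 2L,
                "strongly unfavorable" = 1L)

#' Map a Likert favorability descriptor to its integer score
#'
#' The course protocol uses a 4-category ordinal scale: strongly
#' favorable = 4, moderately favorable = 3, moderately unfavorable = 2,
#' strongly unfavorable = 1. Matching is case-insensitive; anything
#' outside the vocabulary is an error.
#'
#' @param descriptor character vector of descriptors.
#' @return integer scores.
#' @examples
#' likert_encode("strongly favorable")  # 4
#' @export
likert_encode <- function(descriptor) {
  key <- tolower(trimws(descriptor))
  bad <- !key %in% names(LIKERT_MAP)
  if (any(bad)) {
    stop("unknown Likert descriptor(s): ",
         paste(unique(descriptor[bad]), collapse = ", "),
         "; valid categories are: ",
         paste(names(LIKERT_MAP), collapse = ", "), call. = FALSE)
  }
  unname(LIKERT_MAP[key])
}

#' Visual-analog-scale attribute summary
#'
#' Mean and sample SD per rated attribute on the 0-10 satisfaction scale,
#' flagging the lowest- and highest-rated attributes.
#'
#' @param ratings data.frame `participant, attribute, value` with values
#'   in `[0, 10]`.
#' @return data.frame `attribute, n, mean, sd, lowest, highest`.
#' @examples
#' r <- data.frame(participant = rep(1:3, 2),
#'                 attribute = rep(c("comfort", "stability"), each = 3),
#'                 value = c(3, 4, 3, 6, 5, 6))
#' vas_summary(r)
#' @export
vas_summary <- function(ratings) {
  stopifnot(all(c("participant", "attribute", "value") %in% names(ratings)))
  if (any(ratings$value < 0 | ratings$value > 10)) {
    stop("VAS ratings must lie in [0, 10]", call. = FALSE)
  }
  attrs <- unique(ratings$attribute)
  out <- data.frame(
    attribute = attrs,
    n = vapply(attrs, function(a) sum(ratings$attribute == a), integer(1)),
    mean = vapply(attrs, function(a) {
      mean(ratings$value[ratings$attribute == a])
    }, numeric(1)),
    sd = vapply(attrs, function(a) {
      sd(ratings$value[ratings$attribute == a])
    }, numeric(1)),
    row.names = NULL)
  out$lowest <- out$mean == min(out$mean)
  out$highest <- out$mean == max(out$mean)
  out
}

#' Generate synthetic per-participant VAS ratings
#'
#' Raw per-participant VAS scores are not part of the bundled summaries;
#' this seeded generator draws ratings from truncated normals matching a
#' supplied attribute mean/SD table (default: the bundled reference
#' summary), for round-trip testing of [vas_summary()].
#'
#' @param n participants.
#' @param summary data.frame `attribute, mean, sd`.
#' @param seed integer seed.
#' @return data.frame `participant, attribute, value` with values clipped
#'   to `[0, 10]`.
#' @export
generate_vas_ratings <- function(n = 9, summary = study_table("vas_reference"),
                                 seed = 1L) {
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  out <- NULL
  for (i in seq_len(nrow(summary))) {
    v <- pmin(10, pmax(0, rnorm(n, summary$mean[i], summary$sd[i])))
    out <- rbind(out, data.frame(participant = paste0("S", seq_len(n)),
                                 attribute = summary$attribute[i],
                                 value = v))
  }
  out
}
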