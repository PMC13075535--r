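#' Pull-push burst schedule for synthetic lever-propulsion recordings
#'
#' Describes the cyclic activation pattern of lever propulsion: during the
#' pull stroke the elbow flexors and shoulder extensors (BBL,
#' brachioradialis, posterior deltoid) burst; during the push (return)
#' stroke the elbow extensor (TBL) bursts. Defaults use a desk-scale
#' cadence of 1 s pull, 1 s push, 0.5 s rest.
#'
#' @param cycle_count number of pull-push cycles (>= 1).
#' @param pull_duration,push_duration,rest_duration phase durations in
#'   seconds, all > 0.
#' @param phases named character vector mapping each channel label to
#'   `"pull"` or `"push"`.
#' @return an object of class `burst_schedule`.
#' @examples
#' burst_schedule(cycle_count = 3)
#' @export
burst_schedule <- function(cycle_count = 5,
                           pull_duration = 1.0,
                           push_duration = 1.0,
                           rest_duration = 0.5,
                           phases = c(BBL = "pull", TBL = "push",
                                      BRD = "pull", PDT = "pull")) {
  if (!is.numeric(cycle_count) || length(cycle_count) != 1 ||
      cycle_count < 1 || cycle_count != round(cycle_count)) {
    stop("`cycle_count` must be a positive integer", call. = FALSE)
  }
  for (nm in c("pull_duration", "push_duration", "rest_duration")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || v <= 0) {
      stop(sprintf("`%s` must be a positive duration in seconds", nm),
           call. = FALSE)
    }
  }
  if (is.null(names(phases)) || any(!nzchar(names(phases))) ||
      anyDuplicated(names(phases))) {
    stop("`phases` must be a named vector with unique channel labels",
         call. = FALSE)
  }
  if (!all(phases %in% c("pull", "push"))) {
    stop("every channel in `phases` must be assigned 'pull' or 'push'",
         call. = FALSE)
  }
  structure(list(cycle_count = as.integer(cycle_count),
                 pull_duration = pull_duration,
                 push_duration = push_duration,
                 rest_duration = rest_duration,
                 phases = phases),
            class = "burst_schedule")
}

#' Signal model for synthetic sEMG generation
#'
#' Bursts are Gaussian white noise band-passed to `burst_band` (default
#' 20-200 Hz, the usual sEMG spectral support below the 250 Hz Nyquist of
#' the 500 Hz acquisition), scaled per channel to `burst_amplitude`
#' (arbitrary units, matching the unitless amplitudes of the study tables)
#' and superposed on baseline Gaussian noise.
#'
#' @param sampling_rate sampling rate in Hz (default 500).
#' @param burst_band two-element numeric, band-limited carrier (Hz),
#'   `0 < low < high < sampling_rate / 2`.
#' @param burst_amplitude named numeric, per-channel burst standard
#'   deviation in arbitrary units; must exceed `baseline_noise_sd`.
#' @param baseline_noise_sd baseline noise standard deviation (a.u., >= 0).
#' @param seed integer seed for reproducible generation.
#' @return an object of class `signal_model`.
#' @export
signal_model <- function(sampling_rate = 500,
                         burst_band = c(20, 200),
                         burst_amplitude = c(BBL = 10, TBL = 10,
                                             BRD = 10, PDT = 10),
                         baseline_noise_sd = 1,
                         seed = 1L) {
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop("`sampling_rate` must be positive", call. = FALSE)
  }
  if (length(burst_band) != 2 || burst_band[1] <= 0 ||
      burst_band[1] >= burst_band[2] || burst_band[2] >= sampling_rate / 2) {
    stop("`burst_band` must satisfy 0 < low < high < sampling_rate/2",
         call. = FALSE)
  }
  if (baseline_noise_sd < 0) {
    stop("`baseline_noise_sd` must be >= 0", call. = FALSE)
  }
  if (is.null(names(burst_amplitude)) || any(burst_amplitude <= baseline_noise_sd)) {
    stop("`burst_amplitude` must be named and exceed `baseline_noise_sd`",
         call. = FALSE)
  }
  structure(list(sampling_rate = sampling_rate,
                 burst_band = burst_band,
                 burst_amplitude = burst_amplitude,
                 baseline_noise_sd = baseline_noise_sd,
                 seed = as.integer(seed)),
            class = "signal_model")
}

# band-limited Gaussian carrier of unit SD, with 25 ms linear edge tapers
burst_carrier <- function(n, rate, band, taper_s = 0.025) {
  bf <- signal::butter(4, band / (rate / 2), type = "pass")
  x <- signal::filtfilt(bf, rnorm(n))
  s <- sd(x)
  if (s > 0) x <- x / s
  k <- min(n %/% 2, max(1L, round(taper_s * rate)))
  ramp <- seq(0, 1, length.out = k)
  x[seq_len(k)] <- x[seq_len(k)] * ramp
  x[n - k + seq_len(k)] <- x[n - k + seq_len(k)] * rev(ramp)
  x
}

#' Generate one synthetic multi-channel sEMG recording
#'
#' Emulates a lever-propulsion trial: each cycle is pull, then push, then
#' rest; channels assigned to a phase receive a band-limited noise burst of
#' their configured amplitude during that phase; everything rides on
#' baseline Gaussian noise. Identical (schedule, model) input gives
#' bit-identical output.
#'
#' @param schedule a [burst_schedule()].
#' @param model a [signal_model()].
#' @return list with elements
#'   \describe{
#'     \item{recording}{data.frame `time_s` plus one column per channel.}
#'     \item{sampling_rate}{Hz.}
#'     \item{ground_truth}{named list per channel of two-column matrices
#'       `[onset, offset]` of true burst sample indices (1-based,
#'       inclusive), one row per cycle.}
#'     \item{amplitudes}{the generating per-channel burst amplitudes.}
#'   }
#' @examples
#' rec <- generate_recording(burst_schedule(cycle_count = 2), signal_model())
#' nrow(rec$ground_truth$BBL)  # one burst per cycle
#' @export
generate_recording <- function(schedule, model) {
  stopifnot(inherits(schedule, "burst_schedule"),
            inherits(model, "signal_model"))
  rate <- model$sampling_rate
  channels <- names(schedule$phases)
  if (!all(channels %in% names(model$burst_amplitude))) {
    stop("`model$burst_amplitude` must name every channel of the schedule",
         call. = FALSE)
  }
  pull_n <- round(schedule$pull_duration * rate)
  push_n <- round(schedule$push_duration * rate)
  rest_n <- round(schedule$rest_duration * rate)
  cycle_n <- pull_n + push_n + rest_n
  total_n <- schedule$cycle_count * cycle_n

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(model$seed)

  sig <- matrix(0, total_n, length(channels),
                dimnames = list(NULL, channels))
  truth <- setNames(vector("list", length(channels)), channels)
  for (ch in channels) {
    x <- rnorm(total_n, sd = model$baseline_noise_sd)
    phase_off <- if (schedule$phases[[ch]] == "pull") 0L else pull_n
    phase_n <- if (schedule$phases[[ch]] == "pull") pull_n else push_n
    iv <- matrix(NA_integer_, schedule$cycle_count, 2,
                 dimnames = list(NULL, c("onset", "offset")))
    for (cy in seq_len(schedule$cycle_count)) {
      onset <- (cy - 1L) * cycle_n + phase_off + 1L
      offset <- onset + phase_n - 1L
      x[onset:offset] <- x[onset:offset] +
        model$burst_amplitude[[ch]] *
          burst_carrier(phase_n, rate, model$burst_band)
      iv[cy, ] <- c(onset, offset)
    }
    sig[, ch] <- x
    truth[[ch]] <- iv
  }
  rec <- data.frame(time_s = (seq_len(total_n) - 1) / rate)
  rec[channels] <- as.data.frame(sig)
  list(recording = rec, sampling_rate = rate, ground_truth = truth,
       amplitudes = model$burst_amplitude[channels])
}

#' Write / read a synthetic recording in the package CSV dialect
#'
#' The on-disk form is `time_s` plus one column per channel, one row per
#' sample, with the ground truth as a JSON sidecar mapping each channel to
#' a list of `[onset, offset]` sample pairs.
#'
#' @param rec the list returned by [generate_recording()].
#' @param path CSV output path; the sidecar is `path` with extension
#'   `.truth.json`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  write.csv(rec$recording, path, row.names = FALSE)
  truth <- lapply(rec$ground_truth, function(m) {
    lapply(seq_len(nrow(m)), function(i) as.integer(m[i, ]))
  })
  jsonlite::write_json(truth, paste0(path, ".truth.json"), auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @param sampling_rate sampling rate (Hz) to attach on read; the CSV
#'   stores only the time axis.
#' @export
read_recording <- function(path, sampling_rate = 500) {
  rec <- read.csv(path, stringsAsFactors = FALSE)
  if (names(rec)[1] != "time_s") {
    stop("recording CSV must start with a `time_s` column", call. = FALSE)
  }
  list(recording = rec, sampling_rate = sampling_rate,
       ground_truth = NULL, amplitudes = NULL)
}

#' Generate a synthetic anthropometric sample
#'
#' Draws per-feature values from independent normal models truncated at
#' mean +/- 4 SD, matching the summary statistics supplied (typically the
#' bundled `"anthropometry"` study table).
#'
#' @param n number of subjects (>= 2).
#' @param summary data.frame with columns `feature`, `mean`, `sd`.
#' @param seed integer seed.
#' @return data.frame, one row per subject, one column per feature.
#' @examples
#' tab <- generate_anthropometrics(20, study_table("anthropometry"), seed = 1)
#' mean(tab$height)
#' @export
generate_anthropometrics <- function(n, summary = study_table("anthropometry"),
                                     seed = 1L) {
  if (!is.numeric(n) || n < 2) stop("`n` must be >= 2", call. = FALSE)
  if (any(summary$sd < 0)) stop("feature SDs must be >= 0", call. = FALSE)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  out <- data.frame(subject = paste0("S", seq_len(n)))
  for (i in seq_len(nrow(summary))) {
    m <- summary$mean[i]; s <- summary$sd[i]
    x <- rnorm(n, m, s)
    # truncate at +/- 4 SD by redrawing (vanishingly rare)
    while (s > 0 && any(bad <- abs(x - m) > 4 * s)) {
      x[bad] <- rnorm(sum(bad), m, s)
    }
    out[[summary$feature[i]]] <- x
  }
  out
}

#' Generate the 9-run synthetic recording suite for an L9 design
#'
#' One recording per design run; every channel's burst amplitude is the
#' base model amplitude times the product of the run's per-level
#' multipliers from `effect_model`. This makes injected factor effects
#' recoverable by the downstream DOE stage (parameter-recovery testing).
#'
#' @param design a design matrix as returned by [build_l9()] (columns
#'   `run_id` plus one numeric column per factor).
#' @param effect_model named list, one element per factor, each a named
#'   numeric vector mapping level (as character) to an amplitude
#'   multiplier. Missing factors/levels default to multiplier 1.
#' @param base_model a [signal_model()]; per-run seeds are derived from its
#'   seed.
#' @param schedule a [burst_schedule()] shared by all runs.
#' @return named list (run_id -> [generate_recording()] result).
#' @examples
#' suite <- generate_run_suite(build_l9(),
#'   effect_model = list(torso_angle_deg = c(`45` = 2)),
#'   base_model = signal_model(), schedule = burst_schedule(cycle_count = 2))
#' length(suite)
#' @export
generate_run_suite <- function(design = build_l9(),
                               effect_model = list(),
                               base_model = signal_model(),
                               schedule = burst_schedule()) {
  factors <- setdiff(names(design), "run_id")
  if (nrow(design) != 9 || length(factors) != 3) {
    stop("`design` must have 9 runs over 3 factors", call. = FALSE)
  }
  if (anyNA(design[factors])) {
    stop("design row missing a factor level", call. = FALSE)
  }
  out <- setNames(vector("list", nrow(design)), design$run_id)
  for (i in seq_len(nrow(design))) {
    mult <- 1
    for (f in factors) {
      lv <- as.character(design[[f]][i])
      m <- effect_model[[f]]
      if (!is.null(m) && lv %in% names(m)) mult <- mult * m[[lv]]
    }
    run_model <- base_model
    run_model$burst_amplitude <- base_model$burst_amplitude * mult
    run_model$seed <- base_model$seed + 1009L * i
    out[[design$run_id[i]]] <- generate_recording(schedule, run_model)
  }
  out
}
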