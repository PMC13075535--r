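#' Amplitude and RMS features of a processed sEMG series
#'
#' For a series `X = {x1, ..., xn}` the features are the amplitude range
#' `A = max(X) - min(X)` and the root mean square
#' `RMS = sqrt(mean(X^2))`, both in the arbitrary units of the recording.
#'
#' @param x numeric series (filtered signal or envelope), non-empty.
#' @return list with `amplitude` and `rms`.
#' @examples
#' emg_features(c(1, 5, 3))$amplitude  # 4
#' @export
emg_features <- function(x) {
  if (length(x) == 0 || anyNA(x)) {
    stop("`x` must be a non-empty series without missing samples",
         call. = FALSE)
  }
  list(amplitude = max(x) - min(x), rms = sqrt(mean(x^2)))
}

#' Weighted MVC statistic
#'
#' The study's per-task muscle-effort statistic
#' `MVC = w1 * A + w2 * RMS`, with default weights `w1 = 0.7` and
#' `w2 = 0.3`: the amplitude term is sensitive to full recruitment peaks,
#' the RMS term stabilizes against outliers. Despite the name this is a
#' per-task weighted statistic, not a percentage of a calibration maximal
#' contraction.
#'
#' @param amplitude amplitude range `A` (a.u.), or a list as returned by
#'   [emg_features()].
#' @param rms root mean square (a.u.); ignored when `amplitude` is a
#'   feature list.
#' @param w1,w2 non-negative weights (defaults 0.7 / 0.3).
#' @return the MVC value (a.u.).
#' @examples
#' mvc(69.3, 7.8)    # 50.85
#' mvc(179.0, 13.24) # 129.272
#' @export
mvc <- function(amplitude, rms = NULL, w1 = 0.7, w2 = 0.3) {
  if (is.list(amplitude)) {
    rms <- amplitude$rms
    amplitude <- amplitude$amplitude
  }
  if (w1 < 0 || w2 < 0) stop("weights must be >= 0", call. = FALSE)
  w1 * amplitude + w2 * rms
}

#' Compute the run-by-muscle MVC table from a recording suite
#'
#' For each run the chain is: band-pass filter, then per channel the
#' amplitude/RMS features of the full filtered series (optionally
#' restricted to detected activation windows), then the weighted MVC.
#'
#' @param suite named list of recordings (run_id -> recording), e.g. from
#'   [generate_run_suite()].
#' @param spec a [filter_spec()].
#' @param w1,w2 MVC weights.
#' @param windows_only if `TRUE`, features are computed only on samples
#'   inside detected activation events (sensitivity analysis); default
#'   uses the full filtered series.
#' @param ... passed to [detect_activations()] when `windows_only`.
#' @return list with `mvc` (run x muscle matrix), `features` (long
#'   data.frame `run_id, muscle, amplitude, rms, mvc`), and the weights.
#' @export
compute_mvc_table <- function(suite, spec = filter_spec(),
                              w1 = 0.7, w2 = 0.3,
                              windows_only = FALSE, ...) {
  runs <- names(suite)
  channels <- setdiff(names(suite[[1]]$recording), "time_s")
  m <- matrix(NA_real_, length(runs), length(channels),
              dimnames = list(runs, channels))
  feats <- NULL
  for (r in runs) {
    filt <- bandpass_filter(suite[[r]], spec)
    for (ch in channels) {
      x <- filt$recording[[ch]]
      if (windows_only) {
        ev <- detect_activations(x, ...)
        if (nrow(ev) == 0) {
          stop("no activations detected for run ", r, " channel ", ch,
               call. = FALSE)
        }
        idx <- unlist(lapply(seq_len(nrow(ev)),
                             function(i) ev$onset[i]:ev$offset[i]))
        x <- x[idx]
      }
      f <- emg_features(x)
      m[r, ch] <- mvc(f, w1 = w1, w2 = w2)
      feats <- rbind(feats, data.frame(run_id = r, muscle = ch,
                                       amplitude = f$amplitude, rms = f$rms,
                                       mvc = m[r, ch]))
    }
  }
  list(mvc = m, features = feats, w1 = w1, w2 = w2)
}

#' Pearson muscle-coordination matrix
#'
#' Pairwise Pearson correlation of per-run MVC values between muscles.
#' A muscle with constant MVC across runs has no defined correlation; such
#' pairs are returned as `NA` with a warning rather than silently zeroed.
#'
#' @param mvc_matrix numeric run x muscle matrix (>= 3 runs).
#' @return symmetric muscle x muscle matrix of Pearson r, unit diagonal.
#' @examples
#' coordination_matrix(study_mvc_matrix())["BBL", "PDT"]
#' @export
coordination_matrix <- function(mvc_matrix) {
  if (nrow(mvc_matrix) < 3) {
    stop("need at least 3 runs for a coordination matrix", call. = FALSE)
  }
  const <- apply(mvc_matrix, 2, function(x) diff(range(x)) == 0)
  r <- suppressWarnings(cor(mvc_matrix))
  if (any(const)) {
    warning("constant MVC column(s): ",
            paste(colnames(mvc_matrix)[const], collapse = ", "),
            "; correlations reported as NA")
    r[const, ] <- NA_real_
    r[, const] <- NA_real_
  }
  diag(r) <- ifelse(const, NA_real_, 1)
  r
}
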