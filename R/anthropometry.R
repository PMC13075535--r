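#' Percentile summary of an anthropometric sample
#'
#' Per-feature mean, SD and empirical percentiles (linear interpolation
#' between closest order statistics, R's default quantile type 7 — pinned
#' for reproducibility).
#'
#' @param table data.frame, one row per subject, numeric feature columns
#'   (non-numeric columns such as a subject ID are ignored).
#' @param percentiles numeric percentile points (default 5 and 95, the
#'   design bounds used for reach and clearance sizing).
#' @return data.frame `feature, mean, sd` plus one `pX` column per
#'   requested percentile.
#' @examples
#' tab <- generate_anthropometrics(50, seed = 1)
#' percentile_summary(tab)[1:3, ]
#' @export
percentile_summary <- function(table, percentiles = c(5, 95)) {
  num <- vapply(table, is.numeric, TRUE)
  if (!any(num) || nrow(table) < 2) {
    stop("`table` must have >= 2 subjects and numeric feature columns",
         call. = FALSE)
  }
  feats <- names(table)[num]
  out <- data.frame(feature = feats,
                    mean = vapply(feats, function(f) mean(table[[f]]),
                                  numeric(1)),
                    sd = vapply(feats, function(f) sd(table[[f]]),
                                numeric(1)),
                    row.names = NULL)
  for (p in percentiles) {
    out[[paste0("p", p)]] <- vapply(feats, function(f) {
      quantile(table[[f]], p / 100, type = 7, names = FALSE)
    }, numeric(1))
  }
  out
}

#' Wheelchair geometry parameters
#'
#' All lengths in mm. `H1` is the ground-to-seat height (default 500 mm,
#' the prototype value); `L1` and `L2` are the overall length and width
#' used for turning geometry (prototype 600 and 950 mm). `torso_coronal_deg`
#' is the torso angle with the vertical coronal plane (lambda);
#' `torso_sagittal_deg` is the torso angle with the sagittal plane (tau),
#' used only by the lateral-low reach constraint and therefore required
#' explicitly when that constraint is evaluated.
#'
#' @param H1 seat height above ground (mm).
#' @param L1,L2 wheelchair length and width parameters (mm).
#' @param torso_coronal_deg lambda, degrees in `[0, 90]`.
#' @param torso_sagittal_deg tau, degrees in `[0, 90]`.
#' @return an object of class `wheelchair_geometry`.
#' @export
wheelchair_geometry <- function(H1 = 500, L1 = 600, L2 = 950,
                                torso_coronal_deg = 0,
                                torso_sagittal_deg = 0) {
  if (H1 <= 0 || L1 <= 0 || L2 <= 0) {
    stop("H1, L1 and L2 must be positive (mm)", call. = FALSE)
  }
  for (a in c(torso_coronal_deg, torso_sagittal_deg)) {
    if (a < 0 || a > 90) stop("torso angles must lie in [0, 90] degrees",
                              call. = FALSE)
  }
  structure(list(H1 = H1, L1 = L1, L2 = L2,
                 torso_coronal_deg = torso_coronal_deg,
                 torso_sagittal_deg = torso_sagittal_deg),
            class = "wheelchair_geometry")
}

#' Digital-human-model reach constraint check
#'
#' Evaluates the four closed-form reach constraints of the seated
#' digital human model, with `E` the shoulder height above the seat and
#' `K` the shoulder-grip length (both mm), `lambda` the torso angle with
#' the coronal plane and `tau` with the sagittal plane:
#'
#' * forward high:  `H1 + E cos(lambda) + K sin(45 deg) >= 1200`
#' * forward low:   `H1 + E cos(lambda) - K sin(45 deg) >= 400`
#' * lateral high:  `H1 + E + K sin(45 deg) >= 1300`
#' * lateral low:   `H1 + E sin(tau) - K sin(45 deg) >= 250`
#'
#' @param geometry a [wheelchair_geometry()].
#' @param E shoulder height above seat, mm (> 0).
#' @param K shoulder grip length, mm (> 0).
#' @return data.frame `constraint, lhs, bound, margin, pass`; margin is
#'   `lhs - bound` (mm), monotone non-decreasing in `E` and `K` for the
#'   high constraints.
#' @examples
#' reach_check(wheelchair_geometry(), E = 608.5, K = 758)
#' @export
reach_check <- function(geometry, E, K) {
  stopifnot(inherits(geometry, "wheelchair_geometry"))
  if (E <= 0 || K <= 0) stop("E and K must be positive (mm)", call. = FALSE)
  lam <- geometry$torso_coronal_deg * pi / 180
  tau <- geometry$torso_sagittal_deg * pi / 180
  s45 <- sin(pi / 4)
  lhs <- c(forward_high = geometry$H1 + E * cos(lam) + K * s45,
           forward_low  = geometry$H1 + E * cos(lam) - K * s45,
           lateral_high = geometry$H1 + E + K * s45,
           lateral_low  = geometry$H1 + E * sin(tau) - K * s45)
  bound <- c(forward_high = 1200, forward_low = 400,
             lateral_high = 1300, lateral_low = 250)
  data.frame(constraint = names(lhs), lhs = unname(lhs),
             bound = unname(bound), margin = unname(lhs - bound),
             pass = unname(lhs >= bound), row.names = NULL)
}

#' Minimum distance for a 360-degree turn
#'
#' The turning-circle circumference from the wheelchair's length `L1` and
#' width `L2`. Two readings of the turning radius are implemented:
#' `"mean_half_lengths"` (default) takes the radius as `L1/2 + L2/2`,
#' giving a distance of `2 * pi * (L1/2 + L2/2)`; for the prototype
#' (600, 950 mm) this is 4869.5, rounding to 4870 mm — the only reading
#' consistent with the reported prototype value. `"root_sum_squares"`
#' takes the radius as `sqrt(L1^2 + L2^2)` and gives about 7060 mm for
#' the same inputs; it is provided for comparison only.
#'
#' @param geometry a [wheelchair_geometry()] (uses `L1`, `L2`).
#' @param interpretation `"mean_half_lengths"` or `"root_sum_squares"`.
#' @return turning distance in mm.
#' @examples
#' round(turning_distance(wheelchair_geometry()))  # 4870
#' @export
turning_distance <- function(geometry,
                             interpretation = c("mean_half_lengths",
                                                "root_sum_squares")) {
  stopifnot(inherits(geometry, "wheelchair_geometry"))
  interpretation <- match.arg(interpretation)
  switch(interpretation,
         mean_half_lengths = 2 * pi * (geometry$L1 / 2 + geometry$L2 / 2),
         root_sum_squares = 2 * pi * sqrt(geometry$L1^2 + geometry$L2^2))
}

# extract the minimum requirement from a standards entry (scalar or range)
standard_bound <- function(v, which = c("min", "max")) {
  which <- match.arg(which)
  if (is.null(v)) return(NA_real_)
  v <- unlist(v)
  if (which == "min") min(v) else max(v)
}

#' Clearance compliance report against accessibility standards
#'
#' Compares the geometry's computed reach values (per [reach_check()]) and
#' 360-degree turning distance against the bundled reach/clearance bounds
#' from IS-7454, CPWD, CCD and ISO guidelines. Reach rows are compliant
#' when the computed reach meets the standard's minimum; the turning row
#' is compliant when the computed turning distance fits inside the
#' standard's envelope. Bounds a standard does not specify are skipped,
#' not failed.
#'
#' @param geometry a [wheelchair_geometry()].
#' @param E,K as in [reach_check()] (mm).
#' @param standards parsed standards fixture (default
#'   `study_table("clearance_standards")`).
#' @return data.frame `requirement, source, bound, computed, compliant`.
#' @export
clearance_report <- function(geometry, E, K,
                             standards = study_table("clearance_standards")) {
  rc <- reach_check(geometry, E, K)
  computed <- c(setNames(rc$lhs, rc$constraint),
                circular_turn_360 = turning_distance(geometry))
  out <- NULL
  for (row in standards$rows) {
    req <- row$requirement
    if (!req %in% names(computed)) next
    for (src in unlist(standards$sources)) {
      b <- standard_bound(row[[src]],
                          if (row$kind == "reach_min") "min" else "max")
      if (is.na(b)) next
      ok <- if (row$kind == "reach_min") computed[[req]] >= b
            else computed[[req]] <= b
      out <- rbind(out, data.frame(requirement = req, source = src,
                                   bound = b, computed = computed[[req]],
                                   compliant = ok))
    }
  }
  if (is.null(out)) {
    out <- data.frame(requirement = character(), source = character(),
                      bound = numeric(), computed = numeric(),
                      compliant = logical())
  }
  rownames(out) <- NULL
  out
}
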