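#' Factor specification for the ergonomic design of experiments
#'
#' Three seating factors are studied, each at three levels: torso angle
#' lambda (degrees from the vertical coronal plane), lever distance L (mm,
#' seat-to-backrest offset) and lever orientation psi (degrees of forearm
#' rotation; negative = pronation, positive = supination).
#'
#' @param name factor name (one of the standard three, or any string for
#'   custom designs).
#' @param levels exactly 3 distinct numeric levels, in design order
#'   (level 1, 2, 3).
#' @param labels optional text labels per level.
#' @return an object of class `factor_spec`.
#' @export
factor_spec <- function(name, levels, labels = as.character(levels)) {
  if (length(levels) != 3 || anyDuplicated(levels)) {
    stop("`levels` must be 3 distinct numeric values", call. = FALSE)
  }
  structure(list(name = name, levels = as.numeric(levels), labels = labels),
            class = "factor_spec")
}

#' The study's three ergonomic factors at their printed levels
#'
#' Level order follows the design table: torso angle (45, 30, 0) degrees,
#' lever distance (0, 50, 100) mm, lever orientation (-30, 0, +30) degrees.
#'
#' @return list of three [factor_spec()] objects.
#' @export
default_factors <- function() {
  list(
    factor_spec("torso_angle_deg", c(45, 30, 0),
                c("highly inclined", "inclined", "straight")),
    factor_spec("lever_distance_mm", c(0, 50, 100),
                c("farthest", "neutral", "closest")),
    factor_spec("lever_orientation_deg", c(-30, 0, 30),
                c("pronation", "neutral", "supination"))
  )
}

# standard L9(3^3) orthogonal array (first three columns of L9(3^4))
L9_ARRAY <- cbind(A = rep(1:3, each = 3),
                  B = rep(1:3, times = 3),
                  C = c(1, 2, 3, 2, 3, 1, 3, 1, 2))

#' Build the L9 fractional factorial design matrix
#'
#' Assigns the standard L9 orthogonal array to the three factors' level
#' orderings, yielding the 9-run design E1-E9 (a 1/3 fraction of the
#' 27-run full factorial). Every factor level appears in exactly 3 runs
#' and every ordered level pair of any two factors in exactly 1 run.
#'
#' @param factors list of exactly 3 [factor_spec()] objects.
#' @return data.frame with `run_id` (E1-E9) and one numeric column per
#'   factor.
#' @examples
#' build_l9()[1, ]  # E1: 45 deg, 0 mm, -30 deg
#' @export
build_l9 <- function(factors = default_factors()) {
  if (length(factors) != 3 || !all(vapply(factors, inherits, TRUE,
                                          "factor_spec"))) {
    stop("`factors` must be a list of exactly 3 factor_spec objects",
         call. = FALSE)
  }
  out <- data.frame(run_id = paste0("E", 1:9))
  for (k in 1:3) {
    out[[factors[[k]]$name]] <- factors[[k]]$levels[L9_ARRAY[, k]]
  }
  out
}

# responses: run x muscle matrix aligned to design$run_id, with checks
align_responses <- function(design, responses) {
  if (is.list(responses) && !is.null(responses$mvc)) responses <- responses$mvc
  missing <- setdiff(design$run_id, rownames(responses))
  if (length(missing)) {
    stop("responses missing run(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  responses[design$run_id, , drop = FALSE]
}

#' Main effects of the design factors on MVC
#'
#' For each factor, level and muscle: the arithmetic mean of the MVC
#' values of the 3 runs at that level. In a balanced L9 the mean of the 3
#' level means equals the grand mean of all 9 runs.
#'
#' @param design design matrix from [build_l9()].
#' @param responses run x muscle MVC matrix (or [compute_mvc_table()]
#'   output) covering all 9 runs.
#' @return data.frame `factor, level, muscle, mean_mvc`, levels in
#'   ascending numeric order within each factor.
#' @examples
#' me <- main_effects(build_l9(), study_mvc_matrix())
#' subset(me, factor == "torso_angle_deg" & muscle == "BBL")
#' @export
main_effects <- function(design, responses) {
  responses <- align_responses(design, responses)
  factors <- setdiff(names(design), "run_id")
  out <- NULL
  for (f in factors) {
    for (lv in sort(unique(design[[f]]))) {
      runs <- design$run_id[design[[f]] == lv]
      mu <- colMeans(responses[runs, , drop = FALSE])
      out <- rbind(out, data.frame(factor = f, level = lv,
                                   muscle = names(mu), mean_mvc = unname(mu)))
    }
  }
  rownames(out) <- NULL
  out
}

#' Two-factor interaction grid
#'
#' Tabulates mean MVC over the cross of two factors' levels. In an L9
#' every level pair occurs in exactly one run, so each cell is a single
#' run's value and two-factor effects are confounded with the third
#' factor's main effect — the grids describe the observed design space,
#' they do not estimate pure interactions.
#'
#' @inheritParams main_effects
#' @param factor_pair character vector of two distinct factor names.
#' @return named list (muscle -> 3 x 3 matrix); rows are levels of the
#'   first factor, columns of the second, in ascending numeric order.
#' @export
interaction_grid <- function(design, responses, factor_pair) {
  if (length(factor_pair) != 2 || factor_pair[1] == factor_pair[2]) {
    stop("`factor_pair` must name two distinct factors", call. = FALSE)
  }
  responses <- align_responses(design, responses)
  l1 <- sort(unique(design[[factor_pair[1]]]))
  l2 <- sort(unique(design[[factor_pair[2]]]))
  lapply(setNames(colnames(responses), colnames(responses)), function(m) {
    g <- matrix(NA_real_, length(l1), length(l2),
                dimnames = list(as.character(l1), as.character(l2)))
    for (i in seq_along(l1)) for (j in seq_along(l2)) {
      runs <- design$run_id[design[[factor_pair[1]]] == l1[i] &
                            design[[factor_pair[2]]] == l2[j]]
      if (length(runs)) g[i, j] <- mean(responses[runs, m])
    }
    g
  })
}

#' Quadratic response fit of MVC on one factor
#'
#' Ordinary least squares of the 9 run MVCs on `(1, x, x^2)` where `x` is
#' the factor's numeric level. With 3 distinct levels at equal replication
#' the fitted curve interpolates the 3 level means, so the intercept
#' equals the mean response at `x = 0`. R-squared is reported in percent
#' (between-level SS over total SS); the residual standard error is
#' `sqrt(SSE / 6)` (9 runs minus 3 coefficients).
#'
#' @inheritParams main_effects
#' @param factor factor name.
#' @param muscle muscle (response column) name.
#' @return list `b0, b1, b2, r_squared_pct, residual_standard_error,
#'   residual_ss`.
#' @examples
#' fit_quadratic(build_l9(), study_mvc_matrix(),
#'               "torso_angle_deg", "BBL")$r_squared_pct  # ~38.7
#' @export
fit_quadratic <- function(design, responses, factor, muscle) {
  responses <- align_responses(design, responses)
  x <- design[[factor]]
  if (is.null(x)) stop("unknown factor: ", factor, call. = FALSE)
  if (length(unique(x)) < 3) {
    stop("factor needs 3 distinct levels for a quadratic fit", call. = FALSE)
  }
  y <- responses[, muscle]
  fit <- lm(y ~ x + I(x^2))
  sse <- sum(resid(fit)^2)
  sst <- sum((y - mean(y))^2)
  list(b0 = unname(coef(fit)[1]), b1 = unname(coef(fit)[2]),
       b2 = unname(coef(fit)[3]),
       r_squared_pct = 100 * (1 - sse / sst),
       residual_standard_error = sqrt(sse / fit$df.residual),
       residual_ss = sse)
}

#' Quadratic fits for every factor-muscle pair
#'
#' @inheritParams main_effects
#' @return data.frame `muscle, factor, b0, b1, b2, r_squared_pct,
#'   residual_standard_error, residual_ss`.
#' @export
fit_quadratic_all <- function(design, responses) {
  responses <- align_responses(design, responses)
  out <- NULL
  for (m in colnames(responses)) {
    for (f in setdiff(names(design), "run_id")) {
      ft <- fit_quadratic(design, responses, f, m)
      out <- rbind(out, data.frame(muscle = m, factor = f,
                                   b0 = ft$b0, b1 = ft$b1, b2 = ft$b2,
                                   r_squared_pct = ft$r_squared_pct,
                                   residual_standard_error =
                                     ft$residual_standard_error,
                                   residual_ss = ft$residual_ss))
    }
  }
  out
}

#' Per-muscle optimal factor levels (minimum muscle effort)
#'
#' For each muscle and factor, the level with the smallest main-effect
#' mean MVC. Ties are broken toward the lower level index with a warning.
#'
#' @param effects main-effect table from [main_effects()].
#' @return data.frame, one row per muscle, one numeric column per factor.
#' @examples
#' optimal_levels(main_effects(build_l9(), study_mvc_matrix()))
#' @export
optimal_levels <- function(effects) {
  muscles <- unique(effects$muscle)
  factors <- unique(effects$factor)
  out <- data.frame(muscle = muscles)
  for (f in factors) out[[f]] <- NA_real_
  for (m in muscles) {
    for (f in factors) {
      sub <- effects[effects$muscle == m & effects$factor == f, ]
      best <- which(sub$mean_mvc == min(sub$mean_mvc))
      if (length(best) > 1) {
        warning("tie in optimal level for ", m, " / ", f,
                "; taking the lower level")
        best <- best[1]
      }
      out[out$muscle == m, f] <- sub$level[best]
    }
  }
  out
}

#' Overall ergonomic recommendation (averaged across muscles)
#'
#' The per-factor arithmetic mean of the muscles' optimal numeric
#' settings: one generalized seating configuration instead of four
#' muscle-specific ones.
#'
#' @param optima data.frame from [optimal_levels()].
#' @return data.frame `factor, optimal_setting`.
#' @examples
#' overall_recommendation(
#'   optimal_levels(main_effects(build_l9(), study_mvc_matrix())))
#' @export
overall_recommendation <- function(optima) {
  factors <- setdiff(names(optima), "muscle")
  data.frame(factor = factors,
             optimal_setting = vapply(factors,
                                      function(f) mean(optima[[f]]),
                                      numeric(1)),
             row.names = NULL)
}

#' Design-space surface over a factor pair
#'
#' Evaluates a response surface for one muscle over a rectangular grid of
#' two factors. With `from = "grids"` the surface interpolates the
#' observed 3 x 3 interaction grid bilinearly (exact at the design
#' points); with `from = "fits"` it is the additive quadratic
#' `q1(x1) + q2(x2) - grand mean` built from the single-factor fits.
#'
#' @inheritParams interaction_grid
#' @param muscle response column name.
#' @param resolution grid points per axis (>= 2).
#' @param from surface construction, `"grids"` or `"fits"`.
#' @return list `x1, x2` (axis values), `z` (resolution x resolution
#'   matrix), `argmin`, `argmax` (named coordinates and values).
#' @export
design_space_surface <- function(design, responses, factor_pair, muscle,
                                 resolution = 25,
                                 from = c("grids", "fits")) {
  from <- match.arg(from)
  if (resolution < 2) stop("`resolution` must be >= 2", call. = FALSE)
  responses <- align_responses(design, responses)
  l1 <- sort(unique(design[[factor_pair[1]]]))
  l2 <- sort(unique(design[[factor_pair[2]]]))
  x1 <- seq(min(l1), max(l1), length.out = resolution)
  x2 <- seq(min(l2), max(l2), length.out = resolution)
  if (from == "grids") {
    g <- interaction_grid(design, responses, factor_pair)[[muscle]]
    # piecewise-bilinear interpolation of the 3x3 grid
    interp1 <- function(v, grid_x, grid_v) {
      i <- findInterval(v, grid_x, rightmost.closed = TRUE)
      i <- pmin(pmax(i, 1L), length(grid_x) - 1L)
      w <- (v - grid_x[i]) / (grid_x[i + 1] - grid_x[i])
      list(i = i, w = w)
    }
    a1 <- interp1(x1, l1, NULL); a2 <- interp1(x2, l2, NULL)
    z <- matrix(NA_real_, resolution, resolution)
    for (i in seq_len(resolution)) for (j in seq_len(resolution)) {
      i0 <- a1$i[i]; w1 <- a1$w[i]; j0 <- a2$i[j]; w2 <- a2$w[j]
      z[i, j] <- (1 - w1) * (1 - w2) * g[i0, j0] +
        w1 * (1 - w2) * g[i0 + 1, j0] +
        (1 - w1) * w2 * g[i0, j0 + 1] +
        w1 * w2 * g[i0 + 1, j0 + 1]
    }
  } else {
    f1 <- fit_quadratic(design, responses, factor_pair[1], muscle)
    f2 <- fit_quadratic(design, responses, factor_pair[2], muscle)
    gm <- mean(responses[, muscle])
    q1 <- f1$b0 + f1$b1 * x1 + f1$b2 * x1^2
    q2 <- f2$b0 + f2$b1 * x2 + f2$b2 * x2^2
    z <- outer(q1, q2, `+`) - gm
  }
  imin <- which(z == min(z), arr.ind = TRUE)[1, ]
  imax <- which(z == max(z), arr.ind = TRUE)[1, ]
  list(x1 = x1, x2 = x2, z = z,
       argmin = c(setNames(c(x1[imin[1]], x2[imin[2]]), factor_pair),
                  value = min(z)),
       argmax = c(setNames(c(x1[imax[1]], x2[imax[2]]), factor_pair),
                  value = max(z)))
}

#' Plot an interaction grid as a heatmap
#'
#' Minimal base-graphics helper mirroring the study's interaction
#' heatmaps; intended for quick inspection, not publication figures.
#'
#' @param grid a 3 x 3 matrix from [interaction_grid()].
#' @param main plot title.
#' @return invisibly, the grid.
#' @export
plot_interaction_grid <- function(grid, main = "") {
  x <- as.numeric(rownames(grid))
  y <- as.numeric(colnames(grid))
  graphics::image(x, y, grid, main = main, xlab = "", ylab = "",
                  col = grDevices::hcl.colors(24, "YlOrRd", rev = TRUE))
  for (i in seq_along(x)) for (j in seq_along(y)) {
    graphics::text(x[i], y[j], sprintf("%.1f", grid[i, j]))
  }
  invisible(grid)
}
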