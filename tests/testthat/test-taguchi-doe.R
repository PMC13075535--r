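test_that("the L9 design reproduces the study layout and is orthogonal", {
  d <- build_l9()
  expect_equal(d$run_id, paste0("E", 1:9))
  expect_equal(unlist(d[d$run_id == "E1", -1], use.names = FALSE),
               c(45, 0, -30))
  expect_equal(unlist(d[d$run_id == "E9", -1], use.names = FALSE),
               c(0, 100, 0))
  factors <- setdiff(names(d), "run_id")
  # each level in exactly 3 runs; each ordered level pair in exactly 1 run
  for (f in factors) expect_true(all(table(d[[f]]) == 3))
  for (pair in utils::combn(factors, 2, simplify = FALSE)) {
    expect_true(all(table(d[[pair[1]]], d[[pair[2]]]) == 1))
  }
  expect_error(build_l9(default_factors()[1:2]), "3 factor")
  expect_error(factor_spec("x", c(1, 2)), "3 distinct")
})

test_that("main effects are the level means and conserve the grand mean", {
  d <- build_l9()
  m <- study_mvc_matrix()
  me <- main_effects(d, m)
  bbl0 <- me$mean_mvc[me$factor == "torso_angle_deg" & me$level == 0 &
                        me$muscle == "BBL"]
  expect_equal(bbl0, mean(c(36.04, 36.49, 42.86)), tolerance = 1e-12)
  brd45 <- me$mean_mvc[me$factor == "torso_angle_deg" & me$level == 45 &
                         me$muscle == "BRD"]
  expect_equal(round(brd45, 2), 113.41)
  # grand-mean conservation for every factor and muscle
  for (f in unique(me$factor)) for (mu in colnames(m)) {
    lvl <- me$mean_mvc[me$factor == f & me$muscle == mu]
    expect_equal(mean(lvl), mean(m[, mu]), tolerance = 1e-9)
  }
  # constant responses give constant level means
  const <- matrix(7, 9, 2, dimnames = list(d$run_id, c("A", "B")))
  expect_true(all(main_effects(d, const)$mean_mvc == 7))
  expect_error(main_effects(d, m[1:8, ]), "E9")
})

test_that("interaction grids hold single-run cells whose margins are the main effects", {
  d <- build_l9()
  m <- study_mvc_matrix()
  g <- interaction_grid(d, m, c("torso_angle_deg", "lever_distance_mm"))
  # cell (45, 0) is run E1
  expect_equal(g$BRD["45", "0"], m["E1", "BRD"])
  expect_equal(g$BBL["0", "50"], m["E8", "BBL"])
  # row means of the AB grid equal the torso-angle main effects exactly
  me <- main_effects(d, m)
  for (mu in names(g)) {
    rm <- rowMeans(g[[mu]])
    ref <- me[me$factor == "torso_angle_deg" & me$muscle == mu, ]
    expect_equal(unname(rm[as.character(ref$level)]), ref$mean_mvc,
                 tolerance = 1e-12)
    cm <- colMeans(g[[mu]])
    ref2 <- me[me$factor == "lever_distance_mm" & me$muscle == mu, ]
    expect_equal(unname(cm[as.character(ref2$level)]), ref2$mean_mvc,
                 tolerance = 1e-12)
  }
  const <- matrix(3, 9, 1, dimnames = list(d$run_id, "A"))
  expect_true(all(interaction_grid(d, const,
                                   c("torso_angle_deg",
                                     "lever_orientation_deg"))$A == 3))
  expect_error(interaction_grid(d, m, c("torso_angle_deg", "torso_angle_deg")),
               "distinct")
})

test_that("quadratic fits agree with an independent normal-equations solve", {
  d <- build_l9()
  m <- study_mvc_matrix()
  for (f in setdiff(names(d), "run_id")) for (mu in colnames(m)) {
    ft <- fit_quadratic(d, m, f, mu)
    x <- d[[f]]
    X <- cbind(1, x, x^2)
    beta <- solve(t(X) %*% X, t(X) %*% m[, mu])
    expect_equal(c(ft$b0, ft$b1, ft$b2), as.numeric(beta), tolerance = 1e-9)
    # the fitted curve interpolates the three level means
    me <- main_effects(d, m)
    ref <- me[me$factor == f & me$muscle == mu, ]
    pred <- ft$b0 + ft$b1 * ref$level + ft$b2 * ref$level^2
    expect_equal(pred, ref$mean_mvc, tolerance = 1e-9)
  }
})

test_that("quadratic fit coefficients solve the 3x3 interpolation of level means", {
  # independent oracle: exact linear solve through the torso-angle level
  # means of BBL at x = 0, 30, 45
  mns <- c(mean(c(36.04, 36.49, 42.86)),   # 0 deg
           mean(c(39.52, 43.88, 42.39)),   # 30 deg
           mean(c(50.85, 41.04, 42.46)))   # 45 deg
  V <- cbind(1, c(0, 30, 45), c(0, 30, 45)^2)
  beta <- solve(V, mns)
  ft <- fit_quadratic(build_l9(), study_mvc_matrix(), "torso_angle_deg", "BBL")
  expect_equal(c(ft$b0, ft$b1, ft$b2), beta, tolerance = 1e-9)
  # agrees with the reported equation to printed rounding
  expect_equal(round(ft$b0, 2), 38.46)
  expect_equal(round(ft$b2, 6), 0.001659)
})

test_that("an exactly quadratic response with no within-level spread fits perfectly", {
  d <- build_l9()
  x <- d$torso_angle_deg
  y <- matrix(2 + 0.5 * x - 0.01 * x^2, 9, 1,
              dimnames = list(d$run_id, "M"))
  ft <- fit_quadratic(d, y, "torso_angle_deg", "M")
  expect_equal(ft$r_squared_pct, 100)
  expect_equal(ft$residual_standard_error, 0, tolerance = 1e-9)
  d2 <- d
  d2$torso_angle_deg <- rep(c(0, 30, 30), 3)
  expect_error(fit_quadratic(d2, y, "torso_angle_deg", "M"), "3 distinct")
})

test_that("per-muscle optima and the averaged recommendation match the report", {
  me <- main_effects(build_l9(), study_mvc_matrix())
  opt <- optimal_levels(me)
  ref <- study_table("optimal_levels")
  expect_equal(opt[match(ref$muscle, opt$muscle),
                   c("torso_angle_deg", "lever_distance_mm",
                     "lever_orientation_deg")],
               ref[c("torso_angle_deg", "lever_distance_mm",
                     "lever_orientation_deg")],
               ignore_attr = TRUE)
  ov <- overall_recommendation(opt)
  expect_equal(ov$optimal_setting[match(c("torso_angle_deg",
                                          "lever_distance_mm",
                                          "lever_orientation_deg"),
                                        ov$factor)],
               c(0, 37.5, 15))
  # all-equal main effects: first level everywhere, with a tie warning
  flat <- me
  flat$mean_mvc <- 1
  w <- capture_warnings(o2 <- optimal_levels(flat))
  expect_true(all(grepl("tie", w)))
  expect_length(w, 12)  # one tie per muscle-factor pair
  expect_true(all(o2$torso_angle_deg == 0))
  expect_true(all(o2$lever_distance_mm == 0))
  expect_true(all(o2$lever_orientation_deg == -30))
})

test_that("design-space surfaces reproduce grids at design points and locate extremes", {
  d <- build_l9()
  m <- study_mvc_matrix()
  pair <- c("torso_angle_deg", "lever_distance_mm")
  g <- interaction_grid(d, m, pair)$BBL
  # a grid-built surface evaluated on the 3 levels equals the grid
  s <- design_space_surface(d, m, pair, "BBL", resolution = 4, from = "grids")
  # resolution chosen so axis points include the level extremes
  expect_equal(s$z[1, 1], g["0", "0"])
  expect_equal(s$z[4, 4], g["45", "100"])
  # constant response: flat surface under both constructions
  const <- matrix(5, 9, 1, dimnames = list(d$run_id, "A"))
  for (from in c("grids", "fits")) {
    sc <- design_space_surface(d, const, pair, "A", resolution = 5,
                               from = from)
    expect_true(all(abs(sc$z - 5) < 1e-9))
  }
  # injected minimum at (0 deg, 50 mm) is recovered as the argmin cell
  y <- matrix(10 + (d$torso_angle_deg / 45)^2 * 20 +
                ((d$lever_distance_mm - 50) / 50)^2 * 15, 9, 1,
              dimnames = list(d$run_id, "A"))
  sm <- design_space_surface(d, y, pair, "A", resolution = 11, from = "fits")
  expect_equal(unname(sm$argmin["torso_angle_deg"]), 0)
  expect_equal(unname(sm$argmin["lever_distance_mm"]), 50)
  expect_error(design_space_surface(d, m, pair, "BBL", resolution = 1),
               "resolution")
})
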