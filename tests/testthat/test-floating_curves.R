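test_that("constant data give a constant curve; empty windows are masked", {
  xs <- seq(20, 80, by = 0.5)
  cv <- floating_stat_curve(xs, rep(7, length(xs)),
                            axis_config("age", min_window_n = 5))
  expect_true(all(cv$value[!is.na(cv$value)] == 7))
  expect_true(any(!is.na(cv$value)))
  # a hole in xs leaves window_n = 0 and a missing value
  xs2 <- c(1:10, 40:50)
  cv2 <- floating_stat_curve(xs2, xs2, axis_config("age", half_width = 2,
                                                   min_window_n = 1))
  mid <- cv2$grid == 25
  expect_equal(cv2$window_n[mid], 0L)
  expect_true(is.na(cv2$value[mid]))
})

test_that("floating median of ys = xs recovers the grid at interior points", {
  xs <- 0:100
  cv <- floating_stat_curve(xs, xs, axis_config("age", min_window_n = 1))
  interior <- cv$grid >= 5 & cv$grid <= 95
  expect_equal(cv$value[interior], cv$grid[interior])
})

test_that("curves respond locally and shift equivariantly", {
  set.seed(2)
  xs <- runif(400, 20, 80)
  ys <- rlnorm(400, 1.5, 0.5)
  cfg <- axis_config("age", min_window_n = 5)
  base <- floating_stat_curve(xs, ys, cfg, 99)
  # perturb one subject: only grid points whose window holds it may change
  ys2 <- ys
  ys2[17] <- ys2[17] + 50
  pert <- floating_stat_curve(xs, ys2, cfg, 99)
  changed <- which(!isTRUE(all.equal(base$value, pert$value)) &
                   (is.na(base$value) != is.na(pert$value) |
                    abs(ifelse(is.na(base$value), 0, base$value) -
                        ifelse(is.na(pert$value), 0, pert$value)) > 1e-12))
  expect_true(all(abs(base$grid[changed] - xs[17]) <= cfg$half_width))
  # adding a constant shifts every defined value by exactly that constant
  shifted <- floating_stat_curve(xs, ys + 2.5, cfg, 99)
  expect_equal(shifted$value, base$value + 2.5)
})

test_that("floating P50 never exceeds floating P99; bands bracket at matched windows", {
  co <- generate_cohort(generator_params(n_subjects = 3000, seed = 15))
  m <- co[co$sex == "M", ]
  cfg <- axis_config("age")
  p50 <- floating_stat_curve(m$age, m$troponin, cfg, "median")
  p99 <- floating_stat_curve(m$age, m$troponin, cfg, 99)
  both <- !is.na(p50$value) & !is.na(p99$value)
  expect_true(all(p50$value[both] <= p99$value[both]))
  # same-window band strictly brackets the P99 curve
  cfg10 <- axis_config("age", half_width = 10)
  band <- percentile_band(m$age, m$troponin, cfg, band_half_width = 10)
  p99w <- floating_stat_curve(m$age, m$troponin, cfg10, 99)
  ok <- !is.na(band$low$value) & !is.na(p99w$value) & !is.na(band$high$value)
  expect_true(any(ok))
  expect_true(all(band$low$value[ok] <= p99w$value[ok]))
  expect_true(all(p99w$value[ok] <= band$high$value[ok]))
  expect_error(percentile_band(m$age, m$troponin, cfg, p_low = 99,
                               p_high = 97), "p_low")
})

test_that("surfaces are flat for constant data and row-constant for age-only signals", {
  grid <- expand.grid(age = seq(30, 70, 2), cr = seq(60, 110, 5))
  flat <- floating_surface(grid$age, grid$cr, rep(4, nrow(grid)),
                           axis_config("age", min_window_n = 3),
                           axis_config("creatinine", min_window_n = 3))
  vals <- flat$values[!is.na(flat$values)]
  expect_true(all(vals == 4))
  # troponin a deterministic function of age only, full factorial design:
  # every age row is exactly constant across creatinine where defined
  ys <- 2 + 0.1 * grid$age
  sg <- floating_surface(grid$age, grid$cr, ys,
                         axis_config("age", min_window_n = 3),
                         axis_config("creatinine", min_window_n = 3))
  for (i in seq_along(sg$age_grid)) {
    row <- sg$values[i, ]
    row <- row[!is.na(row)]
    if (length(row) > 1) expect_equal(max(row) - min(row), 0)
  }
  expect_error(floating_surface(1:3, 1:2, 1:3), "equal length")
})

test_that("on generated cohorts the creatinine axis adds little beyond age", {
  co <- generate_cohort(generator_params(n_subjects = 6000, seed = 23))
  m <- co[co$sex == "M" & !co$cardiac_disease, ]
  sg <- floating_surface(m$age, m$creatinine, m$troponin)
  col_means <- apply(sg$values, 1, mean, na.rm = TRUE)   # age profile
  row_means <- apply(sg$values, 2, mean, na.rm = TRUE)   # creatinine profile
  age_range <- diff(range(col_means, na.rm = TRUE))
  cr_range <- diff(range(row_means, na.rm = TRUE))
  expect_gt(age_range, 3 * cr_range)
})
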