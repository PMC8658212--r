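# Sliding-window ("floating") percentile statistics: 1-D curves along age,
# creatinine, or eGFR, the extreme-percentile band, and the 2-D
# 99th-percentile surface over (age, creatinine).  Windows are plain
# closed rectangular intervals; no kernel weighting or smoothing.

#' Window configuration for a floating-curve axis
#'
#' Defaults follow the analysis conventions per axis: age in 1-year steps
#' with a ±5-year window; creatinine in 10 µmol/L steps with ±15 µmol/L;
#' eGFR in 3 mL/min/1.73 m² steps with ±10.  `min_window_n` (default 20)
#' masks grid points whose window holds fewer subjects, suppressing wild
#' extreme-percentile estimates in sparse windows.
#'
#' @param axis `"age"`, `"creatinine"`, or `"egfr"`.
#' @param step Grid spacing in axis units (default per axis).
#' @param half_width Window half-width in axis units (default per axis).
#' @param min_window_n Minimum subjects per window, default 20.
#' @return A list with elements `axis`, `step`, `half_width`,
#'   `min_window_n`.
#' @export
axis_config <- function(axis = c("age", "creatinine", "egfr"),
                        step = NULL, half_width = NULL, min_window_n = 20) {
  axis <- match.arg(axis)
  defaults <- switch(axis,
    age = c(step = 1, half_width = 5),
    creatinine = c(step = 10, half_width = 15),
    egfr = c(step = 3, half_width = 10))
  step <- if (is.null(step)) defaults[["step"]] else step
  half_width <- if (is.null(half_width)) defaults[["half_width"]] else half_width
  stopifnot(is.numeric(step), step > 0, is.numeric(half_width),
            half_width > 0, is.numeric(min_window_n), min_window_n >= 1)
  list(axis = axis, step = step, half_width = half_width,
       min_window_n = min_window_n)
}

#' Floating (sliding-window) statistic along a covariate axis
#'
#' At each grid point g the statistic of `{ys : |xs - g| <= half_width}` is
#' computed; the grid spans the observed range of `xs` rounded outward to
#' multiples of `step`, and windows are closed intervals.  Grid points
#' whose window holds fewer than `min_window_n` subjects are reported as
#' missing with their count.
#'
#' @param xs Covariate values (axis units).
#' @param ys Troponin (or other response) values, same length as `xs`.
#' @param config An [axis_config()].
#' @param stat `"median"` or a percentile level in (0, 100) (e.g. 99).
#' @return A data frame of class `"floating_curve"` with columns `grid`,
#'   `value`, `window_n`; axis metadata in attributes.
#' @export
floating_stat_curve <- function(xs, ys, config = axis_config("age"),
                                stat = "median") {
  if (length(xs) != length(ys)) {
    stop("`xs` and `ys` must have equal length", call. = FALSE)
  }
  p <- if (identical(stat, "median")) 50 else {
    if (!is.numeric(stat) || length(stat) != 1L || stat <= 0 || stat >= 100) {
      stop("`stat` must be \"median\" or a percentile in (0, 100)",
           call. = FALSE)
    }
    stat
  }
  if (length(xs) == 0L) {
    out <- data.frame(grid = numeric(0), value = numeric(0),
                      window_n = integer(0))
  } else {
    lo <- floor(min(xs) / config$step) * config$step
    hi <- ceiling(max(xs) / config$step) * config$step
    grid <- seq(lo, hi, by = config$step)
    value <- rep(NA_real_, length(grid))
    window_n <- integer(length(grid))
    for (i in seq_along(grid)) {
      sel <- abs(xs - grid[i]) <= config$half_width
      window_n[i] <- sum(sel)
      if (window_n[i] >= config$min_window_n) {
        value[i] <- percentile_point(ys[sel], p)
      }
    }
    out <- data.frame(grid = grid, value = value, window_n = window_n)
  }
  attr(out, "axis") <- config$axis
  attr(out, "stat") <- if (identical(stat, "median")) "median" else paste0("p", p)
  attr(out, "step") <- config$step
  attr(out, "half_width") <- config$half_width
  attr(out, "min_window_n") <- config$min_window_n
  class(out) <- c("floating_curve", "data.frame")
  out
}

#' Floating extreme-percentile band
#'
#' Lower and upper floating percentile curves (defaults: 97th and 99.4th)
#' bracketing the 99th-percentile curve, computed with the band's own
#' window half-width (default ±10 axis units).
#'
#' @param xs,ys As in [floating_stat_curve()].
#' @param config An [axis_config()]; its `half_width` is replaced by
#'   `band_half_width`.
#' @param p_low,p_high Band percentile levels, `p_low < p_high`.
#' @param band_half_width Window half-width for the band, default 10.
#' @return A list with elements `low` and `high`, each a
#'   `"floating_curve"`.
#' @export
percentile_band <- function(xs, ys, config = axis_config("age"),
                            p_low = 97, p_high = 99.4,
                            band_half_width = 10) {
  if (!is.numeric(p_low) || !is.numeric(p_high) || p_low >= p_high) {
    stop("`p_low` must be smaller than `p_high`", call. = FALSE)
  }
  cfg <- config
  cfg$half_width <- band_half_width
  list(low = floating_stat_curve(xs, ys, cfg, p_low),
       high = floating_stat_curve(xs, ys, cfg, p_high))
}

#' Floating 99th-percentile surface over (age, creatinine)
#'
#' At each (a, c) node of the rectangular grid, the 99th percentile of
#' `ys` within the window `|age - a| <= hw_age` and
#' `|creatinine - c| <= hw_cr` is computed; nodes whose window holds fewer
#' than `min_window_n` subjects (the larger of the two axis settings) are
#' missing.
#'
#' @param ages,creatinines,ys Equal-length subject vectors.
#' @param age_config,cr_config [axis_config()]s for the two axes.
#' @param p Percentile level of the surface, default 99.
#' @return A list of class `"surface_grid"`: `age_grid`, `cr_grid`,
#'   `values` (matrix, ages in rows), `window_n` (matrix).
#' @export
floating_surface <- function(ages, creatinines, ys,
                             age_config = axis_config("age"),
                             cr_config = axis_config("creatinine"),
                             p = 99) {
  n <- length(ys)
  if (length(ages) != n || length(creatinines) != n) {
    stop("`ages`, `creatinines`, `ys` must have equal length", call. = FALSE)
  }
  if (n == 0L) stop("empty input", call. = FALSE)
  agrid <- seq(floor(min(ages) / age_config$step) * age_config$step,
               ceiling(max(ages) / age_config$step) * age_config$step,
               by = age_config$step)
  cgrid <- seq(floor(min(creatinines) / cr_config$step) * cr_config$step,
               ceiling(max(creatinines) / cr_config$step) * cr_config$step,
               by = cr_config$step)
  min_n <- max(age_config$min_window_n, cr_config$min_window_n)
  values <- matrix(NA_real_, length(agrid), length(cgrid))
  window_n <- matrix(0L, length(agrid), length(cgrid))
  for (i in seq_along(agrid)) {
    in_age <- abs(ages - agrid[i]) <= age_config$half_width
    for (j in seq_along(cgrid)) {
      sel <- in_age & abs(creatinines - cgrid[j]) <= cr_config$half_width
      window_n[i, j] <- sum(sel)
      if (window_n[i, j] >= min_n) {
        values[i, j] <- percentile_point(ys[sel], p)
      }
    }
  }
  structure(list(age_grid = agrid, cr_grid = cgrid, values = values,
                 window_n = window_n, p = p),
            class = "surface_grid")
}
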