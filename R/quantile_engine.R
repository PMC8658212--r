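# Percentile point estimates, the detection-limit floor transform, and
# exact (binomial order-statistic) confidence intervals for quantiles.

#' Replace values below the assay reporting limit by the limit
#'
#' High-sensitivity troponin T assays report values below the limit of
#' detection as "< 3 ng/L"; for analysis those values are substituted by the
#' limit itself, producing a left-censored sample whose minimum is exactly
#' the floor.
#'
#' @param values Numeric vector of assay values (ng/L). Must be finite.
#' @param floor Reporting limit (ng/L); default 3.
#' @return Numeric vector of the same length and order with every value
#'   below `floor` replaced by `floor`.
#' @examples
#' apply_detection_floor(c(1.0, 2.9, 3.0, 5.5))
#' @export
apply_detection_floor <- function(values, floor = 3) {
  if (length(values) == 0L) return(numeric(0))
  if (!is.numeric(values)) stop("`values` must be numeric", call. = FALSE)
  if (any(!is.finite(values))) {
    stop("non-finite value at position ", which(!is.finite(values))[1L],
         call. = FALSE)
  }
  if (!is.numeric(floor) || length(floor) != 1L || !is.finite(floor) ||
      floor <= 0) {
    stop("`floor` must be a single positive number", call. = FALSE)
  }
  pmax(values, floor)
}

#' Linear-interpolation percentile point estimate
#'
#' The conventional sample quantile with linear interpolation between order
#' statistics: with the sample sorted as x_(1) <= ... <= x_(n) and
#' h = (n - 1) p / 100, the estimate is
#' x_(floor(h)+1) + (h - floor(h)) (x_(floor(h)+2) - x_(floor(h)+1)).
#' This is quantile type 7 in the Hyndman-Fan taxonomy (the default of both
#' R and NumPy).
#'
#' @param values Nonempty numeric vector.
#' @param p Percentile level in \[0, 100\].
#' @return The percentile point estimate.
#' @examples
#' percentile_point(1:100, 99) # 99.01
#' @export
percentile_point <- function(values, p) {
  if (length(values) == 0L) stop("empty sample", call. = FALSE)
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 100) {
    stop("`p` must be a single value in [0, 100]", call. = FALSE)
  }
  x <- sort(values)
  n <- length(x)
  h <- (n - 1) * p / 100
  lo <- floor(h)
  if (lo >= n - 1) return(x[n])
  x[lo + 1] + (h - lo) * (x[lo + 2] - x[lo + 1])
}

#' Exact order-statistic confidence interval for a quantile
#'
#' Distribution-free two-sided confidence interval for the p-th percentile,
#' with both endpoints taken from the sorted sample without interpolation.
#' With B ~ Binomial(n, p/100), the interval \[x_(j), x_(k)\] has exact
#' coverage P(j <= B <= k - 1).  All index pairs 1 <= j < k <= n are
#' searched; among pairs attaining the nominal level the one with minimal
#' width k - j is chosen, ties broken by maximal coverage, then by smallest
#' j.  If no pair attains the level (small n, extreme p) the interval is
#' marked unavailable.
#'
#' The point estimate uses linear interpolation ([percentile_point()]) while
#' the interval deliberately does not; for extreme percentiles at small n
#' the point estimate can therefore fall outside the interval.  The exact
#' method is conservative: achieved coverage is always >= the nominal level
#' when an interval exists.
#'
#' @param values Nonempty numeric vector.
#' @param p Percentile level, 0 < p < 100.
#' @param conf Nominal two-sided confidence level, default 0.95.
#' @return An object of class `"quantile_estimate"`: a list with elements
#'   `p`, `n`, `point`, `conf`, `available`, `ci_low`, `ci_high`, `j`, `k`,
#'   `achieved_coverage` (the last five `NA` when unavailable).
#' @examples
#' set.seed(1)
#' exact_quantile_ci(rlnorm(348, 1.5, 0.5), 99)
#' @export
exact_quantile_ci <- function(values, p, conf = 0.95) {
  if (length(values) == 0L) stop("empty sample", call. = FALSE)
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p >= 100) {
    stop("`p` must satisfy 0 < p < 100", call. = FALSE)
  }
  if (!is.numeric(conf) || length(conf) != 1L || is.na(conf) ||
      conf <= 0 || conf >= 1) {
    stop("`conf` must satisfy 0 < conf < 1", call. = FALSE)
  }
  x <- sort(values)
  n <- length(x)
  est <- list(p = p, n = n, point = percentile_point(values, p), conf = conf,
              available = FALSE, ci_low = NA_real_, ci_high = NA_real_,
              j = NA_integer_, k = NA_integer_,
              achieved_coverage = NA_real_)
  class(est) <- "quantile_estimate"
  if (n < 2L) return(est)

  # cum[i + 1] = P(B <= i); coverage(j, k) = cum[k] - cum[j]
  cum <- stats::pbinom(0:n, n, p / 100)
  for (w in seq_len(n - 1L)) {
    j <- seq_len(n - w)
    cov <- cum[j + w] - cum[j]
    ok <- cov >= conf
    if (any(ok)) {
      covok <- ifelse(ok, cov, -Inf)
      jj <- which.max(covok)          # first maximum: smallest j among ties
      est$available <- TRUE
      est$j <- jj
      est$k <- jj + w
      est$ci_low <- x[jj]
      est$ci_high <- x[jj + w]
      est$achieved_coverage <- cov[jj]
      break
    }
  }
  est
}

#' @export
print.quantile_estimate <- function(x, ...) {
  cat(sprintf("P%s estimate: %.4g  (n = %d)\n", format(x$p), x$point, x$n))
  if (x$available) {
    cat(sprintf("  exact %.0f%% CI: [%.4g, %.4g]  (order statistics %d, %d; coverage %.4f)\n",
                100 * x$conf, x$ci_low, x$ci_high, x$j, x$k,
                x$achieved_coverage))
  } else {
    cat(sprintf("  exact %.0f%% CI: unavailable at this n\n", 100 * x$conf))
  }
  invisible(x)
}
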