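# Spearman rank correlation (mid-ranks for ties, t-approximation p-value)
# and the Mann-Whitney U sex-difference test (normal approximation with tie
# correction).

#' Spearman rank correlation with p-value
#'
#' rho is the Pearson correlation of mid-ranks (average ranks for ties).
#' The two-sided p-value uses the t-approximation
#' t = rho * sqrt((n - 2) / (1 - rho^2)) on n - 2 degrees of freedom,
#' adequate at cohort sizes; for |rho| = 1 the p-value is reported as 0.
#' An exact permutation p-value is available for n <= 10.
#'
#' @param x,y Equal-length numeric vectors, n >= 3.
#' @param p_method `"t"` (default) or `"exact"` (full permutation
#'   enumeration, n <= 10 only).
#' @return A list of class `"correlation_result"` with `rho`, `n`,
#'   `p_value`.
#' @export
spearman_cor <- function(x, y, p_method = c("t", "exact")) {
  p_method <- match.arg(p_method)
  n <- length(x)
  if (length(y) != n) stop("`x` and `y` must have equal length", call. = FALSE)
  if (n < 3L) stop("need n >= 3", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("non-finite values", call. = FALSE)
  }
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("zero rank variance: correlation undefined", call. = FALSE)
  }
  rho <- stats::cor(rx, ry)
  if (p_method == "exact") {
    if (n > 10L) stop("exact permutation p-value limited to n <= 10",
                      call. = FALSE)
    perms <- permutations_of(n)
    obs <- abs(rho)
    count <- 0L
    for (i in seq_len(nrow(perms))) {
      r <- stats::cor(rx, ry[perms[i, ]])
      if (abs(r) >= obs - 1e-12) count <- count + 1L
    }
    p <- count / nrow(perms)
  } else if (abs(rho) >= 1 - 1e-15) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  structure(list(rho = rho, n = n, p_value = p),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.4f (n = %d, p = %.3g)\n",
              x$rho, x$n, x$p_value))
  invisible(x)
}

# All permutations of 1..n as rows (n small).
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (i in seq_len(nrow(sub))) {
    for (pos in seq_len(n)) {
      r <- r + 1L
      out[r, ] <- append(sub[i, ], n, after = pos - 1L)
    }
  }
  out
}

#' Mann-Whitney U test for a sex difference in troponin
#'
#' Two-sided Mann-Whitney U test with normal approximation and tie
#' correction.  No continuity correction is applied, so identical groups
#' (U at its mean) give p = 1.  Used for the per-stratum female-vs-male
#' troponin comparison.
#'
#' @param values_f,values_m Nonempty numeric vectors.
#' @return Two-sided p-value.
#' @export
sex_difference_test <- function(values_f, values_m) {
  n1 <- length(values_f)
  n2 <- length(values_m)
  if (n1 == 0L || n2 == 0L) stop("both groups must be nonempty", call. = FALSE)
  r <- rank(c(values_f, values_m))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  nn <- n1 + n2
  tie_counts <- table(c(values_f, values_m))
  tie_term <- sum(tie_counts^3 - tie_counts) / (nn * (nn - 1))
  sigma2 <- n1 * n2 / 12 * ((nn + 1) - tie_term)
  if (sigma2 <= 0) return(1)
  z <- (u - mu) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}
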