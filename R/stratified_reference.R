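# Per-sex stratified median / 99th-percentile reference tables over age
# groups, creatinine bins, and eGFR bins, with the minimum-group-size rule
# for reporting extreme percentiles.

# Bin edges behind the printed integer labels.  Contiguous half-open real
# intervals (lo, hi], lowest bin closed at its lower edge.
bin_scheme_def <- function(scheme = c("age", "creatinine", "egfr"),
                           merge_upper = FALSE) {
  scheme <- match.arg(scheme)
  switch(scheme,
    age = list(breaks = c(20, 40, 50, 60, 70, 80),
               labels = c("20-40", "41-50", "51-60", "61-70", "71-80")),
    creatinine = if (merge_upper) {
      list(breaks = c(0, 50, 100, 150, 250),
           labels = c("0-50", "51-100", "101-150", "151-250"))
    } else {
      list(breaks = c(0, 50, 100, 150, 200, 250),
           labels = c("0-50", "51-100", "101-150", "151-200", "201-250"))
    },
    egfr = list(breaks = c(0, 30, 60, 90, 120, 150),
                labels = c("0-30", "31-60", "61-90", "91-120", "121-150")))
}

#' Assign values to the reference-table bins of a stratification scheme
#'
#' Integer-labelled printed bins are mapped to contiguous half-open real
#' intervals (lo, hi] (lowest bin closed at its lower edge), so real-valued
#' ages, creatinines and eGFRs bin without gaps: age 40 falls in `"20-40"`,
#' age 40.5 in `"41-50"`; eGFR 90.5 in `"91-120"`.  Out-of-range values get
#' the `"unbinned"` label — they are counted and reported, never silently
#' dropped.
#'
#' @param value Numeric vector.
#' @param scheme `"age"`, `"creatinine"`, or `"egfr"`.
#' @param merge_upper For the creatinine scheme, merge the sparse upper
#'   bins into `"151-250"`.
#' @return Character vector of bin labels.
#' @examples
#' assign_bin(c(40, 40.5), "age")
#' assign_bin(77, "creatinine")
#' @export
assign_bin <- function(value, scheme = c("age", "creatinine", "egfr"),
                       merge_upper = FALSE) {
  if (!is.numeric(value)) stop("`value` must be numeric", call. = FALSE)
  def <- bin_scheme_def(scheme, merge_upper)
  lab <- as.character(cut(value, breaks = def$breaks, labels = def$labels,
                          right = TRUE, include.lowest = TRUE))
  lab[is.na(lab)] <- "unbinned"
  lab
}

#' Stratified reference table of troponin medians and 99th percentiles
#'
#' One row per sex and bin of the chosen scheme: subject count, median
#' floored hs-cTnT, and the 99th-percentile estimate with its exact
#' order-statistic confidence interval.  For the creatinine and eGFR
#' schemes the 99th percentile (and CI) is reported only in strata with at
#' least `min_n` subjects, following reference-interval guidance for
#' extreme percentiles; for the age scheme it is reported in every stratum
#' (CI availability still follows [exact_quantile_ci()]).  The creatinine
#' table additionally carries the stratum median age with quartiles.
#' Out-of-range axis values are collected in an `"unbinned"` row; counts
#' per sex over all rows always sum to the cohort size.
#'
#' @param cohort Preprocessed cohort data frame (floored `troponin`; for
#'   the eGFR scheme an `egfr` column is used if present, otherwise eGFR is
#'   derived via [ckd_epi_egfr()]).
#' @param scheme `"age"`, `"creatinine"`, or `"egfr"`.
#' @param percentiles Percentile levels; the median (50) and the maximum
#'   level (default 99) are tabulated.
#' @param conf Confidence level for the exact CI, default 0.95.
#' @param min_n Minimum stratum size for reporting the extreme percentile
#'   in the creatinine/eGFR schemes, default 300.
#' @param merge_upper Passed to [assign_bin()] (creatinine scheme).
#' @return A data frame of class `"reference_table"` with columns `sex`,
#'   `bin`, `n`, `median_age`, `age_q1`, `age_q3` (creatinine scheme only),
#'   `median`, `p99`, `p99_lo`, `p99_hi`, `p99_coverage`; unavailable
#'   statistics are `NA`.
#' @export
reference_table <- function(cohort, scheme = c("age", "creatinine", "egfr"),
                            percentiles = c(50, 99), conf = 0.95,
                            min_n = 300, merge_upper = FALSE) {
  scheme <- match.arg(scheme)
  stopifnot(is.data.frame(cohort),
            all(c("age", "sex", "troponin") %in% names(cohort)))
  p_hi <- max(percentiles)
  axis <- switch(scheme,
    age = cohort$age,
    creatinine = {
      stopifnot("creatinine" %in% names(cohort))
      cohort$creatinine
    },
    egfr = {
      if ("egfr" %in% names(cohort)) cohort$egfr
      else ckd_epi_egfr(cohort$creatinine, cohort$age, cohort$sex)
    })
  def <- bin_scheme_def(scheme, merge_upper)
  bins <- assign_bin(axis, scheme, merge_upper)
  sexes <- norm_sex(cohort$sex)
  labels <- def$labels
  if (any(bins == "unbinned")) labels <- c(labels, "unbinned")

  rows <- list()
  for (s in c("F", "M")) {
    for (b in labels) {
      sel <- sexes == s & bins == b
      n <- sum(sel)
      tn <- cohort$troponin[sel]
      med <- if (n > 0L) percentile_point(tn, 50) else NA_real_
      report_p99 <- n > 0L && (scheme == "age" || n >= min_n)
      if (report_p99) {
        est <- exact_quantile_ci(tn, p_hi, conf)
        p99 <- est$point
        p99_lo <- est$ci_low
        p99_hi <- est$ci_high
        p99_cov <- est$achieved_coverage
      } else {
        p99 <- p99_lo <- p99_hi <- p99_cov <- NA_real_
      }
      row <- data.frame(sex = s, bin = b, n = n, stringsAsFactors = FALSE)
      if (scheme == "creatinine") {
        row$median_age <- if (n > 0L) percentile_point(cohort$age[sel], 50) else NA_real_
        row$age_q1 <- if (n > 0L) percentile_point(cohort$age[sel], 25) else NA_real_
        row$age_q3 <- if (n > 0L) percentile_point(cohort$age[sel], 75) else NA_real_
      }
      row$median <- med
      row$p99 <- p99
      row$p99_lo <- p99_lo
      row$p99_hi <- p99_hi
      row$p99_coverage <- p99_cov
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "scheme") <- scheme
  attr(out, "min_n") <- min_n
  attr(out, "conf") <- conf
  class(out) <- c("reference_table", "data.frame")
  out
}
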