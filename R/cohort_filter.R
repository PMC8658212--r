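# Exclusion cascade defining the cardiac-healthy study cohorts:
# stage 1 removes prevalent cardiac disease, stage 2 removes abnormal
# NT-proBNP / HbA1c (survivors = study cohort 2), stage 3 removes impaired
# renal function (survivors = study cohort 1).

#' Exclusion thresholds for the cardiac-healthy cohort cascade
#'
#' NT-proBNP is abnormal above `ntprobnp_limit_young` ng/L below
#' `ntprobnp_age_cut` years and above `ntprobnp_limit_old` ng/L at or above
#' it; HbA1c is abnormal above `hba1c_limit` mmol/mol; renal function is
#' impaired below `egfr_cutoff` mL/min/1.73 m² (raise to 90 for the
#' stricter "normal kidney function" sensitivity analysis).  All
#' comparisons are strict.
#'
#' @param ntprobnp_limit_young ng/L, default 125.
#' @param ntprobnp_age_cut Years, default 75.
#' @param ntprobnp_limit_old ng/L, default 450.
#' @param hba1c_limit mmol/mol, default 42.0.
#' @param egfr_cutoff mL/min/1.73 m², default 60.
#' @return An object of class `"exclusion_config"`.
#' @export
exclusion_config <- function(ntprobnp_limit_young = 125,
                             ntprobnp_age_cut = 75,
                             ntprobnp_limit_old = 450,
                             hba1c_limit = 42.0,
                             egfr_cutoff = 60) {
  cfg <- list(ntprobnp_limit_young = ntprobnp_limit_young,
              ntprobnp_age_cut = ntprobnp_age_cut,
              ntprobnp_limit_old = ntprobnp_limit_old,
              hba1c_limit = hba1c_limit,
              egfr_cutoff = egfr_cutoff)
  for (f in names(cfg)) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("invalid `", f, "`: must be a single positive number",
           call. = FALSE)
    }
  }
  if (cfg$ntprobnp_limit_old < cfg$ntprobnp_limit_young) {
    stop("invalid `ntprobnp_limit_old`: must be >= ntprobnp_limit_young",
         call. = FALSE)
  }
  class(cfg) <- "exclusion_config"
  cfg
}

#' Apply the exclusion cascade
#'
#' Stage order is fixed: (1) drop subjects with cardiac disease; (2) drop
#' subjects whose NT-proBNP exceeds the age-dependent limit or whose HbA1c
#' exceeds its limit — survivors form cohort 2; (3) drop subjects with
#' CKD-EPI eGFR below the cutoff — survivors form cohort 1.  Records are
#' never mutated; per-stage counts are returned in the report.
#'
#' @param cohort Data frame with columns `id`, `age`, `sex`, `troponin`,
#'   `creatinine`, `ntprobnp`, `hba1c`, `cardiac_disease` (as produced by
#'   [generate_cohort()] or [read_cohort_csv()]).
#' @param config An [exclusion_config()].
#' @return A list with elements `cohort1`, `cohort2` (data frames) and
#'   `report` (class `"filter_report"`: `n_input`, `n_excluded_cardiac`,
#'   `n_excluded_biomarker`, `n_cohort2`, `n_excluded_renal`, `n_cohort1`).
#' @export
apply_exclusions <- function(cohort, config = exclusion_config()) {
  stopifnot(inherits(config, "exclusion_config"))
  required <- c("id", "age", "sex", "troponin", "creatinine", "ntprobnp",
                "hba1c", "cardiac_disease")
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(cohort) == 0L) {
    report <- structure(list(n_input = 0L, n_excluded_cardiac = 0L,
                             n_excluded_biomarker = 0L, n_cohort2 = 0L,
                             n_excluded_renal = 0L, n_cohort1 = 0L),
                        class = "filter_report")
    return(list(cohort1 = cohort, cohort2 = cohort, report = report))
  }
  need <- c("age", "sex", "troponin", "creatinine", "ntprobnp", "hba1c",
            "cardiac_disease")
  incomplete <- !stats::complete.cases(cohort[need])
  if (any(incomplete)) {
    stop("missing field value(s) for subject(s): ",
         paste(utils::head(cohort$id[incomplete], 10L), collapse = ", "),
         call. = FALSE)
  }

  healthy <- !cohort$cardiac_disease
  nt_limit <- ifelse(cohort$age >= config$ntprobnp_age_cut,
                     config$ntprobnp_limit_old, config$ntprobnp_limit_young)
  abnormal_bio <- cohort$ntprobnp > nt_limit | cohort$hba1c > config$hba1c_limit
  in2 <- healthy & !abnormal_bio
  cohort2 <- cohort[in2, , drop = FALSE]
  egfr <- ckd_epi_egfr(cohort2$creatinine, cohort2$age, cohort2$sex)
  in1 <- egfr >= config$egfr_cutoff
  cohort1 <- cohort2[in1, , drop = FALSE]

  report <- structure(list(
    n_input = nrow(cohort),
    n_excluded_cardiac = sum(!healthy),
    n_excluded_biomarker = sum(healthy & abnormal_bio),
    n_cohort2 = nrow(cohort2),
    n_excluded_renal = sum(!in1),
    n_cohort1 = nrow(cohort1)), class = "filter_report")
  list(cohort1 = cohort1, cohort2 = cohort2, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Exclusion cascade:\n")
  cat(sprintf("  input subjects:              %d\n", x$n_input))
  cat(sprintf("  - cardiac disease/angina:    %d\n", x$n_excluded_cardiac))
  cat(sprintf("  - abnormal NT-proBNP/HbA1c:  %d\n", x$n_excluded_biomarker))
  cat(sprintf("  = study cohort 2:            %d\n", x$n_cohort2))
  cat(sprintf("  - impaired renal function:   %d\n", x$n_excluded_renal))
  cat(sprintf("  = study cohort 1:            %d\n", x$n_cohort1))
  invisible(x)
}
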