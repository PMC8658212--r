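# CKD-EPI (2009) estimated glomerular filtration rate from serum
# creatinine, age, and sex, plus the eGFR bin scheme of the reference
# tables.

#' Convert serum creatinine from µmol/L to mg/dL
#'
#' @param scr Serum creatinine in µmol/L, >= 0. Vectorised.
#' @return Creatinine in mg/dL (`scr / 88.4`).
#' @export
creatinine_umol_to_mgdl <- function(scr) {
  if (!is.numeric(scr)) stop("`scr` must be numeric", call. = FALSE)
  if (any(is.na(scr) | scr < 0)) {
    stop("`scr` must be non-negative", call. = FALSE)
  }
  scr / 88.4
}

#' CKD-EPI (2009) estimated glomerular filtration rate
#'
#' eGFR = 141 * min(Scr/kappa, 1)^alpha * max(Scr/kappa, 1)^-1.209 *
#' 0.993^age * 1.018\[female\], with Scr in mg/dL, kappa = 0.7 (female) /
#' 0.9 (male) and alpha = -0.329 (female) / -0.411 (male).  The race
#' coefficient (1.159) is not applied by default, appropriate for a
#' predominantly white cohort; set `black = TRUE` to apply it.
#'
#' @param scr Serum creatinine in µmol/L, > 0. Vectorised.
#' @param age Age in years, >= 18. Vectorised.
#' @param sex `"F"`/`"female"` or `"M"`/`"male"` (case-insensitive).
#' @param black Apply the race coefficient 1.159? Default `FALSE`.
#' @return eGFR in mL/min/1.73 m².
#' @examples
#' ckd_epi_egfr(77, 52, "F")  # ~76.5
#' ckd_epi_egfr(80, 60, "M")  # ~91.9
#' @export
ckd_epi_egfr <- function(scr, age, sex, black = FALSE) {
  if (!is.numeric(scr) || any(is.na(scr) | scr <= 0)) {
    stop("`scr` must be positive", call. = FALSE)
  }
  if (!is.numeric(age) || any(is.na(age) | age < 18)) {
    stop("`age` must be >= 18 years", call. = FALSE)
  }
  s <- norm_sex(sex)
  k <- length(scr)
  n <- max(k, length(age), length(s))
  scr <- rep_len(scr, n); age <- rep_len(age, n); s <- rep_len(s, n)
  female <- s == "F"
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  r <- creatinine_umol_to_mgdl(scr) / kappa
  egfr <- 141 * pmin(r, 1)^alpha * pmax(r, 1)^-1.209 * 0.993^age
  egfr <- egfr * ifelse(female, 1.018, 1)
  if (isTRUE(black)) egfr <- egfr * 1.159
  egfr
}

#' Assign an eGFR value to its reference-table bin
#'
#' Bins are the contiguous half-open intervals behind the printed integer
#' labels: \[0,30\], (30,60\], (60,90\], (90,120\], (120,150\]; values above
#' 150 get the `"unbinned"` label.
#'
#' @param egfr eGFR in mL/min/1.73 m², > 0. Vectorised.
#' @return Character vector of bin labels.
#' @examples
#' egfr_bin(c(87.1, 30, 90.5))
#' @export
egfr_bin <- function(egfr) {
  if (!is.numeric(egfr) || any(is.na(egfr) | egfr <= 0)) {
    stop("`egfr` must be positive", call. = FALSE)
  }
  assign_bin(egfr, "egfr")
}

# Normalise sex coding to "F"/"M".
norm_sex <- function(sex) {
  s <- toupper(substr(as.character(sex), 1L, 1L))
  bad <- is.na(s) | !(s %in% c("F", "M"))
  if (any(bad)) {
    stop("invalid sex value: ", paste(unique(sex[bad]), collapse = ", "),
         call. = FALSE)
  }
  s
}
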