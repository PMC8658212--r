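# Cohort CSV dialect and small text-output helpers.  CSVs are UTF-8,
# comma-separated, "." decimal, mandatory header; an optional leading
# "# config_hash: ..." comment stamps outputs with the run configuration.

cohort_csv_header <- c("id", "age", "sex", "troponin_ngL",
                       "creatinine_umolL", "ntprobnp_ngL", "hba1c_mmolmol",
                       "cardiac_disease")

#' Write a cohort to CSV
#'
#' Columns `id,age,sex,troponin_ngL,creatinine_umolL,ntprobnp_ngL,`
#' `hba1c_mmolmol,cardiac_disease`; sex coded F/M, booleans 0/1.
#'
#' @param cohort Cohort data frame (see [generate_cohort()]).
#' @param path Output file path.
#' @param config_hash Optional hash string stamped as a leading comment.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path, config_hash = NULL) {
  # %.17g round-trips IEEE doubles exactly, so statistics recomputed from
  # a re-read CSV match the in-memory cohort bit for bit
  num <- function(x) sprintf("%.17g", x)
  out <- data.frame(id = cohort$id,
                    age = num(cohort$age),
                    sex = norm_sex(cohort$sex),
                    troponin_ngL = num(cohort$troponin),
                    creatinine_umolL = num(cohort$creatinine),
                    ntprobnp_ngL = num(cohort$ntprobnp),
                    hba1c_mmolmol = num(cohort$hba1c),
                    cardiac_disease = as.integer(cohort$cardiac_disease),
                    stringsAsFactors = FALSE)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(config_hash)) {
    writeLines(paste0("# config_hash: ", config_hash), con)
  }
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort CSV written by [write_cohort_csv()]
#'
#' @param path CSV file path.
#' @return Cohort data frame with columns `id`, `age`, `sex`, `troponin`,
#'   `creatinine`, `ntprobnp`, `hba1c`, `cardiac_disease`.
#' @export
read_cohort_csv <- function(path) {
  raw <- utils::read.csv(path, comment.char = "#",
                         stringsAsFactors = FALSE,
                         colClasses = c(id = "character"))
  missing_cols <- setdiff(cohort_csv_header, names(raw))
  if (length(missing_cols)) {
    stop("cohort CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data.frame(id = raw$id,
             age = raw$age,
             sex = raw$sex,
             troponin = raw$troponin_ngL,
             creatinine = raw$creatinine_umolL,
             ntprobnp = raw$ntprobnp_ngL,
             hba1c = raw$hba1c_mmolmol,
             cardiac_disease = raw$cardiac_disease != 0,
             stringsAsFactors = FALSE)
}

# Write any data frame as a stamped CSV.
write_stamped_csv <- function(df, path, config_hash = NULL) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(config_hash)) {
    writeLines(paste0("# config_hash: ", config_hash), con)
  }
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_stamped_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

# 32-bit FNV-1a hash of a character vector, in pure double arithmetic
# (no 32-bit overflow: the product is split into 16-bit halves).
fnv1a32 <- function(txt) {
  bytes <- as.integer(charToRaw(paste(txt, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 65536
    hi <- h %/% 65536
    lo <- bitwXor(as.integer(lo), b)
    # (hi*2^16 + lo) * 16777619 mod 2^32, with 16777619 = 256*2^16 + 403
    h <- (lo * 403 + ((hi * 403 + lo * 256) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}
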