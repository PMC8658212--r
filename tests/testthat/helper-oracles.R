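# Independent oracles, deliberately coded differently from the package
# implementations they check.

# Exhaustive-pair-enumeration oracle for the exact quantile CI: scan all
# 1 <= j < k <= n, keep the pair with minimal width, ties by maximal
# coverage, then smallest j.  Returns NULL when no pair attains conf.
oracle_exact_ci <- function(n, p, conf = 0.95) {
  cum <- pbinom(0:n, n, p / 100)
  best <- NULL
  for (j in seq_len(max(n - 1, 0))) {
    for (k in (j + 1):n) {
      cov <- cum[k] - cum[j]
      if (cov >= conf) {
        w <- k - j
        if (is.null(best) || w < best$w ||
            (w == best$w && cov > best$cov) ||
            (w == best$w && cov == best$cov && j < best$j)) {
          best <- list(j = j, k = k, w = w, cov = cov)
        }
      }
    }
  }
  best
}

# Single-expression CKD-EPI evaluation (scalar), independent of the
# package's vectorised branch structure.
oracle_ckdepi <- function(scr_umol, age, female) {
  scr <- scr_umol / 88.4
  kap <- if (female) 0.7 else 0.9
  alp <- if (female) -0.329 else -0.411
  141 * min(scr / kap, 1)^alp * max(scr / kap, 1)^(-1.209) *
    0.993^age * (if (female) 1.018 else 1)
}

# Exact two-sided Mann-Whitney p-value by full enumeration of group
# assignments (small samples only).
oracle_mw_exact <- function(f, m) {
  pool <- c(f, m)
  n1 <- length(f)
  r <- rank(pool)
  mu <- n1 * length(m) / 2
  ustat <- function(ii) sum(r[ii]) - n1 * (n1 + 1) / 2
  obs <- abs(ustat(seq_len(n1)) - mu)
  sets <- utils::combn(length(pool), n1)
  hits <- sum(apply(sets, 2, function(ii) abs(ustat(ii) - mu) >= obs - 1e-9))
  hits / ncol(sets)
}

# Next-permutation enumeration of Spearman's rho null distribution
# (two-sided exact p), coded without recursion.
oracle_spearman_exact <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  obs <- abs(cor(rx, ry))
  perm <- seq_len(n)
  total <- 0L; hits <- 0L
  repeat {
    total <- total + 1L
    if (abs(cor(rx, ry[perm])) >= obs - 1e-12) hits <- hits + 1L
    # lexicographic next permutation
    i <- n - 1L
    while (i >= 1L && perm[i] >= perm[i + 1L]) i <- i - 1L
    if (i < 1L) break
    j <- n
    while (perm[j] <= perm[i]) j <- j - 1L
    tmp <- perm[i]; perm[i] <- perm[j]; perm[j] <- tmp
    perm[(i + 1L):n] <- rev(perm[(i + 1L):n])
  }
  hits / total
}

# Assemble a minimal cohort data frame for filter/table tests.
make_cohort <- function(n = 0, age = 50, sex = "M", troponin = 5,
                        creatinine = 80, ntprobnp = 50, hba1c = 35,
                        cardiac_disease = FALSE) {
  if (n == 0) n <- max(length(age), length(sex), length(troponin),
                       length(creatinine), length(ntprobnp), length(hba1c),
                       length(cardiac_disease))
  data.frame(id = sprintf("T%03d", seq_len(n)),
             age = rep_len(age, n), sex = rep_len(sex, n),
             troponin = rep_len(troponin, n),
             creatinine = rep_len(creatinine, n),
             ntprobnp = rep_len(ntprobnp, n),
             hba1c = rep_len(hba1c, n),
             cardiac_disease = rep_len(cardiac_disease, n),
             stringsAsFactors = FALSE)
}

# Creatinine (µmol/L) that yields a requested eGFR for given age/sex.
creatinine_for_egfr <- function(target, age, sex) {
  uniroot(function(scr) tnref::ckd_epi_egfr(scr, age, sex) - target,
          c(10, 1000), tol = 1e-10)$root
}
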