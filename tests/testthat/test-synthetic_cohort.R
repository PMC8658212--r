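# Degenerate single-knot parameters: every draw is exp(mu) exactly.
degenerate_params <- function(mu = log(10), n = 50, seed = 3) {
  kn <- data.frame(age = 50, mu_log = mu, sigma_log = 0)
  generator_params(n_subjects = n, troponin_knots = list(F = kn, M = kn),
                   cardiac_disease_prevalence = 0, seed = seed)
}

test_that("degenerate noise gives constant troponin; determinism holds", {
  co <- generate_cohort(degenerate_params())
  expect_equal(co$troponin, rep(10, 50))
  co2 <- generate_cohort(degenerate_params())
  expect_identical(co, co2)
  co3 <- generate_cohort(degenerate_params(seed = 4))
  expect_false(identical(co$age, co3$age))
})

test_that("generated troponin is never below the floor; records are valid", {
  set.seed(12)
  for (seed in c(2, 17, 303)) {
    p <- generator_params(n_subjects = 400, seed = seed)
    co <- generate_cohort(p)
    expect_equal(nrow(co), 400)
    expect_gte(min(co$troponin), p$detection_floor)
    expect_true(all(co$age >= 20 & co$age <= 80))
    expect_true(all(co$sex %in% c("F", "M")))
    expect_true(all(co$creatinine > 0))
    expect_true(all(co$ntprobnp >= 0))
    expect_true(all(co$hba1c > 0))
    expect_type(co$cardiac_disease, "logical")
  }
})

test_that("invalid parameters raise errors naming the offending field", {
  expect_error(generator_params(female_fraction = 1.2), "female_fraction")
  expect_error(generator_params(age_group_weights = c(0.5, 0.5, 0, 0, 0.1)),
               "age_group_weights")
  expect_error(generator_params(detection_floor = 0), "detection_floor")
  kn <- default_troponin_knots()
  kn$F$sigma_log[1] <- -0.1
  expect_error(generator_params(troponin_knots = kn), "troponin_knots")
  expect_error(generator_params(cardiac_disease_prevalence = -0.1),
               "cardiac_disease_prevalence")
  expect_error(generator_params(seed = 1.5), "seed")
})

test_that("a floor-dominated female stratum has sample median exactly at the floor", {
  p <- generator_params(n_subjects = 2000, female_fraction = 1,
                        age_group_weights = c(1, 0, 0, 0, 0),
                        cardiac_disease_prevalence = 0, seed = 21)
  co <- generate_cohort(p)
  expect_true(all(co$age <= 40))
  expect_equal(median(co$troponin), 3.0)
})

test_that("true_stratum_quantile handles degenerate and floored cases", {
  p <- degenerate_params()
  expect_equal(true_stratum_quantile(p, "M", 20, 80, 50), 10, tolerance = 1e-6)
  expect_equal(true_stratum_quantile(p, "F", 35, 62, 99), 10, tolerance = 1e-6)
  # floor-dominated: underlying median below the floor -> exactly the floor
  pf <- generator_params(cardiac_disease_prevalence = 0)
  expect_identical(true_stratum_quantile(pf, "F", 20, 40, 50), 3)
  expect_error(true_stratum_quantile(pf, "F", 50, 50, 50), "age")
  expect_error(true_stratum_quantile(pf, "F", 20, 40, 100), "p")
})

test_that("true_stratum_quantile agrees with a Monte-Carlo oracle", {
  p <- generator_params()
  q <- true_stratum_quantile(p, "M", 70, 80, 99)
  # direct mixture simulation, coded independently of generate_cohort
  set.seed(404)
  nmc <- 2e6
  ages <- runif(nmc, 70, 80)
  kn <- p$troponin_knots$M
  mu <- approx(kn$age, kn$mu_log, ages, rule = 2)$y
  sg <- approx(kn$age, kn$sigma_log, ages, rule = 2)$y
  x <- exp(mu + sg * rnorm(nmc))
  dis <- runif(nmc) < p$cardiac_disease_prevalence
  x[dis] <- x[dis] * p$cardiac_troponin_shift
  x <- pmax(x, p$detection_floor)
  expect_equal(q, quantile(x, 0.99, type = 7, names = FALSE),
               tolerance = 0.005)
})

test_that("raising mu at all knots never decreases a true quantile", {
  set.seed(88)
  for (rep in 1:5) {
    p1 <- generator_params(cardiac_disease_prevalence = 0)
    p2 <- p1
    bump <- runif(1, 0.05, 0.5)
    p2$troponin_knots$F$mu_log <- p2$troponin_knots$F$mu_log + bump
    p2$troponin_knots$M$mu_log <- p2$troponin_knots$M$mu_log + bump
    lo <- runif(1, 20, 70)
    hi <- runif(1, lo + 2, 80)
    pr <- runif(1, 5, 99)
    for (s in c("F", "M")) {
      expect_gte(true_stratum_quantile(p2, s, lo, hi, pr),
                 true_stratum_quantile(p1, s, lo, hi, pr) - 1e-9)
    }
  }
})

test_that("the default calibration reproduces the target stratum medians", {
  # larger cohort than the default so sampling noise is well inside the
  # +/- 0.5 ng/L calibration band
  p <- generator_params(n_subjects = 30000, seed = 42)
  flt <- apply_exclusions(generate_cohort(p))
  c1 <- flt$cohort1
  targets <- list(F = c(3.0, 3.0, 3.4, 4.5, 6.0),
                  M = c(4.2, 4.5, 5.2, 6.4, 8.3))
  bin <- assign_bin(c1$age, "age")
  labs <- c("20-40", "41-50", "51-60", "61-70", "71-80")
  for (s in c("F", "M")) {
    for (i in seq_along(labs)) {
      med <- median(c1$troponin[c1$sex == s & bin == labs[i]])
      expect_lt(abs(med - targets[[s]][i]), 0.5)
    }
  }
  # floor-dominated strata sit exactly on the floor
  expect_equal(median(c1$troponin[c1$sex == "F" & bin == "20-40"]), 3.0)
  expect_equal(median(c1$troponin[c1$sex == "F" & bin == "41-50"]), 3.0)
})
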