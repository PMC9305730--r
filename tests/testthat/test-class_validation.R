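test_that("class profiles reduce to whole-cohort summaries and hand-checked toys", {
  covs <- data.frame(
    age = c(15, 18, 21, 24),
    sex = factor(c("male", "female", "female", "female")),
    phq9 = c(4, 9, 14, 23)
  )
  # single class: summary equals the whole-cohort summary
  p1 <- profile_classes(rep(1, 4), covs)
  age_row <- p1[p1$variable == "age", ]
  expect_equal(age_row$median, median(covs$age))
  expect_equal(age_row$q1, quantile(covs$age, 0.25, names = FALSE))
  expect_equal(age_row$q3, quantile(covs$age, 0.75, names = FALSE))

  # two classes, hand calculation
  p2 <- profile_classes(c(1, 1, 2, 2), covs)
  expect_equal(p2[p2$class == 1 & p2$variable == "phq9", "median"], 6.5)
  expect_equal(p2[p2$class == 2 & p2$variable == "phq9", "median"], 18.5)
  fem <- p2[p2$variable == "sex" & p2$level == "female", ]
  expect_equal(fem$n, c(1L, 2L))
  expect_equal(fem$pct, c(50, 100))

  # utility mean/sd appended from a score set; empty classes give zero counts
  sc <- data.frame(utility = c(0.9, 0.8, 0.5, 0.3))
  p3 <- profile_classes(factor(c(1, 1, 2, 2), levels = 1:3), covs, sc)
  expect_equal(p3[p3$class == "1" & p3$variable == "utility", "mean"], 0.85)
  expect_equal(p3[p3$class == "3" & p3$variable == "utility", "n"], 0)
})

test_that("covariate standardisation scales to unit s.d. and records its metadata", {
  withr::with_seed(41, {
    covs <- data.frame(phq9 = rnorm(500, 12, 6.6), gad7 = rnorm(500, 9, 5.7),
                       siqjr = rnorm(500, 15, 20), psqi = rnorm(500, 9, 3.8),
                       age = rnorm(500, 18, 3))
  })
  st <- standardise_covariates(covs)
  expect_equal(sd(st$phq9), 1, tolerance = 1e-12)
  expect_equal(mean(st$gad7), 0, tolerance = 1e-12)
  expect_equal(st$age, covs$age)   # age untouched
  rec <- attr(st, "standardisation")
  expect_setequal(rec$variable, c("phq9", "gad7", "siqjr", "psqi"))

  # idempotence: standardising an already standardised table changes nothing
  st2 <- standardise_covariates(st)
  expect_equal(st2$phq9, st$phq9, tolerance = 1e-12)

  # fixed external s.d.s are honoured
  fx <- standardise_covariates(covs, sds = c(phq9 = 6.6))
  expect_equal(sd(fx$phq9), sd(covs$phq9) / 6.6, tolerance = 1e-12)

  covs$psqi <- 5
  expect_error(standardise_covariates(covs), "psqi")
})

test_that("chained-equations imputation is deterministic and unbiased under MCAR", {
  withr::with_seed(43, {
    n <- 1500
    x <- rnorm(n, 10, 2)
    y <- 0.7 * x + rnorm(n)
    g <- factor(ifelse(rnorm(n) + x - 10 > 0, "yes", "no"))
    covs <- data.frame(x = x, y = y, g = g)
    covs$x[sample(n, 150)] <- NA
    covs$g[sample(n, 100)] <- NA
  })
  # complete data: copies identical
  imp0 <- impute_covariates(data.frame(a = 1:10, b = rnorm(10)), m = 2,
                            seed = 1)
  expect_identical(imp0$imputations[[1]], imp0$imputations[[2]])

  imp <- impute_covariates(covs, m = 5, seed = 2, n_iter = 5)
  imp_again <- impute_covariates(covs, m = 5, seed = 2, n_iter = 5)
  expect_identical(imp$imputations, imp_again$imputations)

  # non-missing cells untouched
  obs <- !is.na(covs$x)
  for (im in 1:5) {
    expect_identical(imp$imputations[[im]]$x[obs], covs$x[obs])
    expect_false(anyNA(imp$imputations[[im]]))
  }

  # pooled mean of the imputed variable within 3 s.e. of the full-data mean
  pooled_mean <- mean(vapply(imp$imputations, function(d) mean(d$x),
                             numeric(1)))
  expect_lt(abs(pooled_mean - mean(x)), 3 * 2 / sqrt(n))

  expect_error(impute_covariates(covs, m = 1), "at least 2")
  expect_error(
    impute_covariates(data.frame(a = rep(NA_real_, 5), b = 1:5), m = 2,
                      seed = 1),
    "all-missing"
  )
})

test_that("multinomial Newton fit reproduces the 2x2 odds ratio and the nnet oracle", {
  # exposed/unexposed x class counts [[40, 10], [20, 30]] -> OR = 6
  exposure <- rep(c(1, 1, 0, 0), times = c(40, 10, 20, 30))
  cls <- rep(c("a", "b", "a", "b"), times = c(40, 10, 20, 30))
  fit <- fit_multinomial(cls, cbind(1, x = exposure), reference = "b")
  expect_equal(exp(fit$coefficients["a", "x"]), (30 * 40) / (10 * 20),
               tolerance = 1e-6)

  # three classes, two covariates: agree with nnet::multinom
  withr::with_seed(51, {
    n <- 1200
    x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.4)
    eta2 <- -0.3 + 0.8 * x1 - 0.5 * x2
    eta3 <- 0.2 - 0.6 * x1 + 0.9 * x2
    den <- 1 + exp(eta2) + exp(eta3)
    u <- runif(n)
    p2 <- exp(eta2) / den; p3 <- exp(eta3) / den
    y <- ifelse(u < p2, 2, ifelse(u < p2 + p3, 3, 1))
  })
  X <- cbind(`(Intercept)` = 1, x1 = x1, x2 = x2)
  mine <- fit_multinomial(y, X)
  oracle <- nnet::multinom(factor(y) ~ x1 + x2, trace = FALSE,
                           reltol = 1e-14, maxit = 500)
  expect_equal(unname(mine$coefficients), unname(coef(oracle)),
               tolerance = 1e-4)
  # standard errors from the observed information agree too
  se_oracle <- summary(oracle)$standard.errors
  expect_equal(unname(mine$se), unname(se_oracle), tolerance = 1e-3)

  # covariate independent of the outcome: RRR ~ 1 at n = 5000
  withr::with_seed(52, {
    yy <- sample(1:2, 5000, replace = TRUE)
    zz <- rnorm(5000)
  })
  null_fit <- fit_multinomial(yy, cbind(1, z = zz))
  expect_gt(exp(null_fit$coefficients[1, "z"]), 0.9)
  expect_lt(exp(null_fit$coefficients[1, "z"]), 1.1)

  # intercept-only accuracy equals the largest class share
  only1 <- fit_multinomial(y, matrix(1, n, 1))
  expect_equal(only1$accuracy, max(table(y)) / n)

  # rank deficiency is reported with the aliased column
  expect_error(fit_multinomial(y, cbind(1, x1 = x1, dup = x1)), "dup")

  # complete separation falls back to a ridge fit with a warning
  sep_y <- rep(c("lo", "hi"), each = 20)
  sep_x <- c(rnorm(20, -4), rnorm(20, 4))
  expect_warning(sep_fit <- fit_multinomial(sep_y, cbind(1, x = sep_x)),
                 "ridge|separation")
  expect_true(sep_fit$ridged)
})

test_that("Rubin pooling follows the closed-form rules", {
  # identical fits: B = 0, total variance = mean within variance
  est <- rbind(c(0.5, 1.2), c(0.5, 1.2), c(0.5, 1.2))
  vr <- rbind(c(0.04, 0.09), c(0.04, 0.09), c(0.04, 0.09))
  p <- pool_rubin(est, vr)
  expect_equal(p$total_var, c(0.04, 0.09))
  expect_equal(p$between, c(0, 0))
  expect_true(all(!is.finite(p$df)))
  expect_equal(p$ci_high - p$estimate, qnorm(0.975) * sqrt(c(0.04, 0.09)))

  # m = 2, estimates {1, 3}, within variances {1, 1}
  p2 <- pool_rubin(matrix(c(1, 3), 2, 1), matrix(c(1, 1), 2, 1))
  expect_equal(p2$estimate, 2)
  expect_equal(p2$between, 2)
  expect_equal(p2$total_var, 1 + 1.5 * 2)

  # exponentiation preserves interval ordering
  expect_true(all(exp(p2$ci_low) < exp(p2$estimate) &
                    exp(p2$estimate) < exp(p2$ci_high)))

  expect_error(pool_rubin(matrix(1, 1, 2), matrix(1, 1, 2)), "m >= 2")
})

test_that("pooled RRRs cover generator truth at near-nominal rates", {
  # class membership generated from a known two-class logit; x has MCAR
  # missingness handled by imputation; 50 replicates, 95% +/- 8 points
  beta_true <- 0.9
  covered <- logical(50)
  for (r in 1:50) {
    withr::with_seed(600 + r, {
      n <- 700
      x <- rnorm(n)
      p2 <- plogis(-0.2 + beta_true * x)
      y <- ifelse(runif(n) < p2, 2, 1)
      xm <- x; xm[sample(n, 70)] <- NA
    })
    imp <- impute_covariates(data.frame(x = xm), m = 3, seed = 600 + r,
                             n_iter = 3, extra = data.frame(y = factor(y)))
    ests <- vars <- numeric(3)
    for (im in 1:3) {
      f <- fit_multinomial(y, cbind(1, x = imp$imputations[[im]]$x))
      ests[im] <- f$coefficients[1, "x"]
      vars[im] <- f$se[1, "x"]^2
    }
    pl <- pool_rubin(matrix(ests, 3, 1), matrix(vars, 3, 1))
    covered[r] <- pl$ci_low <= beta_true && beta_true <= pl$ci_high
  }
  expect_gte(mean(covered), 0.95 - 0.08)
})

test_that("the two validation models nest: symptom model predicts no worse", {
  prof <- aqol_reference_profile()
  prof$n_subjects <- 400L
  prof$missingness$n_rows <- 14L
  ch <- generate_cohort(prof, seed = 23)
  cc <- complete_case_filter(ch$items)
  keep <- setdiff(seq_len(400), attr(cc, "dropped"))
  sc <- dimension_scores(cc, aqol_surrogate_utility())
  fit <- rank_classes_by_utility(fit_em(cc, K = 4, n_restarts = 8, seed = 2),
                                 sc)
  labels <- factor(fit$class_labels[classify_modal(fit)],
                   levels = fit$class_labels)
  covs <- ch$covariates[keep, setdiff(names(ch$covariates), "site")]
  rep_ <- rrr_report(labels, covs, m = 3, seed = 31, n_iter = 4)
  expect_gte(rep_$accuracy[["model-2"]], rep_$accuracy[["model-1"]])
  expect_identical(rep_$reference, "No/Mild")
  # RRR tables are positive with ordered intervals
  expect_true(all(rep_$rrr$rrr > 0))
  expect_true(all(rep_$rrr$ci_low <= rep_$rrr$rrr &
                    rep_$rrr$rrr <= rep_$rrr$ci_high))
})
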