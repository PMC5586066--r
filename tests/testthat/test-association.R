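# logistic fits, likelihood-ratio tests, score, AUC/DeLong, stepwise,
# determinant regressions

test_that("logistic fits reproduce closed forms and detect pathologies", {
  # intercept-only: log(n_cases / n_controls)
  y <- c(rep(1, 1170), rep(0, 1283))
  d <- data.frame(status = y)
  f0 <- fit_logistic(status ~ 1, d)
  expect_equal(unname(coef(f0$glm)), log(1170 / 1283), tolerance = 1e-8)

  # 2x2 table: coefficient = log odds ratio
  tab <- c(a = 40, b = 25, c = 30, d = 55)
  d2 <- data.frame(status = rep(c(1, 1, 0, 0), tab),
                   x = rep(c(1, 0, 1, 0), tab))
  f2 <- fit_logistic(status ~ x, d2)
  expect_equal(unname(coef(f2$glm)["x"]),
               log(40 * 55 / (25 * 30)), tolerance = 1e-8)

  # perfect separation raises
  d3 <- data.frame(status = rep(c(0, 1), each = 20),
                   x = c(rnorm(20, -3), rnorm(20, 3)))
  expect_error(fit_logistic(status ~ x, d3), "separation")

  # rank deficiency raises
  d4 <- data.frame(status = rbinom(50, 1, 0.5), x = rnorm(50))
  d4$z <- d4$x
  expect_error(fit_logistic(status ~ x + z, d4), "design error")
})

test_that("likelihood-ratio tests match the G statistic on contingency tables", {
  for (s in 1:25) {
    set.seed(s)
    k <- sample(2:6, 1)
    cases <- rpois(k, 60) + 5
    controls <- rpois(k, 80) + 5
    lrt <- lrt_contingency(cases, controls)
    expect_equal(lrt$statistic, g_statistic(cases, controls),
                 tolerance = 1e-8)
    expect_equal(lrt$df, k - 1)
  }
  # identical models: statistic 0, p 1
  d <- data.frame(status = rbinom(80, 1, 0.4), x = rnorm(80))
  f <- fit_logistic(status ~ x, d)
  out <- likelihood_ratio_test(f, f)
  expect_equal(out$statistic, 0)
  expect_equal(out$p, 1)
  # different n rejected
  f2 <- fit_logistic(status ~ x, d[1:60, ])
  expect_error(likelihood_ratio_test(f, f2), "invalid-comparison")
})

test_that("global spatial test requires components and is calibrated under the null", {
  co <- null_cohort_with_noise_fpcs(120, 150, n_fpcs = 5, cohort_seed = 3,
                                    fpc_seed = 14)
  out <- global_spatial_test(co)
  expect_equal(out$df, 5)
  expect_gt(out$p, 1e-4)   # no planted effect: should not be extreme
  # removing all component columns is an error
  co2 <- co[, !grepl("^fpc", names(co))]
  expect_error(global_spatial_test(co2), "invalid-comparison")

  # under repeated null simulation the rejection rate is near the level
  set.seed(99)
  rej <- 0L; R <- 60L
  for (r in seq_len(R)) {
    co$status <- sample(co$status)
    for (k in 1:5) co[[sprintf("fpc%02d", k)]] <- rnorm(nrow(co))
    p <- global_spatial_test(co)$p
    rej <- rej + (p < 0.05)
  }
  # binomial 99% bound around 0.05 * 60 = 3
  expect_lte(rej, qbinom(0.995, R, 0.05) + 1)
})

test_that("score construction and per-SD odds ratios follow the definitions", {
  co <- null_cohort_with_noise_fpcs(100, 100, n_fpcs = 3, cohort_seed = 8,
                                    fpc_seed = 2)
  fit <- fit_logistic(status ~ age + fpc01 + fpc02 + fpc03, co)
  fpcs <- c("fpc01", "fpc02", "fpc03")
  sc <- build_score(fit, fpcs, co)
  beta <- coef(fit$glm)[fpcs]
  expect_equal(sc, as.numeric(as.matrix(co[, fpcs]) %*% beta))
  # score variance equals the quadratic form beta' Sigma beta
  expect_equal(var(sc),
               as.numeric(t(beta) %*% cov(as.matrix(co[, fpcs])) %*% beta),
               tolerance = 1e-10)
  expect_error(build_score(fit, c("fpc01", "nope"), co), "naming error")

  expect_equal(per_sd_odds_ratio(fit, "fpc01", sd = 2),
               exp(2 * coef(fit$glm)[["fpc01"]]))
  # effect size 0.33 corresponds to a per-SD odds ratio of 1.39
  expect_equal(exp(0.33), 1.39, tolerance = 0.005)
})

test_that("AUC is the Mann-Whitney statistic and respects its edge cases", {
  expect_equal(auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1)
  expect_equal(auc(c(1, 2, 2, 3), c(0, 1, 0, 1)), 0.875)  # tie half-credit
  expect_error(auc(rnorm(5), rep(1, 5)), "undefined-AUC")
  set.seed(44)
  n <- 2000
  s <- rnorm(n); y <- rbinom(n, 1, 0.5)
  se <- sqrt(delong_var(s, y))
  expect_lt(abs(auc(s, y) - 0.5), 3 * se)
})

test_that("DeLong test agrees with an independent implementation", {
  set.seed(7)
  n <- 300
  y <- rbinom(n, 1, 0.45)
  s1 <- y * 0.8 + rnorm(n)
  s2 <- 0.5 * s1 + rnorm(n, sd = 0.8)
  ours <- delong_test(s1, s2, y)
  ref <- pROC::roc.test(pROC::roc(y, s1, quiet = TRUE),
                        pROC::roc(y, s2, quiet = TRUE), method = "delong")
  expect_equal(ours$p, as.numeric(ref$p.value), tolerance = 1e-10)
  expect_equal(ours$auc1, as.numeric(pROC::auc(pROC::roc(y, s1, quiet = TRUE))),
               tolerance = 1e-12)
  # single-AUC DeLong variance agrees with pROC too
  expect_equal(delong_var(s1, y),
               as.numeric(pROC::var(pROC::roc(y, s1, quiet = TRUE),
                                    method = "delong")),
               tolerance = 1e-10)
})

test_that("DeLong variance is consistent with bootstrap resampling", {
  set.seed(15)
  n <- 400
  y <- rbinom(n, 1, 0.5)
  s <- y + rnorm(n)
  v_dl <- delong_var(s, y)
  B <- 400
  aucs <- replicate(B, {
    i <- sample.int(n, n, replace = TRUE)
    if (length(unique(y[i])) < 2) NA_real_ else auc(s[i], y[i])
  })
  v_bs <- var(aucs, na.rm = TRUE)
  expect_lt(abs(v_dl - v_bs) / v_bs, 0.15)
})

test_that("stepwise selection keeps real effects and prunes noise", {
  set.seed(23)
  hits <- 0L; sizes <- integer(0)
  for (r in 1:12) {
    co <- null_cohort_with_noise_fpcs(250, 250, n_fpcs = 12,
                                      cohort_seed = 100 + r,
                                      fpc_seed = 200 + r)
    # plant a real effect on fpc03
    lp <- qlogis(0.5) + 1.0 * co$fpc03
    co$status <- rbinom(nrow(co), 1, plogis(lp))
    sel <- stepwise_select(co, grep("^fpc", names(co), value = TRUE))
    hits <- hits + ("fpc03" %in% sel)
    sizes <- c(sizes, length(sel))
  }
  expect_gte(hits, 11)   # >= 90% selection of the real effect

  # all-noise candidates: small selected sets
  set.seed(31)
  null_sizes <- vapply(1:10, function(r) {
    co <- null_cohort_with_noise_fpcs(150, 150, n_fpcs = 10,
                                      cohort_seed = 300 + r,
                                      fpc_seed = 400 + r)
    length(stepwise_select(co, grep("^fpc", names(co), value = TRUE)))
  }, integer(1))
  expect_lte(median(null_sizes), 2)

  expect_identical(stepwise_select(data.frame(status = rbinom(50, 1, .5)),
                                   character(0)), character(0))
})

test_that("determinant regressions recover linear effects", {
  co <- null_cohort_with_noise_fpcs(200, 200, n_fpcs = 1, cohort_seed = 40,
                                    fpc_seed = 41)
  set.seed(42)
  co$fpc01 <- 2 * co$bmi + rnorm(nrow(co), sd = 2)
  out <- fpc_determinant_regression(co, "fpc01")
  bmi_row <- out$coefficients[out$coefficients$term == "bmi", ]
  expect_lt(abs(bmi_row$estimate - 2), 3 * bmi_row$std_error)
  expect_lt(bmi_row$p, 1e-6)
  expect_true(all(c("age", "bmi", "pd") %in% rownames(out$correlations)))
  # centred response, intercept-only: intercept 0
  co$resp <- co$fpc01 - mean(co$fpc01)
  f0 <- lm(resp ~ 1, co)
  expect_lt(abs(coef(f0)[1]), 1e-12)
})
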