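# Case-control association layer: adjusted logistic regression, global
# likelihood-ratio test for the spatial components, spatial-relations risk
# score, per-SD odds ratios, AUC / DeLong comparison, Harrell-style
# optimism-corrected (bootstrap) validation, stepwise component selection
# and linear-model determinants of individual components.

.default_adjustments <- c("age", "bmi", "sqrt_pd", "parity_afb", "hrt")

#' Coerce and validate a cohort table
#'
#' Ensures the per-subject covariate table has the expected columns and
#' reference levels (`Never` for HRT, `Nulliparous` for parity/AFB) and a
#' `sqrt_pd` column.
#'
#' @param df data.frame with at least `status` (0/1), `age`, `bmi`, `pd`,
#'   `hrt`, `parity_afb`.
#' @return the validated data.frame.
#' @export
as_cohort_table <- function(df) {
  need <- c("status", "age", "bmi", "pd", "hrt", "parity_afb")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cohort table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(df$status %in% c(0, 1)))
    stop("status must be 0/1", call. = FALSE)
  if (any(df$pd < 0 | df$pd > 100))
    stop("pd must lie in [0, 100]", call. = FALSE)
  df$sqrt_pd <- sqrt(df$pd)
  df$hrt <- stats::relevel(factor(df$hrt, levels = union(hrt_levels,
                                                         levels(factor(df$hrt)))),
                           ref = "Never")
  df$parity_afb <- stats::relevel(
    factor(df$parity_afb,
           levels = union(parity_levels, levels(factor(df$parity_afb)))),
    ref = "Nulliparous")
  df$hrt <- droplevels(df$hrt)
  df$parity_afb <- droplevels(df$parity_afb)
  df
}

#' Fit a logistic regression model
#'
#' Maximum likelihood by iteratively reweighted least squares
#' (`stats::glm`, binomial logit, log-likelihood tolerance `1e-10`), with
#' explicit detection of rank deficiency and complete/quasi-separation.
#'
#' @param formula model formula with a 0/1 response.
#' @param data data.frame.
#' @return object of class `logistic_fit`: the `glm` fit plus a
#'   `coefficients` table (estimate, SE, Wald z, p), `log_lik`, `n`.
#' @export
fit_logistic <- function(formula, data) {
  fit <- suppressWarnings(
    glm(formula, data = data, family = binomial(),
        control = glm.control(epsilon = 1e-10, maxit = 100L)))
  if (any(is.na(coef(fit))))
    stop("design error: rank-deficient design matrix", call. = FALSE)
  mu <- fitted(fit)
  if (any(abs(coef(fit)) > 15) && (any(mu > 1 - 1e-8) || any(mu < 1e-8)))
    stop("separation error: diverging coefficients (complete or quasi-separation)",
         call. = FALSE)
  sm <- summary(fit)$coefficients
  structure(list(glm = fit,
                 coefficients = data.frame(term = rownames(sm),
                                           estimate = sm[, 1],
                                           std_error = sm[, 2],
                                           z = sm[, 3], p = sm[, 4],
                                           row.names = NULL),
                 log_lik = as.numeric(logLik(fit)),
                 df = length(coef(fit)),
                 n = nrow(fit$model),
                 formula = formula),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> n=%d, %d coefficients, logLik=%.3f\n",
              x$n, x$df, x$log_lik))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Likelihood-ratio test between nested logistic fits
#'
#' `statistic = 2 (ll_full - ll_reduced)`, degrees of freedom the
#' difference in coefficient counts, p-value from the chi-square upper
#' tail.
#'
#' @param full,reduced [fit_logistic()] fits on the same observations,
#'   `reduced` nested in `full`.
#' @return list with `statistic`, `df`, `p`.
#' @export
likelihood_ratio_test <- function(full, reduced) {
  stopifnot(inherits(full, "logistic_fit"), inherits(reduced, "logistic_fit"))
  if (full$n != reduced$n)
    stop("invalid-comparison: models fit on different numbers of observations",
         call. = FALSE)
  df <- full$df - reduced$df
  stat <- 2 * (full$log_lik - reduced$log_lik)
  if (df < 0 || stat < -1e-6)
    stop("invalid-comparison: models are not nested (reduced fits better)",
         call. = FALSE)
  stat <- max(stat, 0)
  p <- if (df == 0) 1 else pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p)
}

#' Unadjusted likelihood-ratio test from a case/control contingency table
#'
#' Fits a logistic model of case status on a single categorical variable
#' (grouped binomial likelihood) against the intercept-only model, as used
#' for unadjusted covariate tests in case-control tables.
#'
#' @param cases,controls per-category counts (same length >= 2).
#' @return list with `statistic`, `df`, `p`.
#' @export
lrt_contingency <- function(cases, controls) {
  stopifnot(length(cases) == length(controls), length(cases) >= 2L,
            all(cases >= 0), all(controls >= 0))
  cat_f <- factor(seq_along(cases))
  full <- suppressWarnings(glm(cbind(cases, controls) ~ cat_f,
                               family = binomial()))
  red <- suppressWarnings(glm(cbind(cases, controls) ~ 1,
                              family = binomial()))
  stat <- as.numeric(2 * (logLik(full) - logLik(red)))
  df <- length(cases) - 1L
  list(statistic = stat, df = df,
       p = pchisq(stat, df, lower.tail = FALSE))
}

.fpc_cols <- function(cohort) grep("^fpc", names(cohort), value = TRUE)

.adj_formula <- function(adjustments, extra = NULL) {
  rhs <- paste(c(adjustments, extra), collapse = " + ")
  if (rhs == "") rhs <- "1"
  as.formula(paste("status ~", rhs))
}

#' Global test of the spatial components
#'
#' Likelihood-ratio test of the adjusted logistic model containing all
#' component scores against the adjusted model without any, on as many
#' degrees of freedom as there are component columns.
#'
#' @param cohort cohort data.frame containing `status`, the adjustment
#'   variables and `fpc*` score columns.
#' @param fpc_cols component column names (default: all columns starting
#'   `fpc`).
#' @param adjustments adjustment variable names (default age, BMI, sqrt PD,
#'   parity/AFB, HRT).
#' @return list with `statistic`, `df`, `p`, and the two fits.
#' @export
global_spatial_test <- function(cohort, fpc_cols = NULL,
                                adjustments = .default_adjustments) {
  if (is.null(fpc_cols)) fpc_cols <- .fpc_cols(cohort)
  if (!length(fpc_cols))
    stop("invalid-comparison: no component score columns present",
         call. = FALSE)
  full <- fit_logistic(.adj_formula(adjustments, fpc_cols), cohort)
  red <- fit_logistic(.adj_formula(adjustments), cohort)
  out <- likelihood_ratio_test(full, red)
  out$full <- full; out$reduced <- red
  out
}

#' Spatial-relations score
#'
#' Per-subject sum of the component values weighted by their estimated
#' logistic coefficients (adjustment terms excluded).
#'
#' @param fit a [fit_logistic()] fit containing the component terms.
#' @param fpc_columns names of the component terms.
#' @param newdata data.frame holding the component columns (defaults to the
#'   fit's data).
#' @return numeric score vector.
#' @export
build_score <- function(fit, fpc_columns, newdata = NULL) {
  stopifnot(inherits(fit, "logistic_fit"))
  beta <- coef(fit$glm)
  miss <- setdiff(fpc_columns, names(beta))
  if (length(miss))
    stop("naming error: terms not in the fit: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(newdata)) newdata <- fit$glm$model
  as.numeric(as.matrix(newdata[, fpc_columns, drop = FALSE]) %*%
               beta[fpc_columns])
}

#' Per-standard-deviation odds ratio
#'
#' `exp(beta_term * sd)`: the odds ratio for a one-SD increase of a term.
#'
#' @param fit a [fit_logistic()] fit.
#' @param term coefficient name.
#' @param sd the standard deviation to scale by (> 0).
#' @return the odds ratio.
#' @export
per_sd_odds_ratio <- function(fit, term, sd) {
  stopifnot(inherits(fit, "logistic_fit"), sd > 0)
  beta <- coef(fit$glm)
  if (!term %in% names(beta))
    stop("naming error: term not in the fit: ", term, call. = FALSE)
  exp(beta[[term]] * sd)
}

#' Area under the ROC curve
#'
#' Mann-Whitney statistic with half credit for ties.
#'
#' @param scores numeric predictions.
#' @param labels 0/1 outcomes (both classes present).
#' @return the AUC.
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("undefined-AUC: both classes must be present", call. = FALSE)
  r <- rank(scores)   # midranks: ties get half credit
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong placement values: V10 (per case) and V01 (per control)
.placements <- function(scores, labels) {
  x <- scores[labels == 1L]; y <- scores[labels == 0L]
  cmp <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(cmp), v01 = colMeans(cmp),
       theta = mean(cmp))
}

#' DeLong variance of a single AUC
#'
#' @param scores numeric predictions.
#' @param labels 0/1 outcomes.
#' @return the estimated variance of the AUC.
#' @export
delong_var <- function(scores, labels) {
  labels <- as.integer(labels)
  pl <- .placements(scores, labels)
  var(pl$v10) / length(pl$v10) + var(pl$v01) / length(pl$v01)
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two score vectors computed on the same subjects via
#' the placement-value covariance matrix and a two-sided z-test on the AUC
#' difference.
#'
#' @param scores1,scores2 paired predictions for the same subjects.
#' @param labels 0/1 outcomes.
#' @return list with `auc1`, `auc2`, `z`, `p`.
#' @export
delong_test <- function(scores1, scores2, labels) {
  labels <- as.integer(labels)
  if (length(scores1) != length(scores2) ||
      length(scores1) != length(labels))
    stop("scores and labels must be paired (equal length)", call. = FALSE)
  p1 <- .placements(scores1, labels)
  p2 <- .placements(scores2, labels)
  n1 <- length(p1$v10); n0 <- length(p1$v01)
  s10 <- cov(cbind(p1$v10, p2$v10))
  s01 <- cov(cbind(p1$v01, p2$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  d <- p1$theta - p2$theta
  z <- if (v > 0) d / sqrt(v) else 0
  list(auc1 = p1$theta, auc2 = p2$theta, z = z,
       p = 2 * pnorm(-abs(z)))
}

#' Stepwise selection of components
#'
#' Bidirectional stepwise minimisation of AIC over the candidate component
#' terms with the adjustment variables always retained (R's `step`
#' machinery, starting from the full candidate model).  The scan order is
#' the column order; ties keep the current model.
#'
#' @param cohort cohort data.frame.
#' @param candidate_fpcs candidate component column names.
#' @param forced_adjustments adjustment variables kept in every model.
#' @return character vector of selected component names (possibly empty).
#' @export
stepwise_select <- function(cohort, candidate_fpcs,
                            forced_adjustments = .default_adjustments) {
  if (!length(candidate_fpcs)) return(character(0))
  if (length(intersect(candidate_fpcs, forced_adjustments)))
    stop("candidates must be disjoint from the forced adjustments",
         call. = FALSE)
  # step() re-evaluates model calls in the formula environment, so the
  # formulas must close over this frame (where `cohort` is bound)
  f_full <- .adj_formula(forced_adjustments, candidate_fpcs)
  lower <- .adj_formula(forced_adjustments)
  environment(f_full) <- environment(lower) <- environment()
  full <- glm(f_full, data = cohort, family = binomial())
  sel <- step(full, scope = list(lower = lower, upper = f_full),
              direction = "both", trace = 0)
  intersect(candidate_fpcs, attr(terms(sel), "term.labels"))
}

#' Linear-model determinants of a component
#'
#' Ordinary least squares of a (standardised) component score on the
#' case-control risk factors, with per-term p-values and the pairwise
#' Pearson correlations of the component with age, BMI and PD.
#'
#' @param cohort cohort data.frame.
#' @param fpc_col name of the component column (the response).
#' @param covariates regressor names (default age, BMI, PD, parity/AFB,
#'   HRT).
#' @return list with `fit` (`lm`), `coefficients` table and `correlations`.
#' @export
fpc_determinant_regression <- function(cohort, fpc_col,
                                       covariates = c("age", "bmi", "pd",
                                                      "parity_afb", "hrt")) {
  f <- as.formula(paste(fpc_col, "~",
                        paste(covariates, collapse = " + ")))
  fit <- lm(f, data = cohort)
  if (any(is.na(coef(fit))))
    stop("design error: rank-deficient design matrix", call. = FALSE)
  sm <- summary(fit)$coefficients
  cont <- intersect(c("age", "bmi", "pd"), covariates)
  cors <- vapply(cont, function(v) {
    ct <- stats::cor.test(cohort[[fpc_col]], cohort[[v]])
    c(r = unname(ct$estimate), p = ct$p.value)
  }, numeric(2))
  list(fit = fit,
       coefficients = data.frame(term = rownames(sm), estimate = sm[, 1],
                                 std_error = sm[, 2], p = sm[, 4],
                                 row.names = NULL),
       correlations = t(cors))
}

#' Format a p-value the way epidemiology tables print them
#'
#' Scientific notation at one significant figure below `1e-3`, otherwise
#' three decimals.
#'
#' @param p p-value(s).
#' @return character vector.
#' @export
format_pvalue <- function(p) {
  ifelse(p < 1e-3, sprintf("%.0e", signif(p, 1)), sprintf("%.3f", p))
}
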