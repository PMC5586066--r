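# Optimism-corrected ("honest") validation of the spatial-relations score,
# following the bootstrap refitting scheme of Harrell-style internal
# validation: the whole supervised procedure (full logistic fit, score
# construction, score-model fit) is repeated on each bootstrap resample,
# each index is evaluated on the resample (apparent) and on the original
# data (test), and the mean apparent-minus-test gap is subtracted from the
# original apparent index.

# design matrices used by the bootstrap; built once so factor levels are
# stable across resamples
.validation_design <- function(cohort, fpc_cols, adjustments) {
  f <- as.formula(paste("~", paste(adjustments, collapse = " + ")))
  Xadj <- model.matrix(f, cohort)      # includes intercept
  Xfpc <- as.matrix(cohort[, fpc_cols, drop = FALSE])
  list(y = as.integer(cohort$status), Xadj = Xadj, Xfpc = Xfpc)
}

.glm_fit_quiet <- function(X, y) {
  fit <- suppressWarnings(
    glm.fit(X, y, family = binomial(),
            control = glm.control(epsilon = 1e-10, maxit = 100L)))
  b <- coef(fit)
  # flag only pathological fits (non-convergence, rank problems, runaway
  # coefficients); small-sample fits with large-but-finite coefficients are
  # legitimate resamples whose noise the optimism average absorbs
  ok <- fit$converged && !any(is.na(b)) && max(abs(b)) <= 100
  list(beta = b, ok = ok)
}

# one full pass of the supervised procedure on rows `idx`; indices are then
# evaluated on `idx` (apparent) and on all rows (test)
.score_procedure <- function(d, idx) {
  Xfull <- cbind(d$Xadj, d$Xfpc)
  f_full <- .glm_fit_quiet(Xfull[idx, , drop = FALSE], d$y[idx])
  if (!f_full$ok) return(NULL)
  beta_fpc <- f_full$beta[colnames(d$Xfpc)]
  s_all <- as.numeric(d$Xfpc %*% beta_fpc)

  fit_score_on <- function(rows) {
    Xs <- cbind(d$Xadj[rows, , drop = FALSE], score = s_all[rows])
    .glm_fit_quiet(Xs, d$y[rows])
  }
  f_score <- fit_score_on(idx)
  f_red <- .glm_fit_quiet(d$Xadj[idx, , drop = FALSE], d$y[idx])
  if (!f_score$ok || !f_red$ok) return(NULL)

  # AUC indices use the trained coefficients on any rows; the effect-size
  # index of the trained score is refit on the evaluation rows
  index_on <- function(rows, refit_effect) {
    fe <- if (refit_effect) fit_score_on(rows) else f_score
    if (!fe$ok) return(NULL)
    lp_full <- as.numeric(cbind(d$Xadj[rows, , drop = FALSE],
                                s_all[rows]) %*% f_score$beta)
    lp_red <- as.numeric(d$Xadj[rows, , drop = FALSE] %*% f_red$beta)
    c(effect = unname(fe$beta["score"]) * sd(s_all[rows]),
      auc_full = auc(lp_full, d$y[rows]),
      auc_reduced = auc(lp_red, d$y[rows]))
  }
  list(apparent = index_on(idx, refit_effect = FALSE),
       test = index_on(seq_along(d$y), refit_effect = TRUE))
}

#' Optimism-corrected validation of the spatial-relations score
#'
#' For each of `B` bootstrap resamples the full supervised pipeline
#' (adjusted logistic fit with all component scores, score construction,
#' score-model fit) is retrained; each index -- the per-SD effect size of
#' the score, the AUC of the adjusted model with the score, and the AUC of
#' the adjusted model without it -- is computed on the resample (apparent)
#' and on the original data (test).  `optimism = mean(apparent_b - test_b)`
#' and `honest = apparent - optimism`, per index.  Component bases are held
#' fixed (they are fit without outcome labels); only the supervised steps
#' are refit.  Deterministic given `seed`.
#'
#' @param cohort cohort data.frame with `status`, adjustments and component
#'   columns.
#' @param fpc_cols component column names (default: all `fpc*` columns).
#' @param adjustments adjustment variable names.
#' @param B number of bootstrap resamples (>= 1).
#' @param seed integer RNG seed.
#' @param .indices optional list of row-index vectors overriding the
#'   bootstrap resamples (for testing).
#' @return object of class `validation_report`.
#' @export
optimism_bootstrap <- function(cohort, fpc_cols = NULL,
                               adjustments = .default_adjustments,
                               B = 1000L, seed = 1L, .indices = NULL) {
  if (is.null(fpc_cols)) fpc_cols <- .fpc_cols(cohort)
  stopifnot(length(fpc_cols) >= 1, B >= 1)
  d <- .validation_design(cohort, fpc_cols, adjustments)
  n <- length(d$y)

  app <- .score_procedure(d, seq_len(n))
  if (is.null(app))
    stop("separation error: the full-data fit did not converge", call. = FALSE)
  apparent <- app$apparent

  idx_list <- if (!is.null(.indices)) .indices else
    with_seed(seed, lapply(seq_len(B), function(b)
      sample.int(n, n, replace = TRUE)))
  B <- length(idx_list)

  opt <- matrix(NA_real_, B, 3L,
                dimnames = list(NULL, c("effect", "auc_full", "auc_reduced")))
  failed <- 0L
  for (b in seq_len(B)) {
    res <- .score_procedure(d, idx_list[[b]])
    if (is.null(res) || is.null(res$test)) { failed <- failed + 1L; next }
    opt[b, ] <- res$apparent - res$test
  }
  if (failed > 0.05 * B)
    stop(sprintf(
      "separation error: %d of %d bootstrap resamples failed to converge",
      failed, B), call. = FALSE)
  optimism <- colMeans(opt, na.rm = TRUE)
  honest <- apparent - optimism
  structure(list(
    apparent_effect = unname(apparent["effect"]),
    honest_effect = unname(honest["effect"]),
    apparent_or = exp(unname(apparent["effect"])),
    honest_or = exp(unname(honest["effect"])),
    apparent_auc_full = unname(apparent["auc_full"]),
    honest_auc_full = unname(honest["auc_full"]),
    apparent_auc_reduced = unname(apparent["auc_reduced"]),
    honest_auc_reduced = unname(honest["auc_reduced"]),
    optimism = as.list(optimism),
    B = B, n_failed = failed, seed = seed), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<validation_report> B=%d bootstrap resamples (%d failed)\n",
    "  per-SD OR of the score: apparent %.3f, honest %.3f\n",
    "  AUC with score:         apparent %.3f, honest %.3f\n",
    "  AUC without score:      apparent %.3f, honest %.3f\n"),
    x$B, x$n_failed, x$apparent_or, x$honest_or,
    x$apparent_auc_full, x$honest_auc_full,
    x$apparent_auc_reduced, x$honest_auc_reduced))
  invisible(x)
}

#' Serialise a validation report to JSON
#'
#' @param report a [optimism_bootstrap()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_validation_json <- function(report, path) {
  stopifnot(inherits(report, "validation_report"))
  jsonlite::write_json(unclass(report), path, digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}
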