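# End-to-end orchestration: images -> forces histograms -> functional PCA
# -> adjusted association analysis, plus transfer of a trained component
# model to a second cohort.

.pair_names <- c("fh12", "fh13", "fh14", "fh23", "fh24", "fh34")

# fpc score column name: fpc{i}{j}_{k}
.score_col <- function(pair_name, k) paste0(sub("fh", "fpc", pair_name), "_", k)

#' Compute the six forces-histogram curves for a list of subjects
#'
#' Generates (or takes) each subject's image, derives a four-class label
#' map either through the full preprocessing + fuzzy C-means route or from
#' the phantom ground truth, and computes the six-pair histogram set.
#'
#' @param phantom_specs list of [phantom_spec()] (one per subject).
#' @param n_angles histogram length (default 180).
#' @param target_spacing_mm analysis grid (default 0.25 mm).
#' @param segmentation `"pipeline"` (preprocess + fuzzy C-means) or
#'   `"ground_truth"` (phantom labels; no image processing).
#' @param pd_truth collect ground-truth percentage density per subject?
#' @return list with `curves` (named list of six n x a matrices), `fh_sets`
#'   (list of `fh_set`), `pd_truth` (vector or NULL).
#' @export
cohort_fh_curves <- function(phantom_specs, n_angles = 180L,
                             target_spacing_mm = 0.25,
                             segmentation = c("pipeline", "ground_truth"),
                             pd_truth = TRUE) {
  segmentation <- match.arg(segmentation)
  n <- length(phantom_specs)
  fh_sets <- vector("list", n)
  pd <- if (pd_truth) numeric(n) else NULL
  for (s in seq_len(n)) {
    ph <- generate_phantom(phantom_specs[[s]])
    map <- if (segmentation == "ground_truth") {
      rescale_labelmap(ph$labels, max(target_spacing_mm,
                                      ph$labels$pixel_spacing_mm))
    } else {
      pre <- preprocess_mammogram(ph$image)
      segment_tissue(pre$denoised, pre$mask,
                     target_spacing_mm = max(target_spacing_mm,
                                             ph$image$pixel_spacing_mm))
    }
    fh_sets[[s]] <- compute_fh_set(map, a = n_angles)
    if (pd_truth) pd[s] <- ph$pd_truth
  }
  curves <- lapply(seq_along(.pair_names), function(p)
    t(vapply(fh_sets, function(fs) fs[[p]]$values, numeric(n_angles))))
  names(curves) <- .pair_names
  list(curves = curves, fh_sets = fh_sets, pd_truth = pd)
}

#' Run the full spatial-relations analysis on a synthetic cohort
#'
#' Orchestrates image generation, preprocessing/segmentation (or
#' ground-truth labels), forces histograms, per-pair functional PCA with
#' the cumulative-variance retention rule, adjusted logistic regression
#' with the global likelihood-ratio test, the spatial-relations score,
#' optional optimism-corrected bootstrap validation and optional stepwise
#' component selection.  Deterministic given the seeds in the specs and
#' `seed`.
#'
#' @param cohort cohort data.frame (from [generate_cohort()]).
#' @param phantom_specs per-subject [phantom_spec()] list, matching
#'   `cohort` rows 1:1.
#' @param n_angles,target_spacing_mm,segmentation see [cohort_fh_curves()].
#' @param variance_threshold component retention rule (default 0.85).
#' @param adjustments adjustment variables for all models.
#' @param pd_source `"ground_truth"` replaces the cohort's `pd`/`sqrt_pd`
#'   with the phantom's true dense fraction (the default, preserving the
#'   confounding between density and the spatial layout); `"table"` keeps
#'   the drawn covariate.
#' @param B bootstrap replicates for validation (0 skips it).
#' @param stepwise run stepwise component selection?
#' @param seed seed for the bootstrap.
#' @param out_dir if non-NULL, write per-image histograms (CSV), component
#'   models (JSON), the scored cohort (CSV), the coefficient table (CSV)
#'   and the validation report (JSON) here.
#' @return object of class `mammospat_run`: list with `cohort` (scored),
#'   `fpca_models`, `global_test`, `full_fit`, `score`, `validation`,
#'   `selected_fpcs`, `fh_sets`, `config`.
#' @export
run_pipeline <- function(cohort, phantom_specs,
                         n_angles = 180L, target_spacing_mm = 0.25,
                         segmentation = c("pipeline", "ground_truth"),
                         variance_threshold = 0.85,
                         adjustments = .default_adjustments,
                         pd_source = c("ground_truth", "table"),
                         B = 0L, stepwise = FALSE, seed = 1L,
                         out_dir = NULL) {
  segmentation <- match.arg(segmentation)
  pd_source <- match.arg(pd_source)
  if (nrow(cohort) != length(phantom_specs))
    stop("join error: cohort rows and phantom specs do not match 1:1",
         call. = FALSE)
  cohort <- as_cohort_table(cohort)

  fh <- cohort_fh_curves(phantom_specs, n_angles, target_spacing_mm,
                         segmentation, pd_truth = pd_source == "ground_truth")
  if (pd_source == "ground_truth") {
    cohort$pd <- pmin(100, pmax(0, fh$pd_truth))
    cohort$sqrt_pd <- sqrt(cohort$pd)
  }

  grid <- .fh_angles(n_angles)
  models <- list()
  for (p in .pair_names) {
    m <- fit_fpca(fh$curves[[p]], grid = grid,
                  variance_threshold = variance_threshold)
    models[[p]] <- m
    for (k in seq_len(m$K))
      cohort[[.score_col(p, k)]] <- m$scores[, k]
  }

  fpc_cols <- .fpc_cols(cohort)
  gt <- global_spatial_test(cohort, fpc_cols, adjustments)
  score <- build_score(gt$full, fpc_cols, cohort)
  cohort$spatial_score <- score

  validation <- if (B > 0)
    optimism_bootstrap(cohort, fpc_cols, adjustments, B = B, seed = seed)
  else NULL
  selected <- if (stepwise)
    stepwise_select(cohort, fpc_cols, adjustments) else NULL

  run <- structure(list(
    cohort = cohort, fpca_models = models, global_test = gt,
    full_fit = gt$full, score = score, validation = validation,
    selected_fpcs = selected, fh_sets = fh$fh_sets,
    config = list(n_angles = n_angles,
                  target_spacing_mm = target_spacing_mm,
                  segmentation = segmentation,
                  variance_threshold = variance_threshold,
                  adjustments = adjustments, pd_source = pd_source,
                  B = B, stepwise = stepwise, seed = seed)),
    class = "mammospat_run")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fh_csv(fh$fh_sets, file.path(out_dir, "forces_histograms.csv"),
                 ids = cohort$id)
    for (p in names(models))
      write_fpca_json(models[[p]],
                      file.path(out_dir, sprintf("fpca_%s.json", p)))
    write.csv(cohort, file.path(out_dir, "cohort_scored.csv"),
              row.names = FALSE)
    write.csv(gt$full$coefficients,
              file.path(out_dir, "coefficients_full_model.csv"),
              row.names = FALSE)
    if (!is.null(validation))
      write_validation_json(validation,
                            file.path(out_dir, "validation_report.json"))
    jsonlite::write_json(run$config, file.path(out_dir, "run_config.json"),
                         digits = NA, auto_unbox = TRUE)
  }
  run
}

#' @export
print.mammospat_run <- function(x, ...) {
  cat(sprintf(paste0(
    "<mammospat_run> n=%d subjects, %d component scores\n",
    "  global LRT: chi2=%.2f on %d df, p=%s\n"),
    nrow(x$cohort), length(.fpc_cols(x$cohort)),
    x$global_test$statistic, x$global_test$df,
    format_pvalue(x$global_test$p)))
  if (!is.null(x$selected_fpcs))
    cat("  stepwise-selected:", paste(x$selected_fpcs, collapse = ", "), "\n")
  if (!is.null(x$validation)) print(x$validation)
  invisible(x)
}

#' Transfer a trained component model to a second cohort
#'
#' Projects the new subjects' forces histograms onto the training
#' eigenfunctions (training standardisation), checks that the dominant
#' angles of the selected components agree between the training model and a
#' refit on the new curves, and fits the adjusted logistic model for the
#' selected components on the new cohort.
#'
#' @param train_run a [run_pipeline()] result.
#' @param new_cohort cohort data.frame for the validation subjects.
#' @param new_phantom_specs per-subject [phantom_spec()] list.
#' @param fpc_cols component columns to carry over (default: the training
#'   run's stepwise selection, else all).
#' @return list with `cohort` (scored new cohort), `fit`, `angle_match`
#'   (per component: training and refit dominant angles and their absolute
#'   difference in grid steps), `refit_models`.
#' @export
validate_transfer <- function(train_run, new_cohort, new_phantom_specs,
                              fpc_cols = NULL) {
  stopifnot(inherits(train_run, "mammospat_run"))
  cfg <- train_run$config
  new_cohort <- as_cohort_table(new_cohort)
  fh <- cohort_fh_curves(new_phantom_specs, cfg$n_angles,
                         cfg$target_spacing_mm, cfg$segmentation,
                         pd_truth = cfg$pd_source == "ground_truth")
  if (cfg$pd_source == "ground_truth") {
    new_cohort$pd <- pmin(100, pmax(0, fh$pd_truth))
    new_cohort$sqrt_pd <- sqrt(new_cohort$pd)
  }
  grid <- .fh_angles(cfg$n_angles)
  refits <- list()
  for (p in .pair_names) {
    m <- train_run$fpca_models[[p]]
    if (sum(m$eigenvalues) <= 0)
      stop("degenerate-data: zero-variance training component family ", p,
           call. = FALSE)
    sc <- project(m, fh$curves[[p]], grid = grid)
    for (k in seq_len(m$K))
      new_cohort[[.score_col(p, k)]] <- sc[, k]
    refits[[p]] <- fit_fpca(fh$curves[[p]], grid = grid,
                            variance_threshold = cfg$variance_threshold)
  }
  if (is.null(fpc_cols))
    fpc_cols <- if (length(train_run$selected_fpcs))
      train_run$selected_fpcs else .fpc_cols(new_cohort)

  # dominant-angle agreement for the carried-over components
  step_deg <- 360 / cfg$n_angles
  angle_match <- lapply(fpc_cols, function(colname) {
    part <- sub("fpc(\\d\\d)_(\\d)", "fh\\1", colname)
    k <- as.integer(sub("fpc\\d\\d_(\\d)", "\\1", colname))
    if (k > refits[[part]]$K) return(NULL)
    tr <- dominant_angles(train_run$fpca_models[[part]], k, 3L)
    nw <- dominant_angles(refits[[part]], k, 3L)
    mm <- min(nrow(tr), nrow(nw))
    d <- vapply(seq_len(mm), function(i) {
      dd <- abs(tr$angle[i] - nw$angle[i]) %% 360
      min(dd, 360 - dd)
    }, numeric(1))
    data.frame(component = colname, rank = seq_len(mm),
               train_angle = tr$angle[seq_len(mm)],
               new_angle = nw$angle[seq_len(mm)],
               diff_steps = d / step_deg)
  })
  angle_match <- do.call(rbind, angle_match)

  fit <- fit_logistic(.adj_formula(cfg$adjustments, fpc_cols), new_cohort)
  list(cohort = new_cohort, fit = fit, angle_match = angle_match,
       refit_models = refits)
}
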