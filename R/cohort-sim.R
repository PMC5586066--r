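#' Specification of a synthetic case-control cohort
#'
#' Covariate distributions default to values calibrated to a Swedish
#' post-menopausal case-control population (ages ~63, BMI ~25, percentage
#' density ~17% with a wide spread, HRT mostly never-users, five
#' parity/age-at-first-birth strata).  Case status is generated from a
#' logistic model whose linear predictor combines the observed covariates
#' with two latent spatial-configuration parameters that also drive each
#' subject's phantom: the vertical position of the dense blob
#' (`dense_angle`) and the lower-quadrant fat weight (`lower_quadrant_fat`).
#'
#' @param n_cases,n_controls target counts (>= 1).
#' @param age_mean,age_sd,bmi_mean,bmi_sd normal covariate parameters.
#' @param hrt_probs probabilities of HRT Never/Past/Current (sum 1).
#' @param parity_probs probabilities of the five parity/AFB categories
#'   Nulliparous, P<=2&AFB<=25, P<=2&AFB>25, P>2&AFB<=25, P>2&AFB>25
#'   (sum 1).
#' @param pd_mean,pd_sd percentage-density normal parameters, truncated to
#'   `[0, 100]`.
#' @param beta named log-odds coefficients; recognised names: `age`, `bmi`,
#'   `sqrt_pd`, `hrt_past`, `hrt_current`, `parity2`..`parity5`,
#'   `dense_angle`, `lower_quadrant_fat`.  Unnamed effects are 0.
#' @param lqf_scale multiplier mapping the standard-normal latent fat
#'   parameter onto the phantom's `lower_quadrant_fat_weight`.
#' @param phantom_canvas canvas size passed to each subject's phantom.
#' @param seed integer RNG seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases, n_controls,
                        age_mean = 63.1, age_sd = 6.5,
                        bmi_mean = 25.1, bmi_sd = 3.7,
                        hrt_probs = c(0.73, 0.06, 0.21),
                        parity_probs = c(0.117, 0.287, 0.295, 0.230, 0.071),
                        pd_mean = 16.7, pd_sd = 14.0,
                        beta = c(bmi = 0.05, sqrt_pd = 0.2,
                                 hrt_past = 0.7, hrt_current = 0.27,
                                 parity2 = -0.19, parity3 = -0.14,
                                 parity4 = -0.67, parity5 = -0.39),
                        lqf_scale = 2,
                        phantom_canvas = c(64L, 64L),
                        seed = 1L) {
  parity_probs <- parity_probs / sum(parity_probs)  # guard rounding
  if (abs(sum(hrt_probs) - 1) > 1e-12 || any(hrt_probs < 0))
    stop("invalid-spec: hrt_probs must be non-negative and sum to 1",
         call. = FALSE)
  if (length(parity_probs) != 5L || any(parity_probs < 0))
    stop("invalid-spec: parity_probs must be 5 non-negative values",
         call. = FALSE)
  if (n_cases < 1 || n_controls < 1)
    stop("invalid-spec: n_cases and n_controls must be >= 1", call. = FALSE)
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 age_mean = age_mean, age_sd = age_sd,
                 bmi_mean = bmi_mean, bmi_sd = bmi_sd,
                 hrt_probs = hrt_probs, parity_probs = parity_probs,
                 pd_mean = pd_mean, pd_sd = pd_sd,
                 beta = beta, lqf_scale = lqf_scale,
                 phantom_canvas = as.integer(phantom_canvas),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

hrt_levels <- c("Never", "Past", "Current")
parity_levels <- c("Nulliparous",
                   "Parity<=2 & AFB<=25", "Parity<=2 & AFB>25",
                   "Parity>2 & AFB<=25", "Parity>2 & AFB>25")

.beta_get <- function(beta, name) if (name %in% names(beta)) beta[[name]] else 0

#' Generate a synthetic case-control cohort with per-subject phantoms
#'
#' Draws covariates and two latent spatial parameters for a subject pool,
#' auto-calibrates the logistic intercept so that the expected case count
#' matches the requested case fraction, draws case status, and then samples
#' subjects by status to the exact `n_cases`/`n_controls`.  Each retained
#' subject receives a [phantom_spec()] whose dense-blob location, blob size
#' (tied to the subject's percentage density) and lower-quadrant fat weight
#' realise the latent parameters.  Deterministic given `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return list with `cohort` (data.frame: `id`, `status`, `age`, `bmi`,
#'   `pd`, `sqrt_pd`, `hrt`, `parity_afb`, `latent_dense_angle`,
#'   `latent_lower_quadrant_fat`) and `phantom_specs` (list of
#'   [phantom_spec()], one per row).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_total <- spec$n_cases + spec$n_controls
  f_case <- spec$n_cases / n_total

  with_seed(spec$seed, {
    pool <- 3L * n_total
    for (attempt in 1:2) {
      age <- rnorm(pool, spec$age_mean, spec$age_sd)
      bmi <- rnorm(pool, spec$bmi_mean, spec$bmi_sd)
      pd <- pmin(100, pmax(0, rnorm(pool, spec$pd_mean, spec$pd_sd)))
      hrt <- factor(sample(hrt_levels, pool, TRUE, spec$hrt_probs),
                    levels = hrt_levels)
      parity <- factor(sample(parity_levels, pool, TRUE, spec$parity_probs),
                       levels = parity_levels)
      z_angle <- rnorm(pool)   # latent dense-location verticality
      z_fat <- rnorm(pool)     # latent lower-quadrant fat concentration

      b <- spec$beta
      lp <- .beta_get(b, "age") * (age - spec$age_mean) +
        .beta_get(b, "bmi") * (bmi - spec$bmi_mean) +
        .beta_get(b, "sqrt_pd") * (sqrt(pd) - sqrt(max(spec$pd_mean, 0))) +
        .beta_get(b, "hrt_past") * (hrt == "Past") +
        .beta_get(b, "hrt_current") * (hrt == "Current") +
        .beta_get(b, "parity2") * (parity == parity_levels[2]) +
        .beta_get(b, "parity3") * (parity == parity_levels[3]) +
        .beta_get(b, "parity4") * (parity == parity_levels[4]) +
        .beta_get(b, "parity5") * (parity == parity_levels[5]) +
        .beta_get(b, "dense_angle") * z_angle +
        .beta_get(b, "lower_quadrant_fat") * z_fat
      if (any(!is.finite(lp)))
        stop("calibration-failure: non-finite linear predictor", call. = FALSE)

      # intercept such that the expected case fraction in the pool is f_case
      g <- function(b0) mean(plogis(b0 + lp)) - f_case
      if (g(-30) > 0 || g(30) < 0)
        stop("calibration-failure: case fraction unachievable", call. = FALSE)
      b0 <- uniroot(g, c(-30, 30), tol = 1e-10)$root
      status <- rbinom(pool, 1L, plogis(b0 + lp))

      if (sum(status == 1L) >= spec$n_cases &&
          sum(status == 0L) >= spec$n_controls) break
      if (attempt == 2L)
        stop("calibration-failure: could not realise requested case/control counts",
             call. = FALSE)
      pool <- 6L * n_total
    }

    keep <- c(which(status == 1L)[seq_len(spec$n_cases)],
              which(status == 0L)[seq_len(spec$n_controls)])
    cohort <- data.frame(
      id = sprintf("S%05d", seq_along(keep)),
      status = status[keep],
      age = age[keep], bmi = bmi[keep],
      pd = pd[keep], sqrt_pd = sqrt(pd[keep]),
      hrt = hrt[keep], parity_afb = parity[keep],
      latent_dense_angle = z_angle[keep],
      latent_lower_quadrant_fat = z_fat[keep],
      stringsAsFactors = FALSE)

    canvas <- spec$phantom_canvas
    a_r <- 0.42 * canvas[1]; a_c <- 0.78 * canvas[2]
    breast_area <- pi / 2 * a_r * a_c
    seeds <- sample.int(.Machine$integer.max - 1L, nrow(cohort))
    phantom_specs <- lapply(seq_len(nrow(cohort)), function(i) {
      # blob angle: latent z maps to [-80, 80] deg about the nipple axis,
      # positive z = upper quadrants
      ang <- 80 * tanh(cohort$latent_dense_angle[i])
      # blob sigma tied to PD so class 3+4 area tracks the PD covariate
      sig <- sqrt(pmax(cohort$pd[i], 1) / 100 * breast_area / (4 * pi))
      sig <- min(max(sig, 2), min(a_r, a_c) / 2.5)
      phantom_spec(
        canvas_size = canvas,
        pixel_spacing_mm = 0.25,
        dense_blob_centers = list(c(0.45, ang)),
        dense_blob_sigma = sig,
        lower_quadrant_fat_weight =
          spec$lqf_scale * cohort$latent_lower_quadrant_fat[i],
        noise_sd = 0.02,
        seed = seeds[i])
    })
    list(cohort = cohort, phantom_specs = phantom_specs)
  })
}

#' Generate curves from a known functional principal component model
#'
#' Fixture generator for functional PCA: `curve_i = mean + sum_k xi_ik
#' phi_k + eps`, with `xi_ik ~ N(0, lambda_k)` and iid `N(0, noise_sd^2)`
#' measurement error.  Eigenfunctions must be orthonormal under the plain
#' grid inner product `sum_j phi_a(theta_j) phi_b(theta_j)`.
#'
#' @param n number of curves (>= 1).
#' @param grid evaluation grid (angles, degrees); default 180 angles at a
#'   2-degree step.
#' @param mean_fn numeric vector on `grid`, or a function of the grid.
#' @param eigenfunctions matrix (length(grid) x K) of orthonormal columns.
#' @param eigenvalues K non-negative score variances.
#' @param noise_sd measurement-error sd.
#' @param seed integer RNG seed.
#' @return n x length(grid) matrix of curves, with attributes `grid` and
#'   `scores` (the latent n x K score matrix).
#' @export
generate_curves <- function(n, grid = seq(0, 358, by = 2), mean_fn = 0,
                            eigenfunctions, eigenvalues, noise_sd = 0,
                            seed = 1L) {
  stopifnot(n >= 1)
  p <- length(grid)
  mu <- if (is.function(mean_fn)) mean_fn(grid) else rep_len(mean_fn, p)
  phi <- as.matrix(eigenfunctions)
  if (nrow(phi) != p)
    stop("invalid-fixture: eigenfunctions not on the grid", call. = FALSE)
  gram <- crossprod(phi)
  if (max(abs(gram - diag(ncol(phi)))) > 1e-6)
    stop("invalid-fixture: eigenfunctions not orthonormal on the grid",
         call. = FALSE)
  if (length(eigenvalues) != ncol(phi) || any(eigenvalues < 0))
    stop("invalid-fixture: eigenvalues must be non-negative, one per eigenfunction",
         call. = FALSE)
  with_seed(seed, {
    xi <- matrix(rnorm(n * ncol(phi)), n) %*% diag(sqrt(eigenvalues),
                                                   ncol(phi))
    X <- matrix(mu, n, p, byrow = TRUE) + xi %*% t(phi)
    if (noise_sd > 0) X <- X + matrix(rnorm(n * p, 0, noise_sd), n, p)
    attr(X, "grid") <- grid
    attr(X, "scores") <- xi
    X
  })
}
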