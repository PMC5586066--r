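# Functional PCA of forces-histogram curves on a dense regular angular
# grid: discretised PCA (eigendecomposition of the sample covariance with
# uniform quadrature weights), component retention by cumulative explained
# variance, standardised per-image scores, modes of variation and
# dominant-angle readout of eigenfunctions.

#' Fit a functional principal component model to curves
#'
#' Curves observed on a common dense grid are centred, the sample
#' covariance matrix (divisor `n - 1`) is eigendecomposed, and eigenfunction
#' signs are fixed so that each eigenfunction has a positive inner product
#' with the first grid basis vector (positive sum as a tie-break).  `K` is
#' the smallest count whose eigenvalues reach `variance_threshold` of the
#' total variance.  Raw scores are grid inner products of the centred
#' curves with the eigenfunctions; standardised scores divide by the
#' training standard deviation (training means are 0 by construction).
#'
#' @param curves n x p matrix, one curve per row, or the output of
#'   [generate_curves()].
#' @param grid evaluation grid; defaults to the `grid` attribute of
#'   `curves`, else 180 angles at a 2-degree step.
#' @param variance_threshold cumulative-variance retention rule (default
#'   0.85).
#' @return object of class `fpc_model`: `grid`, `mean_fn`, `eigenfunctions`
#'   (p x K_all), `eigenvalues` (all, non-increasing), `K`,
#'   `variance_threshold`, `scores` (n x K, standardised), `raw_scores`,
#'   `score_sd`, `n`.
#' @export
fit_fpca <- function(curves, grid = NULL, variance_threshold = 0.85) {
  X <- as.matrix(curves)
  if (is.null(grid)) grid <- attr(curves, "grid")
  if (is.null(grid)) grid <- seq(0, by = 2, length.out = ncol(X))
  if (nrow(X) < 2L)
    stop("insufficient-data: need at least 2 curves", call. = FALSE)
  if (length(grid) != ncol(X))
    stop("grid length must match curve length", call. = FALSE)
  if (variance_threshold <= 0 || variance_threshold > 1)
    stop("variance_threshold must be in (0, 1]", call. = FALSE)
  n <- nrow(X); p <- ncol(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  Cov <- crossprod(Xc) / (n - 1)
  eg <- eigen(Cov, symmetric = TRUE)
  lambda <- pmax(eg$values, 0)
  total <- sum(lambda)
  if (total <= 0)
    stop("degenerate-data: zero total variance", call. = FALSE)
  phi <- eg$vectors
  # sign convention: positive inner product with the first grid basis
  # vector, i.e. phi_k(theta_1) > 0; tie -> positive sum
  for (k in seq_len(ncol(phi))) {
    s <- phi[1L, k]
    if (s == 0) s <- sum(phi[, k])
    if (s < 0) phi[, k] <- -phi[, k]
  }
  K <- which(cumsum(lambda) / total >= variance_threshold - 1e-12)[1L]
  nz <- sum(lambda > total * 1e-12)
  K <- min(K, max(nz, 1L))
  raw <- Xc %*% phi[, seq_len(K), drop = FALSE]
  sdv <- apply(raw, 2L, sd)
  sdv[sdv == 0] <- 1   # degenerate component: leave scores at 0
  std <- sweep(raw, 2L, sdv, "/")
  colnames(raw) <- colnames(std) <- paste0("fpc", seq_len(K))
  structure(list(grid = grid, mean_fn = mu,
                 eigenfunctions = phi, eigenvalues = lambda,
                 K = K, variance_threshold = variance_threshold,
                 scores = std, raw_scores = raw, score_sd = sdv, n = n),
            class = "fpc_model")
}

#' @export
print.fpc_model <- function(x, ...) {
  cat(sprintf("<fpc_model> n=%d curves on %d-point grid; K=%d (%.0f%% rule); lambda: %s ...\n",
              x$n, length(x$grid), x$K, 100 * x$variance_threshold,
              paste(signif(head(x$eigenvalues, 3), 3), collapse = ", ")))
  invisible(x)
}

#' Project new curves onto a fitted component model
#'
#' Centres new curves with the training mean and standardises the inner-
#' product scores with the training standard deviations, mirroring the use
#' of a model trained on one study to score images of another.
#'
#' @param model an [fit_fpca()] model.
#' @param new_curves matrix on the model grid.
#' @param grid optional grid of the new curves (checked against the model).
#' @param standardise return standardised (default) or raw scores.
#' @return n x K score matrix.
#' @export
project <- function(model, new_curves, grid = NULL, standardise = TRUE) {
  stopifnot(inherits(model, "fpc_model"))
  X <- if (is.null(dim(new_curves)))
    matrix(new_curves, nrow = 1L) else as.matrix(new_curves)
  if (is.null(grid)) grid <- attr(new_curves, "grid")
  if (!is.null(grid) &&
      (length(grid) != length(model$grid) ||
       max(abs(grid - model$grid)) > 1e-9))
    stop("incompatible-grid: new curves are not on the model grid",
         call. = FALSE)
  if (ncol(X) != length(model$grid))
    stop("incompatible-grid: curve length does not match the model grid",
         call. = FALSE)
  Xc <- sweep(X, 2L, model$mean_fn)
  raw <- Xc %*% model$eigenfunctions[, seq_len(model$K), drop = FALSE]
  colnames(raw) <- paste0("fpc", seq_len(model$K))
  if (standardise) sweep(raw, 2L, model$score_sd, "/") else raw
}

#' Mode-of-variation curves
#'
#' `V(theta) = mu(theta) + alpha * sqrt(lambda_k) * phi_k(theta)`: the curve
#' family visualising what component `k` changes about the mean curve.
#'
#' @param model an [fit_fpca()] model.
#' @param k component index (1..K).
#' @param alpha numeric vector of multipliers (default `c(-2,-1,0,1,2)`).
#' @return object of class `mode_of_variation`: `k`, `alpha`, `grid`,
#'   `curves` (length(alpha) x p, one row per alpha).
#' @export
mode_of_variation <- function(model, k, alpha = c(-2, -1, 0, 1, 2)) {
  stopifnot(inherits(model, "fpc_model"))
  if (k < 1 || k > model$K)
    stop("out-of-range: k must be in 1..K", call. = FALSE)
  V <- t(vapply(alpha, function(a)
    model$mean_fn + a * sqrt(model$eigenvalues[k]) *
      model$eigenfunctions[, k],
    numeric(length(model$grid))))
  structure(list(k = k, alpha = alpha, grid = model$grid, curves = V),
            class = "mode_of_variation")
}

#' @export
plot.mode_of_variation <- function(x, ...) {
  graphics::matplot(x$grid, t(x$curves), type = "l", lty = 1,
                    col = grDevices::hcl.colors(length(x$alpha), "Zissou 1"),
                    xlab = "angle (degrees)", ylab = "force",
                    main = sprintf("Mode of variation, component %d", x$k),
                    ...)
  invisible(x)
}

#' Dominant angles of an eigenfunction
#'
#' Grid angles of the largest circular local maxima of `|phi_k|`, used to
#' read off where a component captures variability; the sign of the
#' eigenfunction at each angle is reported alongside.
#'
#' @param model an [fit_fpca()] model.
#' @param k component index (1..K).
#' @param top_m number of angles to return.
#' @return data.frame with columns `angle`, `value` (eigenfunction value)
#'   and `sign`, ordered by decreasing `|value|`.
#' @export
dominant_angles <- function(model, k, top_m = 3L) {
  stopifnot(inherits(model, "fpc_model"))
  if (k < 1 || k > model$K)
    stop("out-of-range: k must be in 1..K", call. = FALSE)
  phi <- model$eigenfunctions[, k]
  av <- abs(phi)
  p <- length(av)
  nxt <- c(2:p, 1L); prv <- c(p, 1:(p - 1L))
  is_max <- av > av[nxt] & av > av[prv]
  if (!any(is_max)) is_max <- av >= av[nxt] & av >= av[prv]
  idx <- which(is_max)
  idx <- idx[order(av[idx], decreasing = TRUE)]
  idx <- idx[seq_len(min(top_m, length(idx)))]
  data.frame(angle = model$grid[idx], value = phi[idx],
             sign = sign(phi[idx]))
}

#' Serialise a component model to JSON
#'
#' @param model an [fit_fpca()] model.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fpca_json <- function(model, path) {
  stopifnot(inherits(model, "fpc_model"))
  obj <- list(grid = model$grid, mean_fn = model$mean_fn,
              eigenfunctions = model$eigenfunctions[, seq_len(model$K),
                                                    drop = FALSE],
              eigenvalues = model$eigenvalues,
              K = model$K, variance_threshold = model$variance_threshold,
              score_sd = model$score_sd, n = model$n)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
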