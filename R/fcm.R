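# Four-class tissue partition of the breast by fuzzy C-means on pixel
# intensities, hardening to region labels and nearest-neighbour rescaling
# of label maps to the analysis grid.

#' Fuzzy C-means clustering of intensities
#'
#' Alternating optimisation of the fuzzy C-means objective
#' `sum_p sum_k u_pk^m d_pk^2` on 1-D intensities: memberships
#' `u_pk = 1 / sum_q (d_pk/d_pq)^(2/(m-1))`, centroids
#' `v_k = sum_p u_pk^m x_p / sum_p u_pk^m`, until the largest centroid
#' shift drops below `tol` or `max_iter` is reached.  A point coinciding
#' with a centroid receives membership 1 for that class.  Initialisation is
#' deterministic by default: `"range"` spaces the starting centroids evenly
#' over the observed intensity range, which places one centroid near each
#' intensity stratum even when class sizes are very unbalanced (intensity
#' percentiles, in contrast, can start two centroids inside one dominant
#' stratum and converge to a merged local optimum); `"quantile"` uses the
#' 12.5/37.5/62.5/87.5 percentiles; `"random"` draws `c` distinct data
#' points under `seed`.
#'
#' @param x numeric vector of intensities.
#' @param c number of clusters (default 4).
#' @param m fuzzifier (> 1; default 2).
#' @param tol convergence tolerance on the centroid shift.
#' @param max_iter iteration cap.
#' @param init `"range"`, `"quantile"` or `"random"`.
#' @param seed RNG seed for random initialisation.
#' @return object of class `fcm_result`: `centroids` (ascending),
#'   `memberships` (n x c, rows sum to 1, columns ordered like the
#'   centroids), `objective` (per-iteration trace), `n_iterations`,
#'   `converged`, `fuzzifier_m`.
#' @export
fuzzy_cmeans <- function(x, c = 4L, m = 2, tol = 1e-6, max_iter = 300L,
                         init = c("range", "quantile", "random"), seed = 1L) {
  init <- match.arg(init)
  x <- as.numeric(x)
  if (m <= 1) stop("fuzzifier m must be > 1", call. = FALSE)
  ux <- unique(x)
  if (length(ux) < c)
    stop("degenerate-input: fewer than c distinct values", call. = FALSE)
  v <- if (init == "range") {
    rng <- range(x)
    rng[1] + (seq_len(c) - 0.5) / c * (rng[2] - rng[1])
  } else if (init == "quantile") {
    as.numeric(quantile(x, probs = (seq_len(c) - 0.5) / c, names = FALSE))
  } else {
    with_seed(seed, sort(sample(ux, c)))
  }
  # quantile init can collide on very discrete data; nudge apart
  if (any(diff(sort(v)) == 0)) v <- sort(v) + (seq_len(c) - 1) * 1e-9

  n <- length(x)
  expo <- 2 / (m - 1)
  obj <- numeric(0)
  converged <- FALSE
  u <- matrix(0, n, c)
  for (it in seq_len(max_iter)) {
    d2 <- outer(x, v, function(a, b) (a - b)^2)
    zero <- d2 < 1e-300
    any_zero <- rowSums(zero) > 0
    # u_pk = 1 / sum_q (d_pk/d_pq)^(2/(m-1))
    dpow <- d2^(expo / 2)       # d^(2/(m-1)) since d2 = d^2
    inv <- 1 / dpow
    u <- inv / rowSums(inv)
    if (any(any_zero)) {
      u[any_zero, ] <- 0
      u[cbind(which(any_zero), max.col(-d2[any_zero, , drop = FALSE]))] <- 1
    }
    um <- u^m
    obj <- c(obj, sum(um * d2))
    v_new <- colSums(um * x) / colSums(um)
    shift <- max(abs(v_new - v))
    v <- v_new
    if (shift < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("fuzzy_cmeans did not converge in ", max_iter, " iterations")
  ord <- order(v)
  structure(list(centroids = v[ord],
                 memberships = u[, ord, drop = FALSE],
                 objective = obj,
                 n_iterations = length(obj),
                 converged = converged,
                 fuzzifier_m = m),
            class = "fcm_result")
}

#' @export
print.fcm_result <- function(x, ...) {
  cat(sprintf("<fcm_result> c=%d, m=%g, %d iter%s; centroids: %s\n",
              length(x$centroids), x$fuzzifier_m, x$n_iterations,
              if (x$converged) "" else " (not converged)",
              paste(signif(x$centroids, 4), collapse = ", ")))
  invisible(x)
}

#' Harden fuzzy memberships into a four-class label map
#'
#' Each breast pixel receives the class of its largest membership degree
#' (ties towards the lower class); classes are indexed 1..4 by ascending
#' centroid intensity, so label-wise mean intensities are non-decreasing.
#' An empty hardened class is permitted (e.g. an extremely fatty breast)
#' and flagged via the `empty_classes` attribute.
#'
#' @param fcm an [fuzzy_cmeans()] result computed on `image$pixels[mask]`.
#' @param mask a [breast_mask()].
#' @return a [region_label_map()] (0 outside the mask).
#' @export
harden_labels <- function(fcm, mask) {
  stopifnot(inherits(fcm, "fcm_result"), inherits(mask, "breast_mask"))
  u <- fcm$memberships
  if (nrow(u) != sum(mask$mask))
    stop("memberships do not match the mask pixel count", call. = FALSE)
  # max.col with ties.method first = lowest class wins ties
  hard <- max.col(u, ties.method = "first")
  labels <- matrix(0L, nrow(mask$mask), ncol(mask$mask))
  labels[mask$mask] <- hard
  out <- region_label_map(labels, mask$pixel_spacing_mm)
  empty <- setdiff(seq_len(ncol(u)), unique(hard))
  if (length(empty)) attr(out, "empty_classes") <- empty
  out
}

#' Rescale a label map to a coarser grid
#'
#' Nearest-neighbour resampling to `target_spacing_mm` per pixel (the
#' forces-histogram analysis grid).  Only downscaling (target >= source) is
#' permitted; the label set is preserved.
#'
#' @param map a [region_label_map()].
#' @param target_spacing_mm target pixel spacing (default 0.25 mm).
#' @return a resampled [region_label_map()].
#' @export
rescale_labelmap <- function(map, target_spacing_mm = 0.25) {
  stopifnot(inherits(map, "region_label_map"))
  src <- map$pixel_spacing_mm
  if (target_spacing_mm < src - 1e-12)
    stop("invalid-target: upsampling (target < source spacing) not supported",
         call. = FALSE)
  if (abs(target_spacing_mm - src) < 1e-12) return(map)
  f <- target_spacing_mm / src
  nr <- max(1L, floor(nrow(map$labels) / f))
  nc <- max(1L, floor(ncol(map$labels) / f))
  # sample the source pixel under each target pixel centre
  ri <- pmin(nrow(map$labels), pmax(1L, round((seq_len(nr) - 0.5) * f + 0.5)))
  ci <- pmin(ncol(map$labels), pmax(1L, round((seq_len(nc) - 0.5) * f + 0.5)))
  region_label_map(map$labels[ri, ci, drop = FALSE], target_spacing_mm)
}

#' Partition a masked breast image into four tissue classes
#'
#' Convenience wrapper: fuzzy C-means on the masked pixel intensities,
#' hardening, and optional rescale to the analysis grid.
#'
#' @param image a (preprocessed) [mammogram_image()].
#' @param mask a [breast_mask()].
#' @param target_spacing_mm analysis grid spacing, or `NULL` to skip
#'   rescaling.
#' @param ... passed to [fuzzy_cmeans()].
#' @return a [region_label_map()].
#' @export
segment_tissue <- function(image, mask, target_spacing_mm = 0.25, ...) {
  fcm <- fuzzy_cmeans(image$pixels[mask$mask], c = 4L, ...)
  map <- harden_labels(fcm, mask)
  if (!is.null(target_spacing_mm))
    map <- rescale_labelmap(map, target_spacing_mm)
  map
}
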