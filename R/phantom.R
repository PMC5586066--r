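#' Specification of a synthetic MLO phantom
#'
#' Describes an idealised mediolateral-oblique mammogram: the breast is a
#' half-ellipse flush with the left image edge (the chest wall), a right
#' triangle in the top-left corner stands in for the pectoral muscle, and
#' the breast interior is tiled by four tissue classes (fatty, semi-fatty,
#' semi-dense, dense) with controllable dense-blob locations and a weight
#' that concentrates fatty tissue in the lower quadrants.
#'
#' Angles are measured counter-clockwise from the chest-wall-to-nipple axis
#' (0 deg points at the nipple, 90 deg up, 270 deg down); blob positions are
#' polar `(radius_fraction, angle_deg)` within the half-ellipse.
#'
#' @param canvas_size integer `(rows, cols)` of the image.
#' @param pixel_spacing_mm physical pixel size, mm.
#' @param breast_axes semi-axis lengths `(vertical, horizontal)` of the
#'   breast half-ellipse, pixels.
#' @param pectoral_fraction fraction of image height covered by the pectoral
#'   triangle, in `[0, 0.5]`.
#' @param tissue_levels 4 strictly increasing mean intensities in `[0, 1]`
#'   for classes 1..4.
#' @param dense_blob_centers list of `c(radius_fraction, angle_deg)` dense
#'   blob positions inside the breast.
#' @param dense_blob_sigma Gaussian spread of the dense blobs, pixels.
#' @param lower_quadrant_fat_weight log-odds tilt of the fatty (vs
#'   semi-fatty) class towards the lower quadrants; 0 = no tilt, negative
#'   values push fat upward.
#' @param noise_sd additive Gaussian intensity noise, sd on the `[0,1]`
#'   scale.
#' @param pectoral_level mean intensity of the pectoral triangle.
#' @param skin_taper radial fraction over which intensity falls off at the
#'   skin line (0 disables).
#' @param seed integer RNG seed.
#' @return an object of class `phantom_spec` (a validated list).
#' @export
phantom_spec <- function(canvas_size = c(128L, 128L),
                         pixel_spacing_mm = 0.25,
                         breast_axes = c(0.42, 0.78) *
                           canvas_size[c(1L, 2L)],
                         pectoral_fraction = 0.30,
                         tissue_levels = c(0.25, 0.45, 0.65, 0.85),
                         dense_blob_centers = list(c(0.45, 30)),
                         dense_blob_sigma = 0.09 * min(canvas_size),
                         lower_quadrant_fat_weight = 0,
                         noise_sd = 0.02,
                         pectoral_level = 0.95,
                         skin_taper = 0.03,
                         seed = 1L) {
  spec <- list(canvas_size = as.integer(canvas_size),
               pixel_spacing_mm = pixel_spacing_mm,
               breast_axes = as.numeric(breast_axes),
               pectoral_fraction = pectoral_fraction,
               tissue_levels = as.numeric(tissue_levels),
               dense_blob_centers = dense_blob_centers,
               dense_blob_sigma = dense_blob_sigma,
               lower_quadrant_fat_weight = lower_quadrant_fat_weight,
               noise_sd = noise_sd,
               pectoral_level = pectoral_level,
               skin_taper = skin_taper,
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  stopifnot(length(spec$canvas_size) == 2L, all(spec$canvas_size >= 8L))
  if (spec$pixel_spacing_mm <= 0)
    stop("invalid-spec: pixel_spacing_mm must be > 0", call. = FALSE)
  if (length(spec$tissue_levels) != 4L ||
      any(diff(spec$tissue_levels) <= 0) ||
      any(spec$tissue_levels < 0 | spec$tissue_levels > 1))
    stop("invalid-spec: tissue_levels must be 4 strictly increasing values in [0,1]",
         call. = FALSE)
  if (spec$pectoral_fraction < 0 || spec$pectoral_fraction > 0.5)
    stop("invalid-spec: pectoral_fraction must be in [0, 0.5]", call. = FALSE)
  if (spec$noise_sd < 0 || spec$dense_blob_sigma <= 0)
    stop("invalid-spec: noise_sd >= 0 and dense_blob_sigma > 0 required",
         call. = FALSE)
  nr <- spec$canvas_size[1]; nc <- spec$canvas_size[2]
  a_r <- spec$breast_axes[1]; a_c <- spec$breast_axes[2]
  r0 <- (nr + 1) / 2
  if (a_r <= 0 || a_c <= 0 || r0 - a_r < 0.5 || r0 + a_r > nr + 0.5 ||
      1 + a_c > nc + 0.5)
    stop("invalid-spec: breast ellipse does not fit inside the canvas",
         call. = FALSE)
  for (b in spec$dense_blob_centers) {
    if (length(b) != 2L || b[1] < 0 || b[1] > 1)
      stop("invalid-spec: blob radius fraction must be in [0,1]", call. = FALSE)
    if (cos(b[2] * pi / 180) < -1e-9)
      stop("invalid-spec: blob centre outside the half-ellipse (angle must have cos >= 0)",
           call. = FALSE)
  }
  invisible(spec)
}

# run expr with a locally seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic MLO mammogram with ground truth
#'
#' Renders the phantom described by a [phantom_spec()]: background at
#' intensity ~0, a bright pectoral triangle, and a breast half-ellipse whose
#' pixels are drawn from four Gaussian intensity classes centred at
#' `tissue_levels`.  Dense/semi-dense tissue forms Gaussian blobs at
#' `dense_blob_centers`; the remaining pixels split between fatty and
#' semi-fatty with the fatty probability tilted towards the skin line and,
#' via `lower_quadrant_fat_weight`, towards the lower quadrants.
#' Deterministic given `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `mammo_phantom`: list with `image`
#'   ([mammogram_image()]), `labels` ([region_label_map()]; 0 outside the
#'   breast and on the pectoral), logical matrices `breast_mask` and
#'   `pectoral_mask`, `pd_truth` (percentage of breast pixels in classes
#'   3-4) and the `spec`.
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  nr <- spec$canvas_size[1]; nc <- spec$canvas_size[2]
  a_r <- spec$breast_axes[1]; a_c <- spec$breast_axes[2]
  r0 <- (nr + 1) / 2; c0 <- 1

  r <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  u <- (cc - c0) / a_c            # 0..1 towards the nipple
  v <- (r - r0) / a_r             # signed, positive = lower quadrants
  rho <- sqrt(u^2 + v^2)
  breast_ell <- rho <= 1 & u >= 0

  # pectoral right triangle in the top-left corner
  h <- spec$pectoral_fraction * nr
  pect <- matrix(FALSE, nr, nc)
  if (h >= 1) {
    w <- 0.75 * h
    pect <- (r <= h) & (cc - 1 <= w * (1 - (r - 1) / h))
  }
  breast <- breast_ell & !pect

  labels <- matrix(0L, nr, nc)
  img <- matrix(0, nr, nc)

  with_seed(spec$seed, {
    idx <- which(breast)
    if (length(idx)) {
      # dense blobs: class 4 within ~1 sigma, class 3 within ~2 sigma
      s4 <- numeric(length(idx))
      for (b in spec$dense_blob_centers) {
        phi <- b[2] * pi / 180
        br <- r0 - b[1] * a_r * sin(phi)
        bc <- c0 + b[1] * a_c * cos(phi)
        d2 <- (r[idx] - br)^2 + (cc[idx] - bc)^2
        s4 <- s4 + exp(-d2 / (2 * spec$dense_blob_sigma^2))
      }
      cls <- integer(length(idx))
      cls[s4 >= exp(-2)]   <- 3L
      cls[s4 >= exp(-0.5)] <- 4L
      rest <- cls == 0L
      # fatty vs semi-fatty: tilt towards skin line and lower quadrants
      lower <- pmax(-1, pmin(1, v[idx]))
      p_fat <- plogis(spec$lower_quadrant_fat_weight * lower +
                      3 * (rho[idx] - 0.6))
      cls[rest] <- ifelse(runif(sum(rest)) < p_fat[rest], 1L, 2L)
      labels[idx] <- cls

      intens <- spec$tissue_levels[cls]
      if (spec$skin_taper > 0) {
        edge <- pmax(0, (rho[idx] - (1 - spec$skin_taper)) / spec$skin_taper)
        intens <- intens * (1 - 0.5 * edge)
      }
      img[idx] <- intens
    }
    img[pect] <- spec$pectoral_level
    if (spec$noise_sd > 0)
      img <- img + matrix(rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
  })
  img <- pmin(pmax(img, 0), 1)

  structure(list(
    image = mammogram_image(img, spec$pixel_spacing_mm, "digitised"),
    labels = region_label_map(labels, spec$pixel_spacing_mm),
    breast_mask = breast,
    pectoral_mask = pect,
    pd_truth = if (sum(breast) > 0)
      100 * sum(labels >= 3L) / sum(breast) else NA_real_,
    spec = spec), class = "mammo_phantom")
}

#' @export
print.mammo_phantom <- function(x, ...) {
  cat(sprintf("<mammo_phantom> %d x %d px, breast %d px, PD %.1f%%\n",
              nrow(x$image$pixels), ncol(x$image$pixels),
              sum(x$breast_mask), x$pd_truth))
  invisible(x)
}
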