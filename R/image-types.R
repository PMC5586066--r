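#' Mammogram image container
#'
#' A grayscale pixel grid with a physical pixel spacing.  Intensities are
#' stored in `[0, 1]`; integer input (e.g. 8/12/16-bit grey levels) is
#' rescaled by its maximum representable value, other numeric input by its
#' observed range when it exceeds `[0, 1]`.
#'
#' @param pixels numeric matrix (rows x cols) of intensities.
#' @param pixel_spacing_mm physical size of one pixel in mm (> 0).
#' @param source_kind `"digitised"` (film digitiser; noisy, gets adaptive
#'   denoising) or `"digital-raw"` (full-field digital; denoising skipped).
#' @return an object of class `mammogram_image`: a list with elements
#'   `pixels`, `pixel_spacing_mm`, `source_kind`.
#' @export
mammogram_image <- function(pixels, pixel_spacing_mm,
                            source_kind = c("digitised", "digital-raw")) {
  source_kind <- match.arg(source_kind)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(pixels)))
    stop("invalid-image: non-finite pixel values", call. = FALSE)
  if (!is.numeric(pixel_spacing_mm) || length(pixel_spacing_mm) != 1L ||
      !is.finite(pixel_spacing_mm) || pixel_spacing_mm <= 0)
    stop("`pixel_spacing_mm` must be a single positive number", call. = FALSE)
  rng <- range(pixels)
  if (rng[1] < 0 || rng[2] > 1) {
    # rescale into [0,1]; constant images map to 0
    den <- rng[2] - rng[1]
    pixels <- if (den > 0) (pixels - rng[1]) / den else pixels * 0
  }
  structure(list(pixels = pixels,
                 pixel_spacing_mm = pixel_spacing_mm,
                 source_kind = source_kind),
            class = "mammogram_image")
}

#' @export
print.mammogram_image <- function(x, ...) {
  cat(sprintf("<mammogram_image> %d x %d px, %.3g mm/px, %s\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_spacing_mm,
              x$source_kind))
  invisible(x)
}

#' @export
dim.mammogram_image <- function(x) dim(x$pixels)

#' Breast mask
#'
#' Binary mask aligned to a [mammogram_image()], guaranteed (by the
#' segmentation functions) to be a single connected component.
#'
#' @param mask logical matrix, `TRUE` inside the breast.
#' @param pixel_spacing_mm pixel spacing in mm.
#' @return object of class `breast_mask` with elements `mask`,
#'   `breast_area_px`, `breast_area_mm2`, `pixel_spacing_mm`.
#' @export
breast_mask <- function(mask, pixel_spacing_mm) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop("`mask` must be a logical matrix", call. = FALSE)
  area <- sum(mask)
  structure(list(mask = mask,
                 breast_area_px = area,
                 breast_area_mm2 = area * pixel_spacing_mm^2,
                 pixel_spacing_mm = pixel_spacing_mm),
            class = "breast_mask")
}

#' @export
print.breast_mask <- function(x, ...) {
  cat(sprintf("<breast_mask> %d px (%.1f mm^2) of %d x %d\n",
              x$breast_area_px, x$breast_area_mm2,
              nrow(x$mask), ncol(x$mask)))
  invisible(x)
}

#' Region label map
#'
#' Per-pixel hard tissue labels: 0 outside the breast, then 1 fatty,
#' 2 semi-fatty, 3 semi-dense, 4 dense, ordered by ascending mean intensity.
#'
#' @param labels integer matrix with values in 0..4.
#' @param pixel_spacing_mm pixel spacing in mm.
#' @return object of class `region_label_map`.
#' @export
region_label_map <- function(labels, pixel_spacing_mm) {
  if (!is.matrix(labels))
    stop("`labels` must be a matrix", call. = FALSE)
  storage.mode(labels) <- "integer"
  if (any(is.na(labels)) || any(labels < 0L) || any(labels > 4L))
    stop("labels must be integers in 0..4", call. = FALSE)
  structure(list(labels = labels, pixel_spacing_mm = pixel_spacing_mm),
            class = "region_label_map")
}

#' @export
print.region_label_map <- function(x, ...) {
  tb <- tabulate(x$labels + 1L, nbins = 5L)
  cat(sprintf(
    "<region_label_map> %d x %d px, %.3g mm/px; bg=%d f=%d sf=%d sd=%d d=%d\n",
    nrow(x$labels), ncol(x$labels), x$pixel_spacing_mm,
    tb[1], tb[2], tb[3], tb[4], tb[5]))
  invisible(x)
}

# Fig.-3-style palette for the four classes (dark blue, light blue, yellow,
# red); background black.
.label_palette <- function() {
  rbind(c(0, 0, 0),
        c(0.05, 0.05, 0.55),
        c(0.45, 0.75, 0.95),
        c(0.95, 0.85, 0.10),
        c(0.85, 0.10, 0.10))
}

#' Read a grayscale mammogram from PNG or TIFF
#'
#' @param path file path; format chosen by extension (`.png`, `.tif`,
#'   `.tiff`).
#' @param pixel_spacing_mm pixel spacing in mm (images do not carry it).
#' @param source_kind see [mammogram_image()].
#' @return a [mammogram_image()].
#' @export
read_mammogram <- function(path, pixel_spacing_mm,
                           source_kind = c("digitised", "digital-raw")) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, call. = FALSE))
  if (length(dim(px)) == 3L) px <- px[, , 1L]  # first channel of RGB(A)
  mammogram_image(px, pixel_spacing_mm, match.arg(source_kind))
}

#' Write a mammogram, mask or label map as PNG/TIFF
#'
#' Images are written 16-bit; masks as 0/255 8-bit PNG; label maps as RGB
#' PNG using the standard four-class palette.
#'
#' @param x a `mammogram_image`, `breast_mask` or `region_label_map`.
#' @param path output path (`.png` or `.tif`/`.tiff` for images).
#' @return `path`, invisibly.
#' @export
write_image <- function(x, path) {
  ext <- tolower(tools::file_ext(path))
  if (inherits(x, "mammogram_image")) {
    if (ext == "png") png::writePNG(x$pixels, path)
    else if (ext %in% c("tif", "tiff"))
      tiff::writeTIFF(x$pixels, path, bits.per.sample = 16L)
    else stop("unsupported image format: .", ext, call. = FALSE)
  } else if (inherits(x, "breast_mask")) {
    png::writePNG(ifelse(x$mask, 1, 0), path)
  } else if (inherits(x, "region_label_map")) {
    pal <- .label_palette()
    idx <- x$labels + 1L
    arr <- array(0, c(nrow(x$labels), ncol(x$labels), 3L))
    for (ch in 1:3) arr[, , ch] <- matrix(pal[idx, ch], nrow(x$labels))
    png::writePNG(arr, path)
  } else stop("don't know how to write a ", class(x)[1], call. = FALSE)
  invisible(path)
}
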