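# Breast segmentation and enhancement: adaptive (Wiener-type) denoising,
# logarithmic contrast enhancement, three-class Otsu thresholding, largest
# connected component + morphological smoothing, and a simplified
# straight-line pectoral-muscle removal.

# local box sums via integral images; returns list(sum, sum2, n) over a
# k x k window centred at each pixel (windows clipped at borders)
.box_stats <- function(x, k) {
  h <- (k - 1L) %/% 2L
  nr <- nrow(x); nc <- ncol(x)
  pad_cum <- function(m) {
    cs <- apply(m, 2L, cumsum)
    t(apply(cs, 1L, cumsum))
  }
  sum_rect <- function(cum) {
    # window [r-h, r+h] x [c-h, c+h], clipped
    r2 <- pmin(seq_len(nr) + h, nr); r1 <- pmax(seq_len(nr) - h, 1L)
    c2 <- pmin(seq_len(nc) + h, nc); c1 <- pmax(seq_len(nc) - h, 1L)
    cum_p <- rbind(0, cbind(0, cum))  # 1-padded integral image
    cum_p[r2 + 1L, c2 + 1L] - cum_p[r1, c2 + 1L] -
      cum_p[r2 + 1L, c1] + cum_p[r1, c1]
  }
  ones <- matrix(1, nr, nc)
  list(sum = sum_rect(pad_cum(x)),
       sum2 = sum_rect(pad_cum(x * x)),
       n = sum_rect(pad_cum(ones)))
}

#' Adaptive minimum mean-square-error (Wiener-type) denoising
#'
#' Pixelwise adaptive linear MMSE smoothing: within a `window x window`
#' neighbourhood the local mean `m` and variance `v` are estimated, the
#' noise variance is taken as the mean of the local variances, and the
#' output is `m + max(v - noise, 0)/v * (x - m)` (plain `m` where the local
#' variance does not exceed the noise estimate).  Images of kind
#' `digital-raw` pass through unchanged (their signal-to-noise ratio does
#' not warrant smoothing); `window = 1` is the identity.
#'
#' @param image a [mammogram_image()].
#' @param window odd window size in pixels (>= 1).
#' @return a denoised [mammogram_image()] with intensities in `[0, 1]`.
#' @export
rescale_and_denoise <- function(image, window = 5L) {
  stopifnot(inherits(image, "mammogram_image"))
  if (any(!is.finite(image$pixels)))
    stop("invalid-image: non-finite pixel values", call. = FALSE)
  if (window %% 2L != 1L || window < 1L)
    stop("`window` must be an odd integer >= 1", call. = FALSE)
  if (image$source_kind == "digital-raw" || window == 1L) return(image)
  x <- image$pixels
  bs <- .box_stats(x, window)
  m <- bs$sum / bs$n
  v <- pmax(bs$sum2 / bs$n - m^2, 0)
  noise <- mean(v)
  out <- ifelse(v > noise, m + (v - noise) / v * (x - m), m)
  out <- pmin(pmax(out, 0), 1)
  mammogram_image(out, image$pixel_spacing_mm, image$source_kind)
}

#' Logarithmic contrast enhancement
#'
#' Strictly increasing map `log(1 + c*x)/log(1 + c)` on `[0, 1]`, brightening
#' low-intensity pixels near the skin line ahead of thresholding.
#'
#' @param image a [mammogram_image()] (intensities in `[0, 1]`).
#' @param c gain constant (> 0); default 9 so that mid-greys roughly double.
#' @return enhanced [mammogram_image()].
#' @export
enhance_contrast <- function(image, c = 9) {
  stopifnot(inherits(image, "mammogram_image"), c > 0)
  out <- log1p(c * image$pixels) / log1p(c)
  mammogram_image(out, image$pixel_spacing_mm, image$source_kind)
}

#' Otsu multi-threshold by exhaustive search
#'
#' Finds the `n_classes - 1` thresholds of a 256-bin intensity histogram
#' that maximise the between-class variance, by exhaustive search over all
#' threshold tuples.  Ties are broken towards the lexicographically
#' smallest tuple.  Thresholds are 0-based bin indices; class `k` holds the
#' bins in `(t_{k-1}, t_k]`.
#'
#' @param histogram numeric vector of 256 non-negative bin counts.
#' @param n_classes 2 or 3.
#' @return integer vector of `n_classes - 1` thresholds (ascending).
#' @export
otsu_multithreshold <- function(histogram, n_classes = 3L) {
  if (length(histogram) != 256L || any(histogram < 0) ||
      sum(histogram) <= 0)
    stop("histogram must be 256 non-negative counts with positive total",
         call. = FALSE)
  if (!n_classes %in% c(2L, 3L))
    stop("n_classes must be 2 or 3", call. = FALSE)
  if (sum(histogram > 0) < n_classes)
    stop("degenerate-histogram: fewer occupied bins than classes",
         call. = FALSE)
  p <- histogram / sum(histogram)
  lev <- 0:255
  W <- cumsum(p)              # W[i] = weight of bins 0..i-1? (1-based: 0..i-1 -> use index)
  M <- cumsum(p * lev)
  # class stats for bin range [a, b] (0-based, inclusive), via 1-based cums
  cw <- function(a, b) W[b + 1L] - if (a > 0) W[a] else 0
  cm <- function(a, b) M[b + 1L] - if (a > 0) M[a] else 0
  if (n_classes == 2L) {
    best <- -Inf; bt <- NA_integer_
    for (t1 in 0:254) {
      w1 <- cw(0L, t1); w2 <- cw(t1 + 1L, 255L)
      if (w1 <= 0 || w2 <= 0) next
      s <- cm(0L, t1)^2 / w1 + cm(t1 + 1L, 255L)^2 / w2
      if (s > best + 1e-15) { best <- s; bt <- t1 }
    }
    return(bt)
  }
  best <- -Inf; bt <- c(NA_integer_, NA_integer_)
  for (t1 in 0:253) {
    a1 <- cw(0L, t1)
    if (a1 <= 0) next
    s1 <- cm(0L, t1)^2 / a1
    t2 <- (t1 + 1L):254L
    a2 <- W[t2 + 1L] - W[t1 + 1L]
    a3 <- 1 - W[t2 + 1L]
    mu2 <- M[t2 + 1L] - M[t1 + 1L]
    mu3 <- M[256L] - M[t2 + 1L]
    s <- s1 + ifelse(a2 > 0, mu2^2 / a2, -Inf) +
      ifelse(a3 > 0, mu3^2 / a3, -Inf)
    smax <- max(s)
    # strict improvement + ascending scan order = lexicographically
    # smallest (t1, t2) among ties
    if (is.finite(smax) && smax > best + 1e-15) {
      best <- smax
      bt <- c(t1, t2[which(s >= smax - 1e-15)[1L]])
    }
  }
  if (any(is.na(bt)))
    stop("degenerate-histogram: no valid 3-class split", call. = FALSE)
  bt
}

# 256-bin histogram of [0,1] intensities (0-based bins)
.intensity_hist <- function(x) {
  bins <- pmin(255L, as.integer(floor(x * 256)))
  tabulate(bins + 1L, nbins = 256L)
}

.largest_component <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  if (max(lab) == 0) return(NULL)
  counts <- tabulate(lab[lab > 0])
  lab == which.max(counts)
}

#' Segment the breast region
#'
#' Thresholds the (enhanced) image into three Otsu classes, keeps the two
#' brightest (breast plus any tags/artefacts), extracts the largest
#' 8-connected component and smooths it by morphological closing then
#' opening with a disc.  The result is guaranteed to be one connected
#' component.
#'
#' @param image a contrast-enhanced [mammogram_image()].
#' @param disk_radius structuring-element radius in pixels; default 1% of
#'   the image width (at least 1).
#' @return a [breast_mask()].
#' @export
segment_breast <- function(image, disk_radius = NULL) {
  stopifnot(inherits(image, "mammogram_image"))
  x <- image$pixels
  if (is.null(disk_radius))
    disk_radius <- max(1L, round(0.01 * ncol(x)))
  h <- .intensity_hist(x)
  th <- otsu_multithreshold(h, 3L)
  fg <- x >= (th[1] + 1) / 256   # the two brightest classes
  if (!any(fg)) stop("no-breast-found: empty foreground", call. = FALSE)
  comp <- .largest_component(fg)
  if (is.null(comp)) stop("no-breast-found: empty foreground", call. = FALSE)
  brush <- EBImage::makeBrush(2L * as.integer(disk_radius) + 1L, "disc")
  sm <- EBImage::opening(EBImage::closing(comp * 1, brush), brush) > 0
  comp2 <- .largest_component(sm)
  if (is.null(comp2)) comp2 <- comp   # opening erased everything: keep raw
  breast_mask(comp2, image$pixel_spacing_mm)
}

#' Remove the pectoral muscle from a breast mask (simplified)
#'
#' A simplified straight-line, gradient-guided substitute for full
#' texture-gradient pectoral segmentation: the bright corner component of
#' the mask (auto-detected left/right) is located by two-class Otsu
#' thresholding within the chest-wall corner, its oblique edge is fitted by
#' least squares, and all mask pixels on the muscle side of the fitted line
#' are removed.  If no plausible pectoral candidate is found the mask is
#' returned unchanged with a warning.  The output area never exceeds the
#' input area and remains a single connected component.
#'
#' @param image the [mammogram_image()] the mask was derived from.
#' @param mask a [breast_mask()].
#' @param corner `"auto"`, `"left"` or `"right"`.
#' @return a [breast_mask()] without the pectoral region.
#' @export
remove_pectoral <- function(image, mask, corner = c("auto", "left", "right")) {
  stopifnot(inherits(image, "mammogram_image"), inherits(mask, "breast_mask"))
  corner <- match.arg(corner)
  x <- image$pixels; m <- mask$mask
  nr <- nrow(x); nc <- ncol(x)
  if (corner == "auto") {
    top <- seq_len(max(1L, nr %/% 2L))
    left_cols <- seq_len(max(1L, nc %/% 2L))
    right_cols <- setdiff(seq_len(nc), left_cols)
    ml <- m[top, left_cols]; mr <- m[top, right_cols]
    il <- if (any(ml)) mean(x[top, left_cols][ml]) else -Inf
    ir <- if (any(mr)) mean(x[top, right_cols][mr]) else -Inf
    corner <- if (ir > il) "right" else "left"
  }
  flip <- corner == "right"
  if (flip) { x <- x[, nc:1]; m <- m[, nc:1] }

  corner_rows <- seq_len(round(0.6 * nr))
  corner_cols <- seq_len(round(0.6 * nc))
  sub_mask <- matrix(FALSE, nr, nc)
  sub_mask[corner_rows, corner_cols] <- m[corner_rows, corner_cols]
  res <- NULL
  if (sum(sub_mask) > 16L) {
    vals <- x[sub_mask]
    h <- .intensity_hist(vals)
    t1 <- tryCatch(otsu_multithreshold(h, 2L), error = function(e) NA)
    if (!is.na(t1)) {
      bright <- sub_mask & x >= (t1 + 1) / 256
      lab <- EBImage::bwlabel(bright * 1)
      if (max(lab) > 0) {
        # candidate must touch the chest wall (col 1) or top edge (row 1)
        touching <- unique(c(lab[, 1L], lab[1L, ]))
        touching <- touching[touching > 0]
        if (length(touching)) {
          counts <- tabulate(lab[lab > 0], nbins = max(lab))
          cand_id <- touching[which.max(counts[touching])]
          cand <- lab == cand_id
          if (sum(cand) >= 0.01 * sum(m)) {
            # oblique edge: outermost candidate column per row
            rows <- which(apply(cand, 1L, any))
            edge_c <- vapply(rows, function(r) max(which(cand[r, ])),
                             integer(1))
            if (length(rows) >= 3L && length(unique(edge_c)) > 1L) {
              fit <- lm(edge_c ~ rows)
              pred <- coef(fit)[1] + coef(fit)[2] * seq_len(nr)
              cut <- matrix(rep(pred, nc), nr, nc) >=
                matrix(rep(seq_len(nc), each = nr), nr, nc)
              res <- m & !cut
            } else {
              res <- m & !cand
            }
          }
        }
      }
    }
  }
  if (is.null(res) || !any(res)) {
    warning("no pectoral candidate found; mask returned unchanged")
    return(mask)
  }
  comp <- .largest_component(res)
  if (flip) comp <- comp[, nc:1]
  breast_mask(comp, mask$pixel_spacing_mm)
}

#' Full preprocessing chain
#'
#' Fixed order: rescale/denoise, logarithmic enhancement, three-class Otsu
#' thresholding with largest-component extraction and morphological
#' smoothing, then pectoral removal.
#'
#' @param image a [mammogram_image()].
#' @param window Wiener window (see [rescale_and_denoise()]).
#' @param log_c contrast gain (see [enhance_contrast()]).
#' @param disk_radius morphology radius (see [segment_breast()]).
#' @param pectoral remove the pectoral muscle?
#' @return list with `image` (the enhanced image), `denoised` (the
#'   pre-enhancement image, on whose intensities tissue clustering is run)
#'   and `mask` (a [breast_mask()]).
#' @export
preprocess_mammogram <- function(image, window = 5L, log_c = 9,
                                 disk_radius = NULL, pectoral = TRUE) {
  den <- rescale_and_denoise(image, window)
  enh <- enhance_contrast(den, log_c)
  mask <- segment_breast(enh, disk_radius)
  if (pectoral)
    mask <- suppressWarnings(remove_pectoral(enh, mask))
  list(image = enh, denoised = den, mask = mask)
}
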