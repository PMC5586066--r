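# Forces histograms: directional spatial-relation descriptors between
# pairs of tissue regions.  For each sweep direction theta, parallel
# digital lines cover the image; on every line the force between two
# regions is the sum of inverted squared distances over ordered pixel
# pairs, and the per-line weights are summed into one histogram bin.
#
# Shared conventions (R oracle and C++ sweep): 0-based pixel coordinates,
# x = col, y = -row, theta counter-clockwise from +x; pixel position along
# a line is its projection t = c*cos(theta) - r*sin(theta); "ahead" means
# larger t; round(x) = floor(x + 0.5) for the digital-line intercepts.

.iround <- function(x) floor(x + 0.5)

#' Digital sweep lines covering a pixel grid
#'
#' Returns the family of parallel digital lines with direction `theta_deg`
#' that partitions the grid: every pixel belongs to exactly one line, and
#' pixels on a line are ordered by increasing projection onto the direction
#' vector.  For `|tan theta| <= 1` lines are indexed by row-intercept with
#' nearest-pixel sampling along columns, otherwise the roles of rows and
#' columns are swapped.
#'
#' @param grid_shape integer `(rows, cols)`.
#' @param theta_deg sweep direction in `[0, 360)` degrees.
#' @return list of matrices with columns `row`, `col` (0-based) and `t`
#'   (projection), rows ordered by increasing `t`.
#' @export
sweep_lines <- function(grid_shape, theta_deg) {
  nr <- as.integer(grid_shape[1]); nc <- as.integer(grid_shape[2])
  stopifnot(nr >= 1, nc >= 1, theta_deg >= 0, theta_deg < 360)
  theta <- theta_deg * pi / 180
  ct <- cos(theta); st <- sin(theta)
  drow <- -st; dcol <- ct
  by_col <- abs(dcol) >= abs(drow)
  npar <- if (by_col) nc else nr
  nsec <- if (by_col) nr else nc
  s <- if (by_col) drow / dcol else dcol / drow
  par_seq <- if (if (by_col) dcol > 0 else drow > 0) seq_len(npar) - 1L
             else rev(seq_len(npar) - 1L)
  ro <- .iround(s * par_seq)
  # enumerate pixels in scan order (parameter axis in direction of travel,
  # secondary axis within); within a line this order is increasing t
  P <- rep(par_seq, each = nsec)
  S <- rep.int(0:(nsec - 1L), npar)
  b <- S - rep(ro, each = nsec)
  r <- if (by_col) S else P
  cc <- if (by_col) P else S
  t <- cc * ct - r * st
  idx <- split(seq_along(b), b)   # split preserves within-group order
  lapply(idx, function(ii)
    cbind(row = r[ii], col = cc[ii], t = t[ii]))
}

#' Force between two pixel sets on one line
#'
#' `sum 1/(p - q)^2` over ordered pairs with the A-position `p` strictly
#' ahead of the B-position `q` along the sweep direction; pairs with `p`
#' behind or level with `q` belong to the opposite direction's line and
#' contribute nothing here.
#'
#' @param pos_a,pos_b positions (projections) of region-A and region-B
#'   pixels on a common line, in pixel units.
#' @return the summed weight (>= 0).
#' @export
line_force <- function(pos_a, pos_b) {
  if (!length(pos_a) || !length(pos_b)) return(0)
  d <- outer(pos_a, pos_b, "-")
  if (any(d == 0))
    stop("invalid-labelmap: coincident pixels in both regions", call. = FALSE)
  sum(1 / d[d > 0]^2)
}

.fh_angles <- function(a) (seq_len(a) - 1L) * (360 / a)

.new_fh <- function(values, pair, a, spacing, empty = FALSE) {
  structure(list(pair = pair, n_angles = a, angles = .fh_angles(a),
                 values = values, pixel_spacing_mm = spacing,
                 empty_region = empty),
            class = "forces_histogram")
}

#' @export
print.forces_histogram <- function(x, ...) {
  cat(sprintf("<forces_histogram> FH_%d%d, %d angles, max %.4g%s\n",
              x$pair[1], x$pair[2], x$n_angles, max(x$values),
              if (x$empty_region) " (empty region: all-zero)" else ""))
  invisible(x)
}

.check_pair <- function(map, i, j) {
  stopifnot(inherits(map, "region_label_map"))
  if (i == j) stop("invalid-pair: i and j must differ", call. = FALSE)
  if (!all(c(i, j) %in% 1:4)) stop("regions must be in 1..4", call. = FALSE)
}

#' Forces histogram between two tissue regions
#'
#' Computes the 360-degree forces histogram between regions `i` and `j` of
#' a label map over `a` evenly spaced sweep directions (default 180, a
#' 2-degree step), using the compiled line sweep.  Bin `theta` accumulates
#' `1/d^2` over pixel pairs on common digital lines with the region-`i`
#' pixel ahead of the region-`j` pixel along `theta`; distances are in
#' pixel units of the map's grid.  An empty region yields an all-zero
#' histogram flagged via `empty_region`.
#'
#' @param map a [region_label_map()] (typically rescaled to 0.25 mm/pixel).
#' @param i,j distinct region indices in 1..4.
#' @param a number of angles.
#' @return a `forces_histogram`.
#' @export
compute_fh <- function(map, i, j, a = 180L) {
  .check_pair(map, i, j)
  H <- .fh_all_pairs_cpp(map$labels, as.integer(a))
  empty <- !any(map$labels == i) || !any(map$labels == j)
  .new_fh(H[(i - 1L) * 4L + j, ], c(i, j), a, map$pixel_spacing_mm, empty)
}

#' Reference (brute-force) forces histogram
#'
#' Same definition as [compute_fh()], evaluated by explicit enumeration of
#' every digital line and every pixel pair in pure R.  Intended for testing
#' on small maps (<= 64 x 64 recommended); the compiled sweep must agree
#' bin-wise to within 1e-12.
#'
#' @inheritParams compute_fh
#' @return a `forces_histogram`.
#' @export
fh_oracle <- function(map, i, j, a = 180L) {
  .check_pair(map, i, j)
  vals <- numeric(a)
  angles <- .fh_angles(a)
  empty <- !any(map$labels == i) || !any(map$labels == j)
  if (!empty) {
    for (k in seq_len(a)) {
      lines <- sweep_lines(dim(map$labels), angles[k])
      tot <- 0
      for (ln in lines) {
        labs <- map$labels[cbind(ln[, "row"] + 1L, ln[, "col"] + 1L)]
        tot <- tot + line_force(ln[labs == i, "t"], ln[labs == j, "t"])
      }
      vals[k] <- tot
    }
  }
  .new_fh(vals, c(i, j), a, map$pixel_spacing_mm, empty)
}

#' The six forces histograms of a four-class map
#'
#' One histogram per unordered region pair, stored with the ordered
#' convention `i < j` (the `j`-ahead-of-`i` direction is the same histogram
#' shifted by 180 degrees).
#'
#' @param map a four-class [region_label_map()].
#' @param a number of angles (default 180).
#' @param normalise divide each histogram by its sum (default `FALSE`;
#'   breast size is normally handled downstream as a covariate, not by
#'   normalisation).
#' @return object of class `fh_set`: list of six `forces_histogram`s named
#'   `fh12`, `fh13`, `fh14`, `fh23`, `fh24`, `fh34`.
#' @export
compute_fh_set <- function(map, a = 180L, normalise = FALSE) {
  stopifnot(inherits(map, "region_label_map"))
  H <- .fh_all_pairs_cpp(map$labels, as.integer(a))
  pairs <- list(c(1L, 2L), c(1L, 3L), c(1L, 4L),
                c(2L, 3L), c(2L, 4L), c(3L, 4L))
  out <- lapply(pairs, function(pr) {
    i <- pr[1]; j <- pr[2]
    v <- H[(i - 1L) * 4L + j, ]
    empty <- !any(map$labels == i) || !any(map$labels == j)
    if (normalise && sum(v) > 0) v <- v / sum(v)
    .new_fh(v, pr, a, map$pixel_spacing_mm, empty)
  })
  names(out) <- vapply(pairs, function(pr) sprintf("fh%d%d", pr[1], pr[2]), "")
  structure(out, class = "fh_set")
}

#' @export
print.fh_set <- function(x, ...) {
  cat(sprintf("<fh_set> 6 histograms, %d angles each\n", x[[1]]$n_angles))
  invisible(x)
}

#' Flatten forces-histogram sets into a per-image matrix
#'
#' One row per image, `6 * a` columns named `fh{i}{j}_deg{theta}`.
#'
#' @param fh_sets list of [compute_fh_set()] results.
#' @return numeric matrix.
#' @export
fh_set_matrix <- function(fh_sets) {
  stopifnot(length(fh_sets) >= 1)
  one <- function(fs)
    unlist(lapply(fs, function(h) h$values), use.names = FALSE)
  m <- t(vapply(fh_sets, one, numeric(6L * fh_sets[[1]][[1]]$n_angles)))
  cn <- unlist(lapply(fh_sets[[1]], function(h)
    sprintf("fh%d%d_deg%g", h$pair[1], h$pair[2], h$angles)))
  colnames(m) <- cn
  m
}

#' Write forces-histogram sets to CSV
#'
#' @param fh_sets list of `fh_set` objects.
#' @param path output CSV path.
#' @param ids optional row identifiers.
#' @return `path`, invisibly.
#' @export
write_fh_csv <- function(fh_sets, path, ids = NULL) {
  m <- fh_set_matrix(fh_sets)
  df <- data.frame(id = if (is.null(ids)) seq_len(nrow(m)) else ids, m,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
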