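# forces histograms: sweep lines, line forces, compiled sweep vs oracle,
# symmetry / translation / scaling properties

test_that("sweep lines partition the grid at every angle", {
  for (theta in c(0, 2, 30, 45, 90, 117, 180, 222, 270, 315)) {
    lines <- sweep_lines(c(7, 9), theta)
    pix <- do.call(rbind, lines)
    expect_equal(nrow(pix), 7 * 9)
    expect_false(any(duplicated(pix[, c("row", "col")])))
    # pixels ordered by increasing projection within each line
    for (ln in lines)
      if (nrow(ln) > 1) expect_true(all(diff(ln[, "t"]) > 0))
  }
  # theta = 0: one horizontal line per row
  l0 <- sweep_lines(c(4, 4), 0)
  expect_length(l0, 4)
  expect_true(all(vapply(l0, nrow, 1L) == 4))
  # theta = 45 on n x n: 2n - 1 diagonals
  expect_length(sweep_lines(c(6, 6), 45), 11)
})

test_that("line forces follow the inverse-square closed forms", {
  expect_equal(line_force(3, 0), 1 / 9)
  expect_equal(line_force(numeric(0), numeric(0)), 0)
  # A behind B: zero forward, four reverse pairs
  expect_equal(line_force(c(0, 1), c(4, 6)), 0)
  expect_equal(line_force(c(4, 6), c(0, 1)),
               1 / 16 + 1 / 36 + 1 / 9 + 1 / 25)
  expect_error(line_force(c(0, 2), c(2, 5)), "invalid-labelmap")
})

test_that("compiled sweep equals the brute-force oracle on random maps", {
  for (s in 1:20) {
    map <- random_label_map(32L, seed = s)
    a <- 36L
    for (pr in list(c(1, 2), c(2, 4))) {
      fast <- compute_fh(map, pr[1], pr[2], a)
      slow <- fh_oracle(map, pr[1], pr[2], a)
      expect_lt(max(abs(fast$values - slow$values)), 1e-12)
    }
  }
})

test_that("single-pixel pairs give the exact closed form", {
  map <- two_pixel_map(9, 5, 2, 2L, 5, 6, 1L)   # region 1 four cols ahead
  fh <- compute_fh(map, 1, 2, 180)
  expect_equal(fh$values[1], 1 / 16)             # bin at 0 degrees
  # support confined to within a few degrees of 0; reverse direction empty
  nz <- which(fh$values > 0) - 1L
  deg <- nz * 2
  expect_true(all(pmin(deg, 360 - deg) <= 8))
  fh_rev <- compute_fh(map, 2, 1, 180)
  expect_equal(fh_rev$values[91], 1 / 16)        # 180 degrees
  expect_equal(sum(fh$values > 0), sum(fh_rev$values > 0))
  # oracle agrees bin-wise
  expect_equal(fh$values, fh_oracle(map, 1, 2, 180)$values,
               tolerance = 1e-14)
})

test_that("directional symmetry FH_ij(theta) = FH_ji(theta + 180) holds", {
  for (s in c(1, 7)) {
    map <- random_label_map(24L, seed = s)
    a <- 60L
    f12 <- compute_fh(map, 1, 2, a)
    f21 <- compute_fh(map, 2, 1, a)
    shifted <- f21$values[(seq_len(a) - 1 + a / 2) %% a + 1]
    expect_lt(max(abs(f12$values - shifted)), 1e-12)
  }
})

test_that("translation leaves the histogram unchanged where digitisation allows", {
  set.seed(33)
  base <- matrix(0L, 40, 40)
  base[10:14, 8:12] <- 1L
  base[20:25, 18:22] <- 2L
  map <- region_label_map(base, 0.25)
  shifted <- matrix(0L, 40, 40)
  shifted[13:17, 12:16] <- 1L                    # translate by (3, 4)
  shifted[23:28, 22:26] <- 2L
  map2 <- region_label_map(shifted, 0.25)
  # exact at axis and diagonal angles (digitisation is translation-covariant)
  f1 <- compute_fh(map, 1, 2, 8)
  f2 <- compute_fh(map2, 1, 2, 8)
  expect_lt(max(abs(f1$values - f2$values)), 1e-12)
  # close on the full grid: general angles re-digitise the lines after a
  # shift, so invariance is only approximate there
  g1 <- compute_fh(map, 1, 2, 180)$values
  g2 <- compute_fh(map2, 1, 2, 180)$values
  expect_lt(max(abs(g1 - g2)) / max(g1), 0.15)
  expect_lt(sum(abs(g1 - g2)) / sum(g1), 0.1)
})

test_that("doubling distances divides single-line forces by four", {
  m1 <- two_pixel_map(20, 10, 3, 1L, 10, 7, 2L)   # distance 4 along a row
  m2 <- two_pixel_map(20, 10, 3, 1L, 10, 11, 2L)  # distance 8
  f1 <- compute_fh(m1, 1, 2, 4)
  f2 <- compute_fh(m2, 1, 2, 4)
  k <- which(f1$values > 0)
  expect_equal(f2$values[k], f1$values[k] / 4)
})

test_that("coarse and fine angle grids agree at shared angles", {
  map <- random_label_map(20L, seed = 4)
  f4 <- compute_fh(map, 1, 3, 4L)
  f180 <- compute_fh(map, 1, 3, 180L)
  shared <- match(f4$angles, f180$angles)
  expect_lt(max(abs(f4$values - f180$values[shared])), 1e-12)
})

test_that("histogram sets have six members with consistent conventions", {
  map <- random_label_map(24L, seed = 2)
  fs <- compute_fh_set(map, a = 36L)
  expect_length(fs, 6)
  expect_named(fs, c("fh12", "fh13", "fh14", "fh23", "fh24", "fh34"))
  expect_true(all(vapply(fs, function(h) all(h$values >= 0) &&
                           all(is.finite(h$values)), logical(1))))
  # set members equal the pairwise computations
  expect_equal(fs$fh24$values, compute_fh(map, 2, 4, 36L)$values)

  # relabelling classes 1 <-> 2 turns FH_12 into the reversed direction
  relab <- map$labels
  relab[map$labels == 1L] <- 99L
  relab[map$labels == 2L] <- 1L
  relab[relab == 99L] <- 2L
  map_sw <- region_label_map(relab, 0.25)
  f12_sw <- compute_fh(map_sw, 1, 2, 36L)
  f21 <- compute_fh(map, 2, 1, 36L)
  expect_equal(f12_sw$values, f21$values)

  # empty region: all-zero histogram, flagged
  empty_map <- region_label_map(matrix(c(1L, 2L, 0L, 3L), 2), 0.25)
  fh_e <- compute_fh(empty_map, 1, 4, 12L)
  expect_true(all(fh_e$values == 0))
  expect_true(fh_e$empty_region)
  # invalid pair
  expect_error(compute_fh(empty_map, 2, 2, 12L), "invalid-pair")
})

test_that("blob pairs with limited angular support have empty far bins", {
  # region 2 sits up-and-right of region 1 at ~18 degrees, as in the
  # classic two-object illustration: support near 18, empty elsewhere
  lab <- matrix(0L, 48, 48)
  lab[30:36, 6:12] <- 1L
  lab[24:28, 28:38] <- 2L
  map <- region_label_map(lab, 0.25)
  fh <- compute_fh(map, 2, 1, 180)   # direction from 1 towards 2
  deg <- fh$angles[fh$values > 0]
  expect_true(all(deg <= 60 | deg >= 350))
  expect_gt(max(fh$values), 0)
})
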