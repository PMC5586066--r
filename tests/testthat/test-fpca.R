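# functional PCA: recovery, projection, modes of variation, dominant angles

test_that("noise-free single-component curves are recovered exactly", {
  grid <- seq(0, 358, by = 2)
  phi <- fixture_basis(grid)[, 1, drop = FALSE]
  X <- generate_curves(40, grid, mean_fn = 3, phi, 4, noise_sd = 0, seed = 1)
  m <- fit_fpca(X, grid)
  expect_equal(m$K, 1L)
  expect_lt(max(abs(abs(m$eigenfunctions[, 1]) - abs(phi[, 1]))), 1e-8)
  expect_lt(max(abs(m$mean_fn - (3 + colMeans(attr(X, "scores") %*% t(phi))))),
            1e-10)
  # eigenfunctions orthonormal under the grid inner product
  G <- crossprod(m$eigenfunctions[, 1:3])
  expect_lt(max(abs(G - diag(3))), 1e-8)
  # standardised scores: mean 0, variance 1
  expect_lt(max(abs(colMeans(m$scores))), 1e-8)
  expect_lt(max(abs(apply(m$scores, 2, var) - 1)), 1e-8)
})

test_that("eigenvalues estimated within 20% at n = 500", {
  grid <- seq(0, 358, by = 2)
  phi <- fixture_basis(grid)
  X <- generate_curves(500, grid, mean_fn = 0, phi, c(4, 1),
                       noise_sd = 0, seed = 9)
  m <- fit_fpca(X, grid)
  expect_lt(abs(m$eigenvalues[1] - 4) / 4, 0.2)
  expect_lt(abs(m$eigenvalues[2] - 1) / 1, 0.2)
  expect_true(all(diff(m$eigenvalues) <= 1e-12))
})

test_that("fit matches the explicitly assembled covariance eigendecomposition", {
  set.seed(4)
  X <- matrix(rnorm(15 * 24), 15, 24)
  m <- fit_fpca(X, seq_len(24))
  ev <- eigen(cov(X), symmetric = TRUE)$values
  expect_lt(max(abs(m$eigenvalues - pmax(ev, 0))), 1e-10)
})

test_that("retention rule and degenerate inputs behave", {
  grid <- seq(0, 358, by = 2)
  phi <- fixture_basis(grid)
  X <- generate_curves(50, grid, 0, phi, c(4, 1), noise_sd = 0, seed = 2)
  # threshold 1.0 retains all nonzero eigenvalues
  m_all <- fit_fpca(X, grid, variance_threshold = 1.0)
  expect_equal(m_all$K, sum(m_all$eigenvalues > sum(m_all$eigenvalues) * 1e-12))
  expect_error(fit_fpca(X[1, , drop = FALSE], grid), "insufficient-data")
  Xc <- matrix(5, 10, length(grid))
  expect_error(fit_fpca(Xc, grid), "degenerate-data")
})

test_that("curves differing by additive constants load on a constant component", {
  grid <- seq(0, 358, by = 2)
  set.seed(6)
  X <- matrix(1, 30, length(grid)) * rnorm(30) + 2
  m <- fit_fpca(X, grid)
  phi1 <- m$eigenfunctions[, 1]
  expect_lt(max(abs(phi1 - mean(phi1))), 1e-8)
})

test_that("projection reproduces training scores and obeys the model grid", {
  grid <- seq(0, 358, by = 2)
  phi <- fixture_basis(grid)
  X <- generate_curves(60, grid, mean_fn = 1, phi, c(4, 1),
                       noise_sd = 0.05, seed = 3)
  m <- fit_fpca(X, grid)
  expect_equal(project(m, X, grid), m$scores, tolerance = 1e-10)
  # the mean curve projects to zero
  expect_lt(max(abs(project(m, m$mean_fn, standardise = FALSE))), 1e-10)
  # mu + sqrt(lambda_1) phi_1 -> raw score (sqrt(lambda_1), 0, ...)
  v <- m$mean_fn + sqrt(m$eigenvalues[1]) * m$eigenfunctions[, 1]
  raw <- project(m, v, standardise = FALSE)
  expect_equal(as.numeric(raw[1, 1]), sqrt(m$eigenvalues[1]),
               tolerance = 1e-8)
  if (m$K > 1) expect_lt(max(abs(raw[1, -1])), 1e-8)
  expect_error(project(m, X[, 1:10]), "incompatible-grid")
  expect_error(project(m, X, grid = grid + 1), "incompatible-grid")
})

test_that("reconstruction residuals respect the variance threshold", {
  grid <- seq(0, 358, by = 2)
  phi <- fixture_basis(grid)
  X <- generate_curves(200, grid, 2, phi, c(4, 1), noise_sd = 0.3, seed = 8)
  m <- fit_fpca(X, grid, variance_threshold = 0.85)
  Xc <- sweep(X, 2, m$mean_fn)
  recon <- m$raw_scores %*% t(m$eigenfunctions[, seq_len(m$K), drop = FALSE])
  resid_var <- sum((Xc - recon)^2) / (nrow(X) - 1)
  expect_lte(resid_var, (1 - 0.85) * sum(m$eigenvalues) + 1e-8)
})

test_that("modes of variation follow mu + alpha sqrt(lambda) phi", {
  grid <- seq(0, 358, by = 2)
  phi <- fixture_basis(grid)
  X <- generate_curves(50, grid, 1, phi, c(4, 1), noise_sd = 0, seed = 5)
  m <- fit_fpca(X, grid)
  mv <- mode_of_variation(m, 1, alpha = c(-1, 0, 1, 2))
  expect_equal(mv$curves[2, ], m$mean_fn)
  # +/- 1 curves are reflections about the mean
  expect_equal(mv$curves[3, ] - m$mean_fn, m$mean_fn - mv$curves[1, ],
               tolerance = 1e-12)
  expect_equal(mv$curves[4, ],
               m$mean_fn + 2 * sqrt(m$eigenvalues[1]) * m$eigenfunctions[, 1],
               tolerance = 1e-12)
  expect_error(mode_of_variation(m, m$K + 1L), "out-of-range")
})

test_that("dominant angles find the eigenfunction extrema", {
  grid <- seq(0, 358, by = 2)
  # build an eigenfunction with bumps at 54, 152 and 268 degrees
  bump <- function(c0, w = 14) exp(-((grid - c0)^2) / (2 * w^2))
  phi_raw <- bump(54) + 0.8 * bump(152) + 0.9 * bump(268)
  phi <- phi_raw / sqrt(sum(phi_raw^2))
  X <- generate_curves(80, grid, 5, matrix(phi), 2, noise_sd = 0, seed = 11)
  m <- fit_fpca(X, grid)
  da <- dominant_angles(m, 1, top_m = 3)
  expect_setequal(da$angle, c(54, 152, 268))
  expect_true(all(da$angle %in% grid))

  # pure cosine: single dominant angle at its peak
  phi_cos <- cos((grid - 100) * pi / 180)
  phi_cos <- phi_cos / sqrt(sum(phi_cos^2))
  Xc <- generate_curves(40, grid, 0, matrix(phi_cos), 1, noise_sd = 0,
                        seed = 12)
  mc <- fit_fpca(Xc, grid)
  dc <- dominant_angles(mc, 1, top_m = 1)
  d_to_peak <- min(abs(dc$angle - 100), abs(dc$angle - 280))
  expect_lte(d_to_peak, 2)
})
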