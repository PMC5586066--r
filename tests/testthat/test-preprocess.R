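# denoising, enhancement, Otsu thresholding, breast and pectoral masks

test_that("adaptive denoising reduces noise and respects its edge cases", {
  set.seed(11)
  clean <- matrix(rep(seq(0.2, 0.8, length.out = 64), each = 64), 64, 64)
  noisy <- pmin(pmax(clean + matrix(rnorm(64^2, 0, 0.05), 64), 0), 1)
  img <- mammogram_image(noisy, 0.1)
  den <- rescale_and_denoise(img, 5L)
  mse <- function(a, b) mean((a - b)^2)
  expect_lt(mse(den$pixels, clean), mse(noisy, clean))
  expect_true(all(den$pixels >= 0 & den$pixels <= 1))

  # constant image unchanged; window 1 is the identity
  const <- mammogram_image(matrix(0.4, 16, 16), 0.1)
  expect_equal(rescale_and_denoise(const, 5L)$pixels, const$pixels)
  expect_identical(rescale_and_denoise(img, 1L)$pixels, img$pixels)

  # digital-raw images pass through
  raw <- mammogram_image(noisy, 0.1, "digital-raw")
  expect_identical(rescale_and_denoise(raw, 5L)$pixels, noisy)

  expect_error(mammogram_image(matrix(c(NA, 1, 0, 1), 2), 0.1),
               "non-finite")
})

test_that("logarithmic enhancement is a monotone [0,1] map", {
  x <- matrix(seq(0, 1, length.out = 64), 8, 8)
  img <- mammogram_image(x, 0.1)
  enh <- enhance_contrast(img, c = 9)
  expect_equal(enh$pixels[1], 0)
  expect_equal(enh$pixels[64], 1)
  expect_true(all(diff(as.vector(enh$pixels)) > 0))
  # closed form at c = 9
  expect_equal(enhance_contrast(mammogram_image(matrix(0.1, 1, 1), 1),
                                c = 9)$pixels[1],
               log(1.9) / log(10), tolerance = 1e-12)
})

test_that("Otsu multi-threshold matches brute force and handles edge cases", {
  # three disjoint uniform blocks
  h <- numeric(256)
  h[11:21] <- 50; h[101:111] <- 40; h[201:211] <- 30  # bins 10-20,100-110,200-210
  th <- otsu_multithreshold(h, 3L)
  # class k holds bins (t_{k-1}, t_k], so t1 may sit on a block boundary
  expect_gte(th[1], 20); expect_lt(th[1], 100)
  expect_gte(th[2], 110); expect_lt(th[2], 200)
  expect_identical(th, otsu3_bruteforce(h))

  # scale invariance
  expect_identical(otsu_multithreshold(h * 10, 3L), th)

  # two occupied bins cannot support three classes
  h2 <- numeric(256); h2[51] <- 5; h2[201] <- 7
  expect_error(otsu_multithreshold(h2, 3L), "degenerate-histogram")

  # random histograms: exhaustive-search oracle agreement
  for (s in 1:100) {
    set.seed(s)
    hr <- numeric(256)
    occ <- sample(256, sample(5:40, 1))
    hr[occ] <- rpois(length(occ), 20) + 1
    expect_identical(otsu_multithreshold(hr, 3L), otsu3_bruteforce(hr))
  }
})

test_that("breast segmentation keeps the breast and drops bright tags", {
  sp <- phantom_spec(noise_sd = 0.01, pectoral_fraction = 0, seed = 5)
  ph <- generate_phantom(sp)
  # add a small bright label tag far from the breast
  px <- ph$image$pixels
  px[5:10, 120:125] <- 0.98
  img <- mammogram_image(px, sp$pixel_spacing_mm)
  enh <- enhance_contrast(rescale_and_denoise(img))
  mask <- segment_breast(enh)
  expect_false(any(mask$mask[5:10, 120:125]))          # tag excluded
  truth <- sum(ph$breast_mask)
  expect_lt(abs(mask$breast_area_px - truth) / truth, 0.05)
  expect_equal(mask$breast_area_mm2,
               mask$breast_area_px * sp$pixel_spacing_mm^2)

  # idempotency: re-running on the masked image reproduces the mask
  masked <- enh$pixels * mask$mask
  mask2 <- segment_breast(mammogram_image(masked, sp$pixel_spacing_mm))
  agree <- sum(mask2$mask & mask$mask) / sum(mask2$mask | mask$mask)
  expect_gt(agree, 0.99)

  # all-zero image: nothing to find
  expect_error(segment_breast(mammogram_image(matrix(0, 32, 32), 0.25)))
})

test_that("pectoral removal strips the triangle and never grows the mask", {
  sp <- phantom_spec(pectoral_level = 0.95, noise_sd = 0.01, seed = 9)
  ph <- generate_phantom(sp)
  enh <- enhance_contrast(rescale_and_denoise(ph$image))
  mask <- segment_breast(enh)
  out <- remove_pectoral(enh, mask)
  pect_in_mask <- ph$pectoral_mask & mask$mask
  removed <- pect_in_mask & !out$mask
  expect_gte(sum(removed) / max(sum(pect_in_mask), 1), 0.90)
  breast_removed <- ph$breast_mask & mask$mask & !out$mask
  expect_lte(sum(breast_removed) / sum(ph$breast_mask & mask$mask), 0.05)
  expect_lte(out$breast_area_px, mask$breast_area_px)

  # no pectoral present: mask unchanged (with a warning)
  sp0 <- phantom_spec(pectoral_fraction = 0, noise_sd = 0.01, seed = 9)
  ph0 <- generate_phantom(sp0)
  enh0 <- enhance_contrast(rescale_and_denoise(ph0$image))
  mask0 <- segment_breast(enh0)
  out0 <- suppressWarnings(remove_pectoral(enh0, mask0))
  expect_lte(out0$breast_area_px, mask0$breast_area_px)
  expect_gt(sum(out0$mask & mask0$mask) / sum(mask0$mask), 0.95)
})
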