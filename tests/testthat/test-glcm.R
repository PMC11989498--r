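test_that("quantization bins uniformly, clips, and is monotone", {
  # identity at native 8-bit resolution
  img <- matrix(128, 3, 3)
  expect_equal(unclass(quantize_gray(img))[1, 1], 128L, ignore_attr = TRUE)
  # extremes map to extreme bins
  expect_equal(as.vector(quantize_gray(matrix(c(0, 255), 1), levels = 2)),
               c(0L, 1L))
  # uniform binning floor(v * levels / (input_max + 1))
  expect_equal(as.vector(quantize_gray(matrix(c(0, 100, 200), 1), levels = 8)),
               c(0L, 3L, 6L))
  # clipping of out-of-range input
  expect_equal(as.vector(quantize_gray(matrix(c(-5, 300), 1), levels = 4)),
               c(0L, 3L))
  # monotone for random values
  v <- sort(runif(50, 0, 255))
  q <- as.vector(quantize_gray(matrix(v, 1), levels = 13))
  expect_true(all(diff(q) >= 0))
  expect_error(quantize_gray(matrix(numeric(0), 0, 0)), "empty")
  expect_error(quantize_gray(matrix(1, 2, 2), levels = 1), "levels")
})

test_that("offset constructor follows the image-axis angle convention", {
  expect_identical(offset_from_angle(1, 0), c(0L, 1L))
  expect_identical(offset_from_angle(1, 45), c(-1L, 1L))
  expect_identical(offset_from_angle(1, 90), c(-1L, 0L))
  expect_identical(offset_from_angle(2, 135), c(-2L, -2L))
  expect_error(offset_from_angle(1, 30), "angle")
  expect_error(offset_from_angle(0, 0), "distance")
})

test_that("co-occurrence counting matches hand-enumerated pairs", {
  img <- matrix(c(0L, 1L, 1L, 0L), 2, byrow = TRUE)
  p <- glcm(img, offset = c(0, 1), levels = 2)
  expect_equal(p["0", "1"], 0.5)
  expect_equal(p["1", "0"], 0.5)
  expect_equal(sum(p), 1)
  expect_equal(attr(p, "counts_total"), 2L)

  # vertical offset on [[0,0],[1,1]]: both pairs are (0, 1)
  img2 <- matrix(c(0L, 0L, 1L, 1L), 2, byrow = TRUE)
  p2 <- glcm(img2, offset = c(1, 0), levels = 2)
  expect_equal(p2["0", "1"], 1)

  # constant image: all mass in one cell
  p3 <- glcm(matrix(3L, 4, 4), offset = c(0, 1), levels = 5)
  expect_equal(p3["3", "3"], 1)
  expect_equal(sum(p3 > 0), 1L)

  expect_error(glcm(matrix(0L, 2, 2), offset = c(0, 0)), "offset")
  expect_error(glcm(matrix(0L, 2, 2), offset = c(0, 5), levels = 2),
               "too small")
})

test_that("marginal index statistics match direct summation", {
  img <- matrix(c(0L, 1L, 1L, 0L), 2, byrow = TRUE)
  m <- glcm_marginal_stats(glcm(img, c(0, 1), levels = 2))
  expect_equal(m$mu_i, 0.5); expect_equal(m$mu_j, 0.5)
  expect_equal(m$sigma_i, 0.5); expect_equal(m$sigma_j, 0.5)

  # point mass p(k, k) = 1
  mp <- glcm_marginal_stats(glcm(matrix(2L, 3, 3), c(0, 1), levels = 4))
  expect_equal(mp$mu_i, 2); expect_equal(mp$sigma_i, 0)

  # perfectly diagonal two-level mass
  img3 <- matrix(c(0L, 0L, 1L, 1L), 2, byrow = TRUE)
  m3 <- glcm_marginal_stats(glcm(img3, c(0, 1), levels = 2))
  expect_equal(m3$mu_i, 0.5); expect_equal(m3$sigma_j, 0.5)
})

test_that("descriptor fixtures: analytic values on tiny matrices", {
  two <- function(img, off = c(0, 1)) glcm(img, off, levels = 2)
  anti <- two(matrix(c(0L, 1L, 1L, 0L), 2, byrow = TRUE))  # p(0,1)=p(1,0)=.5
  expect_equal(glcm_contrast(anti), 1)
  expect_equal(glcm_correlation(anti), -1)
  expect_equal(glcm_energy(anti), 0.5)
  expect_equal(glcm_homogeneity(anti), 0.5)

  diag2 <- glcm(matrix(c(0L, 0L, 1L, 1L), 2, byrow = TRUE), c(0, 1), levels = 2)
  expect_equal(glcm_correlation(diag2), 1)  # p(0,0)=p(1,1)=.5
  expect_equal(glcm_contrast(diag2), 0)
  expect_equal(glcm_homogeneity(diag2), 1)

  point <- glcm(matrix(5L, 3, 3), c(0, 1), levels = 8)
  expect_equal(glcm_contrast(point), 0)
  expect_true(is.na(glcm_correlation(point)))
  expect_equal(glcm_energy(point), 1)
  expect_equal(glcm_homogeneity(point), 1)

  # off-diagonal two-step: p(0,2) = 1
  wide <- glcm(matrix(c(0L, 2L), 1, 2), c(0, 1), levels = 3)
  expect_equal(glcm_contrast(wide), 4)
  expect_equal(glcm_homogeneity(wide), 1 / 3)

  # uniform mass over m cells -> energy 1/m
  img_u <- matrix(c(0L, 1L, 2L, 3L), 1)
  pu <- glcm(img_u, c(0, 1), levels = 4)
  expect_equal(glcm_energy(pu), 1 / 3)
})

test_that("matrix-path descriptors equal the pixel-pair double-loop oracle", {
  set.seed(42)
  for (rep in 1:60) {
    L <- sample(2:9, 1)
    img <- random_image(sample(4:12, 1), sample(4:12, 1), L)
    off <- all_offsets[[sample(length(all_offsets), 1)]]
    sym <- sample(c(TRUE, FALSE), 1)
    p <- glcm(img, off, levels = L, symmetric = sym)
    o <- brute_features(img, off, symmetric = sym)
    expect_equal(glcm_contrast(p), o$contrast, tolerance = 1e-10)
    expect_equal(glcm_energy(p), o$energy, tolerance = 1e-10)
    expect_equal(glcm_homogeneity(p), o$homogeneity, tolerance = 1e-10)
    expect_equal(glcm_correlation(p), o$correlation, tolerance = 1e-10)
    m <- glcm_marginal_stats(p)
    expect_equal(m$mu_i, o$mu_i, tolerance = 1e-10)
    expect_equal(m$sigma_j, o$sigma_j, tolerance = 1e-10)
  }
})

test_that("normalization, ranges and diagonal concentration hold for random images", {
  set.seed(7)
  for (rep in 1:200) {
    L <- sample(2:16, 1)
    img <- random_image(sample(4:16, 1), sample(4:16, 1), L)
    off <- all_offsets[[sample(length(all_offsets), 1)]]
    p <- glcm(img, off, levels = L, symmetric = sample(c(TRUE, FALSE), 1))
    expect_lt(abs(sum(p) - 1), 1e-12)
    expect_true(all(p >= 0))
    ct <- glcm_contrast(p); en <- glcm_energy(p); ho <- glcm_homogeneity(p)
    co <- glcm_correlation(p)
    expect_gte(ct, 0)
    expect_true(en > 0 && en <= 1)
    expect_true(ho > 0 && ho <= 1 + 1e-12)
    if (!is.na(co)) expect_true(co >= -1 - 1e-12 && co <= 1 + 1e-12)
    # contrast = 0 <=> homogeneity = 1 <=> diagonal mass
    diag_mass <- sum(diag(p))
    expect_equal(ct == 0, abs(ho - 1) < 1e-12)
    expect_equal(ct == 0, abs(diag_mass - 1) < 1e-12)
  }
})

test_that("transpose symmetry and symmetric-matrix identity hold", {
  set.seed(11)
  for (rep in 1:25) {
    L <- sample(2:8, 1)
    img <- random_image(sample(5:12, 1), sample(5:12, 1), L)
    off <- all_offsets[[sample(length(all_offsets), 1)]]
    # transposed image at swapped offset gives identical descriptors
    p1 <- glcm(img, off, levels = L)
    p2 <- glcm(t(img), c(off[2], off[1]), levels = L)
    expect_equal(glcm_contrast(p1), glcm_contrast(p2), tolerance = 1e-12)
    expect_equal(glcm_energy(p1), glcm_energy(p2), tolerance = 1e-12)
    # symmetric matrix = normalized sum of asymmetric at d and -d
    ps <- glcm(img, off, levels = L, symmetric = TRUE)
    pa <- glcm(img, off, levels = L)
    pb <- glcm(img, -off, levels = L)
    expect_equal(unclass(ps), (unclass(pa) + unclass(pb)) / 2,
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("per-patch descriptors average across offsets correctly", {
  cst <- glcm_features(matrix(7, 4, 4),
                       offsets = list(c(0, 1), c(-1, 1)))
  expect_equal(cst$contrast, 0)
  expect_equal(cst$energy, 1)
  expect_equal(cst$homogeneity, 1)
  expect_true(is.na(cst$correlation))

  f <- glcm_features(matrix(c(0, 1, 1, 0), 2, byrow = TRUE),
                     levels = 2, input_max = 1)
  expect_equal(f$contrast, 1); expect_equal(f$correlation, -1)
  expect_equal(f$energy, 0.5); expect_equal(f$homogeneity, 0.5)

  # checkerboard with two offsets: mean of per-offset values
  cb <- matrix((row(matrix(0, 5, 6)) + col(matrix(0, 5, 6))) %% 2 * 255, 5, 6)
  offs <- list(c(0L, 1L), c(1L, 0L))
  f2 <- glcm_features(cb, levels = 2, offsets = offs)
  per <- sapply(offs, function(o) {
    p <- glcm(quantize_gray(cb, levels = 2), o, levels = 2)
    c(glcm_contrast(p), glcm_energy(p), glcm_homogeneity(p))
  })
  expect_equal(f2$contrast, mean(per[1, ]))
  expect_equal(f2$energy, mean(per[2, ]))
  expect_equal(f2$homogeneity, mean(per[3, ]))

  expect_error(glcm_features(matrix(0, 2, 2), offsets = list(c(0, 9))),
               "too small")
})
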