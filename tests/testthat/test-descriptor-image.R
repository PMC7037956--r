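# Descriptor image construction, variety degree bookkeeping, bit-depth
# compression, and normalization.

test_that("variety degree is the min of patch capacity, levels, and bins", {
  expect_equal(variety_degree(7, 13), 49L)
  expect_equal(variety_degree(65, 8), 256L)
  expect_equal(variety_degree(1, 8), 1L)
  expect_equal(variety_degree(5, 13, bins = 16), 16L)
  expect_error(variety_degree(0, 8), "l >= 1")
})

test_that("monochrome images give all-zero descriptors for every kind", {
  img <- intensity_image(matrix(12, 10, 10), 6)
  for (kind in core_kinds) {
    d <- compute_descriptor_image(img, patch_spec(l = 3), kind)
    expect_equal(max(abs(d$values)), 0, info = kind)
  }
})

test_that("a tiled ramp whose every patch hits all bins equally attains the
           upper bound", {
  # 3x3 tile of 9 values landing in 9 distinct bins; every interior patch
  # then holds each bin exactly once
  vals <- ceiling(256 * (0:8) / 9)
  tile <- matrix(vals, 3, 3)
  img <- intensity_image(tile[rep(1:3, 5), rep(1:3, 5)], 8)
  for (kind in c("m1", "m2")) {
    d <- compute_descriptor_image(img, patch_spec(l = 3, bins = 9), kind)
    interior <- d$values[3:13, 3:13]
    expect_equal(max(abs(interior - upper_bound(kind, 9))), 0,
                 tolerance = 1e-12, info = kind)
  }
})

test_that("descriptor values stay within [0, upper_bound(kind, r)]", {
  withr::with_seed(31, {
    for (i in 1:5) {
      img <- random_image(12, 12, 6, seed = i)
      for (kind in core_kinds) {
        d <- compute_descriptor_image(img, patch_spec(l = 5), kind)
        expect_gte(min(d$values), 0)
        expect_lte(max(d$values), upper_bound(kind, d$r) + 1e-12)
      }
    }
  })
})

test_that("vectorized descriptors match the naive per-pixel oracle", {
  withr::with_seed(41, {
    for (i in seq_len(10)) {
      img <- random_image(16, 16, 8, seed = 100 + i)
      for (kind in core_kinds) {
        d <- compute_descriptor_image(img, patch_spec(l = 3), kind)
        expect_equal(d$values,
                     naive_descriptor(img, 3, d$spec$bins, kind),
                     tolerance = 1e-12,
                     info = sprintf("kind=%s i=%d", kind, i))
      }
    }
  })
})

test_that("weighted and parzen descriptors also match the oracle", {
  img <- random_image(10, 10, 6, seed = 55)
  sg <- patch_spec(l = 3, weighting = "gaussian")
  dg <- compute_descriptor_image(img, sg, "m2")
  wg <- gaussian_weight_map(3, 3 / 4)$w
  expect_equal(dg$values,
               naive_descriptor(img, 3, dg$spec$bins, "m2", weights = wg),
               tolerance = 1e-12)
  sp <- patch_spec(l = 3, estimator = "parzen", bandwidth = 1)
  dp <- compute_descriptor_image(img, sp, "m1")
  expect_equal(dp$values,
               naive_descriptor(img, 3, dp$spec$bins, "m1", bandwidth = 1),
               tolerance = 1e-12)
})

test_that("the sliding large-bins engine agrees with the dense engine", {
  img <- random_image(24, 24, 10, seed = 77)
  dense <- patchentropy:::.compute_descriptors(img, patch_spec(l = 5,
                                                               bins = 1024),
                                               c("m1", "m2"))
  B <- matrix(patchentropy:::.bin_index(unclass(img), 1024, 10), 24, 24)
  slid <- patchentropy:::.sliding_measures(patchentropy:::.mirror_pad(B, 2),
                                           5, 1024, c("m1", "m2"), 24, 24)
  expect_equal(slid$m1, dense$m1, tolerance = 1e-10)
  expect_equal(slid$m2, dense$m2, tolerance = 1e-10)
})

test_that("descriptor images blur and deduplicate as patch size grows", {
  pair <- standard_pair(3, size = 64)
  lap_mean <- function(v) {
    # mean |4-neighbour laplacian| of the min-max normalized descriptor
    rng <- range(v)
    v <- (v - rng[1]) / (rng[2] - rng[1])
    i <- 2:(nrow(v) - 1)
    j <- 2:(ncol(v) - 1)
    lap <- 4 * v[i, j] - v[i - 1, j] - v[i + 1, j] - v[i, j - 1] -
      v[i, j + 1]
    mean(abs(lap))
  }
  ls <- c(3, 7, 11, 15, 19)
  res <- lapply(ls, function(l) {
    compute_descriptor_image(pair$a, patch_spec(l = l), "m2")$values
  })
  lap <- vapply(res, lap_mean, 0)
  expect_true(all(diff(lap) < 0))  # monotone blur trend over the 5 sizes
  dup <- vapply(res, function(v) length(v) - length(unique(as.vector(v))), 0)
  expect_gt(dup[1], dup[5])  # many duplicate values at l = 3
})

test_that("bit-depth compression divides intensities and shrinks the
           descriptor range", {
  img <- intensity_image(matrix(c(8191, 64, 63, 4096), 2, 2), 13)
  same <- compress_bit_depth(img, 13)
  expect_equal(unclass(same), unclass(img), ignore_attr = TRUE)
  c7 <- compress_bit_depth(img, 7)
  expect_equal(as.vector(unclass(c7)), c(127, 1, 0, 64))
  expect_equal(attr(c7, "bit_depth"), 7L)
  expect_error(compress_bit_depth(c7, 8), "1\\.\\.7")
  # descriptor ranges shrink with depth (r drops => bound drops)
  rimg <- random_image(24, 24, 8, seed = 9)
  rngs <- vapply(c(8, 6, 4, 2), function(nt) {
    d <- compute_descriptor_image(compress_bit_depth(rimg, nt),
                                  patch_spec(l = 5), "m2")
    diff(range(d$values)) + max(d$values)
  }, 0)
  expect_true(all(diff(rngs) < 0))
})

test_that("normalization modes behave per contract", {
  img <- random_image(12, 12, 6, seed = 3)
  d <- compute_descriptor_image(img, patch_spec(l = 3), "m2")
  expect_identical(normalize_descriptor(d, "none"), d)
  g <- normalize_descriptor(d, "global_minmax")
  expect_equal(range(g$values), c(0, 1))
  # constant descriptor maps to all zeros
  dc <- d
  dc$values[] <- 2.5
  expect_equal(max(abs(normalize_descriptor(dc, "global_minmax")$values)), 0)
  # two-value image {0, 4} -> {0, 1}
  d2 <- d
  d2$values <- matrix(c(0, 4, 4, 0), 2, 2)
  expect_equal(sort(unique(as.vector(
    normalize_descriptor(d2, "global_minmax")$values))), c(0, 1))
  z <- normalize_descriptor(d, "local_zscore", window = 5)
  expect_equal(dim(z$values), dim(d$values))
  expect_equal(z$normalized, "local_zscore")
  # a monochrome window yields 0 thanks to the epsilon guard
  zc <- normalize_descriptor(dc, "local_zscore", window = 3)
  expect_equal(max(abs(zc$values)), 0)
  expect_error(normalize_descriptor(d, "local_zscore", window = 4), "odd")
})
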