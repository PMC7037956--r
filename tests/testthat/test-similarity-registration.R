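# Similarity measures, rigid transforms, similarity curves, slice matching,
# and deformation selection.

test_that("MAD similarity is the masked mean absolute difference", {
  a <- matrix(c(0, 2, 1, 3), 2)
  b <- matrix(c(1, 2, 1, 1), 2)
  expect_equal(mad_similarity(a, b), (1 + 0 + 0 + 2) / 4)
  expect_equal(mad_similarity(a, a), 0)
  expect_equal(mad_similarity(a, a + 0.7), 0.7, tolerance = 1e-12)
  expect_equal(mad_similarity(a, b), mad_similarity(b, a))
  expect_equal(mad_similarity(a, b, norm = "l2"), sqrt(5 / 4),
               tolerance = 1e-12)
  expect_equal(mad_similarity(a, b, mask = matrix(c(TRUE, FALSE, FALSE,
                                                    TRUE), 2)), 1.5)
  expect_error(mad_similarity(a, matrix(0, 3, 3)), "shapes")
  expect_error(mad_similarity(a, b, mask = matrix(FALSE, 2, 2)),
               "no pixels")
})

test_that("mutual information is symmetric, self-informative, and invariant
           to bijective remaps", {
  img <- random_image(64, 64, 8, seed = 2)
  h <- -sum(patchentropy:::.xlogx(
    tabulate(patchentropy:::.bin_index(as.vector(unclass(img)), 16, 8),
             16) / length(img)))
  expect_equal(mutual_information(img, img, bins = 16), h,
               tolerance = 1e-12)
  # bijective intensity remap preserves the joint structure
  perm <- withr::with_seed(8, sample(0:255))
  remapped <- intensity_image(matrix(perm[unclass(img) + 1], 64, 64), 8)
  expect_equal(mutual_information(img, remapped, bins = 256),
               mutual_information(img, img, bins = 256), tolerance = 1e-9)
  # independent images: MI near its analytic value 0
  a <- random_image(256, 256, 8, seed = 3)
  b <- random_image(256, 256, 8, seed = 4)
  expect_lt(mutual_information(a, b, bins = 16), 0.02)
  expect_equal(mutual_information(a, b, bins = 16),
               mutual_information(b, a, bins = 16), tolerance = 1e-12)
})

test_that("rigid transform: identity, lattice-exact 90 degrees, and
           translation round trip", {
  img <- random_image(32, 32, 8, seed = 6)
  id <- rigid_transform(img, 0, c(0, 0))
  expect_equal(unclass(id$image), unclass(img), ignore_attr = TRUE)
  expect_true(all(id$mask))
  r90 <- rigid_transform(img, 90)
  # 90 degrees on a square image permutes the lattice losslessly
  expect_equal(sort(as.vector(unclass(r90$image))),
               sort(as.vector(unclass(img))))
  expect_equal(mad_similarity(rigid_transform(r90$image, -90)$image, img),
               0, tolerance = 1e-9)
  # shift by +5 then -5 restores the doubly-valid region
  s1 <- rigid_transform(img, 0, c(5, 0))
  s2 <- rigid_transform(s1$image, 0, c(-5, 0))
  both <- s2$mask & rigid_transform(s1$image, 0, c(-5, 0))$mask
  both[, 1:5] <- FALSE  # pixels fed by the zero-filled band
  expect_equal(mad_similarity(s2$image, img, mask = both), 0,
               tolerance = 1e-6)
  expect_error(rigid_transform(img, 270), "180")
})

test_that("similarity curve of an image with itself bottoms at zero at the
           identity and is non-negative", {
  img <- random_image(32, 32, 8, seed = 10)
  cv <- similarity_curve(img, img, "m2", patch_spec(l = 3),
                         parameters = seq(-6, 6, by = 2))
  expect_true(all(cv$similarity >= 0))
  expect_equal(cv$similarity[cv$parameter == 0], 0, tolerance = 1e-12)
  expect_equal(cv$parameter[which.min(cv$similarity)], 0)
  expect_true(attr(cv, "lower_is_better"))
  tv <- similarity_curve(img, img, "mad_raw", parameters = c(-3, 0, 3),
                         mode = "translate_x")
  expect_equal(tv$similarity[tv$parameter == 0], 0)
  expect_error(similarity_curve(img, img, "m1", parameters = numeric(0)),
               "non-empty")
  expect_error(similarity_curve(img, img, "m1", parameters = c(1, 1, 2)),
               "strictly increasing")
})

test_that("contrast inversion breaks raw MAD but not descriptor MAD", {
  pair <- standard_pair(2, size = 64)
  spec <- patch_spec(l = 5)
  d_mad <- similarity_curves(pair$a, pair$b, c("m2", "mad_raw"), spec,
                             parameters = seq(-10, 10, by = 2))
  # descriptor curve attains its minimum at alignment
  expect_lte(abs(d_mad$m2$parameter[which.min(d_mad$m2$similarity)]), 2)
  # raw MAD of the reversed-contrast pair is far from zero at alignment
  expect_gt(d_mad$mad_raw$similarity[d_mad$mad_raw$parameter == 0],
            0.1 * 8191)
})

test_that("normalized convergence rate reads the min-max-scaled curve at
           the radius endpoints", {
  mk <- function(par, val) {
    structure(data.frame(parameter = par, similarity = val,
                         overlap = 1),
              method = "m2", mode = "rotate", lower_is_better = TRUE,
              class = c("similarity_curve", "data.frame"))
  }
  v <- abs(seq(-10, 10))
  expect_equal(normalized_convergence_rate(mk(seq(-10, 10), v / 10), 10), 1)
  expect_equal(normalized_convergence_rate(mk(seq(-10, 10), v / 10), 5),
               0.5)
  expect_equal(normalized_convergence_rate(mk(seq(-10, 10),
                                              rep(2, 21)), 5), 0)
  expect_error(normalized_convergence_rate(mk(seq(-10, 10), v), 15),
               "not covered")
})

test_that("matching a stack against itself yields 100% zero deflection", {
  st <- standard_stack(4, n_slices = 6, size = 32)
  ds <- match_slices(st$a, st$a, "m2", patch_spec(l = 3))
  expect_equal(ds$ZDN, 6L)
  expect_equal(ds$ZDP, 100)
  expect_equal(ds$failures, 0L)
  expect_equal(ds$SUM + ds$failures, ds$total)
  # worked classification rule: found 2 vs reference 3 is a left deflection
  diff <- 2 - 3
  expect_equal(diff, -1L)
  tb <- as.data.frame(ds)
  expect_equal(tb$SUM_probability, 100)
  expect_error(match_slices(list(), st$a, "m2"), "non-empty")
})

test_that("deformation residual equals the naive double loop and the
           Pythagorean constant-offset case", {
  f0 <- deformation_field(matrix(0, 4, 4), matrix(0, 4, 4))
  expect_equal(deformation_residual(f0, f0), 0)
  f34 <- deformation_field(matrix(3, 4, 4), matrix(4, 4, 4))
  expect_equal(deformation_residual(f34, f0), 5)
  withr::with_seed(15, {
    a <- deformation_field(matrix(rnorm(30), 5, 6), matrix(rnorm(30), 5, 6))
    b <- deformation_field(matrix(rnorm(30), 5, 6), matrix(rnorm(30), 5, 6))
    acc <- 0
    for (i in 1:5) for (j in 1:6) {
      acc <- acc + sqrt((a$dr[i, j] - b$dr[i, j])^2 +
                        (a$dc[i, j] - b$dc[i, j])^2)
    }
    expect_equal(deformation_residual(a, b), acc / 30, tolerance = 1e-12)
  })
  expect_error(deformation_residual(f0, deformation_field(matrix(0, 2, 2),
                                                          matrix(0, 2, 2))),
               "domains")
})

test_that("selecting among warps returns the true deformation on clean
           phantoms and index 1 for a single candidate", {
  lab <- matrix(make_label_volume(5, 1, 48, 48)[1, , ], 48, 48)
  a <- render_modality(lab, c(100, 1500, 3000, 5000, 7000), 0, 0, 13, 5)
  b <- render_modality(lab, rev(c(100, 1500, 3000, 5000, 7000)), 0, 0, 13, 5)
  truth <- random_smooth_deformation(6, 48, 48, amplitude = 0)
  cands <- list(
    list(image = warp_image(b, random_smooth_deformation(7, 48, 48, 4, 24)),
         field = random_smooth_deformation(7, 48, 48, 4, 24)),
    list(image = b, field = truth),
    list(image = warp_image(b, random_smooth_deformation(8, 48, 48, 4, 24)),
         field = random_smooth_deformation(8, 48, 48, 4, 24)))
  sel <- select_best_deformation(a, cands, truth, "m2", patch_spec(l = 5))
  expect_equal(sel$index, 2L)
  expect_equal(sel$tau, 0)
  one <- select_best_deformation(a, cands[1], truth, "m2",
                                 patch_spec(l = 5))
  expect_equal(one$index, 1L)
  expect_error(select_best_deformation(a, list(), truth, "m2"), "non-empty")
})

test_that("warping by the zero field is the identity", {
  img <- random_image(20, 20, 8, seed = 30)
  z <- deformation_field(matrix(0, 20, 20), matrix(0, 20, 20))
  expect_equal(unclass(warp_image(img, z)), unclass(img),
               ignore_attr = TRUE)
})
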