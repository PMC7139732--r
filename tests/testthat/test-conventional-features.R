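test_that("statistical features handle constants and simple patterns", {
  f <- statistical_features(matrix(17, 6, 6))
  expect_equal(f[["conv_mean"]], 17)
  expect_equal(f[["conv_median"]], 17)
  expect_equal(f[["conv_max"]], 17)
  expect_equal(f[["conv_min"]], 17)
  expect_equal(f[["conv_std"]], 0)
  expect_equal(f[["conv_skewness"]], 0)
  expect_equal(f[["conv_kurtosis"]], 0)
  expect_true(all(f[paste0("conv_p", seq(10, 90, 10))] == 17))

  tiled <- matrix(rep(c(0, 0, 0, 255), 16), 8, 8)
  g <- statistical_features(tiled)
  expect_equal(g[["conv_mean"]], 63.75)
  expect_equal(g[["conv_max"]], 255)
  expect_equal(g[["conv_min"]], 0)
})

test_that("statistical features equal a loop-based recomputation exactly", {
  set.seed(11)
  for (rep in 1:10) {
    p <- matrix(sample(0:255, 400, TRUE), 20, 20)
    got <- statistical_features(p)
    expect_equal(unname(got), unname(oracle_statistics(p)), tolerance = 1e-12)
  }
  # percentiles nondecreasing, bounded by min/max
  p <- matrix(sample(0:255, 400, TRUE), 20, 20)
  f <- statistical_features(p)
  qs <- f[paste0("conv_p", seq(10, 90, 10))]
  expect_true(all(diff(qs) >= 0))
  expect_true(all(qs >= f[["conv_min"]] & qs <= f[["conv_max"]]))
})

test_that("segmentation counts components subject to the area threshold", {
  n <- 120
  m1 <- disk_mask(n, 30, 25)
  m2 <- disk_mask(n, 90, 25)
  img <- shape_image(m1 | m2)
  expect_equal(segment_components(img, 2, 500)$n_components, 2)
  expect_equal(segment_components(img, 2, 3000)$n_components, 0)
  # isolated single dark pixels: each 8-connected component has area 1,
  # which is <= threshold 1 (strict inequality), so all are dropped
  sparse <- matrix(200L, 20, 20)
  sparse[cbind(seq(2, 18, 4), seq(2, 18, 4))] <- 10L
  expect_equal(segment_components(sparse, 2, 1)$n_components, 0)
  expect_equal(segment_components(sparse, 2, 0)$n_components, 5)
  expect_error(segment_components(matrix(5, 8, 8)), "distinct")
})

test_that("morphology recovers closed-form disk and ellipse descriptors", {
  n <- 121
  img <- shape_image(disk_mask(n, 61, 50))
  cs <- segment_components(img, 2, 100)
  expect_equal(cs$n_components, 1)
  f <- morphological_features(cs, img)
  expect_lt(abs(f[["conv_area"]] - pi * 2500) / (pi * 2500), 0.02)
  expect_lt(f[["conv_eccentricity"]], 0.1)
  expect_equal(f[["conv_euler_number"]], 1)
  expect_lt(abs(f[["conv_compactness"]] - 1), 0.1)
  expect_gte(f[["conv_convex_area"]], f[["conv_area"]])
  expect_lt(abs(f[["conv_major_axis_length"]] - 100) / 100, 0.03)

  img2 <- shape_image(ellipse_mask(n, 61, 40, 20))
  f2 <- morphological_features(segment_components(img2, 2, 100), img2)
  expect_lt(abs(f2[["conv_eccentricity"]] - sqrt(3) / 2), 0.05)
  expect_lt(abs(f2[["conv_orientation"]]), 5)
  expect_lt(abs(f2[["conv_major_axis_length"]] - 80) / 80, 0.05)
  expect_lt(abs(f2[["conv_minor_axis_length"]] - 40) / 40, 0.05)
})

test_that("a disk with an interior hole has Euler number zero", {
  n <- 121
  img <- shape_image(disk_mask(n, 61, 40) & !disk_mask(n, 61, 12))
  f <- morphological_features(segment_components(img, 2, 100), img)
  expect_equal(f[["conv_euler_number"]], 0)
})

test_that("morphology is stable under 90-degree rotation and intensity shift", {
  p <- generate_patch(lgg_params(), 72, rng_seed = 31)
  f <- function(x) morphological_features(segment_components(x, 2, 20), x)
  a <- f(p)
  b <- f(rotate90(p))
  for (nm in c("conv_area", "conv_eccentricity", "conv_euler_number",
               "conv_compactness"))
    expect_equal(a[[nm]], b[[nm]], tolerance = 1e-9)
  expect_lt(abs(a[["conv_perimeter"]] - b[["conv_perimeter"]]) /
              a[["conv_perimeter"]], 0.05)

  # orientation shifts by 90 degrees (mod 180): check on a single component,
  # where the average is the component itself
  n <- 121
  ell <- shape_image(ellipse_mask(n, 61, 40, 20))
  o1 <- morphological_features(segment_components(ell, 2, 100),
                               ell)[["conv_orientation"]]
  o2 <- morphological_features(segment_components(rotate90(ell), 2, 100),
                               rotate90(ell))[["conv_orientation"]]
  expect_lt(min(abs(o2 - o1 - 90), abs(o2 - o1 + 90)), 5)

  # adding a constant leaves the k=2 split, hence all morphology, unchanged
  shifted <- p + 20L
  cs_a <- segment_components(p, 2, 20)
  cs_b <- segment_components(shifted, 2, 20)
  expect_identical(cs_a$labels, cs_b$labels)
})

test_that("empty component sets are rejected and the full vector has 26 features", {
  img <- shape_image(disk_mask(60, 30, 10))
  cs <- segment_components(img, 2, 5000)
  expect_error(morphological_features(cs, img), "no retained components")
  p <- generate_patch(lgg_params(), 72, rng_seed = 41)
  f <- conventional_features(p, area_threshold = 20)
  expect_length(f, 26)
  expect_true(all(startsWith(names(f), "conv_")))
  expect_true(all(is.finite(f)))
})
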