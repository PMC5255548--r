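test_that("quantile clipping matches the interpolated-rank oracle", {
  m <- pmap(matrix(1:100, 10, 10))
  out <- clip_quantiles(m, 0.01, 0.99)
  expect_equal(min(out$voxels), 1.99)
  expect_equal(max(out$voxels), 99.01)
  set.seed(31)
  for (i in 1:5) {
    v <- matrix(rnorm(400), 20, 20)
    m <- pmap(v)
    lo <- oracle_quantile(v, 0.02)
    hi <- oracle_quantile(v, 0.98)
    out <- clip_quantiles(m, 0.02, 0.98)
    expect_equal(out$voxels, pmin(pmax(v, lo), hi), tolerance = 1e-12)
  }
})

test_that("degenerate clipping inputs are handled", {
  m <- pmap(matrix(runif(64), 8, 8))
  expect_identical(clip_quantiles(m, 0, 1)$voxels, m$voxels)
  const <- const_map(3)
  expect_warning(out <- clip_quantiles(const, 0.01, 0.99), "constant")
  expect_identical(out$voxels, const$voxels)
  expect_error(clip_quantiles(m, 0.9, 0.1), "lo_quantile")
})

test_that("normalize01 is the affine rescale to [0, 1]", {
  expect_equal(as.vector(normalize01(pmap(matrix(c(2, 4, 6, 4), 2)))$voxels),
               c(0, 0.5, 1, 0.5))
  expect_equal(as.vector(normalize01(pmap(matrix(c(-5, 0, 5, 0), 2)))$voxels),
               c(0, 0.5, 1, 0.5))
  v <- matrix(c(0, 0.25, 0.5, 1), 2)
  expect_equal(normalize01(pmap(v))$voxels, v)
  expect_warning(out <- normalize01(const_map(7)), "constant")
  expect_true(all(out$voxels == 0.5))
})

test_that("contrast stretch saturates about the requested fraction", {
  v <- matrix(seq(0, 1, length.out = 10000), 100, 100)
  out <- stretch_contrast(pmap(v), 0.01)
  n_sat <- sum(out$voxels == 0) + sum(out$voxels == 1)
  expect_gte(n_sat, 90)
  expect_lte(n_sat, 110)
  expect_equal(range(out$voxels), c(0, 1))
})

test_that("stretch identity and degenerate cases", {
  v <- matrix(runif(100), 10, 10)
  expect_identical(stretch_contrast(pmap(v), 0)$voxels, v)
  bin <- matrix(rep(c(0, 1), 50), 10, 10)
  expect_equal(stretch_contrast(pmap(bin), 0.01)$voxels, bin)
  expect_error(stretch_contrast(pmap(v * 10), 0.01), "\\[0, 1\\]")
})

test_that("clipping and stretching are monotone transforms", {
  set.seed(13)
  v <- matrix(runif(400), 20, 20)
  ord <- order(v)
  clipped <- clip_quantiles(pmap(v), 0.05, 0.95)$voxels
  expect_true(all(diff(clipped[ord]) >= 0))
  stretched <- stretch_contrast(pmap(v), 0.1)$voxels
  expect_true(all(diff(stretched[ord]) >= 0))
})

test_that("resampling onto the identical grid is the identity", {
  v <- matrix(runif(96), 12, 8)
  m <- pmap(v, spacing = c(2, 3), origin = c(5, -1))
  expect_identical(resample_to_reference(m, m, "nearest")$voxels, v)
  expect_equal(resample_to_reference(m, m, "linear")$voxels, v,
               tolerance = 1e-6)
})

test_that("linear resampling reproduces a linear ramp exactly", {
  # ramp in physical x; fine source grid, coarse shifted target grid
  nx <- 41; ny <- 11
  xs <- outer(0:(nx - 1), rep(1, ny))
  src <- parametric_map(2 + 0.5 * xs, spacing = c(1, 1))
  ref <- parametric_map(matrix(0, 16, 5), spacing = c(2, 2),
                        origin = c(1.5, 0.5))
  out <- resample_to_reference(src, ref, "linear")
  want <- 2 + 0.5 * (1.5 + 2 * outer(0:15, rep(1, 5)))
  expect_equal(out$voxels, want, tolerance = 1e-9)
})

test_that("nearest resampling preserves a binary value set", {
  set.seed(3)
  v <- matrix(rbinom(200, 1, 0.4), 20, 10)
  src <- parametric_map(v, spacing = c(1, 1))
  ref <- parametric_map(matrix(0, 9, 4), spacing = c(2.1, 2.3),
                        origin = c(0.2, 0.3))
  out <- resample_to_reference(src, ref, "nearest")
  expect_true(all(out$voxels %in% c(0, 1)))
})

test_that("out-of-field voxels become zero", {
  src <- parametric_map(matrix(5, 4, 4))
  ref <- parametric_map(matrix(0, 12, 12), origin = c(-4, -4))
  out <- resample_to_reference(src, ref, "linear")
  expect_identical(out$voxels[1, 1], 0)
  expect_equal(out$voxels[6, 6], 5)
})

test_that("resampling honors the direction matrix", {
  # source rotated 90 degrees in physical space; sampling it on an
  # axis-aligned reference must un-rotate the array
  set.seed(8)
  v <- matrix(runif(64), 8, 8)
  rot <- matrix(c(0, 1, -1, 0), 2)
  src <- parametric_map(v, direction = rot, origin = c(7, 0))
  ref <- parametric_map(matrix(0, 8, 8))
  out <- resample_to_reference(src, ref, "nearest")
  want <- matrix(0, 8, 8)
  for (a in 0:7) for (b in 0:7) want[a + 1, b + 1] <- v[b + 1, 8 - a]
  expect_equal(out$voxels, want)
})

test_that("the full pipeline lands in [0, 1] with no NaN", {
  set.seed(17)
  for (dataset in c("prostate", "rat_kidney")) {
    cfg <- preprocess_defaults(dataset)
    v <- matrix(rnorm(400, 50, 20), 20, 20)
    out <- preprocess_channel(pmap(v), cfg = cfg)
    expect_true(all(is.finite(out$voxels)))
    expect_gte(min(out$voxels), 0)
    expect_lte(max(out$voxels), 1)
  }
})

test_that("pipeline equals the hand-composed stages on prostate defaults", {
  set.seed(19)
  v <- matrix(rexp(900), 30, 30)
  cfg <- preprocess_defaults("prostate")
  got <- preprocess_channel(pmap(v), cfg = cfg)
  want <- stretch_contrast(normalize01(clip_quantiles(pmap(v), 0.01, 0.99)),
                           0.01)
  expect_equal(got$voxels, want$voxels, tolerance = 1e-12)
})

test_that("normalize01 + zero-fraction stretch is idempotent", {
  set.seed(23)
  v <- matrix(runif(100), 10, 10)
  once <- stretch_contrast(normalize01(pmap(v)), 0)
  twice <- stretch_contrast(normalize01(once), 0)
  expect_equal(twice$voxels, once$voxels, tolerance = 1e-12)
})

test_that("preprocess_config validates its bounds", {
  expect_error(preprocess_config(lo_quantile = 0.6), "lo_quantile")
  expect_error(preprocess_config(hi_quantile = 0.3), "hi_quantile")
  expect_identical(preprocess_defaults("rat_kidney")$lo_quantile, 0.02)
  expect_false(preprocess_defaults("rat_kidney")$resample)
})
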