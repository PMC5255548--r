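cm <- build_colormap("equal_lightness")

test_that("the equal-lightness preset binds the printed anchors to corners", {
  expect_identical(unname(cm$corner_hex[c("000", "111", "100", "010", "001",
                                          "101", "011", "110")]),
                   c("#000000", "#FFFFFF", "#F40000", "#009100", "#1173FE",
                     "#EB009C", "#008B8E", "#A27200"))
  expect_equal(unname(cm$corners["100", ]), as.vector(hex_to_lab("#F40000")))
  expect_equal(unname(cm$corners["000", ]), c(0, 0, 0), tolerance = 1e-6)
})

test_that("map_triplet reproduces every corner exactly", {
  for (preset in c("equal_lightness", "full_spectrum", "no_green")) {
    m <- build_colormap(preset)
    verts <- expand.grid(u = 0:1, v = 0:1, w = 0:1)
    got <- map_triplet(m, verts$u, verts$v, verts$w)
    want <- m$corners[paste0(verts$u, verts$v, verts$w), ]
    expect_lt(max(delta_e(got, want)), 1e-9)
  }
})

test_that("edge midpoints equal the mean of their endpoint corners", {
  verts <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  for (i in 1:7) for (j in (i + 1):8) {
    if (sum(abs(verts[i, ] - verts[j, ])) != 1) next  # not an edge
    mid <- (verts[i, ] + verts[j, ]) / 2
    got <- map_triplet(cm, mid[1], mid[2], mid[3])
    want <- (cm$corners[paste(verts[i, ], collapse = ""), ] +
             cm$corners[paste(verts[j, ], collapse = ""), ]) / 2
    expect_lt(max(abs(got - want)), 1e-9)
  }
})

test_that("map_triplet equals the explicit 8-term trilinear sum", {
  set.seed(21)
  for (i in 1:100) {
    x <- runif(3)
    got <- as.vector(map_triplet(cm, x[1], x[2], x[3]))
    want <- unname(oracle_trilinear(cm$corners, x[1], x[2], x[3]))
    expect_lt(max(abs(got - want)), 1e-9)
  }
  mid <- as.vector(map_triplet(cm, 0.5, 0.5, 0.5))
  expect_equal(mid, unname(colMeans(cm$corners)), tolerance = 1e-12)
})

test_that("coordinates outside the cube are clamped with a warning", {
  expect_warning(got <- map_triplet(cm, 1.2, -0.1, 0.5), "clamped")
  expect_equal(as.vector(got), as.vector(map_triplet(cm, 1, 0, 0.5)))
})

test_that("rotation permutes evaluation coordinates", {
  a <- axis_assignment(c(3, 2, 1))
  cm2 <- rotate_colormap(cm, a)
  set.seed(5)
  for (i in 1:20) {
    x <- runif(3)
    expect_lt(max(abs(map_triplet(cm2, x[1], x[2], x[3]) -
                      map_triplet(cm, x[3], x[2], x[1]))), 1e-9)
  }
  # corners preserved as a set
  expect_setequal(unname(cm2$corner_hex), unname(cm$corner_hex))
  # identity assignment is a no-op
  cm3 <- rotate_colormap(cm, axis_assignment())
  expect_equal(cm3$corners, cm$corners)
})

test_that("rotation composed with its inverse is the identity", {
  set.seed(9)
  for (rep in 1:10) {
    a <- axis_assignment(sample(3), sample(c(TRUE, FALSE), 3, replace = TRUE))
    cm2 <- rotate_colormap(rotate_colormap(cm, a), invert_assignment(a))
    x <- matrix(runif(30), ncol = 3)
    expect_lt(max(abs(map_triplet(cm2, x[, 1], x[, 2], x[, 3]) -
                      map_triplet(cm, x[, 1], x[, 2], x[, 3]))), 1e-9)
  }
  expect_error(axis_assignment(c(1, 1, 2)), "permutation")
})

test_that("the default assignment maps the tumor signature to reddish hues", {
  # prostate channels (b800, ADC, PBF): tumor is (high, low, high)
  tumor_col <- map_triplet(cm, 1, 0, 1)
  expect_gt(tumor_col[, "a"], 0)
  hue <- lab_hue_angle(tumor_col)
  expect_true(hue < 90 || hue > 270)  # red/magenta sector
})

test_that("validation reports the anchor constraints", {
  v <- validate_colormap(cm)
  expect_true(v$black_white_ok)
  expect_length(v$mixed_corner_L, 6)
  expect_lte(v$max_L_deviation_from_50, 5)
  expect_true(v$equal_lightness_ok)
  expect_gt(v$polyhedron_volume, 1e5)
  # full_spectrum violates the equal-lightness constraint
  vfs <- validate_colormap(build_colormap("full_spectrum"))
  expect_false(vfs$equal_lightness_ok)
  # degenerate map: all corners black
  alldark <- setNames(rep("#000000", 8),
                      apply(expand.grid(0:1, 0:1, 0:1), 1, paste, collapse = ""))
  vd <- validate_colormap(build_colormap("custom", corners = alldark))
  expect_identical(vd$polyhedron_volume, 0)
  expect_false(vd$black_white_ok)
})

test_that("the no-green preset avoids green hues", {
  ng <- build_colormap("no_green")
  chrom <- setdiff(rownames(ng$corners), c("000", "111"))
  hues <- lab_hue_angle(ng$corners[chrom, ])
  expect_true(all(hues < 90 | hues >= 200))
})

test_that("convex hull volume matches known and independent values", {
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  expect_equal(convex_hull_volume(cube), 1, tolerance = 1e-9)
  tetra <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(convex_hull_volume(tetra), 1 / 6, tolerance = 1e-9)
  # frozen qhull value for this seeded cloud
  set.seed(7)
  pts <- matrix(runif(60), 20, 3) %*% diag(c(10, 5, 2))
  expect_equal(convex_hull_volume(pts), 34.4718172370, tolerance = 1e-8)
  expect_identical(convex_hull_volume(cbind(runif(10), runif(10), 0)), 0)
})

test_that("LUT export writes one row per grid point with display colors", {
  path <- withr::local_tempfile(fileext = ".csv")
  lut <- export_colormap_lut(cm, path, resolution = 3)
  expect_true(file.exists(path))
  back <- read.csv(path)
  expect_equal(nrow(back), 27)
  expect_named(back, c("u", "v", "w", "L", "a", "b", "R", "G", "B", "hex"))
  corner <- back[back$u == 1 & back$v == 0 & back$w == 0, ]
  expect_identical(corner$hex, "#F40000")
})

test_that("colormap slice rendering writes a PNG strip", {
  path <- withr::local_tempfile(fileext = ".png")
  render_colormap_png(cm, path, resolution = 16, n_slices = 3)
  img <- png::readPNG(path)
  expect_identical(dim(img), c(16L, 48L, 3L))
})
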