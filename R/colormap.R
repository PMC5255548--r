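#' Tri-variate CIELAB color maps
#'
#' A tri-variate color map assigns a CIELAB color to every point of the
#' unit cube \[0,1\]^3 by trilinear interpolation of eight anchor colors
#' bound to the cube corners. The built-in `"equal_lightness"` preset
#' uses black at (0,0,0), white at (1,1,1) and six chromatic anchors that
#' all lie close to the L = 50 plane, so that Euclidean (delta-E)
#' distances in the encoded image approximate perceived color
#' differences uniformly across the three channels.
#'
#' @name trivariate_colormap
NULL

.cube_vertices <- function() {
  v <- as.matrix(expand.grid(u = 0:1, v = 0:1, w = 0:1))
  rownames(v) <- apply(v, 1, paste, collapse = "")
  v
}

.preset_hexes <- list(
  # anchors with the six chromatic corners on (or near) the L = 50 plane
  equal_lightness = c(
    "000" = "#000000", "111" = "#FFFFFF",
    "100" = "#F40000", "010" = "#009100", "001" = "#1173FE",
    "101" = "#EB009C", "011" = "#008B8E", "110" = "#A27200"
  ),
  # fully saturated RGB primaries/secondaries; wide gamut, unequal L
  full_spectrum = c(
    "000" = "#000000", "111" = "#FFFFFF",
    "100" = "#FF0000", "010" = "#00FF00", "001" = "#0000FF",
    "101" = "#FF00FF", "011" = "#00FFFF", "110" = "#FFFF00"
  ),
  # avoids green/cyan hues (deuteranomaly-friendly): red/orange/blue/
  # magenta/violet anchors only
  no_green = c(
    "000" = "#000000", "111" = "#FFFFFF",
    "100" = "#F40000", "010" = "#A27200", "001" = "#1173FE",
    "101" = "#EB009C", "011" = "#6A5ACD", "110" = "#E07000"
  )
)

#' Axis assignment ("rotation") of a tri-variate color map
#'
#' The cube can be rotated by permuting its three axes and optionally
#' inverting any of them; these are the discrete symmetries used to
#' reassign channels to hues (for example so that a tumor's channel
#' signature maps to reddish colors). The assignment acts on cube
#' coordinates as `y[i] = x[perm[i]]`, then `y[i] = 1 - y[i]` where
#' `invert[i]` is `TRUE`.
#'
#' @param perm integer permutation of `1:3`
#' @param invert logical vector of length 3; per-axis inversion flags
#' @return an `axis_assignment` object
#' @export
axis_assignment <- function(perm = 1:3, invert = c(FALSE, FALSE, FALSE)) {
  perm <- as.integer(perm)
  if (length(perm) != 3 || !setequal(perm, 1:3))
    stop("perm must be a permutation of 1:3", call. = FALSE)
  invert <- as.logical(invert)
  if (length(invert) != 3 || anyNA(invert))
    stop("invert must be 3 logical flags", call. = FALSE)
  structure(list(perm = perm, invert = invert), class = "axis_assignment")
}

#' @rdname axis_assignment
#' @param x,a,b `axis_assignment` objects
#' @param coords an n x 3 matrix of cube coordinates
#' @export
apply_assignment <- function(coords, a) {
  stopifnot(inherits(a, "axis_assignment"))
  coords <- if (is.matrix(coords)) coords else matrix(coords, ncol = 3)
  out <- coords[, a$perm, drop = FALSE]
  for (i in 1:3) if (a$invert[i]) out[, i] <- 1 - out[, i]
  out
}

#' @rdname axis_assignment
#' @export
compose_assignment <- function(a, b) {
  # (a o b)(x) = a(b(x))
  axis_assignment(perm = b$perm[a$perm],
                  invert = xor(a$invert, b$invert[a$perm]))
}

#' @rdname axis_assignment
#' @export
invert_assignment <- function(a) {
  q <- order(a$perm)
  axis_assignment(perm = q, invert = a$invert[q])
}

#' Construct a tri-variate color map
#'
#' @param preset `"equal_lightness"` (the default eight printed anchors),
#'   `"full_spectrum"`, `"no_green"`, or `"custom"` (supply `corners`)
#' @param assignment an [axis_assignment()] applied at construction; the
#'   default identity binds channel 1 to the red axis, channel 2 to the
#'   green axis and channel 3 to the blue axis, under which the
#'   prostate-tumor signature (high, low, high) maps to the magenta
#'   anchor, i.e. a reddish hue
#' @param space RGB working space used to interpret the anchor hex
#'   codes, `"srgb"` (default) or `"adobe1998"`
#' @param corners for `preset = "custom"`: named character vector of 8
#'   hex codes with names `"000" ... "111"` (corner coordinates `uvw`)
#' @return a `trivariate_colormap` object with fields `name`, `corners`
#'   (8 x 3 Lab matrix, rownames are corner keys), `corner_hex`,
#'   `axis_assignment` and `space`
#' @examples
#' cm <- build_colormap("equal_lightness")
#' cm$corner_hex[["100"]] # "#F40000"
#' @export
build_colormap <- function(preset = c("equal_lightness", "full_spectrum",
                                      "no_green", "custom"),
                           assignment = axis_assignment(),
                           space = "srgb", corners = NULL) {
  preset <- match.arg(preset)
  if (preset == "custom") {
    if (is.null(corners)) stop("custom preset requires `corners`", call. = FALSE)
    hexes <- corners
  } else {
    hexes <- .preset_hexes[[preset]]
  }
  keys <- rownames(.cube_vertices())
  if (!setequal(names(hexes), keys))
    stop("corners must be named by the 8 cube vertices \"000\"..\"111\"",
         call. = FALSE)
  hexes <- hexes[keys]
  baked <- .bake_corners(hexes, assignment)
  corners_lab <- hex_to_lab(unname(baked), space = space)
  rownames(corners_lab) <- keys
  structure(list(name = preset, corners = corners_lab, corner_hex = baked,
                 axis_assignment = assignment, space = space),
            class = "trivariate_colormap")
}

# corner at vertex v of the rotated map takes the base corner at T(v)
.bake_corners <- function(hexes, assignment) {
  verts <- .cube_vertices()
  tv <- apply_assignment(verts, assignment)
  out <- hexes[apply(tv, 1, paste, collapse = "")]
  names(out) <- rownames(verts)
  out
}

#' @export
print.trivariate_colormap <- function(x, ...) {
  cat("Tri-variate CIELAB color map '", x$name, "' (", x$space, ")\n", sep = "")
  cat("  axis assignment: perm = (", paste(x$axis_assignment$perm, collapse = ","),
      "), invert = (", paste(substr(x$axis_assignment$invert, 1, 1), collapse = ","),
      ")\n", sep = "")
  df <- data.frame(corner = rownames(x$corners), hex = unname(x$corner_hex),
                   round(x$corners, 2))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Evaluate a color map by trilinear interpolation
#'
#' Returns the CIELAB color at cube coordinates `(u, v, w)`, the
#' trilinear (8-term) interpolation of the corner anchors computed
#' component-wise in CIELAB. Interpolating in CIELAB rather than RGB
#' keeps the mapping perceptually linear between anchors.
#'
#' @param cmap a [build_colormap()] object
#' @param u,v,w numeric vectors in \[0, 1\] (equal length or length 1);
#'   values outside the range are clamped with a warning
#' @return an n x 3 Lab matrix
#' @export
map_triplet <- function(cmap, u, v, w) {
  stopifnot(inherits(cmap, "trivariate_colormap"))
  x <- cbind(u, v, w)
  if (any(x < 0 | x > 1)) {
    warning("coordinates outside [0, 1] were clamped")
    x <- pmin(pmax(x, 0), 1)
  }
  verts <- .cube_vertices()
  # weight of vertex c at x: prod_i (c_i x_i + (1-c_i)(1-x_i))
  wts <- matrix(1, nrow(x), 8)
  for (j in 1:8)
    for (i in 1:3)
      wts[, j] <- wts[, j] * (verts[j, i] * x[, i] + (1 - verts[j, i]) * (1 - x[, i]))
  out <- wts %*% cmap$corners
  colnames(out) <- c("L", "a", "b")
  out
}

#' Rotate a color map
#'
#' Applies a further [axis_assignment()]: the rotated map evaluated at
#' `(u, v, w)` equals the original map evaluated at the permuted (and
#' possibly inverted) coordinates. Corners are preserved as a set.
#'
#' @param cmap a `trivariate_colormap`
#' @param assignment an [axis_assignment()]
#' @return a new `trivariate_colormap`
#' @export
rotate_colormap <- function(cmap, assignment) {
  stopifnot(inherits(cmap, "trivariate_colormap"),
            inherits(assignment, "axis_assignment"))
  hexes_new <- .bake_corners(cmap$corner_hex, assignment)
  verts <- .cube_vertices()
  tv <- apply_assignment(verts, assignment)
  keys_t <- apply(tv, 1, paste, collapse = "")
  corners_new <- cmap$corners[keys_t, , drop = FALSE]
  rownames(corners_new) <- rownames(verts)
  out <- cmap
  out$corner_hex <- hexes_new
  out$corners <- corners_new
  out$axis_assignment <- compose_assignment(cmap$axis_assignment, assignment)
  out
}

#' Validate a color map against its design constraints
#'
#' Checks the three anchor constraints: (1) black at (0,0,0) and white
#' at (1,1,1) are the extreme points (L = 0 and L = 100, neutral); (2)
#' the six chromatic anchors lie on the L = 50 plane within
#' `tolerance_L`; (3) the convex hull of the eight anchors spans a large
#' volume of CIELAB. Validation reports; it never raises.
#'
#' @param cmap a `trivariate_colormap`
#' @param tolerance_L allowed |L - 50| for the chromatic anchors
#'   (default 5; the published hexes deviate by about 2 under sRGB/D65)
#' @return a list of class `colormap_validation` with fields
#'   `black_white_ok`, `mixed_corner_L`, `max_L_deviation_from_50`,
#'   `equal_lightness_ok`, `polyhedron_volume` and `symmetry_residual`
#'   (max distance between each chromatic anchor and the reflection of
#'   its opposite corner through the L axis)
#' @export
validate_colormap <- function(cmap, tolerance_L = 5) {
  stopifnot(inherits(cmap, "trivariate_colormap"))
  co <- cmap$corners
  black_ok <- delta_e(co["000", ], c(0, 0, 0)) < 0.01
  white_ok <- delta_e(co["111", ], c(100, 0, 0)) < 0.01
  mixed_keys <- setdiff(rownames(co), c("000", "111"))
  mixedL <- co[mixed_keys, "L"]
  opp <- vapply(mixed_keys, function(k) {
    paste(1 - as.integer(strsplit(k, "")[[1]]), collapse = "")
  }, character(1))
  refl <- co[opp, , drop = FALSE] * matrix(c(1, -1, -1), length(opp), 3, byrow = TRUE)
  sym <- max(sqrt(rowSums((co[mixed_keys, , drop = FALSE] - refl)^2)))
  structure(list(
    black_white_ok = black_ok && white_ok,
    mixed_corner_L = mixedL,
    max_L_deviation_from_50 = max(abs(mixedL - 50)),
    equal_lightness_ok = max(abs(mixedL - 50)) <= tolerance_L,
    polyhedron_volume = convex_hull_volume(co),
    symmetry_residual = sym
  ), class = "colormap_validation")
}

#' @export
print.colormap_validation <- function(x, ...) {
  cat("Color map validation\n")
  cat("  black/white anchors ok: ", x$black_white_ok, "\n", sep = "")
  cat("  chromatic corner L: ", paste(sprintf("%.1f", x$mixed_corner_L),
                                      collapse = ", "), "\n", sep = "")
  cat(sprintf("  max |L - 50|: %.2f (equal-lightness ok: %s)\n",
              x$max_L_deviation_from_50, x$equal_lightness_ok))
  cat(sprintf("  anchor hull volume: %.0f CIELAB^3\n", x$polyhedron_volume))
  cat(sprintf("  symmetry residual: %.1f\n", x$symmetry_residual))
  invisible(x)
}

#' Volume of the convex hull of a 3-D point set
#'
#' Supporting planes are found by exhaustive triple enumeration (the
#' anchor sets are tiny), coplanar points on each face are collected
#' into a polygon, and the hull volume is accumulated as pyramids from
#' the centroid. Degenerate (coplanar or collinear) sets have volume 0.
#'
#' @param pts an n x 3 numeric matrix
#' @param tol relative tolerance for coplanarity
#' @return hull volume (cubic units of the input coordinates)
#' @export
convex_hull_volume <- function(pts, tol = 1e-9) {
  pts <- unique(round(as.matrix(pts), 10))
  dimnames(pts) <- NULL
  n <- nrow(pts)
  if (n < 4) return(0)
  ctr <- colMeans(pts)
  scale <- max(1, max(abs(sweep(pts, 2, ctr))))
  cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])
  seen <- character(0)
  vol <- 0
  combs <- utils::combn(n, 3)
  for (k in seq_len(ncol(combs))) {
    tri <- combs[, k]
    nrm <- cross3(pts[tri[2], ] - pts[tri[1], ], pts[tri[3], ] - pts[tri[1], ])
    nn <- sqrt(sum(nrm^2))
    if (nn < tol * scale^2) next
    nrm <- nrm / nn
    s <- as.vector(pts %*% nrm) - sum(nrm * pts[tri[1], ])
    eps <- tol * scale * 1e3
    if (max(s) <= eps) {
      # already outward if centroid below; flip so normal points away
    } else if (min(s) >= -eps) {
      nrm <- -nrm; s <- -s
    } else next
    d <- sum(nrm * pts[tri[1], ])
    key <- paste(round(c(nrm, d / scale), 7), collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    face <- which(abs(s) <= eps)
    if (length(face) < 3) next
    # orthonormal in-plane basis
    e1 <- pts[face[2], ] - pts[face[1], ]
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- cross3(nrm, e1)
    rel <- sweep(pts[face, , drop = FALSE], 2, pts[face[1], ])
    xy <- cbind(rel %*% e1, rel %*% e2)
    h <- grDevices::chull(xy)
    poly <- xy[h, , drop = FALSE]
    m <- nrow(poly)
    if (m < 3) next
    area <- abs(sum(poly[, 1] * poly[c(2:m, 1), 2] -
                    poly[c(2:m, 1), 1] * poly[, 2])) / 2
    height <- d - sum(nrm * ctr)
    vol <- vol + area * max(height, 0) / 3
  }
  vol
}

#' Export a color map as a lookup table
#'
#' Writes a CSV with one row per grid point of the unit cube: columns
#' `u, v, w, L, a, b, R, G, B, hex`.
#'
#' @param cmap a `trivariate_colormap`
#' @param path output CSV path
#' @param resolution grid points per axis (default 9)
#' @return the LUT data frame, invisibly
#' @export
export_colormap_lut <- function(cmap, path, resolution = 9) {
  stopifnot(resolution >= 2)
  g <- seq(0, 1, length.out = resolution)
  grid <- expand.grid(u = g, v = g, w = g)
  labm <- map_triplet(cmap, grid$u, grid$v, grid$w)
  rgbm <- lab_to_display_rgb(labm, space = cmap$space)
  lut <- data.frame(grid, L = labm[, 1], a = labm[, 2], b = labm[, 3],
                    R = rgbm[, 1], G = rgbm[, 2], B = rgbm[, 3],
                    hex = attr(rgbm, "hex"))
  utils::write.csv(lut, path, row.names = FALSE)
  invisible(lut)
}

#' Render cube slices of a color map to PNG
#'
#' Produces a horizontal strip of `n_slices` square patches; patch k
#' shows the (u, v) face at w fixed to `k/(n_slices - 1)`.
#'
#' @param cmap a `trivariate_colormap`
#' @param path output PNG path
#' @param resolution pixels per patch edge
#' @param n_slices number of w levels
#' @return `path`, invisibly
#' @export
render_colormap_png <- function(cmap, path, resolution = 64, n_slices = 5) {
  g <- seq(0, 1, length.out = resolution)
  wlev <- seq(0, 1, length.out = n_slices)
  strip <- array(0, dim = c(resolution, resolution * n_slices, 3))
  for (k in seq_along(wlev)) {
    grid <- expand.grid(u = g, v = g)
    rgbm <- lab_to_display_rgb(map_triplet(cmap, grid$u, grid$v, wlev[k]),
                               space = cmap$space)
    cols <- (k - 1) * resolution + seq_len(resolution)
    for (ch in 1:3)
      strip[, cols, ch] <- matrix(rgbm[, ch], resolution, resolution)[resolution:1, ]
  }
  png::writePNG(strip, path)
  invisible(path)
}
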