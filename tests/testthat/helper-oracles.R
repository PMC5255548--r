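# Independent reference implementations used as test oracles. These are
# deliberately written from first principles and never call the package
# code paths they check.

# textbook two-step sRGB -> XYZ -> Lab with the published sRGB/D65
# matrices (IEC 61966-2-1 transfer, Lindbloom matrix)
oracle_srgb_to_lab <- function(rgb) {
  lin <- ifelse(rgb <= 0.04045, rgb / 12.92, ((rgb + 0.055) / 1.055)^2.4)
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
  xyz <- as.vector(M %*% lin)
  wp <- c(0.95047, 1, 1.08883)
  f <- function(t) ifelse(t > (6 / 29)^3, t^(1 / 3), t / (3 * (6 / 29)^2) + 4 / 29)
  fx <- f(xyz[1] / wp[1]); fy <- f(xyz[2] / wp[2]); fz <- f(xyz[3] / wp[3])
  c(116 * fy - 16, 500 * (fx - fy), 200 * (fy - fz))
}

# explicit 8-term trilinear sum over a colormap's corner table
oracle_trilinear <- function(corners, u, v, w) {
  out <- 0
  for (cu in 0:1) for (cv in 0:1) for (cw in 0:1) {
    wt <- (if (cu) u else 1 - u) * (if (cv) v else 1 - v) * (if (cw) w else 1 - w)
    out <- out + wt * corners[paste0(cu, cv, cw), ]
  }
  out
}

# sort-based quantile with linear interpolation between closest ranks
oracle_quantile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# small constant-valued parametric map
const_map <- function(value, shape = c(8, 8), name = "const") {
  parametric_map(matrix(value, shape[1], shape[2]), channel_name = name)
}

# parametric map from a matrix/array
pmap <- function(v, ...) parametric_map(v, ...)

# flatten a fused image's Lab array to pixels x 3
fused_lab_matrix_for_test <- function(f) {
  sp <- utils::head(dim(f$lab), -1)
  matrix(f$lab, prod(sp), 3, dimnames = list(NULL, c("L", "a", "b")))
}

# is a Lab point inside the convex hull of the anchor set? adding an
# interior point must not grow the hull volume
inside_hull <- function(corners, p, tol = 1e-6) {
  v0 <- convex_hull_volume(corners)
  v1 <- convex_hull_volume(rbind(corners, matrix(p, 1)))
  v1 <= v0 * (1 + tol) + tol
}
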