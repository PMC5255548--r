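#' CIELAB color constructors and conversions
#'
#' Colors are represented throughout the package as numeric matrices with
#' one row per color and columns `L`, `a`, `b` (CIELAB, D65 white point).
#' `lab()` builds such a matrix; scalar inputs give a single-row matrix.
#'
#' @param L lightness in \[0, 100\]
#' @param a green--red opponent coordinate
#' @param b blue--yellow opponent coordinate
#' @return a numeric matrix with columns `L`, `a`, `b`
#' @examples
#' lab(50, 10, -10)
#' @export
lab <- function(L, a, b) {
  out <- cbind(L = as.numeric(L), a = as.numeric(a), b = as.numeric(b))
  if (any(out[, "L"] < -1e-9 | out[, "L"] > 100 + 1e-9))
    stop("L must lie in [0, 100]", call. = FALSE)
  out
}

#' @keywords internal
as_lab_matrix <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 3)
    colnames(x) <- c("L", "a", "b")
    return(x)
  }
  if (is.numeric(x) && length(x) == 3)
    return(matrix(x, 1, dimnames = list(NULL, c("L", "a", "b"))))
  stop("expected a Lab triple or an n x 3 Lab matrix", call. = FALSE)
}

# Adobe RGB (1998) <-> XYZ, D65. Matrix from the published primaries;
# gamma is the exact 563/256 of the specification.
.adobe_gamma <- 563 / 256
.adobe_to_xyz <- matrix(c(
  0.5767309, 0.1855540, 0.1881852,
  0.2973769, 0.6273491, 0.0752741,
  0.0270343, 0.0706872, 0.9911085
), 3, 3, byrow = TRUE)
.d65 <- c(X = 0.95047, Y = 1.00000, Z = 1.08883)

.xyz_to_lab <- function(xyz) {
  f <- function(t) ifelse(t > (6 / 29)^3, t^(1 / 3), t / (3 * (6 / 29)^2) + 4 / 29)
  fx <- f(xyz[, 1] / .d65[1]); fy <- f(xyz[, 2] / .d65[2]); fz <- f(xyz[, 3] / .d65[3])
  cbind(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

.lab_to_xyz <- function(lab) {
  lab <- as_lab_matrix(lab)
  finv <- function(t) ifelse(t > 6 / 29, t^3, 3 * (6 / 29)^2 * (t - 4 / 29))
  fy <- (lab[, "L"] + 16) / 116
  fx <- fy + lab[, "a"] / 500
  fz <- fy - lab[, "b"] / 200
  cbind(finv(fx) * .d65[1], finv(fy) * .d65[2], finv(fz) * .d65[3])
}

#' Parse hexadecimal RGB codes
#'
#' @param hex character vector of 6-digit hex codes, with or without a
#'   leading `#`
#' @return an n x 3 matrix of components in \[0, 1\]
#' @export
hex_to_rgb <- function(hex) {
  hex <- as.character(hex)
  ok <- grepl("^#?[0-9A-Fa-f]{6}$", hex)
  if (any(!ok))
    stop("malformed hex code(s): ", paste(hex[!ok], collapse = ", "), call. = FALSE)
  hex <- ifelse(startsWith(hex, "#"), hex, paste0("#", hex))
  t(grDevices::col2rgb(hex)) / 255
}

#' Format RGB components as hex codes
#'
#' Components are quantized to 8 bits by rounding.
#'
#' @param rgb an n x 3 matrix (or length-3 vector) of components in \[0, 1\]
#' @return character vector of `#RRGGBB` codes
#' @export
rgb_to_hex <- function(rgb) {
  if (!is.matrix(rgb)) rgb <- matrix(rgb, ncol = 3)
  q <- round(pmin(pmax(rgb, 0), 1) * 255)
  sprintf("#%02X%02X%02X", q[, 1], q[, 2], q[, 3])
}

.check_space <- function(space) {
  space <- tolower(space)
  if (!space %in% c("srgb", "adobe1998"))
    stop("unknown RGB space: '", space, "' (use \"srgb\" or \"adobe1998\")",
         call. = FALSE)
  space
}

#' Convert display RGB to CIELAB
#'
#' The sRGB path uses [grDevices::convertColor()]; Adobe RGB (1998) goes
#' through the explicit gamma-2.2 primaries matrix. Both assume a D65
#' white point, so black maps to (0, 0, 0) and white to (100, 0, 0).
#'
#' @param rgb an n x 3 matrix (or length-3 vector) of components in \[0, 1\]
#' @param space `"srgb"` (default) or `"adobe1998"`
#' @return an n x 3 Lab matrix
#' @export
rgb_to_lab <- function(rgb, space = "srgb") {
  space <- .check_space(space)
  if (!is.matrix(rgb)) rgb <- matrix(rgb, ncol = 3)
  if (space == "srgb") {
    out <- grDevices::convertColor(rgb, from = "sRGB", to = "Lab")
  } else {
    xyz <- t(.adobe_to_xyz %*% t(rgb^.adobe_gamma))
    out <- .xyz_to_lab(xyz)
  }
  dimnames(out) <- list(NULL, c("L", "a", "b"))
  out
}

#' Convert a hex code to CIELAB
#'
#' @inheritParams hex_to_rgb
#' @inheritParams rgb_to_lab
#' @return an n x 3 Lab matrix
#' @examples
#' hex_to_lab("#F40000")
#' @export
hex_to_lab <- function(hex, space = "srgb") {
  rgb_to_lab(hex_to_rgb(hex), space = space)
}

#' Render CIELAB colors in a display RGB space
#'
#' Out-of-gamut components are clipped to \[0, 1\]; clipping is reported
#' through the `out_of_gamut` attribute (one logical per color) rather
#' than by raising.
#'
#' @param lab an n x 3 Lab matrix or a length-3 triple
#' @inheritParams rgb_to_lab
#' @return an n x 3 RGB matrix in \[0, 1\] with attributes `out_of_gamut`
#'   (logical vector) and `hex` (character vector)
#' @export
lab_to_display_rgb <- function(lab, space = "srgb") {
  space <- .check_space(space)
  lab <- as_lab_matrix(lab)
  if (space == "srgb") {
    raw <- grDevices::convertColor(lab, from = "Lab", to = "sRGB", clip = NA)
  } else {
    lin <- t(solve(.adobe_to_xyz) %*% t(.lab_to_xyz(lab)))
    raw <- sign(lin) * abs(lin)^(1 / .adobe_gamma)
  }
  oog <- apply(!is.finite(raw) | raw < -1e-6 | raw > 1 + 1e-6, 1, any)
  raw[!is.finite(raw)] <- NA
  clipped <- pmin(pmax(raw, 0), 1)
  clipped[is.na(clipped)] <- 0
  # convertColor(clip = NA) marks any out-of-gamut color as all-NA; redo
  # those rows with plain clipping to get the displayable fallback.
  if (space == "srgb" && any(oog)) {
    redo <- grDevices::convertColor(lab[oog, , drop = FALSE],
                                    from = "Lab", to = "sRGB", clip = TRUE)
    clipped[oog, ] <- pmin(pmax(redo, 0), 1)
  }
  colnames(clipped) <- c("r", "g", "b")
  attr(clipped, "out_of_gamut") <- as.vector(oog)
  attr(clipped, "hex") <- rgb_to_hex(clipped)
  clipped
}

#' CIE76 perceptual color difference
#'
#' Plain Euclidean distance in CIELAB, the delta-E formulation under
#' which the space is approximately perceptually uniform.
#'
#' @param c1,c2 Lab triples or n x 3 Lab matrices (recycled row-wise if
#'   one argument is a single color)
#' @return non-negative numeric vector of distances
#' @examples
#' delta_e(lab(50, 10, 0), lab(50, 0, 10)) # sqrt(200)
#' @export
delta_e <- function(c1, c2) {
  c1 <- as_lab_matrix(c1); c2 <- as_lab_matrix(c2)
  if (nrow(c1) == 1 && nrow(c2) > 1) c1 <- c1[rep(1, nrow(c2)), , drop = FALSE]
  if (nrow(c2) == 1 && nrow(c1) > 1) c2 <- c2[rep(1, nrow(c1)), , drop = FALSE]
  if (nrow(c1) != nrow(c2)) stop("incompatible numbers of colors", call. = FALSE)
  sqrt(rowSums((c1 - c2)^2))
}

#' CIELAB hue angle
#'
#' @param lab a Lab triple or n x 3 matrix
#' @return hue angle `atan2(b, a)` in degrees, in \[0, 360)
#' @export
lab_hue_angle <- function(lab) {
  lab <- as_lab_matrix(lab)
  (atan2(lab[, "b"], lab[, "a"]) * 180 / pi) %% 360
}
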