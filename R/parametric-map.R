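#' Parametric map container
#'
#' A light container for one imaging channel: a 2-D or 3-D voxel array
#' plus physical grid geometry. The physical position of 0-based voxel
#' index `i` is `origin + direction %*% (i * spacing)`, the standard
#' medical-imaging convention.
#'
#' @param voxels 2-D or 3-D numeric array
#' @param spacing per-axis voxel spacing in mm (strictly positive)
#' @param origin physical position of voxel (0, 0\[, 0\]) in mm
#' @param direction axis orientation matrix (defaults to identity)
#' @param channel_name label such as `"b800"`, `"ADC"`, `"PBF"`
#' @return a `parametric_map` object
#' @export
parametric_map <- function(voxels, spacing = NULL, origin = NULL,
                           direction = NULL, channel_name = "") {
  voxels <- as.array(voxels)
  d <- length(dim(voxels))
  if (!d %in% c(2L, 3L)) stop("voxels must be 2-D or 3-D", call. = FALSE)
  if (is.null(spacing)) spacing <- rep(1, d)
  if (is.null(origin)) origin <- rep(0, d)
  if (is.null(direction)) direction <- diag(d)
  if (length(spacing) != d || any(spacing <= 0))
    stop("spacing must be ", d, " strictly positive values", call. = FALSE)
  if (length(origin) != d) stop("origin must have length ", d, call. = FALSE)
  direction <- as.matrix(direction)
  if (!all(dim(direction) == c(d, d)) || abs(det(direction)) < 1e-12)
    stop("direction must be an invertible ", d, "x", d, " matrix", call. = FALSE)
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), direction = direction,
                 channel_name = channel_name),
            class = "parametric_map")
}

#' @export
print.parametric_map <- function(x, ...) {
  cat("Parametric map '", x$channel_name, "': ",
      paste(dim(x$voxels), collapse = " x "),
      " voxels, spacing (", paste(x$spacing, collapse = ", "), ") mm\n",
      sep = "")
  rng <- range(x$voxels, finite = TRUE)
  cat(sprintf("  intensity range [%.4g, %.4g]\n", rng[1], rng[2]))
  invisible(x)
}

#' @keywords internal
same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$voxels), dim(b$voxels)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol &&
    max(abs(a$direction - b$direction)) < tol
}

#' @keywords internal
geometry_of <- function(m) {
  m[c("spacing", "origin", "direction")]
}
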