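#' Fuse three preprocessed channels into a color image
#'
#' Each pixel's three channel values (all in \[0, 1\]) are used as
#' coordinates into the tri-variate color map; the interpolated CIELAB
#' color is rendered to display RGB with gamut clipping.
#'
#' @param c1,c2,c3 [parametric_map()] objects on a common grid with
#'   values in \[0, 1\]
#' @param cmap a [build_colormap()] color map
#' @return a `fused_image` with fields `lab` and `rgb` (arrays whose
#'   last dimension holds the 3 color components), `geometry`, and
#'   `provenance` (channel names, colormap name, axis assignment,
#'   RGB space, package version)
#' @export
fuse_channels <- function(c1, c2, c3, cmap) {
  stopifnot(inherits(cmap, "trivariate_colormap"))
  chans <- list(c1, c2, c3)
  for (i in 1:3)
    if (!inherits(chans[[i]], "parametric_map"))
      stop("channel ", i, " is not a parametric_map", call. = FALSE)
  for (i in 2:3)
    if (!same_grid(chans[[i]], c1))
      stop("channel ", i, " ('", chans[[i]]$channel_name,
           "') is not on the same grid as channel 1", call. = FALSE)
  spatial <- dim(c1$voxels)
  labm <- map_triplet(cmap, as.vector(c1$voxels), as.vector(c2$voxels),
                      as.vector(c3$voxels))
  rgbm <- lab_to_display_rgb(labm, space = cmap$space)
  structure(list(
    lab = array(labm, dim = c(spatial, 3)),
    rgb = array(rgbm, dim = c(spatial, 3)),
    geometry = geometry_of(c1),
    provenance = list(
      channels = vapply(chans, `[[`, "", "channel_name"),
      colormap = cmap$name,
      axis_assignment = cmap$axis_assignment,
      rgb_space = cmap$space,
      version = as.character(utils::packageVersion("trivarmap"))
    )
  ), class = "fused_image")
}

#' @export
print.fused_image <- function(x, ...) {
  sp <- utils::head(dim(x$lab), -1)
  cat("Fused color image: ", paste(sp, collapse = " x "),
      " pixels, colormap '", x$provenance$colormap, "'\n", sep = "")
  cat("  channels: ", paste(x$provenance$channels, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @keywords internal
fused_lab_matrix <- function(f) {
  spatial <- utils::head(dim(f$lab), -1)
  matrix(f$lab, prod(spatial), 3, dimnames = list(NULL, c("L", "a", "b")))
}

#' @keywords internal
fused_rgb_matrix <- function(f) {
  spatial <- utils::head(dim(f$rgb), -1)
  matrix(f$rgb, prod(spatial), 3, dimnames = list(NULL, c("r", "g", "b")))
}

#' Blend a fused image over an anatomical grayscale underlay
#'
#' Standard alpha compositing in display RGB: each output component is
#' `alpha * fused + (1 - alpha) * t2`. `alpha = 1` returns the fused
#' image unchanged; `alpha = 0` the pure grayscale anatomy.
#'
#' @param f a [fuse_channels()] result
#' @param t2 anatomical [parametric_map()] on `f`'s grid, values in
#'   \[0, 1\]
#' @param alpha blending weight of the color image, in \[0, 1\]
#'   (default 0.5)
#' @return a `fused_image` with blended `rgb` (the `lab` field is
#'   recomputed from the blended RGB)
#' @export
overlay_on_anatomy <- function(f, t2, alpha = 0.5) {
  stopifnot(inherits(f, "fused_image"), inherits(t2, "parametric_map"))
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]", call. = FALSE)
  spatial <- utils::head(dim(f$rgb), -1)
  if (!identical(dim(t2$voxels), as.integer(spatial)))
    stop("t2 grid does not match the fused image", call. = FALSE)
  if (alpha == 1) return(f)
  g <- as.vector(t2$voxels)
  if (min(g) < -1e-9 || max(g) > 1 + 1e-9)
    stop("t2 must be normalized to [0, 1]", call. = FALSE)
  rgbm <- fused_rgb_matrix(f)
  blended <- alpha * rgbm + (1 - alpha) * cbind(g, g, g)
  out <- f
  out$rgb <- array(blended, dim = dim(f$rgb))
  out$lab <- array(rgb_to_lab(blended, space = f$provenance$rgb_space),
                   dim = dim(f$lab))
  out$provenance$overlay_alpha <- alpha
  out
}
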