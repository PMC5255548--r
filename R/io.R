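#' Read an image file into a parametric map
#'
#' Supported formats are NIfTI (`.nii`, `.nii.gz`, read with the RNifti
#' backend, rescale slope/intercept applied) and single-slice grayscale
#' PNG (unit spacing is assumed, with a warning). DICOM series are not
#' read directly; convert them to NIfTI first.
#'
#' @param path file path
#' @param format `"auto"` (by extension), `"nifti"` or `"png"`
#' @param channel_name label for the resulting channel (defaults to the
#'   file name without extension)
#' @return a [parametric_map()]
#' @export
read_image <- function(path, format = c("auto", "nifti", "png"),
                       channel_name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read '", path, "': no such file",
                               call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.png$", path, ignore.case = TRUE)) "png"
    else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) "nifti"
    else if (grepl("\\.dcm$|\\.dicom$", path, ignore.case = TRUE))
      stop("DICOM input is not supported; convert the series to NIfTI ",
           "(e.g. with dcm2niix) and retry: ", path, call. = FALSE)
    else stop("cannot infer format of '", path, "'", call. = FALSE)
  }
  if (is.null(channel_name))
    channel_name <- sub("\\.(png|nii|nii\\.gz)$", "", basename(path),
                        ignore.case = TRUE)
  if (format == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3) img <- img[, , 1]
    warning("PNG carries no physical geometry; assuming unit spacing")
    return(parametric_map(t(img)[, rev(seq_len(nrow(img))), drop = FALSE],
                          channel_name = channel_name))
  }
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  d <- length(dim(arr))
  if (d == 3 && dim(arr)[3] == 1) {
    arr <- arr[, , 1]
    d <- 2L
  }
  if (!d %in% c(2L, 3L))
    stop("only 2-D/3-D images are supported; '", path, "' has ", d,
         " dimensions", call. = FALSE)
  spacing <- RNifti::pixdim(img)[seq_len(d)]
  spacing[spacing <= 0] <- 1
  xf <- try(RNifti::xform(img), silent = TRUE)
  origin <- rep(0, d)
  direction <- diag(d)
  if (!inherits(xf, "try-error")) {
    A <- xf[seq_len(d), seq_len(d), drop = FALSE]
    dirc <- A %*% diag(1 / spacing, d)
    if (all(is.finite(dirc)) && abs(det(dirc)) > 1e-9) {
      direction <- dirc
      origin <- xf[seq_len(d), 4]
    }
  }
  parametric_map(arr, spacing = spacing, origin = origin,
                 direction = direction, channel_name = channel_name)
}

#' Write a parametric map to NIfTI
#'
#' Geometry (spacing, origin, direction) is stored in the sform so that
#' [read_image()] round-trips it.
#'
#' @param m a [parametric_map()]
#' @param path output path (`.nii` or `.nii.gz`)
#' @return `path`, invisibly
#' @export
write_image <- function(m, path) {
  stopifnot(inherits(m, "parametric_map"))
  d <- length(dim(m$voxels))
  img <- RNifti::asNifti(m$voxels)
  RNifti::pixdim(img) <- m$spacing
  aff <- diag(4)
  aff[seq_len(d), seq_len(d)] <- m$direction %*% diag(m$spacing, d)
  aff[seq_len(d), 4] <- m$origin
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a fused color image
#'
#' `"png"` writes an 8-bit RGB PNG with the provenance embedded as a
#' PNG text chunk and duplicated in a JSON sidecar (`<path>.json`);
#' `"nifti_rgb"` writes the RGB components as a float NIfTI volume with
#' a trailing channel dimension, plus the same sidecar.
#'
#' @param f a [fuse_channels()] result
#' @param path output path
#' @param format `"png"` or `"nifti_rgb"`
#' @return `path`, invisibly
#' @export
write_fused <- function(f, path, format = c("png", "nifti_rgb")) {
  format <- match.arg(format)
  stopifnot(inherits(f, "fused_image"))
  prov <- f$provenance
  prov$axis_assignment <- list(perm = prov$axis_assignment$perm,
                               invert = prov$axis_assignment$invert)
  prov_json <- jsonlite::toJSON(prov, auto_unbox = TRUE, digits = NA)
  if (format == "png") {
    spatial <- utils::head(dim(f$rgb), -1)
    if (length(spatial) != 2)
      stop("PNG output requires a 2-D fused image", call. = FALSE)
    # our arrays are [x, y, channel] with y increasing upward; PNG rows
    # run top-down
    img <- aperm(f$rgb[, rev(seq_len(spatial[2])), , drop = FALSE], c(2, 1, 3))
    png::writePNG(img, path, text = c(provenance = as.character(prov_json)))
  } else {
    img <- RNifti::asNifti(f$rgb)
    RNifti::pixdim(img) <- c(f$geometry$spacing, 1)
    RNifti::writeNifti(img, path)
  }
  jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a binary ROI mask as PNG
#'
#' @param roi a [roi_mask()]
#' @param path output PNG path
#' @return `path`, invisibly
#' @export
write_mask_png <- function(roi, path) {
  stopifnot(inherits(roi, "roi_mask"))
  m <- roi$mask
  png::writePNG(t(m[, rev(seq_len(ncol(m))), drop = FALSE]) * 1, path)
  invisible(path)
}

#' Read a binary ROI mask from PNG
#'
#' @param path PNG path
#' @param label mask label
#' @return a [roi_mask()]
#' @export
read_mask_png <- function(path, label = "roi") {
  m <- suppressWarnings(read_image(path, "png"))
  roi_mask(m$voxels > 0.5, label)
}
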