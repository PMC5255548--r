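#' Region-of-interest mask
#'
#' @param mask logical (or 0/1) array matching a fused image's spatial
#'   grid
#' @param label `"tumor"`, `"non_tumor"` or any custom label
#' @return a `roi_mask` object
#' @export
roi_mask <- function(mask, label = "roi") {
  mask <- as.array(mask)
  if (is.numeric(mask)) {
    if (!all(mask %in% c(0, 1))) stop("mask must be binary", call. = FALSE)
    mask <- array(mask == 1, dim = dim(mask))
  }
  if (!is.logical(mask)) stop("mask must be logical or 0/1", call. = FALSE)
  structure(list(mask = mask, label = label), class = "roi_mask")
}

.check_roi <- function(f, roi) {
  stopifnot(inherits(f, "fused_image"), inherits(roi, "roi_mask"))
  spatial <- utils::head(dim(f$lab), -1)
  if (!identical(dim(roi$mask), as.integer(spatial)))
    stop("ROI mask shape does not match the fused image", call. = FALSE)
  if (!any(roi$mask)) stop("ROI mask '", roi$label, "' is empty", call. = FALSE)
  invisible(TRUE)
}

#' Mean color of a region in CIELAB
#'
#' Component-wise arithmetic mean of (L, a, b) over the masked pixels --
#' the reference color used for perceptual-contrast analysis.
#'
#' @param f a [fuse_channels()] result
#' @param roi a non-empty [roi_mask()]
#' @return a 1 x 3 Lab matrix
#' @export
mean_roi_color <- function(f, roi) {
  .check_roi(f, roi)
  labm <- fused_lab_matrix(f)
  m <- colMeans(labm[as.vector(roi$mask), , drop = FALSE])
  matrix(m, 1, dimnames = list(NULL, c("L", "a", "b")))
}

#' Per-pixel perceptual distance to a reference color
#'
#' Computes the CIE76 delta-E from every pixel to `ref`; because CIELAB
#' is approximately perceptually uniform, the map shows how different
#' each pixel looks from the reference (typically the mean tumor color).
#'
#' @param f a [fuse_channels()] result
#' @param ref a Lab triple or 1 x 3 matrix
#' @return numeric array with `f`'s spatial shape
#' @export
perceptual_distance_map <- function(f, ref) {
  stopifnot(inherits(f, "fused_image"))
  spatial <- utils::head(dim(f$lab), -1)
  array(delta_e(fused_lab_matrix(f), as_lab_matrix(ref)), dim = spatial)
}

#' Tumor vs. non-tumor perceptual contrast report
#'
#' Uses the mean tumor color as the reference point, computes per-pixel
#' delta-E within each region, and compares region medians: the regions
#' are perceptually separable when the median non-tumor distance
#' exceeds the median tumor distance.
#'
#' @param f a [fuse_channels()] result
#' @param tumor,nontumor disjoint non-empty [roi_mask()]s
#' @param n_bins number of histogram bins (over \[0, max distance\])
#' @return a `contrast_report` with fields `reference_color`,
#'   `median_tumor_distance`, `median_nontumor_distance`,
#'   `histogram_tumor`, `histogram_nontumor` (each a list with `breaks`
#'   and `counts`) and `separation`
#' @export
contrast_report <- function(f, tumor, nontumor, n_bins = 50) {
  .check_roi(f, tumor)
  .check_roi(f, nontumor)
  if (any(tumor$mask & nontumor$mask))
    stop("tumor and non-tumor masks overlap", call. = FALSE)
  ref <- mean_roi_color(f, tumor)
  dmap <- perceptual_distance_map(f, ref)
  d_t <- dmap[tumor$mask]
  d_n <- dmap[nontumor$mask]
  top <- max(d_t, d_n, .Machine$double.eps)
  breaks <- seq(0, top, length.out = n_bins + 1)
  h_t <- graphics::hist(d_t, breaks = breaks, plot = FALSE)
  h_n <- graphics::hist(d_n, breaks = breaks, plot = FALSE)
  structure(list(
    reference_color = ref,
    median_tumor_distance = stats::median(d_t),
    median_nontumor_distance = stats::median(d_n),
    histogram_tumor = list(breaks = breaks, counts = h_t$counts),
    histogram_nontumor = list(breaks = breaks, counts = h_n$counts),
    n_tumor = length(d_t), n_nontumor = length(d_n),
    separation = stats::median(d_n) > stats::median(d_t)
  ), class = "contrast_report")
}

#' @export
print.contrast_report <- function(x, ...) {
  cat("Perceptual contrast report (CIE76 delta-E to mean tumor color)\n")
  cat(sprintf("  reference color: L = %.1f, a = %.1f, b = %.1f\n",
              x$reference_color[1], x$reference_color[2], x$reference_color[3]))
  cat(sprintf("  median delta-E, tumor:     %.2f  (n = %d)\n",
              x$median_tumor_distance, x$n_tumor))
  cat(sprintf("  median delta-E, non-tumor: %.2f  (n = %d)\n",
              x$median_nontumor_distance, x$n_nontumor))
  cat("  perceptually separable: ", x$separation, "\n", sep = "")
  invisible(x)
}
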