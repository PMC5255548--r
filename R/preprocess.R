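#' Preprocessing configuration
#'
#' Bundles the per-channel conditioning parameters. The prostate
#' defaults winsorize at the 1st/99th percentile; rat-kidney data, being
#' noisier, uses 2nd/98th and skips resampling (see
#' [preprocess_defaults()]).
#'
#' @param lo_quantile lower outlier quantile in \[0, 0.5)
#' @param hi_quantile upper outlier quantile in (0.5, 1\]
#' @param saturation_fraction fraction of pixels driven to full black or
#'   white by the contrast stretch (default 0.01, i.e. "1% saturated")
#' @param resample resample to the reference grid before intensity steps?
#' @param interpolation `"linear"` or `"nearest"`
#' @param symmetric_saturation if `TRUE` (default) the stretch saturates
#'   `saturation_fraction/2` at each tail; if `FALSE`, the full fraction
#'   at each tail
#' @return a `preprocess_config` list
#' @export
preprocess_config <- function(lo_quantile = 0.01, hi_quantile = 0.99,
                              saturation_fraction = 0.01, resample = TRUE,
                              interpolation = c("linear", "nearest"),
                              symmetric_saturation = TRUE) {
  interpolation <- match.arg(interpolation)
  if (!(lo_quantile >= 0 && lo_quantile < 0.5))
    stop("lo_quantile must be in [0, 0.5)", call. = FALSE)
  if (!(hi_quantile > 0.5 && hi_quantile <= 1))
    stop("hi_quantile must be in (0.5, 1]", call. = FALSE)
  if (saturation_fraction < 0 || saturation_fraction >= 1)
    stop("saturation_fraction must be in [0, 1)", call. = FALSE)
  structure(list(lo_quantile = lo_quantile, hi_quantile = hi_quantile,
                 saturation_fraction = saturation_fraction,
                 resample = resample, interpolation = interpolation,
                 symmetric_saturation = symmetric_saturation),
            class = "preprocess_config")
}

#' @rdname preprocess_config
#' @param dataset `"prostate"` (1%/99%, resampling on) or `"rat_kidney"`
#'   (2%/98%, resampling off)
#' @export
preprocess_defaults <- function(dataset = c("prostate", "rat_kidney")) {
  dataset <- match.arg(dataset)
  if (dataset == "prostate")
    preprocess_config(0.01, 0.99, resample = TRUE)
  else
    preprocess_config(0.02, 0.98, resample = FALSE)
}

#' Winsorize intensity outliers at quantile bounds
#'
#' Pixels below the `lo` quantile are set to the quantile value and
#' pixels above the `hi` quantile to that value (clipping rather than
#' deletion, so every voxel keeps a value for fusion). Quantiles use the
#' sorted-order statistic with linear interpolation between closest
#' ranks ([stats::quantile()] type 7).
#'
#' @param m a [parametric_map()]
#' @param lo_quantile,hi_quantile clipping quantiles, `lo < hi`
#' @return a `parametric_map` with winsorized voxels
#' @export
clip_quantiles <- function(m, lo_quantile = 0.01, hi_quantile = 0.99) {
  stopifnot(inherits(m, "parametric_map"))
  if (lo_quantile >= hi_quantile)
    stop("lo_quantile must be < hi_quantile", call. = FALSE)
  v <- m$voxels
  if (!all(is.finite(v))) stop("voxels must be finite", call. = FALSE)
  rng <- range(v)
  if (rng[1] == rng[2]) {
    warning("constant image: quantile clipping is a no-op")
    return(m)
  }
  q <- stats::quantile(v, c(lo_quantile, hi_quantile), names = FALSE, type = 7)
  m$voxels[] <- pmin(pmax(v, q[1]), q[2])
  m
}

#' Rescale intensities to the unit interval
#'
#' Applies `(x - min) / (max - min)`. A constant image has no usable
#' range; it is returned as all 0.5 with a warning.
#'
#' @param m a [parametric_map()]
#' @return a `parametric_map` with voxels in \[0, 1\]
#' @export
normalize01 <- function(m) {
  stopifnot(inherits(m, "parametric_map"))
  v <- m$voxels
  rng <- range(v, finite = TRUE)
  if (!all(is.finite(rng))) stop("voxels must be finite", call. = FALSE)
  if (rng[1] == rng[2]) {
    warning("constant image: normalized to 0.5 everywhere")
    m$voxels[] <- 0.5
    return(m)
  }
  m$voxels[] <- (v - rng[1]) / (rng[2] - rng[1])
  m
}

#' Percentile contrast stretch
#'
#' Maximizes within-channel contrast by linearly mapping the
#' `fraction/2` quantile to 0 and the `1 - fraction/2` quantile to 1
#' (symmetric stretch-limits convention), clamping outside, so that
#' approximately `fraction` of the pixels end up fully saturated at 0
#' or 1. Set `symmetric = FALSE` to saturate the full fraction at each
#' tail instead.
#'
#' @param m a [parametric_map()] with values in \[0, 1\]
#' @param saturation_fraction total fraction of pixels saturated
#' @param symmetric split the fraction across both tails?
#' @return a `parametric_map` with stretched voxels in \[0, 1\]
#' @export
stretch_contrast <- function(m, saturation_fraction = 0.01, symmetric = TRUE) {
  stopifnot(inherits(m, "parametric_map"))
  v <- m$voxels
  if (min(v) < -1e-9 || max(v) > 1 + 1e-9)
    stop("stretch_contrast expects values in [0, 1]; run normalize01 first",
         call. = FALSE)
  if (saturation_fraction <= 0) return(m)
  tail <- if (symmetric) saturation_fraction / 2 else saturation_fraction
  q <- stats::quantile(v, c(tail, 1 - tail), names = FALSE, type = 7)
  if (q[2] - q[1] < .Machine$double.eps) {
    warning("degenerate quantile span: contrast stretch is a no-op")
    return(m)
  }
  m$voxels[] <- pmin(pmax((v - q[1]) / (q[2] - q[1]), 0), 1)
  m
}

#' Resample a map onto a reference grid
#'
#' The output takes the reference's shape, spacing, origin and
#' direction; values are interpolated from `m` at the physical position
#' of each reference voxel. Positions outside `m`'s field of view get 0.
#'
#' @param m a [parametric_map()] to resample
#' @param ref a [parametric_map()] defining the target grid
#' @param interpolation `"linear"` (n-linear) or `"nearest"`
#' @return a `parametric_map` on `ref`'s grid
#' @export
resample_to_reference <- function(m, ref,
                                  interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  stopifnot(inherits(m, "parametric_map"), inherits(ref, "parametric_map"))
  d <- length(dim(m$voxels))
  if (length(dim(ref$voxels)) != d)
    stop("reference dimensionality differs from input", call. = FALSE)
  if (same_grid(m, ref)) {
    out <- m
    out$voxels <- m$voxels
    return(out)
  }
  dims_ref <- dim(ref$voxels)
  idx_ref <- as.matrix(do.call(expand.grid, lapply(dims_ref, function(n) 0:(n - 1))))
  phys <- sweep(idx_ref %*% diag(ref$spacing, d) %*% t(ref$direction),
                2, ref$origin, "+")
  # continuous 0-based index into m
  rel <- sweep(phys, 2, m$origin, "-") %*% t(solve(m$direction))
  cont <- sweep(rel, 2, m$spacing, "/")
  vals <- .sample_nlinear(m$voxels, cont, interpolation)
  out <- ref
  out$voxels <- array(vals, dim = dims_ref)
  out$channel_name <- m$channel_name
  out
}

# n-linear / nearest sampling of `vox` at continuous 0-based indices
# (rows of `cont`); positions outside the array return 0
.sample_nlinear <- function(vox, cont, interpolation) {
  d <- length(dim(vox))
  dims <- dim(vox)
  n <- nrow(cont)
  if (interpolation == "nearest") {
    idx <- round(cont)
    inside <- rowSums(idx < 0 | idx >= matrix(dims, n, d, byrow = TRUE)) == 0
    vals <- numeric(n)
    if (any(inside)) {
      lin <- as.vector((idx[inside, , drop = FALSE]) %*% cumprod(c(1, dims[-d]))) + 1
      vals[inside] <- vox[lin]
    }
    return(vals)
  }
  lo <- floor(cont)
  fr <- cont - lo
  vals <- numeric(n)
  strides <- cumprod(c(1, dims[-d]))
  corners <- as.matrix(do.call(expand.grid, rep(list(0:1), d)))
  for (k in seq_len(nrow(corners))) {
    off <- corners[k, ]
    idx <- sweep(lo, 2, off, "+")
    w <- rep(1, n)
    for (i in seq_len(d))
      w <- w * (if (off[i] == 1) fr[, i] else 1 - fr[, i])
    inside <- rowSums(idx < 0 | idx >= matrix(dims, n, d, byrow = TRUE)) == 0
    keep <- inside & w > 0
    if (any(keep)) {
      lin <- as.vector(idx[keep, , drop = FALSE] %*% strides) + 1
      vals[keep] <- vals[keep] + w[keep] * vox[lin]
    }
  }
  vals
}

#' Full per-channel preprocessing pipeline
#'
#' Applies, in order: resampling to the reference grid (if configured
#' and a reference is given), quantile winsorization, normalization to
#' \[0, 1\], and the percentile contrast stretch. Resampling comes
#' first so intensity statistics are computed on the analysis grid.
#'
#' @param m a [parametric_map()]
#' @param ref optional reference [parametric_map()] (e.g. the T2 grid)
#' @param cfg a [preprocess_config()]
#' @return a `parametric_map` with voxels in \[0, 1\]
#' @export
preprocess_channel <- function(m, ref = NULL, cfg = preprocess_config()) {
  stopifnot(inherits(cfg, "preprocess_config"))
  if (isTRUE(cfg$resample) && !is.null(ref))
    m <- resample_to_reference(m, ref, cfg$interpolation)
  m <- clip_quantiles(m, cfg$lo_quantile, cfg$hi_quantile)
  m <- normalize01(m)
  stretch_contrast(m, cfg$saturation_fraction, cfg$symmetric_saturation)
}
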