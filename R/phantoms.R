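#' Synthetic phantom specification
#'
#' Parameters of the prostate-like test phantom. The defaults encode
#' the typical multiparametric signature of prostate carcinoma: the
#' lesion is hyperintense in the diffusion (b800-like) channel,
#' hypointense in the ADC-like channel and hyperintense in the
#' perfusion (PBF-like) channel, against a background with the inverted
#' pattern. Intensities live on the \[0, 1\] scale; noise is additive
#' Gaussian.
#'
#' @param shape 2-D grid size (pixels)
#' @param organ_center,organ_axes center and semi-axes of the organ
#'   ellipse (pixel units)
#' @param lesion_center,lesion_radius center and radius of the circular
#'   lesion; must lie strictly inside the organ
#' @param lesion_levels,background_levels per-channel mean intensities
#'   for (b800, ADC, PBF)-like channels, each in \[0, 1\]
#' @param noise_sigma standard deviation of the additive Gaussian noise
#' @param seed RNG seed; the phantom is a pure function of spec + seed
#' @return a `phantom_spec` list
#' @export
phantom_spec <- function(shape = c(96, 96),
                         organ_center = c(48, 48), organ_axes = c(38, 30),
                         lesion_center = c(62, 40), lesion_radius = 9,
                         lesion_levels = c(0.85, 0.15, 0.80),
                         background_levels = c(0.25, 0.75, 0.20),
                         noise_sigma = 0.05, seed = 1L) {
  stopifnot(length(shape) == 2, all(shape >= 8))
  if (any(lesion_levels < 0 | lesion_levels > 1) ||
      any(background_levels < 0 | background_levels > 1))
    stop("signal levels must lie in [0, 1]", call. = FALSE)
  # lesion strictly inside organ: check the lesion's bounding circle
  # against the organ ellipse
  th <- seq(0, 2 * pi, length.out = 64)
  pts <- cbind(lesion_center[1] + lesion_radius * cos(th),
               lesion_center[2] + lesion_radius * sin(th))
  inside <- ((pts[, 1] - organ_center[1]) / organ_axes[1])^2 +
    ((pts[, 2] - organ_center[2]) / organ_axes[2])^2 < 1
  if (!all(inside)) stop("lesion must lie strictly inside the organ",
                         call. = FALSE)
  structure(list(shape = as.integer(shape), organ_center = organ_center,
                 organ_axes = organ_axes, lesion_center = lesion_center,
                 lesion_radius = lesion_radius,
                 lesion_levels = lesion_levels,
                 background_levels = background_levels,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

.pixel_grid <- function(shape) {
  list(x = matrix(rep(seq_len(shape[1]), shape[2]), shape[1], shape[2]),
       y = matrix(rep(seq_len(shape[2]), each = shape[1]), shape[1], shape[2]))
}

.add_noise <- function(v, sigma) {
  if (sigma <= 0) return(v)
  pmin(pmax(v + stats::rnorm(length(v), 0, sigma), 0), 1)
}

#' Generate a prostate-like phantom
#'
#' Builds three channels with the lesion/background signature of
#' [phantom_spec()], a T2-like anatomical image, and disjoint tumor /
#' non-tumor ROI masks (the non-tumor ROI is the organ minus the
#' lesion). Deterministic for a fixed spec.
#'
#' @param spec a [phantom_spec()]
#' @return a list with `channels` (3 [parametric_map()]s named b800,
#'   ADC, PBF), `t2` (a `parametric_map`), `tumor_mask` and
#'   `nontumor_mask` ([roi_mask()]s)
#' @export
make_prostate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- .pixel_grid(spec$shape)
  organ <- ((g$x - spec$organ_center[1]) / spec$organ_axes[1])^2 +
    ((g$y - spec$organ_center[2]) / spec$organ_axes[2])^2 <= 1
  lesion <- (g$x - spec$lesion_center[1])^2 + (g$y - spec$lesion_center[2])^2 <=
    spec$lesion_radius^2
  names_ch <- c("b800", "ADC", "PBF")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  channels <- lapply(1:3, function(i) {
    v <- matrix(spec$background_levels[i] / 3, spec$shape[1], spec$shape[2])
    v[organ] <- spec$background_levels[i]
    v[lesion] <- spec$lesion_levels[i]
    v[] <- .add_noise(v, spec$noise_sigma)
    parametric_map(v, channel_name = names_ch[i])
  })
  names(channels) <- names_ch
  t2v <- matrix(0.2, spec$shape[1], spec$shape[2])
  t2v[organ] <- 0.6
  t2v[lesion] <- 0.5
  t2v[] <- .add_noise(t2v, spec$noise_sigma)
  t2 <- parametric_map(t2v, channel_name = "T2")
  list(channels = channels, t2 = t2,
       tumor_mask = roi_mask(lesion, "tumor"),
       nontumor_mask = roi_mask(organ & !lesion, "non_tumor"))
}

# save/restore the global RNG state so generators are pure functions of
# their seed without disturbing the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Generate a kidney-like phantom
#'
#' Two elliptical kidneys with a stratified cortex/medulla pattern:
#' tubular flow is high in the inner medullary band and plasma volume
#' high in the outer cortical band, with a uniform plasma-flow channel.
#' With `disrupted = TRUE` the pixel values of the right kidney are
#' randomly permuted within the organ, collapsing the band-mean
#' contrast there while the contralateral kidney keeps its regular
#' stratification.
#'
#' @param disrupted disrupt the right kidney's banding?
#' @param seed RNG seed
#' @param shape 2-D grid size
#' @param noise_sigma additive Gaussian noise level
#' @return a list with `channels` (tubular_flow, plasma_flow,
#'   plasma_volume [parametric_map()]s) and `masks` (logical arrays:
#'   `left_cortex`, `left_medulla`, `right_cortex`, `right_medulla`)
#' @export
make_kidney_phantom <- function(disrupted = FALSE, seed = 1L,
                                shape = c(96, 160), noise_sigma = 0.05) {
  g <- .pixel_grid(shape)
  kid <- function(cx) {
    r2 <- ((g$x - shape[1] / 2) / (shape[1] * 0.32))^2 +
      ((g$y - cx) / (shape[2] * 0.17))^2
    list(organ = r2 <= 1, medulla = r2 <= 0.45, r2 = r2)
  }
  left <- kid(shape[2] * 0.28)
  right <- kid(shape[2] * 0.72)
  levels <- list(tubular_flow = c(medulla = 0.85, cortex = 0.20),
                 plasma_flow = c(medulla = 0.50, cortex = 0.50),
                 plasma_volume = c(medulla = 0.20, cortex = 0.85))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  channels <- lapply(names(levels), function(ch) {
    lv <- levels[[ch]]
    v <- matrix(0.05, shape[1], shape[2])
    for (k in list(left, right)) {
      v[k$organ] <- lv[["cortex"]]
      v[k$medulla] <- lv[["medulla"]]
    }
    if (disrupted) {
      idx <- which(right$organ)
      v[idx] <- v[sample(idx)]
    }
    v[] <- .add_noise(v, noise_sigma)
    parametric_map(v, channel_name = ch)
  })
  names(channels) <- names(levels)
  list(channels = channels,
       masks = list(left_cortex = left$organ & !left$medulla,
                    left_medulla = left$medulla,
                    right_cortex = right$organ & !right$medulla,
                    right_medulla = right$medulla))
}

#' Systematic test image sweeping a color map
#'
#' Renders every point of a `resolution^3` grid of the unit cube
#' through the map, arranged as a `resolution^2 x resolution` image,
#' for visual or statistical inspection of the map's color coverage.
#'
#' @param cmap a [build_colormap()] color map
#' @param resolution grid points per axis (>= 2)
#' @return a `fused_image` with `resolution^3` pixels
#' @export
make_colormap_test_image <- function(cmap, resolution = 8) {
  stopifnot(inherits(cmap, "trivariate_colormap"), resolution >= 2)
  g <- seq(0, 1, length.out = resolution)
  grid <- expand.grid(u = g, v = g, w = g)
  shape <- c(resolution^2, resolution)
  chan <- function(vals, nm)
    parametric_map(matrix(vals, shape[1], shape[2]), channel_name = nm)
  fuse_channels(chan(grid$u, "u"), chan(grid$v, "v"), chan(grid$w, "w"), cmap)
}
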