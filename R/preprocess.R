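# Slice selection, HU windowing, resizing and augmentation.
#
# Images are interpolated with cubic splines (Catmull-Rom for in-plane
# warps, natural splines for separable resizing); labels always use
# nearest-neighbour so masks stay exactly binary.

#' Hounsfield window specification
#'
#' The retained intensity band is `[level - width/2, level + width/2]`.
#' Defaults (width 420 HU, level 190 HU) give the clip range `[-20, 400]`,
#' chosen so that essentially all annotated vessel voxels fall inside the
#' window on contrast-enhanced liver CT.
#'
#' @param width window width in HU; must be positive.
#' @param level window level (centre) in HU.
#' @return A `window_spec` with fields `width`, `level`, `lo`, `hi`.
#' @export
window_spec <- function(width = 420, level = 190) {
  if (width <= 0) stop("window width must be > 0, got ", width)
  structure(list(width = width, level = level,
                 lo = level - width / 2, hi = level + width / 2),
            class = "window_spec")
}

#' Window a CT volume and normalize to [-1, 1]
#'
#' Voxels are clipped to the window's band and affinely mapped so the lower
#' clip bound becomes -1, the window level 0 and the upper bound +1 (the
#' tanh output range of the stage-1 generators). The map is monotone, and
#' the function is idempotent: a volume already in normalized units is
#' returned unchanged.
#'
#' @param volume a [ct_volume()] in HU.
#' @param spec a [window_spec()].
#' @return A [ct_volume()] in normalized units (attribute `units` set to
#'   `"normalized"`).
#' @export
window_and_normalize <- function(volume, spec = window_spec()) {
  if (identical(attr(volume, "units"), "normalized")) return(volume)
  v <- pmin(pmax(volume$voxels, spec$lo), spec$hi)
  v <- 2 * (v - spec$lo) / (spec$hi - spec$lo) - 1
  out <- ct_volume(array(v, dim = dim(volume$voxels)), spacing = volume$spacing,
                   phase = volume$phase, case_id = volume$case_id)
  attr(out, "units") <- "normalized"
  out
}

#' Fraction of labelled voxels inside the window band
#'
#' Diagnostic for window choice: the share of annotated vessel voxels whose
#' raw intensity lies strictly inside the clip range (voxels at or beyond
#' the bounds are saturated by windowing).
#'
#' @param volume a [ct_volume()] in HU.
#' @param label an aligned [label_volume()].
#' @param spec a [window_spec()].
#' @return Fraction in `[0, 1]`.
#' @export
label_window_coverage <- function(volume, label, spec = window_spec()) {
  check_aligned(volume, label)
  v <- volume$voxels[label$mask == 1]
  if (length(v) == 0) stop("label mask is empty")
  mean(v > spec$lo & v < spec$hi)
}

#' Restrict a volume to its vessel-annotated slice range
#'
#' Keeps only the z-range carrying annotations (plus an optional margin),
#' mirroring the fact that vessel labels are concentrated in the liver
#' slices of a full-abdomen scan. No annotated voxel is ever dropped.
#'
#' @param volume a [ct_volume()].
#' @param labels a [label_volume()] or list of them, aligned with `volume`.
#' @param margin extra slices to keep on each side (default 0).
#' @return List with the cropped `volume` and cropped `labels` (same class
#'   as supplied: single label in, single label out).
#' @export
crop_to_labeled_slices <- function(volume, labels, margin = 0L) {
  single <- inherits(labels, "label_volume")
  if (single) labels <- list(labels)
  for (l in labels) check_aligned(volume, l)
  nz <- sort(unique(unlist(lapply(labels, function(l)
    which(apply(l$mask, 1, sum) > 0)))))
  if (length(nz) == 0) stop("all label masks are empty; nothing to crop to")
  D <- dim(volume$voxels)[1]
  z0 <- max(1L, min(nz) - margin)
  z1 <- min(D, max(nz) + margin)
  vol <- ct_volume(volume$voxels[z0:z1, , , drop = FALSE], volume$spacing,
                   volume$phase, volume$case_id)
  attr(vol, "units") <- attr(volume, "units")
  labs <- lapply(labels, function(l)
    label_volume(l$mask[z0:z1, , , drop = FALSE], l$vessel_class, l$case_id))
  list(volume = vol, labels = if (single) labs[[1]] else labs)
}

# natural cubic-spline resampling of a length-n signal to length m, with
# pixel-centre alignment (the standard resize convention)
resample_spline <- function(y, m, nearest = FALSE) {
  n <- length(y)
  if (n == m) return(y)
  src <- (seq_len(m) - 0.5) * n / m - 0.5     # 0-based source coords
  if (nearest) {
    idx <- pmin(pmax(round(src), 0), n - 1)
    return(y[idx + 1])
  }
  spline(x = 0:(n - 1), y = y, xout = src, method = "natural")$y
}

resize_plane <- function(mat, out_hw, nearest = FALSE) {
  tmp <- apply(mat, 2, resample_spline, m = out_hw[1], nearest = nearest)
  tmp <- matrix(tmp, nrow = out_hw[1])
  t(apply(tmp, 1, resample_spline, m = out_hw[2], nearest = nearest))
}

#' Resize each slice of a volume (and its labels) in-plane
#'
#' Image slices are resampled with cubic-spline interpolation; label masks
#' with nearest-neighbour, so they remain exactly binary. The in-plane
#' voxel spacing is rescaled by the inverse zoom (512 -> 352 multiplies the
#' spacing by 512/352). The default target recovers GPU-era memory savings
#' while keeping few-pixel vessels resolvable.
#'
#' @param volume a [ct_volume()].
#' @param labels optional [label_volume()] or list of them.
#' @param out_hw target in-plane size `(H, W)`, default `c(352, 352)`.
#' @return If `labels` is `NULL`, the resized volume; otherwise a list
#'   `(volume, labels)`.
#' @export
resize_slicewise <- function(volume, labels = NULL, out_hw = c(352L, 352L)) {
  d <- dim(volume$voxels)
  if (d[2] / out_hw[1] != d[3] / out_hw[2])
    message("non-isotropic in-plane rescale: ", d[2], "x", d[3], " -> ",
            out_hw[1], "x", out_hw[2])
  vox <- array(0, dim = c(d[1], out_hw))
  for (z in seq_len(d[1]))
    vox[z, , ] <- resize_plane(volume$voxels[z, , ], out_hw)
  sp <- volume$spacing * c(1, d[2] / out_hw[1], d[3] / out_hw[2])
  vol <- ct_volume(vox, sp, volume$phase, volume$case_id)
  attr(vol, "units") <- attr(volume, "units")
  if (is.null(labels)) return(vol)
  single <- inherits(labels, "label_volume")
  if (single) labels <- list(labels)
  labs <- lapply(labels, function(l) {
    check_aligned(volume, l)
    m <- array(0, dim = c(d[1], out_hw))
    for (z in seq_len(d[1]))
      m[z, , ] <- resize_plane(l$mask[z, , ], out_hw, nearest = TRUE)
    label_volume(m, l$vessel_class, l$case_id)
  })
  list(volume = vol, labels = if (single) labs[[1]] else labs)
}

#' Augmentation specification
#'
#' In-plane random rotation (simulating small body twists between
#' acquisitions) and random isotropic scaling (simulating subject girth).
#' Magnitudes default to +/-10 degrees and 0.9-1.1x.
#'
#' @param max_rotation_deg rotation bound in degrees, `>= 0`.
#' @param scale_range multiplicative `(low, high)` with `low <= 1 <= high`.
#' @param seed optional integer; when set, [augment()] reseeds the RNG so
#'   its draw is reproducible call-for-call.
#' @return An `augment_spec`.
#' @export
augment_spec <- function(max_rotation_deg = 10, scale_range = c(0.9, 1.1),
                         seed = NULL) {
  if (max_rotation_deg < 0) stop("rotation bound must be >= 0")
  if (!(scale_range[1] <= 1 && 1 <= scale_range[2]))
    stop("scale_range must bracket 1")
  structure(list(max_rotation_deg = max_rotation_deg,
                 scale_range = scale_range, seed = seed),
            class = "augment_spec")
}

#' Randomly rotate and scale an image patch with its mask
#'
#' One rotation angle and one scale factor are drawn and applied in-plane
#' to every slice of both patch and mask. The image is resampled bicubically
#' with reflection padding (no empty corners); the mask nearest-neighbour,
#' so it stays binary.
#'
#' @param patch image `patch3d` (or plain rank-3 array).
#' @param mask aligned mask `patch3d` (or rank-3 array of 0/1).
#' @param spec an [augment_spec()].
#' @return List `(patch, mask)` of the same types as the inputs.
#' @export
augment <- function(patch, mask, spec = augment_spec()) {
  if (!is.null(spec$seed)) set.seed(spec$seed)
  theta <- runif(1, -spec$max_rotation_deg, spec$max_rotation_deg) * pi / 180
  scale <- runif(1, spec$scale_range[1], spec$scale_range[2])
  parr <- if (is.list(patch)) patch$voxels else patch
  marr <- if (is.list(mask)) mask$voxels else mask
  stopifnot(identical(dim(parr), dim(marr)))
  if (theta == 0 && scale == 1) return(list(patch = patch, mask = mask))
  # inverse map: output pixel -> source location (rotate by -theta, unzoom)
  A <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)),
              2, 2) / scale
  D <- dim(parr)[1]
  pout <- parr; mout <- marr
  for (z in seq_len(D)) {
    pout[z, , ] <- .warp_affine2d(parr[z, , ], A, 1L)
    mout[z, , ] <- .warp_affine2d(marr[z, , ], A, 0L)
  }
  if (is.list(patch)) patch$voxels <- pout else patch <- pout
  if (is.list(mask)) mask$voxels <- mout else mask <- mout
  list(patch = patch, mask = mask)
}

#' Read a pipeline configuration file
#'
#' YAML with optional blocks `preprocess:` (window width/level, out size,
#' augmentation, seed), `vra:` and `seg:`; missing entries fall back to the
#' package defaults.
#'
#' @param path YAML file.
#' @return Nested list of configuration values.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  yaml::read_yaml(path)
}

#' @rdname read_config
#' @param cfg list from [read_config()] (its `preprocess` block or the
#'   full config).
#' @export
preprocess_config <- function(cfg = list()) {
  p <- if (!is.null(cfg$preprocess)) cfg$preprocess else cfg
  list(window = window_spec(width = p$window_width %||% 420,
                            level = p$window_level %||% 190),
       out_hw = p$out_hw %||% c(352L, 352L),
       augment = augment_spec(
         max_rotation_deg = p$max_rotation_deg %||% 10,
         scale_range = unlist(p$scale_range %||% c(0.9, 1.1)),
         seed = p$seed),
       margin = p$margin %||% 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
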