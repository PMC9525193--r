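# Synthetic two-phase liver-vessel phantoms.
#
# The clinical premise being emulated: the same vascular anatomy is imaged
# twice — arteries bright in the arterial phase, veins bright in the venous
# phase, each class barely visible in the other phase — and the patient
# moves slightly between acquisitions, so the two phases are related by a
# smooth deformation, not a rigid shift. Labels exist only for the bright
# class of each phase.

MURRAY_TAPER <- 0.79   # child/parent radius ratio at a symmetric bifurcation

#' Phantom dataset specification
#'
#' Defaults mirror a contrast-enhanced liver acquisition: 512x512 slices at
#' 0.8 mm in-plane spacing and 0.9 mm slice thickness, pseudo-HU contrasts
#' inside the default CT window `[-20, 400]`, branching trees whose finest
#' branches are only 1-2 voxels in radius. Tests pass smaller `shape`s
#' explicitly.
#'
#' @param shape volume dimensions `(D, H, W)` in voxels.
#' @param n_trees number of vessel trees per class.
#' @param branching_depth bifurcation generations per tree.
#' @param radius_root,radius_min root and minimum branch radius, voxels.
#' @param artery_contrast `(vessel_mean, background_mean)` pseudo-HU for the
#'   arterial phase.
#' @param vein_contrast same for the venous phase.
#' @param cross_artery_frac fraction of full artery contrast retained in the
#'   venous phase (arteries are faint there).
#' @param cross_vein_frac fraction of full vein contrast visible in the
#'   arterial phase.
#' @param noise_sd additive Gaussian noise, pseudo-HU.
#' @param deformation_amp peak smooth inter-phase displacement, voxels.
#' @param spacing voxel spacing `(dz, dy, dx)` in mm.
#' @param seed RNG seed; generation is fully reproducible from (spec, seed).
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(96L, 512L, 512L), n_trees = 2L,
                         branching_depth = 7L, radius_root = 8,
                         radius_min = 1, artery_contrast = c(300, 60),
                         vein_contrast = c(220, 80),
                         cross_artery_frac = 0.3, cross_vein_frac = 0.1,
                         noise_sd = 15, deformation_amp = 2,
                         spacing = c(0.9, 0.8, 0.8), seed = 1L) {
  if (radius_min < 1) stop("radius_min must be >= 1 voxel")
  if (radius_root >= min(shape[2], shape[3]) / 4)
    stop("infeasible geometry: root radius ", radius_root,
         " >= min(H, W)/4 = ", min(shape[2], shape[3]) / 4)
  structure(list(shape = as.integer(shape), n_trees = as.integer(n_trees),
                 branching_depth = as.integer(branching_depth),
                 radius_root = radius_root, radius_min = radius_min,
                 artery_contrast = artery_contrast,
                 vein_contrast = vein_contrast,
                 cross_artery_frac = cross_artery_frac,
                 cross_vein_frac = cross_vein_frac,
                 noise_sd = noise_sd, deformation_amp = deformation_amp,
                 spacing = spacing, seed = as.integer(seed)),
            class = "phantom_spec")
}

# rasterize a capsule (line segment with radius) into mask, in-place
draw_capsule <- function(mask, p0, p1, r) {
  d <- dim(mask)
  lo <- pmax(floor(pmin(p0, p1) - r - 1), c(1, 1, 1))
  hi <- pmin(ceiling(pmax(p0, p1) + r + 1), d)
  if (any(lo > hi)) return(mask)
  zs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; xs <- lo[3]:hi[3]
  g <- expand.grid(z = zs, y = ys, x = xs)
  v <- p1 - p0
  len2 <- sum(v^2)
  w <- cbind(g$z - p0[1], g$y - p0[2], g$x - p0[3])
  t <- if (len2 > 0) pmin(pmax(as.numeric(w %*% v) / len2, 0), 1) else 0
  closest <- cbind(p0[1] + t * v[1], p0[2] + t * v[2], p0[3] + t * v[3])
  dist2 <- (g$z - closest[, 1])^2 + (g$y - closest[, 2])^2 +
           (g$x - closest[, 3])^2
  inside <- dist2 <= r^2
  if (any(inside))
    mask[cbind(g$z, g$y, g$x)[inside, , drop = FALSE]] <- 1
  mask
}

# random unit vector within `cone_deg` of `dir`
jitter_dir <- function(dir, cone_deg) {
  repeat {
    u <- rnorm(3)
    u <- u / sqrt(sum(u^2))
    cand <- dir + tan(runif(1, 0, cone_deg * pi / 180)) * (u - sum(u * dir) * dir)
    n <- sqrt(sum(cand^2))
    if (n > 1e-8) return(cand / n)
  }
}

#' Grow a random branching vessel tree
#'
#' Recursive bifurcation: each branch runs a jittered straight segment, then
#' splits in two with radii shrunk by the Murray-law factor 0.79 per
#' generation (floored at `radius_min`), producing the multi-scale taper of
#' real hepatic trees down to branches 1-2 voxels across. The tree is
#' connected by construction and voxelized as overlapping capsules.
#'
#' @param spec a [phantom_spec()].
#' @param vessel_class `"artery"` or `"vein"`.
#' @param case_id case identifier.
#' @return A [label_volume()]; attribute `radii` holds every drawn branch
#'   radius (generation order).
#' @export
grow_vessel_tree <- function(spec, vessel_class = "artery",
                             case_id = "phantom") {
  set.seed(spec$seed + ifelse(vessel_class == "artery", 0L, 100003L))
  d <- spec$shape
  mask <- array(0, dim = d)
  radii <- numeric(0)
  seg_len <- max(3, d[1] / (spec$branching_depth + 1))
  grow <- function(p0, dir, r, generation) {
    len <- seg_len * runif(1, 0.7, 1.2)
    p1 <- p0 + dir * len
    p1 <- pmin(pmax(p1, r + 1), d - r)   # stay inside the volume
    mask <<- draw_capsule(mask, p0, p1, r)
    radii <<- c(radii, r)
    if (generation >= spec$branching_depth) return(invisible(NULL))
    r2 <- max(r * MURRAY_TAPER, spec$radius_min)
    for (k in 1:2) grow(p1, jitter_dir(dir, 35), r2, generation + 1)
    invisible(NULL)
  }
  for (t in seq_len(spec$n_trees)) {
    p0 <- c(2, runif(1, 0.3, 0.7) * d[2], runif(1, 0.3, 0.7) * d[3])
    dir <- c(1, rnorm(1, 0, 0.2), rnorm(1, 0, 0.2))
    dir <- dir / sqrt(sum(dir^2))
    grow(p0, dir, spec$radius_root, 1)
  }
  out <- label_volume(mask, vessel_class = vessel_class, case_id = case_id)
  attr(out, "radii") <- radii
  out
}

# smooth random displacement field with peak amplitude `amp` voxels:
# coarse white noise upsampled by natural splines along each axis
smooth_field <- function(d, amp) {
  if (amp == 0) return(array(0, dim = d))
  cd <- pmax(c(3L, 3L, 3L), ceiling(d / 16))
  f <- array(rnorm(prod(cd)), dim = cd)
  g <- array(0, dim = c(d[1], cd[2], cd[3]))
  for (j in seq_len(cd[2])) for (k in seq_len(cd[3]))
    g[, j, k] <- resample_spline(f[, j, k], d[1])
  h <- array(0, dim = c(d[1], d[2], cd[3]))
  for (i in seq_len(d[1])) for (k in seq_len(cd[3]))
    h[i, , k] <- resample_spline(g[i, , k], d[2])
  out <- array(0, dim = d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2]))
    out[i, j, ] <- resample_spline(h[i, j, ], d[3])
  out / max(abs(out)) * amp
}

warp_mask <- function(mask, dy, dx) {
  d <- dim(mask)
  zi <- slice.index(mask, 1)
  yi <- pmin(pmax(round(slice.index(mask, 2) - dy), 1), d[2])
  xi <- pmin(pmax(round(slice.index(mask, 3) - dx), 1), d[3])
  array(mask[cbind(as.vector(zi), as.vector(yi), as.vector(xi))], dim = d)
}

#' Render the two CT phases of a phantom case
#'
#' The arterial phase shows arteries at full contrast and veins near
#' background; the venous phase shows veins at full contrast and arteries at
#' `cross_artery_frac` of theirs, after displacing all vessels by a smooth
#' random deformation (respiration / body-position shift between the two
#' acquisitions). Gaussian noise is added to both phases.
#'
#' @param artery,vein [label_volume()]s sharing the phase-A geometry.
#' @param spec a [phantom_spec()].
#' @param case_id case identifier.
#' @return List: `vol_a`, `vol_b` ([ct_volume()]s, pseudo-HU),
#'   `label_a` (arteries, phase-A geometry), `label_b` (veins, phase-B
#'   geometry), and `artery_b` (arteries warped to phase-B geometry — the
#'   cross-phase ground truth a radiologist would have to annotate by hand).
#' @export
render_phases <- function(artery, vein, spec, case_id = artery$case_id) {
  stopifnot(identical(dim(artery$mask), dim(vein$mask)))
  ws <- window_spec()
  means <- c(spec$artery_contrast, spec$vein_contrast)
  if (any(means < ws$lo | means > ws$hi))
    warning("contrast means outside the CT window [", ws$lo, ", ", ws$hi,
            "]; vessels would be clipped away by preprocessing")
  set.seed(spec$seed + 7L)
  d <- spec$shape
  dy <- smooth_field(d, spec$deformation_amp)
  dx <- smooth_field(d, spec$deformation_amp)
  artery_b <- warp_mask(artery$mask, dy, dx)
  vein_b <- warp_mask(vein$mask, dy, dx)

  bg_a <- spec$artery_contrast[2]; bg_b <- spec$vein_contrast[2]
  vein_in_a <- bg_a + spec$cross_vein_frac *
    (spec$vein_contrast[1] - spec$vein_contrast[2])
  artery_in_b <- bg_b + spec$cross_artery_frac *
    (spec$artery_contrast[1] - spec$artery_contrast[2])

  img_a <- array(bg_a, dim = d)
  img_a[vein$mask == 1] <- vein_in_a
  img_a[artery$mask == 1] <- spec$artery_contrast[1]   # native class on top
  img_b <- array(bg_b, dim = d)
  img_b[artery_b == 1] <- artery_in_b
  img_b[vein_b == 1] <- spec$vein_contrast[1]
  if (spec$noise_sd > 0) {
    img_a <- img_a + array(rnorm(prod(d), 0, spec$noise_sd), dim = d)
    img_b <- img_b + array(rnorm(prod(d), 0, spec$noise_sd), dim = d)
  }
  list(vol_a = ct_volume(img_a, spec$spacing, "arterial", case_id),
       vol_b = ct_volume(img_b, spec$spacing, "venous", case_id),
       label_a = label_volume(artery$mask, "artery", case_id),
       label_b = label_volume(vein_b, "vein", case_id),
       artery_b = label_volume(artery_b, "artery", case_id))
}

#' Generate one complete phantom case
#'
#' @param spec a [phantom_spec()]; its `seed` is offset by `case_index` so
#'   cases differ but the dataset is reproducible as a whole.
#' @param case_index integer; also forms the case id `phantom###`.
#' @return As [render_phases()].
#' @export
phantom_case <- function(spec, case_index = 1L) {
  spec$seed <- spec$seed + 1000L * as.integer(case_index)
  cid <- sprintf("phantom%03d", case_index)
  artery <- grow_vessel_tree(spec, "artery", cid)
  vein <- grow_vessel_tree(spec, "vein", cid)
  render_phases(artery, vein, spec, cid)
}

#' Generate a phantom dataset on disk
#'
#' Writes NIfTI files under the package naming convention:
#' `{case}_arterial.nii.gz`, `{case}_venous.nii.gz`,
#' `{case}_artery_label.nii.gz` (phase-A geometry),
#' `{case}_vein_label.nii.gz` (phase-B geometry).
#'
#' @param spec a [phantom_spec()].
#' @param dir output directory (created if needed).
#' @param n_cases number of cases.
#' @return Tibble of written file paths, invisibly.
#' @export
write_phantom_dataset <- function(spec, dir, n_cases = 6L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_len(n_cases), function(i) {
    cs <- phantom_case(spec, i)
    cid <- cs$vol_a$case_id
    write_volume(cs$vol_a, volume_path(dir, cid, "arterial"))
    write_volume(cs$vol_b, volume_path(dir, cid, "venous"))
    write_label(cs$label_a, label_path(dir, cid, "artery"), spec$spacing)
    write_label(cs$label_b, label_path(dir, cid, "vein"), spec$spacing)
    tibble::tibble(case_id = cid,
                   arterial = volume_path(dir, cid, "arterial"),
                   venous = volume_path(dir, cid, "venous"))
  })
  invisible(dplyr::bind_rows(rows))
}

#' Standardized vessel/background intensity separation
#'
#' Two-sample separation statistic (difference of means over pooled SD)
#' between voxels inside and outside a vessel mask — large when the vessel
#' class is conspicuous in a phase, near zero when it is hidden.
#'
#' @param volume a [ct_volume()].
#' @param label an aligned [label_volume()].
#' @return Numeric scalar.
#' @export
vessel_separation <- function(volume, label) {
  check_aligned(volume, label)
  inside <- volume$voxels[label$mask == 1]
  outside <- volume$voxels[label$mask == 0]
  sp <- sqrt((stats::var(inside) + stats::var(outside)) / 2)
  (mean(inside) - mean(outside)) / sp
}
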