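#' @useDynLib vesselda, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif setNames spline sd
NULL

PHASES <- c("arterial", "venous", "pseudo_venous", "pseudo_arterial")
VESSEL_CLASSES <- c("artery", "vein")

#' CT volume container
#'
#' A `ct_volume` wraps a rank-3 voxel array in `(z, y, x)` order (z is the
#' slice index, counted from the top of the scan), together with the voxel
#' spacing in millimetres and an acquisition-phase tag. Intensities are in
#' Hounsfield units before preprocessing and in normalized `[-1, 1]` units
#' after [window_and_normalize()].
#'
#' @param voxels numeric rank-3 array, axis order `(z, y, x)`.
#' @param spacing numeric length-3, `(dz, dy, dx)` in mm; strictly positive.
#' @param phase one of `"arterial"`, `"venous"`, `"pseudo_venous"`,
#'   `"pseudo_arterial"`.
#' @param case_id character scalar identifying the subject.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1), phase = "venous",
                      case_id = "case") {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L)
    stop("voxels must have rank 3, got rank ", length(dim(voxels)))
  if (any(!is.finite(voxels)))
    stop("voxels contain non-finite values")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 strictly positive values (dz, dy, dx)")
  phase <- match.arg(phase, PHASES)
  structure(list(voxels = voxels, spacing = spacing, phase = phase,
                 case_id = as.character(case_id)),
            class = "ct_volume")
}

#' Binary vessel label volume
#'
#' A mask aligned voxel-for-voxel with its `ct_volume`; values are exactly
#' 0 or 1 and stay binary through every resampling step in the pipeline
#' (labels are always resampled nearest-neighbour).
#'
#' @param mask rank-3 array of 0/1 values, `(z, y, x)` order.
#' @param vessel_class `"artery"` or `"vein"`.
#' @param case_id character scalar.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(mask, vessel_class = "vein", case_id = "case") {
  mask <- as.array(mask)
  if (length(dim(mask)) != 3L)
    stop("mask must have rank 3, got rank ", length(dim(mask)))
  if (!all(mask %in% c(0, 1)))
    stop("mask values must be exactly 0 or 1")
  vessel_class <- match.arg(vessel_class, VESSEL_CLASSES)
  structure(list(mask = mask, vessel_class = vessel_class,
                 case_id = as.character(case_id)),
            class = "label_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume %s> phase=%s dim=%s spacing=%s mm range=[%.3g, %.3g]\n",
              x$case_id, x$phase, paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume %s> class=%s dim=%s foreground=%d voxels\n",
              x$case_id, x$vessel_class, paste(dim(x$mask), collapse = "x"),
              sum(x$mask)))
  invisible(x)
}

check_aligned <- function(volume, label) {
  if (!identical(dim(volume$voxels), dim(label$mask)))
    stop("label mask shape (", paste(dim(label$mask), collapse = "x"),
         ") does not match volume shape (",
         paste(dim(volume$voxels), collapse = "x"), ")")
  invisible(TRUE)
}

# ---------------------------------------------------------------- NIfTI I/O

# The pipeline's native layout is (z, y, x); NIfTI stores (x, y, z) fastest-
# first, so arrays are transposed on the way in and out. Files written by
# this package carry an identity orientation, so read(write(v)) is exact.

#' Read a CT volume from a NIfTI file
#'
#' @param path a `.nii` / `.nii.gz` file containing a rank-3 image.
#' @param phase phase tag to attach (the file format does not record it).
#' @param case_id optional case id; default is derived from the file name.
#' @return A [ct_volume()].
#' @export
read_volume <- function(path, phase = "venous", case_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop("rank ", length(dim(arr)), ", expected 3: ", path)
  if (any(!is.finite(arr)))
    stop("non-finite voxels in ", path)
  pd <- RNifti::pixdim(img)            # (dx, dy, dz)
  if (is.null(case_id))
    case_id <- sub("(_[a-z_]+)?\\.nii(\\.gz)?$", "", basename(path))
  ct_volume(aperm(arr, c(3, 2, 1)), spacing = rev(pd[1:3]), phase = phase,
            case_id = case_id)
}

#' Write a CT volume to a NIfTI file
#'
#' @param volume a [ct_volume()].
#' @param path output `.nii` / `.nii.gz` path.
#' @param datatype NIfTI storage type; `"float"` for images, `"int16"` for
#'   raw HU volumes.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, datatype = "float") {
  arr <- aperm(volume$voxels, c(3, 2, 1))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rev(volume$spacing)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a vessel label volume from a NIfTI file
#'
#' @param path NIfTI file with 0/1 voxel values.
#' @param vessel_class `"artery"` or `"vein"`.
#' @param case_id optional case id (default: from file name).
#' @return A [label_volume()].
#' @export
read_label <- function(path, vessel_class, case_id = NULL) {
  v <- read_volume(path, phase = "venous", case_id = case_id)
  label_volume(v$voxels, vessel_class = vessel_class, case_id = v$case_id)
}

#' Write a vessel label volume to a NIfTI file
#' @param label a [label_volume()].
#' @param path output path.
#' @param spacing voxel spacing `(dz, dy, dx)` to record in the header.
#' @return `path`, invisibly.
#' @export
write_label <- function(label, path, spacing = c(1, 1, 1)) {
  v <- ct_volume(label$mask, spacing = spacing, phase = "venous",
                 case_id = label$case_id)
  write_volume(v, path, datatype = "uint8")
}

#' File names under the package's naming convention
#'
#' Volumes are stored as `{case_id}_{phase}.nii.gz` and labels as
#' `{case_id}_{vessel_class}_label.nii.gz`.
#'
#' @param dir directory.
#' @param case_id case identifier.
#' @param phase phase tag (for volumes).
#' @param vessel_class vessel class (for labels).
#' @return A file path.
#' @export
volume_path <- function(dir, case_id, phase) {
  file.path(dir, sprintf("%s_%s.nii.gz", case_id, phase))
}

#' @rdname volume_path
#' @export
label_path <- function(dir, case_id, vessel_class) {
  file.path(dir, sprintf("%s_%s_label.nii.gz", case_id, vessel_class))
}

# ------------------------------------------------------------------ patches

#' Patch start indices along the slice axis
#'
#' Patches of depth `patch_depth` are taken from top to bottom at multiples
#' of `stride`; the top-aligned (start 0) and bottom-aligned
#' (start `depth - patch_depth`) patches are always included and exact
#' coincidences deduplicated, so the union of patches covers every slice and
#' at least two patches exist whenever `depth > patch_depth`.
#'
#' @param depth number of slices in the source volume.
#' @param patch_depth patch size along z (default 96).
#' @param stride step between consecutive patch starts (default 80).
#' @return Sorted integer vector of 0-based start indices.
#' @export
patch_starts <- function(depth, patch_depth = 96L, stride = 80L) {
  if (depth < patch_depth)
    stop("volume depth ", depth, " < patch depth ", patch_depth,
         "; pad the volume before patch extraction")
  s <- seq.int(0L, by = as.integer(stride), length.out = depth)  # overshoot ok
  s <- s[s + patch_depth <= depth]
  sort(unique(c(s, as.integer(depth - patch_depth))))
}

#' Extract overlapping 3D patches from a volume
#'
#' @param volume a [ct_volume()] (or a [label_volume()], patched identically).
#' @param patch_depth patch size along z.
#' @param stride step between patch starts.
#' @return List of `patch3d` objects, each holding `voxels` (depth
#'   `patch_depth`), its 0-based `start_z` and the `case_id`.
#' @export
extract_patches <- function(volume, patch_depth = 96L, stride = 80L) {
  arr <- if (inherits(volume, "label_volume")) volume$mask else volume$voxels
  D <- dim(arr)[1]
  starts <- patch_starts(D, patch_depth, stride)
  lapply(starts, function(s0) {
    structure(list(voxels = arr[(s0 + 1):(s0 + patch_depth), , , drop = FALSE],
                   start_z = s0, case_id = volume$case_id),
              class = "patch3d")
  })
}

#' Stitch per-patch predictions back into a full volume
#'
#' Overlapping predictions are combined voxelwise by their mean (default) or
#' maximum.
#'
#' @param patches list of `patch3d` objects whose `voxels` hold the
#'   prediction (probabilities in `[0, 1]`).
#' @param depth slice count of the target volume.
#' @param combine `"mean"` or `"max"`.
#' @return Rank-3 probability array of depth `depth`.
#' @export
stitch_patches <- function(patches, depth, combine = c("mean", "max")) {
  combine <- match.arg(combine)
  hw <- dim(patches[[1]]$voxels)[2:3]
  acc <- array(if (combine == "mean") 0 else -Inf, dim = c(depth, hw))
  cnt <- numeric(depth)
  for (p in patches) {
    pd <- dim(p$voxels)[1]
    if (p$start_z < 0 || p$start_z + pd > depth)
      stop("patch at start_z=", p$start_z, " exceeds depth ", depth)
    idx <- (p$start_z + 1):(p$start_z + pd)
    if (combine == "mean") acc[idx, , ] <- acc[idx, , ] + p$voxels
    else acc[idx, , ] <- pmax(acc[idx, , ], p$voxels)
    cnt[idx] <- cnt[idx] + 1
  }
  if (any(cnt == 0))
    stop("slices not covered by any patch: ",
         paste(which(cnt == 0) - 1, collapse = ", "))
  if (combine == "mean") acc <- acc / array(cnt, dim = dim(acc))
  acc
}
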