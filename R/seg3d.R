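# Stage 2: 3D U-shaped segmentation network trained with soft Dice plus an
# orthogonal depth-projection similarity loss. Projecting the predicted and
# true vessel masks onto the three coordinate planes and comparing the
# (flattened) projections by cosine similarity constrains the global 3D
# geometry of the tree — a signal a voxelwise overlap loss does not carry.

DICE_EPS <- 1e-5
PROJ_EPS <- 1e-8

#' Segmentation network configuration
#'
#' @param patch_shape training patch `(D, H, W)`; every dimension must be
#'   divisible by 16 so four resolution halvings fit. The clinical-scale
#'   default is `(96, 352, 352)`; phantom-scale work uses `(32, 32, 32)`.
#' @param base_channels first-level channel count (default 16).
#' @param lambda_ps weight of the projection-similarity loss (default 1).
#' @param epochs,steps_per_epoch,lr training schedule (Adam, betas 0.9 /
#'   0.999).
#' @param seed RNG seed.
#' @return A `seg_config`.
#' @export
seg_config <- function(patch_shape = c(96L, 352L, 352L), base_channels = 16L,
                       lambda_ps = 1.0, epochs = 50L, steps_per_epoch = 20L,
                       lr = 1e-3, seed = 1L) {
  if (any(patch_shape %% 16L != 0L))
    stop("patch_shape must be divisible by 16 in every dimension (four ",
         "resolution halvings); got ", paste(patch_shape, collapse = "x"))
  if (lambda_ps < 0) stop("lambda_ps must be >= 0")
  structure(list(patch_shape = as.integer(patch_shape),
                 base_channels = as.integer(base_channels),
                 lambda_ps = lambda_ps, epochs = as.integer(epochs),
                 steps_per_epoch = as.integer(steps_per_epoch), lr = lr,
                 seed = as.integer(seed)),
            class = "seg_config")
}

# ------------------------------------------------------------ projections --

#' Orthogonal depth projection of a 3D mask
#'
#' Sums the mask along one coordinate axis (x, y or z of the `(z, y, x)`
#' array), yielding the density matrix over the two remaining axes, and
#' flattens it row-major (later axis fastest). Works on soft probability
#' masks, so the operation is differentiable end to end; mass is conserved:
#' each projection sums to the total mask mass.
#'
#' @param mask rank-3 array with values in `[0, 1]`.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @return Numeric vector (the flattened density matrix).
#' @export
depth_project <- function(mask, axis = c("z", "y", "x")) {
  if (length(dim(mask)) != 3L)
    stop("mask must have rank 3, got rank ", length(dim(mask)))
  axis <- match.arg(axis)
  m <- switch(axis,
              z = colSums(mask),                            # (y, x)
              y = rowSums(aperm(mask, c(1, 3, 2)), dims = 2), # (z, x)
              x = rowSums(mask, dims = 2))                  # (z, y)
  as.vector(t(m))
}

#' Projection-similarity loss
#'
#' `1 - mean of the cosine similarities` between the three axis projections
#' of prediction and truth. Zero iff all three projection pairs are
#' parallel. Degenerate axes: two empty projections count as similarity 1
#' (identical emptiness), exactly one empty counts as 0; norms are
#' epsilon-stabilized so gradients stay finite.
#'
#' @param X predicted soft mask, values in `[0, 1]`.
#' @param Y ground-truth mask of the same shape.
#' @return Scalar in `[0, 1]` for non-negative inputs.
#' @export
projection_similarity_loss <- function(X, Y) {
  stopifnot(identical(dim(X), dim(Y)))
  cs <- vapply(c("x", "y", "z"), function(ax) {
    px <- depth_project(X, ax); py <- depth_project(Y, ax)
    nx <- sqrt(sum(px^2)); ny <- sqrt(sum(py^2))
    if (nx == 0 && ny == 0) return(1)
    if (nx == 0 || ny == 0) return(0)
    sum(px * py) / (nx * ny)
  }, numeric(1))
  1 - mean(cs)
}

# gradient of projection_similarity_loss wrt X, as a full array
proj_loss_grad <- function(X, Y) {
  d <- dim(X)
  g <- array(0, dim = d)
  for (ax in c("x", "y", "z")) {
    px <- depth_project(X, ax); py <- depth_project(Y, ax)
    nx <- sqrt(sum(px^2)); ny <- sqrt(sum(py^2))
    if (ny == 0 || nx == 0) next          # flat region of the convention
    co <- sum(px * py) / (nx * ny)
    gp <- -(py / (nx * ny) - co * px / (nx^2 + PROJ_EPS)) / 3
    # unflatten (row-major) and broadcast back along the summed axis
    gm <- switch(ax,
                 z = t(matrix(gp, d[3], d[2])),   # (y, x)
                 y = t(matrix(gp, d[3], d[1])),   # (z, x)
                 x = t(matrix(gp, d[2], d[1])))   # (z, y)
    g <- g + switch(ax,
                    z = aperm(array(gm, c(d[2], d[3], d[1])), c(3, 1, 2)),
                    y = aperm(array(gm, c(d[1], d[3], d[2])), c(1, 3, 2)),
                    x = array(gm, d))
  }
  g
}

#' Soft Dice loss
#'
#' `1 - (2 sum(XY) + eps) / (sum(X) + sum(Y) + eps)`, the standard
#' differentiable relaxation of the Dice overlap; `eps = 1e-5` guards the
#' empty-empty case.
#'
#' @param X predicted soft mask.
#' @param Y ground-truth mask of the same shape.
#' @return Scalar in `[0, 1]`.
#' @export
dice_loss <- function(X, Y) {
  stopifnot(identical(dim(X), dim(Y)))
  1 - (2 * sum(X * Y) + DICE_EPS) / (sum(X) + sum(Y) + DICE_EPS)
}

dice_loss_grad <- function(X, Y) {
  den <- sum(X) + sum(Y) + DICE_EPS
  num <- 2 * sum(X * Y) + DICE_EPS
  array(-(2 * Y * den - num) / den^2, dim = dim(X))
}

#' Combined segmentation loss
#'
#' `dice + lambda_ps * projection_similarity`; the components are reported
#' separately.
#'
#' @param X predicted soft mask.
#' @param Y ground-truth mask.
#' @param config a [seg_config()] (only `lambda_ps` is used).
#' @return List `(total, dice, ps)`.
#' @export
seg_loss <- function(X, Y, config = seg_config()) {
  ld <- dice_loss(X, Y)
  lp <- projection_similarity_loss(X, Y)
  list(total = ld + config$lambda_ps * lp, dice = ld, ps = lp)
}

seg_loss_grad <- function(X, Y, lambda_ps) {
  g <- dice_loss_grad(X, Y)
  if (lambda_ps > 0) g <- g + lambda_ps * proj_loss_grad(X, Y)
  g
}

# ------------------------------------------------------------------ U-Net --

unet_channels <- function(base) c(base, 2L * base, 4L * base, 8L * base,
                                  16L * base)

#' Build the 3D U-shaped segmentation network
#'
#' Four downsampling levels, each two 3x3x3 convolutions with batch
#' normalization and ReLU followed by 2x2x2 max-pooling; a two-conv
#' bottleneck; four upsampling levels that splice the matching encoder
#' features onto the upsampled ones before two more convolutions; and a
#' 1x1x1 sigmoid output at input resolution. Channel widths double per
#' level from `base_channels`.
#'
#' @param config a [seg_config()].
#' @return A `unet3d` object (parameters + config).
#' @export
build_unet3d <- function(config = seg_config()) {
  ch <- unet_channels(config$base_channels)
  params <- list()
  cin <- 1L
  for (l in 1:4) {
    params <- init_conv(params, sprintf("enc%d.1", l), cin, ch[l], 3L, TRUE,
                        nd = 3L)
    params <- init_conv(params, sprintf("enc%d.2", l), ch[l], ch[l], 3L, TRUE,
                        nd = 3L)
    cin <- ch[l]
  }
  params <- init_conv(params, "mid.1", ch[4], ch[5], 3L, TRUE, nd = 3L)
  params <- init_conv(params, "mid.2", ch[5], ch[5], 3L, TRUE, nd = 3L)
  for (l in 4:1) {
    params <- init_conv(params, sprintf("up%d", l), ch[l + 1], ch[l], 3L, TRUE,
                        nd = 3L)
    params <- init_conv(params, sprintf("dec%d.1", l), 2L * ch[l], ch[l], 3L,
                        TRUE, nd = 3L)
    params <- init_conv(params, sprintf("dec%d.2", l), ch[l], ch[l], 3L, TRUE,
                        nd = 3L)
  }
  params <- init_conv(params, "head", ch[1], 1L, 1L, FALSE, nd = 3L)
  buffers <- list()
  for (nm in grep("\\.g$", names(params), value = TRUE)) {
    base <- sub("\\.g$", "", nm)
    buffers[[paste0(base, ".rm")]] <- numeric(length(params[[nm]]))
    buffers[[paste0(base, ".rv")]] <- rep(1, length(params[[nm]]))
  }
  structure(list(params = params, buffers = buffers, config = config),
            class = "unet3d")
}

#' @export
print.unet3d <- function(x, ...) {
  cat(sprintf("<unet3d> base=%d lambda_ps=%g parameters=%d\n",
              x$config$base_channels, x$config$lambda_ps,
              sum(vapply(x$params, length, 1L))))
  invisible(x)
}

cu3_f <- function(p, name, x, k = 3L, pad = 1L, norm = TRUE, act = "relu",
                  buffers = NULL, bn_mode = "batch")
  conv_unit_f(p, name, x, k, 1L, pad, norm, act, nd = 3L,
              buffers = buffers, bn_mode = bn_mode)

cu3_b <- function(p, name, cache, gy, grads, k = 3L, pad = 1L, norm = TRUE,
                  act = "relu")
  conv_unit_b(p, name, cache, gy, k, 1L, pad, norm, act, nd = 3L,
              grads = grads)

# `train = TRUE` uses batch statistics and returns momentum-updated running
# moments; `train = FALSE` (inference) normalizes with the stored moments
unet_forward <- function(net, x, cache = FALSE, train = cache) {
  p <- net$params
  bn_mode <- if (train) "batch" else "running"
  buf <- net$buffers
  newbuf <- list()
  take <- function(u) {
    if (!is.null(u$buffers)) newbuf[names(u$buffers)] <<- u$buffers
    u
  }
  if (length(dim(x)) == 3L) x <- array(x, c(dim(x), 1L))
  if (any(dim(x)[1:3] %% 16L != 0L))
    stop("input shape ", paste(dim(x)[1:3], collapse = "x"),
         " not divisible by 16; pad the patch first")
  enc <- list(); caches <- list()
  for (l in 1:4) {
    u1 <- take(cu3_f(p, sprintf("enc%d.1", l), x, buffers = buf,
                     bn_mode = bn_mode))
    u2 <- take(cu3_f(p, sprintf("enc%d.2", l), u1$y, buffers = buf,
                     bn_mode = bn_mode))
    enc[[l]] <- u2$y
    pool <- .maxpool3d_forward(u2$y, dim(u2$y))
    caches[[sprintf("e%d", l)]] <- list(c1 = u1$cache, c2 = u2$cache,
                                        arg = pool$arg, pdim = dim(u2$y))
    x <- pool$y
  }
  m1 <- take(cu3_f(p, "mid.1", x, buffers = buf, bn_mode = bn_mode))
  m2 <- take(cu3_f(p, "mid.2", m1$y, buffers = buf, bn_mode = bn_mode))
  caches$mid <- list(c1 = m1$cache, c2 = m2$cache)
  x <- m2$y
  for (l in 4:1) {
    xu <- .upsample2_forward(x, dim(x), 3L)
    uu <- take(cu3_f(p, sprintf("up%d", l), xu, buffers = buf,
                     bn_mode = bn_mode))
    skip <- enc[[l]]
    xc <- array(c(skip, uu$y), dim = dim(skip) + c(0, 0, 0, dim(uu$y)[4]))
    d1 <- take(cu3_f(p, sprintf("dec%d.1", l), xc, buffers = buf,
                     bn_mode = bn_mode))
    d2 <- take(cu3_f(p, sprintf("dec%d.2", l), d1$y, buffers = buf,
                     bn_mode = bn_mode))
    caches[[sprintf("d%d", l)]] <- list(updim = dim(x), up = uu$cache,
                                        skipch = dim(skip)[4],
                                        c1 = d1$cache, c2 = d2$cache)
    x <- d2$y
  }
  hd <- cu3_f(p, "head", x, k = 1L, pad = 0L, norm = FALSE, act = "sigmoid")
  caches$head <- hd$cache
  if (cache) list(y = hd$y, caches = caches, buffers = newbuf) else hd$y
}

unet_backward <- function(net, caches, gy) {
  p <- net$params
  grads <- list()
  r <- cu3_b(p, "head", caches$head, gy, grads, k = 1L, pad = 0L,
             norm = FALSE, act = "sigmoid")
  gy <- r$gx; grads <- r$grads
  enc_gy <- list()
  for (l in 1:4) {
    cc <- caches[[sprintf("d%d", l)]]
    r <- cu3_b(p, sprintf("dec%d.2", l), cc$c2, gy, grads)
    r <- cu3_b(p, sprintf("dec%d.1", l), cc$c1, r$gx, r$grads)
    grads <- r$grads
    gcat <- r$gx
    nskip <- cc$skipch
    enc_gy[[l]] <- gcat[, , , seq_len(nskip), drop = FALSE]
    gup <- gcat[, , , nskip + seq_len(dim(gcat)[4] - nskip), drop = FALSE]
    r <- cu3_b(p, sprintf("up%d", l), cc$up, gup, grads)
    grads <- r$grads
    gy <- .upsample2_backward(r$gx, cc$updim, 3L)
  }
  r <- cu3_b(p, "mid.2", caches$mid$c2, gy, grads)
  r <- cu3_b(p, "mid.1", caches$mid$c1, r$gx, r$grads)
  gy <- r$gx; grads <- r$grads
  for (l in 4:1) {
    cc <- caches[[sprintf("e%d", l)]]
    gpool <- .maxpool3d_backward(gy, cc$arg, cc$pdim)
    gpool <- gpool + enc_gy[[l]]
    r <- cu3_b(p, sprintf("enc%d.2", l), cc$c2, gpool, grads)
    r <- cu3_b(p, sprintf("enc%d.1", l), cc$c1, r$gx, r$grads)
    gy <- r$gx; grads <- r$grads
  }
  grads
}

# random patch of `shape` from aligned (volume, mask) arrays
sample_patch <- function(vox, msk, shape) {
  d <- dim(vox)
  s <- vapply(1:3, function(i) sample.int(d[i] - shape[i] + 1L, 1L), 1L)
  idx <- lapply(1:3, function(i) s[i]:(s[i] + shape[i] - 1L))
  list(x = vox[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
       y = msk[idx[[1]], idx[[2]], idx[[3]], drop = FALSE])
}

#' Train the 3D segmentation network
#'
#' Classical supervised patch training: at each step one random patch of
#' `config$patch_shape` is drawn from a random case and one Adam step taken
#' on [seg_loss()]. For arterial segmentation the volumes are translated
#' pseudo-venous images with the arterial annotations as ground truth; for
#' venous segmentation, native venous images with vein annotations.
#'
#' @param dataset list of cases, each `(volume, label)`: a normalized
#'   [ct_volume()] and aligned [label_volume()].
#' @param config a [seg_config()].
#' @param net optionally, a [build_unet3d()] network to continue training.
#' @param augment_spec optional [augment_spec()]; when supplied each patch
#'   is randomly rotated/scaled in-plane.
#' @param verbose print per-epoch means.
#' @return List `(net, log)`; log is a per-step tibble (class `seg_log`)
#'   of the loss components.
#' @export
train_seg <- function(dataset, config = seg_config(), net = NULL,
                      augment_spec = NULL, verbose = FALSE) {
  if (length(dataset) == 0) stop("empty training dataset")
  set.seed(config$seed)
  if (is.null(net)) net <- build_unet3d(config)
  opt <- adam_init(net$params)
  logs <- list()
  for (ep in seq_len(config$epochs)) {
    for (s in seq_len(config$steps_per_epoch)) {
      cs <- dataset[[sample.int(length(dataset), 1L)]]
      pt <- sample_patch(cs$volume$voxels, cs$label$mask, config$patch_shape)
      if (!is.null(augment_spec)) {
        au <- augment(pt$x, pt$y, augment_spec)
        pt <- list(x = au$patch, y = round(au$mask))
      }
      fw <- unet_forward(net, pt$x, cache = TRUE, train = TRUE)
      net$buffers[names(fw$buffers)] <- fw$buffers
      X <- array(fw$y, dim = config$patch_shape)
      ls <- seg_loss(X, pt$y, config)
      if (!is.finite(ls$total))
        stop("non-finite segmentation loss at epoch ", ep, " step ", s)
      gy <- array(seg_loss_grad(X, pt$y, config$lambda_ps),
                  dim = c(config$patch_shape, 1L))
      grads <- unet_backward(net, fw$caches, gy)
      up <- adam_step(net$params, grads, opt, lr = config$lr, beta1 = 0.9)
      net$params <- up$params; opt <- up$st
      logs[[length(logs) + 1L]] <-
        tibble::tibble(epoch = ep, step = s, dice = ls$dice, ps = ls$ps,
                       total = ls$total)
    }
    if (verbose) {
      ld <- dplyr::bind_rows(logs)
      ld <- ld[ld$epoch == ep, ]
      message(sprintf("epoch %d: dice=%.4f ps=%.4f", ep, mean(ld$dice),
                      mean(ld$ps)))
    }
  }
  log <- dplyr::bind_rows(logs)
  class(log) <- c("seg_log", class(log))
  list(net = net, log = log)
}

#' Segment a full volume with a trained network
#'
#' Extracts overlapping depth patches, runs the network on each, stitches
#' the probabilities (mean over overlaps) and thresholds.
#'
#' @param net a trained `unet3d`.
#' @param volume a normalized [ct_volume()].
#' @param threshold probability cutoff (default 0.5).
#' @param patch_depth,stride patching parameters (defaults from the
#'   network's `patch_shape` and the standard stride 80 scaled to it).
#' @return A [label_volume()] (vessel class `"artery"` tag left to caller
#'   via `vessel_class`).
#' @param vessel_class class tag for the output mask.
#' @export
predict_volume <- function(net, volume, threshold = 0.5,
                           patch_depth = net$config$patch_shape[1],
                           stride = NULL, vessel_class = "artery") {
  d <- dim(volume$voxels)
  if (is.null(stride)) stride <- max(1L, round(patch_depth * 80 / 96))
  patches <- extract_patches(volume, patch_depth, stride)
  preds <- lapply(patches, function(p) {
    pr <- unet_forward(net, p$voxels)
    p$voxels <- array(pr, dim = dim(p$voxels))
    p
  })
  prob <- stitch_patches(preds, d[1])
  label_volume(array(as.numeric(prob >= threshold), dim = d),
               vessel_class = vessel_class, case_id = volume$case_id)
}
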