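# Stage 1: vascular-reinforcement domain-adaptive network.
#
# Unpaired translation between arterial-phase (domain A) and venous-phase
# (domain B) slices: two generators (G_AB, G_BA), two global discriminators
# (D_A, D_B) and two mask-activated local discriminators (LD_A, LD_B) whose
# inputs keep only vessel-annotated pixels, so the adversarial signal does
# not ignore branches a few pixels across. Trained with the four-term
# objective: cycle consistency + global adversarial + local information +
# identity.

BCE_EPS <- 1e-7
NORM_FLOOR <- -1   # background value of mask-activated inputs, in [-1,1] units

#' Loss weights of the stage-1 objective
#'
#' `L = lambda1 * L_cycle + lambda2 * L_adv + lambda3 * L_local +
#' lambda4 * L_idt`; defaults 10 / 1 / 1 / 5.
#'
#' @param lambda1 cycle-consistency weight.
#' @param lambda2 global adversarial weight.
#' @param lambda3 local information weight.
#' @param lambda4 identity weight.
#' @return A `vra_weights` list.
#' @export
vra_weights <- function(lambda1 = 10, lambda2 = 1, lambda3 = 1, lambda4 = 5) {
  w <- c(lambda1, lambda2, lambda3, lambda4)
  if (any(w < 0)) stop("loss weights must be >= 0")
  structure(list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
                 lambda4 = lambda4), class = "vra_weights")
}

# binary cross-entropy over a grid of sigmoid scores, with clamping;
# returns the mean loss and its gradient wrt the (unclamped) scores
bce_grid <- function(scores, target) {
  s <- pmin(pmax(scores, BCE_EPS), 1 - BCE_EPS)
  n <- length(s)
  loss <- -mean(target * log(s) + (1 - target) * log(1 - s))
  g <- -(target / s - (1 - target) / (1 - s)) / n
  g[scores < BCE_EPS | scores > 1 - BCE_EPS] <- 0
  list(loss = loss, grad = array(g, dim = dim(scores)))
}

# least-squares alternative (common in the CycleGAN lineage)
ls_grid <- function(scores, target) {
  n <- length(scores)
  list(loss = mean((scores - target)^2),
       grad = array(2 * (scores - target) / n, dim = dim(scores)))
}

gan_grid <- function(scores, target, objective = "bce") {
  if (objective == "bce") bce_grid(scores, target) else ls_grid(scores, target)
}

#' Adversarial loss of a discriminator on a real/fake image pair
#'
#' Cross-entropy form: the discriminator loss is
#' `-(E log D(real) + E log(1 - D(fake)))`, averaged over the score grid;
#' the generator sees the non-saturating `-E log D(fake)`. Scores are
#' clamped to `[1e-7, 1 - 1e-7]`. The fake image is treated as detached:
#' no gradient is propagated here.
#'
#' @param D a discriminator `nn_net`.
#' @param real,fake image arrays `(H, W, 1)` in `[-1, 1]`.
#' @param objective `"bce"` (the printed cross-entropy form) or `"ls"`
#'   (least squares).
#' @return List `(d_loss, g_loss)`.
#' @export
adversarial_loss <- function(D, real, fake, objective = "bce") {
  sr <- net_forward(D, real)
  sf <- net_forward(D, fake)
  d_loss <- gan_grid(sr, 1, objective)$loss + gan_grid(sf, 0, objective)$loss
  g_loss <- gan_grid(sf, 1, objective)$loss
  list(d_loss = d_loss, g_loss = g_loss)
}

#' Mask-activate an image for the local discriminators
#'
#' Keeps only vessel-annotated pixels: `image * mask`, with the background
#' set exactly to the normalization floor (-1). An empty mask yields an
#' all-floor image flagged for exclusion from the local-loss batch.
#'
#' @param image 2D array (or `(H, W, 1)`).
#' @param mask binary 2D array of the same in-plane shape.
#' @return Activated image with attribute `empty` (TRUE when the mask has
#'   no foreground).
#' @export
local_activation <- function(image, mask) {
  im <- if (length(dim(image)) == 3L) image[, , 1] else image
  stopifnot(identical(dim(im), dim(mask)), all(mask %in% c(0, 1)))
  out <- im * mask + NORM_FLOOR * (1 - mask)
  if (length(dim(image)) == 3L) out <- array(out, dim = dim(image))
  attr(out, "empty") <- !any(mask == 1)
  out
}

#' Local information loss on mask-activated crops
#'
#' The adversarial loss of [adversarial_loss()], computed after mask
#' activation: the real image is activated with its own phase's vessel
#' annotation and the generated image with the source image's annotation
#' (to which it is spatially aligned). With `mask_real = FALSE` only the
#' fake input is masked (the objective exactly as printed). If both masks
#' are empty the contribution is 0.
#'
#' @param LD local discriminator `nn_net`.
#' @param real_pair list `(image, mask)` from the target phase.
#' @param fake_pair list `(image, mask)`: generated image + source-phase
#'   annotation.
#' @param objective `"bce"` or `"ls"`.
#' @param mask_real mask the real input too (default TRUE).
#' @return List `(d_loss, g_loss, empty)`.
#' @export
local_information_loss <- function(LD, real_pair, fake_pair,
                                   objective = "bce", mask_real = TRUE) {
  ar <- if (mask_real) local_activation(real_pair$image, real_pair$mask)
        else structure(real_pair$image, empty = !any(real_pair$mask == 1))
  af <- local_activation(fake_pair$image, fake_pair$mask)
  if (attr(ar, "empty") && attr(af, "empty"))
    return(list(d_loss = 0, g_loss = 0, empty = TRUE))
  al <- adversarial_loss(LD, ar, af, objective)
  c(al, list(empty = FALSE))
}

#' Cycle-consistency loss
#'
#' Mean squared difference between an image and its round-trip
#' reconstruction through both generators (squared-norm form; `type =
#' "l1"` gives the absolute-difference variant).
#'
#' @param image,reconstruction arrays of identical shape.
#' @param type `"l2"` (default, squared) or `"l1"`.
#' @return Scalar loss.
#' @export
cycle_loss <- function(image, reconstruction, type = "l2") {
  stopifnot(identical(dim(image), dim(reconstruction)))
  d <- reconstruction - image
  if (type == "l1") mean(abs(d)) else mean(d^2)
}

#' Identity loss
#'
#' Penalty keeping a generator from restyling images already in its target
#' domain: mean squared difference between `G(target_image)` and
#' `target_image`.
#'
#' @param G generator `nn_net`.
#' @param target_image image array from `G`'s output domain.
#' @return Scalar loss.
#' @export
identity_loss <- function(G, target_image) {
  mean((net_forward(G, target_image) - target_image)^2)
}

# ------------------------------------------------------------------ state --

#' Initialize the stage-1 training state
#'
#' @param base generator/discriminator base channel count.
#' @param n_res residual blocks in each generator.
#' @param weights a [vra_weights()].
#' @param lr Adam learning rate (2e-4, betas 0.5/0.999).
#' @param objective `"bce"` or `"ls"` adversarial objective.
#' @param mask_real mask the local discriminators' real inputs (see
#'   [local_information_loss()]).
#' @param cycle_type `"l2"` or `"l1"` cycle/identity norm.
#' @param epochs planned epoch budget (learning rate decays linearly to 0
#'   over the second half).
#' @param seed RNG seed for weight initialization and batch order.
#' @return A `vra_state`.
#' @export
vra_init <- function(base = 64L, n_res = 6L, weights = vra_weights(),
                     lr = 2e-4, objective = "bce", mask_real = TRUE,
                     cycle_type = "l2", epochs = 200L, seed = 1L) {
  set.seed(seed)
  nets <- list(G_AB = build_generator(base, n_res),
               G_BA = build_generator(base, n_res),
               D_A = build_discriminator(base, 3L),
               D_B = build_discriminator(base, 3L),
               LD_A = build_discriminator(base, 2L),
               LD_B = build_discriminator(base, 2L))
  opt <- lapply(nets, function(n) adam_init(n$params))
  opt$G <- adam_init(c(prefix_names(nets$G_AB$params, "AB."),
                       prefix_names(nets$G_BA$params, "BA.")))
  structure(list(nets = nets, opt = opt, weights = weights, lr = lr,
                 objective = objective, mask_real = mask_real,
                 cycle_type = cycle_type, epochs = epochs, epoch = 0L,
                 step = 0L, seed = seed),
            class = "vra_state")
}

prefix_names <- function(x, p) setNames(x, paste0(p, names(x)))

# gradient of the (l2 or l1) reconstruction penalty
rec_grad <- function(image, target, type) {
  n <- length(image)
  if (type == "l1") array(sign(image - target) / n, dim = dim(image))
  else array(2 * (image - target) / n, dim = dim(image))
}

# discriminator score + gradient wrt its input image, for generator updates
disc_input_grad <- function(D, x, objective) {
  fw <- net_forward(D, x, cache = TRUE)
  gg <- gan_grid(fw$y, 1, objective)          # non-saturating generator term
  bw <- net_backward(D, fw$caches, gg$grad)
  list(loss = gg$loss, gx = bw$gx)
}

# one optimizer update of a single discriminator on (real, fake) inputs;
# returns new (net, opt state, loss)
disc_update <- function(net, st, real, fake, lr, objective) {
  fr <- net_forward(net, real, cache = TRUE)
  gr <- gan_grid(fr$y, 1, objective)
  br <- net_backward(net, fr$caches, gr$grad)
  ff <- net_forward(net, fake, cache = TRUE)
  gf <- gan_grid(ff$y, 0, objective)
  bf <- net_backward(net, ff$caches, gf$grad)
  grads <- mapply(function(a, b) a + b, br$grads[names(net$params)],
                  bf$grads[names(net$params)], SIMPLIFY = FALSE)
  up <- adam_step(net$params, grads, st, lr = lr)
  net$params <- up$params
  list(net = net, st = up$st, loss = gr$loss + gf$loss)
}

#' One training step of the stage-1 network
#'
#' Runs both translation paths (A -> B -> A and B -> A -> B) on one slice
#' pair from each domain, takes one Adam step for the two generators on the
#' weighted objective, then one Adam step for each of the four
#' discriminators on its own loss (fakes detached).
#'
#' @param state a `vra_state`.
#' @param batch list with elements `a` and `b`, each `(image, mask)`:
#'   image `(H, W, 1)` in `[-1, 1]`, mask binary `(H, W)`.
#' @param lr optional learning-rate override (for decay schedules).
#' @return List `(state, report)`; the report holds every loss term
#'   separately plus the weighted total.
#' @export
vra_training_step <- function(state, batch, lr = state$lr) {
  w <- state$weights; obj <- state$objective; ct <- state$cycle_type
  n <- state$nets
  ia <- batch$a$image; ib <- batch$b$image
  ya <- batch$a$mask; yb <- batch$b$mask

  # ---- forward, both paths -------------------------------------------
  f_ab <- net_forward(n$G_AB, ia, cache = TRUE)     # fake B
  f_aba <- net_forward(n$G_BA, f_ab$y, cache = TRUE) # rec A
  f_ba <- net_forward(n$G_BA, ib, cache = TRUE)     # fake A
  f_bab <- net_forward(n$G_AB, f_ba$y, cache = TRUE) # rec B
  f_idb <- net_forward(n$G_AB, ib, cache = TRUE)    # identity on B
  f_ida <- net_forward(n$G_BA, ia, cache = TRUE)    # identity on A

  l_cycle <- cycle_loss(ia, f_aba$y, ct) + cycle_loss(ib, f_bab$y, ct)
  l_idt <- mean((f_idb$y - ib)^2) + mean((f_ida$y - ia)^2)

  # ---- generator gradients -------------------------------------------
  gAB <- list(); gBA <- list()
  l_adv_g <- 0; l_local_g <- 0

  # cycle path A: grad into rec A, back through G_BA then G_AB
  g_recA <- w$lambda1 * rec_grad(f_aba$y, ia, ct)
  bw <- net_backward(n$G_BA, f_aba$caches, g_recA)
  gBA <- acc_grads(gBA, bw$grads)
  g_fakeB <- bw$gx
  # adversarial + local pressure on fake B
  if (w$lambda2 > 0) {
    dg <- disc_input_grad(n$D_B, f_ab$y, obj)
    l_adv_g <- l_adv_g + dg$loss
    g_fakeB <- g_fakeB + w$lambda2 * dg$gx
  }
  if (w$lambda3 > 0 && any(ya == 1)) {
    act <- local_activation(f_ab$y, ya)
    dg <- disc_input_grad(n$LD_B, act, obj)
    l_local_g <- l_local_g + dg$loss
    g_fakeB <- g_fakeB + w$lambda3 * dg$gx * array(ya, dim = dim(dg$gx))
  }
  bw <- net_backward(n$G_AB, f_ab$caches, g_fakeB)
  gAB <- acc_grads(gAB, bw$grads)

  # cycle path B
  g_recB <- w$lambda1 * rec_grad(f_bab$y, ib, ct)
  bw <- net_backward(n$G_AB, f_bab$caches, g_recB)
  gAB <- acc_grads(gAB, bw$grads)
  g_fakeA <- bw$gx
  if (w$lambda2 > 0) {
    dg <- disc_input_grad(n$D_A, f_ba$y, obj)
    l_adv_g <- l_adv_g + dg$loss
    g_fakeA <- g_fakeA + w$lambda2 * dg$gx
  }
  if (w$lambda3 > 0 && any(yb == 1)) {
    act <- local_activation(f_ba$y, yb)
    dg <- disc_input_grad(n$LD_A, act, obj)
    l_local_g <- l_local_g + dg$loss
    g_fakeA <- g_fakeA + w$lambda3 * dg$gx * array(yb, dim = dim(dg$gx))
  }
  bw <- net_backward(n$G_BA, f_ba$caches, g_fakeA)
  gBA <- acc_grads(gBA, bw$grads)

  # identity terms
  if (w$lambda4 > 0) {
    bw <- net_backward(n$G_AB, f_idb$caches,
                       w$lambda4 * rec_grad(f_idb$y, ib, "l2"))
    gAB <- acc_grads(gAB, bw$grads)
    bw <- net_backward(n$G_BA, f_ida$caches,
                       w$lambda4 * rec_grad(f_ida$y, ia, "l2"))
    gBA <- acc_grads(gBA, bw$grads)
  }

  total <- w$lambda1 * l_cycle + w$lambda2 * l_adv_g +
    w$lambda3 * l_local_g + w$lambda4 * l_idt
  if (!is.finite(total))
    stop("non-finite stage-1 loss at step ", state$step,
         " (cycle=", l_cycle, ", adv=", l_adv_g, ", local=", l_local_g,
         ", idt=", l_idt, ")")

  # at a numerically exact minimum the adaptive step would otherwise
  # amplify float round-off into a full-size update
  if (total > 1e-12) {
    gen_grads <- c(prefix_names(gAB[names(n$G_AB$params)], "AB."),
                   prefix_names(gBA[names(n$G_BA$params)], "BA."))
    gen_params <- c(prefix_names(n$G_AB$params, "AB."),
                    prefix_names(n$G_BA$params, "BA."))
    up <- adam_step(gen_params, gen_grads, state$opt$G, lr = lr)
    state$opt$G <- up$st
    nn <- names(n$G_AB$params)
    n$G_AB$params <- setNames(up$params[paste0("AB.", nn)], nn)
    nn <- names(n$G_BA$params)
    n$G_BA$params <- setNames(up$params[paste0("BA.", nn)], nn)
  }

  # ---- discriminator updates (fakes detached) ------------------------
  du <- disc_update(n$D_B, state$opt$D_B, ib, f_ab$y, lr, obj)
  n$D_B <- du$net; state$opt$D_B <- du$st; l_d_b <- du$loss
  du <- disc_update(n$D_A, state$opt$D_A, ia, f_ba$y, lr, obj)
  n$D_A <- du$net; state$opt$D_A <- du$st; l_d_a <- du$loss
  l_ld_b <- l_ld_a <- NA_real_
  if (any(ya == 1) || any(yb == 1)) {
    if (any(ya == 1)) {
      real_in <- if (state$mask_real) local_activation(ib, yb) else ib
      du <- disc_update(n$LD_B, state$opt$LD_B, real_in,
                        local_activation(f_ab$y, ya), lr, obj)
      n$LD_B <- du$net; state$opt$LD_B <- du$st; l_ld_b <- du$loss
    }
    if (any(yb == 1)) {
      real_in <- if (state$mask_real) local_activation(ia, ya) else ia
      du <- disc_update(n$LD_A, state$opt$LD_A, real_in,
                        local_activation(f_ba$y, yb), lr, obj)
      n$LD_A <- du$net; state$opt$LD_A <- du$st; l_ld_a <- du$loss
    }
  }

  state$nets <- n
  state$step <- state$step + 1L
  report <- tibble::tibble(step = state$step, l_cycle = l_cycle,
                           l_adv = l_adv_g, l_local = l_local_g,
                           l_idt = l_idt, l_total = total,
                           d_A = l_d_a, d_B = l_d_b,
                           ld_A = l_ld_a, ld_B = l_ld_b)
  list(state = state, report = report)
}

acc_grads <- function(acc, new) {
  for (nm in names(new)) acc[[nm]] <- add_grad(acc[[nm]], new[[nm]])
  acc
}

#' Slice a volume/label pair into 2D training units
#'
#' @param volume a normalized [ct_volume()].
#' @param label an aligned [label_volume()].
#' @return List over slices of `(image (H,W,1), mask (H,W))`.
#' @export
make_slice_pairs <- function(volume, label) {
  check_aligned(volume, label)
  d <- dim(volume$voxels)
  lapply(seq_len(d[1]), function(z)
    list(image = array(volume$voxels[z, , ], c(d[2], d[3], 1L)),
         mask = label$mask[z, , ]))
}

#' Train the stage-1 network
#'
#' @param pairs_a,pairs_b lists of slice pairs (see [make_slice_pairs()])
#'   from the arterial and venous domains.
#' @param state a `vra_state` from [vra_init()].
#' @param steps number of training steps (one random slice pair per domain
#'   per step).
#' @param decay_after apply linear learning-rate decay to zero after this
#'   fraction of the steps (default 0.5).
#' @param verbose print progress every 50 steps.
#' @return List `(state, log)`; the log is a tibble of per-step loss terms
#'   (class `vra_log`).
#' @export
train_vra <- function(pairs_a, pairs_b, state, steps = 200L,
                      decay_after = 0.5, verbose = FALSE) {
  logs <- vector("list", steps)
  set.seed(state$seed + 17L)
  for (s in seq_len(steps)) {
    frac <- s / steps
    lr <- if (frac <= decay_after) state$lr
          else state$lr * (1 - frac) / (1 - decay_after)
    batch <- list(a = pairs_a[[sample.int(length(pairs_a), 1)]],
                  b = pairs_b[[sample.int(length(pairs_b), 1)]])
    r <- vra_training_step(state, batch, lr = lr)
    state <- r$state
    logs[[s]] <- r$report
    if (verbose && s %% 50 == 0)
      message(sprintf("step %d: cycle=%.4f adv=%.4f local=%.4f idt=%.4f",
                      s, r$report$l_cycle, r$report$l_adv,
                      r$report$l_local, r$report$l_idt))
  }
  log <- dplyr::bind_rows(logs)
  class(log) <- c("vra_log", class(log))
  list(state = state, log = log)
}

#' Translate a volume slice-by-slice with a trained generator
#'
#' Applies `G` to every slice and restacks in order; shape and spacing are
#' preserved and the phase tag becomes the corresponding pseudo phase.
#'
#' @param G generator `nn_net` (e.g. `state$nets$G_AB`).
#' @param volume a normalized [ct_volume()].
#' @param direction `"a2b"` (arterial -> pseudo-venous) or `"b2a"`.
#' @return A [ct_volume()] tagged `pseudo_venous` / `pseudo_arterial`.
#' @export
translate_volume <- function(G, volume, direction = "a2b") {
  d <- dim(volume$voxels)
  out <- array(0, dim = d)
  for (z in seq_len(d[1])) {
    sl <- array(volume$voxels[z, , ], c(d[2], d[3], 1L))
    out[z, , ] <- net_forward(G, sl)[, , 1]
  }
  v <- ct_volume(out, volume$spacing,
                 if (direction == "a2b") "pseudo_venous" else "pseudo_arterial",
                 volume$case_id)
  attr(v, "units") <- "normalized"
  v
}
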