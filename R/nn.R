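# Minimal CPU conv-net engine.
#
# Parameters live in flat named lists of arrays; every forward returns the
# output plus caches, every backward returns input gradients plus parameter
# gradients under the same names, so optimizers are generic. Feature maps
# are plain R arrays, channel-last: (H, W, C) in 2D, (D, H, W, C) in 3D;
# batch size is one (one slice / one patch per step). Convolutions run as
# im2col + BLAS matrix products in compiled code; gradients of every layer
# are verified against finite differences in the test suite.

EPS_NORM <- 1e-5

# ----------------------------------------------------------- activations --

act_f <- function(x, kind) {
  switch(kind,
         linear = x,
         relu = pmax(x, 0),
         lrelu = ifelse(x > 0, x, 0.2 * x),
         tanh = tanh(x),
         sigmoid = 1 / (1 + exp(-x)),
         stop("unknown activation ", kind))
}

# gradient wrt pre-activation, expressed through the activation output y
act_b <- function(gy, y, kind) {
  switch(kind,
         linear = gy,
         relu = gy * (y > 0),
         lrelu = gy * ifelse(y > 0, 1, 0.2),
         tanh = gy * (1 - y^2),
         sigmoid = gy * y * (1 - y),
         stop("unknown activation ", kind))
}

# -------------------------------------------------- per-channel norm layer --

# instance normalization over all spatial positions of each channel
# (with one sample per step this is also what batch norm computes)
inorm_f <- function(x, gamma, beta) {
  d <- dim(x); C <- d[length(d)]
  m <- matrix(x, ncol = C)
  mu <- colMeans(m)
  xc <- sweep(m, 2, mu)
  v <- colMeans(xc^2)
  istd <- 1 / sqrt(v + EPS_NORM)
  xhat <- sweep(xc, 2, istd, `*`)
  y <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  list(y = array(y, dim = d), xhat = xhat, istd = istd, mu = mu, v = v)
}

inorm_b <- function(gy, cache, gamma, xdim) {
  C <- length(gamma)
  g <- matrix(gy, ncol = C)
  n <- nrow(g)
  ggamma <- colSums(g * cache$xhat)
  gbeta <- colSums(g)
  gxhat <- sweep(g, 2, gamma, `*`)
  # d/dx of (x - mu) / sd with mu, sd functions of x
  t1 <- sweep(gxhat, 2, colMeans(gxhat))
  t2 <- sweep(cache$xhat, 2, colMeans(gxhat * cache$xhat), `*`)
  gx <- sweep(t1 - t2, 2, cache$istd, `*`)
  list(gx = array(gx, dim = xdim), ggamma = ggamma, gbeta = gbeta)
}

# --------------------------------------------------------- initialisation --

he_init <- function(fan_in, cout) {
  matrix(rnorm(fan_in * cout, sd = sqrt(2 / fan_in)), fan_in, cout)
}

# ------------------------------------------------------ layer descriptors --

conv2d_spec <- function(name, cin, cout, k, stride = 1L, pad = (k - 1L) %/% 2L,
                        norm = TRUE, act = "relu") {
  list(type = "conv2d", name = name, cin = cin, cout = cout, k = k,
       stride = stride, pad = pad, norm = norm, act = act)
}

res2d_spec <- function(name, ch) list(type = "res2d", name = name, ch = ch)

up2d_spec <- function(name, cin, cout, act = "relu")
  list(type = "up2d", name = name, cin = cin, cout = cout, k = 3L,
       stride = 1L, pad = 1L, norm = TRUE, act = act)

init_conv <- function(params, name, cin, cout, k, norm, nd = 2L,
                      identity = FALSE) {
  fan <- k^nd * cin
  if (identity) {
    W <- matrix(0, fan, cout)
    centre <- (k^nd - 1) %/% 2 + 1          # delta kernel
    for (c in seq_len(min(cin, cout))) W[(c - 1) * k^nd + centre, c] <- 1
    params[[paste0(name, ".W")]] <- W
  } else {
    params[[paste0(name, ".W")]] <- he_init(fan, cout)
  }
  params[[paste0(name, ".b")]] <- numeric(cout)
  if (norm) {
    params[[paste0(name, ".g")]] <- rep(1, cout)
    params[[paste0(name, ".be")]] <- numeric(cout)
  }
  params
}

# norm modes: "batch" computes batch statistics (and, when `buffers` is
# supplied, returns momentum-updated running moments); "running" normalizes
# with the stored moments (inference)
conv_unit_f <- function(params, name, x, k, stride, pad, norm, act, nd = 2L,
                        buffers = NULL, bn_mode = "batch") {
  W <- params[[paste0(name, ".W")]]; b <- params[[paste0(name, ".b")]]
  y <- if (nd == 2L)
    .conv2d_forward(x, dim(x), W, b, k, k, stride, pad)
  else
    .conv3d_forward(x, dim(x), W, b, k, stride, pad)
  ydim <- dim(y)
  nrm <- NULL
  newbuf <- NULL
  if (norm) {
    gam <- params[[paste0(name, ".g")]]; bet <- params[[paste0(name, ".be")]]
    if (bn_mode == "running") {
      rm <- buffers[[paste0(name, ".rm")]]; rv <- buffers[[paste0(name, ".rv")]]
      d <- dim(y); C <- d[length(d)]
      m <- matrix(y, ncol = C)
      m <- sweep(sweep(m, 2, rm), 2, 1 / sqrt(rv + EPS_NORM), `*`)
      y <- array(sweep(sweep(m, 2, gam, `*`), 2, bet, `+`), dim = d)
    } else {
      nrm <- inorm_f(y, gam, bet)
      if (!is.null(buffers)) {
        mo <- 0.1   # running-moment update rate
        newbuf <- list()
        newbuf[[paste0(name, ".rm")]] <-
          (1 - mo) * buffers[[paste0(name, ".rm")]] + mo * nrm$mu
        newbuf[[paste0(name, ".rv")]] <-
          (1 - mo) * buffers[[paste0(name, ".rv")]] + mo * nrm$v
      }
      y <- nrm$y
    }
  }
  a <- act_f(y, act)
  list(y = a, cache = list(x = x, ydim = ydim, nrm = nrm, a = a),
       buffers = newbuf)
}

conv_unit_b <- function(params, name, cache, gy, k, stride, pad, norm, act,
                        nd = 2L, grads) {
  gy <- act_b(gy, cache$a, act)
  if (norm) {
    nb <- inorm_b(gy, cache$nrm, params[[paste0(name, ".g")]], cache$ydim)
    grads[[paste0(name, ".g")]] <- add_grad(grads[[paste0(name, ".g")]], nb$ggamma)
    grads[[paste0(name, ".be")]] <- add_grad(grads[[paste0(name, ".be")]], nb$gbeta)
    gy <- nb$gx
  }
  W <- params[[paste0(name, ".W")]]
  bk <- if (nd == 2L)
    .conv2d_backward(gy, cache$x, dim(cache$x), W, k, k, stride, pad)
  else
    .conv3d_backward(gy, cache$x, dim(cache$x), W, k, stride, pad)
  grads[[paste0(name, ".W")]] <- add_grad(grads[[paste0(name, ".W")]], bk$gW)
  grads[[paste0(name, ".b")]] <- add_grad(grads[[paste0(name, ".b")]], bk$gb)
  list(gx = bk$gx, grads = grads)
}

add_grad <- function(old, new) if (is.null(old)) new else old + new

# ------------------------------------------------------- sequential nets --

init_seq <- function(layers, identity = FALSE) {
  params <- list()
  for (ly in layers) {
    if (ly$type == "conv2d")
      params <- init_conv(params, ly$name, ly$cin, ly$cout, ly$k, ly$norm,
                          identity = identity)
    else if (ly$type == "up2d")
      params <- init_conv(params, ly$name, ly$cin, ly$cout, ly$k, ly$norm)
    else if (ly$type == "res2d") {
      params <- init_conv(params, paste0(ly$name, ".1"), ly$ch, ly$ch, 3L, TRUE)
      params <- init_conv(params, paste0(ly$name, ".2"), ly$ch, ly$ch, 3L, TRUE)
    }
  }
  params
}

seq_forward <- function(layers, params, x) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "conv2d") {
      u <- conv_unit_f(params, ly$name, x, ly$k, ly$stride, ly$pad,
                       ly$norm, ly$act)
      caches[[i]] <- u$cache; x <- u$y
    } else if (ly$type == "up2d") {
      xu <- .upsample2_forward(x, dim(x), 2L)
      u <- conv_unit_f(params, ly$name, xu, ly$k, ly$stride, ly$pad,
                       ly$norm, ly$act)
      caches[[i]] <- list(unit = u$cache, updim = dim(x)); x <- u$y
    } else if (ly$type == "res2d") {
      u1 <- conv_unit_f(params, paste0(ly$name, ".1"), x, 3L, 1L, 1L,
                        TRUE, "relu")
      u2 <- conv_unit_f(params, paste0(ly$name, ".2"), u1$y, 3L, 1L, 1L,
                        TRUE, "linear")
      caches[[i]] <- list(c1 = u1$cache, c2 = u2$cache)
      x <- x + u2$y
    }
  }
  list(y = x, caches = caches)
}

seq_backward <- function(layers, params, caches, gy) {
  grads <- list()
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    if (ly$type == "conv2d") {
      r <- conv_unit_b(params, ly$name, caches[[i]], gy, ly$k, ly$stride,
                       ly$pad, ly$norm, ly$act, grads = grads)
      gy <- r$gx; grads <- r$grads
    } else if (ly$type == "up2d") {
      r <- conv_unit_b(params, ly$name, caches[[i]]$unit, gy, ly$k, ly$stride,
                       ly$pad, ly$norm, ly$act, grads = grads)
      grads <- r$grads
      gy <- .upsample2_backward(r$gx, caches[[i]]$updim, 2L)
    } else if (ly$type == "res2d") {
      r2 <- conv_unit_b(params, paste0(ly$name, ".2"), caches[[i]]$c2, gy,
                        3L, 1L, 1L, TRUE, "linear", grads = grads)
      r1 <- conv_unit_b(params, paste0(ly$name, ".1"), caches[[i]]$c1, r2$gx,
                        3L, 1L, 1L, TRUE, "relu", grads = r2$grads)
      gy <- gy + r1$gx          # skip connection
      grads <- r1$grads
    }
  }
  list(gx = gy, grads = grads)
}

# ------------------------------------------------------------ architectures

#' Build a 2D image-translation generator
#'
#' Residual encoder-decoder in the CycleGAN lineage: a 7x7 stem, two
#' stride-2 downsampling convolutions, `n_res` residual blocks at the
#' bottleneck resolution, two nearest-upsample+conv stages and a 7x7 output
#' convolution. Instance normalization throughout; `tanh` output matches
#' the `[-1, 1]` intensity normalization.
#'
#' @param base base channel count (64 at clinical resolution; tests use 8).
#' @param n_res number of residual blocks (default 6).
#' @param out_act output activation, `"tanh"` or `"linear"`.
#' @param identity if `TRUE`, build a single linear 1x1 convolution
#'   initialized to the exact identity map (used for diagnostics and the
#'   stationarity checks).
#' @return A `nn_net` list with `layers` and `params`.
#' @export
build_generator <- function(base = 64L, n_res = 6L, out_act = "tanh",
                            identity = FALSE) {
  if (identity) {
    layers <- list(conv2d_spec("g0", 1L, 1L, 1L, norm = FALSE, act = "linear"))
    params <- init_seq(layers, identity = TRUE)
  } else {
    layers <- c(list(
      conv2d_spec("stem", 1L, base, 7L),
      conv2d_spec("down1", base, 2L * base, 3L, stride = 2L),
      conv2d_spec("down2", 2L * base, 4L * base, 3L, stride = 2L)),
      lapply(seq_len(n_res), function(i)
        res2d_spec(paste0("res", i), 4L * base)),
      list(up2d_spec("up1", 4L * base, 2L * base),
           up2d_spec("up2", 2L * base, base),
           conv2d_spec("head", base, 1L, 7L, norm = FALSE, act = out_act)))
    params <- init_seq(layers)
  }
  structure(list(layers = layers, params = params), class = "nn_net")
}

#' Build a patch-classifying discriminator
#'
#' Strided convolutional classifier emitting a grid of sigmoid realness
#' scores. The global form has three stride-2 stages; the local form
#' (`n_strided = 2`) keeps a smaller receptive field suited to the
#' few-pixel vessels that mask-activated inputs contain.
#'
#' @param base base channel count.
#' @param n_strided number of stride-2 stages (3 global, 2 local).
#' @return A `nn_net`.
#' @export
build_discriminator <- function(base = 64L, n_strided = 3L) {
  ch <- base * 2L^(seq_len(n_strided) - 1L)
  layers <- c(list(conv2d_spec("d1", 1L, ch[1], 4L, stride = 2L, pad = 1L,
                               norm = FALSE, act = "lrelu")),
              lapply(seq_len(n_strided - 1L), function(i)
                conv2d_spec(paste0("d", i + 1L), ch[i], ch[i + 1L], 4L,
                            stride = 2L, pad = 1L, act = "lrelu")),
              list(conv2d_spec("dout", ch[n_strided], 1L, 4L, stride = 1L,
                               pad = 1L, norm = FALSE, act = "sigmoid")))
  structure(list(layers = layers, params = init_seq(layers)), class = "nn_net")
}

#' Run a network forward
#' @param net a `nn_net` from [build_generator()] or [build_discriminator()].
#' @param x input array `(H, W, C)`.
#' @param cache keep layer caches for a subsequent backward pass.
#' @return The output array, or (if `cache`) a list `(y, caches)`.
#' @export
net_forward <- function(net, x, cache = FALSE) {
  r <- seq_forward(net$layers, net$params, x)
  if (cache) r else r$y
}

net_backward <- function(net, caches, gy)
  seq_backward(net$layers, net$params, caches, gy)

n_params <- function(net) sum(vapply(net$params, length, 1L))

# ------------------------------------------------------------------- Adam --

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, st, lr = 2e-4, beta1 = 0.5,
                      beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t; bc2 <- 1 - beta2^st$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  list(params = params, st = st)
}
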