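# The conv-net engine is hand-written, so its gradients are checked against
# central finite differences layer by layer and end to end. Convolution
# arithmetic is single precision internally; tolerances reflect that.

grad_tol <- 5e-3

test_that("2D convolution gradients match finite differences", {
  set.seed(11)
  x <- array(rnorm(5 * 6 * 2), c(5, 6, 2))
  W <- matrix(rnorm(3 * 3 * 2 * 3, sd = 0.5), 18, 3)
  b <- rnorm(3)
  for (stride in c(1L, 2L)) {
    pad <- 1L
    loss <- function(xv) {
      y <- vesselda:::.conv2d_forward(array(xv, dim(x)), dim(x), W, b,
                                      3L, 3L, stride, pad)
      sum(y^2) / 2
    }
    y <- vesselda:::.conv2d_forward(x, dim(x), W, b, 3L, 3L, stride, pad)
    bk <- vesselda:::.conv2d_backward(y, x, dim(x), W, 3L, 3L, stride, pad)
    ng <- array(num_grad(loss, as.numeric(x)), dim(x))
    expect_lt(max(abs(bk$gx - ng)) / max(abs(ng)), grad_tol)
    lossW <- function(wv) {
      y <- vesselda:::.conv2d_forward(x, dim(x), matrix(wv, 18, 3), b,
                                      3L, 3L, stride, pad)
      sum(y^2) / 2
    }
    ngW <- matrix(num_grad(lossW, as.numeric(W)), 18, 3)
    expect_lt(max(abs(bk$gW - ngW)) / max(abs(ngW)), grad_tol)
  }
})

test_that("3D convolution gradients match finite differences", {
  set.seed(12)
  x <- array(rnorm(4 * 5 * 6 * 2), c(4, 5, 6, 2))
  W <- matrix(rnorm(27 * 2 * 2, sd = 0.3), 54, 2)
  b <- rnorm(2)
  loss <- function(xv) {
    y <- vesselda:::.conv3d_forward(array(xv, dim(x)), dim(x), W, b, 3L, 1L, 1L)
    sum(y^2) / 2
  }
  y <- vesselda:::.conv3d_forward(x, dim(x), W, b, 3L, 1L, 1L)
  bk <- vesselda:::.conv3d_backward(y, x, dim(x), W, 3L, 1L, 1L)
  ng <- array(num_grad(loss, as.numeric(x)), dim(x))
  expect_lt(max(abs(bk$gx - ng)) / max(abs(ng)), grad_tol)
})

test_that("instance norm gradients match finite differences", {
  set.seed(13)
  x <- array(rnorm(7 * 8 * 3), c(7, 8, 3))
  gam <- rnorm(3) + 1; bet <- rnorm(3)
  tgt <- array(rnorm(7 * 8 * 3), c(7, 8, 3))
  loss <- function(xv) {
    r <- vesselda:::inorm_f(array(xv, dim(x)), gam, bet)
    sum((r$y - tgt)^2) / 2
  }
  r <- vesselda:::inorm_f(x, gam, bet)
  nb <- vesselda:::inorm_b(r$y - tgt, r, gam, dim(x))
  ng <- array(num_grad(loss, as.numeric(x), eps = 1e-5), dim(x))
  expect_lt(max(abs(nb$gx - ng)) / max(abs(ng)), 1e-4)
})

test_that("generator propagates exact input gradients end to end", {
  set.seed(14)
  g <- build_generator(base = 2L, n_res = 1L)
  x <- array(rnorm(8 * 8), c(8, 8, 1))
  loss <- function(xv) sum(net_forward(g, array(xv, dim(x)))^2) / 2
  fw <- net_forward(g, x, cache = TRUE)
  bw <- vesselda:::net_backward(g, fw$caches, fw$y)
  ng <- array(num_grad(loss, as.numeric(x)), dim(x))
  expect_lt(max(abs(bw$gx - ng)) / max(abs(ng)), grad_tol)
  # parameter gradient spot check on a residual-block weight
  nm <- "res1.1.W"; i <- 3L
  pg <- function(v) { g2 <- g; g2$params[[nm]][i] <- v
    sum(net_forward(g2, x)^2) / 2 }
  v0 <- g$params[[nm]][i]
  num <- (pg(v0 + 1e-3) - pg(v0 - 1e-3)) / 2e-3
  expect_equal(bw$grads[[nm]][i], num, tolerance = 1e-2)
})

test_that("discriminator and U-Net gradients match finite differences", {
  set.seed(15)
  d <- build_discriminator(base = 2L, n_strided = 2L)
  xd <- array(rnorm(16 * 16), c(16, 16, 1))
  fwd <- net_forward(d, xd, cache = TRUE)
  bwd <- vesselda:::net_backward(d, fwd$caches, array(1, dim(fwd$y)))
  lossd <- function(xv) sum(net_forward(d, array(xv, dim(xd))))
  ngd <- array(num_grad(lossd, as.numeric(xd)), dim(xd))
  expect_lt(max(abs(bwd$gx - ngd)) / max(abs(ngd)), grad_tol)

  cfg <- seg_config(patch_shape = c(16, 16, 16), base_channels = 2L, seed = 5)
  net <- build_unet3d(cfg)
  xt <- array(runif(16^3), c(16, 16, 16, 1))
  yt <- array(as.numeric(runif(16^3) > 0.9), c(16, 16, 16))
  fw <- vesselda:::unet_forward(net, xt, cache = TRUE)
  gy <- array(vesselda:::seg_loss_grad(array(fw$y, dim(yt)), yt, 1),
              c(dim(yt), 1))
  gr <- vesselda:::unet_backward(net, fw$caches, gy)
  lossu <- function(n2) {
    X <- array(vesselda:::unet_forward(n2, xt, train = TRUE), dim(yt))
    seg_loss(X, yt, cfg)$total
  }
  # float32 forward arithmetic leaves ~1e-7 noise on the loss, so the
  # finite-difference step and tolerance are kept coarse
  for (nm in c("enc1.1.W", "dec1.2.W", "up3.W", "head.W")) {
    i <- which.max(abs(gr[[nm]]))      # check the most active weight
    pg <- function(v) { n2 <- net; n2$params[[nm]][i] <- v; lossu(n2) }
    v0 <- net$params[[nm]][i]
    num <- (pg(v0 + 5e-3) - pg(v0 - 5e-3)) / 1e-2
    expect_lt(abs(gr[[nm]][i] - num), max(5e-2 * abs(num), 5e-4))
    expect_equal(sign(gr[[nm]][i]), sign(num), info = nm)
  }
})

test_that("network construction is deterministic and shape-correct", {
  set.seed(20); g1 <- build_generator(base = 2L, n_res = 2L)
  set.seed(20); g2 <- build_generator(base = 2L, n_res = 2L)
  expect_identical(g1$params, g2$params)
  x <- array(rnorm(12 * 16), c(12, 16, 1))
  y <- net_forward(g1, x)
  expect_identical(dim(y), dim(x))                 # image-to-image, same shape
  expect_true(all(abs(y) <= 1))                    # tanh output range

  gi <- build_generator(identity = TRUE)
  expect_equal(net_forward(gi, x), x, tolerance = 1e-6)  # identity map

  cfg <- seg_config(patch_shape = c(96, 64, 64), base_channels = 2L)
  n1 <- build_unet3d(cfg)
  expect_identical(sum(vapply(n1$params, length, 1L)),
                   sum(vapply(build_unet3d(cfg)$params, length, 1L)))
  xp <- array(runif(32 * 16 * 16), c(32, 16, 16, 1))
  fw <- vesselda:::unet_forward(n1, xp, cache = TRUE)
  expect_identical(dim(fw$y), c(32L, 16L, 16L, 1L))
  expect_true(all(fw$y > 0 & fw$y < 1))            # sigmoid output
  # deepest feature map is input / 16 per axis (four halvings)
  expect_identical(fw$caches$mid$c1$ydim[1:3], c(32L, 16L, 16L) %/% 16L)
  expect_error(vesselda:::unet_forward(n1, array(0, c(15, 16, 16, 1))),
               "divisible by 16")
})
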