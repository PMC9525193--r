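test_that("depth projection matches the brute-force oracle and conserves
           mass", {
  ones <- array(1, c(2, 2, 2))
  for (ax in c("x", "y", "z"))
    expect_equal(depth_project(ones, ax), c(2, 2, 2, 2))
  pt <- array(0, c(2, 2, 2)); pt[1, 1, 1] <- 1
  for (ax in c("x", "y", "z"))
    expect_equal(depth_project(pt, ax), c(1, 0, 0, 0))

  set.seed(21)
  for (i in 1:5) {
    m <- array(as.numeric(runif(64) > 0.5), c(4, 4, 4))
    s <- array(runif(60), c(3, 4, 5))              # soft, non-cubic
    for (ax in c("x", "y", "z")) {
      expect_equal(depth_project(m, ax), oracle_project(m, ax))
      expect_equal(depth_project(s, ax), oracle_project(s, ax))
      expect_equal(sum(depth_project(s, ax)), sum(s))   # mass conservation
    }
  }
  expect_error(depth_project(matrix(1, 2, 2)), "rank 3")
})

test_that("projection similarity loss: closed forms, conventions, symmetry", {
  set.seed(22)
  X <- array(as.numeric(runif(60) > 0.6), c(3, 4, 5))
  expect_equal(projection_similarity_loss(X, X), 0)

  # constructed 2x2x1 pair: in-plane projections agree, the z-plane
  # density matrices are orthogonal -> loss = 1/3
  A <- array(0, c(1, 2, 2)); A[1, 1, 1] <- 1; A[1, 2, 2] <- 1
  B <- array(0, c(1, 2, 2)); B[1, 1, 2] <- 1; B[1, 2, 1] <- 1
  expect_equal(projection_similarity_loss(A, B), 1 / 3, tolerance = 1e-12)
  expect_equal(oracle_ps_loss(A, B), 1 / 3, tolerance = 1e-12)

  empty <- array(0, c(3, 4, 5))
  expect_equal(projection_similarity_loss(empty, X), 1)  # one-sided emptiness
  expect_equal(projection_similarity_loss(empty, empty), 0)  # identical emptiness
  expect_equal(projection_similarity_loss(X, empty),
               projection_similarity_loss(empty, X))     # symmetry
  Y <- array(runif(60), c(3, 4, 5))
  expect_equal(projection_similarity_loss(X, Y),
               projection_similarity_loss(Y, X))
})

test_that("projection loss is blind to projection-preserving rearrangements", {
  # the 2x2x2 'tetrahedral swap' changes the voxel pattern but leaves all
  # three axis-sum projections identical
  set.seed(23)
  for (i in 1:10) {
    base <- array(as.numeric(runif(6 * 6 * 6) > 0.8), c(6, 6, 6))
    z <- sample(5, 1); y <- sample(5, 1); x <- sample(5, 1)
    blk <- base[z:(z + 1), y:(y + 1), x:(x + 1)]
    if (sum(blk) > 0) next                        # need an empty 2x2x2 site
    X <- base; Y <- base
    X[z, y, x] <- X[z, y + 1, x + 1] <- X[z + 1, y, x + 1] <-
      X[z + 1, y + 1, x] <- 1
    Y[z + 1, y + 1, x + 1] <- Y[z + 1, y, x] <- Y[z, y + 1, x] <-
      Y[z, y, x + 1] <- 1
    for (ax in c("x", "y", "z"))
      expect_equal(depth_project(X, ax), depth_project(Y, ax))
    expect_equal(projection_similarity_loss(X, Y), 0, tolerance = 1e-12)
  }
})

test_that("dice loss reproduces set arithmetic and pairs with the DSC", {
  X <- array(0, c(2, 2, 2)); X[1:3] <- 1          # |X| = 3
  Y <- array(0, c(2, 2, 2)); Y[2:6] <- 1          # |Y| = 5, overlap 2
  expect_equal(dice_loss(X, Y), 0.5, tolerance = 1e-5)
  expect_equal(dice_loss(X, X), 0, tolerance = 1e-5)
  disj <- array(0, c(2, 2, 2)); disj[7:8] <- 1
  expect_equal(dice_loss(X, disj), 1, tolerance = 1e-5)
  expect_equal(dice_loss(X, Y), dice_loss(Y, X))
  set.seed(24)
  S <- array(runif(24), c(2, 3, 4)); T <- array(runif(24), c(2, 3, 4))
  expect_equal(dice_loss(S, T), oracle_dice_loss(S, T), tolerance = 1e-12)
})

test_that("combined segmentation loss composes its two terms", {
  set.seed(25)
  X <- array(runif(60), c(3, 4, 5))
  Y <- array(as.numeric(runif(60) > 0.7), c(3, 4, 5))
  cfg0 <- seg_config(); cfg0$lambda_ps <- 0
  expect_equal(seg_loss(X, Y, cfg0)$total, dice_loss(X, Y))
  cfg1 <- seg_config()                             # lambda = 1
  r <- seg_loss(X, Y, cfg1)
  expect_equal(r$total, oracle_dice_loss(X, Y) + oracle_ps_loss(X, Y),
               tolerance = 1e-6)
  expect_equal(seg_loss(Y, Y, cfg1)$total, 0, tolerance = 1e-5)
})

test_that("loss gradients are finite everywhere, including degenerate
           projections", {
  set.seed(26)
  X <- array(runif(60, 0.01, 0.99), c(3, 4, 5))
  Y <- array(as.numeric(runif(60) > 0.7), c(3, 4, 5))
  g <- vesselda:::seg_loss_grad(X, Y, 1)
  expect_true(all(is.finite(g)))
  # numeric check of the analytic gradient
  f <- function(xv) {
    x <- array(xv, dim(X))
    dice_loss(x, Y) + projection_similarity_loss(x, Y)
  }
  ng <- array(num_grad(f, as.numeric(X), eps = 1e-5), dim(X))
  expect_equal(g, ng, tolerance = 1e-4)
  # empty ground truth still yields finite gradients
  g0 <- vesselda:::seg_loss_grad(X, Y * 0, 1)
  expect_true(all(is.finite(g0)))
})

test_that("seg_config validates the four-halving constraint", {
  expect_error(seg_config(patch_shape = c(96, 100, 100)), "divisible by 16")
  expect_error(seg_config(lambda_ps = -1), "lambda_ps")
  cfg <- seg_config(patch_shape = c(32, 32, 32), base_channels = 8)
  expect_s3_class(build_unet3d(cfg), "unet3d")
})

test_that("prediction assembles patches and thresholds correctly", {
  cfg <- seg_config(patch_shape = c(16, 16, 16), base_channels = 2L, seed = 3)
  net <- build_unet3d(cfg)
  # a zeroed network emits exactly 0.5 everywhere: thresholds bracket it
  net$params <- lapply(net$params, function(p) p * 0)
  for (nm in grep("\\.g$", names(net$params), value = TRUE))
    net$params[[nm]] <- net$params[[nm]] + 1
  v <- ct_volume(array(runif(24 * 16 * 16, -1, 1), c(24, 16, 16)),
                 case_id = "p")
  lo <- predict_volume(net, v, threshold = 0.5)    # 0.5 >= 0.5
  expect_true(all(lo$mask == 1))
  hi <- predict_volume(net, v, threshold = 0.6)
  expect_true(all(hi$mask == 0))
  expect_identical(dim(lo$mask), dim(v$voxels))    # shape conservation
})

test_that("a short training run reduces the dice loss", {
  set.seed(27)
  m <- array(0, c(32, 32, 32)); m[, 14:18, 10:26] <- 1
  img <- array(-0.8, c(32, 32, 32)) + m * 1.2 +
    array(rnorm(32^3, 0, 0.05), c(32, 32, 32))
  ds <- list(list(volume = ct_volume(img, case_id = "t"),
                  label = label_volume(m, "vein", "t")))
  cfg <- seg_config(patch_shape = c(32, 32, 32), base_channels = 4L,
                    lambda_ps = 0, epochs = 2L, steps_per_epoch = 10L,
                    lr = 3e-3, seed = 9)
  fit <- train_seg(ds, cfg)
  expect_lt(mean(tail(fit$log$dice, 5)), fit$log$dice[1])
  # seeded determinism of the whole loss curve
  fit2 <- train_seg(ds, cfg)
  expect_identical(fit$log, fit2$log)
})
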