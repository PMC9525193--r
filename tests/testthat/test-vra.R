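# Stage-1 losses against closed forms and independent oracles, plus the
# structural contracts of the training step.

zero_net <- function(net) {
  net$params <- lapply(net$params, function(p) p * 0)
  # norm gains of 1 keep the zeroed network well-defined
  for (nm in grep("\\.g$", names(net$params), value = TRUE))
    net$params[[nm]] <- net$params[[nm]] + 1
  net
}

rand_img <- function(h = 16, w = 16, seed = 1) {
  set.seed(seed)
  array(runif(h * w, -1, 1), c(h, w, 1))
}

test_that("adversarial loss matches its closed forms and a BCE oracle", {
  D <- zero_net(build_discriminator(base = 2L, n_strided = 2L))
  real <- rand_img(seed = 1); fake <- rand_img(seed = 2)
  al <- adversarial_loss(D, real, fake)
  # an indifferent discriminator scores 0.5 everywhere: d_loss = 2 ln 2
  expect_equal(al$d_loss, 2 * log(2), tolerance = 1e-9)
  expect_equal(al$g_loss, log(2), tolerance = 1e-9)

  # random fixed score grids against an elementwise cross-entropy oracle
  set.seed(3)
  for (i in 1:5) {
    sr <- array(runif(12), c(3, 4)); sf <- array(runif(12), c(3, 4))
    d_loss <- vesselda:::gan_grid(sr, 1)$loss + vesselda:::gan_grid(sf, 0)$loss
    expect_equal(d_loss, oracle_bce(sr, 1) + oracle_bce(sf, 0),
                 tolerance = 1e-6)
    expect_equal(vesselda:::gan_grid(sf, 1)$loss, oracle_bce(sf, 1),
                 tolerance = 1e-6)
  }
  # saturated scores are clamped, not infinite
  expect_true(is.finite(vesselda:::gan_grid(array(c(0, 1), c(1, 2)), 1)$loss))
  expect_equal(vesselda:::gan_grid(array(1, c(2, 2)), 1)$loss, 0,
               tolerance = 1e-6)         # perfect scores: loss ~ 0 up to clamp
})

test_that("mask activation keeps vessel pixels and floors the background", {
  img <- rand_img(8, 8, seed = 4)
  ones <- matrix(1, 8, 8)
  expect_equal(local_activation(img, ones), img, ignore_attr = TRUE)
  z <- local_activation(img, matrix(0, 8, 8))
  expect_true(attr(z, "empty"))
  expect_true(all(z == -1))                        # normalization floor
  chk <- matrix(rep_len(c(0, 1), 64), 8, 8)
  a <- local_activation(img, chk)
  expect_equal(sum(a != -1), sum(chk))   # support equals the mask support
})

test_that("local information loss masks, degenerates and matches the oracle", {
  LD <- zero_net(build_discriminator(base = 2L, n_strided = 2L))
  img <- rand_img(16, 16, seed = 5)
  mask <- matrix(0, 16, 16); mask[4:9, 6:12] <- 1
  # identical inputs under an indifferent LD: the 2 ln 2 fixed point
  r <- local_information_loss(LD, list(image = img, mask = mask),
                              list(image = img, mask = mask))
  expect_equal(r$d_loss, 2 * log(2), tolerance = 1e-9)
  # both masks empty: defined null contribution
  r0 <- local_information_loss(LD, list(image = img, mask = mask * 0),
                               list(image = img, mask = mask * 0))
  expect_equal(r0$d_loss, 0)
  expect_true(r0$empty)
  # with an all-ones mask the local path degenerates to the global path
  set.seed(6)
  LD2 <- build_discriminator(base = 2L, n_strided = 2L)
  fake <- rand_img(16, 16, seed = 7)
  ones <- matrix(1, 16, 16)
  rl <- local_information_loss(LD2, list(image = img, mask = ones),
                               list(image = fake, mask = ones))
  rg <- adversarial_loss(LD2, img, fake)
  expect_identical(rl$d_loss, rg$d_loss)
  expect_identical(rl$g_loss, rg$g_loss)
})

test_that("cycle and identity losses reduce to their closed forms", {
  img <- rand_img(8, 8, seed = 8)
  expect_equal(cycle_loss(img, img), 0)
  expect_equal(cycle_loss(img, img + 0.3), 0.09, tolerance = 1e-12)
  expect_equal(cycle_loss(img, img + 0.3, type = "l1"), 0.3, tolerance = 1e-12)
  other <- rand_img(8, 8, seed = 9)
  expect_equal(cycle_loss(img, other), mean((other - img)^2))  # oracle

  Gid <- build_generator(identity = TRUE)
  expect_equal(identity_loss(Gid, img), 0, tolerance = 1e-12)
  Gplus <- Gid; Gplus$params$g0.b <- 0.1
  expect_equal(identity_loss(Gplus, img), 0.01, tolerance = 1e-6)
})

make_batch <- function(seed = 10, h = 16) {
  set.seed(seed)
  mk <- function() {
    m <- matrix(0, h, h); m[sample(h, 3), sample(h, 3)] <- 1
    list(image = array(runif(h * h, -1, 1), c(h, h, 1)), mask = m)
  }
  list(a = mk(), b = mk())
}

test_that("identity-initialized generators are stationary when only
           reconstruction terms are active", {
  st <- vra_init(base = 2L, n_res = 1L,
                 weights = vra_weights(lambda2 = 0, lambda3 = 0), seed = 1)
  st$nets$G_AB <- build_generator(identity = TRUE)
  st$nets$G_BA <- build_generator(identity = TRUE)
  st$opt$G <- vesselda:::adam_init(
    c(vesselda:::prefix_names(st$nets$G_AB$params, "AB."),
      vesselda:::prefix_names(st$nets$G_BA$params, "BA.")))
  before <- list(AB = st$nets$G_AB$params, BA = st$nets$G_BA$params)
  r <- vra_training_step(st, make_batch())
  expect_equal(r$report$l_cycle, 0, tolerance = 1e-12)
  expect_equal(r$report$l_idt, 0, tolerance = 1e-12)
  expect_equal(r$report$l_total, 0, tolerance = 1e-12)
  expect_identical(r$state$nets$G_AB$params, before$AB)   # stationary
  expect_identical(r$state$nets$G_BA$params, before$BA)
})

test_that("the loss report is consistent and the step is deterministic", {
  run_once <- function() {
    st <- vra_init(base = 2L, n_res = 1L, seed = 7)
    out <- list()
    for (i in 1:3) {
      r <- vra_training_step(st, make_batch(seed = i))
      st <- r$state
      out[[i]] <- r$report
    }
    dplyr::bind_rows(out)
  }
  l1 <- run_once()
  l2 <- run_once()
  expect_identical(l1, l2)                         # seeded determinism
  w <- vra_weights()
  expect_equal(l1$l_total,
               w$lambda1 * l1$l_cycle + w$lambda2 * l1$l_adv +
                 w$lambda3 * l1$l_local + w$lambda4 * l1$l_idt,
               tolerance = 1e-6)
  expect_true(all(l1$l_cycle >= 0 & l1$l_adv >= 0 &
                    l1$l_local >= 0 & l1$l_idt >= 0))
})

test_that("volume translation preserves shape, order and tags", {
  v <- ct_volume(array(runif(5 * 16 * 16, -1, 1), c(5, 16, 16)),
                 phase = "arterial", case_id = "t")
  Gid <- build_generator(identity = TRUE)
  out <- translate_volume(Gid, v)
  expect_equal(out$voxels, v$voxels, tolerance = 1e-6)  # identity generator
  expect_identical(out$phase, "pseudo_venous")
  expect_identical(dim(out$voxels), dim(v$voxels))
  expect_identical(translate_volume(Gid, v, "b2a")$phase, "pseudo_arterial")
})
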