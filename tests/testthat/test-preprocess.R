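test_that("window defaults give the [-20, 400] band and normalized anchors", {
  ws <- window_spec()
  expect_equal(c(ws$lo, ws$hi), c(-20, 400))
  v <- ct_volume(array(c(-500, -20, 190, 400, 1000, 0, 0, 0), c(2, 2, 2)))
  n <- window_and_normalize(v, ws)
  expect_equal(n$voxels[1, 1, 1], -1)   # below the band clips to -1
  expect_equal(n$voxels[2, 1, 1], -1)   # lower bound
  expect_equal(n$voxels[1, 2, 1], 0)    # window level maps to the midpoint
  expect_equal(n$voxels[2, 2, 1], 1)    # upper bound
  expect_equal(n$voxels[1, 1, 2], 1)    # above the band clips to +1
  expect_error(window_spec(width = 0), "width")
})

test_that("windowing is monotone and idempotent", {
  set.seed(7)
  x <- sort(runif(64, -600, 900))
  v <- ct_volume(array(x, c(4, 4, 4)))
  n1 <- window_and_normalize(v)
  expect_true(all(diff(as.numeric(n1$voxels)) >= 0))      # monotone
  n2 <- window_and_normalize(n1)
  expect_identical(n2$voxels, n1$voxels)                  # idempotent
})

test_that("cropping keeps exactly the annotated slice range", {
  D <- 300
  m <- array(0, c(D, 6, 6))
  m[40:120, 3, 3] <- 1
  v <- ct_volume(array(rnorm(D * 36), c(D, 6, 6)))
  lab <- label_volume(m, "vein")
  r <- crop_to_labeled_slices(v, lab, margin = 0)
  expect_equal(dim(r$volume$voxels)[1], 81)
  expect_equal(sum(r$labels$mask), sum(m))       # no annotated voxel lost
  r5 <- crop_to_labeled_slices(v, lab, margin = 5)
  expect_equal(dim(r5$volume$voxels)[1], 91)
  expect_error(crop_to_labeled_slices(v, label_volume(array(0, dim(m)), "vein")),
               "empty")
})

test_that("slice resizing keeps labels binary and reproduces constants", {
  set.seed(8)
  v <- ct_volume(array(5.5, c(2, 64, 64)))
  m <- array(0, c(2, 64, 64)); m[, 20:26, 30:33] <- 1
  r <- resize_slicewise(v, label_volume(m, "vein"), out_hw = c(44, 44))
  expect_true(all(r$labels$mask %in% c(0, 1)))
  expect_true(sum(r$labels$mask) > 0)
  expect_equal(max(abs(r$volume$voxels - 5.5)), 0, tolerance = 1e-6)
  expect_equal(r$volume$spacing[2], 1 * 64 / 44)

  # a 6-voxel-wide tube in a 512x512 slice survives the 352/512 shrink,
  # cross-checked against a stand-alone nearest-neighbour oracle
  big <- array(0, c(1, 512, 512)); big[1, 250:255, ] <- 1
  rb <- resize_slicewise(ct_volume(array(0, c(1, 512, 512))),
                         label_volume(big, "artery"))
  expect_true(sum(rb$labels$mask) > 0)
  src <- round((seq_len(352) - 0.5) * 512 / 352 - 0.5)
  oracle_rows <- sum(src >= 249 & src <= 254)    # 0-based rows of the tube
  expect_equal(sum(rb$labels$mask[1, , 1]), oracle_rows)
})

test_that("augmentation is seeded, shared between image and mask, and a
           90-degree rotation conserves mask voxels", {
  img <- array(rnorm(4 * 16 * 16), c(4, 16, 16))
  m <- array(0, c(4, 16, 16)); m[, 5:7, 9:12] <- 1

  null_spec <- augment_spec(max_rotation_deg = 0, scale_range = c(1, 1))
  a0 <- augment(img, m, null_spec)
  expect_identical(a0$patch, img)
  expect_identical(a0$mask, m)

  sp <- augment_spec(seed = 33)
  a1 <- augment(img, m, sp)
  a2 <- augment(img, m, sp)
  expect_identical(a1$patch, a2$patch)
  expect_identical(a1$mask, a2$mask)
  expect_true(all(a1$mask %in% c(0, 1)))

  # exact quarter-turn: nearest-neighbour sampling must match the array
  # rotation oracle, so the voxel count is conserved
  rot90 <- function(sl) t(sl)[, rev(seq_len(ncol(sl)))]
  th <- 90 * pi / 180
  A <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  w <- vesselda:::.warp_affine2d(m[1, , ], A, 0L)
  expect_equal(sum(w), sum(m[1, , ]))
  expect_true(sum(w) > 0)
})

test_that("window coverage diagnostic counts in-band label voxels", {
  v <- ct_volume(array(c(100, 100, -300, 100, 100, 100, 100, 100), c(2, 2, 2)))
  m <- array(1, c(2, 2, 2))
  expect_equal(label_window_coverage(v, label_volume(m, "vein")), 7 / 8)
})

test_that("YAML config round-trips preprocessing parameters", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("preprocess:", "  window_width: 400", "  window_level: 40",
               "  out_hw: [64, 64]"), f)
  cfg <- preprocess_config(read_config(f))
  expect_equal(cfg$window$lo, -160)
  expect_equal(cfg$out_hw, c(64, 64))
  expect_equal(cfg$augment$max_rotation_deg, 10)   # default retained
})
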