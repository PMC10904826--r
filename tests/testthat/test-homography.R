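test_that("build_homography solves the trapezoid corner mapping", {
  # identity at delta = 0
  H0 <- build_homography(101, 51, 0)
  expect_equal(H0$matrix, diag(3), tolerance = 1e-9)

  # W=101, H=51, delta=+0.05: bottom corners move by +-2.5 px
  H <- build_homography(101, 51, 0.05)
  corners <- rbind(c(0, 0), c(100, 0), c(0, 50), c(100, 50))
  mapped <- apply_homography(H, corners)
  expect_equal(mapped[1, ], c(0, 0), tolerance = 1e-9)
  expect_equal(mapped[2, ], c(100, 0), tolerance = 1e-9)
  expect_equal(mapped[3, ], c(-2.5, 50), tolerance = 1e-9)
  expect_equal(mapped[4, ], c(102.5, 50), tolerance = 1e-9)

  # top edge is fixed pointwise; matrix invertible for legal deltas
  for (delta in c(-0.4, -0.05, 0.02, 0.3)) {
    Hd <- build_homography(64, 48, delta)
    expect_gt(abs(det(Hd$matrix)), 0)
    xs <- seq(0, 63, by = 7)
    top <- apply_homography(Hd, cbind(xs, 0))
    expect_equal(top, cbind(xs, 0), tolerance = 1e-8, ignore_attr = TRUE)
    # bottom width scales by (1 + delta)
    bot <- apply_homography(Hd, rbind(c(0, 47), c(63, 47)))
    expect_equal(bot[2, 1] - bot[1, 1], 63 * (1 + delta), tolerance = 1e-8)
  }

  # bottom-anchored variant fixes the bottom edge instead
  Hb <- build_homography(64, 48, 0.1, anchor = "bottom")
  bot <- apply_homography(Hb, rbind(c(0, 47), c(63, 47)))
  expect_equal(bot, rbind(c(0, 47), c(63, 47)), tolerance = 1e-8,
               ignore_attr = TRUE)

  expect_error(build_homography(64, 48, 0.6), "<= 0.5")
})

test_that("warp round trip recovers interior blobs (IoU >= 0.95)", {
  h <- 120; w <- 160
  msk <- disk_mask(h, w, cx = 80, cy = 60, r = 12)   # ~450 px, interior
  img <- 0.2 + 0.6 * msk
  H <- build_homography(w, h, 0.05)
  fwd <- warp_homography(img, H, msk)
  back <- warp_homography(fwd$image, invert_homography(H), fwd$mask)
  expect_gte(binary_iou(back$mask, msk), 0.95)
  expect_gte(binary_iou((back$image > 0.5) * 1L, msk), 0.95)
})

test_that("image-path and mask-path warps stay aligned (IoU >= 0.9)", {
  h <- 120; w <- 160
  for (case in list(list(flip = TRUE, delta = 0.05),
                    list(flip = FALSE, delta = -0.05),
                    list(flip = TRUE, delta = -0.03))) {
    msk <- disk_mask(h, w, cx = 100, cy = 70, r = 9)  # >= 200 px blob
    expect_gte(sum(msk), 200)
    indicator <- matrix(as.numeric(msk), h, w)
    fl <- horizontal_flip(indicator, msk, force = case$flip)
    tr <- trapezoid_transform(fl$image, fl$mask, delta = case$delta)
    via_image <- (tr$image >= 0.5) * 1L
    expect_gte(binary_iou(via_image, tr$mask), 0.9)
    # nearest-neighbor keeps masks binary
    expect_true(all(tr$mask %in% c(0L, 1L)))
  }
})

test_that("trapezoid_transform maps the mask centroid with the homography", {
  h <- 100; w <- 140
  msk <- disk_mask(h, w, cx = 60, cy = 55, r = 8)
  img <- matrix(0.5, h, w)
  tr <- trapezoid_transform(img, msk, delta = 0.05)
  px0 <- which(msk == 1, arr.ind = TRUE)
  c0 <- c(mean(px0[, 2]) - 1, mean(px0[, 1]) - 1)        # (x, y), 0-based
  H <- build_homography(w, h, 0.05)
  c_exp <- apply_homography(H, matrix(c0, 1))
  px1 <- which(tr$mask == 1, arr.ind = TRUE)
  c1 <- c(mean(px1[, 2]) - 1, mean(px1[, 1]) - 1)
  expect_lt(sqrt(sum((c1 - c_exp)^2)), 1.5)

  # delta_range = 0 is the identity
  tr0 <- trapezoid_transform(img, msk, delta_range = 0)
  expect_identical(tr0$image, img)
  expect_identical(tr0$mask, msk)
})

test_that("compose_augmentation applies the fixed op order jointly", {
  cfg <- tiny_phantom_config()
  s <- generate_phantom(cfg, "CystTumor", seed = 4, sample_id = "t")
  ac <- augmentation_config(crop_size = c(80, 60))

  # all ops disabled -> crop only
  ac0 <- augmentation_config(crop_size = c(80, 60), enabled_ops = character(0))
  out0 <- compose_augmentation(s, ac0)
  cr <- center_crop(s$image, c(80, 60), s$attention_label)
  expect_identical(out0$image, cr$image)
  expect_identical(out0$attention_label, cr$mask)

  # forced (b=1, c=1, flip, delta=0) == flip then crop
  out1 <- compose_augmentation(s, ac, b = 1, contrast = 1,
                               force_flip = TRUE, delta = 0)
  fl <- horizontal_flip(s$image, s$attention_label, force = TRUE)
  cr1 <- center_crop(fl$image, c(80, 60), fl$mask)
  expect_equal(out1$image, cr1$image, tolerance = 1e-12)
  expect_identical(out1$attention_label, cr1$mask)

  # joint contract: output mask shape equals output image shape
  set.seed(5)
  out2 <- compose_augmentation(s, ac)
  expect_identical(dim(out2$attention_label), dim(out2$image))
  log <- attr(out2, "aug_log")
  expect_named(log, c("intensity", "flipped", "delta"))

  # reproducible under a fixed seed
  set.seed(99); a <- compose_augmentation(s, ac)
  set.seed(99); b <- compose_augmentation(s, ac)
  expect_identical(a, b)
})
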