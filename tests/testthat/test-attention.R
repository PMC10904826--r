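test_that("compute_gradcam is the GAP-weighted feature sum", {
  cfg <- loss_config(gradcam_relu = FALSE)

  # all-zero gradients -> zero map
  fs <- list(maps = array(runif(2 * 3 * 4), c(2, 3, 4)),
             gradients = array(0, c(2, 3, 4)))
  expect_equal(compute_gradcam(fs, cfg), matrix(0, 2, 3))

  # K=2 constant gradients {2, -1} -> H = 2A - B (GAP of a constant is itself)
  A <- matrix(c(1, 2, 3, 4), 2, 2); B <- matrix(c(5, 6, 7, 8), 2, 2)
  fs2 <- list(maps = array(c(A, B), c(2, 2, 2)),
              gradients = array(c(rep(2, 4), rep(-1, 4)), c(2, 2, 2)))
  expect_equal(compute_gradcam(fs2, cfg), 2 * A - B)
  # ReLU clips negatives when enabled
  expect_equal(compute_gradcam(fs2, loss_config(gradcam_relu = TRUE)),
               pmax(2 * A - B, 0))

  expect_error(compute_gradcam(list(maps = array(0, c(2, 2, 2)),
                                    gradients = array(0, c(2, 3, 2)))),
               "identical shape")
})

test_that("Grad-CAM equals closed-form CAM on a conv + GAP + linear network", {
  # oracle: CAM = sum_k headW[y, k] * A_k, computed straight from the head
  # weights; for a GAP head the class-score gradient is headW[y, k]/(m*n)
  set.seed(8)
  img <- matrix(runif(48 * 64), 48, 64)
  mdl <- build_model(train_config(backbone = "tiny16", seed = 8), 3)
  fw <- attnguide:::model_forward(mdl, img)
  mn <- fw$mn
  for (y in 1:3) {
    cam <- matrix(0, dim(fw$featmaps)[1], dim(fw$featmaps)[2])
    for (k in seq_len(mdl$n_features))
      cam <- cam + mdl$fcW[y, k] / mdl$feat_sd[k] * fw$featmaps[, , k]
    att <- model_attention(mdl, img, class_idx = y,
                           config = loss_config(gradcam_relu = FALSE))
    expect_lt(max(abs(att$map - cam / mn)), 1e-5)
    att_r <- model_attention(mdl, img, class_idx = y,
                             config = loss_config(gradcam_relu = TRUE))
    expect_lt(max(abs(att_r$map - pmax(cam / mn, 0))), 1e-5)
  }
})

test_that("soft_mask implements upsample, min-max normalize, steep sigmoid", {
  cfg <- loss_config(theta = 0.5, omega = 100)

  # entry exactly at theta -> 0.5; entry at 1 -> s(50) ~ 1
  m <- matrix(c(0, 0.5, 1, 0.25), 2, 2)   # m[2,1] = 0.5, m[1,2] = 1
  sm <- soft_mask(m, c(2, 2), cfg)
  expect_equal(sm[2, 1], 0.5, tolerance = 1e-5)   # H-bar = theta -> s(0)
  expect_lt(abs(sm[1, 2] - 1), 1e-15)             # H-bar = 1 -> s(50)
  expect_lt(sm[1, 1], 1e-15)                      # H-bar = 0 -> s(-50)
  # mathematically in (0,1); the upper end saturates to 1.0 in doubles
  expect_true(all(sm > 0 & sm <= 1))

  # constant map: epsilon guard makes H-bar ~ 0 -> s(-omega * theta)
  cm <- soft_mask(matrix(0.7, 3, 3), c(3, 3), cfg)
  expect_equal(as.numeric(cm), rep(1 / (1 + exp(100 * 0.5)), 9),
               tolerance = 1e-12)

  # sharpening limit: omega = 1e4 approximates the indicator of {H-bar > theta}
  set.seed(12)
  vals <- sample(c(seq(0, 0.45, by = 0.05), seq(0.55, 1, by = 0.05)), 16,
                 replace = TRUE)
  vals[1] <- 0; vals[2] <- 1                       # pin the min-max range
  mm <- matrix(vals, 4, 4)
  smm <- soft_mask(mm, c(4, 4), loss_config(theta = 0.5, omega = 1e4))
  expect_lt(max(abs(smm - (mm > 0.5))), 1e-6)
})

test_that("soft_iou equals pixel-counting IoU on binary grids", {
  # frozen 2x2 example: |intersection| = 1, |union| = 3
  Hm <- matrix(c(1, 0, 1, 0), 2, 2)
  Y <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_equal(soft_iou(Hm, Y), 1 / 3)
  expect_equal(soft_iou(Hm, Y, relaxation = "minmax"), 1 / 3)

  expect_equal(soft_iou(Y, Y), 1)
  expect_equal(soft_iou(matrix(c(1, 0, 0, 0), 2), matrix(c(0, 0, 0, 1), 2)), 0)

  # property: 200 random binary grids against the counting oracle, both
  # relaxations
  set.seed(31)
  for (i in 1:200) {
    h <- sample(2:16, 1); w <- sample(2:16, 1)
    a <- matrix(rbinom(h * w, 1, runif(1, 0.2, 0.8)), h, w)
    b <- matrix(rbinom(h * w, 1, runif(1, 0.2, 0.8)), h, w)
    if (sum(b) == 0) b[1, 1] <- 1
    expect_identical(soft_iou(a, b), binary_iou(a, b))
    expect_identical(soft_iou(a, b, "minmax"), binary_iou(a, b))
  }

  expect_error(soft_iou(Hm, matrix(0, 2, 2)), "foreground")
  expect_error(soft_iou(Hm, matrix(0.5, 2, 2)), "binary")
  expect_error(soft_iou(Hm, matrix(1, 3, 3)), "shapes differ")
})

test_that("soft_iou is monotone in the soft mask relative to the label", {
  set.seed(13)
  Y <- disk_mask(8, 8, 4, 4, 2)
  m <- matrix(runif(64, 0.05, 0.6), 8, 8)
  base <- soft_iou(m, Y)
  # growing inside the label support never decreases IoU
  m_in <- m; m_in[Y == 1] <- pmin(m_in[Y == 1] + 0.3, 1)
  expect_gte(soft_iou(m_in, Y), base)
  # growing strictly outside never increases it
  m_out <- m; m_out[Y == 0] <- pmin(m_out[Y == 0] + 0.3, 1)
  expect_lte(soft_iou(m_out, Y), base)
})

test_that("attention_loss is conditional on the label", {
  expect_identical(attention_loss(NULL, NULL), 0)
  Y <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_equal(attention_loss(Y, Y), 0)
  expect_equal(attention_loss(matrix(c(1, 0, 1, 0), 2, 2),
                              matrix(c(1, 1, 0, 0), 2, 2)), 2 / 3)
  expect_error(attention_loss(NULL, Y), "no soft mask")
})

test_that("classification_loss matches direct softmax evaluation", {
  # uniform logits -> log(N_c)
  expect_equal(classification_loss(c(0, 0, 0), 1), log(3), tolerance = 1e-12)
  # saturated softmax -> ~0
  expect_lt(classification_loss(c(100, 0, 0), 1), 1e-10)
  # direct evaluation oracle on (1, 2, 3), y = 3
  direct <- -log(exp(3) / sum(exp(1:3)))
  expect_equal(classification_loss(c(1, 2, 3), 3), direct, tolerance = 1e-10)
  expect_equal(classification_loss(c(1, 2, 3), 3), 0.40760596444658, # frozen
               tolerance = 1e-10)
  # log-sum-exp stability at extreme logits
  expect_true(is.finite(classification_loss(c(1e4, -1e4, 0), 2)))
  # property: matches naive formula on random logits where both are stable
  set.seed(14)
  for (i in 1:50) {
    z <- rnorm(sample(2:6, 1), sd = 3)
    y <- sample(length(z), 1)
    expect_equal(classification_loss(z, y), -log(exp(z[y]) / sum(exp(z))),
                 tolerance = 1e-10)
  }
  expect_error(classification_loss(c(1, 2, 3), 4), "invalid class index")
  expect_error(classification_loss(5, 1), "at least 2 classes")
})

test_that("total_loss is the weighted sum with the stated defaults", {
  cfg <- loss_config()           # alpha_cls = 2, alpha_att = 1
  expect_identical(total_loss(0, 0, cfg), 0)
  expect_identical(total_loss(1.0, 0.5, cfg), 2.5)
  # unlabeled sample: l_att = 0 leaves only the weighted cross-entropy
  expect_identical(total_loss(0.7, attention_loss(NULL, NULL), cfg), 1.4)
})

test_that("attention-loss gradients match central finite differences", {
  # 3-channel 4x4 toy stack, away from ReLU/min-max kinks
  set.seed(21)
  for (relu in c(FALSE, TRUE)) {
    cfg <- loss_config(omega = 4, theta = 0.5, gradcam_relu = relu)
    maps <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
    w <- rnorm(3)
    Y <- matrix(rbinom(64, 1, 0.4), 8, 8); Y[1, 1] <- 1L
    ch <- attnguide:::attention_chain(maps, w, Y, cfg)
    h <- 1e-5
    for (i in sample(length(maps), 12)) {
      mp <- maps; mp[i] <- mp[i] + h
      mm <- maps; mm[i] <- mm[i] - h
      fd <- (attnguide:::attention_chain(mp, w, Y, cfg)$loss -
             attnguide:::attention_chain(mm, w, Y, cfg)$loss) / (2 * h)
      expect_equal(ch$dmaps[i], fd,
                   tolerance = 1e-4 * max(1, abs(fd)))
    }
    for (k in 1:3) {
      wp <- w; wp[k] <- wp[k] + h
      wm <- w; wm[k] <- wm[k] - h
      fd <- (attnguide:::attention_chain(maps, wp, Y, cfg)$loss -
             attnguide:::attention_chain(maps, wm, Y, cfg)$loss) / (2 * h)
      expect_equal(ch$dweights[k], fd, tolerance = 1e-4 * max(1, abs(fd)))
    }
  }
})

test_that("loss_config validates hyperparameters", {
  expect_error(loss_config(theta = 1.2), "theta")
  expect_error(loss_config(omega = 0), "omega")
  expect_error(loss_config(alpha_cls = -1), "weights")
  expect_error(loss_config(epsilon = 0), "epsilon")
})
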