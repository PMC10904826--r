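test_that("split_dataset is stratified, seeded, disjoint and exhaustive", {
  cfg <- tiny_phantom_config(n = 10L)
  d <- generate_dataset(cfg, 1, seed = 1)

  sp <- split_dataset(d$samples, seed = 5)
  # 10 per class at 6:2:2 -> exactly (6, 2, 2) per class
  counts <- c(train = 6L, val = 2L, test = 2L)
  for (nm in names(sp)) {
    tab <- table(vapply(sp[[nm]], `[[`, character(1), "class_label"))
    expect_true(all(tab == counts[[nm]]), info = nm)
  }
  ids <- lapply(sp, function(p) vapply(p, `[[`, character(1), "sample_id"))
  expect_length(intersect(ids$train, ids$val), 0)
  expect_length(intersect(ids$train, ids$test), 0)
  expect_length(intersect(ids$val, ids$test), 0)
  expect_setequal(unlist(ids), names(d$samples))

  # same seed twice -> identical partition
  sp2 <- split_dataset(d$samples, seed = 5)
  expect_identical(ids, lapply(sp2, function(p)
    vapply(p, `[[`, character(1), "sample_id")))

  # floor rounding with remainder assigned train-first: n = 11 -> (7, 2, 2)
  d11 <- generate_dataset(tiny_phantom_config(n = 11L), 1, seed = 2)
  one_class <- Filter(function(s) s$class_label == "Normal", d11$samples)
  sp11 <- split_dataset(one_class, seed = 3)
  expect_identical(lengths(sp11), c(train = 7L, val = 2L, test = 2L))

  expect_error(split_dataset(one_class[1:2], seed = 1), ">= 3 samples")
})

test_that("attention budget flags exact ceil counts with nested subsets", {
  # synthetic budget fixture: 259 lesion samples with masks
  mk <- function(i, masked) structure(list(
    image = matrix(0.5, 4, 4), class_label = "CystTumor",
    attention_label = if (masked) matrix(1L, 4, 4),
    sample_id = sprintf("s%03d", i)), class = "radiograph_sample")
  train <- lapply(1:259, mk, masked = TRUE)

  flagged_ids <- function(tr) vapply(Filter(function(s) s$use_attention, tr),
                                     `[[`, character(1), "sample_id")

  b0 <- assign_attention_budget(train, 0, seed = 9)
  expect_length(flagged_ids(b0), 0)
  b1 <- assign_attention_budget(train, 1, seed = 9)
  expect_length(flagged_ids(b1), 259)
  # ceil(0.05 * 259) = 13
  b05 <- assign_attention_budget(train, 0.05, seed = 9)
  expect_length(flagged_ids(b05), 13)

  # monotone nesting under the same seed
  prev <- character(0)
  for (rate in c(0, 0.05, 0.1, 0.2, 0.5, 1)) {
    cur <- flagged_ids(assign_attention_budget(train, rate, seed = 9))
    expect_length(cur, ceiling(rate * 259))
    expect_true(all(prev %in% cur))
    prev <- cur
  }

  # unmasked samples are never flagged
  mixed <- c(lapply(1:5, mk, masked = TRUE), lapply(6:10, mk, masked = FALSE))
  bm <- assign_attention_budget(mixed, 1, seed = 2)
  expect_length(flagged_ids(bm), 5)
})

test_that("training is reproducible and decomposes its loss exactly", {
  cfg <- tiny_phantom_config()
  d <- generate_dataset(cfg, 1, seed = 6)
  sp <- split_dataset(d$samples, seed = 6)
  tr <- assign_attention_budget(sp$train, 1, seed = 6)
  tc <- tiny_train_config(epochs = 2L, seed = 6)

  r1 <- train_model(tr, sp$val, tc)
  r2 <- train_model(tr, sp$val, tc)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$model, r2$model)

  # loss decomposition: total = alpha_cls * cls + alpha_att * att
  with(r1$history, expect_equal(
    loss_total, tc$loss$alpha_cls * loss_cls + tc$loss$alpha_att * loss_att,
    tolerance = 1e-6))

  # best_val_accuracy is the max of the history
  expect_equal(r1$best_val_accuracy, max(r1$history$val_accuracy))
  expect_equal(r1$best_epoch,
               which.max(r1$history$val_accuracy))
})

test_that("rate-0 budget and alpha_att = 0 give identical trajectories", {
  cfg <- tiny_phantom_config()
  d <- generate_dataset(cfg, 1, seed = 8)
  sp <- split_dataset(d$samples, seed = 8)
  tc <- tiny_train_config(epochs = 2L, seed = 8)

  tr0 <- assign_attention_budget(sp$train, 0, seed = 8)
  r0 <- train_model(tr0, sp$val, tc)

  tc_a0 <- tc; tc_a0$loss$alpha_cls <- tc$loss$alpha_cls
  tc_a0$loss$alpha_att <- 0
  tr1 <- assign_attention_budget(sp$train, 1, seed = 8)
  ra0 <- train_model(tr1, sp$val, tc_a0)

  # epoch-1 classification loss and the whole parameter trajectory agree:
  # Eq-style conditional attention term contributes nothing either way
  expect_equal(r0$history$loss_cls[1], ra0$history$loss_cls[1],
               tolerance = 1e-12)
  expect_identical(r0$model$fcW, ra0$model$fcW)
  expect_identical(r0$model$layers, ra0$model$layers)
  expect_equal(r0$history$val_accuracy, ra0$history$val_accuracy)
  # rate 0 logs a zero attention loss (the "otherwise" branch)
  expect_true(all(r0$history$loss_att == 0))
})

test_that("test samples never reach training (no-leak)", {
  cfg <- tiny_phantom_config()
  d <- generate_dataset(cfg, 1, seed = 10)
  sp <- split_dataset(d$samples, seed = 10)
  tr <- assign_attention_budget(sp$train, 0.5, seed = 10)
  tc <- tiny_train_config(epochs = 2L, seed = 10)
  res <- train_model(tr, sp$val, tc)
  test_ids <- vapply(sp$test, `[[`, character(1), "sample_id")
  expect_length(intersect(res$train_ids, test_ids), 0)
  val_ids <- vapply(sp$val, `[[`, character(1), "sample_id")
  expect_length(intersect(res$train_ids, val_ids), 0)
})

test_that("run_experiment emits the per-rate summary schema", {
  cfg <- tiny_phantom_config()
  d <- generate_dataset(cfg, 1, seed = 12)
  tc <- tiny_train_config(epochs = 1L, seed = 12)
  tc$repeats <- 2L
  ex <- run_experiment(d$samples, rates = c(0, 1), config = tc)
  expect_identical(nrow(ex$runs), 4L)
  expect_identical(nrow(ex$summary), 2L)
  expect_true(all(c("accuracy.mean", "accuracy.sd", "sensitivity.mean",
                    "specificity.mean", "localization_iou.mean") %in%
                  names(ex$summary)))
  # per-repeat seeds derive from the base seed
  expect_identical(ex$runs$seed, rep(c(13L, 14L), 2))
})

test_that("train_config validates the protocol invariants", {
  expect_error(train_config(patience = 200, epochs = 100), "patience")
  expect_error(train_config(learning_rate = 0), "positive")
})
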