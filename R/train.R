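#' Training configuration
#'
#' Defaults follow the full-scale protocol: SGD with initial learning rate
#' 1e-3 and weight decay 1e-5, cosine-annealed per epoch with T_max = 50,
#' 100 epochs, batch size 8, dropout 0.25 on the pooled features,
#' early-stopping patience 40 epochs, 5 repeats, loss weights (2, 1).
#' Desk-scale runs shrink \code{epochs}/\code{patience} and use a tiny
#' backbone.
#'
#' @param backbone \code{"tiny16"} (default), \code{"tiny32"} or
#'   \code{"resnet50"} (errors offline; see \code{\link{build_model}}).
#' @param dropout_rate,learning_rate,weight_decay,cosine_T_max,epochs,
#'   batch_size,patience,repeats numeric scalars as described above.
#' @param grad_clip per-parameter-group L2 gradient-norm ceiling (Inf
#'   disables); stabilizes from-scratch desk-scale training, where the
#'   feature-standardized head passes large gradients into the backbone.
#' @param momentum SGD momentum coefficient (0 disables).
#' @param backbone_lr_scale multiplier on the learning rate for the conv
#'   layers (1 = same as head).
#' @param recalibrate_every re-freeze the GAP-feature standardization every
#'   this many epochs (0 = calibrate once at initialization only).
#' @param loss a \code{\link{loss_config}}.
#' @param augmentation an \code{\link{augmentation_config}} or NULL to train
#'   on raw (uncropped) images.
#' @param seed base RNG seed.
#' @return a \code{train_config} object.
#' @export
train_config <- function(backbone = "tiny16", dropout_rate = 0.25,
                         learning_rate = 1e-3, weight_decay = 1e-5,
                         cosine_T_max = 50L, epochs = 100L, batch_size = 8L,
                         patience = 40L, repeats = 5L, grad_clip = 5,
                         momentum = 0.9,
                         backbone_lr_scale = 1, recalibrate_every = 0L,
                         loss = loss_config(),
                         augmentation = augmentation_config(),
                         seed = 1L) {
  if (patience > epochs) stop("patience must be <= epochs")
  if (any(c(dropout_rate < 0, learning_rate <= 0, weight_decay < 0,
            cosine_T_max <= 0, epochs <= 0, batch_size <= 0, repeats <= 0)))
    stop("training hyperparameters must be positive")
  structure(list(backbone = backbone, dropout_rate = dropout_rate,
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 cosine_T_max = as.integer(cosine_T_max),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 repeats = as.integer(repeats),
                 grad_clip = grad_clip,
                 momentum = momentum,
                 backbone_lr_scale = backbone_lr_scale,
                 recalibrate_every = as.integer(recalibrate_every),
                 loss = loss, augmentation = augmentation,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Stratified train/validation/test split
#'
#' Class-stratified seeded partition at the given ratios (default 6:2:2).
#' Within each class, split sizes are \code{floor(ratio * n)} and leftover
#' samples are assigned train-first, then validation, then test. The
#' partition is disjoint and exhaustive.
#'
#' @param samples list of \code{radiograph_sample}.
#' @param ratios length-3 numeric summing to 1.
#' @param seed integer seed.
#' @return list \code{(train, val, test)} of sample lists.
#' @export
split_dataset <- function(samples, ratios = c(0.6, 0.2, 0.2), seed = 1L) {
  if (abs(sum(ratios) - 1) > 1e-9) stop("ratios must sum to 1")
  classes <- vapply(samples, `[[`, character(1), "class_label")
  tab <- table(classes)
  if (any(tab < 3))
    stop("every class needs >= 3 samples; got: ",
         paste(names(tab), tab, sep = "=", collapse = ", "))
  set.seed(seed)
  idx <- list(train = integer(0), val = integer(0), test = integer(0))
  for (cls in names(tab)) {
    ci <- sample(which(classes == cls))
    n <- length(ci)
    sizes <- floor(ratios * n)
    rem <- n - sum(sizes)
    if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
    part <- rep.int(1:3, sizes)
    idx$train <- c(idx$train, ci[part == 1])
    idx$val <- c(idx$val, ci[part == 2])
    idx$test <- c(idx$test, ci[part == 3])
  }
  lapply(idx, function(i) samples[i])
}

#' Assign the attention-label budget to a training set
#'
#' Flags exactly \code{ceiling(rate * n)} of the mask-carrying training
#' samples (seeded shuffle) as \code{use_attention = TRUE}; the rest keep
#' their class label but do not use their mask for supervision. With a fixed
#' seed the flagged set at rate r1 is a subset of the set at r2 > r1.
#'
#' @param train list of \code{radiograph_sample}.
#' @param rate fraction in \[0,1\].
#' @param seed integer seed.
#' @return the training list with a \code{use_attention} field per sample.
#' @export
assign_attention_budget <- function(train, rate, seed = 1L) {
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  has_mask <- which(vapply(train, function(s)
    !is.null(s$attention_label), logical(1)))
  k <- ceiling(rate * length(has_mask))
  set.seed(seed)
  flagged <- head(has_mask[sample(length(has_mask))], k)
  for (i in seq_along(train))
    train[[i]]$use_attention <- i %in% flagged
  train
}

cosine_lr <- function(lr0, epoch, t_max, eta_min = 0) {
  eta_min + (lr0 - eta_min) * (1 + cos(pi * (epoch - 1) / t_max)) / 2
}

sgd_step <- function(model, grads, lr, wd, backbone_scale = 1) {
  lrb <- lr * backbone_scale
  for (i in seq_along(model$layers)) {
    model$layers[[i]]$W <- model$layers[[i]]$W -
      lrb * (grads$layers[[i]]$W + wd * model$layers[[i]]$W)
    model$layers[[i]]$b <- model$layers[[i]]$b - lrb * grads$layers[[i]]$b
  }
  model$fcW <- model$fcW - lr * (grads$fcW + wd * model$fcW)
  model$fcb <- model$fcb - lr * grads$fcb
  model
}

zero_like_grads <- function(model) {
  list(layers = lapply(model$layers, function(L)
         list(W = matrix(0, nrow(L$W), ncol(L$W)), b = numeric(length(L$b)))),
       fcW = matrix(0, nrow(model$fcW), ncol(model$fcW)),
       fcb = numeric(length(model$fcb)))
}

grad_norm <- function(g) {
  s <- sum(g$fcW^2) + sum(g$fcb^2)
  for (L in g$layers) s <- s + sum(L$W^2) + sum(L$b^2)
  sqrt(s)
}

scale_grads <- function(g, f) {
  for (i in seq_along(g$layers)) {
    g$layers[[i]]$W <- g$layers[[i]]$W * f
    g$layers[[i]]$b <- g$layers[[i]]$b * f
  }
  g$fcW <- g$fcW * f; g$fcb <- g$fcb * f
  g
}

add_grads <- function(a, b, w = 1) {
  for (i in seq_along(a$layers)) {
    a$layers[[i]]$W <- a$layers[[i]]$W + w * b$layers[[i]]$W
    a$layers[[i]]$b <- a$layers[[i]]$b + w * b$layers[[i]]$b
  }
  a$fcW <- a$fcW + w * b$fcW
  a$fcb <- a$fcb + w * b$fcb
  a
}

plain_accuracy <- function(model, samples, class_levels) {
  truth <- match(vapply(samples, `[[`, character(1), "class_label"),
                 class_levels)
  mean(predict_classes(model, samples) == truth)
}

#' Train the attention-guided classifier
#'
#' Per batch: augment on the fly (when configured); forward; softmax
#' cross-entropy for every sample; for samples flagged
#' \code{use_attention}, Grad-CAM for the ground-truth class -> soft mask ->
#' IoU attention loss, backpropagated into the feature extractor. Batch loss
#' is \code{alpha_cls * mean(cls) + alpha_att * mean(att over flagged)} (the
#' attention mean runs over flagged samples only, so its per-sample scale is
#' independent of the budget rate; 0 when none in the batch). SGD with weight
#' decay; learning rate cosine-annealed per epoch. Validation accuracy is
#' tracked each epoch; training stops once \code{patience} epochs pass
#' without improvement, and the best-validation weights are returned.
#'
#' @param train,val sample lists (train from
#'   \code{\link{assign_attention_budget}}; unflagged samples train with
#'   class labels only).
#' @param config a \code{\link{train_config}}.
#' @param verbose print one line per epoch.
#' @return a \code{run_result}: list with \code{model},
#'   \code{best_val_accuracy}, \code{best_epoch}, \code{history} (data.frame
#'   epoch/lr/loss_total/loss_cls/loss_att/val_accuracy), \code{class_levels},
#'   \code{train_ids}, \code{seed}.
#' @export
train_model <- function(train, val, config = train_config(), verbose = FALSE) {
  if (!length(train) || !length(val)) stop("empty train or validation set")
  class_levels <- sort(unique(vapply(c(train, val), `[[`, character(1),
                                     "class_label")))
  n_classes <- length(class_levels)
  model <- build_model(config, n_classes)
  model <- calibrate_features(model,
    lapply(train, function(s) preprocess_eval(s, config)))
  val_p <- lapply(val, function(s) preprocess_eval(s, config))
  lossc <- config$loss
  set.seed(config$seed)
  best_acc <- -Inf; best_epoch <- 0L; best_model <- model
  vel <- NULL
  hist <- vector("list", config$epochs)
  train_ids <- vapply(train, `[[`, character(1), "sample_id")
  for (epoch in seq_len(config$epochs)) {
    if (config$recalibrate_every > 0 &&
        (epoch - 1L) %% config$recalibrate_every == 0L && epoch > 1L)
      model <- calibrate_features(model,
        lapply(train, function(s) preprocess_eval(s, config)))
    lr <- cosine_lr(config$learning_rate, epoch, config$cosine_T_max)
    ord <- sample(length(train))
    ep_cls <- ep_att <- ep_tot <- 0; n_batches <- 0L
    for (start in seq(1, length(ord), by = config$batch_size)) {
      bidx <- ord[start:min(start + config$batch_size - 1L, length(ord))]
      nb <- length(bidx)
      batch <- lapply(bidx, function(i) {
        s <- train[[i]]
        if (!is.null(config$augmentation))
          s <- compose_augmentation(s, config$augmentation)
        s
      })
      # crop/warp can empty a mask; such samples fall back to class-only
      use_att <- vapply(batch, function(s)
        isTRUE(s$use_attention) && !is.null(s$attention_label) &&
          sum(s$attention_label) > 0, logical(1))
      n_att <- sum(use_att)
      g <- zero_like_grads(model)
      b_cls <- 0; b_att <- 0
      for (j in seq_len(nb)) {
        s <- batch[[j]]
        y <- match(s$class_label, class_levels)
        fw <- model_forward(model, s$image, train = TRUE)
        p <- softmax(fw$logits)
        b_cls <- b_cls + classification_loss(fw$logits, y)
        dlog <- (p - (seq_len(n_classes) == y)) * lossc$alpha_cls / nb
        dfeat <- NULL
        if (use_att[j]) {
          wscale <- fw$dropout / (model$feat_sd * fw$mn)
          w_k <- model$fcW[y, ] * wscale
          ch <- attention_chain(fw$featmaps, w_k, s$attention_label, lossc)
          b_att <- b_att + ch$loss
          dfeat <- ch$dmaps * lossc$alpha_att / n_att
          g$fcW[y, ] <- g$fcW[y, ] +
            ch$dweights * wscale * lossc$alpha_att / n_att
        }
        g <- add_grads(g, model_backward(model, fw, dlog, dfeat))
      }
      l_cls <- b_cls / nb
      l_att <- if (n_att > 0) b_att / n_att else 0
      l_tot <- total_loss(l_cls, l_att, lossc)
      if (!is.finite(l_tot))
        stop("non-finite loss at epoch ", epoch, " (cls=", l_cls,
             ", att=", l_att, ")")
      # per-parameter-group clipping: the feature-standardized head sends
      # gradients into the backbone at a much larger scale than its own, so a
      # global norm cap would squash the head updates
      if (is.finite(config$grad_clip)) {
        for (li in seq_along(g$layers)) {
          nl <- sqrt(sum(g$layers[[li]]$W^2) + sum(g$layers[[li]]$b^2))
          if (nl > config$grad_clip) {
            f <- config$grad_clip / nl
            g$layers[[li]]$W <- g$layers[[li]]$W * f
            g$layers[[li]]$b <- g$layers[[li]]$b * f
          }
        }
        nh <- sqrt(sum(g$fcW^2) + sum(g$fcb^2))
        if (nh > config$grad_clip) {
          f <- config$grad_clip / nh
          g$fcW <- g$fcW * f; g$fcb <- g$fcb * f
        }
      }
      # SGD with momentum: v <- mu*v + grad; w <- w - lr*(v + wd*w)
      if (config$momentum > 0) {
        if (is.null(vel)) vel <- g
        else vel <- add_grads(scale_grads(vel, config$momentum), g)
        model <- sgd_step(model, vel, lr, config$weight_decay,
                          config$backbone_lr_scale)
      } else {
        model <- sgd_step(model, g, lr, config$weight_decay,
                          config$backbone_lr_scale)
      }
      ep_cls <- ep_cls + l_cls; ep_att <- ep_att + l_att
      ep_tot <- ep_tot + l_tot; n_batches <- n_batches + 1L
    }
    val_acc <- plain_accuracy(model, val_p, class_levels)
    hist[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                loss_total = ep_tot / n_batches,
                                loss_cls = ep_cls / n_batches,
                                loss_att = ep_att / n_batches,
                                val_accuracy = val_acc)
    if (verbose)
      message(sprintf("epoch %3d lr %.2e loss %.4f val %.3f", epoch, lr,
                      ep_tot / n_batches, val_acc))
    if (val_acc > best_acc) {
      best_acc <- val_acc; best_epoch <- epoch; best_model <- model
    }
    if (epoch - best_epoch >= config$patience) break
  }
  structure(list(model = best_model,
                 best_val_accuracy = best_acc,
                 best_epoch = best_epoch,
                 history = do.call(rbind, hist[!vapply(hist, is.null, logical(1))]),
                 class_levels = class_levels,
                 train_ids = train_ids,
                 seed = config$seed),
            class = "run_result")
}

#' Evaluate a trained model on a held-out set
#'
#' @param result a \code{run_result} from \code{\link{train_model}}.
#' @param test list of samples.
#' @param config \code{\link{train_config}} used (for crop geometry: test
#'   images are center-cropped like training images, with no random ops).
#' @param loc_threshold binarization threshold for localization IoU.
#' @return list with \code{confusion}, \code{metrics}
#'   (\code{\link{macro_metrics}}), \code{localization}
#'   (\code{\link{localization_iou}} over mask-carrying test samples).
#' @export
evaluate_model <- function(result, test, config = train_config(),
                           loc_threshold = NULL) {
  test_p <- lapply(test, function(s) preprocess_eval(s, config))
  truth <- match(vapply(test_p, `[[`, character(1), "class_label"),
                 result$class_levels)
  pred <- predict_classes(result$model, test_p)
  cm <- confusion_matrix(truth, pred, length(result$class_levels),
                         labels = result$class_levels)
  loc <- localization_iou(result$model, test_p,
                          bin_threshold = loc_threshold %||%
                            config$loss$theta,
                          config = config$loss)
  list(confusion = cm, metrics = macro_metrics(cm), localization = loc)
}

# deterministic eval-time preprocessing: center crop only
preprocess_eval <- function(sample, config) {
  if (is.null(config$augmentation)) return(sample)
  cr <- center_crop(sample$image,
                    crop_size_for(config$augmentation, sample$image),
                    sample$attention_label)
  sample$image <- cr$image
  sample$attention_label <- cr$mask
  sample
}

#' Run the repeated attention-budget experiment
#'
#' For each attention rate and repeat (per-repeat seed = base seed + repeat
#' index): split 6:2:2, assign the budget, train, evaluate on the test split.
#' Emits a per-run table and a per-rate summary (mean and sd of macro
#' accuracy / sensitivity / specificity and localization IoU).
#'
#' @param samples full sample list (all lesions carrying masks).
#' @param rates numeric vector of attention rates.
#' @param config a \code{\link{train_config}} (\code{repeats}, \code{seed}).
#' @param verbose print progress.
#' @return list with \code{runs} (data.frame) and \code{summary}
#'   (data.frame, one row per rate).
#' @export
run_experiment <- function(samples, rates = c(0, 0.05, 0.1, 0.2, 0.5, 1),
                           config = train_config(), verbose = FALSE) {
  rows <- list()
  for (rate in rates) {
    for (rep_i in seq_len(config$repeats)) {
      seed_r <- config$seed + rep_i
      sp <- split_dataset(samples, seed = seed_r)
      tr <- assign_attention_budget(sp$train, rate, seed = seed_r)
      cfg <- config; cfg$seed <- seed_r
      res <- train_model(tr, sp$val, cfg)
      ev <- evaluate_model(res, sp$test, cfg)
      rows[[length(rows) + 1L]] <- data.frame(
        rate = rate, repeat_idx = rep_i, seed = seed_r,
        accuracy = ev$metrics$macro["accuracy"],
        sensitivity = ev$metrics$macro["sensitivity"],
        specificity = ev$metrics$macro["specificity"],
        overall_accuracy = ev$metrics$overall_accuracy,
        localization_iou = ev$localization$mean,
        best_epoch = res$best_epoch)
      if (verbose)
        message(sprintf("rate %.2f rep %d: acc %.2f loc-IoU %.3f",
                        rate, rep_i, rows[[length(rows)]]$accuracy,
                        rows[[length(rows)]]$localization_iou))
    }
  }
  runs <- do.call(rbind, rows); rownames(runs) <- NULL
  agg <- function(v) c(mean = mean(v), sd = if (length(v) > 1) sd(v) else 0)
  summ <- do.call(rbind, lapply(split(runs, runs$rate), function(d) {
    data.frame(rate = d$rate[1],
               t(c(accuracy = agg(d$accuracy),
                   sensitivity = agg(d$sensitivity),
                   specificity = agg(d$specificity),
                   localization_iou = agg(d$localization_iou))))
  }))
  rownames(summ) <- NULL
  list(runs = runs, summary = summ)
}

#' Frozen desk-scale experiment configuration
#'
#' The scaled-down counterpart of the full clinical protocol, used by the
#' package's own acceptance experiment: tiny16 backbone trained from scratch
#' on 320x180 phantoms for at most 20 epochs. Optimization is adapted to the
#' from-scratch short-schedule regime (frozen after a single pilot run, not
#' revisited): learning rate 0.02 with momentum 0.9, per-layer gradient
#' clipping at 1, per-epoch feature recalibration, soft-mask sharpness
#' omega = 10 (the full-scale default of 100 leaves almost no gradient band
#' over a 20-epoch from-scratch run). Everything else follows the full
#' protocol: 6:2:2 split, batch 8, dropout 0.25, weight decay 1e-5, cosine
#' T_max 50, loss weights (2, 1), 5 repeats.
#'
#' @param seed base seed (per-repeat seeds are \code{seed + repeat}).
#' @return a \code{\link{train_config}}.
#' @export
desk_train_config <- function(seed = 1L) {
  train_config(backbone = "tiny16", learning_rate = 0.02, momentum = 0.9,
               grad_clip = 1, recalibrate_every = 1L, epochs = 20L,
               patience = 20L, cosine_T_max = 50L, repeats = 5L,
               loss = loss_config(omega = 10), seed = seed)
}

#' Augmentation-ablation grid
#'
#' Trains one configuration per combination of enabled augmentation ops
#' (default: the 8 subsets of intensity/flip/trapezoid) at a fixed attention
#' rate and reports macro accuracy per combination.
#'
#' @param samples full sample list.
#' @param combos list of character vectors (subsets of
#'   \code{c("intensity","flip","trapezoid")}).
#' @param rate attention rate used for every combination.
#' @param config a \code{\link{train_config}}.
#' @return data.frame: combo, accuracy mean and sd over repeats.
#' @export
run_ablation <- function(samples,
                         combos = list(character(0), "intensity", "flip",
                                       "trapezoid", c("intensity", "flip"),
                                       c("intensity", "trapezoid"),
                                       c("flip", "trapezoid"),
                                       c("intensity", "flip", "trapezoid")),
                         rate = 1, config = train_config()) {
  rows <- lapply(combos, function(ops) {
    cfg <- config
    cfg$augmentation$enabled_ops <- ops
    ex <- run_experiment(samples, rates = rate, config = cfg)
    data.frame(combo = paste(ops, collapse = "+"),
               accuracy_mean = ex$summary$accuracy.mean,
               accuracy_sd = ex$summary$accuracy.sd)
  })
  out <- do.call(rbind, rows); rownames(out) <- NULL
  out
}
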