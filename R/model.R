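#' Build a classification model
#'
#' Assembles feature extractor -> global average pooling -> dropout ->
#' fully-connected head. Because the head is GAP + linear, the Grad-CAM
#' importance weights have the closed form \code{w_k = fcW[y, k] / (m*n)}
#' (dropout-scaled during training), so the attention map equals the
#' classical CAM up to that constant and the attention loss is exactly
#' differentiable without a second autodiff pass.
#'
#' Backbones: \code{"tiny16"} (3 conv blocks, overall stride 16; default) and
#' \code{"tiny32"} (4 blocks, stride 32 — last-conv grid
#' \code{ceiling(h/32) x ceiling(w/32)}, e.g. 940x520 input -> 30x17).
#' \code{"resnet50"} is the architecture of record for full-scale clinical
#' runs but has no pretrained weights available in a pure-R offline build and
#' raises an informative error.
#'
#' Conv and FC weights use Kaiming-uniform initialization
#' (\code{U(-sqrt(6/fan_in), +sqrt(6/fan_in))}); biases start at zero.
#'
#' @param config a \code{\link{train_config}} (uses \code{backbone},
#'   \code{dropout_rate}, \code{seed}).
#' @param n_classes number of output classes (>= 2).
#' @return an \code{attn_model} object.
#' @export
build_model <- function(config = train_config(), n_classes = 3L) {
  if (n_classes < 2) stop("need >= 2 classes")
  specs <- switch(config$backbone,
    tiny16 = list(list(c_out = 8L,  k = 7L, stride = 4L, pad = 3L),
                  list(c_out = 16L, k = 3L, stride = 2L, pad = 1L),
                  list(c_out = 32L, k = 3L, stride = 2L, pad = 1L)),
    tiny32 = list(list(c_out = 8L,  k = 7L, stride = 4L, pad = 3L),
                  list(c_out = 16L, k = 3L, stride = 2L, pad = 1L),
                  list(c_out = 32L, k = 3L, stride = 2L, pad = 1L),
                  list(c_out = 32L, k = 3L, stride = 2L, pad = 1L)),
    resnet50 = stop("backbone 'resnet50' requires pretrained torch weights, ",
                    "which are unavailable in this offline R build; ",
                    "use 'tiny16' or 'tiny32'"),
    stop("unknown backbone '", config$backbone,
         "'; available: tiny16, tiny32"))
  set.seed(config$seed)
  layers <- list(); c_in <- 1L
  for (sp in specs) {
    fan_in <- c_in * sp$k * sp$k
    bound <- sqrt(6 / fan_in)
    sp$W <- matrix(runif(sp$c_out * fan_in, -bound, bound), sp$c_out, fan_in)
    sp$b <- numeric(sp$c_out)
    sp$c_in <- c_in
    layers[[length(layers) + 1L]] <- sp
    c_in <- sp$c_out
  }
  K <- c_in
  bound <- sqrt(6 / K)
  structure(list(layers = layers,
                 fcW = matrix(runif(n_classes * K, -bound, bound), n_classes, K),
                 fcb = numeric(n_classes),
                 n_classes = as.integer(n_classes),
                 n_features = K,
                 dropout_rate = config$dropout_rate,
                 # frozen feature standardization between GAP and the head
                 # (identity until calibrated; see calibrate_features)
                 feat_mu = numeric(K),
                 feat_sd = rep(1, K),
                 backbone = config$backbone),
            class = "attn_model")
}

# Forward pass. The input is z-scored per image (standard radiograph
# preprocessing; also removes the common-mode offset an all-positive input
# would push through the ReLU stack into the pooled features). Training mode
# draws a fresh inverted-dropout mask on the pooled features. Returns logits,
# last-conv feature maps, and caches needed for the backward pass.
model_forward <- function(model, image, train = FALSE) {
  image <- (image - mean(image)) / (sd(image) + 1e-6)
  x <- array(image, c(dim(image), 1L))
  caches <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    L <- model$layers[[i]]
    pre <- conv2d_forward(x, L$W, L$b, L$k, L$k, L$stride, L$pad)
    caches[[i]] <- list(input = x, pre = pre)
    x <- pmax(pre, 0)
  }
  feat <- x                                  # h x w x K, post-ReLU
  mn <- dim(feat)[1] * dim(feat)[2]
  pooled <- apply(feat, 3, mean)
  pooled_n <- (pooled - model$feat_mu) / model$feat_sd
  drop <- if (train && model$dropout_rate > 0) {
    keep <- (runif(model$n_features) >= model$dropout_rate) * 1
    keep / (1 - model$dropout_rate)
  } else rep(1, model$n_features)
  logits <- as.numeric(model$fcW %*% (pooled_n * drop) + model$fcb)
  list(logits = logits, featmaps = feat, pooled_n = pooled_n, dropout = drop,
       mn = mn, caches = caches)
}

# Freeze the GAP-feature standardization (per-feature mean/sd over a set of
# preprocessed training images, at the initialized weights). A frozen
# data-dependent normalization: removes the common-mode feature offset that
# otherwise ill-conditions the linear head, while keeping d logits / d
# featmaps constant (the closed-form Grad-CAM property).
calibrate_features <- function(model, samples) {
  P <- vapply(samples, function(s)
    apply_convs_pooled(model, s$image), numeric(model$n_features))
  mu <- rowMeans(P)
  sdv <- apply(P, 1, sd)
  model$feat_mu <- mu
  model$feat_sd <- pmax(sdv, 1e-3 * max(sdv, 1e-8))
  model
}

apply_convs_pooled <- function(model, image) {
  image <- (image - mean(image)) / (sd(image) + 1e-6)
  x <- array(image, c(dim(image), 1L))
  for (L in model$layers)
    x <- pmax(conv2d_forward(x, L$W, L$b, L$k, L$k, L$stride, L$pad), 0)
  apply(x, 3, mean)
}

# Backward pass: dlogits (length n_classes) and an optional extra gradient
# dfeat arriving directly at the last-conv feature maps (the attention-loss
# path). Returns gradients for every parameter.
model_backward <- function(model, fw, dlogits, dfeat = NULL) {
  gfcW <- outer(dlogits, fw$pooled_n * fw$dropout)
  gfcb <- dlogits
  dpooled <- as.numeric(t(model$fcW) %*% dlogits) * fw$dropout / model$feat_sd
  K <- model$n_features
  dft <- if (is.null(dfeat)) array(0, dim(fw$featmaps)) else dfeat
  for (k in seq_len(K)) dft[, , k] <- dft[, , k] + dpooled[k] / fw$mn
  # feat was post-ReLU of the last conv
  grads <- vector("list", length(model$layers))
  g <- dft
  for (i in rev(seq_along(model$layers))) {
    L <- model$layers[[i]]
    cache <- fw$caches[[i]]
    g <- g * (cache$pre > 0)                  # ReLU backward
    bw <- conv2d_backward(cache$input, L$W, g, L$k, L$k, L$stride, L$pad)
    grads[[i]] <- list(W = bw$dweights, b = as.numeric(bw$dbias))
    g <- bw$dinput
  }
  list(layers = grads, fcW = gfcW, fcb = gfcb)
}

softmax <- function(z) { e <- exp(z - max(z)); e / sum(e) }

#' Predict class indices for a list of samples
#' @param model an \code{attn_model}.
#' @param samples list of \code{radiograph_sample}.
#' @return integer vector of predicted class indices (1-based, in the order
#'   of \code{class_levels} used at training; see \code{\link{train_model}}).
#' @export
predict_classes <- function(model, samples) {
  vapply(samples, function(s)
    which.max(model_forward(model, s$image)$logits), integer(1))
}

#' Attention map of a trained model for one image
#'
#' Runs a forward pass and returns the Grad-CAM map for the requested class
#' (default: the predicted class, the inference-time convention; training
#' uses the ground-truth class).
#'
#' @param model an \code{attn_model}.
#' @param image image matrix.
#' @param class_idx target class index, or NULL for the predicted class.
#' @param config a \code{\link{loss_config}}.
#' @return list with \code{map} (last-conv grid), \code{class_idx},
#'   \code{logits}.
#' @export
model_attention <- function(model, image, class_idx = NULL,
                            config = loss_config()) {
  fw <- model_forward(model, image)
  if (is.null(class_idx)) class_idx <- which.max(fw$logits)
  # d logits[class]/d feat[,,k] = fcW[class,k]/(feat_sd[k]*m*n)
  weights <- model$fcW[class_idx, ] / (model$feat_sd * fw$mn)
  features <- list(maps = fw$featmaps,
                   gradients = array(rep(weights, each = fw$mn),
                                     dim(fw$featmaps)))
  list(map = compute_gradcam(features, config), class_idx = class_idx,
       logits = fw$logits)
}
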