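#' Loss/attention hyperparameter configuration
#'
#' Houses the soft-mask and objective hyperparameters: threshold
#' \code{theta}, sigmoid scale \code{omega} (large = near-binary
#' thresholding), loss weights \code{alpha_cls}/\code{alpha_att}, the min-max
#' normalization guard \code{epsilon}, the Grad-CAM ReLU switch, and the IoU
#' relaxation variant.
#'
#' @param theta soft-mask threshold in \[0,1\] (default 0.5).
#' @param omega sigmoid sharpness > 0 (default 100).
#' @param alpha_cls,alpha_att nonnegative loss weights (defaults 2 and 1).
#' @param epsilon min-max denominator guard > 0 (default 1e-8); makes the
#'   normalization well-defined on constant maps (e.g. an all-zero
#'   post-ReLU map early in training).
#' @param gradcam_relu apply elementwise ReLU after the weighted feature sum.
#' @param iou_relaxation \code{"product"} (probabilistic union; default) or
#'   \code{"minmax"} (sum-min over sum-max). Both coincide with exact set IoU
#'   on binary inputs.
#' @return a \code{loss_config} object.
#' @export
loss_config <- function(theta = 0.5, omega = 100, alpha_cls = 2,
                        alpha_att = 1, epsilon = 1e-8, gradcam_relu = TRUE,
                        iou_relaxation = c("product", "minmax")) {
  if (theta < 0 || theta > 1) stop("theta must be in [0, 1]")
  if (omega <= 0) stop("omega must be > 0")
  if (alpha_cls < 0 || alpha_att < 0) stop("loss weights must be >= 0")
  if (epsilon <= 0) stop("epsilon must be > 0")
  structure(list(theta = theta, omega = omega, alpha_cls = alpha_cls,
                 alpha_att = alpha_att, epsilon = epsilon,
                 gradcam_relu = isTRUE(gradcam_relu),
                 iou_relaxation = match.arg(iou_relaxation)),
            class = "loss_config")
}

#' Grad-CAM attention map from a feature stack
#'
#' Computes the gradient-weighted class activation map: each last-layer
#' feature map is weighted by the spatial mean (global average pooling) of
#' the target-class score's gradient with respect to that map, the weighted
#' maps are summed, and (optionally) a ReLU keeps the positively contributing
#' regions. Linear in the feature maps, hence differentiable end-to-end.
#'
#' @param features list with \code{maps} and \code{gradients}, both
#'   \code{h x w x K} arrays (same shape, finite).
#' @param config a \code{\link{loss_config}} (controls the ReLU).
#' @return \code{h x w} attention-map matrix.
#' @export
compute_gradcam <- function(features, config = loss_config()) {
  maps <- features$maps; grads <- features$gradients
  if (is.matrix(maps)) maps <- array(maps, c(dim(maps), 1L))
  if (is.matrix(grads)) grads <- array(grads, c(dim(grads), 1L))
  if (!all(dim(maps) == dim(grads)))
    stop("maps and gradients must have identical shape")
  if (!all(is.finite(maps)) || !all(is.finite(grads)))
    stop("feature stack must be finite")
  K <- dim(maps)[3]
  weights <- vapply(seq_len(K), function(k) mean(grads[, , k]), numeric(1))
  H <- matrix(0, dim(maps)[1], dim(maps)[2])
  for (k in seq_len(K)) H <- H + weights[k] * maps[, , k]
  if (config$gradcam_relu) H <- pmax(H, 0)
  H
}

# Row-interpolation matrix for separable bilinear resize with half-pixel
# centers and edge clamping: out = R %*% in %*% t(C). Exact linear operator,
# so the adjoint (for gradients) is t(R) %*% g %*% C.
interp_matrix <- function(n_in, n_out) {
  M <- matrix(0, n_out, n_in)
  if (n_in == 1L) { M[, 1] <- 1; return(M) }
  scale <- n_in / n_out
  src <- (seq_len(n_out) - 0.5) * scale - 0.5        # 0-based source coord
  src <- pmin(pmax(src, 0), n_in - 1)
  i0 <- pmin(floor(src), n_in - 2)
  f <- src - i0
  for (j in seq_len(n_out)) {
    M[j, i0[j] + 1] <- 1 - f[j]
    M[j, i0[j] + 2] <- f[j]
  }
  M
}

#' Bilinear resize of a matrix
#' @param x matrix.
#' @param out_h,out_w output size.
#' @return resized matrix.
#' @export
bilinear_resize <- function(x, out_h, out_w) {
  interp_matrix(nrow(x), out_h) %*% x %*% t(interp_matrix(ncol(x), out_w))
}

#' Soft mask from an attention map
#'
#' Bilinearly upsamples the attention map to the attention-label resolution,
#' min-max normalizes it to \[0,1\] (with an epsilon guard for constant
#' maps), and pushes it through a steep logistic threshold:
#' \code{s(omega * (Hbar - theta))}. The result is a differentiable
#' near-binary relaxation of the thresholded attention map, with entries
#' strictly in (0, 1).
#'
#' @param map attention-map matrix (from \code{\link{compute_gradcam}}).
#' @param label_shape integer \code{c(h, w)} of the attention label.
#' @param config a \code{\link{loss_config}}.
#' @return matrix of soft-mask values in (0, 1).
#' @export
soft_mask <- function(map, label_shape = dim(map), config = loss_config()) {
  if (!all(is.finite(map))) stop("attention map must be finite")
  U <- bilinear_resize(map, label_shape[1], label_shape[2])
  Hbar <- (U - min(U)) / (max(U) - min(U) + config$epsilon)
  1 / (1 + exp(-config$omega * (Hbar - config$theta)))
}

#' Differentiable (soft) intersection-over-union
#'
#' Product relaxation: intersection \code{sum(m*y)}, union
#' \code{sum(m + y - m*y)}; reduces exactly to set IoU on binary inputs. The
#' \code{"minmax"} variant uses \code{sum(pmin)/sum(pmax)}. IoU is invariant
#' to lesion size, which keeps the attention-loss scale comparable across
#' small and large lesions.
#'
#' @param mask soft-mask matrix, entries in \[0,1\].
#' @param label binary matrix of the same shape with >= 1 foreground pixel.
#' @param relaxation \code{"product"} or \code{"minmax"}.
#' @return scalar in \[0, 1\].
#' @export
soft_iou <- function(mask, label, relaxation = c("product", "minmax")) {
  relaxation <- match.arg(relaxation)
  if (!all(dim(mask) == dim(label))) stop("mask and label shapes differ")
  if (!all(label %in% c(0, 1))) stop("label must be binary")
  if (sum(label) == 0) stop("label has no foreground pixels (empty lesion)")
  if (relaxation == "product") {
    inter <- sum(mask * label)
    union <- sum(mask + label - mask * label)
  } else {
    inter <- sum(pmin(mask, label))
    union <- sum(pmax(mask, label))
  }
  inter / union
}

#' Conditional attention loss
#'
#' \code{1 - soft_iou(mask, label)} when an attention label exists, exactly 0
#' otherwise — location supervision only ever applies to annotated samples.
#'
#' @param mask soft mask (may be NULL only when \code{label} is NULL).
#' @param label binary attention label or NULL.
#' @param relaxation IoU relaxation variant.
#' @return scalar in \[0, 1\].
#' @export
attention_loss <- function(mask, label, relaxation = "product") {
  if (is.null(label)) return(0)
  if (is.null(mask))
    stop("attention label present but no soft mask supplied")
  1 - soft_iou(mask, label, relaxation)
}

#' Softmax cross-entropy classification loss
#'
#' \code{-log(exp(f_y) / sum_k exp(f_k))}, computed with log-sum-exp
#' stabilization.
#'
#' @param logits numeric vector of class scores (length >= 2).
#' @param true_class integer class index in \code{1..length(logits)}.
#' @return nonnegative scalar.
#' @export
classification_loss <- function(logits, true_class) {
  if (length(logits) < 2) stop("need at least 2 classes")
  if (true_class < 1 || true_class > length(logits) ||
      true_class != round(true_class))
    stop("invalid class index ", true_class)
  m <- max(logits)
  lse <- m + log(sum(exp(logits - m)))
  lse - logits[true_class]
}

#' Combined training objective
#'
#' Weighted sum \code{alpha_cls * l_cls + alpha_att * l_att} (defaults 2 and
#' 1). With no attention label, \code{l_att = 0} and the objective is plain
#' weighted cross-entropy.
#'
#' @param l_cls,l_att nonnegative finite loss values.
#' @param config a \code{\link{loss_config}}.
#' @return scalar.
#' @export
total_loss <- function(l_cls, l_att, config = loss_config()) {
  stopifnot_scalar(l_cls, "l_cls"); stopifnot_scalar(l_att, "l_att")
  config$alpha_cls * l_cls + config$alpha_att * l_att
}

# --- internal differentiable chain -----------------------------------------
# Attention loss and its exact gradients, for feature maps A (h x w x K) and
# fixed Grad-CAM weights w_k (the GAP'd gradients, constants for a
# GAP + linear head). Chain: H = sum_k w_k A_k [-> ReLU] -> bilinear upsample
# -> min-max normalize (subgradient at arg-min/max) -> logistic(omega(.-theta))
# -> product-relaxed IoU -> 1 - IoU. Returns loss, dL/dA, dL/dw, soft mask.
attention_chain <- function(maps, weights, label, config) {
  hw <- dim(maps)[1:2]; K <- dim(maps)[3]
  H <- matrix(0, hw[1], hw[2])
  for (k in seq_len(K)) H <- H + weights[k] * maps[, , k]
  relu_mask <- if (config$gradcam_relu) (H > 0) * 1 else 1
  Hr <- if (config$gradcam_relu) pmax(H, 0) else H
  R <- interp_matrix(hw[1], nrow(label))
  C <- interp_matrix(hw[2], ncol(label))
  U <- R %*% Hr %*% t(C)
  imin <- which.min(U); imax <- which.max(U)
  D <- U[imax] - U[imin] + config$epsilon
  N <- (U - U[imin]) / D
  S <- 1 / (1 + exp(-config$omega * (N - config$theta)))
  Y <- label
  inter <- sum(S * Y); uni <- sum(S + Y - S * Y)
  iou <- inter / uni
  loss <- 1 - iou
  # backward
  dS <- -(Y * uni - inter * (1 - Y)) / uni^2      # d(1-IoU)/dS
  dN <- dS * config$omega * S * (1 - S)
  dU <- dN / D
  sN <- sum(dN * N)
  dU[imax] <- dU[imax] - sN / D
  dU[imin] <- dU[imin] + (sN - sum(dN)) / D
  dHr <- t(R) %*% dU %*% C
  dH <- dHr * relu_mask
  dA <- array(0, dim(maps))
  dw <- numeric(K)
  for (k in seq_len(K)) {
    dA[, , k] <- weights[k] * dH
    dw[k] <- sum(dH * maps[, , k])
  }
  list(loss = loss, dmaps = dA, dweights = dw, soft_mask = S)
}
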