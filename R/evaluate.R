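#' Confusion matrix
#'
#' \code{counts[i, j]} = number of samples with true class i predicted as j.
#'
#' @param true_labels,predicted_labels integer vectors of class indices in
#'   \code{1..n_classes}, equal length.
#' @param n_classes number of classes.
#' @param labels optional class names for dimnames.
#' @return n_classes x n_classes integer matrix (rows = truth).
#' @export
confusion_matrix <- function(true_labels, predicted_labels, n_classes,
                             labels = NULL) {
  if (length(true_labels) != length(predicted_labels))
    stop("true and predicted label vectors differ in length")
  if (length(true_labels) &&
      (any(true_labels < 1 | true_labels > n_classes) ||
       any(predicted_labels < 1 | predicted_labels > n_classes)))
    stop("labels out of range 1..", n_classes)
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(true_labels))
    cm[true_labels[i], predicted_labels[i]] <-
      cm[true_labels[i], predicted_labels[i]] + 1L
  if (!is.null(labels)) dimnames(cm) <- list(true = labels, predicted = labels)
  cm
}

#' Macro-averaged one-vs-rest metrics
#'
#' For each class c (treated as positive, all others negative):
#' TP = cm\[c,c\], FN = row c - TP, FP = column c - TP, TN = rest;
#' accuracy = (TP+TN)/(TP+TN+FP+FN), sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP), each as a percentage. Macro values are the
#' unweighted mean over classes; classes with a zero denominator are reported
#' as NA and excluded from the macro mean with a warning. The plain
#' multiclass accuracy (trace/total) is also returned.
#'
#' @param cm confusion matrix from \code{\link{confusion_matrix}}.
#' @return list with \code{per_class} (data.frame), \code{macro} (named
#'   vector: accuracy, sensitivity, specificity, in percent) and
#'   \code{overall_accuracy} (percent).
#' @export
macro_metrics <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  n <- nrow(cm)
  per <- data.frame(class = seq_len(n), accuracy = NA_real_,
                    sensitivity = NA_real_, specificity = NA_real_)
  if (!is.null(dimnames(cm))) per$class <- colnames(cm)
  for (c_i in seq_len(n)) {
    TP <- cm[c_i, c_i]
    FN <- sum(cm[c_i, ]) - TP
    FP <- sum(cm[, c_i]) - TP
    TN <- total - TP - FN - FP
    per$accuracy[c_i] <- 100 * (TP + TN) / total
    per$sensitivity[c_i] <- if (TP + FN > 0) 100 * TP / (TP + FN) else NA_real_
    per$specificity[c_i] <- if (TN + FP > 0) 100 * TN / (TN + FP) else NA_real_
  }
  if (anyNA(per[, -1]))
    warning("class(es) with zero denominator excluded from macro average")
  macro <- c(accuracy = mean(per$accuracy, na.rm = TRUE),
             sensitivity = mean(per$sensitivity, na.rm = TRUE),
             specificity = mean(per$specificity, na.rm = TRUE))
  list(per_class = per, macro = macro,
       overall_accuracy = 100 * sum(diag(cm)) / total)
}

#' Localization quality of the model's attention
#'
#' For every mask-carrying sample: Grad-CAM for the predicted class,
#' bilinear upsampling to mask resolution, min-max normalization, hard
#' binarization at \code{bin_threshold}, exact binary IoU against the
#' ground-truth mask. Samples without masks are skipped and counted.
#'
#' @param model an \code{attn_model}.
#' @param samples list of samples (lesion test set).
#' @param bin_threshold binarization threshold in \[0,1\] (default
#'   \code{config$theta}).
#' @param config a \code{\link{loss_config}}.
#' @return list: \code{per_sample} (named numeric), \code{mean}, \code{sd},
#'   \code{threshold}, \code{n_skipped}.
#' @export
localization_iou <- function(model, samples, bin_threshold = NULL,
                             config = loss_config()) {
  thr <- bin_threshold %||% config$theta
  ious <- numeric(0); skipped <- 0L
  for (s in samples) {
    if (is.null(s$attention_label) || sum(s$attention_label) == 0) {
      skipped <- skipped + 1L
      next
    }
    att <- model_attention(model, s$image, config = config)
    U <- bilinear_resize(att$map, nrow(s$attention_label),
                         ncol(s$attention_label))
    Hbar <- (U - min(U)) / (max(U) - min(U) + config$epsilon)
    pred <- (Hbar > thr) * 1L
    inter <- sum(pred & s$attention_label)
    uni <- sum(pred | s$attention_label)
    ious[s$sample_id] <- if (uni > 0) inter / uni else 0
  }
  list(per_sample = ious,
       mean = if (length(ious)) mean(ious) else NA_real_,
       sd = if (length(ious) > 1) sd(ious) else 0,
       threshold = thr, n_skipped = skipped)
}

#' Export an attention overlay image
#'
#' Writes a PNG with the grayscale radiograph as base layer, a blue-to-red
#' heat overlay of the (min-max normalized) attention map, and the
#' ground-truth mask contour in green. True/predicted classes, when given,
#' go to a JSON sidecar next to the image.
#'
#' @param sample a \code{radiograph_sample}.
#' @param attention_map matrix (any resolution; upsampled to the image).
#' @param out_path output PNG path.
#' @param true_class,pred_class optional class names for the sidecar.
#' @return \code{out_path}, invisibly.
#' @export
export_overlay <- function(sample, attention_map, out_path,
                           true_class = NULL, pred_class = NULL) {
  img <- sample$image
  att <- bilinear_resize(attention_map, nrow(img), ncol(img))
  rng <- max(att) - min(att)
  att <- if (rng > 0) (att - min(att)) / rng else att * 0
  ramp <- grDevices::colorRamp(c("blue", "cyan", "yellow", "red"))
  cols <- ramp(as.numeric(att)) / 255
  alpha <- 0.35 * as.numeric(att)
  out <- array(0, c(nrow(img), ncol(img), 3))
  for (ch in 1:3)
    out[, , ch] <- (1 - alpha) * as.numeric(img) + alpha * cols[, ch]
  if (!is.null(sample$attention_label)) {
    m <- sample$attention_label
    inner <- m
    inner[] <- 0L
    h <- nrow(m); w <- ncol(m)
    core <- m[2:(h - 1), 2:(w - 1)] & m[1:(h - 2), 2:(w - 1)] &
            m[3:h, 2:(w - 1)] & m[2:(h - 1), 1:(w - 2)] & m[2:(h - 1), 3:w]
    inner[2:(h - 1), 2:(w - 1)] <- core * 1L
    contour <- m == 1L & inner == 0L
    out[, , 1][contour] <- 0; out[, , 2][contour] <- 1; out[, , 3][contour] <- 0
  }
  png::writePNG(clip01(out), out_path)
  if (!is.null(true_class) || !is.null(pred_class))
    jsonlite::write_json(list(sample_id = sample$sample_id,
                              true_class = true_class,
                              pred_class = pred_class),
                         paste0(tools::file_path_sans_ext(out_path), ".json"),
                         auto_unbox = TRUE)
  invisible(out_path)
}
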