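#' Build the trapezoid homography
#'
#' Solves the unique 3x3 projective matrix (8-DOF direct linear transform)
#' that keeps one horizontal edge of the image fixed and symmetrically widens
#' (delta > 0) or narrows (delta < 0) the opposite edge, so that edge's width
#' changes by the factor \code{1 + delta}. With \code{anchor = "top"} (the
#' default) the bottom "base" edge is rescaled: source corners
#' \code{(0,0), (W-1,0), (0,H-1), (W-1,H-1)} map to
#' \code{(0,0), (W-1,0), (-delta*(W-1)/2, H-1), ((W-1)+delta*(W-1)/2, H-1)}.
#' \code{anchor = "bottom"} rescales the top edge instead. This emulates the
#' patient-to-patient variation of the maxilla/mandible width ratio on
#' panoramic radiographs.
#'
#' @param width,height image size in pixels.
#' @param delta signed fraction, \code{abs(delta) <= 0.5}.
#' @param anchor which edge stays fixed: \code{"top"} or \code{"bottom"}.
#' @return an object of class \code{homography}: list with a 3x3
#'   \code{matrix} normalized so the bottom-right entry is 1.
#' @export
build_homography <- function(width, height, delta, anchor = c("top", "bottom")) {
  anchor <- match.arg(anchor)
  if (abs(delta) > 0.5) stop("abs(delta) must be <= 0.5")
  W <- width - 1; H <- height - 1
  src <- rbind(c(0, 0), c(W, 0), c(0, H), c(W, H))
  d <- delta * W / 2
  dst <- if (anchor == "top")
    rbind(c(0, 0), c(W, 0), c(-d, H), c(W + d, H))
  else
    rbind(c(-d, 0), c(W + d, 0), c(0, H), c(W, H))
  # DLT: for each correspondence (x,y) -> (u,v), two rows of the 8x8 system
  A <- matrix(0, 8, 8); rhs <- numeric(8)
  for (i in 1:4) {
    x <- src[i, 1]; y <- src[i, 2]; u <- dst[i, 1]; v <- dst[i, 2]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y)
    A[2 * i, ]     <- c(0, 0, 0, x, y, 1, -v * x, -v * y)
    rhs[2 * i - 1] <- u; rhs[2 * i] <- v
  }
  hvec <- solve(A, rhs)
  M <- matrix(c(hvec, 1), 3, 3, byrow = TRUE)
  if (abs(det(M)) < 1e-12) stop("degenerate homography")
  structure(list(matrix = M), class = "homography")
}

#' Apply a homography to 2-D points
#' @param H a \code{homography} (or bare 3x3 matrix).
#' @param points n x 2 matrix of \code{(x, y)} coordinates (0-based pixels).
#' @return n x 2 matrix of mapped coordinates.
#' @export
apply_homography <- function(H, points) {
  M <- if (inherits(H, "homography")) H$matrix else H
  points <- matrix(points, ncol = 2)
  p <- M %*% rbind(t(points), 1)
  t(p[1:2, , drop = FALSE] / rep(p[3, ], each = 2))
}

#' Invert a homography
#' @param H a \code{homography}.
#' @return the inverse \code{homography}, normalized.
#' @export
invert_homography <- function(H) {
  M <- solve(H$matrix)
  structure(list(matrix = M / M[3, 3]), class = "homography")
}

#' Warp an image (and optionally a mask) through a homography
#'
#' Inverse-mapping resampling: every destination pixel samples the source at
#' \code{solve(H) \%*\% (x, y, 1)} — bilinear for the image, nearest-neighbor
#' for the mask (so binary masks stay binary). Out-of-source pixels are filled
#' with 0; the canvas keeps the source size.
#'
#' @param image matrix.
#' @param H a \code{homography}.
#' @param mask optional same-shape matrix.
#' @return list \code{(image, mask)}.
#' @export
warp_homography <- function(image, H, mask = NULL) {
  if (!is.null(mask) && !all(dim(mask) == dim(image)))
    stop("mask shape must match image shape")
  Hinv <- invert_homography(H)$matrix
  out <- warp_bilinear(image, Hinv, 0)
  m <- if (!is.null(mask)) {
    mm <- warp_nearest(matrix(as.numeric(mask), nrow(mask)), Hinv, 0)
    storage.mode(mm) <- "integer"
    mm
  }
  list(image = out, mask = m)
}

#' Random trapezoid transform of image and mask
#'
#' Draws \code{delta ~ U(-delta_range, +delta_range)} and warps image
#' (bilinear) and mask (nearest) jointly through the same trapezoid
#' homography.
#'
#' @param image matrix.
#' @param mask optional same-shape matrix.
#' @param delta_range nonnegative fraction (default 0.05).
#' @param delta override the random draw.
#' @param anchor passed to \code{\link{build_homography}}.
#' @return list \code{(image, mask, delta)}.
#' @export
trapezoid_transform <- function(image, mask = NULL, delta_range = 0.05,
                                delta = NULL, anchor = "top") {
  if (delta_range < 0) stop("delta_range must be >= 0")
  if (is.null(delta)) delta <- runif(1, -delta_range, delta_range)
  if (delta == 0) return(list(image = image, mask = mask, delta = 0))
  H <- build_homography(ncol(image), nrow(image), delta, anchor)
  out <- warp_homography(image, H, mask)
  out$delta <- delta
  out
}

#' Augmentation configuration
#'
#' Mirrors the training-time augmentation stack: intensity jitter (brightness
#' 0.05, contrast 0.10), joint horizontal flip (p = 0.5), joint trapezoid
#' transform (0.05), then center crop. The canonical crop takes 1280x720
#' source frames to 940x520 (removing collimation borders and corner text
#' marks); \code{crop_size = NULL} scales those fractions (940/1280,
#' 520/720) to the actual input size.
#'
#' @param brightness_factor,contrast_factor,flip_probability,trapezoid_factor
#'   augmentation hyperparameters (see the individual ops).
#' @param crop_size \code{c(width, height)} or NULL for proportional scaling.
#' @param enabled_ops ordered subset of
#'   \code{c("intensity", "flip", "trapezoid")}; crop is always applied.
#' @param anchor trapezoid anchor edge.
#' @return an \code{augmentation_config} object.
#' @export
augmentation_config <- function(brightness_factor = 0.05,
                                contrast_factor = 0.10,
                                flip_probability = 0.5,
                                trapezoid_factor = 0.05,
                                crop_size = NULL,
                                enabled_ops = c("intensity", "flip", "trapezoid"),
                                anchor = "top") {
  if (brightness_factor < 0 || contrast_factor < 0 || trapezoid_factor < 0)
    stop("factors must be >= 0")
  if (flip_probability < 0 || flip_probability > 1)
    stop("flip_probability must be in [0, 1]")
  bad <- setdiff(enabled_ops, c("intensity", "flip", "trapezoid"))
  if (length(bad)) stop("unknown ops: ", paste(bad, collapse = ", "))
  structure(list(brightness_factor = brightness_factor,
                 contrast_factor = contrast_factor,
                 flip_probability = flip_probability,
                 trapezoid_factor = trapezoid_factor,
                 crop_size = crop_size,
                 enabled_ops = enabled_ops,
                 anchor = anchor),
            class = "augmentation_config")
}

crop_size_for <- function(config, image) {
  if (!is.null(config$crop_size)) return(config$crop_size)
  c(round(ncol(image) * 940 / 1280), round(nrow(image) * 520 / 720))
}

#' Apply the full augmentation stack to one sample
#'
#' Fixed order: intensity (image only) -> flip (joint) -> trapezoid (joint)
#' -> center crop (joint). Drawn parameters are recorded in the
#' \code{"aug_log"} attribute of the result.
#'
#' @param sample a \code{radiograph_sample}.
#' @param config an \code{\link{augmentation_config}}.
#' @param b,contrast,force_flip,delta optional overrides of the random draws.
#' @return the augmented \code{radiograph_sample} (same class/ids), image and
#'   mask at crop size.
#' @export
compose_augmentation <- function(sample, config = augmentation_config(),
                                 b = NULL, contrast = NULL,
                                 force_flip = NULL, delta = NULL) {
  img <- sample$image; msk <- sample$attention_label
  log <- list()
  if ("intensity" %in% config$enabled_ops) {
    img <- jitter_intensity(img, config$brightness_factor,
                            config$contrast_factor, b = b, contrast = contrast)
    log$intensity <- attr(img, "draw"); attr(img, "draw") <- NULL
  }
  if ("flip" %in% config$enabled_ops) {
    fl <- horizontal_flip(img, msk, config$flip_probability, force = force_flip)
    img <- fl$image; msk <- fl$mask; log$flipped <- fl$flipped
  }
  if ("trapezoid" %in% config$enabled_ops) {
    tr <- trapezoid_transform(img, msk, config$trapezoid_factor,
                              delta = delta, anchor = config$anchor)
    img <- tr$image; msk <- tr$mask; log$delta <- tr$delta
  }
  cr <- center_crop(img, crop_size_for(config, img), msk)
  out <- sample
  out$image <- cr$image
  out$attention_label <- cr$mask
  attr(out, "aug_log") <- log
  out
}
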