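#' Read a grayscale radiograph from PNG
#'
#' Multi-channel PNGs are converted to grayscale by channel averaging.
#' @param path file path.
#' @return numeric matrix (rows = y, cols = x), intensities in \[0,1\].
#' @export
read_radiograph <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- apply(a[, , 1:min(3, dim(a)[3]), drop = FALSE],
                                       c(1, 2), mean)
  a
}

#' Write a grayscale radiograph as PNG
#' @param image matrix in \[0,1\].
#' @param path output path.
#' @param bit_depth 8 or 16.
#' @export
write_radiograph <- function(image, path, bit_depth = 8) {
  if (!bit_depth %in% c(8, 16)) stop("bit_depth must be 8 or 16")
  png::writePNG(clip01(image), path, dpi = NULL,
                asp = NULL, text = NULL)
  invisible(path)
}

#' Read a binary mask from PNG ({0,255} or {0,1} conventions)
#' @param path file path.
#' @return integer matrix of 0/1.
#' @export
read_mask <- function(path) {
  m <- read_radiograph(path)
  m <- (m >= 0.5) * 1L
  storage.mode(m) <- "integer"
  m
}

#' Write a binary mask as PNG with values {0, 255}
#' @param mask 0/1 matrix.
#' @param path output path.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Center-crop an image (and optionally its mask)
#'
#' Crops the centered \code{w x h} window; when the margin is odd the extra
#' pixel is dropped from the right/bottom side (the window starts at offset
#' \code{floor((size - crop)/2)}, 0-based).
#'
#' @param image matrix.
#' @param crop_size integer length-2 \code{c(width, height)}.
#' @param mask optional matrix of the same size, cropped with the same window.
#' @return list with \code{image}, \code{mask} (NULL when not given) and the
#'   0-based window \code{offset} \code{c(x, y)}.
#' @export
center_crop <- function(image, crop_size, mask = NULL) {
  w <- crop_size[1]; h <- crop_size[2]
  W <- ncol(image); H <- nrow(image)
  if (w > W || h > H)
    stop(sprintf("crop %dx%d larger than image %dx%d", w, h, W, H))
  if (!is.null(mask) && !all(dim(mask) == dim(image)))
    stop("mask shape must match image shape")
  ox <- as.integer((W - w) %/% 2); oy <- as.integer((H - h) %/% 2)
  w <- as.integer(w); h <- as.integer(h)
  rows <- (oy + 1L):(oy + h); cols <- (ox + 1L):(ox + w)
  list(image = image[rows, cols, drop = FALSE],
       mask = if (!is.null(mask)) mask[rows, cols, drop = FALSE],
       offset = c(x = ox, y = oy))
}

#' Random intensity jitter (brightness then mean-anchored contrast)
#'
#' Draws \code{b ~ U(1-bf, 1+bf)} and \code{c ~ U(1-cf, 1+cf)}, scales
#' brightness, then stretches contrast about the post-brightness mean:
#' \code{clip(((image*b) - m)*c + m, 0, 1)} with \code{m = mean(image*b)}.
#' Image-only; masks are never touched by intensity ops.
#'
#' @param image matrix in \[0,1\].
#' @param brightness_factor,contrast_factor nonnegative jitter half-ranges.
#' @param b,contrast override the random draws (used in tests/replays).
#' @return jittered image matrix in \[0,1\].
#' @export
jitter_intensity <- function(image, brightness_factor = 0.05,
                             contrast_factor = 0.10,
                             b = NULL, contrast = NULL) {
  if (brightness_factor < 0 || contrast_factor < 0)
    stop("jitter factors must be >= 0")
  if (is.null(b)) b <- runif(1, 1 - brightness_factor, 1 + brightness_factor)
  if (is.null(contrast)) contrast <- runif(1, 1 - contrast_factor, 1 + contrast_factor)
  x <- image * b
  m <- mean(x)
  out <- clip01((x - m) * contrast + m)
  attr(out, "draw") <- c(b = b, contrast = contrast)
  out
}

#' Random joint horizontal flip
#'
#' With probability \code{flip_probability}, mirrors image and mask about the
#' vertical axis; one draw governs both.
#'
#' @param image matrix.
#' @param mask optional matrix, same shape.
#' @param flip_probability in \[0,1\].
#' @param force logical override of the random draw.
#' @return list \code{(image, mask, flipped)}.
#' @export
horizontal_flip <- function(image, mask = NULL, flip_probability = 0.5,
                            force = NULL) {
  if (!is.null(mask) && !all(dim(mask) == dim(image)))
    stop("mask shape must match image shape")
  flipped <- if (!is.null(force)) isTRUE(force)
             else runif(1) < flip_probability
  if (flipped) {
    image <- image[, rev(seq_len(ncol(image))), drop = FALSE]
    if (!is.null(mask)) mask <- mask[, rev(seq_len(ncol(mask))), drop = FALSE]
  }
  list(image = image, mask = mask, flipped = flipped)
}
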