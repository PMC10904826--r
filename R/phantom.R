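#' Phantom radiograph generator configuration
#'
#' Describes the synthetic panoramic-radiograph world: image size, per-class
#' sample counts, lesion geometry/contrast, background noise, and the two
#' horizontal "jaw bands" standing in for maxilla and mandible. The default
#' canvas is 320x180, a quarter-scale panoramic frame (full scale 1280x720
#' is available by configuration).
#'
#' Classes are \code{Normal} (no lesion), \code{CystTumor} (radiolucent blob
#' with a sharp, faintly corticated border, anywhere along the mandibular
#' band) and \code{LMBD} (a lingual-mandibular-bone-depression mimic: softer
#' border, posterior/lateral third of the mandibular band only).
#'
#' @param image_width,image_height canvas size in pixels (each >= 64).
#' @param n_per_class named integer vector of sample counts; names must be a
#'   subset of \code{c("Normal", "CystTumor", "LMBD")}.
#' @param lesion_radius_range numeric length-2, min/max ellipse semi-axis in
#'   pixels; must fit inside the lower jaw band.
#' @param lesion_contrast named numeric, per-lesion-class intensity offset in
#'   \[-1, 1\] (negative = radiolucent/dark).
#' @param background_noise_sd sd of additive Gaussian pixel noise.
#' @param jaw_band_geometry list with fractions of image height:
#'   \code{upper_center}, \code{lower_center}, \code{halfwidth}, and the band
#'   \code{intensity} offset above background.
#' @param seed default dataset seed.
#' @return an object of class \code{phantom_config}.
#' @export
phantom_config <- function(image_width = 320L,
                           image_height = 180L,
                           n_per_class = c(Normal = 60L, CystTumor = 60L, LMBD = 60L),
                           lesion_radius_range = NULL,
                           lesion_contrast = c(CystTumor = -0.35, LMBD = -0.25),
                           background_noise_sd = 0.02,
                           jaw_band_geometry = list(upper_center = 0.30,
                                                    lower_center = 0.70,
                                                    halfwidth = 0.13,
                                                    intensity = 0.40),
                           seed = 1L) {
  if (image_width < 64 || image_height < 64)
    stop("image_width and image_height must be >= 64")
  if (any(n_per_class < 0)) stop("class counts must be >= 0")
  bad <- setdiff(names(n_per_class), phantom_classes())
  if (length(bad))
    stop("unknown class name(s) ", paste(bad, collapse = ", "),
         "; valid classes: ", paste(phantom_classes(), collapse = ", "))
  if (is.null(lesion_radius_range)) {
    # scale with the canvas: 7..16 px at the default 180-px height
    lesion_radius_range <- round(c(7, 16) * image_height / 180)
  }
  band_px <- jaw_band_geometry$halfwidth * image_height
  if (max(lesion_radius_range) > band_px)
    stop(sprintf("lesion radii (max %g px) must fit inside the lower jaw band (halfwidth %g px)",
                 max(lesion_radius_range), band_px))
  structure(list(image_width = as.integer(image_width),
                 image_height = as.integer(image_height),
                 n_per_class = n_per_class,
                 lesion_radius_range = lesion_radius_range,
                 lesion_contrast = lesion_contrast,
                 background_noise_sd = background_noise_sd,
                 jaw_band_geometry = jaw_band_geometry,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' Valid phantom class names
#' @return character vector of the three class names.
#' @export
phantom_classes <- function() c("Normal", "CystTumor", "LMBD")

# Plateau-shaped (super-Gaussian) band profile: flat interior, smooth roll-off.
band_profile <- function(y_frac, center, halfwidth) {
  exp(-0.5 * ((y_frac - center) / halfwidth)^6)
}

# Rasterize one rotated ellipse; returns the normalized radial coordinate rho
# (<= 1 inside) over the full canvas, Inf outside a bounding box for speed.
ellipse_rho <- function(h, w, cx, cy, a, b, phi) {
  rho <- matrix(Inf, h, w)
  r <- max(a, b)
  xs <- max(1, floor(cx - r)):min(w, ceiling(cx + r))
  ys <- max(1, floor(cy - r)):min(h, ceiling(cy + r))
  if (!length(xs) || !length(ys)) return(rho)
  dx <- outer(rep(1, length(ys)), xs - cx)
  dy <- outer(ys - cy, rep(1, length(xs)))
  u <-  dx * cos(phi) + dy * sin(phi)
  v <- -dx * sin(phi) + dy * cos(phi)
  rho[ys, xs] <- sqrt((u / a)^2 + (v / b)^2)
  rho
}

#' Generate one phantom radiograph sample
#'
#' Builds a grayscale image with two smooth horizontal jaw bands over a noisy
#' background plus a faint non-diagnostic "shadow" distractor in the upper
#' band. Lesion classes get one free-form blob (union of 2-5 overlapping
#' ellipses) in the lower band with a class-specific signature; the returned
#' \code{attention_label} is the exact blob support. Normal samples carry no
#' blob and no mask.
#'
#' @param config a \code{\link{phantom_config}}.
#' @param class_name one of \code{phantom_classes()}.
#' @param seed optional integer; when given, the sample is reproducible
#'   bit-exactly. When \code{NULL}, the current RNG stream is used.
#' @param sample_id id string stored on the sample.
#' @return a \code{radiograph_sample}: list with \code{image} (h x w matrix in
#'   \[0,1\]), \code{class_label}, \code{attention_label} (binary matrix or
#'   \code{NULL}), \code{sample_id}.
#' @export
generate_phantom <- function(config, class_name, seed = NULL,
                             sample_id = class_name) {
  if (!inherits(config, "phantom_config")) stop("config must be a phantom_config")
  if (!class_name %in% phantom_classes())
    stop("unknown class name '", class_name, "'; valid classes: ",
         paste(phantom_classes(), collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  h <- config$image_height; w <- config$image_width
  g <- config$jaw_band_geometry
  y_frac <- (seq_len(h) - 0.5) / h
  prof <- band_profile(y_frac, g$upper_center, g$halfwidth) +
          band_profile(y_frac, g$lower_center, g$halfwidth)
  base <- 0.22 + g$intensity * matrix(prof, h, w)
  # slow horizontal modulation emulating exposure falloff
  xmod <- 1 - 0.06 * cos(2 * pi * (seq_len(w) - 0.5) / w + runif(1, 0, 2 * pi))
  img <- base * matrix(xmod, h, w, byrow = TRUE)

  # non-diagnostic dark shadow in the upper band (all classes)
  scx <- runif(1, 0.15, 0.85) * w
  scy <- (g$upper_center + runif(1, -0.3, 0.3) * g$halfwidth) * h
  sr <- runif(1, 0.6, 1.0) * mean(config$lesion_radius_range)
  srho <- ellipse_rho(h, w, scx, scy, sr, 0.8 * sr, runif(1, 0, pi))
  sfeather <- clip01((1 - pmin(srho, 2)) / 0.6)
  img <- img - 0.12 * sfeather

  mask <- NULL
  if (class_name != "Normal") {
    rr <- config$lesion_radius_range
    contrast <- config$lesion_contrast[[class_name]]
    cy <- (g$lower_center + runif(1, -0.25, 0.25) * g$halfwidth) * h
    cx <- if (class_name == "LMBD") {
      # posterior (lateral) third of the mandibular band
      side <- sample(c(-1, 1), 1)
      (0.5 + side * runif(1, 0.27, 0.44)) * w
    } else runif(1, 0.08, 0.92) * w
    n_ell <- sample(2:5, 1)
    rho_list <- vector("list", n_ell)
    a0 <- runif(1, rr[1], rr[2])
    for (i in seq_len(n_ell)) {
      a <- runif(1, rr[1], rr[2]); b <- runif(1, rr[1], rr[2])
      off <- if (i == 1) c(0, 0) else runif(2, -0.5, 0.5) * a0
      rho_list[[i]] <- ellipse_rho(h, w, cx + off[1], cy + off[2], a, b,
                                   runif(1, 0, pi))
    }
    rho_min <- Reduce(pmin, rho_list)
    mask <- (rho_min <= 1) * 1L
    edge_soft <- if (class_name == "LMBD") 0.40 else 0.06
    feather <- clip01((1 - rho_min) / edge_soft)
    img <- img + contrast * feather
    if (class_name == "CystTumor") {
      # faint corticated rim just inside the border
      rim <- (rho_min <= 1 & rho_min >= 0.85) * 1
      img <- img + 0.15 * rim
    }
    storage.mode(mask) <- "integer"
  }

  img <- img + rnorm(h * w, 0, config$background_noise_sd)
  structure(list(image = clip01(img),
                 class_label = class_name,
                 attention_label = mask,
                 sample_id = sample_id),
            class = "radiograph_sample")
}

#' Generate a phantom dataset with an attention-label budget
#'
#' Generates \code{config$n_per_class} samples per class, then keeps the
#' attention mask on exactly \code{ceiling(attention_rate * n_lesion)}
#' lesion-class samples (chosen by a seeded shuffle); the rest have the mask
#' stripped. Class labels are always kept. With a fixed seed, two calls at
#' rates r1 < r2 produce bit-identical images and the r1 mask-kept set is a
#' subset of the r2 set.
#'
#' @param config a \code{\link{phantom_config}}.
#' @param attention_rate fraction in \[0,1\] of lesion samples keeping masks.
#' @param seed integer; defaults to \code{config$seed}.
#' @return list with \code{samples} (list of \code{radiograph_sample}) and
#'   \code{manifest} (data.frame: sample_id, class, mask_present).
#' @export
generate_dataset <- function(config, attention_rate = 1, seed = config$seed) {
  if (attention_rate < 0 || attention_rate > 1)
    stop("attention_rate must be in [0, 1]")
  set.seed(seed)
  samples <- list()
  for (cls in names(config$n_per_class)) {
    n <- config$n_per_class[[cls]]
    if (n <= 0) next
    for (i in seq_len(n)) {
      sid <- sprintf("%s_%04d", cls, i)
      samples[[sid]] <- generate_phantom(config, cls, seed = NULL,
                                         sample_id = sid)
    }
  }
  lesion_ids <- names(samples)[vapply(samples, function(s)
    !is.null(s$attention_label), logical(1))]
  n_keep <- ceiling(attention_rate * length(lesion_ids))
  set.seed(seed)  # fresh stream: selection identical across rates
  keep <- head(sample(lesion_ids), n_keep)
  for (sid in setdiff(lesion_ids, keep)) samples[[sid]]$attention_label <- NULL
  manifest <- data.frame(
    sample_id = names(samples),
    class = vapply(samples, `[[`, character(1), "class_label"),
    mask_present = vapply(samples, function(s)
      !is.null(s$attention_label), logical(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(samples = samples, manifest = manifest)
}

#' Write a phantom dataset to disk
#'
#' Images and masks are written as 8- or 16-bit grayscale PNG, the manifest as
#' CSV with header \code{sample_id,class,image_path,mask_path} (empty
#' mask_path when absent), and a JSON sidecar records the configuration and
#' seed.
#'
#' @param dataset result of \code{\link{generate_dataset}}.
#' @param dir output directory (created if missing).
#' @param config the \code{phantom_config} used (stored in the sidecar).
#' @param seed the seed used (stored in the sidecar).
#' @param bit_depth 8 or 16.
#' @return the manifest data.frame (with file paths), invisibly.
#' @export
write_dataset <- function(dataset, dir, config = NULL, seed = NULL,
                          bit_depth = 8) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- dataset$manifest
  man$image_path <- file.path(dir, paste0(man$sample_id, ".png"))
  man$mask_path <- ifelse(man$mask_present,
                          file.path(dir, paste0(man$sample_id, "_mask.png")), "")
  for (i in seq_len(nrow(man))) {
    s <- dataset$samples[[man$sample_id[i]]]
    write_radiograph(s$image, man$image_path[i], bit_depth = bit_depth)
    if (man$mask_present[i]) write_mask(s$attention_label, man$mask_path[i])
  }
  write.csv(man[, c("sample_id", "class", "image_path", "mask_path")],
            file.path(dir, "manifest.csv"), row.names = FALSE)
  sidecar <- list(config = unclass(config), seed = seed)
  jsonlite::write_json(sidecar, file.path(dir, "dataset.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(man)
}

#' Read a dataset back from a manifest
#' @param manifest_path path to a manifest CSV written by
#'   \code{\link{write_dataset}} (or following the same schema).
#' @return list with \code{samples} and \code{manifest} as in
#'   \code{\link{generate_dataset}}.
#' @export
read_dataset <- function(manifest_path) {
  man <- read.csv(manifest_path, stringsAsFactors = FALSE)
  base <- dirname(manifest_path)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, basename(p))
  samples <- list()
  for (i in seq_len(nrow(man))) {
    img <- read_radiograph(resolve(man$image_path[i]))
    msk <- if (nzchar(man$mask_path[i] %||% "")) read_mask(resolve(man$mask_path[i]))
    samples[[man$sample_id[i]]] <- structure(
      list(image = img, class_label = man$class[i],
           attention_label = msk, sample_id = man$sample_id[i]),
      class = "radiograph_sample")
  }
  man$mask_present <- nzchar(man$mask_path %||% rep("", nrow(man)))
  list(samples = samples, manifest = man)
}
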