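# Shared fixtures: tiny phantom worlds and geometric test objects, all
# generated in code at test time.

tiny_phantom_config <- function(n = 6L, seed = 11L) {
  phantom_config(image_width = 96L, image_height = 72L,
                 n_per_class = c(Normal = n, CystTumor = n, LMBD = n),
                 lesion_radius_range = c(4, 8),
                 seed = seed)
}

tiny_train_config <- function(epochs = 2L, seed = 7L, ...) {
  train_config(learning_rate = 0.02, momentum = 0.9, grad_clip = 1,
               recalibrate_every = 1L, epochs = epochs, patience = epochs,
               cosine_T_max = 50L, repeats = 1L,
               loss = loss_config(omega = 10),
               augmentation = augmentation_config(crop_size = c(80, 60)),
               seed = seed, ...)
}

# filled disk mask (area ~ pi r^2) centered at (cx, cy), 0/1 integer matrix
disk_mask <- function(h, w, cx, cy, r) {
  xs <- matrix(seq_len(w), h, w, byrow = TRUE)
  ys <- matrix(seq_len(h), h, w)
  m <- ((xs - cx)^2 + (ys - cy)^2 <= r^2) * 1L
  storage.mode(m) <- "integer"
  m
}

# exact pixel-counting IoU oracle for binary grids
binary_iou <- function(a, b) {
  inter <- sum(a == 1 & b == 1)
  uni <- sum(a == 1 | b == 1)
  if (uni == 0) return(NaN)
  inter / uni
}
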