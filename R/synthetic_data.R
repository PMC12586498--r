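#' Specification for a synthetic leaf-lesion dataset
#'
#' Describes a parametric dataset of leaf images: class 0 is a healthy leaf,
#' every class `c >= 1` carries a class-specific lesion motif (circular brown
#' spots, elongated yellow stripes, clustered dark blobs — cycling for more
#' classes) drawn only inside the leaf region, together with a ground-truth
#' binary lesion mask. The generator is a pure function of the spec and its
#' seed, so identical calls give bit-identical datasets.
#'
#' @param n_classes Number of classes (>= 2); class 0 is healthy.
#' @param per_class_count Images generated per class.
#' @param image_size Square image side in pixels.
#' @param lesion_count_mean Poisson mean of the lesion count per diseased
#'   image (truncated to >= 1).
#' @param lesion_size_range Length-2 vector of minimum/maximum lesion radius
#'   in pixels.
#' @param color_jitter_sd Gaussian s.d. of the per-lesion motif colour jitter.
#' @param seed Integer seed; the dataset is a deterministic function of it.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_classes = 3, per_class_count = 70, image_size = 64,
                           lesion_count_mean = 3, lesion_size_range = c(4, 8),
                           color_jitter_sd = 0.03, seed = 1) {
  if (!is_count(n_classes, 2)) abort_config("n_classes must be an integer >= 2")
  if (!is_count(per_class_count, 1)) abort_config("per_class_count must be a positive integer")
  if (!is_count(image_size, 8)) abort_config("image_size must be an integer >= 8")
  if (!is.numeric(lesion_count_mean) || lesion_count_mean <= 0)
    abort_config("lesion_count_mean must be positive")
  if (length(lesion_size_range) != 2 || any(lesion_size_range <= 0) ||
      lesion_size_range[1] > lesion_size_range[2])
    abort_config("lesion_size_range must be an increasing pair of positive radii")
  if (image_size < 4 * max(lesion_size_range))
    abort_config("image_size %d too small to contain lesions of radius %g",
                 image_size, max(lesion_size_range))
  if (color_jitter_sd < 0) abort_config("color_jitter_sd must be nonnegative")
  structure(list(n_classes = as.integer(n_classes),
                 per_class_count = as.integer(per_class_count),
                 image_size = as.integer(image_size),
                 lesion_count_mean = lesion_count_mean,
                 lesion_size_range = as.numeric(lesion_size_range),
                 color_jitter_sd = color_jitter_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Construct a labeled image sample
#'
#' @param image_id Opaque identifier.
#' @param pixels `height x width x 3` array with values in `[0, 1]`.
#' @param label Integer class index in `{0, ..., C-1}`.
#' @param lesion_mask Optional binary `height x width` matrix.
#' @param split Optional split tag, `"train"` or `"test"`.
#' @return An object of class `image_sample`.
#' @export
image_sample <- function(image_id, pixels, label, lesion_mask = NULL, split = NA_character_) {
  stopifnot(length(dim(pixels)) == 3, dim(pixels)[3] == 3)
  if (any(pixels < 0) || any(pixels > 1)) abort_config("pixel values must lie in [0,1]")
  if (!is.null(lesion_mask)) {
    if (!all(dim(lesion_mask) == dim(pixels)[1:2]))
      abort_config("lesion_mask dimensions must match pixels")
    lesion_mask <- matrix(as.integer(lesion_mask != 0), nrow(lesion_mask), ncol(lesion_mask))
  }
  if (!is_count(label, 0)) abort_config("label must be a nonnegative integer")
  structure(list(image_id = as.character(image_id), pixels = pixels,
                 label = as.integer(label), lesion_mask = lesion_mask,
                 split = split),
            class = "image_sample")
}

# Rotated ellipse leaf silhouette with a low-frequency boundary wobble;
# returns a logical matrix.
leaf_silhouette <- function(side, angle, wobble_phase) {
  cx <- (side + 1) / 2; cy <- (side + 1) / 2
  a <- 0.42 * side; b <- 0.30 * side
  x <- matrix(rep(seq_len(side), each = side), side, side) - cx  # column coord
  y <- matrix(rep(seq_len(side), times = side), side, side) - cy # row coord
  xr <- x * cos(angle) + y * sin(angle)
  yr <- -x * sin(angle) + y * cos(angle)
  phi <- atan2(yr, xr)
  scale <- 1 + 0.06 * sin(3 * phi + wobble_phase)
  (xr / (a * scale))^2 + (yr / (b * scale))^2 <= 1
}

# Pixel support of one lesion, restricted to the leaf. motif: 1 = circular
# spot, 2 = elongated stripe (4:1 aspect), 3 = clustered blobs.
lesion_support <- function(side, leaf, motif, center, radius) {
  x <- matrix(rep(seq_len(side), each = side), side, side) - center[2]
  y <- matrix(rep(seq_len(side), times = side), side, side) - center[1]
  if (motif == 1) {
    supp <- x^2 + y^2 <= radius^2
  } else if (motif == 2) {
    th <- runif(1, 0, pi)
    u <- x * cos(th) + y * sin(th)
    v <- -x * sin(th) + y * cos(th)
    supp <- (u / (2.2 * radius))^2 + (v / (0.55 * radius))^2 <= 1
  } else {
    nb <- sample(3:5, 1)
    supp <- matrix(FALSE, side, side)
    for (j in seq_len(nb)) {
      off <- runif(2, -radius, radius)
      rr <- radius * runif(1, 0.35, 0.6)
      supp <- supp | ((x - off[2])^2 + (y - off[1])^2 <= rr^2)
    }
  }
  supp & leaf
}

motif_base_color <- function(motif) {
  switch(motif,
         c(0.42, 0.26, 0.10),  # brown spot
         c(0.80, 0.72, 0.25),  # yellow stripe
         c(0.12, 0.10, 0.08))  # dark blob
}

#' Generate a synthetic leaf-lesion dataset
#'
#' Class 0 is a lesion-free leaf (empty mask); each diseased class draws
#' `~Poisson(lesion_count_mean)` lesions (at least one) of its motif, centers
#' uniform inside the leaf, motif colours perturbed by Gaussian jitter. The
#' lesion mask is exactly the union of drawn lesion supports.
#'
#' @param spec A [synthetic_spec()].
#' @return List of [image_sample()] objects, `per_class_count` per class.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  side <- spec$image_size
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  samples <- vector("list", spec$n_classes * spec$per_class_count)
  n <- 0L
  for (cls in seq_len(spec$n_classes) - 1L) {
    motif <- if (cls >= 1) ((cls - 1L) %% 3L) + 1L else 0L
    for (i in seq_len(spec$per_class_count)) {
      leaf <- leaf_silhouette(side, runif(1, -pi / 6, pi / 6), runif(1, 0, 2 * pi))
      px <- array(0, c(side, side, 3))
      bg <- c(0.93, 0.92, 0.88)
      green <- c(0.18, 0.50, 0.16) + runif(3, 0, c(0.08, 0.12, 0.06))
      for (ch in 1:3) {
        plane <- matrix(bg[ch], side, side)
        plane[leaf] <- green[ch]
        px[, , ch] <- plane
      }
      mask <- matrix(0L, side, side)
      if (cls >= 1) {
        repeat { nles <- rpois(1, spec$lesion_count_mean); if (nles >= 1) break }
        leaf_idx <- which(leaf)
        for (l in seq_len(nles)) {
          ci <- leaf_idx[sample.int(length(leaf_idx), 1)]
          center <- c((ci - 1) %% side + 1, (ci - 1) %/% side + 1)  # (row, col)
          radius <- runif(1, spec$lesion_size_range[1], spec$lesion_size_range[2])
          supp <- lesion_support(side, leaf, motif, center, radius)
          col <- clamp01(motif_base_color(motif) + rnorm(3, 0, spec$color_jitter_sd))
          for (ch in 1:3) {
            plane <- px[, , ch]
            plane[supp] <- col[ch]
            px[, , ch] <- plane
          }
          mask[supp] <- 1L
        }
      }
      # mild sensor noise everywhere, lesions untouched in the mask
      px <- clamp01(px + array(rnorm(side * side * 3, 0, 0.015), dim(px)))
      n <- n + 1L
      samples[[n]] <- image_sample(sprintf("c%d_i%04d", cls, i), px, cls,
                                   lesion_mask = mask)
    }
  }
  samples
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

sample_labels <- function(samples) vapply(samples, function(s) s$label, 0L)
sample_ids <- function(samples) vapply(samples, function(s) s$image_id, "")

#' Stratified train/test split
#'
#' Splits a dataset by label so each class is within one sample of
#' `train_fraction`; the assignment is a deterministic function of the seed.
#'
#' @param samples List of [image_sample()].
#' @param train_fraction Fraction of each class assigned to training.
#' @param seed Integer seed.
#' @return A manifest `data.frame` with columns `image_id`, `image_path`,
#'   `label`, `split`, `mask_path`.
#' @export
split_dataset <- function(samples, train_fraction = 0.8, seed = 1) {
  if (!(train_fraction > 0 && train_fraction < 1))
    abort_config("train_fraction must be in (0,1)")
  labels <- sample_labels(samples)
  if (any(table(labels) < 2)) abort_config("every class needs >= 2 samples to stratify")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, "split"))
  split <- character(length(samples))
  for (cls in sort(unique(labels))) {
    idx <- which(labels == cls)
    idx <- idx[sample.int(length(idx))]
    ntr <- round(train_fraction * length(idx))
    ntr <- min(max(ntr, 1), length(idx) - 1)
    split[idx[seq_len(ntr)]] <- "train"
    split[idx[-seq_len(ntr)]] <- "test"
  }
  manifest_frame(samples, split)
}

manifest_frame <- function(samples, split) {
  ids <- sample_ids(samples)
  data.frame(image_id = ids,
             image_path = file.path("images", paste0(ids, ".png")),
             label = sample_labels(samples),
             split = split,
             mask_path = ifelse(vapply(samples, function(s) is.null(s$lesion_mask), TRUE),
                                NA_character_, file.path("masks", paste0(ids, ".png"))),
             stringsAsFactors = FALSE)
}

#' Stratified k-fold partition
#'
#' @param samples List of [image_sample()].
#' @param k Number of folds (>= 2, at most the smallest class count).
#' @param seed Integer seed.
#' @return List of `k` manifests; each sample is in the test split of exactly
#'   one manifest.
#' @export
make_kfold_splits <- function(samples, k, seed = 1) {
  if (!is_count(k, 2)) abort_config("k must be an integer >= 2")
  labels <- sample_labels(samples)
  if (min(table(labels)) < k)
    abort_config("k = %d exceeds the smallest class count (%d)", k, min(table(labels)))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, "kfold"))
  fold <- integer(length(samples))
  off <- 0L  # round-robin continues across classes so fold sizes balance
  for (cls in sort(unique(labels))) {
    idx <- which(labels == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- ((seq_along(idx) - 1L + off) %% k) + 1L
    off <- (off + length(idx)) %% k
  }
  lapply(seq_len(k), function(f)
    manifest_frame(samples, ifelse(fold == f, "test", "train")))
}

#' Attach a manifest's split assignment to samples
#'
#' @param samples List of [image_sample()].
#' @param manifest Manifest `data.frame` from [split_dataset()].
#' @return Samples with their `split` fields set.
#' @export
apply_split <- function(samples, manifest) {
  sp <- manifest$split[match(sample_ids(samples), manifest$image_id)]
  if (anyNA(sp)) abort_config("manifest does not cover all samples")
  Map(function(s, v) { s$split <- v; s }, samples, sp)
}

#' Resize a sample to a square side
#'
#' Pixels are resampled bilinearly, the lesion mask (if any) with
#' nearest-neighbour filtering; pixel values stay in `[0, 1]`.
#'
#' @param sample An [image_sample()].
#' @param side Target side in pixels (>= 8).
#' @return The resized [image_sample()].
#' @export
resize_sample <- function(sample, side) {
  if (!is_count(side, 8)) abort_config("side must be an integer >= 8")
  if (all(dim(sample$pixels)[1:2] == side)) return(sample)
  px <- EBImage::resize(sample$pixels, w = side, h = side, filter = "bilinear")
  px <- clamp01(array(px, c(side, side, 3)))
  mask <- sample$lesion_mask
  if (!is.null(mask)) {
    mask <- EBImage::resize(mask + 0, w = side, h = side, filter = "none")
    mask <- matrix(as.integer(mask > 0.5), side, side)
  }
  image_sample(sample$image_id, px, sample$label, mask, sample$split)
}

#' Write a dataset and its manifest to disk
#'
#' Images are written as PNG, masks as single-channel 0/255 PNG, the manifest
#' as `manifest.csv` with header `image_path,label,split,mask_path` (paths
#' relative to `dir`).
#'
#' @param samples List of [image_sample()].
#' @param manifest Manifest `data.frame` (see [split_dataset()]).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the path to `manifest.csv`.
#' @export
materialize_dataset <- function(samples, manifest, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  by_id <- match(manifest$image_id, sample_ids(samples))
  for (i in seq_len(nrow(manifest))) {
    s <- samples[[by_id[i]]]
    png::writePNG(s$pixels, file.path(dir, manifest$image_path[i]))
    if (!is.na(manifest$mask_path[i]))
      png::writePNG(s$lesion_mask + 0, file.path(dir, manifest$mask_path[i]))
  }
  path <- file.path(dir, "manifest.csv")
  write.csv(manifest[, c("image_path", "label", "split", "mask_path")], path,
            row.names = FALSE)
  invisible(path)
}

#' Load a dataset from a manifest CSV
#'
#' @param manifest_csv Path to a `manifest.csv` written by
#'   [materialize_dataset()].
#' @return List of [image_sample()] with splits set.
#' @export
load_dataset <- function(manifest_csv) {
  dir <- dirname(manifest_csv)
  mf <- read.csv(manifest_csv, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(mf)), function(i) {
    px <- png::readPNG(file.path(dir, mf$image_path[i]))
    if (length(dim(px)) == 2) px <- array(rep(px, 3), c(dim(px), 3))
    if (dim(px)[3] > 3) px <- px[, , 1:3]
    mask <- NULL
    if (!is.na(mf$mask_path[i]) && nzchar(mf$mask_path[i])) {
      m <- png::readPNG(file.path(dir, mf$mask_path[i]))
      if (length(dim(m)) == 3) m <- m[, , 1]
      mask <- matrix(as.integer(m > 0.5), nrow(m), ncol(m))
    }
    image_sample(tools::file_path_sans_ext(basename(mf$image_path[i])),
                 px, mf$label[i], mask, mf$split[i])
  })
}
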