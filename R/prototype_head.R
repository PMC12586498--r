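#' Create a prototype bank
#'
#' `per_class` learnable D-dimensional prototypes per class, each of 1x1
#' spatial extent, initialized uniformly in `[0, 1]^D` to match the
#' sigmoid-bounded feature range. Prototypes are ordered class-major:
#' indices `1..per_class` belong to class 0, and so on.
#'
#' @param n_classes Number of classes C.
#' @param depth Latent depth D (must equal the extractor's `addon_channels`).
#' @param per_class Prototypes per class (default 10).
#' @param epsilon Similarity-kernel floor; bounds the maximal similarity at
#'   `log(1/epsilon)`.
#' @return An object of class `prototype_bank`.
#' @export
prototype_bank <- function(n_classes, depth, per_class = 10, epsilon = 1e-4) {
  if (!is_count(n_classes, 2)) abort_config("n_classes must be >= 2")
  if (!is_count(per_class, 1)) abort_config("per_class must be >= 1")
  if (epsilon <= 0) abort_config("epsilon must be positive")
  m <- n_classes * per_class
  structure(list(vectors = matrix(runif(m * depth), m, depth),
                 class_of = rep(seq_len(n_classes) - 1L, each = per_class),
                 per_class = as.integer(per_class),
                 n_classes = as.integer(n_classes),
                 epsilon = epsilon,
                 provenance = NULL),
            class = "prototype_bank")
}

#' Log-ratio similarity kernel
#'
#' Maps a squared Euclidean distance to `log((d2 + 1) / (d2 + epsilon))`:
#' strictly decreasing in the distance, maximal at `log(1/epsilon)` for an
#' exact match, and approaching 0 from above as the distance grows.
#'
#' @param sq_dist Nonnegative squared distance(s).
#' @param epsilon Positive kernel floor.
#' @return Similarity value(s) in `(0, log(1/epsilon)]`.
#' @export
similarity_from_sqdist <- function(sq_dist, epsilon = 1e-4) {
  if (any(sq_dist < 0)) stop("sq_dist must be nonnegative", call. = FALSE)
  if (epsilon <= 0) stop("epsilon must be positive", call. = FALSE)
  log((sq_dist + 1) / (sq_dist + epsilon))
}

# Squared distances between all 1x1 latent patches (rows of Z, npos x D) and
# all prototypes (rows of P, m x D); numerically safe expansion clamped at 0.
patch_sqdist <- function(Zm, P) {
  d2 <- matrix(rowSums(Zm^2), nrow(Zm), nrow(P)) -
    2 * tcrossprod(Zm, P) +
    matrix(rowSums(P^2), nrow(Zm), nrow(P), byrow = TRUE)
  d2[d2 < 0] <- 0
  d2
}

# Row-major-first argmax of an H x W matrix: smallest row, then column.
argmax_rowmajor <- function(field) {
  mx <- max(field)
  cand <- which(field == mx)
  H <- nrow(field)
  r <- (cand - 1L) %% H + 1L
  cc <- (cand - 1L) %/% H + 1L
  o <- order(r, cc)[1]
  c(r[o], cc[o])
}

#' Per-prototype similarity fields of a feature volume
#'
#' For every prototype, computes the squared Euclidean distance to every 1x1
#' latent patch, maps it through [similarity_from_sqdist()], and records the
#' field maximum (the layer's global max pooling). Ties in the argmax cell
#' resolve to the first cell in row-major order.
#'
#' @param volume A `feature_volume` from [extract_features()].
#' @param bank A [prototype_bank()] of matching depth.
#' @return List of `similarity_field`s: each has `map` (H x W matrix),
#'   `max_score`, `argmax_cell` (row, col) and `prototype_id`.
#' @export
compute_similarity_fields <- function(volume, bank) {
  Zm <- vol_matrix(volume)
  if (ncol(Zm) != ncol(bank$vectors))
    abort_config("volume depth %d does not match prototype depth %d",
                 ncol(Zm), ncol(bank$vectors))
  H <- dim(volume$values)[1]; W <- dim(volume$values)[2]
  S <- similarity_from_sqdist(patch_sqdist(Zm, bank$vectors), bank$epsilon)
  lapply(seq_len(nrow(bank$vectors)), function(j) {
    map <- matrix(S[, j], H, W)
    cell <- argmax_rowmajor(map)
    structure(list(map = map, max_score = map[cell[1], cell[2]],
                   argmax_cell = cell, prototype_id = j),
              class = "similarity_field")
  })
}

#' Initialize the fully connected classifier head
#'
#' The head weight connects each prototype to each class logit. Entries for a
#' prototype's own class start at +1, entries to other classes at -0.5,
#' biases at 0 (the prototypical-part-network convention).
#'
#' @param bank A [prototype_bank()].
#' @return A `classifier_head`: list with `weight` (m x C) and `bias` (C).
#' @export
classifier_head <- function(bank) {
  C <- bank$n_classes
  W <- matrix(-0.5, nrow(bank$vectors), C)
  for (j in seq_len(nrow(bank$vectors))) W[j, bank$class_of[j] + 1L] <- 1
  structure(list(weight = W, bias = numeric(C)), class = "classifier_head")
}

#' Predict a class from a feature volume
#'
#' The similarity vector is the per-prototype field maximum; logits are its
#' linear image under the head; probabilities are the softmax of the logits.
#'
#' @param volume A `feature_volume`.
#' @param bank A [prototype_bank()].
#' @param head A [classifier_head()].
#' @return A `prediction`: `similarity_vector`, `logits`, `probabilities`,
#'   `predicted_class` (0-based).
#' @export
predict_volume <- function(volume, bank, head) {
  Zm <- vol_matrix(volume)
  S <- similarity_from_sqdist(patch_sqdist(Zm, bank$vectors), bank$epsilon)
  s <- apply(S, 2, max)
  logits <- as.vector(s %*% head$weight) + head$bias
  if (any(!is.finite(logits)))
    stop("non-finite logits; check feature extractor and head parameters", call. = FALSE)
  probs <- softmax(logits)
  structure(list(similarity_vector = s, logits = logits, probabilities = probs,
                 predicted_class = which.max(probs) - 1L),
            class = "prediction")
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

#' Project prototypes onto real training patches (the "push" step)
#'
#' Replaces every prototype by the nearest (squared L2) 1x1 latent patch
#' among the training volumes of its own class, and records provenance: the
#' source image id, latent cell, and the aligned pixel box. Ties resolve to
#' the first candidate in enumeration order (volumes in input order, cells
#' column-major). The classifier head is untouched.
#'
#' @param bank A [prototype_bank()].
#' @param volumes List of `feature_volume`s of training images.
#' @param labels Integer labels (0-based) aligned with `volumes`.
#' @return The bank with projected `vectors` and filled `provenance`.
#' @export
project_prototypes <- function(bank, volumes, labels) {
  stopifnot(length(volumes) == length(labels))
  prov <- vector("list", nrow(bank$vectors))
  vecs <- bank$vectors
  for (cls in sort(unique(bank$class_of))) {
    vidx <- which(labels == cls)
    if (length(vidx) == 0)
      abort_config("no training volumes for class %d", cls)
    mats <- lapply(volumes[vidx], vol_matrix)
    patches <- do.call(rbind, mats)
    npatch <- vapply(mats, nrow, 0L)
    owner <- rep(vidx, npatch)
    within <- unlist(lapply(npatch, seq_len))
    pidx <- which(bank$class_of == cls)
    d2 <- patch_sqdist(patches, bank$vectors[pidx, , drop = FALSE])
    for (jj in seq_along(pidx)) {
      best <- which.min(d2[, jj])  # first occurrence on ties
      vol <- volumes[[owner[best]]]
      H <- dim(vol$values)[1]
      cell <- c((within[best] - 1L) %% H + 1L, (within[best] - 1L) %/% H + 1L)
      vecs[pidx[jj], ] <- patches[best, ]
      prov[[pidx[jj]]] <- list(prototype_id = pidx[jj], class = cls,
                               image_id = vol$source_image_id,
                               latent_cell = cell,
                               pixel_box = latent_to_pixel_box(cell[1], cell[2], vol))
    }
  }
  bank$vectors <- vecs
  bank$provenance <- prov
  bank
}
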