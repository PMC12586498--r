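#' Loss weights for the composite training objective
#'
#' The total objective is
#' `ce + lambda1 * cluster + lambda2 * separation + lambda3 * contrastive`.
#' The separation term is nonpositive by construction (it carries its own
#' minus sign), so a positive `lambda2` rewards distance from wrong-class
#' prototypes. Defaults follow the prototypical-part-network convention for
#' `lambda1`/`lambda2`; `lambda3` keeps the contrastive term a perturbation.
#'
#' @param lambda1 Cluster weight (default 0.8).
#' @param lambda2 Separation weight (default 0.08).
#' @param lambda3 Contrastive weight (default 0.1).
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(lambda1 = 0.8, lambda2 = 0.08, lambda3 = 0.1) {
  stopifnot(is.finite(lambda1), is.finite(lambda2), is.finite(lambda3))
  structure(list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3),
            class = "loss_weights")
}

#' Cross-entropy loss
#'
#' Mean negative log-probability of the true class; probabilities are
#' clipped below at 1e-12 before the log so the loss stays finite.
#'
#' @param probabilities N x C matrix (or length-C vector) of class
#'   probabilities, rows summing to 1.
#' @param labels Integer class labels, 0-based.
#' @return Nonnegative scalar.
#' @export
cross_entropy <- function(probabilities, labels) {
  if (is.null(dim(probabilities))) probabilities <- matrix(probabilities, 1)
  N <- nrow(probabilities); C <- ncol(probabilities)
  if (length(labels) != N) abort_config("need one label per probability row")
  if (any(labels < 0 | labels >= C)) stop("label out of range", call. = FALSE)
  p <- probabilities[cbind(seq_len(N), labels + 1L)]
  -mean(log(pmax(p, 1e-12)))
}

# InfoNCE without input validation; keys = rbind(positive, negatives).
infonce <- function(query, positive_key, negative_keys, tau) {
  keys <- rbind(positive_key, negative_keys)
  logits <- as.vector(keys %*% query) / tau
  m <- max(logits)
  -(logits[1] - (m + log(sum(exp(logits - m)))))
}

# Analytic gradient of infonce w.r.t. query, positive and negative keys.
infonce_grad <- function(query, positive_key, negative_keys, tau) {
  keys <- rbind(positive_key, negative_keys)
  logits <- as.vector(keys %*% query) / tau
  p <- softmax(logits)
  dq <- (as.vector(p %*% keys) - positive_key) / tau
  dkeys <- outer(p, query) / tau
  dkeys[1, ] <- dkeys[1, ] - query / tau
  list(dq = dq, dpos = dkeys[1, ], dnegs = dkeys[-1, , drop = FALSE])
}

#' InfoNCE contrastive loss
#'
#' Matches a query embedding against one positive key among K negatives at
#' temperature `tau`: `-log( exp(q.v+/tau) / sum_k exp(q.v_k/tau) )`, the
#' denominator running over the positive plus the K negatives.
#'
#' @param query,positive_key Unit-norm length-E vectors.
#' @param negative_keys K x E matrix of unit-norm rows.
#' @param tau Positive temperature.
#' @return Nonnegative scalar.
#' @export
contrastive_loss <- function(query, positive_key, negative_keys, tau = 0.07) {
  if (tau <= 0) abort_config("tau must be positive")
  if (is.null(dim(negative_keys))) negative_keys <- matrix(negative_keys, 1)
  all_vecs <- rbind(query, positive_key, negative_keys)
  nrm <- sqrt(rowSums(all_vecs^2))
  if (any(nrm == 0)) stop("zero-norm embedding", call. = FALSE)
  if (any(abs(nrm - 1) > 1e-6))
    abort_config("embeddings must be L2-normalized within 1e-6")
  infonce(query, positive_key, negative_keys, tau)
}

# Per-image minimal squared distance to a prototype subset, with argmins.
min_dist_info <- function(Zm, bank, cols) {
  d2 <- patch_sqdist(Zm, bank$vectors[cols, , drop = FALSE])
  k <- arrayInd(which.min(d2), dim(d2))
  list(value = d2[k[1], k[2]], patch = k[1], proto = cols[k[2]])
}

#' Cluster loss
#'
#' Mean over images of the minimal squared L2 distance between any latent
#' patch and any prototype of the image's own class; pulling it down ensures
#' every training image has at least one patch close to an own-class
#' prototype.
#'
#' @param volumes List of `feature_volume`s.
#' @param labels Integer labels (0-based) aligned with `volumes`.
#' @param bank A [prototype_bank()].
#' @return Nonnegative scalar.
#' @export
cluster_loss <- function(volumes, labels, bank) {
  stopifnot(length(volumes) >= 1, length(volumes) == length(labels))
  if (!all(labels %in% bank$class_of))
    abort_config("every label must own prototypes in the bank")
  vals <- mapply(function(v, y)
    min_dist_info(vol_matrix(v), bank, which(bank$class_of == y))$value,
    volumes, labels)
  mean(vals)
}

#' Separation loss
#'
#' Negative mean over images of the minimal squared L2 distance between any
#' latent patch and any wrong-class prototype; always nonpositive, and
#' minimizing it pushes patches away from other classes' prototypes.
#'
#' @inheritParams cluster_loss
#' @return Nonpositive scalar.
#' @export
separation_loss <- function(volumes, labels, bank) {
  stopifnot(length(volumes) >= 1, length(volumes) == length(labels))
  if (length(unique(bank$class_of)) < 2)
    stop("separation loss needs prototypes from at least two classes", call. = FALSE)
  vals <- mapply(function(v, y)
    min_dist_info(vol_matrix(v), bank, which(bank$class_of != y))$value,
    volumes, labels)
  -mean(vals)
}

# Gradients of cluster/separation w.r.t. prototypes and volumes.
# sign = +1 for cluster, -1 for separation.
clustersep_grad <- function(volumes, labels, bank, own = TRUE) {
  N <- length(volumes)
  sign <- if (own) 1 else -1
  dP <- matrix(0, nrow(bank$vectors), ncol(bank$vectors))
  dZ <- vector("list", N)
  for (i in seq_len(N)) {
    Zm <- vol_matrix(volumes[[i]])
    cols <- if (own) which(bank$class_of == labels[i]) else which(bank$class_of != labels[i])
    info <- min_dist_info(Zm, bank, cols)
    diff <- Zm[info$patch, ] - bank$vectors[info$proto, ]
    dzi <- matrix(0, nrow(Zm), ncol(Zm))
    dzi[info$patch, ] <- sign * 2 * diff / N
    dP[info$proto, ] <- dP[info$proto, ] - sign * 2 * diff / N
    dZ[[i]] <- dzi
  }
  list(dP = dP, dZ = dZ)
}

#' Combine loss terms into the total objective
#'
#' @param ce,cluster,separation,contrastive Finite loss components.
#' @param weights A [loss_weights()].
#' @return A `loss_breakdown`: the four components plus `total`.
#' @export
total_loss <- function(ce, cluster, separation, contrastive, weights = loss_weights()) {
  parts <- c(ce, cluster, separation, contrastive)
  if (any(!is.finite(parts))) stop("non-finite loss component", call. = FALSE)
  structure(list(ce = ce, cluster = cluster, separation = separation,
                 contrastive = contrastive,
                 total = ce + weights$lambda1 * cluster +
                   weights$lambda2 * separation + weights$lambda3 * contrastive),
            class = "loss_breakdown")
}

# Cross-entropy gradient through the prototype head for one volume:
# returns loss and gradients w.r.t. the volume, the prototypes and the head.
# grad_cap bounds the kernel-derivative factor d(sim)/d(d2), which grows
# like 1/epsilon as a patch coincides with a prototype (always the case
# right after a push); capping it is the per-term analog of gradient
# clipping and leaves the gradient exact wherever d2 >~ 1/grad_cap.
ce_head_grad <- function(volume, label, bank, head, grad_cap = Inf) {
  Zm <- vol_matrix(volume)
  d2 <- patch_sqdist(Zm, bank$vectors)
  S <- similarity_from_sqdist(d2, bank$epsilon)
  wm <- max.col(t(S), ties.method = "first")   # argmax patch per prototype
  m <- nrow(bank$vectors)
  s <- S[cbind(wm, seq_len(m))]
  logits <- as.vector(s %*% head$weight) + head$bias
  probs <- softmax(logits)
  loss <- -log(max(probs[label + 1L], 1e-12))
  dlogits <- probs
  dlogits[label + 1L] <- dlogits[label + 1L] - 1
  ds <- as.vector(head$weight %*% dlogits)
  d2w <- d2[cbind(wm, seq_len(m))]
  gk <- 1 / (d2w + 1) - 1 / (d2w + bank$epsilon)   # d sim / d d2
  gk <- pmax(gk, -grad_cap)
  dd2 <- ds * gk
  dZ <- matrix(0, nrow(Zm), ncol(Zm))
  dP <- matrix(0, m, ncol(Zm))
  for (j in seq_len(m)) {
    diff <- Zm[wm[j], ] - bank$vectors[j, ]
    dZ[wm[j], ] <- dZ[wm[j], ] + dd2[j] * 2 * diff
    dP[j, ] <- dP[j, ] - dd2[j] * 2 * diff
  }
  list(loss = loss, dZ = dZ, dP = dP,
       dW = outer(s, dlogits), db = dlogits, probs = probs, s = s)
}
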