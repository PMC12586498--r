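#' Contrastive learning state: momentum key encoder + FIFO dictionary
#'
#' Holds a shadow ("key") copy of the feature-extractor and projection
#' parameters, updated as an exponential moving average of the query
#' parameters, and a FIFO queue of unit-norm key embeddings with their class
#' labels that supplies positives and negatives for the supervised
#' contrastive loss.
#'
#' @param params Query parameters (the key encoder starts as a copy).
#' @param queue_size Queue capacity Q.
#' @param momentum EMA coefficient in `[0, 1]` (1 freezes the key encoder).
#' @param tau Temperature of the InfoNCE loss.
#' @param embed_dim Embedding dimension E.
#' @return An object of class `contrastive_state`.
#' @export
contrastive_state <- function(params, queue_size = 1024, momentum = 0.999,
                              tau = 0.07, embed_dim = 64) {
  stopifnot(momentum >= 0, momentum <= 1, tau > 0, is_count(queue_size, 1))
  structure(list(key_params = params,
                 queue_emb = matrix(0, 0, embed_dim),
                 queue_lab = integer(0),
                 queue_size = as.integer(queue_size),
                 momentum = momentum, tau = tau,
                 embed_dim = as.integer(embed_dim)),
            class = "contrastive_state")
}

blend_params <- function(key, query, m) {
  if (is.list(key)) return(Map(blend_params, key, query, MoreArgs = list(m = m)))
  if (is.numeric(key)) {
    if (length(key) != length(query)) stop("parameter shape mismatch", call. = FALSE)
    return(m * key + (1 - m) * query)
  }
  key
}

#' Momentum update of the key encoder
#'
#' Element-wise `key <- momentum * key + (1 - momentum) * query`.
#'
#' @param state A [contrastive_state()].
#' @param query_params Current query parameters (same shapes).
#' @return The state with updated `key_params`.
#' @export
momentum_update <- function(state, query_params) {
  state$key_params <- blend_params(state$key_params, query_params, state$momentum)
  state
}

# Embedding with the intermediates needed for backprop.
embed_with_cache <- function(Zm, projW) {
  pooled <- apply(Zm, 2, max)
  rows <- apply(Zm, 2, which.max)
  v0 <- as.vector(pooled %*% projW)
  nrm <- sqrt(sum(v0^2))
  if (nrm == 0) stop("zero vector before normalization", call. = FALSE)
  list(emb = v0 / nrm, v0 = v0, nrm = nrm, pooled = pooled, rows = rows)
}

#' Embed a feature volume for the contrastive branch
#'
#' Global max pooling over the spatial grid, a linear projection to E
#' dimensions, then L2 normalization.
#'
#' @param volume A `feature_volume`.
#' @param proj_params Projection parameters: list with `W` (D x E).
#' @return Unit-norm length-E numeric vector.
#' @export
embed_for_contrast <- function(volume, proj_params) {
  embed_with_cache(vol_matrix(volume), proj_params$W)$emb
}

# Backprop d(loss)/d(emb) through normalization and projection down to the
# volume matrix. Returns dZ (npos x D) and dprojW.
embed_backward <- function(demb, cache, projW, npos) {
  q <- cache$emb
  dv0 <- (demb - q * sum(q * demb)) / cache$nrm
  dproj <- outer(cache$pooled, dv0)
  dpooled <- as.vector(projW %*% dv0)
  dZ <- matrix(0, npos, nrow(projW))
  dZ[cbind(cache$rows, seq_along(dpooled))] <- dpooled
  list(dZ = dZ, dproj = dproj)
}

#' Supervised contrastive step against the key dictionary
#'
#' For every query, the InfoNCE loss is averaged over its same-class queue
#' keys (each acting once as the positive) with all different-class keys as
#' negatives; queries lacking either a same-class or a different-class key
#' are skipped and counted. Afterwards the batch's key-encoder embeddings
#' are enqueued and the oldest entries dequeued.
#'
#' @param query_embs N x E matrix of unit-norm query embeddings.
#' @param labels Integer labels (0-based) of the queries.
#' @param key_embs N x E matrix of unit-norm key-encoder embeddings of the
#'   same batch (enqueued after the loss).
#' @param state A [contrastive_state()].
#' @return List: `loss` (mean over non-skipped queries, 0 if all skipped),
#'   `grad` (N x E gradient w.r.t. the query embeddings), `skipped` (count),
#'   and the updated `state`.
#' @export
supervised_contrastive_step <- function(query_embs, labels, key_embs, state) {
  if (is.null(dim(query_embs))) query_embs <- matrix(query_embs, 1)
  if (is.null(dim(key_embs))) key_embs <- matrix(key_embs, 1)
  N <- nrow(query_embs)
  if (nrow(state$queue_emb) == 0) stop("empty queue", call. = FALSE)
  tau <- state$tau
  grads <- matrix(0, N, ncol(query_embs))
  losses <- numeric(0)
  used <- logical(N)
  for (i in seq_len(N)) {
    pos <- which(state$queue_lab == labels[i])
    neg <- which(state$queue_lab != labels[i])
    if (length(pos) == 0 || length(neg) == 0) next
    used[i] <- TRUE
    q <- query_embs[i, ]
    dots <- as.vector(state$queue_emb %*% q) / tau
    eneg <- exp(dots[neg])
    Sneg <- sum(eneg)
    Vneg <- as.vector(crossprod(state$queue_emb[neg, , drop = FALSE], eneg))
    epos <- exp(dots[pos])
    denom <- epos + Sneg
    losses <- c(losses, mean(-log(epos / denom)))
    # dL_t/dq = ((e_t v_t + Vneg)/denom_t - v_t)/tau, averaged over positives t
    coef <- (epos / denom - 1) / (tau * length(pos))
    grads[i, ] <- as.vector(crossprod(state$queue_emb[pos, , drop = FALSE], coef)) +
      Vneg * sum(1 / denom) / (tau * length(pos))
  }
  n_used <- sum(used)
  loss <- if (n_used > 0) mean(losses) else 0
  if (n_used > 0) grads <- grads / n_used else grads[] <- 0
  state$queue_emb <- rbind(state$queue_emb, key_embs)
  state$queue_lab <- c(state$queue_lab, as.integer(labels))
  if (nrow(state$queue_emb) > state$queue_size) {
    keep <- (nrow(state$queue_emb) - state$queue_size + 1):nrow(state$queue_emb)
    state$queue_emb <- state$queue_emb[keep, , drop = FALSE]
    state$queue_lab <- state$queue_lab[keep]
  }
  list(loss = loss, grad = grads, skipped = N - n_used, state = state)
}
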