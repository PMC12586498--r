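# Minimal convolutional-network engine. Convolutions are evaluated as
# im2col gathers followed by BLAS matrix multiplication; the col2im scatter
# needed for input gradients is a precomputed sparse matrix product. All
# spatial maps are stored as (npos x channels) matrices with positions in
# column-major order (row fastest), npos = ho * wo.

.geom_cache <- new.env(parent = emptyenv())

conv_geometry <- function(h, w, cin, k = 3L, stride = 2L, pad = 1L) {
  key <- paste(h, w, cin, k, stride, pad, sep = "_")
  g <- .geom_cache[[key]]
  if (!is.null(g)) return(g)
  ho <- (h + 2L * pad - k) %/% stride + 1L
  wo <- (w + 2L * pad - k) %/% stride + 1L
  hp <- h + 2L * pad; wp <- w + 2L * pad
  orow <- rep(seq_len(ho), times = wo); ocol <- rep(seq_len(wo), each = ho)
  r0 <- (orow - 1L) * stride; c0 <- (ocol - 1L) * stride
  kr <- rep(seq_len(k) - 1L, times = k); kc <- rep(seq_len(k) - 1L, each = k)
  npos <- ho * wo; kk <- k * k
  idx2d <- outer(r0, kr, "+") + 1L + outer(c0, kc, "+") * hp
  P <- matrix(0L, npos, kk * cin)
  for (ch in seq_len(cin)) P[, ((ch - 1L) * kk + 1L):(ch * kk)] <- idx2d + (ch - 1L) * hp * wp
  S <- Matrix::sparseMatrix(i = as.vector(P), j = seq_along(P), x = 1,
                            dims = c(hp * wp * cin, length(P)))
  g <- list(h = h, w = w, cin = cin, k = k, stride = stride, pad = pad,
            ho = ho, wo = wo, hp = hp, wp = wp, npos = npos, P = P, S = S)
  .geom_cache[[key]] <- g
  g
}

# x: (h, w, cin) array -> list(X = im2col matrix, Y = npos x cout preact)
conv_forward <- function(x, W, b, g) {
  xpad <- array(0, c(g$hp, g$wp, g$cin))
  xpad[(g$pad + 1):(g$pad + g$h), (g$pad + 1):(g$pad + g$w), ] <- x
  v <- as.vector(xpad)
  X <- v[g$P]; dim(X) <- dim(g$P)
  Y <- X %*% W
  Y <- Y + rep(b, each = g$npos)
  list(X = X, Y = Y)
}

# dY: npos x cout gradient of the preactivation.
conv_backward <- function(dY, X, W, g, need_dx = TRUE) {
  dW <- crossprod(X, dY)
  db <- colSums(dY)
  dx <- NULL
  if (need_dx) {
    dXc <- tcrossprod(dY, W)
    dxp <- as.vector(g$S %*% as.vector(dXc))
    dim(dxp) <- c(g$hp, g$wp, g$cin)
    dx <- dxp[(g$pad + 1):(g$pad + g$h), (g$pad + 1):(g$pad + g$w), , drop = FALSE]
  }
  list(dW = dW, db = db, dx = dx)
}

he_init <- function(nin, nout) matrix(rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
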