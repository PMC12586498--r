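# Inverse-mapped image warping: every geometric augmentation (projective
# skew, shear, flip, elastic distortion) is expressed as a map from output
# pixel coordinates to source coordinates, sampled bilinearly for images and
# nearest-neighbour for masks. One engine, one coordinate convention:
# (row, col), 1-based, row = y, col = x.

# Sample img (h x w matrix) at continuous (rows, cols); border replicated.
bilinear_sample_plane <- function(img, rows, cols) {
  h <- nrow(img); w <- ncol(img)
  r <- pmin(pmax(rows, 1), h); cc <- pmin(pmax(cols, 1), w)
  r0 <- pmin(floor(r), h - 1); c0 <- pmin(floor(cc), w - 1)
  fr <- r - r0; fc <- cc - c0
  i00 <- r0 + (c0 - 1) * h
  v <- (1 - fr) * (1 - fc) * img[i00] + fr * (1 - fc) * img[i00 + 1] +
       (1 - fr) * fc * img[i00 + h] + fr * fc * img[i00 + h + 1]
  v
}

nearest_sample_plane <- function(img, rows, cols, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  r <- round(rows); cc <- round(cols)
  ok <- r >= 1 & r <= h & cc >= 1 & cc <= w
  out <- rep(fill, length(rows))
  out[ok] <- img[r[ok] + (cc[ok] - 1) * h]
  out
}

# Homography H (3x3) with [u, v, 1]^T ~ H [x, y, 1]^T from 4 correspondences
# (x, y) -> (u, v); x = col, y = row.
solve_homography <- function(xy, uv) {
  A <- matrix(0, 8, 8); b <- numeric(8)
  for (i in 1:4) {
    x <- xy[i, 1]; y <- xy[i, 2]; u <- uv[i, 1]; v <- uv[i, 2]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y)
    A[2 * i, ]     <- c(0, 0, 0, x, y, 1, -v * x, -v * y)
    b[2 * i - 1] <- u; b[2 * i] <- v
  }
  h <- solve(A, b)
  matrix(c(h, 1), 3, 3, byrow = TRUE)
}

identity_homography <- function() diag(3)

# Keystone ("skew") homography: projective tilt of the image plane by
# angle_deg about the horizontal axis through the image center — the top edge
# of the source quad is inset (angle > 0) or the bottom edge (angle < 0).
skew_homography <- function(angle_deg, h, w) {
  t <- tan(angle_deg * pi / 180) * 0.25
  inset <- abs(t) * (w - 1) / 2
  if (t >= 0) {
    src <- rbind(c(1 + inset, 1), c(w - inset, 1), c(w, h), c(1, h))
  } else {
    src <- rbind(c(1, 1), c(w, 1), c(w - inset, h), c(1 + inset, h))
  }
  dst <- rbind(c(1, 1), c(w, 1), c(w, h), c(1, h))
  solve_homography(dst, src)
}

# Horizontal shear by angle_deg about the image center: u = x + sh*(y - cy).
shear_homography <- function(angle_deg, h, w) {
  sh <- tan(angle_deg * pi / 180)
  cy <- (h + 1) / 2
  matrix(c(1, sh, -sh * cy,
           0, 1, 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

flip_homography <- function(h, w) {
  matrix(c(-1, 0, w + 1,
           0, 1, 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

# Elastic displacement field: a g x g grid of i.i.d. Gaussian control-point
# displacements (s.d. = intensity scaled to the working resolution relative
# to the 224-pixel reference) bilinearly upsampled to full resolution.
elastic_field <- function(h, w, intensity, grid = 4) {
  sd <- intensity * max(h, w) / 224
  ctrl_r <- matrix(rnorm(grid * grid, 0, sd), grid, grid)
  ctrl_c <- matrix(rnorm(grid * grid, 0, sd), grid, grid)
  rows <- (seq_len(h) - 1) / (h - 1) * (grid - 1) + 1
  cols <- (seq_len(w) - 1) / (w - 1) * (grid - 1) + 1
  rg <- rep(rows, times = w); cg <- rep(cols, each = h)
  list(dr = matrix(bilinear_sample_plane(ctrl_r, rg, cg), h, w),
       dc = matrix(bilinear_sample_plane(ctrl_c, rg, cg), h, w))
}

# Apply homography + optional elastic field to an image (h x w x 3) and an
# optional mask. Returns list(pixels, mask).
warp_sample <- function(pixels, mask, H, elastic = NULL) {
  h <- dim(pixels)[1]; w <- dim(pixels)[2]
  xg <- rep(seq_len(w), each = h)   # col
  yg <- rep(seq_len(h), times = w)  # row
  den <- H[3, 1] * xg + H[3, 2] * yg + H[3, 3]
  u <- (H[1, 1] * xg + H[1, 2] * yg + H[1, 3]) / den  # source col
  v <- (H[2, 1] * xg + H[2, 2] * yg + H[2, 3]) / den  # source row
  if (!is.null(elastic)) {
    u <- u + as.vector(elastic$dc)
    v <- v + as.vector(elastic$dr)
  }
  out <- array(0, dim(pixels))
  for (ch in 1:3)
    out[, , ch] <- matrix(bilinear_sample_plane(pixels[, , ch], v, u), h, w)
  m <- NULL
  if (!is.null(mask))
    m <- matrix(as.integer(nearest_sample_plane(mask, v, u) > 0.5), h, w)
  list(pixels = clamp01(out), mask = m)
}
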