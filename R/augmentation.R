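#' Offline augmentation policy
#'
#' The ten-fold offline augmentation used before training: each source image
#' yields `fold` outputs — the original plus `fold - 1` transformed copies.
#' Per copy, a projective skew angle is drawn uniformly in `skew_range_deg`,
#' a shear angle uniformly in `[0, shear_max_deg]`, an elastic grid
#' distortion of the given intensity (control-point displacement magnitude in
#' pixels at the 224-pixel reference resolution) is applied, the image is
#' left-right flipped with probability `flip_probability`, and independent
#' uniform shifts bounded by (`hue_shift`, `saturation_shift`,
#' `brightness_shift`) are applied in HSV space. Masks undergo the same
#' geometric (not photometric) transforms.
#'
#' @param skew_range_deg Length-2 skew angle range in degrees.
#' @param shear_max_deg Maximum shear angle in degrees.
#' @param distortion_intensity Elastic distortion intensity coefficient.
#' @param flip_probability Probability of a horizontal flip.
#' @param hue_shift,saturation_shift,brightness_shift HSV shift bounds.
#' @param fold Total outputs per input (original included).
#' @param seed Integer seed.
#' @return An object of class `augmentation_policy`.
#' @export
augmentation_policy <- function(skew_range_deg = c(-45, 45), shear_max_deg = 10,
                                distortion_intensity = 5, flip_probability = 0.5,
                                hue_shift = 0.1, saturation_shift = 0.3,
                                brightness_shift = 0.2, fold = 10, seed = 1) {
  if (!is_count(fold, 1)) abort_config("fold must be a positive integer")
  if (flip_probability < 0 || flip_probability > 1)
    abort_config("flip_probability must be in [0,1]")
  if (any(c(shear_max_deg, distortion_intensity, hue_shift, saturation_shift,
            brightness_shift) < 0))
    abort_config("shift magnitudes must be nonnegative")
  if (length(skew_range_deg) != 2 || skew_range_deg[1] > skew_range_deg[2])
    abort_config("skew_range_deg must be an ordered pair")
  structure(list(skew_range_deg = as.numeric(skew_range_deg),
                 shear_max_deg = shear_max_deg,
                 distortion_intensity = distortion_intensity,
                 flip_probability = flip_probability,
                 hue_shift = hue_shift, saturation_shift = saturation_shift,
                 brightness_shift = brightness_shift,
                 fold = as.integer(fold), seed = as.integer(seed)),
            class = "augmentation_policy")
}

rgb_to_hsv_planes <- function(pixels) {
  n <- prod(dim(pixels)[1:2])
  m <- grDevices::rgb2hsv(r = as.vector(pixels[, , 1]),
                          g = as.vector(pixels[, , 2]),
                          b = as.vector(pixels[, , 3]), maxColorValue = 1)
  list(h = m[1, ], s = m[2, ], v = m[3, ])
}

hsv_to_rgb_planes <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6) %% 6; f <- h6 - floor(h6)
  p <- v * (1 - s); q <- v * (1 - f * s); tt <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, tt, v)))))
  g <- ifelse(i == 0, tt, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, tt,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  list(r = r, g = g, b = b)
}

#' Random HSV colour jitter
#'
#' Applies independent uniform shifts in HSV space: hue wraps modulo 1,
#' saturation and value are clipped to `[0, 1]`. With all bounds zero the
#' operation is the identity up to the RGB-HSV round trip (tolerance 1e-6).
#'
#' @param pixels `h x w x 3` array in `[0, 1]`.
#' @param hue_shift,sat_shift,bright_shift Uniform shift bounds.
#' @param seed Optional integer seed; if `NULL` the current RNG stream is used.
#' @return The jittered array, values in `[0, 1]`.
#' @export
hsv_jitter <- function(pixels, hue_shift = 0.1, sat_shift = 0.3,
                       bright_shift = 0.2, seed = NULL) {
  if (!is.null(seed)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  d <- runif(3, -1, 1) * c(hue_shift, sat_shift, bright_shift)
  hsv <- rgb_to_hsv_planes(pixels)
  out <- hsv_to_rgb_planes((hsv$h + d[1]) %% 1,
                           clamp01(hsv$s + d[2]),
                           clamp01(hsv$v + d[3]))
  res <- array(0, dim(pixels))
  res[, , 1] <- out$r; res[, , 2] <- out$g; res[, , 3] <- out$b
  clamp01(res)
}

augment_one <- function(sample, policy) {
  h <- dim(sample$pixels)[1]; w <- dim(sample$pixels)[2]
  H <- identity_homography()
  skew <- runif(1, policy$skew_range_deg[1], policy$skew_range_deg[2])
  if (skew != 0) H <- H %*% skew_homography(skew, h, w)
  shear <- runif(1, 0, policy$shear_max_deg)
  if (shear != 0) H <- H %*% shear_homography(shear, h, w)
  do_flip <- runif(1) < policy$flip_probability
  if (do_flip) H <- flip_homography(h, w) %*% H
  el <- if (policy$distortion_intensity > 0)
    elastic_field(h, w, policy$distortion_intensity) else NULL
  wp <- warp_sample(sample$pixels, sample$lesion_mask, H, el)
  px <- hsv_jitter(wp$pixels, policy$hue_shift, policy$saturation_shift,
                   policy$brightness_shift, seed = NULL)
  image_sample(sample$image_id, px, sample$label, wp$mask, sample$split)
}

#' Offline dataset augmentation
#'
#' Expands every input sample into `policy$fold` outputs: the original plus
#' `fold - 1` independently transformed copies (see
#' [augmentation_policy()]). Labels and split tags are preserved; output ids
#' get an `_aNN` suffix.
#'
#' @param samples Nonempty list of [image_sample()].
#' @param policy An [augmentation_policy()].
#' @return List of `fold * length(samples)` samples.
#' @export
augment_dataset <- function(samples, policy) {
  stopifnot(inherits(policy, "augmentation_policy"))
  if (length(samples) == 0) abort_config("samples must be nonempty")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(policy$seed, "augment"))
  out <- vector("list", policy$fold * length(samples))
  n <- 0L
  for (s in samples) {
    n <- n + 1L
    out[[n]] <- s
    if (policy$fold > 1) for (j in seq_len(policy$fold - 1)) {
      a <- augment_one(s, policy)
      a$image_id <- sprintf("%s_a%02d", s$image_id, j)
      n <- n + 1L
      out[[n]] <- a
    }
  }
  out
}
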