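#' Feature-extractor configuration
#'
#' The built-in `"tiny"` backbone is four convolution blocks (channels 16,
#' 32, 64, 64, ReLU): two 3x3 stride-2 blocks, a 3x3 stride-1 block and a
#' 1x1 block, giving a latent grid of side/4 with a ~15-pixel receptive
#' field; it trains on CPU in minutes at image side 64. Two add-on 1x1 convolutions follow the backbone: the first maps
#' the backbone channels to `addon_channels` with ReLU, the second keeps the
#' depth and applies a sigmoid, so every latent value lies strictly inside
#' (0, 1). The named large backbones (`vgg19`, `resnet152`, `densenet161`)
#' are adapter slots behind the same contract: they require externally
#' supplied weights registered via `register_backbone()` and are not bundled.
#'
#' @param backbone_name One of `"tiny"`, `"vgg19"`, `"resnet152"`,
#'   `"densenet161"`, or a name registered with [register_backbone()].
#' @param addon_channels Latent depth D of the feature volume.
#' @param pretrained Whether adapter backbones should load supplied weights.
#' @param input_side Input image side in pixels.
#' @return An object of class `backbone_config`.
#' @export
backbone_config <- function(backbone_name = "tiny", addon_channels = 32,
                            pretrained = FALSE, input_side = 64) {
  if (!is_count(addon_channels, 1)) abort_config("addon_channels must be >= 1")
  if (!is_count(input_side, 16)) abort_config("input_side must be an integer >= 16")
  structure(list(backbone_name = backbone_name,
                 addon_channels = as.integer(addon_channels),
                 pretrained = isTRUE(pretrained),
                 input_side = as.integer(input_side)),
            class = "backbone_config")
}

.backbone_registry <- new.env(parent = emptyenv())

#' Register a custom backbone adapter
#'
#' An adapter supplies `init(config)` returning parameters and
#' `forward(x, params, keep_cache)` / `backward(dZ, cache, params)` functions
#' matching the tiny backbone's contract. Used to plug externally trained
#' feature extractors behind the same interface; nothing in the package
#' depends on one being present.
#'
#' @param name Backbone name.
#' @param adapter List with elements `init`, `forward`, `backward`.
#' @export
register_backbone <- function(name, adapter) {
  stopifnot(is.list(adapter), all(c("init", "forward") %in% names(adapter)))
  .backbone_registry[[name]] <- adapter
  invisible(name)
}

# Four conv blocks; the last two keep spatial resolution (stride 1, and a
# 1x1 final kernel) so the latent grid is side/4 with a ~15-pixel receptive
# field — the scale of a single lesion, which is what lets activation maps
# peak on lesions instead of diffusing over the leaf.
tiny_channels <- c(16L, 32L, 64L, 64L)
tiny_strides <- c(2L, 2L, 1L, 1L)
tiny_kernels <- c(3L, 3L, 3L, 1L)

tiny_geoms <- function(side) {
  cin <- c(3L, tiny_channels[-length(tiny_channels)])
  h <- side
  gs <- vector("list", length(tiny_channels))
  for (l in seq_along(tiny_channels)) {
    gs[[l]] <- conv_geometry(h, h, cin[l], k = tiny_kernels[l],
                             stride = tiny_strides[l],
                             pad = (tiny_kernels[l] - 1L) %/% 2L)
    h <- gs[[l]]$ho
  }
  gs
}

#' Initialize feature-extractor parameters
#'
#' He-normal initialization for convolution weights, zero biases; the add-on
#' and contrastive-projection weights are included. Draws from the current
#' RNG stream, so wrap in `set.seed()` for reproducibility.
#'
#' @param config A [backbone_config()].
#' @param embed_dim Dimension E of the contrastive projection head.
#' @return Parameter list (`conv`, `addon1`, `addon2`, `proj`).
#' @export
init_feature_params <- function(config, embed_dim = 64) {
  if (config$backbone_name != "tiny") {
    ad <- .backbone_registry[[config$backbone_name]]
    if (is.null(ad))
      abort_config(paste0("backbone '%s' requires externally supplied weights; ",
                          "register an adapter with register_backbone()"),
                   config$backbone_name)
    return(ad$init(config))
  }
  cin <- c(3L, tiny_channels[-length(tiny_channels)])
  conv <- Map(function(ci, co, k) list(W = he_init(k * k * ci, co), b = numeric(co)),
              cin, tiny_channels, as.integer(tiny_kernels))
  D <- config$addon_channels
  cb <- tail(tiny_channels, 1)
  list(conv = conv,
       addon1 = list(W = he_init(cb, D), b = numeric(D)),
       addon2 = list(W = he_init(D, D), b = numeric(D)),
       proj = list(W = he_init(D, embed_dim)))
}

# Forward pass to the latent volume. Returns list(Z = npos x D matrix in
# (0,1), H, W, cache). cache is NULL unless keep_cache.
forward_features <- function(x, params, config, keep_cache = FALSE) {
  if (config$backbone_name != "tiny") {
    ad <- .backbone_registry[[config$backbone_name]]
    if (is.null(ad)) abort_config("backbone '%s' is not registered", config$backbone_name)
    return(ad$forward(x, params, keep_cache))
  }
  side <- dim(x)[1]
  gs <- tiny_geoms(side)
  caches <- if (keep_cache) vector("list", length(gs)) else NULL
  # standardize [0,1] pixels to zero mean, unit-order scale before conv1
  a <- (x - 0.5) * 4
  for (l in seq_along(gs)) {
    f <- conv_forward(a, params$conv[[l]]$W, params$conv[[l]]$b, gs[[l]])
    Y <- pmax(f$Y, 0)
    if (keep_cache) caches[[l]] <- list(X = f$X, mask = f$Y > 0)
    a <- array(Y, c(gs[[l]]$ho, gs[[l]]$wo, ncol(Y)))
  }
  gl <- gs[[length(gs)]]
  C4 <- matrix(a, gl$ho * gl$wo, dim(a)[3])
  A1 <- C4 %*% params$addon1$W + rep(params$addon1$b, each = nrow(C4))
  A1r <- pmax(A1, 0)
  A2 <- A1r %*% params$addon2$W + rep(params$addon2$b, each = nrow(C4))
  Z <- sigmoid_safe(A2)
  cache <- NULL
  if (keep_cache)
    cache <- list(convs = caches, gs = gs, C4 = C4, A1pos = A1 > 0, A1r = A1r, Z = Z)
  list(Z = Z, H = gl$ho, W = gl$wo, cache = cache)
}

# Backprop dZ (npos x D) through add-ons and conv stack; returns gradients
# with the same structure as the parameter list (proj untouched).
backward_features <- function(dZ, cache, params, config) {
  if (config$backbone_name != "tiny") {
    ad <- .backbone_registry[[config$backbone_name]]
    return(ad$backward(dZ, cache, params))
  }
  Z <- cache$Z
  dA2 <- dZ * Z * (1 - Z)
  gW2 <- crossprod(cache$A1r, dA2); gb2 <- colSums(dA2)
  dA1 <- (dA2 %*% t(params$addon2$W)) * cache$A1pos
  gW1 <- crossprod(cache$C4, dA1); gb1 <- colSums(dA1)
  dC4 <- dA1 %*% t(params$addon1$W)
  gs <- cache$gs
  gconv <- vector("list", length(gs))
  dY <- dC4
  for (l in rev(seq_along(gs))) {
    dY <- dY * cache$convs[[l]]$mask
    bk <- conv_backward(dY, cache$convs[[l]]$X, params$conv[[l]]$W, gs[[l]],
                        need_dx = l > 1)
    gconv[[l]] <- list(W = bk$dW, b = bk$db)
    if (l > 1) {
      gprev <- gs[[l - 1]]
      dY <- matrix(bk$dx, gprev$ho * gprev$wo, dim(bk$dx)[3])
    }
  }
  list(conv = gconv,
       addon1 = list(W = gW1, b = gb1),
       addon2 = list(W = gW2, b = gb2))
}

#' Extract the latent feature volume of an image
#'
#' Runs the convolutional stack plus the two 1x1 add-on layers (ReLU then
#' sigmoid) and returns the H x W x D feature volume with every value
#' strictly inside (0, 1).
#'
#' @param image An [image_sample()] already resized to `config$input_side`.
#' @param config A [backbone_config()].
#' @param params Parameters from [init_feature_params()] or a trained model.
#' @return A `feature_volume`: list with `values` (H x W x D array),
#'   `source_image_id`, `spatial_scale` (input pixels per latent cell) and
#'   `input_side`.
#' @export
extract_features <- function(image, config, params) {
  if (!all(dim(image$pixels)[1:2] == config$input_side))
    abort_config("image must be resized to the configured input side %d",
                 config$input_side)
  f <- forward_features(image$pixels, params, config)
  feature_volume(array(f$Z, c(f$H, f$W, ncol(f$Z))), image$image_id,
                 config$input_side)
}

feature_volume <- function(values, source_image_id, input_side) {
  H <- dim(values)[1]
  structure(list(values = values, source_image_id = source_image_id,
                 spatial_scale = input_side / H, input_side = input_side),
            class = "feature_volume")
}

vol_matrix <- function(volume) {
  d <- dim(volume$values)
  matrix(volume$values, d[1] * d[2], d[3])
}

#' Map a latent cell to its aligned input-pixel rectangle
#'
#' Cells are 1-based `(row, col)` in the H x W latent grid; the returned box
#' uses 0-based half-open pixel coordinates `[top, bottom) x [left, right)`,
#' clipped to the image bounds.
#'
#' @param row,col Latent cell indices (1-based).
#' @param volume A `feature_volume`.
#' @return A `patch_box` list with fields `top`, `left`, `bottom`, `right`.
#' @export
latent_to_pixel_box <- function(row, col, volume) {
  d <- dim(volume$values)
  if (row < 1 || row > d[1] || col < 1 || col > d[2])
    stop("latent cell out of range", call. = FALSE)
  sc <- volume$spatial_scale
  side <- volume$input_side
  patch_box(top = min(floor((row - 1) * sc), side - 1),
            left = min(floor((col - 1) * sc), side - 1),
            bottom = min(ceiling(row * sc), side),
            right = min(ceiling(col * sc), side))
}

patch_box <- function(top, left, bottom, right) {
  stopifnot(top < bottom, left < right, top >= 0, left >= 0)
  structure(list(top = as.integer(top), left = as.integer(left),
                 bottom = as.integer(bottom), right = as.integer(right)),
            class = "patch_box")
}
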