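# Shared fixtures. Everything is generated in code; heavier artifacts
# (trained models) are built lazily once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

unit_vec <- function(x) x / sqrt(sum(x^2))

rand_unit_rows <- function(n, e) t(apply(matrix(rnorm(n * e), n, e), 1, unit_vec))

make_volume <- function(values, id = "vol", input_side = 64) {
  leafproto:::feature_volume(values, id, input_side)
}

random_volume <- function(H = 3, W = 3, D = 5, id = "vol") {
  make_volume(array(runif(H * W * D), c(H, W, D)), id)
}

# Brute-force similarity-field oracle: explicit loops over prototypes,
# cells and depth.
oracle_fields <- function(volume, bank) {
  vals <- volume$values
  H <- dim(vals)[1]; W <- dim(vals)[2]; D <- dim(vals)[3]
  lapply(seq_len(nrow(bank$vectors)), function(j) {
    map <- matrix(0, H, W)
    for (r in seq_len(H)) for (cc in seq_len(W)) {
      d2 <- 0
      for (d in seq_len(D)) d2 <- d2 + (vals[r, cc, d] - bank$vectors[j, d])^2
      map[r, cc] <- log((d2 + 1) / (d2 + bank$epsilon))
    }
    map
  })
}

# Brute-force cluster/separation oracle with explicit loops.
oracle_clustersep <- function(volumes, labels, bank, own = TRUE) {
  total <- 0
  for (i in seq_along(volumes)) {
    vals <- volumes[[i]]$values
    H <- dim(vals)[1]; W <- dim(vals)[2]
    best <- Inf
    for (j in seq_len(nrow(bank$vectors))) {
      match_own <- bank$class_of[j] == labels[i]
      if (own != match_own) next
      for (r in seq_len(H)) for (cc in seq_len(W)) {
        d2 <- sum((vals[r, cc, ] - bank$vectors[j, ])^2)
        if (d2 < best) best <- d2
      }
    }
    total <- total + best
  }
  if (own) total / length(volumes) else -total / length(volumes)
}

central_diff <- function(f, x, h = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- x[i] + h; xm[i] <- x[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

rel_err <- function(a, b) max(abs(a - b)) / max(max(abs(a)), max(abs(b)), 1e-8)

# A micro dataset + trained model for structural tests: 2 classes at side
# 32, a few epochs. Cached for the whole run.
micro_dataset <- function() {
  if (is.null(.fixture_cache$micro_ds)) {
    spec <- synthetic_spec(n_classes = 2, per_class_count = 8, image_size = 32,
                           lesion_count_mean = 2, lesion_size_range = c(3, 5),
                           seed = 11)
    ds <- generate_dataset(spec)
    .fixture_cache$micro_ds <- apply_split(ds, split_dataset(ds, 0.75, seed = 11))
  }
  .fixture_cache$micro_ds
}

micro_fit <- function() {
  if (is.null(.fixture_cache$micro_fit)) {
    cfg <- desk_train_config(seed = 5, epochs = 3, batch_size = 8,
                             input_side = 32, push_every = 3,
                             head_tune_epochs = 1)
    .fixture_cache$micro_fit <- train_model(micro_dataset(), cfg,
                                            backbone_config(input_side = 32,
                                                            addon_channels = 16),
                                            per_class = 3, embed_dim = 16)
  }
  .fixture_cache$micro_fit
}

# The study-conditions training run shared by the end-to-end tests:
# 3 classes, 50 train + 20 test per class at side 64, three-fold offline
# augmentation of the training split, 30 epochs.
study_dataset <- function(seed = 1) {
  spec <- synthetic_spec(n_classes = 3, per_class_count = 70, image_size = 64,
                         seed = leafproto:::derive_seed(seed, "generate"))
  ds <- generate_dataset(spec)
  apply_split(ds, split_dataset(ds, 5 / 7, seed = seed))
}

study_train_samples <- function(ds, seed = 1) {
  tr <- ds[vapply(ds, function(s) s$split == "train", TRUE)]
  pol <- augmentation_policy(fold = 3,
                             seed = leafproto:::derive_seed(seed, "augment"))
  augment_dataset(tr, pol)
}

study_fit <- function() {
  if (is.null(.fixture_cache$study_fit)) {
    ds <- study_dataset(seed = 1)
    tra <- study_train_samples(ds, seed = 1)
    te <- ds[vapply(ds, function(s) s$split == "test", TRUE)]
    .fixture_cache$study_fit <- list(
      fit = train_model(c(tra, te), desk_train_config(seed = 1)),
      samples = ds, train_aug = tra)
  }
  .fixture_cache$study_fit
}
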