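test_that("contrastive embeddings are unit-norm, deterministic and scale invariant", {
  set.seed(51)
  proj <- list(W = matrix(rnorm(5 * 4), 5, 4))
  v <- random_volume(3, 3, 5)
  e1 <- embed_for_contrast(v, proj)
  expect_equal(sqrt(sum(e1^2)), 1, tolerance = 1e-6)
  expect_identical(embed_for_contrast(v, proj), e1)
  # scaling the projection rescales the pre-normalization vector only
  expect_equal(embed_for_contrast(v, list(W = proj$W * 3)), e1, tolerance = 1e-9)
})

test_that("momentum update interpolates parameters element-wise", {
  key <- list(a = matrix(0, 2, 2), b = list(c = rep(0, 3)))
  query <- list(a = matrix(2, 2, 2), b = list(c = rep(2, 3)))
  st <- contrastive_state(key, queue_size = 4, momentum = 1, embed_dim = 2)
  expect_identical(momentum_update(st, query)$key_params, key)
  st$momentum <- 0
  expect_equal(momentum_update(st, query)$key_params, query)
  st$momentum <- 0.5
  expect_equal(momentum_update(st, query)$key_params$a, matrix(1, 2, 2))
  st_bad <- st; st_bad$key_params$a <- matrix(0, 3, 2)
  expect_error(momentum_update(st_bad, query), "shape")
})

test_that("queue is FIFO with conserved length", {
  st <- contrastive_state(list(), queue_size = 5, embed_dim = 3)
  total <- 0
  set.seed(52)
  first_batch <- rand_unit_rows(2, 3)
  st$queue_emb <- first_batch; st$queue_lab <- c(0L, 1L)
  total <- 2
  for (i in 1:4) {
    ke <- rand_unit_rows(2, 3)
    res <- supervised_contrastive_step(rand_unit_rows(2, 3), c(0L, 1L), ke, st)
    st <- res$state
    total <- total + 2
    expect_equal(nrow(st$queue_emb), min(5, total))
    expect_length(st$queue_lab, min(5, total))
  }
  # newest entries are at the tail; oldest were dequeued
  expect_equal(unname(st$queue_emb[nrow(st$queue_emb), ]), unname(ke[2, ]))
})

test_that("supervised step reduces to the single-positive contrastive loss", {
  set.seed(53)
  E <- 6
  q <- unit_vec(rnorm(E))
  pos <- unit_vec(rnorm(E))
  negs <- rand_unit_rows(3, E)
  st <- contrastive_state(list(), queue_size = 10, tau = 0.3, embed_dim = E)
  st$queue_emb <- rbind(pos, negs)
  st$queue_lab <- c(0L, 1L, 1L, 2L)
  res <- supervised_contrastive_step(matrix(q, 1), 0L, matrix(q, 1), st)
  expect_equal(res$loss, contrastive_loss(q, pos, negs, tau = 0.3),
               tolerance = 1e-9)
  expect_equal(res$skipped, 0)
  # two positives with equal logits equal the single-positive value
  st2 <- contrastive_state(list(), queue_size = 10, tau = 0.3, embed_dim = E)
  st2$queue_emb <- rbind(pos, pos, negs)
  st2$queue_lab <- c(0L, 0L, 1L, 1L, 2L)
  res2 <- supervised_contrastive_step(matrix(q, 1), 0L, matrix(q, 1), st2)
  expect_equal(res2$loss, contrastive_loss(q, pos, negs, tau = 0.3),
               tolerance = 1e-9)
})

test_that("queries without negatives are skipped; empty queue errors", {
  set.seed(54)
  E <- 4
  st <- contrastive_state(list(), queue_size = 10, embed_dim = E)
  st$queue_emb <- rand_unit_rows(3, E)
  st$queue_lab <- c(0L, 0L, 0L)  # all same class: no negatives for class 0
  qs <- rand_unit_rows(2, E)
  res <- supervised_contrastive_step(qs, c(0L, 0L), qs, st)
  expect_equal(res$loss, 0)
  expect_equal(res$skipped, 2)
  expect_true(all(res$grad == 0))
  st0 <- contrastive_state(list(), queue_size = 10, embed_dim = E)
  expect_error(supervised_contrastive_step(qs, c(0L, 0L), qs, st0), "empty queue")
})

test_that("training runs, logs every epoch, and pushes fill provenance", {
  fit <- micro_fit()
  expect_s3_class(fit$model, "leafproto_model")
  expect_equal(nrow(fit$log$epochs), 3)
  expect_true(all(is.finite(fit$log$epochs$ce)))
  expect_true(all(fit$log$epochs$separation <= 0))
  expect_gte(length(fit$log$pushes), 1)
  # after the final push every prototype equals a training patch of its class
  bank <- fit$model$bank
  expect_false(is.null(bank$provenance))
  tr <- micro_dataset()
  tr <- tr[vapply(tr, function(s) s$split == "train", TRUE)]
  vols <- lapply(leafproto:::resize_all(tr, 32), extract_features,
                 config = fit$model$backbone, params = fit$model$params)
  labels <- leafproto:::sample_labels(tr)
  for (j in seq_len(nrow(bank$vectors))) {
    patches <- do.call(rbind, lapply(vols[labels == bank$class_of[j]],
                                     leafproto:::vol_matrix))
    expect_lt(min(leafproto:::patch_sqdist(patches,
                                           bank$vectors[j, , drop = FALSE])), 1e-6)
  }
})

test_that("a cross-entropy-only objective trains and stays finite", {
  ds <- micro_dataset()
  cfg <- desk_train_config(seed = 3, epochs = 1, batch_size = 8, input_side = 32,
                           weights = loss_weights(0, 0, 0), push_every = 1,
                           head_tune_epochs = 0)
  fit <- train_model(ds, cfg, backbone_config(input_side = 32, addon_channels = 8),
                     per_class = 2, embed_dim = 8)
  expect_true(all(is.finite(fit$log$epochs$ce)))
  expect_equal(fit$log$epochs$contrastive, 0)
})

test_that("head fine-tuning leaves extractor and prototypes bit-identical", {
  fit <- micro_fit()
  tr <- micro_dataset()
  tr <- leafproto:::resize_all(tr[vapply(tr, function(s) s$split == "train", TRUE)], 32)
  cfg <- desk_train_config(seed = 5, epochs = 3, batch_size = 8, input_side = 32,
                           push_every = 3, head_tune_epochs = 1)
  tuned <- leafproto:::head_tune(fit$model, tr, cfg)
  expect_identical(tuned$model$params, fit$model$params)
  expect_identical(tuned$model$bank$vectors, fit$model$bank$vectors)
})

test_that("training is reproducible: identical seeds give identical logs", {
  ds <- micro_dataset()
  cfg <- desk_train_config(seed = 19, epochs = 2, batch_size = 8, input_side = 32,
                           push_every = 2, head_tune_epochs = 1)
  bb <- backbone_config(input_side = 32, addon_channels = 8)
  f1 <- train_model(ds, cfg, bb, per_class = 2, embed_dim = 8)
  f2 <- train_model(ds, cfg, bb, per_class = 2, embed_dim = 8)
  expect_identical(f1$log$epochs, f2$log$epochs)
  expect_identical(f1$model$params, f2$model$params)
  expect_identical(f1$model$head, f2$model$head)
})

test_that("model bundles round-trip through save and load", {
  fit <- micro_fit()
  dir <- withr::local_tempdir()
  save_model(fit$model, dir)
  expect_true(file.exists(file.path(dir, "checkpoint.rds")))
  expect_true(file.exists(file.path(dir, "config.yaml")))
  expect_true(file.exists(file.path(dir, "prototypes.json")))
  back <- load_model(dir)
  expect_identical(back$params, fit$model$params)
  expect_identical(back$bank$vectors, fit$model$bank$vectors)
})
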