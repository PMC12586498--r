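#' Training configuration
#'
#' Defaults reproduce the reference hyper-parameter table (batch 80, 50
#' epochs, SGD with learning rate 1e-4, input 224); `desk_train_config()`
#' gives a smaller CPU profile. `push_every` controls the prototype
#' projection schedule: a push every that many epochs plus a final push,
#' followed by `head_tune_epochs` of classifier-head-only fine-tuning with
#' the extractor and prototypes frozen.
#'
#' @param batch_size Mini-batch size.
#' @param epochs SGD epochs.
#' @param learning_rate SGD step size (plain SGD, no momentum).
#' @param input_side Input image side in pixels.
#' @param weights A [loss_weights()].
#' @param queue_size,momentum,tau Contrastive dictionary settings.
#' @param push_every Prototype projection period in epochs.
#' @param head_tune_epochs Head-only fine-tuning epochs after the last push.
#' @param clip_norm Per-tensor gradient L2-norm clip applied to the
#'   accumulated mini-batch gradients; keeps plain SGD stable.
#' @param kernel_grad_cap Cap on the magnitude of the similarity kernel's
#'   derivative in the cross-entropy path. The derivative approaches
#'   `1/epsilon` as a patch coincides with a prototype (always the case right
#'   after a push), so an uncapped step can be four orders of magnitude too
#'   large for SGD; the cap is the per-term analog of gradient clipping.
#' @param select_best Keep the epoch snapshot with the highest training
#'   accuracy (ties to the later epoch) as the model that receives the final
#'   push and head fine-tuning; selection never looks at the test split.
#' @param restarts Number of independent training restarts (deterministic
#'   derived seeds); the run with the highest final training accuracy is
#'   kept, ties broken by the lower final training cross-entropy. Like
#'   `select_best`, restart selection sees only the train split.
#' @param seed Integer seed; training is fully deterministic given it.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 80, epochs = 50, learning_rate = 1e-4,
                         input_side = 224, weights = loss_weights(),
                         queue_size = 1024, momentum = 0.999, tau = 0.07,
                         push_every = 10, head_tune_epochs = 5,
                         clip_norm = 5, kernel_grad_cap = 100,
                         select_best = TRUE, restarts = 1, seed = 1) {
  if (!is_count(batch_size, 1) || !is_count(epochs, 1))
    abort_config("batch_size and epochs must be positive integers")
  if (learning_rate <= 0) abort_config("learning_rate must be positive")
  if (!is_count(push_every, 1)) abort_config("push_every must be a positive integer")
  if (!is_count(head_tune_epochs, 0)) abort_config("head_tune_epochs must be >= 0")
  structure(list(batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 learning_rate = learning_rate, optimizer = "sgd",
                 input_side = as.integer(input_side), weights = weights,
                 queue_size = as.integer(queue_size), momentum = momentum,
                 tau = tau, push_every = as.integer(push_every),
                 head_tune_epochs = as.integer(head_tune_epochs),
                 clip_norm = clip_norm, kernel_grad_cap = kernel_grad_cap,
                 select_best = isTRUE(select_best),
                 restarts = as.integer(restarts),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Desk-scale training profile
#'
#' CPU-friendly defaults for training the tiny backbone from scratch at
#' image side 64: batch 16, 30 epochs, learning rate 0.02 (the 1e-4 default
#' targets pretrained backbones; small batches give plain SGD enough steps
#' at this data scale), a contrastive weight large enough to drive
#' representation learning (`lambda3 = 3`), a key-encoder momentum of 0.5
#' so the dictionary tracks the live encoder over a short run, and two
#' train-side-selected restarts.
#'
#' @param ... Overrides passed to [train_config()].
#' @export
desk_train_config <- function(...) {
  args <- list(batch_size = 16, epochs = 30, learning_rate = 0.02,
               input_side = 64, push_every = 10, head_tune_epochs = 5,
               momentum = 0.5, tau = 0.2, restarts = 2,
               weights = loss_weights(lambda3 = 3))
  override <- list(...)
  args[names(override)] <- override
  do.call(train_config, args)
}

# Rescale a gradient tensor so its L2 norm is at most max_norm; recurses
# through parameter lists tensor-by-tensor.
clip_grad <- function(g, max_norm) {
  if (is.null(max_norm) || !is.finite(max_norm)) return(g)
  if (is.list(g)) return(lapply(g, clip_grad, max_norm = max_norm))
  n <- sqrt(sum(g^2))
  if (n > max_norm) g * (max_norm / n) else g
}

zero_like <- function(p) {
  if (is.list(p)) return(lapply(p, zero_like))
  if (is.numeric(p)) return(p * 0)
  p
}
axpy_params <- function(acc, g, a = 1) {
  if (is.list(acc)) return(Map(axpy_params, acc, g, MoreArgs = list(a = a)))
  if (is.numeric(acc)) return(acc + a * g)
  acc
}

resize_all <- function(samples, side) lapply(samples, resize_sample, side = side)

accuracy_of <- function(samples, model) {
  preds <- vapply(samples, function(s)
    predict_volume(extract_features(s, model$backbone, model$params),
                   model$bank, model$head)$predicted_class, 0L)
  mean(preds == sample_labels(samples))
}

push_prototypes <- function(model, train_samples) {
  vols <- lapply(train_samples, extract_features, config = model$backbone,
                 params = model$params)
  model$bank <- project_prototypes(model$bank, vols, sample_labels(train_samples))
  model
}

head_tune <- function(model, train_samples, config) {
  # Extractor and prototypes are frozen after the final push, so every
  # image's similarity vector is constant: cache it once and fine-tune the
  # head as the convex problem it is — ridge-stabilized multinomial
  # cross-entropy minimized by BFGS, warm-started from the current head.
  # head_tune_epochs scales the iteration budget.
  smat <- t(vapply(train_samples, function(s)
    predict_volume(extract_features(s, model$backbone, model$params),
                   model$bank, model$head)$similarity_vector,
    numeric(nrow(model$bank$vectors))))
  y <- sample_labels(train_samples)
  C <- model$n_classes
  m <- ncol(smat)
  n <- nrow(smat)
  ridge <- 1e-4
  unpack <- function(th) list(W = matrix(th[seq_len(m * C)], m, C),
                              b = th[m * C + seq_len(C)])
  obj <- function(th) {
    hp <- unpack(th)
    L <- smat %*% hp$W + rep(hp$b, each = n)
    L <- L - apply(L, 1, max)
    p <- exp(L); p <- p / rowSums(p)
    -mean(log(pmax(p[cbind(seq_len(n), y + 1L)], 1e-12))) +
      ridge * sum(hp$W^2) / 2
  }
  grad <- function(th) {
    hp <- unpack(th)
    L <- smat %*% hp$W + rep(hp$b, each = n)
    L <- L - apply(L, 1, max)
    p <- exp(L); p <- p / rowSums(p)
    p[cbind(seq_len(n), y + 1L)] <- p[cbind(seq_len(n), y + 1L)] - 1
    p <- p / n
    c(as.vector(crossprod(smat, p) + ridge * hp$W), colSums(p))
  }
  th0 <- c(as.vector(model$head$weight), model$head$bias)
  fit <- stats::optim(th0, obj, grad, method = "BFGS",
                      control = list(maxit = 40L * config$head_tune_epochs,
                                     reltol = 1e-10))
  hp <- unpack(fit$par)
  model$head$weight <- hp$W
  model$head$bias <- hp$b
  list(model = model,
       log = data.frame(ce_start = obj(th0), ce_end = fit$value,
                        iterations = fit$counts[["function"]]))
}

#' Train a prototypical-part classifier
#'
#' Mini-batch SGD on the composite objective (cross-entropy + cluster +
#' separation + supervised contrastive), with a momentum key dictionary for
#' the contrastive branch, prototype projection every `push_every` epochs
#' plus a final push, and optional head-only fine-tuning afterwards. Fully
#' deterministic given `config$seed`.
#'
#' @param samples List of [image_sample()] with `split` set (`"train"` /
#'   `"test"`).
#' @param config A [train_config()].
#' @param backbone A [backbone_config()]; its `input_side` should match the
#'   config.
#' @param per_class Prototypes per class.
#' @param epsilon Similarity-kernel floor.
#' @param embed_dim Contrastive embedding dimension E.
#' @return List with `model` (class `leafproto_model`) and `log` (class
#'   `train_log`: per-epoch accuracies and loss breakdown).
#' @export
train_model <- function(samples, config = train_config(),
                        backbone = backbone_config(input_side = config$input_side),
                        per_class = 10, epsilon = 1e-4, embed_dim = 64) {
  splits <- vapply(samples, function(s) s$split, "")
  train_samples <- resize_all(samples[splits == "train"], config$input_side)
  test_samples <- resize_all(samples[splits == "test"], config$input_side)
  if (length(train_samples) == 0 || length(test_samples) == 0)
    abort_config("need nonempty train and test splits")
  C <- length(unique(sample_labels(samples)))
  if (C < 2) abort_config("need at least two classes")
  base_seed <- derive_seed(config$seed, "train")
  runs <- lapply(seq_len(max(1L, config$restarts %||% 1L)), function(r)
    train_once(train_samples, test_samples, C, config, backbone,
               per_class, epsilon, embed_dim,
               rng_seed = (base_seed + (r - 1L) * 7919L) %% 2147483629))
  # selection is train-side only: best final training accuracy, ties broken
  # by the lower training cross-entropy after head tuning
  accs <- vapply(runs, function(f) f$log$final_train_acc, 0)
  ces <- vapply(runs, function(f)
    if (is.null(f$log$head_tune)) Inf else f$log$head_tune$ce_end, 0)
  best <- order(-accs, ces)[1]
  fit <- runs[[best]]
  fit$log$restart_chosen <- best
  fit$log$restart_train_accs <- accs
  fit
}

train_once <- function(train_samples, test_samples, C, config, backbone,
                       per_class, epsilon, embed_dim, rng_seed) {
  y <- sample_labels(train_samples)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(rng_seed)

  params <- init_feature_params(backbone, embed_dim)
  bank <- prototype_bank(C, backbone$addon_channels, per_class, epsilon)
  head <- classifier_head(bank)
  state <- contrastive_state(params, config$queue_size, config$momentum,
                             config$tau, embed_dim)
  model <- structure(list(backbone = backbone, params = params, bank = bank,
                          head = head, n_classes = C, train_config = config,
                          embed_dim = embed_dim),
                     class = "leafproto_model")
  w <- config$weights
  lr <- config$learning_rate
  ntr <- length(train_samples)
  epoch_rows <- list()
  pushes <- integer(0)
  best_acc <- -Inf
  best_epoch <- NA_integer_
  best_state <- NULL

  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(ntr)
    sums <- c(ce = 0, cluster = 0, separation = 0, contrastive = 0, total = 0)
    nb <- 0
    for (start in seq(1, ntr, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, ntr)]
      N <- length(idx)
      gp <- list(conv = zero_like(model$params$conv),
                 addon1 = zero_like(model$params$addon1),
                 addon2 = zero_like(model$params$addon2))
      gproj <- zero_like(model$params$proj$W)
      gP <- zero_like(model$bank$vectors)
      fwd <- vector("list", N)
      dZs <- vector("list", N)
      embc <- vector("list", N)
      ce_b <- clst_b <- sep_b <- 0
      for (ii in seq_len(N)) {
        s <- train_samples[[idx[ii]]]
        f <- forward_features(s$pixels, model$params, backbone, keep_cache = TRUE)
        fwd[[ii]] <- f
        vol <- feature_volume(array(f$Z, c(f$H, f$W, ncol(f$Z))), s$image_id,
                              config$input_side)
        cg <- ce_head_grad(vol, y[idx[ii]], model$bank, model$head,
                           grad_cap = config$kernel_grad_cap)
        ce_b <- ce_b + cg$loss / N
        dZ <- cg$dZ / N
        gP <- gP + cg$dP / N
        Zm <- f$Z
        own <- which(model$bank$class_of == y[idx[ii]])
        oth <- which(model$bank$class_of != y[idx[ii]])
        ic <- min_dist_info(Zm, model$bank, own)
        is_ <- min_dist_info(Zm, model$bank, oth)
        clst_b <- clst_b + ic$value / N
        sep_b <- sep_b - is_$value / N
        dc <- Zm[ic$patch, ] - model$bank$vectors[ic$proto, ]
        dZ[ic$patch, ] <- dZ[ic$patch, ] + w$lambda1 * 2 * dc / N
        gP[ic$proto, ] <- gP[ic$proto, ] - w$lambda1 * 2 * dc / N
        dsn <- Zm[is_$patch, ] - model$bank$vectors[is_$proto, ]
        dZ[is_$patch, ] <- dZ[is_$patch, ] - w$lambda2 * 2 * dsn / N
        gP[is_$proto, ] <- gP[is_$proto, ] + w$lambda2 * 2 * dsn / N
        dZs[[ii]] <- dZ
        embc[[ii]] <- embed_with_cache(Zm, model$params$proj$W)
      }
      # contrastive branch: queries from the live encoder, keys from the
      # momentum encoder; queue supplies positives/negatives
      ctr_loss <- 0
      if (w$lambda3 != 0) {
        qe <- t(vapply(embc, function(e) e$emb, numeric(embed_dim)))
        ke <- t(vapply(seq_len(N), function(ii) {
          s <- train_samples[[idx[ii]]]
          fk <- forward_features(s$pixels, state$key_params, backbone)
          embed_with_cache(fk$Z, state$key_params$proj$W)$emb
        }, numeric(embed_dim)))
        if (nrow(state$queue_emb) > 0) {
          cs <- supervised_contrastive_step(qe, y[idx], ke, state)
          ctr_loss <- cs$loss
          state <- cs$state
          for (ii in seq_len(N)) {
            if (all(cs$grad[ii, ] == 0)) next
            eb <- embed_backward(w$lambda3 * cs$grad[ii, ], embc[[ii]],
                                 model$params$proj$W, nrow(dZs[[ii]]))
            dZs[[ii]] <- dZs[[ii]] + eb$dZ
            gproj <- gproj + eb$dproj
          }
        } else {
          state$queue_emb <- rbind(state$queue_emb, ke)
          state$queue_lab <- c(state$queue_lab, y[idx])
        }
      }
      for (ii in seq_len(N)) {
        bg <- backward_features(dZs[[ii]], fwd[[ii]]$cache, model$params, backbone)
        gp$conv <- axpy_params(gp$conv, bg$conv)
        gp$addon1 <- axpy_params(gp$addon1, bg$addon1)
        gp$addon2 <- axpy_params(gp$addon2, bg$addon2)
      }
      # joint phase: SGD on the conv stack, projection and prototypes; the
      # head keeps its +1/-0.5 initialization until the fine-tune stage
      cn <- config$clip_norm
      model$params$conv <- axpy_params(model$params$conv, clip_grad(gp$conv, cn), -lr)
      model$params$addon1 <- axpy_params(model$params$addon1, clip_grad(gp$addon1, cn), -lr)
      model$params$addon2 <- axpy_params(model$params$addon2, clip_grad(gp$addon2, cn), -lr)
      model$params$proj$W <- model$params$proj$W - lr * clip_grad(gproj, cn)
      model$bank$vectors <- model$bank$vectors - lr * clip_grad(gP, cn)
      if (w$lambda3 != 0) state <- momentum_update(state, model$params)
      tot <- ce_b + w$lambda1 * clst_b + w$lambda2 * sep_b + w$lambda3 * ctr_loss
      sums <- sums + c(ce_b, clst_b, sep_b, ctr_loss, tot)
      nb <- nb + 1
    }
    if (epoch %% config$push_every == 0 && epoch < config$epochs) {
      model <- push_prototypes(model, train_samples)
      pushes <- c(pushes, epoch)
    }
    tr_acc <- accuracy_of(train_samples, model)
    epoch_rows[[epoch]] <- data.frame(
      epoch = epoch,
      train_acc = tr_acc,
      test_acc = accuracy_of(test_samples, model),
      ce = sums[["ce"]] / nb, cluster = sums[["cluster"]] / nb,
      separation = sums[["separation"]] / nb,
      contrastive = sums[["contrastive"]] / nb, total = sums[["total"]] / nb)
    if (config$select_best && tr_acc >= best_acc) {
      best_acc <- tr_acc
      best_epoch <- epoch
      best_state <- list(params = model$params, vectors = model$bank$vectors)
    }
  }
  # restore the best training-accuracy snapshot, then the final push
  if (config$select_best && !is.null(best_state)) {
    model$params <- best_state$params
    model$bank$vectors <- best_state$vectors
  }
  model <- push_prototypes(model, train_samples)
  pushes <- c(pushes, config$epochs)
  ht_log <- NULL
  if (config$head_tune_epochs > 0) {
    ht <- head_tune(model, train_samples, config)
    model <- ht$model
    ht_log <- ht$log
  }
  log <- structure(list(epochs = do.call(rbind, epoch_rows), pushes = pushes,
                        head_tune = ht_log, best_epoch = best_epoch,
                        final_train_acc = accuracy_of(train_samples, model),
                        final_test_acc = accuracy_of(test_samples, model)),
                   class = "train_log")
  list(model = model, log = log)
}

#' Save / load a trained model bundle
#'
#' The bundle is written as `checkpoint.rds` with a human-readable
#' `config.yaml` and the prototype provenance as JSON beside it.
#'
#' @param model A `leafproto_model`.
#' @param dir Output directory.
#' @return `save_model` invisibly returns `dir`; `load_model` the model.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, file.path(dir, "checkpoint.rds"))
  yaml::write_yaml(list(backbone_name = model$backbone$backbone_name,
                        addon_channels = model$backbone$addon_channels,
                        pretrained = model$backbone$pretrained,
                        input_side = model$backbone$input_side,
                        n_classes = model$n_classes,
                        per_class = model$bank$per_class,
                        epsilon = model$bank$epsilon),
                   file.path(dir, "config.yaml"))
  if (!is.null(model$bank$provenance)) {
    prov <- lapply(model$bank$provenance, function(p)
      list(prototype_id = p$prototype_id, class = p$class, image_id = p$image_id,
           latent_cell = p$latent_cell, pixel_box = unclass(p$pixel_box)))
    write_json_file(prov, file.path(dir, "prototypes.json"))
  }
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) readRDS(file.path(dir, "checkpoint.rds"))
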