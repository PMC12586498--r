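test_that("cross-entropy reproduces closed forms and hand values", {
  # perfect prediction
  p <- matrix(0, 3, 4); p[cbind(1:3, c(1, 2, 3))] <- 1
  expect_equal(cross_entropy(p, c(0, 1, 2)), 0, tolerance = 1e-9)
  # uniform over C = 5
  expect_equal(cross_entropy(matrix(0.2, 1, 5), 2), log(5), tolerance = 1e-9)
  # N = 2 with true-class probabilities 0.8 and 0.5
  p2 <- rbind(c(0.8, 0.2), c(0.5, 0.5))
  expect_equal(cross_entropy(p2, c(0, 0)), (-log(0.8) - log(0.5)) / 2,
               tolerance = 1e-6)
  expect_error(cross_entropy(p2, c(0, 5)), "range")
})

test_that("contrastive loss reproduces closed forms", {
  e <- 6
  base <- unit_vec(rep(1, e))
  # all K+1 = 8 inner products equal -> log 8
  negs <- matrix(rep(base, 7), 7, byrow = TRUE)
  expect_equal(contrastive_loss(base, base, negs, tau = 0.5), log(8),
               tolerance = 1e-9)
  # saturation: the positive dominates by >= 50 / tau
  q <- unit_vec(c(1, rep(0, e - 1)))
  neg <- unit_vec(c(-1, rep(0, e - 1)))
  expect_lt(contrastive_loss(q, q, matrix(neg, 1), tau = 0.02), 1e-20)
  # q.v+ = 1, one negative with q.v = 0, tau = 1 -> log(1 + exp(-1))
  northo <- unit_vec(c(0, 1, rep(0, e - 2)))
  expect_equal(contrastive_loss(q, q, matrix(northo, 1), tau = 1),
               log(1 + exp(-1)), tolerance = 1e-9)
  expect_error(contrastive_loss(q * 2, q, matrix(northo, 1), 1), "normalized")
  expect_error(contrastive_loss(q * 0, q, matrix(northo, 1), 1), "zero-norm")
})

test_that("cluster and separation losses match hand values", {
  bank <- prototype_bank(2, 2, per_class = 2)
  bank$vectors <- rbind(c(1, 0), c(0, 2),   # class 0
                        c(3, 4), c(5, 5))   # class 1
  z0 <- make_volume(array(c(0, 0), c(1, 1, 2)))
  # own-class prototypes {(1,0),(0,2)}: min(1, 4) = 1
  expect_equal(cluster_loss(list(z0), 0L, bank), 1, tolerance = 1e-9)
  # wrong-class prototypes {(3,4),(5,5)}: -min(25, 50) = -25
  expect_equal(separation_loss(list(z0), 0L, bank), -25, tolerance = 1e-9)
  # batch mean: per-image values 1 and 3 -> 2
  z1 <- make_volume(array(c(1, -sqrt(3)), c(1, 1, 2)))  # min d2 = 3
  expect_equal(cluster_loss(list(z0, z1), c(0L, 0L), bank), 2, tolerance = 1e-9)
  # a patch equal to an own prototype gives zero
  zp <- make_volume(array(c(1, 0), c(1, 1, 2)))
  expect_equal(cluster_loss(list(zp), 0L, bank), 0, tolerance = 1e-12)
  # homogeneity: scaling all coordinates by 2 scales the loss by 4
  bank2 <- bank; bank2$vectors <- bank$vectors * 2
  z2 <- make_volume(z0$values * 2)
  expect_equal(separation_loss(list(z2), 0L, bank2),
               4 * separation_loss(list(z0), 0L, bank), tolerance = 1e-9)
  # a single-class bank cannot define separation
  bank1 <- bank; bank1$class_of <- rep(0L, 4)
  expect_error(separation_loss(list(z0), 0L, bank1), "two classes")
})

test_that("cluster/separation agree with the nested-loop oracle on random instances", {
  set.seed(41)
  for (rep in 1:10) {
    D <- sample(c(2, 4, 8), 1)
    C <- sample(2:3, 1)
    bank <- prototype_bank(C, D, per_class = 2)
    n <- sample(1:3, 1)
    vols <- lapply(seq_len(n), function(i)
      random_volume(sample(2:4, 1), sample(2:4, 1), D))
    labels <- sample(0:(C - 1), n, replace = TRUE)
    expect_equal(cluster_loss(vols, labels, bank),
                 oracle_clustersep(vols, labels, bank, own = TRUE),
                 tolerance = 1e-6)
    expect_equal(separation_loss(vols, labels, bank),
                 oracle_clustersep(vols, labels, bank, own = FALSE),
                 tolerance = 1e-6)
  }
})

test_that("total loss combines terms with the configured weights", {
  w <- loss_weights(0.5, 0.25, 0.1)
  lb <- total_loss(1, 2, -4, 3, w)
  expect_equal(lb$total, 1 + 0.5 * 2 + 0.25 * (-4) + 0.1 * 3, tolerance = 1e-9)
  expect_equal(total_loss(7, 0, 0, 0, loss_weights(0, 0, 0))$total, 7)
  # zero cluster term makes lambda1 irrelevant
  expect_equal(total_loss(1, 0, -1, 2, loss_weights(9, 0.1, 0.2))$total,
               total_loss(1, 0, -1, 2, loss_weights(0.8, 0.1, 0.2))$total)
  expect_error(total_loss(NaN, 0, 0, 0, w), "finite")
})

test_that("loss sign contracts hold on random instances", {
  set.seed(42)
  for (rep in 1:20) {
    C <- sample(2:4, 1); D <- 4
    bank <- prototype_bank(C, D, per_class = 2)
    vols <- lapply(1:2, function(i) random_volume(2, 2, D))
    labels <- sample(0:(C - 1), 2, replace = TRUE)
    probs <- matrix(runif(2 * C), 2, C); probs <- probs / rowSums(probs)
    ce <- cross_entropy(probs, labels)
    cl <- cluster_loss(vols, labels, bank)
    sp <- separation_loss(vols, labels, bank)
    expect_gte(ce, 0)
    expect_gte(cl, 0)
    expect_lte(sp, 0)
    lb <- total_loss(ce, cl, sp, 0.3, loss_weights())
    expect_equal(lb$total, ce + 0.8 * cl + 0.08 * sp + 0.1 * 0.3,
                 tolerance = 1e-6)
  }
})

test_that("analytic gradients match central finite differences", {
  set.seed(43)
  # cross-entropy through the prototype head, w.r.t. prototypes and volume
  bank <- prototype_bank(3, 5, per_class = 2)
  head <- classifier_head(bank)
  vol <- random_volume(3, 3, 5)
  g <- leafproto:::ce_head_grad(vol, 1L, bank, head)
  fd_p <- central_diff(function(v) {
    b <- bank; b$vectors <- matrix(v, nrow(bank$vectors))
    leafproto:::ce_head_grad(vol, 1L, b, head)$loss
  }, as.vector(bank$vectors))
  expect_lt(rel_err(as.vector(g$dP), fd_p), 1e-3)
  fd_z <- central_diff(function(v) {
    vv <- vol; vv$values <- array(v, dim(vol$values))
    leafproto:::ce_head_grad(vv, 1L, bank, head)$loss
  }, as.vector(vol$values))
  expect_lt(rel_err(as.vector(g$dZ), fd_z), 1e-3)

  # cluster and separation, w.r.t. prototypes and volume
  vols <- list(random_volume(2, 2, 5), random_volume(2, 2, 5))
  labels <- c(0L, 2L)
  for (own in c(TRUE, FALSE)) {
    loss_fn <- if (own) cluster_loss else separation_loss
    gc_ <- leafproto:::clustersep_grad(vols, labels, bank, own = own)
    fd_p <- central_diff(function(v) {
      b <- bank; b$vectors <- matrix(v, nrow(bank$vectors))
      loss_fn(vols, labels, b)
    }, as.vector(bank$vectors))
    expect_lt(rel_err(as.vector(gc_$dP), fd_p), 1e-3)
    fd_z <- central_diff(function(v) {
      vv <- vols; vv[[1]]$values <- array(v, dim(vols[[1]]$values))
      loss_fn(vv, labels, bank)
    }, as.vector(vols[[1]]$values))
    expect_lt(rel_err(as.vector(gc_$dZ[[1]]), fd_z), 1e-3)
  }

  # contrastive, w.r.t. query and keys
  q <- unit_vec(rnorm(6)); pos <- unit_vec(rnorm(6))
  negs <- rand_unit_rows(4, 6)
  gi <- leafproto:::infonce_grad(q, pos, negs, 0.2)
  expect_lt(rel_err(gi$dq, central_diff(function(v)
    leafproto:::infonce(v, pos, negs, 0.2), q)), 1e-3)
  expect_lt(rel_err(gi$dpos, central_diff(function(v)
    leafproto:::infonce(q, v, negs, 0.2), pos)), 1e-3)
  expect_lt(rel_err(as.vector(gi$dnegs), central_diff(function(v)
    leafproto:::infonce(q, pos, matrix(v, 4), 0.2), as.vector(negs))), 1e-3)
})
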