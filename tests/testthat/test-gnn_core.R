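test_that("gcn_layer matches the dense propagation oracle", {
  # single isolated node, identity weights: output equals input
  g1 <- build_knn_graph(cbind(c(0, 1), c(0, 0)), 1)  # two-node path
  S1 <- matrix(1)                                     # isolated node operator
  expect_equal(gcn_layer(matrix(c(1, 2), 1, 2), S1, diag(2), c(0, 0), FALSE),
               matrix(c(1, 2), 1, 2), ignore_attr = TRUE)
  # two connected nodes, H = I, W = I: all entries 0.5
  H <- diag(2)
  expect_equal(gcn_layer(H, g1$norm_adjacency, diag(2), c(0, 0), FALSE),
               matrix(0.5, 2, 2), ignore_attr = TRUE)
  # random instances against dense sigma(D^-1/2 A~ D^-1/2 H W + b)
  set.seed(17)
  for (rep in 1:5) {
    A <- random_adjacency(8)
    Hr <- matrix(rnorm(8 * 4), 8, 4)
    W <- matrix(rnorm(4 * 3), 4, 3)
    b <- rnorm(3)
    dense <- dense_norm_adjacency(A) %*% Hr %*% W
    dense <- pmax(sweep(dense, 2, b, "+"), 0)
    expect_equal(gcn_layer(Hr, normalize_adjacency(A), W, b, TRUE), dense,
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  expect_error(gcn_layer(matrix(1, 2, 3), diag(2), matrix(1, 2, 2), c(0, 0)),
               "H columns")
})

test_that("encode composes gcn layers and is permutation-equivariant", {
  set.seed(23)
  coords <- matrix(runif(24), 12, 2)
  g <- build_knn_graph(coords, 3)
  X <- matrix(rnorm(12 * 6), 12, 6)
  cfg <- train_config(hidden_dim = 5, embed_dim = 3, seed = 2)
  params <- init_params(6, cfg)
  Z <- encode(X, g, params)
  manual <- gcn_layer(
    gcn_layer(X, g$norm_adjacency, params$encoder[[1]]$W, params$encoder[[1]]$b, TRUE),
    g$norm_adjacency, params$encoder[[2]]$W, params$encoder[[2]]$b, FALSE)
  expect_equal(Z, manual, tolerance = 1e-12)
  # zero weights: embeddings collapse to broadcast biases
  p0 <- params
  p0$encoder[[1]]$W[] <- 0; p0$encoder[[2]]$W[] <- 0
  p0$encoder[[2]]$b <- c(1, 2, 3)
  expect_equal(encode(X, g, p0), matrix(rep(c(1, 2, 3), each = 12), 12, 3),
               ignore_attr = TRUE)
  # equivariance: permuting spots and graph permutes embeddings identically
  perm <- sample(12)
  g2 <- build_knn_graph(coords[perm, ], 3)
  expect_equal(encode(X[perm, ], g2, params), Z[perm, ], tolerance = 1e-10)
  # decode mirrors the encoder back to gene space
  Xhat <- decode(Z, g, params)
  expect_equal(dim(Xhat), c(12, 6))
  manual_dec <- gcn_layer(
    gcn_layer(Z, g$norm_adjacency, params$decoder[[1]]$W, params$decoder[[1]]$b, TRUE),
    g$norm_adjacency, params$decoder[[2]]$W, params$decoder[[2]]$b, FALSE)
  expect_equal(Xhat, manual_dec, tolerance = 1e-12)
})

test_that("reconstruction loss is the squared Frobenius norm of the error", {
  X <- matrix(rnorm(12), 4, 3)
  expect_equal(reconstruction_loss(X, X), 0)
  Y <- X; Y[2, 3] <- Y[2, 3] + 0.7
  expect_equal(reconstruction_loss(X, Y), 0.49)
  set.seed(3)
  Z <- matrix(rnorm(12), 4, 3)
  expect_equal(reconstruction_loss(X, Z), sum((X - Z)^2), tolerance = 1e-12)
  expect_error(reconstruction_loss(X, matrix(0, 2, 2)), "shape")
})

test_that("corrupt_features permutes rows deterministically, preserving the multiset", {
  set.seed(9)
  X <- matrix(rnorm(30), 10, 3)
  Xc <- corrupt_features(X, 4)
  expect_equal(Xc[order(Xc[, 1]), ], X[order(X[, 1]), ])
  expect_identical(corrupt_features(X, 4), Xc)
  expect_false(identical(Xc, corrupt_features(X, 5)))
  expect_identical(corrupt_features(X[1, , drop = FALSE], 4), X[1, , drop = FALSE])
  # the caller's RNG stream is untouched
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(corrupt_features(X, 4)); after <- runif(1)
  expect_identical(before, after)
})

test_that("readout is the sigmoid of the neighbor mean, excluding the spot", {
  Z <- rbind(c(0, 0), c(2, -2), c(0, 0))
  expect_equal(readout(Z, c(1, 3)), c(0.5, 0.5))
  expect_equal(readout(Z, 2), 1 / (1 + exp(-c(2, -2))))
  expect_equal(readout(rbind(c(2, -2), c(0, 0)), c(1, 2)),
               1 / (1 + exp(-c(1, -1))), tolerance = 1e-12)
  expect_error(readout(Z, integer(0)), "non-empty")
})

test_that("discriminator is a sigmoid bilinear score, monotone in z'Mg", {
  expect_equal(discriminator(c(0, 0), c(1, 2), diag(2)), 0.5)
  expect_equal(discriminator(c(1, 1), c(1, 1), diag(2)), 1 / (1 + exp(-2)))
  scores <- sapply(seq(-3, 3, by = 0.5),
                   function(a) discriminator(c(a, 0), c(1, 0), diag(2)))
  expect_true(all(diff(scores) > 0))
  expect_error(discriminator(c(1, 2, 3), c(1, 2), diag(2)), "mismatch")
})

test_that("contrastive losses hit their closed forms", {
  n <- 6; d <- 3
  G <- matrix(runif(n * d), n, d)
  Z0 <- matrix(0, n, d)                  # zero embeddings: every score is 0.5
  expect_equal(contrastive_loss(Z0, Z0, G, diag(d)), log(2), tolerance = 1e-12)
  expect_equal(contrastive_loss_corrupt(Z0, Z0, G, diag(d)), log(2),
               tolerance = 1e-12)
  # perfect discrimination limit: loss approaches 0
  big <- matrix(20, n, d)
  expect_lt(contrastive_loss(big, -big, matrix(1, n, d), diag(d)), 1e-6)
  # direct summation oracle on a random instance
  set.seed(31)
  Z <- matrix(rnorm(n * d), n, d); Zc <- matrix(rnorm(n * d), n, d)
  M <- matrix(rnorm(d * d), d, d)
  s <- function(A, B) 1 / (1 + exp(-rowSums((A %*% M) * B)))
  manual <- -sum(log(s(Z, G)) + log(1 - s(Zc, G))) / (2 * n)
  expect_equal(contrastive_loss(Z, Zc, G, M), manual, tolerance = 1e-12)
  Gc <- matrix(runif(n * d), n, d)
  manual_c <- -sum(log(s(Zc, Gc)) + log(1 - s(Z, Gc))) / (2 * n)
  expect_equal(contrastive_loss_corrupt(Z, Zc, Gc, M), manual_c, tolerance = 1e-12)
  expect_gte(contrastive_loss(Z, Zc, G, M), 0)
})

test_that("total loss is the weighted sum of its components", {
  cfg <- train_config()
  expect_equal(total_loss(0.5, 0.2, 0.3, cfg), 5.5)
  expect_equal(total_loss(1, 2, 3, train_config(lambda1 = 0, lambda2 = 0)), 0)
  expect_equal(total_loss(0.7, 9, 9, train_config(lambda1 = 1, lambda2 = 0)), 0.7)
})

test_that("analytic gradients agree with central finite differences", {
  set.seed(3)
  coords <- cbind(runif(7), runif(7))
  g <- build_knn_graph(coords, 2)
  X <- matrix(rnorm(35), 7, 5)
  cfg <- train_config(hidden_dim = 4, embed_dim = 3, seed = 5)
  params <- init_params(5, cfg)
  S <- g$norm_adjacency
  R <- spotgcn:::neighbor_mean_operator(g)
  Xc <- corrupt_features(X, 11)
  fb <- spotgcn:::pretrain_forward_backward(X, Xc, S, R, params, cfg)
  flat <- spotgcn:::params_to_flat(params)
  loss_at <- function(fl)
    spotgcn:::pretrain_forward_backward(X, Xc, S, R,
                                        spotgcn:::flat_to_params(params, fl),
                                        cfg)$loss
  eps <- 1e-6
  for (k in names(fb$grads)) {
    idx <- seq_len(min(4, length(flat[[k]])))
    for (i in idx) {
      up <- flat; up[[k]][i] <- up[[k]][i] + eps
      dn <- flat; dn[[k]][i] <- dn[[k]][i] - eps
      num <- (loss_at(up) - loss_at(dn)) / (2 * eps)
      ana <- fb$grads[[k]][i]
      expect_equal(ana, num, tolerance = 1e-3,
                   label = sprintf("grad %s[%d] analytic", k, i))
    }
  }
})

test_that("pre-training lowers the loss, is seed-deterministic, and 0 epochs is a no-op", {
  pm <- small_pretrained()
  h <- attr(pm, "history")
  expect_lt(h$total[nrow(h)], h$total[1])
  pm2 <- pretrain(small_pp()$matrix, small_graph(), small_config())
  expect_equal(attr(pm2, "history")$total, h$total, tolerance = 1e-6)
  cfg0 <- small_config(); cfg0$pretrain_epochs <- 0L
  init <- init_params(ncol(small_pp()$matrix), cfg0)
  expect_equal(pretrain(small_pp()$matrix, small_graph(), cfg0, params = init)$encoder,
               init$encoder)
})

test_that("fine-tuning stops at the accuracy threshold and 0 epochs is a no-op", {
  ds <- small_dataset(); pp <- small_pp(); g <- small_graph()
  noise <- inject_label_noise(ds$truth_labels, 0.3, 0, seed = 5)
  cfg <- small_config()
  ft <- finetune(small_pretrained(), pp$matrix, g, noise$labels, cfg)
  fh <- attr(ft, "finetune_history")
  expect_lt(nrow(fh), cfg$finetune_max_epochs)        # stopped early
  expect_gt(fh$accuracy[nrow(fh)], cfg$early_stop_accuracy)
  expect_true(all(fh$accuracy[-nrow(fh)] <= cfg$early_stop_accuracy))
  expect_false(fh$updated[nrow(fh)])                  # no update past the stop
  # zero-epoch no-op
  cfg0 <- small_config(); cfg0$finetune_max_epochs <- 0L
  ft0 <- finetune(small_pretrained(), pp$matrix, g, noise$labels, cfg0)
  expect_equal(ft0$encoder, small_pretrained()$encoder)
  # unknown class guard
  bad <- identified_labels(1:3, c("x", "y", "z"), ds$n_spot)
  expect_error(finetune(ft, pp$matrix, g,
                        identified_labels(1, "nope", ds$n_spot), cfg),
               "unknown|classes")
})

test_that("a head that is already accurate stops after one epoch without updating", {
  ds <- small_dataset(); pp <- small_pp(); g <- small_graph()
  noise <- inject_label_noise(ds$truth_labels, 0.3, 0, seed = 5)
  cfg <- small_config()
  ft <- finetune(small_pretrained(), pp$matrix, g, noise$labels, cfg)
  # re-fine-tuning from already-converged params must stop immediately
  ft2 <- finetune(ft, pp$matrix, g, noise$labels, cfg)
  fh2 <- attr(ft2, "finetune_history")
  expect_equal(nrow(fh2), 1)
  expect_false(fh2$updated[1])
  expect_equal(ft2$encoder, ft$encoder)
})
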