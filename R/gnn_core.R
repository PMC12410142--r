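#' Training configuration for the graph autoencoder
#'
#' Holds every tunable of pre-training and fine-tuning. The loss weights
#' default to `lambda1 = 10` (reconstruction) and `lambda2 = 1` (the two
#' contrastive terms); the fine-tuning early stop fires at the first epoch
#' whose labeled-spot accuracy exceeds `early_stop_accuracy` (default 0.9),
#' which both limits overfitting to the small labeled set and avoids chasing
#' noise in marker-derived labels.
#'
#' @param lambda1 Weight of the reconstruction loss (default 10).
#' @param lambda2 Weight of the contrastive losses (default 1).
#' @param learning_rate Adam step size (default 1e-3).
#' @param pretrain_epochs Full-graph gradient steps in pre-training
#'   (default 600).
#' @param finetune_max_epochs Cap on fine-tuning epochs (default 200).
#' @param early_stop_accuracy Labeled-spot accuracy above which fine-tuning
#'   halts (default 0.9).
#' @param embed_dim Dimension of the spot embedding (default 64).
#' @param hidden_dim Width of the first encoder layer / last decoder layer
#'   (default 256).
#' @param classifier_hidden Width of the classifier MLP hidden layer
#'   (default 32).
#' @param seed Integer seed controlling weight initialization and the
#'   per-epoch corruption permutations.
#' @return A list of class `train_config`.
#' @export
train_config <- function(lambda1 = 10, lambda2 = 1, learning_rate = 1e-3,
                         pretrain_epochs = 600, finetune_max_epochs = 200,
                         early_stop_accuracy = 0.9, embed_dim = 64,
                         hidden_dim = 256, classifier_hidden = 32, seed = 0) {
  stopifnot(lambda1 >= 0, lambda2 >= 0, learning_rate > 0,
            pretrain_epochs >= 0, finetune_max_epochs >= 0,
            early_stop_accuracy > 0, early_stop_accuracy <= 1,
            embed_dim >= 1, hidden_dim >= 1, classifier_hidden >= 1)
  structure(list(lambda1 = lambda1, lambda2 = lambda2,
                 learning_rate = learning_rate,
                 pretrain_epochs = as.integer(pretrain_epochs),
                 finetune_max_epochs = as.integer(finetune_max_epochs),
                 early_stop_accuracy = early_stop_accuracy,
                 embed_dim = as.integer(embed_dim),
                 hidden_dim = as.integer(hidden_dim),
                 classifier_hidden = as.integer(classifier_hidden),
                 seed = as.integer(seed)),
            class = "train_config")
}

# run code under a temporary RNG state, restoring the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

#' Initialize model parameters
#'
#' Glorot-uniform weights, zero biases: a 2-layer GCN encoder
#' (`n_gene -> hidden_dim -> embed_dim`, ReLU after layer 1, linear layer 2),
#' a mirrored decoder, a bilinear discriminator matrix, and (when
#' `n_clusters` is given) a one-hidden-layer classifier MLP
#' (`embed_dim -> classifier_hidden -> n_clusters`).
#'
#' @param n_gene Number of input features (genes after HVG selection).
#' @param config A [train_config()].
#' @param n_clusters Optional number of classes for the classifier head.
#' @return A list of class `gnn_params` with elements `encoder`, `decoder`
#'   (each a list of `(W, b)` layers), `disc_M`, `classifier` (or `NULL`),
#'   `classes` (or `NULL`), and `dims`.
#' @export
init_params <- function(n_gene, config = train_config(), n_clusters = NULL) {
  h <- config$hidden_dim; d <- config$embed_dim
  with_seed(config$seed, {
    p <- list(
      encoder = list(list(W = glorot(n_gene, h), b = rep(0, h)),
                     list(W = glorot(h, d), b = rep(0, d))),
      decoder = list(list(W = glorot(d, h), b = rep(0, h)),
                     list(W = glorot(h, n_gene), b = rep(0, n_gene))),
      disc_M = glorot(d, d),
      classifier = NULL, classes = NULL,
      dims = list(n_gene = n_gene, hidden_dim = h, embed_dim = d,
                  classifier_hidden = config$classifier_hidden)
    )
    if (!is.null(n_clusters)) {
      p$classifier <- list(
        list(W = glorot(d, config$classifier_hidden), b = rep(0, config$classifier_hidden)),
        list(W = glorot(config$classifier_hidden, n_clusters), b = rep(0, n_clusters)))
      p$dims$n_clusters <- n_clusters
    }
    structure(p, class = "gnn_params")
  })
}

relu <- function(x) (x + abs(x)) / 2
sigmoid <- function(x) 1 / (1 + exp(-x))

#' One graph convolutional layer
#'
#' Computes `act(S %*% H %*% W + b)` where `S` is the symmetric-normalized
#' self-looped adjacency ([normalize_adjacency()]), the bias is broadcast
#' across rows, and `act` is ReLU when `use_activation` and identity
#' otherwise.
#'
#' @param H Input feature matrix (`n_spot x d_in`).
#' @param norm_adjacency `S`, sparse or dense `n_spot x n_spot`.
#' @param W Weight matrix (`d_in x d_out`).
#' @param b Bias vector (length `d_out`).
#' @param use_activation Apply ReLU (default `TRUE`).
#' @return Matrix `n_spot x d_out`.
#' @export
gcn_layer <- function(H, norm_adjacency, W, b, use_activation = TRUE) {
  H <- as.matrix(H)
  if (ncol(H) != nrow(W)) stop("gcn_layer: H columns must match W rows")
  if (length(b) != ncol(W)) stop("gcn_layer: bias length must match W columns")
  out <- as.matrix(norm_adjacency %*% H %*% W)
  out <- sweep(out, 2, b, "+")
  if (use_activation) relu(out) else out
}

#' Encode spots into the latent space
#'
#' Two GCN layers (ReLU, then linear); deterministic given the parameters.
#'
#' @param X Preprocessed expression matrix (`n_spot x n_gene`).
#' @param graph A `spot_graph`.
#' @param params A `gnn_params`.
#' @return Embedding matrix `Z` (`n_spot x embed_dim`).
#' @export
encode <- function(X, graph, params) {
  S <- graph$norm_adjacency
  H1 <- gcn_layer(X, S, params$encoder[[1]]$W, params$encoder[[1]]$b, TRUE)
  gcn_layer(H1, S, params$encoder[[2]]$W, params$encoder[[2]]$b, FALSE)
}

#' Decode embeddings back to expression space
#'
#' Mirror of [encode()]: ReLU GCN layer then linear GCN layer, returning a
#' reconstruction of the input expression matrix.
#'
#' @param Z Embedding matrix.
#' @inheritParams encode
#' @return Reconstructed matrix (`n_spot x n_gene`).
#' @export
decode <- function(Z, graph, params) {
  S <- graph$norm_adjacency
  D1 <- gcn_layer(Z, S, params$decoder[[1]]$W, params$decoder[[1]]$b, TRUE)
  gcn_layer(D1, S, params$decoder[[2]]$W, params$decoder[[2]]$b, FALSE)
}

#' Reconstruction loss
#'
#' Sum over spots of the squared Euclidean norm of the reconstruction error —
#' equivalently the squared Frobenius norm of `X - X_hat`.
#'
#' @param X,X_hat Matrices of identical shape.
#' @return Non-negative scalar.
#' @export
reconstruction_loss <- function(X, X_hat) {
  if (!all(dim(X) == dim(X_hat))) stop("shape mismatch")
  sum((X - X_hat)^2)
}

#' Corrupt features by row permutation
#'
#' Draws a uniform random permutation of the spots from `seed` and reorders
#' the rows of `X`, manufacturing the negative view for contrastive learning:
#' expression profiles are detached from their spatial positions while the
#' graph topology and the multiset of profiles stay intact.
#'
#' @param X Feature matrix.
#' @param seed Integer seed; the caller's RNG stream is left untouched.
#' @return Row-permuted copy of `X`.
#' @export
corrupt_features <- function(X, seed) {
  n <- nrow(X)
  perm <- with_seed(seed, sample.int(n))
  X[perm, , drop = FALSE]
}

#' Subgraph readout for one spot
#'
#' Elementwise logistic sigmoid of the mean of the embeddings of the spot's
#' immediate graph neighbors (the spot itself is excluded). Entries lie in
#' (0, 1).
#'
#' @param Z Embedding matrix.
#' @param neighbors Integer indices of the spot's neighbors (non-empty).
#' @return Numeric vector of length `ncol(Z)`.
#' @export
readout <- function(Z, neighbors) {
  if (length(neighbors) == 0L) stop("readout needs a non-empty neighbor list")
  sigmoid(colMeans(Z[neighbors, , drop = FALSE]))
}

# all readouts at once: sigmoid(R Z) with R the row-normalized adjacency
readout_all <- function(Z, graph) {
  sigmoid(as.matrix(neighbor_mean_operator(graph) %*% Z))
}

#' Bilinear discriminator score
#'
#' `sigmoid(z' M g)` with the trainable bilinear matrix `M`; with `M = I`
#' this reduces to a plain dot-product similarity. Scores the compatibility
#' of a spot embedding with a subgraph readout.
#'
#' @param z Spot embedding vector.
#' @param g Readout vector (same length).
#' @param params A `gnn_params`, or the bilinear matrix itself.
#' @return Scalar in (0, 1).
#' @export
discriminator <- function(z, g, params) {
  M <- if (inherits(params, "gnn_params")) params$disc_M else as.matrix(params)
  if (length(z) != nrow(M) || length(g) != ncol(M)) stop("dimension mismatch")
  sigmoid(sum(z * (M %*% g)))
}

disc_scores <- function(Z, G, M) sigmoid(rowSums((Z %*% M) * G))

EPS_SCORE <- 1e-7
clamp01 <- function(s) pmin(pmax(s, EPS_SCORE), 1 - EPS_SCORE)

#' Contrastive loss on the original view
#'
#' Binary cross-entropy of the discriminator over positive pairs
#' `(z_i, g_i)` — embedding and readout from the original graph — and
#' negative pairs `(z'_i, g_i)` pairing the corrupted embedding with the
#' original readout:
#' `-(1/(2 n)) * sum_i [log s(z_i, g_i) + log(1 - s(z'_i, g_i))]`.
#' Scores are clamped to `[1e-7, 1 - 1e-7]` before the logarithm.
#'
#' @param Z Embeddings of the original features.
#' @param Z_corrupt Embeddings of the corrupted features (same graph).
#' @param G Readout matrix of the original view (rows `g_i`).
#' @param params `gnn_params` or bilinear matrix.
#' @return Non-negative scalar.
#' @export
contrastive_loss <- function(Z, Z_corrupt, G, params) {
  M <- if (inherits(params, "gnn_params")) params$disc_M else as.matrix(params)
  pos <- clamp01(disc_scores(Z, G, M))
  neg <- clamp01(disc_scores(Z_corrupt, G, M))
  if (any(!is.finite(pos)) || any(!is.finite(neg))) stop("non-finite discriminator scores")
  -mean(log(pos) + log(1 - neg)) / 2
}

#' Contrastive loss on the corrupted view
#'
#' Role-swapped counterpart of [contrastive_loss()]: positives pair the
#' corrupted embedding with the corrupted readout, negatives pair the
#' original embedding with the corrupted readout.
#'
#' @inheritParams contrastive_loss
#' @param G_corrupt Readout matrix of the corrupted view.
#' @return Non-negative scalar.
#' @export
contrastive_loss_corrupt <- function(Z, Z_corrupt, G_corrupt, params) {
  contrastive_loss(Z_corrupt, Z, G_corrupt, params)
}

#' Combined pre-training loss
#'
#' `lambda1 * l_recon + lambda2 * (l_scl + l_scl_corrupt)`.
#'
#' @param l_recon,l_scl,l_scl_corrupt Component losses.
#' @param config A [train_config()] supplying `lambda1`, `lambda2`.
#' @return Scalar.
#' @export
total_loss <- function(l_recon, l_scl, l_scl_corrupt, config) {
  config$lambda1 * l_recon + config$lambda2 * (l_scl + l_scl_corrupt)
}

# --- internal: full forward + hand-derived reverse-mode gradients ----------
#
# The architecture is small and fixed, so gradients are written out
# analytically (verified against finite differences in the tests) instead of
# pulling in an autodiff framework.

pretrain_forward_backward <- function(X, Xc, S, R, params, config) {
  enc <- params$encoder; dec <- params$decoder; M <- params$disc_M
  n <- nrow(X)

  enc_fwd <- function(Xin) {
    P1 <- as.matrix(S %*% Xin)
    A1 <- sweep(P1 %*% enc[[1]]$W, 2, enc[[1]]$b, "+")
    H1 <- relu(A1)
    P2 <- as.matrix(S %*% H1)
    Z <- sweep(P2 %*% enc[[2]]$W, 2, enc[[2]]$b, "+")
    list(P1 = P1, A1 = A1, H1 = H1, P2 = P2, Z = Z)
  }
  fo <- enc_fwd(X)
  fc <- enc_fwd(Xc)
  Z <- fo$Z; Zc <- fc$Z

  Q1 <- as.matrix(S %*% Z)
  B1 <- sweep(Q1 %*% dec[[1]]$W, 2, dec[[1]]$b, "+")
  D1 <- relu(B1)
  Q2 <- as.matrix(S %*% D1)
  Xhat <- sweep(Q2 %*% dec[[2]]$W, 2, dec[[2]]$b, "+")

  G <- sigmoid(as.matrix(R %*% Z))
  Gc <- sigmoid(as.matrix(R %*% Zc))
  ZM <- Z %*% M; ZcM <- Zc %*% M
  s_pos <- sigmoid(rowSums(ZM * G))
  s_neg <- sigmoid(rowSums(ZcM * G))
  s_posc <- sigmoid(rowSums(ZcM * Gc))
  s_negc <- sigmoid(rowSums(ZM * Gc))

  l_recon <- sum((X - Xhat)^2)
  l_scl <- -mean(log(clamp01(s_pos)) + log(1 - clamp01(s_neg))) / 2
  l_sclc <- -mean(log(clamp01(s_posc)) + log(1 - clamp01(s_negc))) / 2
  loss <- total_loss(l_recon, l_scl, l_sclc, config)
  if (!is.finite(loss)) stop("pre-training diverged: non-finite loss")

  # ---- backward ----
  lam1 <- config$lambda1; lam2 <- config$lambda2
  g <- list()

  # decoder (feeds dZ)
  dXhat <- lam1 * 2 * (Xhat - X)
  g$dec2_W <- crossprod(Q2, dXhat); g$dec2_b <- colSums(dXhat)
  dQ2 <- dXhat %*% t(dec[[2]]$W)
  dD1 <- as.matrix(S %*% dQ2)                  # S symmetric
  dB1 <- dD1 * (B1 > 0)
  g$dec1_W <- crossprod(Q1, dB1); g$dec1_b <- colSums(dB1)
  dQ1 <- dB1 %*% t(dec[[1]]$W)
  dZ <- as.matrix(S %*% dQ1)

  # contrastive terms; d loss / d u for u = z' M g, s = sigmoid(u)
  c_pos <- -(lam2 / (2 * n)) * (1 - s_pos)
  c_neg <- (lam2 / (2 * n)) * s_neg
  c_posc <- -(lam2 / (2 * n)) * (1 - s_posc)
  c_negc <- (lam2 / (2 * n)) * s_negc

  dG <- c_pos * ZM + c_neg * ZcM
  dGc <- c_posc * ZcM + c_negc * ZM
  dZ <- dZ + (c_pos * G) %*% t(M) + (c_negc * Gc) %*% t(M)
  dZc <- (c_neg * G) %*% t(M) + (c_posc * Gc) %*% t(M)
  g$disc_M <- crossprod(Z, c_pos * G + c_negc * Gc) +
    crossprod(Zc, c_neg * G + c_posc * Gc)

  # readout: G = sigmoid(R Z)
  dZ <- dZ + as.matrix(Matrix::t(R) %*% (dG * G * (1 - G)))
  dZc <- dZc + as.matrix(Matrix::t(R) %*% (dGc * Gc * (1 - Gc)))

  enc_bwd <- function(fwd, dZ_in) {
    dW2 <- crossprod(fwd$P2, dZ_in); db2 <- colSums(dZ_in)
    dP2 <- dZ_in %*% t(enc[[2]]$W)
    dH1 <- as.matrix(S %*% dP2)
    dA1 <- dH1 * (fwd$A1 > 0)
    dW1 <- crossprod(fwd$P1, dA1); db1 <- colSums(dA1)
    list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
  }
  bo <- enc_bwd(fo, dZ)
  bc <- enc_bwd(fc, dZc)
  g$enc1_W <- bo$W1 + bc$W1; g$enc1_b <- bo$b1 + bc$b1
  g$enc2_W <- bo$W2 + bc$W2; g$enc2_b <- bo$b2 + bc$b2

  list(loss = loss, l_recon = l_recon, l_scl = l_scl, l_scl_corrupt = l_sclc,
       grads = g)
}

# --- internal: Adam optimizer over a flat list of arrays -------------------
adam_init <- function(shapes) {
  list(m = lapply(shapes, function(x) x * 0), v = lapply(shapes, function(x) x * 0),
       t = 0L)
}

adam_step <- function(state, values, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (k in names(grads)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    values[[k]] <- values[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(state = state, values = values)
}

params_to_flat <- function(params) {
  list(enc1_W = params$encoder[[1]]$W, enc1_b = params$encoder[[1]]$b,
       enc2_W = params$encoder[[2]]$W, enc2_b = params$encoder[[2]]$b,
       dec1_W = params$decoder[[1]]$W, dec1_b = params$decoder[[1]]$b,
       dec2_W = params$decoder[[2]]$W, dec2_b = params$decoder[[2]]$b,
       disc_M = params$disc_M)
}

flat_to_params <- function(params, flat) {
  params$encoder[[1]]$W <- flat$enc1_W; params$encoder[[1]]$b <- flat$enc1_b
  params$encoder[[2]]$W <- flat$enc2_W; params$encoder[[2]]$b <- flat$enc2_b
  params$decoder[[1]]$W <- flat$dec1_W; params$decoder[[1]]$b <- flat$dec1_b
  params$decoder[[2]]$W <- flat$dec2_W; params$decoder[[2]]$b <- flat$dec2_b
  params$disc_M <- flat$disc_M
  params
}

#' Pre-train the graph autoencoder with contrastive learning
#'
#' Full-graph Adam descent on the combined loss
#' `lambda1 * L_recon + lambda2 * (L_scl + L_scl_corrupt)`. Each epoch draws
#' a fresh corruption permutation (deterministically from
#' `config$seed + epoch`), encodes both views on the same graph, scores
#' positive and negative (embedding, readout) pairs with the bilinear
#' discriminator, and updates encoder, decoder and discriminator together.
#'
#' @param X Preprocessed expression matrix (spots x HVGs), e.g. from
#'   [preprocess()].
#' @param graph A `spot_graph` on the same spot order.
#' @param config A [train_config()].
#' @param params Optional starting `gnn_params`; freshly initialized from
#'   `config$seed` when omitted. With `pretrain_epochs = 0` the starting
#'   parameters are returned unchanged.
#' @param verbose Print the loss every 50 epochs.
#' @return Trained `gnn_params` with attribute `"history"`, a data frame
#'   (epoch, l_recon, l_scl, l_scl_corrupt, total).
#' @export
pretrain <- function(X, graph, config = train_config(), params = NULL,
                     verbose = FALSE) {
  X <- as.matrix(X)
  if (is.null(params)) params <- init_params(ncol(X), config)
  S <- graph$norm_adjacency
  R <- neighbor_mean_operator(graph)
  flat <- params_to_flat(params)
  opt <- adam_init(flat)
  hist <- vector("list", config$pretrain_epochs)

  for (epoch in seq_len(config$pretrain_epochs)) {
    Xc <- corrupt_features(X, config$seed + epoch)
    fb <- pretrain_forward_backward(X, Xc, S, R,
                                    flat_to_params(params, flat), config)
    step <- adam_step(opt, flat, fb$grads, config$learning_rate)
    opt <- step$state; flat <- step$values
    hist[[epoch]] <- data.frame(epoch = epoch, l_recon = fb$l_recon,
                                l_scl = fb$l_scl,
                                l_scl_corrupt = fb$l_scl_corrupt,
                                total = fb$loss)
    if (verbose && (epoch == 1L || epoch %% 50L == 0L))
      message(sprintf("epoch %4d  total %.4f  recon %.4f", epoch, fb$loss, fb$l_recon))
  }
  params <- flat_to_params(params, flat)
  attr(params, "history") <- if (config$pretrain_epochs > 0)
    do.call(rbind, hist) else
    data.frame(epoch = integer(), l_recon = numeric(), l_scl = numeric(),
               l_scl_corrupt = numeric(), total = numeric())
  params
}

classifier_forward <- function(Z, classifier) {
  B <- sweep(Z %*% classifier[[1]]$W, 2, classifier[[1]]$b, "+")
  F1 <- relu(B)
  logits <- sweep(F1 %*% classifier[[2]]$W, 2, classifier[[2]]$b, "+")
  list(B = B, F1 = F1, logits = logits)
}

softmax_rows <- function(L) {
  e <- exp(L - apply(L, 1, max))
  e / rowSums(e)
}

#' Fine-tune the encoder and classifier on identified labels
#'
#' Starting from pre-trained weights, attaches (or reuses) a classifier MLP
#' and minimizes the cross-entropy of the labeled spots, updating both the
#' encoder and the head. Before each epoch's update the labeled-spot accuracy
#' is measured; training halts at the first epoch where it exceeds
#' `config$early_stop_accuracy`, or after `config$finetune_max_epochs`
#' epochs. With `finetune_max_epochs = 0` the parameters are returned
#' unchanged.
#'
#' @param params Pre-trained `gnn_params`.
#' @param X Preprocessed expression matrix.
#' @param graph A `spot_graph`.
#' @param labels An `identified_labels` object (non-empty).
#' @param config A [train_config()].
#' @return Updated `gnn_params` with `classes` set (sorted unique label
#'   values) and attribute `"finetune_history"`, a data frame
#'   (epoch, loss, accuracy, updated).
#' @export
finetune <- function(params, X, graph, labels, config = train_config()) {
  stopifnot(inherits(labels, "identified_labels"))
  if (length(labels$spots) == 0L) stop("no labeled spots to fine-tune on")
  X <- as.matrix(X)
  classes <- sort(unique(labels$labels))
  if (!is.null(params$classifier)) {
    k_out <- ncol(params$classifier[[2]]$W)
    if (length(classes) > k_out)
      stop("labels contain more classes than the classifier output dimension")
    if (!is.null(params$classes)) classes <- params$classes
  } else {
    d_embed <- ncol(params$encoder[[2]]$W)
    head_init <- with_seed(config$seed + 7L, list(
      list(W = glorot(d_embed, config$classifier_hidden),
           b = rep(0, config$classifier_hidden)),
      list(W = glorot(config$classifier_hidden, length(classes)),
           b = rep(0, length(classes)))))
    params$classifier <- head_init
    params$dims$n_clusters <- length(classes)
  }
  miss <- setdiff(labels$labels, classes)
  if (length(miss) > 0L)
    stop("label(s) unknown to the classifier: ", paste(miss, collapse = ", "))
  params$classes <- classes
  y <- match(labels$labels, classes)
  lab <- labels$spots
  n_lab <- length(lab)
  S <- graph$norm_adjacency
  enc_flat <- params_to_flat(params)
  flat <- c(enc_flat[c("enc1_W", "enc1_b", "enc2_W", "enc2_b")],
            list(cls1_W = params$classifier[[1]]$W, cls1_b = params$classifier[[1]]$b,
                 cls2_W = params$classifier[[2]]$W, cls2_b = params$classifier[[2]]$b))
  opt <- adam_init(flat)
  hist <- list()

  for (epoch in seq_len(config$finetune_max_epochs)) {
    # forward with current weights
    P1 <- as.matrix(S %*% X)
    A1 <- sweep(P1 %*% flat$enc1_W, 2, flat$enc1_b, "+")
    H1 <- relu(A1)
    P2 <- as.matrix(S %*% H1)
    Z <- sweep(P2 %*% flat$enc2_W, 2, flat$enc2_b, "+")
    cf <- classifier_forward(Z[lab, , drop = FALSE],
                             list(list(W = flat$cls1_W, b = flat$cls1_b),
                                  list(W = flat$cls2_W, b = flat$cls2_b)))
    prob <- softmax_rows(cf$logits)
    pred <- max.col(cf$logits, ties.method = "first")
    acc <- mean(pred == y)
    loss <- -mean(log(pmax(prob[cbind(seq_len(n_lab), y)], 1e-12)))
    stopped <- acc > config$early_stop_accuracy
    hist[[length(hist) + 1L]] <- data.frame(epoch = epoch, loss = loss,
                                            accuracy = acc, updated = !stopped)
    if (stopped) break                  # early stop: threshold met, no update

    dlogits <- prob
    dlogits[cbind(seq_len(n_lab), y)] <- dlogits[cbind(seq_len(n_lab), y)] - 1
    dlogits <- dlogits / n_lab
    g <- list()
    g$cls2_W <- crossprod(cf$F1, dlogits); g$cls2_b <- colSums(dlogits)
    dF1 <- dlogits %*% t(flat$cls2_W)
    dB <- dF1 * (cf$B > 0)
    g$cls1_W <- crossprod(Z[lab, , drop = FALSE], dB); g$cls1_b <- colSums(dB)
    dZlab <- dB %*% t(flat$cls1_W)
    dZ <- matrix(0, nrow(X), ncol(dZlab))
    dZ[lab, ] <- dZlab
    g$enc2_W <- crossprod(P2, dZ); g$enc2_b <- colSums(dZ)
    dP2 <- dZ %*% t(flat$enc2_W)
    dH1 <- as.matrix(S %*% dP2)
    dA1 <- dH1 * (A1 > 0)
    g$enc1_W <- crossprod(P1, dA1); g$enc1_b <- colSums(dA1)

    step <- adam_step(opt, flat, g, config$learning_rate)
    opt <- step$state; flat <- step$values
  }

  params$encoder[[1]]$W <- flat$enc1_W; params$encoder[[1]]$b <- flat$enc1_b
  params$encoder[[2]]$W <- flat$enc2_W; params$encoder[[2]]$b <- flat$enc2_b
  params$classifier <- list(list(W = flat$cls1_W, b = flat$cls1_b),
                            list(W = flat$cls2_W, b = flat$cls2_b))
  attr(params, "finetune_history") <- if (length(hist) > 0) do.call(rbind, hist) else
    data.frame(epoch = integer(), loss = numeric(), accuracy = numeric(),
               updated = logical())
  params
}

#' Write a per-epoch training log
#'
#' @param params A trained `gnn_params` (uses its `"history"` attribute).
#' @param path Output CSV.
#' @return Invisibly, `path`.
#' @export
write_training_log <- function(params, path) {
  h <- attr(params, "history")
  if (is.null(h)) stop("params carry no training history")
  utils::write.csv(h, path, row.names = FALSE)
  invisible(path)
}
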