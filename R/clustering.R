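#' Gaussian mixture fit of spot embeddings
#'
#' Expectation-maximization for a full-covariance Gaussian mixture with a
#' fixed number of components `K` (known from the marker map in every
#' intended use). Each of `n_init` runs starts from k-means++-seeded centers;
#' the run with the highest final log-likelihood wins. Covariances are
#' regularized by adding `1e-6 * I` at every M step; a component that
#' collapses (vanishing responsibility mass) is re-seeded at a random point
#' with a message.
#'
#' @param Z Numeric matrix (spots x dims).
#' @param K Number of mixture components, `1 <= K <= nrow(Z)`.
#' @param seed Integer seed for the initializations.
#' @param n_init Number of EM restarts (default 10).
#' @param max_iter EM iteration cap per restart (default 200).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-8).
#' @return An object of class `gmm_fit`: list with `weights`, `means`
#'   (`K x d`), `covariances` (list of `d x d`), `loglik_trace` (best
#'   restart), `loglik`, `responsibilities` and `labels` (argmax posterior).
#' @export
gmm_fit <- function(Z, K, seed = 0, n_init = 10, max_iter = 200, tol = 1e-8) {
  Z <- as.matrix(Z)
  n <- nrow(Z); d <- ncol(Z)
  if (K < 1) stop("K must be >= 1")
  if (K > n) stop("K exceeds the number of points")
  reg <- diag(1e-6, d)

  log_dens <- function(mu, Sigma) {
    # multivariate normal log-density via Cholesky
    ch <- chol(Sigma)
    diff <- sweep(Z, 2, mu)
    y <- backsolve(ch, t(diff), transpose = TRUE)
    -0.5 * colSums(y^2) - sum(log(diag(ch))) - 0.5 * d * log(2 * pi)
  }

  run_em <- function(centers) {
    mu <- centers
    Sigma <- replicate(K, stats::cov(Z) + reg, simplify = FALSE)
    if (any(!is.finite(unlist(Sigma)))) stop("non-finite covariance")
    w <- rep(1 / K, K)
    trace <- numeric(0)
    prev <- -Inf
    for (it in seq_len(max_iter)) {
      logd <- vapply(seq_len(K), function(k) log(w[k]) + log_dens(mu[k, ], Sigma[[k]]),
                     numeric(n))
      mx <- apply(logd, 1, max)
      lse <- mx + log(rowSums(exp(logd - mx)))
      ll <- sum(lse)
      resp <- exp(logd - lse)
      trace <- c(trace, ll)
      if (is.finite(prev) && ll - prev <= tol * abs(ll)) break
      prev <- ll
      nk <- colSums(resp)
      for (k in seq_len(K)) {
        if (nk[k] < 1e-8) {                    # degenerate component: re-seed
          message("re-initializing empty mixture component ", k)
          mu[k, ] <- Z[sample.int(n, 1), ]
          Sigma[[k]] <- stats::cov(Z) + reg
          w[k] <- 1 / n
          next
        }
        mu[k, ] <- colSums(resp[, k] * Z) / nk[k]
        diff <- sweep(Z, 2, mu[k, ])
        Sigma[[k]] <- crossprod(diff * sqrt(resp[, k])) / nk[k] + reg
        w[k] <- nk[k] / n
      }
      w <- w / sum(w)
    }
    list(weights = w, means = mu, covariances = Sigma, loglik_trace = trace,
         loglik = trace[length(trace)], responsibilities = resp)
  }

  best <- NULL
  with_seed(seed, {
    for (init in seq_len(n_init)) {
      centers <- Z[kmeanspp_centers(Z, K), , drop = FALSE]
      fit <- run_em(centers)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
  })
  best$labels <- max.col(best$responsibilities, ties.method = "first")
  structure(best, class = "gmm_fit")
}

# k-means++ seeding: first center uniform, then distance-squared-proportional
kmeanspp_centers <- function(Z, K) {
  n <- nrow(Z)
  idx <- integer(K)
  idx[1] <- sample.int(n, 1)
  if (K == 1) return(idx)
  d2 <- rowSums(sweep(Z, 2, Z[idx[1], ])^2)
  for (k in 2:K) {
    if (all(d2 == 0)) {
      idx[k] <- sample.int(n, 1)
    } else {
      idx[k] <- sample.int(n, 1, prob = d2 / sum(d2))
    }
    d2 <- pmin(d2, rowSums(sweep(Z, 2, Z[idx[k], ])^2))
  }
  idx
}

#' Cluster embeddings with a Gaussian mixture
#'
#' Convenience wrapper around [gmm_fit()] that returns a cluster assignment.
#'
#' @inheritParams gmm_fit
#' @return A `cluster_assignment`: list with `labels` (integer, 1..K),
#'   `method_used = "gmm"` and the underlying `fit`.
#' @export
gmm_cluster <- function(Z, K, seed = 0, n_init = 10) {
  fit <- gmm_fit(Z, K, seed = seed, n_init = n_init)
  structure(list(labels = fit$labels, method_used = "gmm", fit = fit),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment (%s): %d spots, %d cluster(s)\n",
              x$method_used, length(x$labels), length(unique(x$labels))))
  invisible(x)
}

#' Classify every spot with the fine-tuned head
#'
#' Runs the encoder on all spots and takes the argmax of the classifier
#' logits (ties resolve to the lower class index).
#'
#' @param params Fine-tuned `gnn_params` (classifier present).
#' @param X Preprocessed expression matrix.
#' @param graph A `spot_graph`.
#' @return A `cluster_assignment` with `method_used = "classifier"`, integer
#'   `labels` (class indices) and `class_names` (original label values).
#' @export
classify_all <- function(params, X, graph) {
  if (is.null(params$classifier)) stop("classifier head is untrained")
  Z <- encode(X, graph, params)
  lg <- classifier_forward(Z, params$classifier)$logits
  structure(list(labels = max.col(lg, ties.method = "first"),
                 method_used = "classifier",
                 class_names = params$classes),
            class = "cluster_assignment")
}

#' Dynamic choice between mixture clustering and the classifier
#'
#' Applies the label-coverage switch: when the labeled fraction `p` is below
#' 0.20 the classifier risks overfitting its few training spots, so the
#' embeddings are clustered unsupervised with [gmm_cluster()]; when `p` is
#' 0.20 or more the fine-tuned classifier labels every spot. The boundary
#' `p == 0.20` goes to the classifier branch.
#'
#' @param params Fine-tuned `gnn_params`.
#' @param X Preprocessed expression matrix.
#' @param graph A `spot_graph`.
#' @param labels The `identified_labels` that drove fine-tuning (supplies
#'   `p`).
#' @param K Number of clusters for the mixture branch.
#' @param seed Seed for the mixture initializations.
#' @param n_init Mixture restarts (default 10).
#' @return A `cluster_assignment` with `method_used` recording the branch.
#' @export
dynamic_cluster <- function(params, X, graph, labels, K, seed = 0, n_init = 10) {
  stopifnot(inherits(labels, "identified_labels"))
  if (labels$p < 0.20) {
    Z <- encode(X, graph, params)
    gmm_cluster(Z, K, seed = seed, n_init = n_init)
  } else {
    classify_all(params, X, graph)
  }
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement from the contingency table under the
#' permutation model:
#' `(sum_ij C(n_ij,2) - E) / (0.5 * (sum_i C(a_i,2) + sum_j C(b_j,2)) - E)`
#' with `E = sum_i C(a_i,2) * sum_j C(b_j,2) / C(n,2)`. Invariant to label
#' renaming; 1 for identical partitions, about 0 for independent ones.
#'
#' @param labels_a,labels_b Equal-length label vectors (any atomic type),
#'   at least 2 items.
#' @return Scalar in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop("length mismatch")
  n <- length(labels_a)
  if (n < 2) stop("need at least 2 items")
  tab <- table(labels_a, labels_b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  a <- sum(ch2(rowSums(tab)))
  b <- sum(ch2(colSums(tab)))
  expected <- a * b / ch2(n)
  max_idx <- (a + b) / 2
  if (max_idx == expected) return(1)    # both partitions trivial: treat as agreement
  (sum_ij - expected) / (max_idx - expected)
}

#' Write the final assignment (and optional evaluation) to CSV
#'
#' @param assignment A `cluster_assignment`.
#' @param spot_ids Dataset spot ids in canonical order.
#' @param path Output CSV (`spot_id, predicted_label, method_used`).
#' @param truth Optional truth labels; when given, an ARI report CSV is
#'   written beside `path` (suffix `_ari`).
#' @return Invisibly, the path(s) written.
#' @export
write_assignment <- function(assignment, spot_ids, path, truth = NULL) {
  lab <- assignment$labels
  if (assignment$method_used == "classifier" && !is.null(assignment$class_names))
    lab <- assignment$class_names[lab]
  utils::write.csv(data.frame(spot_id = spot_ids, predicted_label = lab,
                              method_used = assignment$method_used),
                   path, row.names = FALSE)
  out <- path
  if (!is.null(truth)) {
    ari_path <- sub("(\\.csv)?$", "_ari.csv", path)
    utils::write.csv(data.frame(metric = "ARI",
                                value = adjusted_rand_index(assignment$labels, truth)),
                     ari_path, row.names = FALSE)
    out <- c(path, ari_path)
  }
  invisible(out)
}
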