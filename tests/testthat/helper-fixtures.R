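# Shared fixtures, built once per test run and cached.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = fixture_cache, inherits = FALSE))
    assign(name, expr, envir = fixture_cache)
  get(name, envir = fixture_cache)
}

# 30 x 30 lattice, 5 bands, 2 exclusive markers per band, 8-fold marker
# elevation: the reference fixture for labeling fidelity and the end-to-end
# noise-robustness runs.
bench_dataset <- function() cached("bench_ds", generate_synthetic_st(synthetic_config(seed = 0)))
bench_graph <- function() cached("bench_graph", build_knn_graph(bench_dataset()$coords, 3))
bench_pp <- function() cached("bench_pp", preprocess(bench_dataset()))
bench_config <- function() train_config(pretrain_epochs = 150, hidden_dim = 64, seed = 0)
bench_pretrained <- function()
  cached("bench_pm", pretrain(bench_pp()$matrix, bench_graph(), bench_config()))

# smaller 15 x 15 lattice for unit-level training tests
small_dataset <- function() cached("small_ds", generate_synthetic_st(
  synthetic_config(grid_rows = 15, grid_cols = 15, n_domains = 3,
                   n_genes = 60, seed = 1)))
small_graph <- function() cached("small_graph", build_knn_graph(small_dataset()$coords, 3))
small_pp <- function() cached("small_pp", preprocess(small_dataset()))
small_config <- function(...) train_config(pretrain_epochs = 40, hidden_dim = 32,
                                           embed_dim = 16, seed = 1, ...)
small_pretrained <- function()
  cached("small_pm", pretrain(small_pp()$matrix, small_graph(), small_config()))

# random Erdos-Renyi-style symmetric adjacency for operator oracles
random_adjacency <- function(n, p = 0.4) {
  A <- matrix(0, n, n)
  up <- upper.tri(A)
  A[up] <- as.numeric(stats::runif(sum(up)) < p)
  A + t(A)
}

# dense oracle for the symmetric-normalized self-looped adjacency
dense_norm_adjacency <- function(A) {
  At <- A + diag(nrow(A))
  d <- rowSums(At)
  diag(1 / sqrt(d)) %*% At %*% diag(1 / sqrt(d))
}

# independent ARI oracle: exhaustive pair counting over all C(n,2) pairs
ari_pair_counting <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (!sa && !sb) n00 <- n00 + 1
    else if (sa) n10 <- n10 + 1
    else n01 <- n01 + 1
  }
  num <- 2 * (n11 * n00 - n10 * n01)
  den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (den == 0) return(1)
  num / den
}

# tiny deterministic dataset for I/O tests
toy_dataset <- function() {
  st_dataset(matrix(c(0, 1, 2, 3, 4, 5), 2, 3),
             cbind(c(0, 1), c(0, 0)), c("s1", "s2"), c("g1", "g2", "g3"),
             truth_labels = c("a", "b"))
}
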