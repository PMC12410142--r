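#' Configuration for the synthetic lattice generator
#'
#' Describes a triangular (hexagonal-packing) lattice of spots partitioned
#' into contiguous horizontal bands — the layered-domain geometry of cortical
#' tissue — with negative-binomial counts and per-domain exclusive marker
#' genes whose mean is raised by `marker_fold` inside their own band.
#'
#' @param grid_rows,grid_cols Lattice dimensions (default 30 x 30).
#' @param n_domains Number of contiguous bands (default 5;
#'   must not exceed `grid_rows`).
#' @param n_genes Total genes (default 200).
#' @param markers_per_domain Exclusive markers per band (default 2).
#' @param base_mean Background NB mean per gene (default 2).
#' @param marker_fold Mean multiplier for a marker inside its band
#'   (default 8, > 1).
#' @param nb_dispersion NB size parameter; smaller = more overdispersed
#'   (default 2).
#' @param seed Integer seed.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(grid_rows = 30, grid_cols = 30, n_domains = 5,
                             n_genes = 200, markers_per_domain = 2,
                             base_mean = 2, marker_fold = 8,
                             nb_dispersion = 2, seed = 0) {
  stopifnot(grid_rows >= 1, grid_cols >= 1, n_domains >= 1,
            n_domains <= grid_rows, n_genes >= 1, markers_per_domain >= 1,
            base_mean > 0, marker_fold > 1 || marker_fold == 1,
            nb_dispersion > 0)
  if (markers_per_domain * n_domains > n_genes)
    stop("markers_per_domain * n_domains must not exceed n_genes")
  structure(list(grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
                 n_domains = as.integer(n_domains), n_genes = as.integer(n_genes),
                 markers_per_domain = as.integer(markers_per_domain),
                 base_mean = base_mean, marker_fold = marker_fold,
                 nb_dispersion = nb_dispersion, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic spatial transcriptomics dataset
#'
#' Spots sit on a triangular lattice (odd rows offset by half a spacing, row
#' pitch `sqrt(3)/2`), giving interior spots six equidistant neighbors as on
#' array-based platforms. Rows are split into `n_domains` near-equal
#' contiguous bands; every gene draws counts from a negative binomial with
#' mean `base_mean`, except each domain's markers, whose mean is
#' `base_mean * marker_fold` inside that domain. Fully reproducible from
#' `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return An [st_dataset()] with `truth_labels` (`"domain_1"`, ...) and
#'   attribute `"marker_map"` (named list domain -> marker gene names).
#' @export
generate_synthetic_st <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  nr <- config$grid_rows; nc <- config$grid_cols
  n <- nr * nc
  row_i <- rep(seq_len(nr), each = nc)
  col_i <- rep(seq_len(nc), times = nr)
  coords <- cbind(x = col_i + 0.5 * (row_i %% 2), y = row_i * sqrt(3) / 2)

  # contiguous near-equal horizontal bands
  band <- cut(row_i, breaks = round(seq(0, nr, length.out = config$n_domains + 1)),
              labels = FALSE)
  truth <- paste0("domain_", band)

  genes <- paste0("gene_", seq_len(config$n_genes))
  marker_idx <- matrix(seq_len(config$markers_per_domain * config$n_domains),
                       nrow = config$n_domains, byrow = TRUE)
  marker_map <- stats::setNames(
    lapply(seq_len(config$n_domains), function(d) genes[marker_idx[d, ]]),
    paste0("domain_", seq_len(config$n_domains)))

  mu <- matrix(config$base_mean, n, config$n_genes)
  for (d in seq_len(config$n_domains))
    mu[band == d, marker_idx[d, ]] <- config$base_mean * config$marker_fold

  counts <- with_seed(config$seed, {
    matrix(stats::rnbinom(n * config$n_genes, size = config$nb_dispersion,
                          mu = as.vector(mu)),
           n, config$n_genes)
  })
  ds <- st_dataset(counts, coords, paste0("spot_", seq_len(n)), genes, truth)
  attr(ds, "marker_map") <- marker_map
  ds
}

round_half_up <- function(x) floor(x + 0.5)   # round half away from zero (x >= 0)

#' Inject label noise per the sampling/masking protocol
#'
#' Samples `round(p * N)` spots uniformly without replacement and gives them
#' labels; a `round(q * |sampled|)`-sized uniform subset of those is
#' reassigned a false label drawn uniformly from the other classes, while the
#' rest keep their true label. Rounding is half-away-from-zero. The
#' complement of the sampled set is the held-out evaluation set.
#'
#' @param truth_labels Complete per-spot truth vector.
#' @param p Fraction of spots to label, in (0, 1].
#' @param q Fraction of those labels to falsify, in [0, 1].
#' @param seed Integer seed.
#' @return List with `labels` (an `identified_labels`), `held_out` (integer
#'   indices of the unsampled spots), and `corrupted` (indices, within the
#'   sampled set, whose label was falsified).
#' @export
inject_label_noise <- function(truth_labels, p, q, seed = 0) {
  n <- length(truth_labels)
  if (p <= 0 || p > 1) stop("p must be in (0, 1]")
  if (q < 0 || q > 1) stop("q must be in [0, 1]")
  classes <- unique(truth_labels)
  if (q > 0 && length(classes) < 2)
    stop("label corruption needs at least 2 classes")
  n_samp <- round_half_up(p * n)
  with_seed(seed, {
    sampled <- sort(sample.int(n, n_samp))
    lab <- as.character(truth_labels[sampled])
    n_corr <- round_half_up(q * n_samp)
    corr <- if (n_corr > 0) sample.int(n_samp, n_corr) else integer(0)
    for (i in corr) {
      others <- setdiff(classes, truth_labels[sampled[i]])
      lab[i] <- if (length(others) == 1L) others else sample(others, 1)
    }
    list(labels = identified_labels(sampled, lab, n),
         held_out = setdiff(seq_len(n), sampled),
         corrupted = sampled[corr])
  })
}

#' Run the label-noise simulation grid
#'
#' For every combination of sampling fraction `p`, noise fraction `q` and
#' replicate: inject noise into the truth labels with a cell-specific seed,
#' fine-tune the pre-trained model on the noisy sparse labels, apply the
#' dynamic clustering switch, and score the result by adjusted Rand index
#' against truth restricted to the held-out (unsampled) spots. Pre-training
#' depends only on the expression and the graph, so it is performed once and
#' shared across all cells.
#'
#' @param dataset An [st_dataset()] with `truth_labels`.
#' @param p_set Sampling fractions (default `c(0.15, 0.2, 0.25, 0.3)`).
#' @param q_set Noise fractions (default `c(0.1, 0.2, 0.3, 0.4, 0.5)`).
#' @param n_reps Replicates per cell (default 10).
#' @param config A [train_config()]; its `seed` also seeds the noise draws
#'   (replicate seed = `seed + 1000 * cell_index`).
#' @param k Spatial graph neighbors (default 3).
#' @param n_hvg Genes kept in preprocessing (default 3000).
#' @param pretrained Optional pre-trained `gnn_params` to reuse; computed
#'   when omitted.
#' @param verbose Print one line per completed cell.
#' @return Data frame with columns `p, q, rep, method_used, ari`.
#' @export
run_simulation_grid <- function(dataset, p_set = c(0.15, 0.2, 0.25, 0.3),
                                q_set = c(0.1, 0.2, 0.3, 0.4, 0.5),
                                n_reps = 10, config = train_config(),
                                k = 3, n_hvg = 3000, pretrained = NULL,
                                verbose = FALSE) {
  stopifnot(inherits(dataset, "st_dataset"))
  if (is.null(dataset$truth_labels)) stop("dataset has no truth labels")
  pp <- preprocess(dataset, n_hvg = n_hvg)
  graph <- build_knn_graph(dataset$coords, k = k)
  if (is.null(pretrained)) pretrained <- pretrain(pp$matrix, graph, config)
  K <- length(unique(dataset$truth_labels))

  grid <- expand.grid(rep = seq_len(n_reps), q = q_set, p = p_set,
                      KEEP.OUT.ATTRS = FALSE)
  out <- vector("list", nrow(grid))
  for (cell in seq_len(nrow(grid))) {
    p <- grid$p[cell]; q <- grid$q[cell]; rep_i <- grid$rep[cell]
    cell_seed <- config$seed + 1000L * cell
    noisy <- inject_label_noise(dataset$truth_labels, p, q, seed = cell_seed)
    ft_config <- config
    ft_config$seed <- cell_seed
    ft <- finetune(pretrained, pp$matrix, graph, noisy$labels, ft_config)
    asg <- dynamic_cluster(ft, pp$matrix, graph, noisy$labels, K,
                           seed = cell_seed)
    held <- noisy$held_out
    ari <- adjusted_rand_index(asg$labels[held], dataset$truth_labels[held])
    out[[cell]] <- data.frame(p = p, q = q, rep = rep_i,
                              method_used = asg$method_used, ari = ari)
    if (verbose)
      message(sprintf("p=%.2f q=%.2f rep=%d  %s  ARI=%.3f",
                      p, q, rep_i, asg$method_used, ari))
  }
  do.call(rbind, out)
}
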