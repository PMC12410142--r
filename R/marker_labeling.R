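#' Parameters for marker-gene label identification
#'
#' @param n_pcs Number of principal components summarizing each spot's
#'   neighborhood expression (default 15).
#' @param cosine_threshold Minimum cosine similarity between the candidate
#'   spot's neighbor-mean PC vector and that of the previously accepted spot
#'   for the candidate to be accepted (default 0.05).
#' @param patience_limit Number of consecutive-or-not rejections tolerated per
#'   cluster before its walk stops (default 10).
#' @param max_frac_per_cluster Per-cluster acceptance cap expressed as a
#'   fraction: cap = `max_frac_per_cluster * n_spot / n_clusters` (default
#'   0.3). Prevents over-identification of small domains.
#' @return A list of class `labeling_params`.
#' @export
labeling_params <- function(n_pcs = 15, cosine_threshold = 0.05,
                            patience_limit = 10, max_frac_per_cluster = 0.3) {
  stopifnot(n_pcs >= 1, cosine_threshold >= -1, cosine_threshold <= 1,
            patience_limit >= 1, max_frac_per_cluster > 0, max_frac_per_cluster <= 1)
  structure(list(n_pcs = as.integer(n_pcs), cosine_threshold = cosine_threshold,
                 patience_limit = as.integer(patience_limit),
                 max_frac_per_cluster = max_frac_per_cluster),
            class = "labeling_params")
}

#' Keep only markers unique to one cluster and present in the data
#'
#' Drops marker genes absent from `gene_names`, then removes any gene listed
#' under two or more clusters from all of them. A cluster left with no marker
#' is an error: it could never be seeded.
#'
#' @param marker_map Named list: cluster name -> character vector of gene
#'   symbols.
#' @param gene_names Genes available in the dataset.
#' @return Filtered marker map (same structure). Clusters with exactly one
#'   surviving marker trigger a warning (ranking then rests on a single gene).
#' @export
filter_unique_markers <- function(marker_map, gene_names) {
  if (length(marker_map) == 0L) stop("marker map is empty")
  present <- lapply(marker_map, function(g) unique(g[g %in% gene_names]))
  all_genes <- unlist(present, use.names = FALSE)
  dup <- unique(all_genes[duplicated(all_genes)])
  out <- lapply(present, function(g) setdiff(g, dup))
  empty <- names(out)[lengths(out) == 0L]
  if (length(empty) > 0L)
    stop("cluster(s) with no unique marker present in the data: ",
         paste(empty, collapse = ", "))
  single <- names(out)[lengths(out) == 1L]
  if (length(single) > 0L)
    warning("cluster(s) with a single marker gene: ", paste(single, collapse = ", "))
  out
}

#' Negative-binomial Pearson residual normalization
#'
#' A variance-stabilizing transform in the spirit of regularized NB
#' regression: each count is compared with its library-size-proportional
#' expectation `mu_ig = lib_i * gene_total_g / grand_total` and standardized
#' by the NB standard deviation with a fixed dispersion,
#' `r = (x - mu) / sqrt(mu + mu^2 / theta)`. Residuals are clipped to
#' `+-sqrt(n_spot)`. All-zero genes yield all-zero residuals.
#'
#' @param counts Non-negative matrix (spots x genes) or an [st_dataset()].
#' @param theta Fixed NB dispersion (default 100; large theta approaches
#'   Poisson residuals).
#' @return Residual matrix, same shape and dimnames.
#' @export
vst_normalize <- function(counts, theta = 100) {
  x <- if (inherits(counts, "st_dataset")) counts$counts else as.matrix(counts)
  if (any(x < 0)) stop("counts must be non-negative")
  lib <- rowSums(x)
  gene_tot <- colSums(x)
  grand <- sum(lib)
  if (grand == 0) stop("all counts are zero")
  mu <- outer(lib, gene_tot) / grand
  denom <- sqrt(mu + mu^2 / theta)
  r <- (x - mu) / denom
  r[denom == 0] <- 0                    # all-zero gene (or zero-library spot)
  clip <- sqrt(nrow(x))
  pmin(pmax(r, -clip), clip)
}

#' Principal component scores of an expression matrix
#'
#' Column-centered PCA; components are ordered by decreasing explained
#' variance and each component's sign is fixed so that its largest-magnitude
#' loading is positive.
#'
#' @param normalized Numeric matrix, spots x genes.
#' @param n_pcs Number of components, at most `min(dim(normalized))`.
#' @return Score matrix, `n_spot x n_pcs`, with attribute `"sdev"` holding the
#'   component standard deviations.
#' @export
compute_pcs <- function(normalized, n_pcs = 15) {
  normalized <- as.matrix(normalized)
  if (n_pcs > min(dim(normalized)))
    stop("n_pcs exceeds min(n_spot, n_gene)")
  pc <- stats::prcomp(normalized, center = TRUE, scale. = FALSE, rank. = n_pcs)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x[, seq_len(n_pcs), drop = FALSE], 2, flip, "*")
  attr(scores, "sdev") <- pc$sdev[seq_len(n_pcs)]
  scores
}

#' Rank spots by marker expression for one cluster
#'
#' For each marker gene of `cluster`, spots get dense ranks with rank 1 for
#' the highest normalized expression; for multi-marker clusters the per-gene
#' ranks are summed and spots are ordered by ascending cumulative rank. Ties
#' resolve toward the lower spot index.
#'
#' @param normalized Normalized expression matrix (spots x genes) with gene
#'   column names.
#' @param marker_map Filtered marker map.
#' @param cluster Cluster name to rank for.
#' @return Integer vector of spot indices, best candidate first.
#' @export
rank_spots <- function(normalized, marker_map, cluster) {
  if (!cluster %in% names(marker_map)) stop("unknown cluster: ", cluster)
  genes <- marker_map[[cluster]]
  missing <- setdiff(genes, colnames(normalized))
  if (length(missing) > 0L) stop("marker gene(s) not in matrix: ",
                                 paste(missing, collapse = ", "))
  n <- nrow(normalized)
  cum <- rep(0, n)
  for (g in genes)
    cum <- cum + rank(-normalized[, g], ties.method = "first")
  order(cum, seq_len(n))
}

#' Sparse spot labels identified from marker genes
#'
#' Implements a spatially-regularized greedy walk per cluster. Spots are
#' ranked by marker expression ([rank_spots()] on [vst_normalize()]d counts).
#' The top-ranked unlabeled spot is accepted unconditionally; each subsequent
#' candidate is accepted only if the mean PC-score vector of its graph
#' neighbors has cosine similarity above `cosine_threshold` with that of the
#' previously accepted spot's neighbors — the idea being that members of one
#' tissue domain are spatial neighbors with coherent local expression. Each
#' rejection increments a patience counter; a cluster's walk stops when
#' patience exceeds `patience_limit` or its acceptance cap is reached. A spot
#' already claimed by an earlier cluster is skipped (first cluster in map
#' order wins).
#'
#' @param dataset An [st_dataset()].
#' @param graph A [build_knn_graph()] result on the same spot order.
#' @param marker_map Named list cluster -> marker genes; filtered internally
#'   via [filter_unique_markers()].
#' @param params A [labeling_params()].
#' @return An object of class `identified_labels`: list with `spots`
#'   (1-based indices), `labels` (cluster names, parallel to `spots`), `p`
#'   (coverage fraction), and `n_spot`.
#' @export
identify_labels <- function(dataset, graph, marker_map, params = labeling_params()) {
  stopifnot(inherits(dataset, "st_dataset"), inherits(graph, "spot_graph"))
  if (nrow(graph$adjacency) != dataset$n_spot)
    stop("graph and dataset disagree on the number of spots")
  marker_map <- suppressWarnings(filter_unique_markers(marker_map, dataset$gene_names))
  n <- dataset$n_spot
  vst <- vst_normalize(dataset)
  pcs <- compute_pcs(vst, params$n_pcs)
  nb_mean <- as.matrix(neighbor_mean_operator(graph) %*% pcs)
  cap <- max(1L, floor(params$max_frac_per_cluster * n / length(marker_map)))

  assigned <- rep(NA_character_, n)
  cosine <- function(a, b) {
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) return(0)
    sum(a * b) / (na * nb)
  }
  for (cl in names(marker_map)) {
    ord <- rank_spots(vst, marker_map, cl)
    accepted <- 0L
    patience <- 0L
    prev <- NA_integer_
    for (s in ord) {
      if (accepted >= cap || patience > params$patience_limit) break
      if (!is.na(assigned[s])) next           # claimed by an earlier cluster
      if (is.na(prev)) {
        ok <- TRUE                            # top-ranked spot: unconditional
      } else {
        ok <- cosine(nb_mean[s, ], nb_mean[prev, ]) > params$cosine_threshold
      }
      if (ok) {
        assigned[s] <- cl
        prev <- s
        accepted <- accepted + 1L
      } else {
        patience <- patience + 1L
      }
    }
    if (accepted == 0L)
      message("cluster '", cl, "' accepted no spots")
  }
  idx <- which(!is.na(assigned))
  structure(list(spots = idx, labels = assigned[idx], p = length(idx) / n, n_spot = n),
            class = "identified_labels")
}

#' Bundle externally supplied labels
#'
#' Wraps user- or simulation-provided sparse labels in the container returned
#' by [identify_labels()], bypassing the marker-gene step.
#'
#' @param spots Integer spot indices (1-based).
#' @param labels Cluster labels, parallel to `spots`.
#' @param n_spot Total number of spots in the dataset.
#' @return An `identified_labels` object.
#' @export
identified_labels <- function(spots, labels, n_spot) {
  spots <- as.integer(spots)
  stopifnot(length(spots) == length(labels), n_spot >= 1,
            all(spots >= 1), all(spots <= n_spot))
  if (anyDuplicated(spots)) stop("a spot can carry at most one label")
  structure(list(spots = spots, labels = as.character(labels),
                 p = length(spots) / n_spot, n_spot = as.integer(n_spot)),
            class = "identified_labels")
}

#' @export
print.identified_labels <- function(x, ...) {
  cat(sprintf("identified_labels: %d of %d spots labeled (p = %.3f), %d cluster(s)\n",
              length(x$spots), x$n_spot, x$p, length(unique(x$labels))))
  invisible(x)
}

#' Read a marker map from CSV or JSON
#'
#' CSV needs columns `cluster,gene`; JSON is an object mapping cluster name to
#' an array of gene symbols.
#'
#' @param path File path ending in `.csv` or `.json`.
#' @return Named list cluster -> character vector of genes.
#' @export
read_marker_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    mm <- jsonlite::read_json(path, simplifyVector = TRUE)
    lapply(mm, as.character)
  } else {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("cluster", "gene") %in% names(tab)))
      stop("marker CSV must have columns cluster, gene")
    split(tab$gene, factor(tab$cluster, levels = unique(tab$cluster)))
  }
}

#' Read sparse spot labels from CSV
#'
#' @param path CSV with columns `spot_id,label`.
#' @param spot_ids Full spot id vector of the dataset (defines indices).
#' @return An `identified_labels` object.
#' @export
read_labels_csv <- function(path, spot_ids) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  idx <- match(tab[[1]], spot_ids)
  if (anyNA(idx)) stop("label file contains spot ids not in the dataset")
  identified_labels(idx, tab[[2]], length(spot_ids))
}

#' Write sparse or full labels to CSV
#'
#' @param labels An `identified_labels` object or a full per-spot vector.
#' @param spot_ids Dataset spot ids.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_labels_csv <- function(labels, spot_ids, path) {
  if (inherits(labels, "identified_labels")) {
    df <- data.frame(spot_id = spot_ids[labels$spots], label = labels$labels)
  } else {
    df <- data.frame(spot_id = spot_ids, label = labels)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
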