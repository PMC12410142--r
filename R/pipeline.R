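#' Run the full clustering pipeline
#'
#' End-to-end orchestration: preprocess (log-normalize, HVG selection), build
#' the spatial k-NN graph, obtain sparse labels (from a marker map via
#' [identify_labels()], or user-supplied, exactly one of the two), pre-train
#' the graph autoencoder with contrastive learning, fine-tune the classifier
#' with the accuracy early stop, then assign every spot through the dynamic
#' GMM/classifier switch. Optionally writes labels, embeddings, the training
#' log and an ARI report to `out_dir`.
#'
#' @param dataset An [st_dataset()].
#' @param marker_map Named list cluster -> marker genes (mutually exclusive
#'   with `labels`).
#' @param labels An `identified_labels` object with user-supplied sparse
#'   labels (mutually exclusive with `marker_map`).
#' @param K Number of clusters; defaults to the number of distinct label
#'   values.
#' @param k Spatial neighbors per spot (default 3).
#' @param n_hvg Genes kept in preprocessing (default 3000).
#' @param config A [train_config()].
#' @param labeling A [labeling_params()] (marker path only).
#' @param pretrained Optional pre-trained `gnn_params` to reuse.
#' @param out_dir Optional output directory.
#' @param verbose Print stage progress.
#' @return List with `assignment` (a `cluster_assignment`), `embeddings`
#'   (fine-tuned encoder output), `labels` (the sparse labels used, with
#'   coverage `p`), `params`, `graph`, and `report` (data frame of run
#'   metrics; includes held-in ARI vs truth when the dataset carries truth
#'   labels).
#' @export
run_pipeline <- function(dataset, marker_map = NULL, labels = NULL, K = NULL,
                         k = 3, n_hvg = 3000, config = train_config(),
                         labeling = labeling_params(), pretrained = NULL,
                         out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(dataset, "st_dataset"))
  if (is.null(marker_map) == is.null(labels))
    stop("provide exactly one of marker_map or labels")
  say <- function(...) if (verbose) message(sprintf(...))

  say("preprocess: %d spots, %d genes -> up to %d HVGs", dataset$n_spot,
      dataset$n_gene, n_hvg)
  pp <- preprocess(dataset, n_hvg = n_hvg)
  graph <- build_knn_graph(dataset$coords, k = k)

  if (!is.null(marker_map)) {
    say("identify labels from %d marker clusters", length(marker_map))
    labels <- identify_labels(dataset, graph, marker_map, labeling)
  } else if (!inherits(labels, "identified_labels")) {
    stop("labels must be an identified_labels object (see identified_labels())")
  }
  if (length(labels$spots) == 0L) stop("no labeled spots available")
  if (is.null(K)) K <- length(unique(labels$labels))
  say("labels: %d spots (p = %.3f), K = %d", length(labels$spots), labels$p, K)

  if (is.null(pretrained)) {
    say("pre-train: %d epochs (seed %d)", config$pretrain_epochs, config$seed)
    pretrained <- pretrain(pp$matrix, graph, config)
  }
  say("fine-tune: up to %d epochs, early stop at accuracy > %.2f",
      config$finetune_max_epochs, config$early_stop_accuracy)
  ft <- finetune(pretrained, pp$matrix, graph, labels, config)
  asg <- dynamic_cluster(ft, pp$matrix, graph, labels, K, seed = config$seed)
  emb <- encode(pp$matrix, graph, ft)
  say("assignment by %s", asg$method_used)

  fh <- attr(ft, "finetune_history")
  report <- data.frame(
    n_spot = dataset$n_spot, n_gene_used = ncol(pp$matrix), K = K,
    p = labels$p, method_used = asg$method_used,
    finetune_epochs = nrow(fh),
    finetune_accuracy = if (nrow(fh) > 0) fh$accuracy[nrow(fh)] else NA_real_)
  if (!is.null(dataset$truth_labels))
    report$ari_vs_truth <- adjusted_rand_index(asg$labels, dataset$truth_labels)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_assignment(asg, dataset$spot_ids, file.path(out_dir, "labels.csv"),
                     truth = dataset$truth_labels)
    emb_df <- data.frame(spot_id = dataset$spot_ids, emb)
    names(emb_df)[-1] <- paste0("dim_", seq_len(ncol(emb)))
    utils::write.csv(emb_df, file.path(out_dir, "embeddings.csv"), row.names = FALSE)
    if (!is.null(attr(pretrained, "history")))
      write_training_log(pretrained, file.path(out_dir, "training_log.csv"))
    utils::write.csv(report, file.path(out_dir, "report.csv"), row.names = FALSE)
  }
  list(assignment = asg, embeddings = emb, labels = labels, params = ft,
       graph = graph, report = report)
}
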