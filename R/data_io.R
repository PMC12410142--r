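#' Construct a spatial transcriptomics dataset
#'
#' Bundles a raw spot-by-gene count matrix with 2-D spot coordinates and
#' identifiers into the container used by every downstream step. Spots are
#' rows throughout the package; the row order of `coords` is canonical and
#' shared by all derived matrices (graph, embeddings, labels).
#'
#' @param counts Non-negative numeric matrix, spots in rows, genes in columns.
#'   A `Matrix` sparse matrix is accepted and densified lazily where needed.
#' @param coords Numeric matrix or data frame with two columns (x, y), one row
#'   per spot, finite entries.
#' @param spot_ids Character vector of unique spot identifiers, one per row.
#' @param gene_names Character vector of unique gene symbols, one per column.
#' @param truth_labels Optional vector of ground-truth domain labels per spot,
#'   used only for evaluation.
#' @return An object of class `st_dataset`: a list with elements `counts`,
#'   `coords`, `spot_ids`, `gene_names`, `truth_labels`, `n_spot`, `n_gene`.
#' @examples
#' d <- st_dataset(matrix(0:5, 2, 3), cbind(c(0, 1), c(0, 0)),
#'                 c("s1", "s2"), c("g1", "g2", "g3"))
#' d$n_spot
#' @export
st_dataset <- function(counts, coords, spot_ids, gene_names, truth_labels = NULL) {
  counts <- as.matrix(counts)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (nrow(coords) != nrow(counts))
    stop("counts and coords must have the same number of spots (rows)")
  if (ncol(coords) != 2L)
    stop("coords must have exactly two columns (x, y)")
  if (length(spot_ids) != nrow(counts))
    stop("spot_ids length must equal the number of spots")
  if (length(gene_names) != ncol(counts))
    stop("gene_names length must equal the number of genes")
  if (anyDuplicated(spot_ids)) stop("spot_ids contain duplicates")
  if (anyDuplicated(gene_names)) stop("gene_names contain duplicates")
  if (any(!is.finite(coords))) stop("coordinates must be finite")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!is.null(truth_labels) && length(truth_labels) != nrow(counts))
    stop("truth_labels length must equal the number of spots")
  rownames(counts) <- spot_ids
  colnames(counts) <- gene_names
  rownames(coords) <- spot_ids
  colnames(coords) <- c("x", "y")
  structure(list(
    counts = counts, coords = coords,
    spot_ids = as.character(spot_ids), gene_names = as.character(gene_names),
    truth_labels = truth_labels,
    n_spot = nrow(counts), n_gene = ncol(counts)
  ), class = "st_dataset")
}

#' @export
print.st_dataset <- function(x, ...) {
  cat(sprintf("st_dataset: %d spots x %d genes%s\n", x$n_spot, x$n_gene,
              if (is.null(x$truth_labels)) "" else
                sprintf(", %d truth domains", length(unique(x$truth_labels)))))
  invisible(x)
}

#' Load a spatial dataset from disk
#'
#' Reads counts either from a 10x-style Matrix Market triplet
#' (`matrix.mtx` + `barcodes.tsv` + `features.tsv` in one directory, genes x
#' spots or spots x genes auto-detected from the companion file lengths) or
#' from a dense CSV whose header row holds gene names and whose first column
#' holds spot ids. Coordinates come from a CSV with columns
#' `spot_id, x, y`. Spots are aligned by id to the coordinate-file order;
#' spots present in only one file are dropped with a warning.
#'
#' @param count_path Path to a `.mtx` file (its directory must also contain
#'   `barcodes.tsv` and `features.tsv`) or to a dense counts CSV.
#' @param coord_path Path to the coordinates CSV (`spot_id,x,y`).
#' @param label_path Optional path to a truth-label CSV (`spot_id,label`).
#' @return An [st_dataset()].
#' @export
load_st_dataset <- function(count_path, coord_path, label_path = NULL) {
  for (p in c(count_path, coord_path, label_path))
    if (!file.exists(p)) stop("file not found: ", p)
  if (grepl("\\.mtx$", count_path)) {
    dir <- dirname(count_path)
    bpath <- file.path(dir, "barcodes.tsv")
    fpath <- file.path(dir, "features.tsv")
    if (!file.exists(bpath) || !file.exists(fpath))
      stop("Matrix Market input needs barcodes.tsv and features.tsv beside ", count_path)
    m <- as.matrix(Matrix::readMM(count_path))
    barcodes <- utils::read.table(bpath, sep = "\t", header = FALSE,
                                  stringsAsFactors = FALSE)[[1]]
    feats <- utils::read.table(fpath, sep = "\t", header = FALSE,
                               stringsAsFactors = FALSE)
    genes <- feats[[min(2L, ncol(feats))]]
    if (nrow(m) == length(genes) && ncol(m) == length(barcodes)) {
      m <- t(m)                        # 10x convention: genes x spots
    } else if (!(nrow(m) == length(barcodes) && ncol(m) == length(genes))) {
      stop("matrix dimensions match neither barcodes x features nor its transpose")
    }
    rownames(m) <- barcodes
    colnames(m) <- genes
  } else {
    tab <- utils::read.csv(count_path, check.names = FALSE, row.names = 1)
    m <- as.matrix(tab)
  }
  if (any(m < 0)) stop("negative counts in ", count_path)

  co <- utils::read.csv(coord_path, stringsAsFactors = FALSE)
  if (!all(c("spot_id", "x", "y") %in% names(co)))
    stop("coordinate file must have columns spot_id, x, y")
  keep <- intersect(co$spot_id, rownames(m))
  if (length(keep) == 0L) stop("no overlapping spot ids between counts and coordinates")
  n_drop <- (nrow(co) - length(keep)) + (nrow(m) - length(keep))
  if (n_drop > 0L)
    warning(sprintf("dropping %d spot(s) present in only one of counts/coordinates", n_drop))
  co <- co[co$spot_id %in% keep, , drop = FALSE]  # canonical order: coord file
  m <- m[co$spot_id, , drop = FALSE]

  truth <- NULL
  if (!is.null(label_path)) {
    lab <- utils::read.csv(label_path, stringsAsFactors = FALSE)
    truth <- lab[[2]][match(co$spot_id, lab[[1]])]
  }
  st_dataset(m, cbind(co$x, co$y), co$spot_id, colnames(m), truth)
}

#' Write a spatial dataset as the standard file set
#'
#' Emits `matrix.mtx` (spots x genes), `barcodes.tsv`, `features.tsv`,
#' `coords.csv`, and, when present, `truth_labels.csv` and `markers.csv`
#' into `dir`. The files round-trip through [load_st_dataset()].
#'
#' @param dataset An [st_dataset()].
#' @param dir Output directory (created if missing).
#' @param marker_map Optional named list mapping cluster name to a character
#'   vector of marker genes, written as a two-column `cluster,gene` CSV.
#' @return Invisibly, the paths written.
#' @export
write_st_dataset <- function(dataset, dir, marker_map = NULL) {
  stopifnot(inherits(dataset, "st_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mtx <- file.path(dir, "matrix.mtx")
  Matrix::writeMM(methods::as(Matrix::Matrix(dataset$counts, sparse = TRUE), "generalMatrix"), mtx)
  writeLines(dataset$spot_ids, file.path(dir, "barcodes.tsv"))
  writeLines(dataset$gene_names, file.path(dir, "features.tsv"))
  utils::write.csv(data.frame(spot_id = dataset$spot_ids,
                              x = dataset$coords[, 1], y = dataset$coords[, 2]),
                   file.path(dir, "coords.csv"), row.names = FALSE)
  paths <- c(mtx, file.path(dir, c("barcodes.tsv", "features.tsv", "coords.csv")))
  if (!is.null(dataset$truth_labels)) {
    p <- file.path(dir, "truth_labels.csv")
    utils::write.csv(data.frame(spot_id = dataset$spot_ids, label = dataset$truth_labels),
                     p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(marker_map)) {
    p <- file.path(dir, "markers.csv")
    utils::write.csv(data.frame(
      cluster = rep(names(marker_map), lengths(marker_map)),
      gene = unlist(marker_map, use.names = FALSE)), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Library-size normalization followed by log1p
#'
#' Scales each spot's counts so its total equals `target_sum` (the median of
#' per-spot totals by default, the standard single-cell workflow), then applies
#' `log(1 + x)` elementwise. Spots with zero total count stay all-zero rows and
#' trigger a warning so the graph keeps its alignment with the coordinates.
#'
#' @param dataset An [st_dataset()], or a bare non-negative matrix.
#' @param target_sum Positive number, or `"median"` for the median per-spot
#'   total.
#' @return Numeric matrix of log-normalized expression, same shape and
#'   dimnames as the counts.
#' @export
log_normalize <- function(dataset, target_sum = "median") {
  x <- if (inherits(dataset, "st_dataset")) dataset$counts else as.matrix(dataset)
  totals <- rowSums(x)
  if (all(totals == 0)) stop("all spots have zero total count")
  if (identical(target_sum, "median")) {
    target <- stats::median(totals[totals > 0])
  } else {
    target <- as.numeric(target_sum)
    if (!is.finite(target) || target <= 0) stop("target_sum must be positive")
  }
  if (any(totals == 0))
    warning(sprintf("%d spot(s) with zero total count kept as zero rows", sum(totals == 0)))
  scale <- ifelse(totals > 0, target / totals, 0)
  log1p(x * scale)
}

#' Select highly variable genes
#'
#' Ranks genes by the variance of their (log-normalized) expression across
#' spots and keeps the top `n_hvg`, preserving the original column order among
#' the kept genes. With `n_hvg >= ncol` the input passes through unchanged.
#'
#' @param normalized Numeric matrix, spots x genes.
#' @param gene_names Character vector naming the columns.
#' @param n_hvg Number of genes to keep (default 3000).
#' @return List with `matrix` (reduced) and `genes` (kept names, input order).
#' @export
select_hvg <- function(normalized, gene_names = colnames(normalized), n_hvg = 3000) {
  normalized <- as.matrix(normalized)
  if (n_hvg < 1) stop("n_hvg must be >= 1")
  if (is.null(gene_names)) gene_names <- paste0("g", seq_len(ncol(normalized)))
  if (n_hvg >= ncol(normalized))
    return(list(matrix = normalized, genes = as.character(gene_names)))
  v <- apply(normalized, 2, stats::var)
  keep <- sort(order(v, decreasing = TRUE)[seq_len(n_hvg)])
  list(matrix = normalized[, keep, drop = FALSE], genes = as.character(gene_names[keep]))
}

#' Preprocess counts for the graph model
#'
#' Convenience wrapper: [log_normalize()] then [select_hvg()], the order used
#' by the standard workflow.
#'
#' @inheritParams log_normalize
#' @inheritParams select_hvg
#' @return As [select_hvg()].
#' @export
preprocess <- function(dataset, n_hvg = 3000, target_sum = "median") {
  gn <- if (inherits(dataset, "st_dataset")) dataset$gene_names else colnames(dataset)
  select_hvg(log_normalize(dataset, target_sum), gn, n_hvg)
}
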