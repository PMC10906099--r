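#' Construct a timecourse dataset
#'
#' The central container of the package: a sparse cells-by-genes count
#' matrix with per-cell metadata (time point on a declared grid, batch,
#' anatomical section, optional state label), per-gene metadata, optional
#' normalized layer and embedding, optional ground-truth terminal-fate
#' probabilities (from simulation), and free-form provenance.
#'
#' @param counts cells x genes matrix of nonnegative integer counts (coerced
#'   to sparse `dgCMatrix`); rownames are cell ids, colnames gene ids.
#' @param cell_table data.frame with at least `cell_id`, `time_point`,
#'   `batch_id`, `section_id`; one row per cell, in counts row order.
#' @param gene_table data.frame with at least `gene_id`; defaults to the
#'   counts colnames with no blacklist flags.
#' @param time_grid Declared grid of days; every `time_point` must lie on it.
#' @param fate_probs Optional cells x terminal-states matrix of ground-truth
#'   fate probabilities (rows on the simplex).
#' @param ground_truth Optional list of simulation-side truths (tree, batch
#'   offsets, ...).
#' @param layers,embedding Optional derived data.
#' @param provenance Optional list recording how the object was made.
#' @return An object of class `timecourse_dataset`.
#' @export
timecourse_dataset <- function(counts, cell_table, gene_table = NULL,
                               time_grid = NULL, fate_probs = NULL,
                               ground_truth = NULL, layers = NULL,
                               embedding = NULL, provenance = NULL) {
  counts <- as_sparse_counts(counts)
  if (is.null(gene_table)) {
    gene_table <- data.frame(gene_id = colnames(counts),
                             blacklist = FALSE, stringsAsFactors = FALSE)
  }
  if (is.null(time_grid)) time_grid <- sort(unique(cell_table$time_point))
  ds <- structure(list(counts = counts, cell_table = cell_table,
                       gene_table = gene_table, time_grid = time_grid,
                       fate_probs = fate_probs, ground_truth = ground_truth,
                       layers = layers %||% list(), embedding = embedding,
                       provenance = provenance %||% list()),
                  class = "timecourse_dataset")
  validate_timecourse_dataset(ds)
  ds
}

#' Validate a timecourse dataset
#'
#' Enforces the container invariants: unique cell ids matching the counts
#' rows, mandatory metadata columns, time points on the declared grid,
#' nonnegative integer counts, and ground-truth fate rows on the simplex.
#'
#' @param ds A `timecourse_dataset`.
#' @return `ds` invisibly; errors on violation.
#' @export
validate_timecourse_dataset <- function(ds) {
  ct <- ds$cell_table
  need <- c("cell_id", "time_point", "batch_id", "section_id")
  miss <- setdiff(need, names(ct))
  if (length(miss)) stop("cell_table is missing mandatory column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(ct$cell_id)) stop("cell_ids must be unique.")
  if (nrow(ds$counts) != nrow(ct)) stop("counts rows != cell_table rows.")
  if (!is.null(rownames(ds$counts)) && nrow(ct) > 0 &&
      !identical(rownames(ds$counts), ct$cell_id)) {
    stop("counts rownames must equal cell_table$cell_id in order.")
  }
  if (!all(ct$time_point %in% ds$time_grid)) {
    bad <- setdiff(unique(ct$time_point), ds$time_grid)
    stop("time_point(s) off the declared grid: ", paste(bad, collapse = ", "))
  }
  x <- ds$counts@x
  if (length(x) && (any(x < 0) || any(abs(x - round(x)) > 1e-8))) {
    stop("counts must be nonnegative integers.")
  }
  if (!is.null(ds$fate_probs) && nrow(ds$fate_probs) > 0) {
    rs <- rowSums(ds$fate_probs)
    if (any(abs(rs - 1) > 1e-9)) {
      stop("ground-truth fate probability rows must sum to 1 (+/- 1e-9).")
    }
  }
  invisible(ds)
}

#' @exportS3Method base::print
print.timecourse_dataset <- function(x, ...) {
  cat(sprintf("timecourse_dataset: %d cells x %d genes, %d time points (%s)\n",
              nrow(x$counts), ncol(x$counts), length(x$time_grid),
              paste(x$time_grid, collapse = ", ")))
  cat(sprintf("  batches: %s | layers: %s | embedding: %s | ground truth: %s\n",
              paste(unique(x$cell_table$batch_id), collapse = ","),
              paste(names(x$layers), collapse = ",") ,
              if (is.null(x$embedding)) "none" else "present",
              if (is.null(x$fate_probs)) "none" else "present"))
  invisible(x)
}

#' Subset a timecourse dataset by cells
#'
#' All per-cell slots (metadata, layers, embedding, ground-truth fate
#' probabilities) are carried forward consistently.
#'
#' @param ds A `timecourse_dataset`.
#' @param cells Logical mask, integer indices, or cell ids.
#' @return The subset `timecourse_dataset`.
#' @export
subset_cells <- function(ds, cells) {
  if (is.character(cells)) cells <- match(cells, ds$cell_table$cell_id)
  if (is.logical(cells)) cells <- which(cells)
  ds$counts <- ds$counts[cells, , drop = FALSE]
  ds$cell_table <- ds$cell_table[cells, , drop = FALSE]
  rownames(ds$cell_table) <- NULL
  if (!is.null(ds$fate_probs)) ds$fate_probs <- ds$fate_probs[cells, , drop = FALSE]
  ds$layers <- lapply(ds$layers, function(m) m[cells, , drop = FALSE])
  if (!is.null(ds$embedding)) {
    ds$embedding$coords <- ds$embedding$coords[cells, , drop = FALSE]
  }
  ds
}

#' Write a timecourse dataset to plain-text files
#'
#' Serialises counts as Matrix Market (`counts.mtx`), cell and gene metadata
#' as TSV (`cells.tsv`, `genes.tsv`), and a JSON sidecar
#' (`ground_truth.json`) carrying the time grid plus any ground-truth fate
#' probabilities and batch offsets. The round trip through
#' [read_dataset()] is lossless.
#'
#' @param ds A `timecourse_dataset`.
#' @param path Directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create directory: ", path)
  Matrix::writeMM(ds$counts, file.path(path, "counts.mtx"))
  utils::write.table(ds$cell_table, file.path(path, "cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ds$gene_table, file.path(path, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gt <- list(time_grid = ds$time_grid)
  if (!is.null(ds$fate_probs)) {
    gt$fate_states <- colnames(ds$fate_probs)
    gt$fate_probs <- unname(apply(ds$fate_probs, 1, as.numeric, simplify = FALSE))
  }
  if (!is.null(ds$ground_truth$batch_offsets)) {
    bo <- ds$ground_truth$batch_offsets
    gt$batch_offsets <- list(batches = rownames(bo), genes = colnames(bo),
                             values = unname(apply(bo, 1, as.numeric,
                                                   simplify = FALSE)))
  }
  jsonlite::write_json(gt, file.path(path, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dataset
#' @export
write_fixture <- write_dataset

#' Read a timecourse dataset written by [write_dataset()]
#'
#' Gzip-compressed `counts.mtx.gz` / `cells.tsv.gz` / `genes.tsv.gz` are
#' accepted transparently. A missing ground-truth sidecar is not an error:
#' the dataset loads with ground truth absent.
#'
#' @param path Directory containing the fixture files.
#' @return A `timecourse_dataset`.
#' @export
read_dataset <- function(path) {
  pick <- function(base) {
    for (f in file.path(path, c(base, paste0(base, ".gz")))) {
      if (file.exists(f)) return(f)
    }
    stop("missing file: ", file.path(path, base))
  }
  mtx <- pick("counts.mtx")
  counts <- tryCatch({
    if (grepl("\\.gz$", mtx)) {
      con <- gzfile(mtx); on.exit(close(con), add = TRUE)
      Matrix::readMM(con)
    } else Matrix::readMM(mtx)
  }, error = function(e) {
    stop("malformed Matrix Market file '", mtx, "': ", conditionMessage(e))
  })
  read_tsv0 <- function(f) utils::read.delim(f, sep = "\t", header = TRUE,
                                             stringsAsFactors = FALSE,
                                             colClasses = NA)
  cells <- read_tsv0(pick("cells.tsv"))
  genes <- read_tsv0(pick("genes.tsv"))
  cells$cell_id <- as.character(cells$cell_id)
  genes$gene_id <- as.character(genes$gene_id)
  need <- c("cell_id", "time_point", "batch_id", "section_id")
  miss <- setdiff(need, names(cells))
  if (length(miss)) stop("cells.tsv is missing mandatory column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(counts) != nrow(cells)) {
    stop("counts has ", nrow(counts), " rows but cells.tsv has ",
         nrow(cells), " rows.")
  }
  dimnames(counts) <- list(cells$cell_id, genes$gene_id)

  fate_probs <- NULL; ground_truth <- NULL; time_grid <- NULL
  gt_file <- file.path(path, "ground_truth.json")
  if (file.exists(gt_file)) {
    gt <- jsonlite::read_json(gt_file, simplifyVector = TRUE)
    time_grid <- gt$time_grid
    if (!is.null(gt$fate_probs)) {
      fp <- gt$fate_probs
      if (is.list(fp)) fp <- do.call(rbind, fp)
      fate_probs <- as.matrix(fp)
      dimnames(fate_probs) <- list(cells$cell_id, gt$fate_states)
    }
    if (!is.null(gt$batch_offsets)) {
      bo <- gt$batch_offsets
      vals <- bo$values
      if (is.list(vals)) vals <- do.call(rbind, vals)
      dimnames(vals) <- list(bo$batches, bo$genes)
      ground_truth <- list(batch_offsets = vals)
    }
  }
  timecourse_dataset(counts, cells, genes, time_grid = time_grid,
                     fate_probs = fate_probs, ground_truth = ground_truth)
}
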