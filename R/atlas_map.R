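#' Jointly embed a query dataset into a reference space
#'
#' Counts from reference and query are merged on their shared genes,
#' normalized and log-transformed together; highly variable genes and
#' principal components are computed once on the merged data; the query is
#' then rescaled onto the reference by MNN correction, treating each query
#' chunk as an incoming batch. Queries larger than `chunk_size` are split
#' into contiguous blocks after a seeded shuffle and the corrected chunks
#' are concatenated back in the original cell order.
#'
#' @param reference,query `timecourse_dataset` objects sharing gene ids.
#' @param n_components Components of the joint PCA (default 50).
#' @param chunk_size Maximum query cells corrected at once (default 10000).
#' @param k_mnn,sigma_frac Passed to [mnn_correct()].
#' @param hvg_fdr Passed to [select_hvgs()].
#' @param seed Seed for the chunk shuffle (logged in the result).
#' @return List with `ref` and `query` embeddings in the shared corrected
#'   space, the `genes` used, and the chunking used.
#' @export
joint_embed <- function(reference, query, n_components = 50,
                        chunk_size = 10000, k_mnn = 20, sigma_frac = 0.5,
                        hvg_fdr = 0.05, seed = 1L) {
  shared <- intersect(colnames(reference$counts), colnames(query$counts))
  if (length(shared) == 0L) {
    stop("no shared genes between reference (", ncol(reference$counts),
         " genes) and query (", ncol(query$counts), " genes).")
  }
  ref_counts <- reference$counts[, shared, drop = FALSE]
  qry_counts <- query$counts[, shared, drop = FALSE]
  merged <- rbind(ref_counts, qry_counts)
  sf <- compute_size_factors(merged)
  norm <- log_normalize(merged, sf)
  hvg <- select_hvgs(norm, fdr = hvg_fdr)
  genes <- hvg$gene_id[hvg$selected]
  if (length(genes) < n_components) {
    genes <- hvg$gene_id[order(hvg$p)][
      seq_len(min(length(shared), max(n_components, 20)))]
  }
  n_comp <- min(n_components, length(genes), nrow(merged) - 1L)
  emb <- embed_pca(norm, genes, n_comp)

  n_ref <- nrow(ref_counts)
  ref_coords <- emb$coords[seq_len(n_ref), , drop = FALSE]
  qry_coords <- emb$coords[-seq_len(n_ref), , drop = FALSE]

  n_q <- nrow(qry_coords)
  rng <- local_rng(seed)
  ord <- if (n_q > chunk_size) sample.int(n_q) else seq_len(n_q)
  n_chunks <- max(1L, ceiling(n_q / chunk_size))
  chunk_of <- integer(n_q)
  chunk_of[ord] <- rep(seq_len(n_chunks),
                       each = ceiling(n_q / n_chunks))[seq_len(n_q)]
  corrected <- matrix(NA_real_, n_q, n_comp,
                      dimnames = dimnames(qry_coords))
  for (ch in seq_len(n_chunks)) {
    idx <- which(chunk_of == ch)
    blocks <- list(reference = ref_coords,
                   query = qry_coords[idx, , drop = FALSE])
    mc <- mnn_correct(blocks, k_mnn = k_mnn, sigma_frac = sigma_frac,
                      merge_order = c("reference", "query"))
    corrected[idx, ] <- mc$coords[rownames(qry_coords)[idx], , drop = FALSE]
  }
  list(ref = structure(list(coords = ref_coords, n_components = n_comp,
                            provenance = "joint_pca", genes = genes),
                       class = "embedding"),
       query = structure(list(coords = corrected, n_components = n_comp,
                              provenance = "mnn_corrected", genes = genes),
                         class = "embedding"),
       genes = genes, n_chunks = n_chunks, chunk_seed = seed)
}

#' Transfer labels from a reference by the mode of k nearest neighbours
#'
#' For each query cell, finds its `k` nearest reference cells (exact
#' Euclidean KNN in the shared embedding) and assigns the most frequent
#' label among them. Ties are broken by the label of the nearest neighbour
#' among the tied labels, then lexicographically. Confidence is the mode
#' count divided by `k`.
#'
#' @param ref_emb Reference cells x components matrix (or `embedding`).
#' @param ref_labels Vector of reference labels, one per reference cell.
#' @param query_emb Query cells x components matrix (or `embedding`).
#' @param k Number of neighbours (stage transfer conventionally uses 30,
#'   fine cell types 10, deep-coverage query cells 15).
#' @return A `transfer_result` data.frame: `cell_id`, `label`, `k`,
#'   `confidence`, `nearest_id`, `nearest_distance`, plus the neighbour
#'   label counts as a list column.
#' @export
transfer_labels <- function(ref_emb, ref_labels, query_emb, k) {
  R <- if (inherits(ref_emb, "embedding")) ref_emb$coords else as.matrix(ref_emb)
  Q <- if (inherits(query_emb, "embedding")) query_emb$coords else as.matrix(query_emb)
  if (k < 1) stop("k must be >= 1.")
  if (k > nrow(R)) stop("k (", k, ") exceeds the reference size (",
                        nrow(R), ").")
  if (length(ref_labels) != nrow(R)) stop("one label per reference cell required.")
  ref_labels <- as.character(ref_labels)
  d2 <- cross_dist2(Q, R)
  out <- vector("list", nrow(Q))
  for (i in seq_len(nrow(Q))) {
    ord <- order(d2[i, ], seq_len(ncol(d2)))[seq_len(k)]
    labs <- ref_labels[ord]
    tab <- table(labs)
    top <- names(tab)[tab == max(tab)]
    lab <- if (length(top) == 1L) top else {
      # nearest neighbour among tied labels, then lexicographic
      first_hit <- vapply(sort(top), function(l) match(l, labs), 0L)
      sort(top)[which.min(first_hit)]
    }
    out[[i]] <- data.frame(
      label = lab, k = k, confidence = max(tab) / k,
      nearest_id = rownames(R)[ord[1]] %||% as.character(ord[1]),
      nearest_distance = sqrt(d2[i, ord[1]]),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- cbind(data.frame(cell_id = rownames(Q) %||%
                            as.character(seq_len(nrow(Q))),
                          stringsAsFactors = FALSE), res)
  rownames(res) <- NULL
  structure(res, class = c("transfer_result", "data.frame"))
}

#' Exact nearest reference cell for each query cell
#'
#' Brute-force (exact, not approximate) nearest neighbour under Euclidean
#' distance; used to anchor query cells to the atlas before fate lookup.
#'
#' @param ref_emb Reference cells x components matrix (or `embedding`).
#' @param query_emb Query cells x components matrix (or `embedding`).
#' @return Data.frame `cell_id`, `nearest_id`, `nearest_distance` (empty
#'   for an empty query).
#' @export
nearest_reference_cells <- function(ref_emb, query_emb) {
  R <- if (inherits(ref_emb, "embedding")) ref_emb$coords else as.matrix(ref_emb)
  Q <- if (inherits(query_emb, "embedding")) query_emb$coords else as.matrix(query_emb)
  if (nrow(R) == 0L) stop("reference embedding is empty.")
  if (nrow(Q) == 0L) {
    return(data.frame(cell_id = character(0), nearest_id = character(0),
                      nearest_distance = numeric(0)))
  }
  d2 <- cross_dist2(Q, R)
  j <- apply(d2, 1, which.min)
  data.frame(cell_id = rownames(Q) %||% as.character(seq_len(nrow(Q))),
             nearest_id = rownames(R)[j] %||% as.character(j),
             nearest_distance = sqrt(d2[cbind(seq_len(nrow(Q)), j)]),
             stringsAsFactors = FALSE)
}
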