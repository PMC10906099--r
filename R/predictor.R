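#' Predict query-cell fates via the nearest atlas cell
#'
#' Each query cell inherits the fate-matrix row of its nearest reference
#' (atlas) cell; the predicted fate is the arg-max of that row. Arg-max
#' ties are broken lexicographically and flagged.
#'
#' @param transfer A `transfer_result` (or any data.frame with `cell_id`
#'   and `nearest_id`) anchoring query cells to atlas cells, e.g. from
#'   [transfer_labels()] or [nearest_reference_cells()].
#' @param fm A `fate_matrix` covering every `nearest_id`.
#' @return Data.frame `cell_id`, `nearest_id`, `fate`, `probability`,
#'   `tie`.
#' @export
predict_query_fates <- function(transfer, fm) {
  missing <- setdiff(transfer$nearest_id, rownames(fm$probs))
  if (length(missing)) {
    stop("nearest atlas cell(s) absent from the fate matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  rows <- fm$probs[transfer$nearest_id, , drop = FALSE]
  ord <- order(colnames(rows))                 # lexicographic tie-break
  rows <- rows[, ord, drop = FALSE]
  j <- max.col(rows, ties.method = "first")
  prob <- rows[cbind(seq_len(nrow(rows)), j)]
  tie <- rowSums(rows == prob) > 1L
  data.frame(cell_id = transfer$cell_id, nearest_id = transfer$nearest_id,
             fate = colnames(rows)[j], probability = prob, tie = tie,
             stringsAsFactors = FALSE)
}

#' Region-by-fate fraction table (fate plot data)
#'
#' Tallies fate assignments within each query region into row-normalized
#' fractions, zero-filling fates absent from a region. Rows may be based
#' on individual cell counts (transcriptional fates) or on embryo counts
#' (microscopically observed fates); the basis is recorded.
#'
#' @param assignments Data.frame with columns `region` and `fate`, one row
#'   per cell (or per embryo-fate observation); an optional `count` column
#'   gives weights.
#' @param basis `"cell_counts"` or `"embryo_counts"` (bookkeeping only).
#' @return A `fate_fraction_table`: regions x fates matrix of fractions
#'   (rows sum to 1) with attributes `counts` (the raw tallies) and
#'   `basis`. Regions with no cells are dropped with a warning.
#' @export
fate_fraction_table <- function(assignments, basis = "cell_counts") {
  stopifnot(all(c("region", "fate") %in% names(assignments)))
  w <- assignments$count %||% rep(1, nrow(assignments))
  counts <- tapply(w, list(region = assignments$region,
                           fate = assignments$fate), sum, default = 0)
  counts <- as.matrix(counts)
  empty <- rowSums(counts) == 0
  if (any(empty)) {
    warning("dropping region(s) with no cells: ",
            paste(rownames(counts)[empty], collapse = ", "))
    counts <- counts[!empty, , drop = FALSE]
  }
  frac <- counts / rowSums(counts)
  structure(frac, counts = counts, basis = basis,
            class = c("fate_fraction_table", class(frac)))
}

#' Concordance between predicted and observed fate tables
#'
#' Harmonizes fate names (via an optional mapping), restricts both tables
#' to their shared fates, re-normalizes rows, and reports per-region
#' cosine similarity and Spearman rank correlation plus their means. A
#' seeded permutation baseline (regions of the second table shuffled)
#' contextualizes the matched scores; the metric itself is symmetric in
#' the two tables.
#'
#' @param predicted,observed `fate_fraction_table`s (or plain matrices)
#'   over the same regions.
#' @param fate_map Optional named character vector renaming `observed`
#'   fates into `predicted` fate names (e.g. anatomical labels to cell
#'   types); never fuzzy-matched.
#' @param n_permutations Permutations for the baseline (default 1000).
#' @param seed Seed for the permutation baseline.
#' @return List with `per_region` (data.frame of cosine and Spearman per
#'   region), `mean_cosine`, `mean_spearman`, `baseline_mean_cosine`,
#'   `perm_p` (fraction of permutations with mean cosine >= observed), and
#'   the shared fate set.
#' @export
concordance_score <- function(predicted, observed, fate_map = NULL,
                              n_permutations = 1000, seed = 1L) {
  P <- as.matrix(predicted); O <- as.matrix(observed)
  if (!is.null(fate_map)) {
    hit <- colnames(O) %in% names(fate_map)
    colnames(O)[hit] <- fate_map[colnames(O)[hit]]
  }
  shared <- intersect(colnames(P), colnames(O))
  if (length(shared) < 2L) {
    stop("fewer than 2 shared fates after name harmonization (",
         length(shared), "); supply a fate_map.")
  }
  regions <- intersect(rownames(P), rownames(O))
  if (length(regions) == 0L) stop("no shared regions.")
  P <- P[regions, shared, drop = FALSE]; O <- O[regions, shared, drop = FALSE]
  P <- P / pmax(rowSums(P), 1e-300); O <- O / pmax(rowSums(O), 1e-300)

  cosine <- function(x, y) {
    nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
    if (nx == 0 || ny == 0) return(0)
    sum(x * y) / (nx * ny)
  }
  per_region <- data.frame(
    region = regions,
    cosine = vapply(regions, function(r) cosine(P[r, ], O[r, ]), 0),
    spearman = vapply(regions, function(r) {
      suppressWarnings(stats::cor(P[r, ], O[r, ], method = "spearman"))
    }, 0),
    stringsAsFactors = FALSE)
  mean_cos <- mean(per_region$cosine)
  mean_sp <- mean(per_region$spearman, na.rm = TRUE)

  base <- NA_real_; perm_p <- NA_real_
  if (n_permutations > 0 && length(regions) > 1L) {
    rng <- local_rng(seed)
    perm_means <- vapply(seq_len(n_permutations), function(i) {
      sh <- sample(regions)
      mean(vapply(seq_along(regions),
                  function(r) cosine(P[regions[r], ], O[sh[r], ]), 0))
    }, 0)
    base <- mean(perm_means)
    perm_p <- (1 + sum(perm_means >= mean_cos)) / (1 + n_permutations)
  }
  list(per_region = per_region, mean_cosine = mean_cos,
       mean_spearman = mean_sp, baseline_mean_cosine = base,
       perm_p = perm_p, shared_fates = shared)
}
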