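# Per-cluster mean/variance/n/fraction-expressing for every gene.
cluster_stats <- function(norm, clusters) {
  cl <- split(seq_along(clusters), clusters)
  lapply(cl, function(idx) {
    x <- norm[idx, , drop = FALSE]
    list(n = length(idx), mean = colMeans(x),
         var = apply(x, 2, stats::var),
         frac = colMeans(x > 0))
  })
}

#' Pairwise marker detection with rank aggregation
#'
#' For each cluster, Welch two-sample t-tests against every other cluster
#' are run per gene; per-comparison ranks (by p-value) are combined by
#' their minimum (a gene ranks high if it separates the cluster from at
#' least one other), and p-values are combined by Simes' method before a
#' Benjamini-Hochberg correction within cluster. The log fold change
#' reported is the cluster mean minus the mean of all other cells on the
#' log2-normalized layer. The conventional reporting filter is
#' adjusted p < 0.05 and |LFC| > 0.5, with display truncated to genes
#' ranked in the top `top_rank` (dense ranks: ties at the boundary are all
#' kept, so lists may exceed `top_rank` genes).
#'
#' @param norm cells x genes log2-normalized matrix.
#' @param clusters Cluster label per cell; clusters with fewer than 3
#'   cells are excluded with a warning.
#' @param fdr,min_lfc Reporting filter on adjusted p and |LFC|.
#' @param top_rank Display cutoff on the aggregated rank (default 20).
#' @return A `marker_table` data.frame: `cluster`, `gene_id`, `lfc`,
#'   `frac_in`, `frac_out`, `p`, `p_adj`, `rank`, `reported`.
#' @export
markers_pairwise <- function(norm, clusters, fdr = 0.05, min_lfc = 0.5,
                             top_rank = 20) {
  clusters <- as.character(clusters)
  sizes <- table(clusters)
  small <- names(sizes)[sizes < 3]
  if (length(small)) {
    warning("excluding cluster(s) with fewer than 3 cells: ",
            paste(small, collapse = ", "))
    keep <- !clusters %in% small
    norm <- norm[keep, , drop = FALSE]
    clusters <- clusters[keep]
  }
  cls <- sort(unique(clusters))
  if (length(cls) < 2L) stop("need at least 2 clusters with >= 3 cells.")
  st <- cluster_stats(norm, clusters)
  out <- list()
  for (ci in cls) {
    others <- setdiff(cls, ci)
    pmat <- sapply(others, function(cj) {
      welch_p(st[[ci]], st[[cj]])
    })
    pmat <- matrix(pmat, ncol = length(others))
    ranks <- apply(pmat, 2, rank, ties.method = "min")
    agg_rank <- apply(matrix(ranks, ncol = length(others)), 1, min)
    # Simes combination across the pairwise comparisons
    p_comb <- apply(pmat, 1, function(p) {
      p <- sort(p); min(p * length(p) / seq_along(p))
    })
    p_adj <- stats::p.adjust(p_comb, method = "BH")
    rest_idx <- clusters != ci
    rest_mean <- colMeans(norm[rest_idx, , drop = FALSE])
    rest_frac <- colMeans(norm[rest_idx, , drop = FALSE] > 0)
    lfc <- st[[ci]]$mean - rest_mean
    dense <- match(agg_rank, sort(unique(agg_rank)))
    out[[ci]] <- data.frame(
      cluster = ci, gene_id = colnames(norm), lfc = lfc,
      frac_in = st[[ci]]$frac, frac_out = rest_frac,
      p = p_comb, p_adj = p_adj, rank = agg_rank,
      reported = p_adj < fdr & abs(lfc) > min_lfc & dense <= top_rank,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("marker_table", "data.frame"))
}

# Welch t-test p-values from per-cluster summary stats (two-sided).
welch_p <- function(s1, s2) {
  se2 <- s1$var / s1$n + s2$var / s2$n
  t <- (s1$mean - s2$mean) / sqrt(pmax(se2, 1e-300))
  df <- se2^2 / pmax(
    (s1$var / s1$n)^2 / (s1$n - 1) + (s2$var / s2$n)^2 / (s2$n - 1), 1e-300)
  df <- pmax(df, 1)
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  p[se2 <= 1e-300] <- 1      # both clusters constant: no evidence
  p
}

#' One-vs-rest Wilcoxon marker detection with expression filters
#'
#' Per cluster, genes expressed in fewer than `min_frac` of the cluster's
#' cells or with log fold change below `min_lfc` against the rest are
#' excluded before testing (the conventional `min.pct = 0.25`,
#' `logfc.threshold = 0.25` pre-filters); remaining genes are tested with
#' a Wilcoxon rank-sum test (normal approximation with tie correction)
#' and BH-adjusted over the tested genes only.
#'
#' @param norm cells x genes log2-normalized matrix.
#' @param clusters Cluster label per cell.
#' @param min_frac Minimum in-cluster expressing fraction (default 0.25).
#' @param min_lfc Minimum log2 fold change (default 0.25).
#' @return A `marker_table` data.frame with `tested` indicating whether
#'   the gene passed the pre-filters; untested genes carry `NA` p-values.
#' @export
markers_onevsrest <- function(norm, clusters, min_frac = 0.25,
                              min_lfc = 0.25) {
  clusters <- as.character(clusters)
  sizes <- table(clusters)
  small <- names(sizes)[sizes < 3]
  if (length(small)) {
    warning("excluding cluster(s) with fewer than 3 cells: ",
            paste(small, collapse = ", "))
    keep <- !clusters %in% small
    norm <- norm[keep, , drop = FALSE]
    clusters <- clusters[keep]
  }
  cls <- sort(unique(clusters))
  out <- list()
  for (ci in cls) {
    in_idx <- clusters == ci
    x_in <- norm[in_idx, , drop = FALSE]
    x_out <- norm[!in_idx, , drop = FALSE]
    frac_in <- colMeans(x_in > 0)
    frac_out <- colMeans(x_out > 0)
    lfc <- colMeans(x_in) - colMeans(x_out)
    tested <- frac_in >= min_frac & lfc >= min_lfc
    p <- rep(NA_real_, ncol(norm))
    for (g in which(tested)) {
      p[g] <- wilcox_p(x_in[, g], x_out[, g])
    }
    p_adj <- rep(NA_real_, ncol(norm))
    p_adj[tested] <- stats::p.adjust(p[tested], method = "BH")
    rk <- rep(NA_integer_, ncol(norm))
    rk[tested] <- rank(p[tested], ties.method = "min")
    out[[ci]] <- data.frame(
      cluster = ci, gene_id = colnames(norm), lfc = lfc,
      frac_in = frac_in, frac_out = frac_out, p = p, p_adj = p_adj,
      rank = rk, tested = tested,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("marker_table", "data.frame"))
}

# Two-sided Wilcoxon rank-sum p (normal approximation, tie-corrected).
wilcox_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  sig2 <- n1 * n2 / 12 *
    ((n1 + n2 + 1) - sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
  if (sig2 <= 0) return(1)
  z <- (W - mu) / sqrt(sig2)
  2 * stats::pnorm(abs(z), lower.tail = FALSE)
}
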