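#' Quality-control filter on cells
#'
#' Removes cells with total counts below `min_total_counts` (default
#' 10,000, the conventional cutoff for deep plate-based libraries) or a
#' mitochondrial read fraction above `max_mito_fraction` (default 4%).
#' Mitochondrial genes are identified by id prefix.
#'
#' @param ds A `timecourse_dataset`.
#' @param min_total_counts Minimum total counts per cell (strict: a cell
#'   with fewer counts is removed).
#' @param max_mito_fraction Maximum tolerated mitochondrial fraction.
#' @param mito_gene_prefix Gene-id prefix marking mitochondrial genes.
#' @return A list with `dataset` (filtered) and `report` (per-cell
#'   data.frame: total counts, genes detected, mito fraction, pass flag and
#'   reason).
#' @export
qc_filter <- function(ds, min_total_counts = 10000, max_mito_fraction = 0.04,
                      mito_gene_prefix = "mt-") {
  totals <- Matrix::rowSums(ds$counts)
  detected <- Matrix::rowSums(ds$counts > 0)
  mito <- startsWith(colnames(ds$counts), mito_gene_prefix)
  mito_frac <- if (any(mito)) {
    Matrix::rowSums(ds$counts[, mito, drop = FALSE]) / pmax(totals, 1)
  } else rep(0, nrow(ds$counts))
  low <- totals < min_total_counts
  high_mito <- mito_frac > max_mito_fraction
  pass <- !low & !high_mito
  reason <- rep("pass", length(pass))
  reason[high_mito] <- "high_mito_fraction"
  reason[low] <- "low_total_counts"           # low counts takes precedence
  report <- data.frame(cell_id = ds$cell_table$cell_id,
                       total_counts = totals, genes_detected = detected,
                       mito_fraction = mito_frac, pass = pass,
                       reason = reason, stringsAsFactors = FALSE)
  if (!any(pass)) {
    stop("qc_filter removed every cell; review min_total_counts (",
         min_total_counts, ") and max_mito_fraction (", max_mito_fraction,
         ") against the library-size distribution.")
  }
  list(dataset = subset_cells(ds, pass), report = report)
}

#' Library-size size factors centred at unity
#'
#' Per-cell factors proportional to total counts, rescaled so their
#' geometric mean is exactly 1.
#'
#' @param counts cells x genes count matrix (dense or sparse).
#' @return Numeric vector of positive size factors named by cell.
#' @export
compute_size_factors <- function(counts) {
  lib <- Matrix::rowSums(counts)
  if (any(lib <= 0)) {
    bad <- rownames(counts)[lib <= 0] %||% which(lib <= 0)
    stop("cell(s) with zero total counts: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  sf <- lib / exp(mean(log(lib)))
  names(sf) <- rownames(counts)
  sf
}

#' Log-normalize counts
#'
#' `log2(count / size_factor + pseudocount)`, so a zero count maps to
#' `log2(pseudocount)` and the transform is monotone in the count.
#'
#' @param counts cells x genes counts.
#' @param sf Size factors from [compute_size_factors()].
#' @param pseudocount Positive pseudocount (default 1).
#' @return Dense cells x genes matrix of normalized values.
#' @export
log_normalize <- function(counts, sf, pseudocount = 1) {
  if (pseudocount <= 0) stop("pseudocount must be > 0.")
  m <- as.matrix(counts)
  if (any(m < 0)) stop("counts must be nonnegative.")
  if (length(sf) != nrow(m)) stop("one size factor per cell required.")
  log2(m / sf + pseudocount)
}

#' Select highly variable genes against a fitted mean-variance trend
#'
#' Fits a local-regression trend of per-gene variance on per-gene mean of
#' the log-normalized layer (loess, degree 1, default span 0.05), and
#' tests each gene's variance ratio above the trend with a scaled
#' chi-square approximation (`(n-1) * variance / trend ~ chi^2_{n-1}`
#' under the null). Genes with Benjamini-Hochberg adjusted p below `fdr`
#' are selected; genes below `min_mean` or on the blacklist (e.g. sex-linked
#' genes or reporter constructs) are excluded regardless of variance.
#'
#' @param norm cells x genes log-normalized matrix.
#' @param trend_span Loess span as a fraction of genes (default 0.05).
#' @param fdr BH-adjusted significance threshold (default 0.05).
#' @param min_mean Minimum mean log2 normalized count (default 1e-3).
#' @param blacklist Character vector of gene ids excluded a priori.
#' @return Data.frame (class `hvg_result`) with per-gene mean, variance,
#'   trend, excess variance, p, adjusted p, `selected`, `exclusion_reason`.
#' @export
select_hvgs <- function(norm, trend_span = 0.05, fdr = 0.05,
                        min_mean = 1e-3, blacklist = character(0)) {
  if (ncol(norm) < 10) stop("need at least 10 genes to fit a variance trend.")
  n <- nrow(norm)
  means <- colMeans(norm)
  vars <- apply(norm, 2, stats::var)
  res <- data.frame(gene_id = colnames(norm), mean = means, variance = vars,
                    trend = NA_real_, excess = NA_real_, p = NA_real_,
                    p_adj = NA_real_, selected = FALSE,
                    exclusion_reason = "none", stringsAsFactors = FALSE,
                    row.names = NULL)
  res$exclusion_reason[means < min_mean] <- "low_mean"
  res$exclusion_reason[res$gene_id %in% blacklist] <- "blacklist"

  fit_on <- res$exclusion_reason != "blacklist" & means >= min_mean
  if (all(vars[fit_on] < 1e-12)) {
    warning("degenerate zero-variance data; no genes selected.")
    return(structure(res, class = c("hvg_result", "data.frame")))
  }
  # order by mean for a stable smoother; span is a fraction of fitted genes
  span <- max(trend_span, 4 / sum(fit_on))
  lo <- stats::loess(vars[fit_on] ~ means[fit_on], span = span, degree = 1,
                     family = "gaussian",
                     control = stats::loess.control(surface = "direct"))
  trend <- rep(NA_real_, ncol(norm))
  trend[fit_on] <- pmax(stats::predict(lo, means[fit_on]), 1e-12)
  res$trend <- trend
  res$excess <- vars - trend
  ok <- fit_on & !is.na(trend)
  res$p[ok] <- stats::pchisq((n - 1) * vars[ok] / trend[ok], df = n - 1,
                             lower.tail = FALSE)
  res$p_adj[ok] <- stats::p.adjust(res$p[ok], method = "BH")
  res$selected <- !is.na(res$p_adj) & res$p_adj < fdr &
    res$exclusion_reason == "none"
  structure(res, class = c("hvg_result", "data.frame"))
}

#' Principal-component embedding of the normalized layer
#'
#' PCA on the selected genes (centred, unscaled), with components ordered
#' by decreasing explained variance and each component's sign fixed so its
#' largest-magnitude gene loading is positive, making the embedding
#' deterministic.
#'
#' @param norm cells x genes log-normalized matrix.
#' @param genes Gene ids to use (typically selected HVGs).
#' @param n_components Number of components (default 50).
#' @return An `embedding` object: list with `coords` (cells x components),
#'   `n_components`, `provenance = "pca"`, `genes`, `sdev`, plus the
#'   centring vector and rotation for projecting new data.
#' @export
embed_pca <- function(norm, genes = colnames(norm), n_components = 50) {
  genes <- intersect(genes, colnames(norm))
  if (length(genes) < 1) stop("no usable genes for PCA.")
  if (n_components > min(nrow(norm), length(genes))) {
    stop("n_components (", n_components, ") exceeds min(cells, genes) = ",
         min(nrow(norm), length(genes)), ".")
  }
  x <- norm[, genes, drop = FALSE]
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_components)
  rot <- pc$rotation
  flip <- apply(rot, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  rot <- sweep(rot, 2, flip, "*")
  coords <- sweep(pc$x[, seq_len(n_components), drop = FALSE], 2,
                  flip[seq_len(n_components)], "*")
  rownames(coords) <- rownames(norm)
  structure(list(coords = coords, n_components = n_components,
                 provenance = "pca", genes = genes,
                 sdev = pc$sdev[seq_len(n_components)],
                 center = pc$center, rotation = rot),
            class = "embedding")
}

#' Mutual-nearest-neighbour batch correction of an embedding
#'
#' Sequentially merges batches in `merge_order` (default: decreasing batch
#' size). For each incoming batch, mutual nearest neighbour pairs
#' (`k_mnn` each way) with the accumulated reference define per-pair
#' correction vectors (reference position minus incoming position); each
#' incoming cell receives a Gaussian-kernel-weighted average of these
#' vectors (bandwidth `sigma_frac` times the mean reference-incoming
#' distance). The first batch is the reference and is never moved.
#'
#' @param embeddings Named list of cells x components matrices, one per
#'   batch, in a shared component space.
#' @param k_mnn Neighbours per direction for the mutual pairs (default 20).
#' @param sigma_frac Kernel bandwidth as a fraction of the mean pairwise
#'   distance between reference and incoming cells (default 0.5; wide
#'   smoothing keeps the correction field near-constant per batch, which
#'   matches an additive batch model and leaves coinciding batches
#'   essentially untouched).
#' @param merge_order Optional character vector of batch names.
#' @return An `embedding` with `provenance = "mnn_corrected"`, rows in the
#'   concatenated original order of `embeddings`, plus per-cell applied
#'   `corrections` and the `pairs` found at each merge.
#' @export
mnn_correct <- function(embeddings, k_mnn = 20, sigma_frac = 0.5,
                        merge_order = NULL) {
  if (is.null(names(embeddings))) {
    names(embeddings) <- paste0("batch", seq_along(embeddings))
  }
  if (is.null(merge_order)) {
    merge_order <- names(sort(vapply(embeddings, nrow, 0L), decreasing = TRUE))
  }
  stopifnot(setequal(merge_order, names(embeddings)))
  all_ids <- unlist(lapply(embeddings, rownames), use.names = FALSE)
  corrected <- list()
  corrections <- list()
  pairs_log <- list()

  ref <- embeddings[[merge_order[1]]]
  corrected[[merge_order[1]]] <- ref
  corrections[[merge_order[1]]] <-
    matrix(0, nrow(ref), ncol(ref), dimnames = dimnames(ref))
  for (b in merge_order[-1]) {
    inc <- embeddings[[b]]
    k_use <- min(k_mnn, nrow(ref), nrow(inc))
    d2 <- cross_dist2(ref, inc)
    # k nearest incoming cells of each reference cell, and vice versa
    nn_ri <- t(apply(d2, 1, function(r) order(r)[seq_len(k_use)]))
    nn_ir <- t(apply(d2, 2, function(r) order(r)[seq_len(k_use)]))
    mutual_r <- rep(seq_len(nrow(ref)), each = k_use)
    mutual_i <- as.vector(t(nn_ri))
    keep <- vapply(seq_along(mutual_r), function(j) {
      mutual_r[j] %in% nn_ir[mutual_i[j], ]
    }, logical(1))
    pr <- mutual_r[keep]; pi <- mutual_i[keep]
    if (length(pr) == 0L) {
      stop("no mutual nearest neighbour pairs between the reference and ",
           "batch '", b, "'; try a larger k_mnn.")
    }
    vecs <- ref[pr, , drop = FALSE] - inc[pi, , drop = FALSE]
    sigma <- sigma_frac * mean(sqrt(d2))
    w <- exp(-cross_dist2(inc, inc[pi, , drop = FALSE]) /
               (2 * max(sigma, 1e-12)^2))
    w <- w / pmax(rowSums(w), 1e-300)
    corr <- w %*% vecs
    # Mutual pairs form between the facing surfaces of the two batch
    # clouds, which systematically underestimates a shared shift (the
    # "kissing" effect). Re-match locations along the mean batch vector:
    # after the smoothed per-cell correction, translate the incoming batch
    # along that direction so the median projections coincide.
    u <- colMeans(vecs)
    nu <- sqrt(sum(u^2))
    # only re-match locations when the mean pair vector is distinguishable
    # from sampling noise, so batches that already coincide are untouched
    if (nu > 1e-12) {
      proj_se <- stats::sd(vecs %*% (u / nu)) / sqrt(nrow(vecs))
      if (is.finite(proj_se) && nu > 3 * proj_se) {
        u <- u / nu
        delta <- stats::median(ref %*% u) -
          stats::median((inc + corr) %*% u)
        corr <- corr + matrix(delta * u, nrow(inc), ncol(inc), byrow = TRUE)
      }
    }
    corrected[[b]] <- inc + corr
    corrections[[b]] <- corr
    pairs_log[[b]] <- data.frame(ref_id = rownames(ref)[pr],
                                 incoming_id = rownames(inc)[pi])
    ref <- rbind(ref, corrected[[b]])
  }
  coords <- do.call(rbind, corrected[names(embeddings)])[all_ids, , drop = FALSE]
  corr_all <- do.call(rbind, corrections[names(embeddings)])[all_ids, , drop = FALSE]
  structure(list(coords = coords, n_components = ncol(coords),
                 provenance = "mnn_corrected", genes = NULL,
                 corrections = corr_all, pairs = pairs_log,
                 merge_order = merge_order),
            class = "embedding")
}

#' Run the full preprocessing chain on a dataset
#'
#' Convenience wrapper: size factors, log-normalization, HVG selection,
#' PCA, and (when several batches are present) MNN batch correction. The
#' corrected embedding is stored in `ds$embedding` and the normalized
#' layer in `ds$layers$normalized`.
#'
#' @param ds A `timecourse_dataset`.
#' @param n_components Principal components to keep (default 50).
#' @param hvg_fdr,trend_span,min_mean,blacklist Passed to [select_hvgs()].
#' @param k_mnn,sigma_frac Passed to [mnn_correct()].
#' @param pseudocount Passed to [log_normalize()].
#' @return The dataset with `layers$normalized`, `hvg`, and `embedding`
#'   filled in.
#' @export
preprocess_dataset <- function(ds, n_components = 50, hvg_fdr = 0.05,
                               trend_span = 0.05, min_mean = 1e-3,
                               blacklist = character(0), k_mnn = 20,
                               sigma_frac = 0.5, pseudocount = 1) {
  sf <- compute_size_factors(ds$counts)
  norm <- log_normalize(ds$counts, sf, pseudocount)
  hvg <- select_hvgs(norm, trend_span = trend_span, fdr = hvg_fdr,
                     min_mean = min_mean, blacklist = blacklist)
  genes <- hvg$gene_id[hvg$selected]
  if (length(genes) < n_components) genes <- hvg$gene_id[
    order(hvg$p)][seq_len(min(ncol(norm), max(n_components, 20)))]
  n_comp <- min(n_components, length(genes), nrow(norm))
  emb <- embed_pca(norm, genes, n_comp)
  batches <- ds$cell_table$batch_id
  if (length(unique(batches)) > 1L) {
    by_batch <- lapply(split(seq_along(batches), batches), function(idx) {
      emb$coords[idx, , drop = FALSE]
    })
    # merge batches largest-first within ascending time of first appearance
    emb <- mnn_correct(by_batch, k_mnn = k_mnn, sigma_frac = sigma_frac)
    emb$coords <- emb$coords[ds$cell_table$cell_id, , drop = FALSE]
    emb$genes <- genes
  }
  ds$layers$normalized <- norm
  ds$size_factors <- sf
  ds$hvg <- hvg
  ds$embedding <- emb
  ds
}
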