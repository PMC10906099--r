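make_counts_ds <- function(counts, time_point = 0) {
  rownames(counts) <- sprintf("c%03d", seq_len(nrow(counts)))
  colnames(counts) <- sprintf("g%03d", seq_len(ncol(counts)))
  timecourse_dataset(counts, data.frame(
    cell_id = rownames(counts), time_point = time_point,
    batch_id = "b1", section_id = "s1", stringsAsFactors = FALSE))
}

test_that("qc_filter applies strict count and mitochondrial thresholds", {
  counts <- matrix(0, 4, 20)
  counts[, 3:20] <- 555                    # totals 9,990: just under cutoff
  counts[2, 3] <- 565                      # cell 2: exactly 10,000
  counts[3, 1:2] <- 250                    # cell 3: mito-heavy
  counts[3, 3:20] <- 528                   # total 10,004, mito ~5%
  counts[4, 3] <- 1000                     # cell 4: comfortably above
  ds <- make_counts_ds(counts)
  colnames(ds$counts)[1:2] <- c("mt-nd1", "mt-co1")
  ds$gene_table$gene_id <- colnames(ds$counts)

  res <- qc_filter(ds)
  expect_equal(res$report$reason[1], "low_total_counts")
  expect_equal(res$report$reason[3], "high_mito_fraction")
  expect_equal(res$dataset$cell_table$cell_id, c("c002", "c004"))

  # all cells above threshold: unchanged
  ok <- make_counts_ds(matrix(1000, 3, 15))
  res2 <- qc_filter(ok)
  expect_equal(nrow(res2$dataset$counts), 3)
  expect_true(all(res2$report$pass))
  expect_error(qc_filter(ok, min_total_counts = 1e9), "every cell")
})

test_that("size factors are library-proportional with geometric mean one", {
  counts <- diag(c(100, 200, 300))
  rownames(counts) <- paste0("c", 1:3)
  sf <- compute_size_factors(counts)
  expect_equal(unname(sf), c(0.5503, 1.1006, 1.6510), tolerance = 1e-3)
  expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-9)
  expect_equal(unname(compute_size_factors(matrix(7, 5, 3))), rep(1, 5))
  bad <- rbind(c1 = c(1, 2), c2 = c(0, 0))
  expect_error(compute_size_factors(bad), "c2")
})

test_that("log normalization is monotone and scales with the size factor", {
  counts <- matrix(c(0, 1, 2, 4), 1)
  expect_equal(log_normalize(counts, 1)[1, 1], 0)
  v1 <- log_normalize(counts, 1, pseudocount = 0.5)
  v2 <- log_normalize(counts, 2, pseudocount = 0.5)
  expect_equal(2^v2[1, ] - 0.5, (2^v1[1, ] - 0.5) / 2, tolerance = 1e-12)
  expect_true(all(diff(v1[1, ]) >= 0))
  expect_error(log_normalize(matrix(-1, 1, 1), 1), "nonnegative")
  expect_error(log_normalize(counts, 1, pseudocount = 0), "pseudocount")
})

test_that("HVG selection finds planted variance and honours exclusions", {
  set.seed(42)
  n <- 200; g <- 120
  means <- runif(g, 1, 6)
  norm <- sapply(means, function(m) rnorm(n, m, sqrt(m) * 0.3))
  norm[, 5] <- rnorm(n, means[5], sqrt(means[5] * 10) * 0.3)  # 10x trend var
  norm[, 9] <- rnorm(n, means[9], sqrt(means[9] * 10) * 0.3)
  colnames(norm) <- sprintf("g%03d", seq_len(g))
  res <- select_hvgs(norm, trend_span = 0.3)
  expect_true(res$selected[5])
  expect_true(res$selected[9])
  expect_lt(sum(res$selected), 15)

  # blacklisted gene with huge excess variance is excluded
  res_bl <- select_hvgs(norm, trend_span = 0.3, blacklist = "g005")
  expect_false(res_bl$selected[5])
  expect_equal(res_bl$exclusion_reason[5], "blacklist")
  expect_true(res_bl$selected[9])

  # a low-mean gene is excluded regardless of variance
  norm2 <- norm
  norm2[, 12] <- norm[, 12] * 1e-5
  res_lm <- select_hvgs(norm2, trend_span = 0.3)
  expect_equal(res_lm$exclusion_reason[12], "low_mean")
  expect_false(res_lm$selected[12])

  # gene-order invariance of the selected set
  perm <- sample(g)
  res_p <- select_hvgs(norm[, perm], trend_span = 0.3)
  expect_setequal(res_p$gene_id[res_p$selected], res$gene_id[res$selected])

  expect_error(select_hvgs(norm[, 1:5]), "at least 10 genes")
  flat <- matrix(3, 50, 20, dimnames = list(NULL, sprintf("g%02d", 1:20)))
  expect_warning(res_f <- select_hvgs(flat), "degenerate")
  expect_false(any(res_f$selected))
})

test_that("PCA embedding is ordered, deterministic, and reconstructs low rank", {
  set.seed(1)
  scores <- matrix(rnorm(200), 100, 2)
  load <- matrix(rnorm(40), 2, 20)
  x <- scores %*% load
  colnames(x) <- sprintf("g%02d", 1:20); rownames(x) <- sprintf("c%03d", 1:100)
  emb <- embed_pca(x, n_components = 2)
  recon <- sweep(emb$coords %*% t(emb$rotation[, 1:2]), 2, -emb$center)
  expect_lt(max(abs(recon - x)), 1e-8)
  expect_true(all(diff(emb$sdev) <= 1e-12))
  # duplicated cells project identically
  x2 <- rbind(x, x[1, , drop = FALSE]); rownames(x2)[101] <- "dup"
  emb2 <- embed_pca(x2, n_components = 2)
  expect_equal(unname(emb2$coords["dup", ]), unname(emb2$coords["c001", ]))
  expect_identical(emb$coords, embed_pca(x, n_components = 2)$coords)
  expect_error(embed_pca(x, n_components = 50), "exceeds")
})

test_that("MNN correction recovers a constant batch shift", {
  set.seed(11)
  n <- 500; d <- 10
  base <- matrix(rnorm(n * d), n, d)
  v <- rnorm(d, 0, 2)                    # injected shift
  ref <- base; rownames(ref) <- sprintf("r%04d", 1:n)
  inc <- base + matrix(v, n, d, byrow = TRUE)
  rownames(inc) <- sprintf("q%04d", 1:n)
  out <- mnn_correct(list(A = ref, B = inc), merge_order = c("A", "B"))
  expect_identical(out$provenance, "mnn_corrected")
  # reference batch untouched
  expect_true(all(out$corrections[1:n, ] == 0))
  applied <- colMeans(out$corrections[n + 1:n, ])
  expect_lt(sqrt(sum((applied + v)^2)), 0.1 * sqrt(sum(v^2)))

  # post-correction mixing: own-batch fraction of 15 NN near chance 0.5
  coords <- out$coords
  batch <- rep(c("A", "B"), each = n)
  idx <- sample(2 * n, 200)
  own <- sapply(idx, function(i) {
    d2 <- colSums((t(coords) - coords[i, ])^2)
    d2[i] <- Inf
    mean(batch[order(d2)[1:15]] == batch[i])
  })
  expect_lt(abs(mean(own) - 0.5), 0.1)

  # single batch: identity
  solo <- mnn_correct(list(A = ref))
  expect_equal(solo$coords, ref)
  far <- matrix(1e6, 5, d, dimnames = list(paste0("f", 1:5), NULL))
  expect_error(mnn_correct(list(A = ref, B = far), k_mnn = 1,
                           merge_order = c("A", "B")), NA)
})

test_that("preprocess_dataset produces a finite corrected embedding", {
  ds <- default_timecourse(cells_per_tp = 60)
  ds <- inject_batch_effect(ds, 0.3, seed = 2)
  ds <- preprocess_dataset(ds, n_components = 15)
  expect_identical(dim(ds$embedding$coords),
                   c(nrow(ds$counts), 15L))
  expect_true(all(is.finite(ds$embedding$coords)))
  expect_identical(rownames(ds$embedding$coords), ds$cell_table$cell_id)
  expect_equal(exp(mean(log(ds$size_factors))), 1, tolerance = 1e-9)
})
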