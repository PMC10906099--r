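test_that("lineage tree construction is valid, branching, and deterministic", {
  expect_error(build_lineage_tree(1, 50), "n_states must be >= 2")

  tree <- build_lineage_tree(3, 100, depth = 1, seed = 7)
  expect_length(tree$terminal_states, 2)
  kids <- tree$states$state_id[!is.na(tree$states$parent_id)]
  expect_setequal(kids, tree$terminal_states)
  expect_true(all(tree$states$growth > 0))
  expect_true(all(tree$programs >= 0))
  # sibling programs differ in at least 10% of genes
  diff_frac <- mean(tree$programs[kids[1], ] != tree$programs[kids[2], ])
  expect_gte(diff_frac, 0.1)

  expect_identical(tree, build_lineage_tree(3, 100, depth = 1, seed = 7))
  tree2 <- build_lineage_tree(3, 100, depth = 1, seed = 8)
  expect_false(identical(tree$programs, tree2$programs))

  deep <- build_lineage_tree(7, 60, depth = 2, seed = 2)
  expect_length(deep$terminal_states, 4)
  expect_true(all(diff(deep$states$birth_time[order(deep$states$birth_time)]) >= 0))
})

test_that("simulated fate ground truth is a simplex and respects tree shape", {
  ds <- default_timecourse(cells_per_tp = 60)
  expect_true(all(abs(rowSums(ds$fate_probs) - 1) < 1e-9))
  # linear tree: point mass on the single terminal state
  lin <- make_linear_tree()
  dl <- simulate_timecourse(lin, c(0, 0.5, 1), 30, count_depth = 1000,
                            seed = 5)
  expect_true(all(dl$fate_probs[, "state02"] == 1))
  # symmetric two-leaf tree with equal growth: 0.5/0.5 for pre-branch cells
  sym <- make_binary_tree(growth = c(1, 1, 1))
  dsym <- simulate_timecourse(sym, c(0, 0.25, 0.5), 40, count_depth = 1000,
                              seed = 5)
  pre <- dsym$cell_table$state_label == "state01"
  expect_true(all(abs(dsym$fate_probs[pre, ] - 0.5) < 1e-12))
})

test_that("unequal growth matches an independent ODE integration of the two-type model", {
  skip_if_not_installed("deSolve")
  g <- c(1, 2, 1)            # leaf state02 grows at 2x the rate of state03
  tree <- make_binary_tree(growth = g)
  ds <- simulate_timecourse(tree, c(0, 0.25, 0.5, 0.75, 1), 20,
                            count_depth = 500, seed = 9)
  pre <- which(ds$cell_table$state_label == "state01" &
                 ds$cell_table$time_point == 0)[1]
  got <- ds$fate_probs[pre, c("state02", "state03")]
  # oracle: integrate dm_i/dt = g_i m_i from the branch (0.5, 0.5 split)
  # at t = 0.5 to the grid end at t = 1
  sol <- deSolve::ode(y = c(m1 = 0.5, m2 = 0.5), times = c(0.5, 1),
                      func = function(t, y, p) list(c(p[1] * y[1],
                                                      p[2] * y[2])),
                      parms = c(2, 1), rtol = 1e-10, atol = 1e-12)
  m <- sol[2, c("m1", "m2")]
  expect_equal(unname(got), unname(m / sum(m)), tolerance = 1e-6)
})

test_that("state occupancy converges to the growth-weighted branch masses", {
  tree <- make_binary_tree(growth = c(1.2, 2, 0.7))
  occ <- state_occupancy(tree, c(0.3, 0.8))
  for (k in 1:2) {
    oracle <- euler_occupancy(tree, c(0.3, 0.8)[k])
    expect_equal(occ[k, ], oracle, tolerance = 1e-3)
  }
  # sampled state fractions approach the analytic occupancy at large n
  ds <- simulate_timecourse(tree, 0.8, 4000, count_depth = 300, seed = 2)
  frac <- table(factor(ds$cell_table$state_label,
                       levels = tree$states$state_id)) / 4000
  expect_lt(max(abs(as.numeric(frac) - occ[2, ])), 0.03)
})

test_that("total counts concentrate around the requested depth", {
  tree <- make_binary_tree()
  ds <- simulate_timecourse(tree, c(0, 0.5), 600, count_depth = 2000,
                            dispersion = 0.1, seed = 4)
  totals <- Matrix::rowSums(ds$counts)
  se <- sd(totals) / sqrt(length(totals))
  expect_lt(abs(mean(totals) - 2000), 3 * se)
})

test_that("simulation handles edge cases and is deterministic", {
  tree <- make_binary_tree()
  expect_error(simulate_timecourse(tree, c(-0.5, 0.5), 10),
               "before the root birth")
  expect_error(simulate_timecourse(tree, c(0.5, 0.25), 10),
               "strictly increasing")
  empty <- simulate_timecourse(tree, c(0, 0.5), 0)
  expect_equal(nrow(empty$counts), 0)
  expect_s3_class(empty, "timecourse_dataset")
  d1 <- simulate_timecourse(tree, c(0, 0.5), 25, seed = 6)
  d2 <- simulate_timecourse(tree, c(0, 0.5), 25, seed = 6)
  expect_identical(as.matrix(d1$counts), as.matrix(d2$counts))
  expect_identical(d1$cell_table, d2$cell_table)
})

test_that("batch-effect injection stores recoverable offsets", {
  tree <- make_binary_tree()
  ds <- simulate_timecourse(tree, c(0, 0.5), 400, count_depth = 3000,
                            seed = 8, n_batches = 2)
  expect_identical(inject_batch_effect(ds, 0, seed = 1)$counts, ds$counts)

  shifted <- inject_batch_effect(ds, magnitude = 0.5, seed = 2)
  off <- shifted$ground_truth$batch_offsets
  expect_true(all(off["batch1", ] == 0))
  b2 <- shifted$cell_table$batch_id == "batch2"
  # mean log2 count difference per gene tracks the stored offset
  m1 <- colMeans(log2(as.matrix(shifted$counts[!b2, ]) + 1))
  m2 <- colMeans(log2(as.matrix(shifted$counts[b2, ]) + 1))
  keep <- colMeans(as.matrix(ds$counts)) > 5   # rounding noise dominates low counts
  expect_gt(cor(m2[keep] - m1[keep], off["batch2", keep]), 0.95)

  expect_identical(inject_batch_effect(ds, 0.5, seed = 2)$counts,
                   shifted$counts)
  one_batch <- ds
  one_batch$cell_table$batch_id <- "batch1"
  expect_warning(inject_batch_effect(one_batch, 0.5), "no-op")
})

test_that("fixture write/read roundtrip is lossless", {
  ds <- default_timecourse(cells_per_tp = 20, n_genes = 40)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(as.matrix(back$counts), as.matrix(ds$counts))
  expect_equal(back$cell_table$cell_id, ds$cell_table$cell_id)
  expect_equal(back$cell_table$time_point, ds$cell_table$time_point)
  expect_equal(back$fate_probs, ds$fate_probs, tolerance = 1e-12)
  expect_equal(back$time_grid, ds$time_grid)

  # missing sidecar: loads with ground truth absent
  file.remove(file.path(dir, "ground_truth.json"))
  no_gt <- read_dataset(dir)
  expect_null(no_gt$fate_probs)

  # malformed MTX header: parse error naming the file
  writeLines(c("%%MatrixMarket matrix oops", "1 1 1", "1 1 1"),
             file.path(dir, "counts.mtx"))
  expect_error(read_dataset(dir), "malformed Matrix Market")
})
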