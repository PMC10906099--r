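test_that("cost matrix is squared Euclidean with optional median scaling", {
  a <- rbind(c(0, 0), c(3, 4))
  C <- cost_matrix(a, a)
  expect_equal(diag(C), c(0, 0))
  expect_equal(C[1, 2], 25)
  expect_equal(C, t(C))
  Cn <- cost_matrix(a, rbind(c(1, 0), c(0, 2), c(3, 3)), normalize = TRUE)
  expect_equal(stats::median(Cn[Cn > 0] * attr(Cn, "median")),
               attr(Cn, "median"))
  expect_error(cost_matrix(a, rbind(c(1, 2, 3))), "dimensions differ")
})

test_that("constant cost with balanced marginals returns the outer product", {
  C <- matrix(2, 3, 4)
  a <- c(0.2, 0.3, 0.5); b <- c(0.1, 0.2, 0.3, 0.4)
  cfg <- transport_config(epsilon = 0.5, lambda_source = Inf,
                          lambda_target = Inf)
  tm <- unbalanced_sinkhorn(C, a, b, cfg)
  expect_lt(max(abs(tm$gamma - outer(a, b))), 1e-8)
  expect_true(tm$diagnostics$converged)
})

test_that("balanced sinkhorn at small epsilon matches the brute-force LP optimum", {
  cfg <- transport_config(epsilon = 1e-3, lambda_source = Inf,
                          lambda_target = Inf, max_iterations = 20000)
  C2 <- matrix(c(0, 1, 1, 0), 2, 2)
  tm2 <- suppressWarnings(unbalanced_sinkhorn(C2, rep(0.5, 2), rep(0.5, 2),
                                              cfg))
  lp2 <- lp_transport_oracle(C2)
  expect_lt(max(abs(tm2$gamma - lp2$gamma)), 1e-3)

  set.seed(1)
  for (rep in 1:3) {
    C3 <- matrix(runif(9), 3, 3)
    tm3 <- suppressWarnings(
      unbalanced_sinkhorn(C3, rep(1 / 3, 3), rep(1 / 3, 3), cfg))
    lp3 <- lp_transport_oracle(C3)
    expect_lt(max(abs(tm3$gamma - lp3$gamma)), 1e-3)
  }
})

test_that("balanced mode reproduces the prescribed marginals", {
  set.seed(2)
  C <- matrix(runif(30), 5, 6)
  a <- runif(5); a <- a / sum(a)
  b <- runif(6); b <- b / sum(b)
  cfg <- transport_config(epsilon = 0.1, lambda_source = Inf,
                          lambda_target = Inf)
  tm <- unbalanced_sinkhorn(C, a, b, cfg)
  expect_lt(max(abs(rowSums(tm$gamma) - a)), 1e-6)
  expect_lt(max(abs(colSums(tm$gamma) - b)), 1e-6)
  expect_true(all(tm$gamma >= 0))
  # unbalanced mode relaxes but stays near the marginals
  cfg_u <- transport_config(epsilon = 0.1)
  tm_u <- unbalanced_sinkhorn(C, a, b, cfg_u)
  expect_true(all(is.finite(tm_u$gamma)))
  expect_lt(max(abs(colSums(tm_u$gamma) - b)), 0.05)
})

test_that("entropic cost decreases toward the LP optimum as epsilon shrinks", {
  set.seed(3)
  C <- matrix(runif(9), 3, 3)
  lp <- lp_transport_oracle(C)
  costs <- sapply(c(0.1, 0.02, 0.004, 8e-4), function(eps) {
    cfg <- transport_config(epsilon = eps, lambda_source = Inf,
                            lambda_target = Inf, max_iterations = 50000)
    sum(suppressWarnings(
      unbalanced_sinkhorn(C, rep(1/3, 3), rep(1/3, 3), cfg))$gamma * C)
  })
  # monotone decrease toward the LP optimum, within solver tolerance
  expect_true(all(diff(costs) <= 1e-6))
  expect_gte(costs[4] + 1e-5, lp$cost)
  expect_lt(costs[4] - lp$cost, 1e-3)
})

test_that("growth learning finds symmetry and detects expansion", {
  # symmetric fixture: identical clouds in an embedding-like dimension,
  # growth should stay ~1
  set.seed(4)
  x <- matrix(rnorm(100 * 10), 100, 10)
  C <- cost_matrix(x, x, normalize = TRUE)
  res <- learn_growth_rates(C, config = transport_config(), dt = 0.25)
  expect_lt(max(abs(res$growth$rates - 1)), 0.05)

  # growth_iterations = 0 returns the initial rates unchanged
  g0 <- runif(100, 0.5, 2)
  res0 <- learn_growth_rates(C, initial_growth = g0,
                             config = transport_config(growth_iterations = 0),
                             dt = 0.25)
  expect_identical(res0$growth$rates, g0)

  # one branch triples its mass over dt = 0.25: its source cells learn
  # higher growth than the other branch's (one-sided)
  set.seed(5)
  n <- 250
  srcA <- matrix(rnorm(n * 2), n, 2)
  srcB <- matrix(rnorm(n * 2), n, 2) + 8
  tgt <- rbind(matrix(rnorm(3 * n * 2), 3 * n, 2),
               matrix(rnorm(n * 2), n, 2) + 8)
  C2 <- cost_matrix(rbind(srcA, srcB), tgt, normalize = TRUE)
  res2 <- learn_growth_rates(C2, config = transport_config(), dt = 0.25)
  expect_gt(mean(res2$growth$rates[1:n]), mean(res2$growth$rates[n + 1:n]))
  expect_error(learn_growth_rates(C, dt = 0), "dt must be > 0")
})

test_that("composition yields row-stochastic chains and is associative", {
  set.seed(6)
  mk <- function(n, m, src, tgt) {
    structure(list(gamma = matrix(runif(n * m), n, m),
                   source_ids = src, target_ids = tgt,
                   config = NULL, growth = NULL, diagnostics = list()),
              class = "transport_map")
  }
  ids <- lapply(c(4, 5, 3, 6), function(n) sprintf("t%d_%d", n, seq_len(n)))
  A <- mk(4, 5, ids[[1]], ids[[2]])
  B <- mk(5, 3, ids[[2]], ids[[3]])
  D <- mk(3, 6, ids[[3]], ids[[4]])
  full <- compose_maps(list(A, B, D))
  expect_lt(max(abs(rowSums(full$gamma) - 1)), 1e-9)
  left <- compose_maps(list(compose_maps(list(A, B)), D))
  right <- compose_maps(list(A, compose_maps(list(B, D))))
  expect_lt(max(abs(left$gamma - right$gamma)), 1e-10)
  # identity coupling leaves a transition matrix unchanged
  I <- mk(3, 3, ids[[3]], ids[[3]])
  I$gamma <- diag(3)
  expect_equal(compose_maps(list(B, I))$gamma, compose_maps(list(B))$gamma)
  expect_error(compose_maps(list(A, D)), "do not chain")
})

test_that("pushing distributions conserves mass and inverts symmetrically", {
  set.seed(7)
  mk <- function(g, src, tgt) structure(
    list(gamma = g, source_ids = src, target_ids = tgt, config = NULL,
         growth = NULL, diagnostics = list()), class = "transport_map")
  s1 <- paste0("a", 1:4); s2 <- paste0("b", 1:4); s3 <- paste0("c", 1:5)
  m1 <- mk(matrix(runif(16), 4, 4), s1, s2)
  m2 <- mk(matrix(runif(20), 4, 5), s2, s3)
  fwd <- push_distribution(c(1, 0, 0, 0), list(m1, m2), "forward")
  expect_equal(sum(fwd), 1, tolerance = 1e-9)
  bwd <- push_distribution(rep(0.2, 5), list(m1, m2), "backward")
  expect_equal(sum(bwd), 1, tolerance = 1e-9)
  expect_named(bwd, s1)
  # point mass through an identity coupling is preserved
  mI <- mk(diag(4), s1, s2)
  expect_equal(unname(push_distribution(c(0, 1, 0, 0), list(mI), "forward")),
               c(0, 1, 0, 0))
  expect_error(push_distribution(c(0.5, 0.5), list(m1), "forward"),
               "does not match")
  # forward-then-backward of uniform stays near uniform on a symmetric fixture
  x <- matrix(rnorm(60), 30, 2)
  Cs <- cost_matrix(x, x, normalize = TRUE)
  tm <- unbalanced_sinkhorn(Cs, rep(1 / 30, 30), rep(1 / 30, 30),
                            transport_config(epsilon = 0.05,
                                             lambda_source = Inf,
                                             lambda_target = Inf,
                                             max_iterations = 50000))
  tm$source_ids <- paste0("s", 1:30); tm$target_ids <- paste0("t", 1:30)
  u <- rep(1 / 30, 30)
  rt <- push_distribution(push_distribution(u, list(tm), "forward"),
                          list(tm), "backward")
  expect_lt(0.5 * sum(abs(rt - u)), 0.05)
})

test_that("collapse_timepoints relabels cells and updates the grid", {
  ds <- default_timecourse(cells_per_tp = 15)
  out <- collapse_timepoints(ds, list("0.875" = c(0.75, 1)))
  expect_false(any(out$cell_table$time_point %in% c(0.75, 1)))
  expect_equal(sum(out$cell_table$time_point == 0.875), 30)
  expect_equal(out$time_grid, c(0, 0.25, 0.5, 0.875))
  expect_identical(out$counts, ds$counts)
  expect_identical(collapse_timepoints(ds, list()), ds)
  expect_warning(collapse_timepoints(ds, list("0.6" = c(0.25, 1))),
                 "non-adjacent")
  expect_error(collapse_timepoints(ds, list("2" = c(1.5, 2))), "not on the grid")
})

test_that("backward pushing concentrates mass on true ancestors", {
  ds <- default_timecourse(cells_per_tp = 120)
  ds <- preprocess_dataset(ds, n_components = 15)
  maps <- transport_timecourse(ds)
  ct <- ds$cell_table
  tree <- ds$ground_truth$tree
  last <- maps[[length(maps)]]
  for (leaf in tree$terminal_states) {
    ind <- as.numeric(ct$state_label[match(last$target_ids, ct$cell_id)] == leaf)
    if (sum(ind) == 0) next
    anc <- push_distribution(ind / sum(ind), list(last), "backward")
    anc_states <- ct$state_label[match(names(anc), ct$cell_id)]
    expect_gte(sum(anc[anc_states == leaf]), 0.7)
  }
})
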