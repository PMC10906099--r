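# Shared fixtures built in code at test time.

# Small binary tree: root + two terminal leaves branching at t = 0.5.
make_binary_tree <- function(n_genes = 120, seed = 7, growth = NULL,
                             t_max = 1) {
  tree <- build_lineage_tree(3, n_genes, depth = 1, seed = seed,
                             t_max = t_max)
  if (!is.null(growth)) tree$states$growth <- growth
  tree
}

# Linear (non-branching) two-state tree built by hand: root -> one terminal.
make_linear_tree <- function(n_genes = 50, seed = 1) {
  tree <- build_lineage_tree(3, n_genes, depth = 1, seed = seed)
  keep <- c("state01", "state02")
  tree$states <- tree$states[tree$states$state_id %in% keep, ]
  tree$programs <- tree$programs[keep, ]
  tree$branch_times <- tree$branch_times[keep]
  tree$terminal_states <- "state02"
  validate_lineage_tree(tree)
  tree
}

# Default branching timecourse used by several integration tests:
# 5 time points, two terminal fates, well-separated branches.
default_timecourse <- function(cells_per_tp = 120, n_genes = 150, seed = 3,
                               dispersion = 0.1) {
  tree <- make_binary_tree(n_genes = n_genes, seed = 7)
  simulate_timecourse(tree, c(0, 0.25, 0.5, 0.75, 1), cells_per_tp,
                      count_depth = 2000, dispersion = dispersion,
                      seed = seed)
}

# Gaussian cluster embedding: `n_per` points per cluster, cluster centres
# separated by `sep` times the within-cluster SD.
make_cluster_embedding <- function(centres, n_per, sd = 1, seed = 1,
                                   prefix = "c") {
  set.seed(seed)
  coords <- do.call(rbind, lapply(seq_len(nrow(centres)), function(i) {
    matrix(rnorm(n_per * ncol(centres), 0, sd), n_per) +
      matrix(centres[i, ], n_per, ncol(centres), byrow = TRUE)
  }))
  rownames(coords) <- sprintf("%s%04d", prefix, seq_len(nrow(coords)))
  labels <- rep(rownames(centres), each = n_per)
  list(coords = coords, labels = labels)
}

# Brute-force balanced-OT linear program over permutation vertices
# (valid for uniform marginals on square problems: the optimum lies at a
# scaled permutation matrix by Birkhoff's theorem).
lp_transport_oracle <- function(cost) {
  n <- nrow(cost)
  stopifnot(n == ncol(cost))
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  best <- NULL; best_cost <- Inf
  for (p in perms(seq_len(n))) {
    gam <- matrix(0, n, n)
    gam[cbind(seq_len(n), p)] <- 1 / n
    cc <- sum(gam * cost)
    if (cc < best_cost) { best_cost <- cc; best <- gam }
  }
  list(gamma = best, cost = best_cost)
}

# Forward-Euler integration of the branch-mass growth equations;
# independent of state_occupancy()'s closed-form exponentials.
euler_occupancy <- function(tree, t_query, dt = 1e-4) {
  st <- tree$states
  mass <- stats::setNames(rep(0, nrow(st)), st$state_id)
  root <- st$state_id[is.na(st$parent_id)]
  mass[root] <- 1
  active <- stats::setNames(st$state_id == root, st$state_id)
  t <- min(st$birth_time)
  while (t < t_query - dt / 2) {
    for (id in names(mass)[active]) {
      i <- match(id, st$state_id)
      bt <- tree$branch_times[[id]]
      if (!is.na(bt) && t + dt >= bt) {
        kids <- st$state_id[!is.na(st$parent_id) & st$parent_id == id]
        # grow up to the branch, then split
        m <- mass[id] * exp(st$growth[i] * (bt - t))
        mass[id] <- 0; active[id] <- FALSE
        mass[kids] <- mass[kids] + m / length(kids)
        active[kids] <- TRUE
        grow_left <- t + dt - bt
        for (k in kids) {
          ki <- match(k, st$state_id)
          mass[k] <- mass[k] * (1 + st$growth[ki] * grow_left)
        }
      } else {
        mass[id] <- mass[id] * (1 + st$growth[i] * dt)
      }
    }
    t <- t + dt
  }
  mass[!active] <- 0
  mass / sum(mass)
}
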