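#' Build a random branching lineage tree
#'
#' Constructs a ground-truth model of branching cell states for timecourse
#' simulation: a rooted tree in which every state carries a nonnegative
#' per-gene mean expression program and a strictly positive exponential
#' growth rate (per day). Children of a state appear at that state's branch
#' time; states without children are the terminal fates.
#'
#' States are laid out level by level: the root is born at time 0 and the
#' states of level `l` are born at `t_max * l / (depth + 1)`, so with the
#' default `t_max = 1` and `depth = 1` a binary tree branches halfway
#' through the timecourse. Each child inherits its parent's program and
#' perturbs a fraction of genes (`frac_shift`) by lognormal fold changes,
#' which guarantees sibling programs differ in well over 10% of genes.
#'
#' @param n_states Total number of states (root + internal + terminal),
#'   at least 2.
#' @param n_genes Number of genes (>= 10).
#' @param depth Number of branching levels below the root.
#' @param seed Integer seed; the tree is deterministic given the seed.
#' @param t_max Day at which the timecourse ends; branch times are spread
#'   evenly over `[0, t_max]`.
#' @param frac_shift Fraction of genes whose program is perturbed in each
#'   child relative to its parent.
#' @param lfc_sd Standard deviation (log2 scale) of the perturbation fold
#'   changes.
#' @param growth_sd Standard deviation (natural-log scale) of per-state
#'   growth rates around 1 per day.
#'
#' @return An object of class `lineage_tree`: a list with `states`
#'   (data.frame of `state_id`, `parent_id`, `birth_time`, `growth`),
#'   `programs` (states x genes matrix of nonnegative means),
#'   `branch_times` (named vector, `NA` for terminal states),
#'   `terminal_states`, and `t_max`.
#' @export
build_lineage_tree <- function(n_states, n_genes, depth = 1L, seed = 1L,
                               t_max = 1, frac_shift = 0.3, lfc_sd = 1.5,
                               growth_sd = 0.2) {
  if (n_states < 2) {
    stop("n_states must be >= 2: a single state cannot branch into ",
         "distinct terminal fates.")
  }
  if (n_genes < 10) stop("n_genes must be >= 10.")
  if (depth < 1) stop("depth must be >= 1.")
  rng <- local_rng(seed)

  # breadth-first allocation of states across `depth` levels below the root
  level_of <- integer(n_states)
  parent <- rep(NA_integer_, n_states)
  level_members <- list(`0` = 1L)
  next_id <- 2L
  for (lv in seq_len(depth)) {
    prev <- level_members[[as.character(lv - 1L)]]
    remaining <- n_states - next_id + 1L
    if (remaining <= 0L) break
    # give every parent at the previous level two children while ids last;
    # at the last level allow single children so n_states is hit exactly
    kids <- integer(0)
    for (p in prev) {
      n_kids <- min(2L, n_states - next_id + 1L)
      if (lv == depth && length(prev) == 1L && n_kids == 1L) {
        stop("n_states/depth combination leaves a single terminal state; ",
             "increase n_states.")
      }
      if (n_kids <= 0L) break
      ids <- seq.int(next_id, next_id + n_kids - 1L)
      parent[ids] <- p
      level_of[ids] <- lv
      kids <- c(kids, ids)
      next_id <- next_id + n_kids
    }
    level_members[[as.character(lv)]] <- kids
  }
  if (next_id <= n_states) {
    stop("depth ", depth, " cannot accommodate ", n_states,
         " states with binary branching; increase depth.")
  }

  state_id <- sprintf("state%02d", seq_len(n_states))
  birth_time <- t_max * level_of / (depth + 1)
  growth <- exp(stats::rnorm(n_states, 0, growth_sd))

  programs <- matrix(0, n_states, n_genes,
                     dimnames = list(state_id, sprintf("gene%04d", seq_len(n_genes))))
  programs[1, ] <- stats::rgamma(n_genes, shape = 2, rate = 1) + 0.05
  for (i in seq_len(n_states)[-1]) {
    prog <- programs[parent[i], ]
    n_shift <- max(ceiling(frac_shift * n_genes), ceiling(0.15 * n_genes))
    idx <- sample.int(n_genes, n_shift)
    prog[idx] <- prog[idx] * 2^stats::rnorm(n_shift, 0, lfc_sd)
    programs[i, ] <- prog
  }

  has_child <- seq_len(n_states) %in% parent
  branch_times <- rep(NA_real_, n_states)
  names(branch_times) <- state_id
  for (i in which(has_child)) {
    branch_times[i] <- min(birth_time[parent == i & !is.na(parent)])
  }

  tree <- structure(list(
    states = data.frame(state_id = state_id,
                        parent_id = ifelse(is.na(parent), NA_character_,
                                           state_id[parent]),
                        birth_time = birth_time,
                        growth = growth,
                        stringsAsFactors = FALSE),
    programs = programs,
    branch_times = branch_times,
    terminal_states = state_id[!has_child],
    t_max = t_max
  ), class = "lineage_tree")
  validate_lineage_tree(tree)
  tree
}

#' Validate a lineage tree
#'
#' Checks the structural invariants: exactly one root, children born after
#' their parents, every non-terminal state has at least one child, growth
#' rates strictly positive, programs nonnegative.
#'
#' @param tree A `lineage_tree`.
#' @return `tree`, invisibly; errors on violation.
#' @export
validate_lineage_tree <- function(tree) {
  st <- tree$states
  roots <- which(is.na(st$parent_id))
  if (length(roots) != 1L) stop("lineage tree must have exactly one root.")
  for (i in seq_len(nrow(st))[-roots]) {
    p <- match(st$parent_id[i], st$state_id)
    if (is.na(p)) stop("unknown parent_id: ", st$parent_id[i])
    if (st$birth_time[i] <= st$birth_time[p]) {
      stop("child ", st$state_id[i], " born no later than its parent.")
    }
  }
  if (any(st$growth <= 0)) stop("all growth rates must be > 0.")
  if (any(tree$programs < 0)) stop("programs must be nonnegative.")
  non_terminal <- setdiff(st$state_id, tree$terminal_states)
  kids <- st$parent_id[!is.na(st$parent_id)]
  if (!all(non_terminal %in% kids)) {
    stop("every non-terminal state must have at least one child.")
  }
  invisible(tree)
}

# Children of a state (ids).
tree_children <- function(tree, id) {
  st <- tree$states
  st$state_id[!is.na(st$parent_id) & st$parent_id == id]
}

# Active interval of a state: [birth, branch_time) for internal states,
# [birth, Inf) for terminal states.
state_end_time <- function(tree, id) {
  bt <- tree$branch_times[[id]]
  if (is.na(bt)) Inf else bt
}

#' Growth-weighted state occupancy at given times
#'
#' Deterministic branch-mass model underlying the simulator: the root starts
#' with mass 1 at its birth, every state's mass grows exponentially at its
#' own rate while the state is active, and at a state's branch time its mass
#' is split equally among its children. Occupancy at time `t` is the
#' normalised mass of the states active at `t`.
#'
#' @param tree A `lineage_tree`.
#' @param times Numeric vector of days.
#' @return A matrix `length(times)` x n_states of occupancy fractions (rows
#'   sum to 1; inactive states have 0).
#' @export
state_occupancy <- function(tree, times) {
  st <- tree$states
  n <- nrow(st)
  # mass of each state at its own birth
  birth_mass <- stats::setNames(rep(NA_real_, n), st$state_id)
  root <- st$state_id[is.na(st$parent_id)]
  birth_mass[root] <- 1
  ord <- order(st$birth_time)
  for (i in ord) {
    id <- st$state_id[i]
    if (is.na(birth_mass[id])) next
    kids <- tree_children(tree, id)
    if (length(kids) == 0L) next
    bt <- tree$branch_times[[id]]
    m_at_branch <- birth_mass[id] * exp(st$growth[i] * (bt - st$birth_time[i]))
    birth_mass[kids] <- m_at_branch / length(kids)
  }
  occ <- matrix(0, length(times), n, dimnames = list(NULL, st$state_id))
  for (k in seq_along(times)) {
    t <- times[k]
    for (i in seq_len(n)) {
      id <- st$state_id[i]
      if (t < st$birth_time[i] || t >= state_end_time(tree, id)) next
      occ[k, i] <- birth_mass[id] * exp(st$growth[i] * (t - st$birth_time[i]))
    }
    s <- sum(occ[k, ])
    if (s <= 0) stop("no active state at time ", t,
                     "; time grid extends before the root birth time?")
    occ[k, ] <- occ[k, ] / s
  }
  occ
}

# Terminal-fate probabilities for a cell sitting in `state` at time `t`,
# pushing unit mass forward to `horizon` under the tree's growth rates with
# equal splitting at branch points. Mass still sitting in an internal state
# at the horizon is divided equally among that state's terminal descendants.
terminal_fate_probs <- function(tree, state, t, horizon) {
  terms <- tree$terminal_states
  out <- stats::setNames(numeric(length(terms)), terms)
  st <- tree$states
  recurse <- function(id, t0, mass) {
    i <- match(id, st$state_id)
    bt <- tree$branch_times[[id]]
    if (id %in% terms) {
      out[id] <<- out[id] + mass * exp(st$growth[i] * (max(horizon, t0) - t0))
      return(invisible())
    }
    if (!is.na(bt) && bt <= horizon) {
      kids <- tree_children(tree, id)
      m <- mass * exp(st$growth[i] * (bt - t0))
      for (k in kids) recurse(k, bt, m / length(kids))
    } else {
      # still internal at the horizon: attribute equally to descendants
      desc <- terminal_descendants(tree, id)
      out[desc] <<- out[desc] + mass * exp(st$growth[i] * (horizon - t0)) / length(desc)
    }
  }
  recurse(state, t, 1)
  out / sum(out)
}

# Terminal states in the subtree rooted at `id`.
terminal_descendants <- function(tree, id) {
  if (id %in% tree$terminal_states) return(id)
  unlist(lapply(tree_children(tree, id), terminal_descendants, tree = tree))
}

# Section labels: each child-of-root subtree is one anatomical section; the
# root itself (pre-branching lineage) gets its own label.
default_section_map <- function(tree) {
  st <- tree$states
  root <- st$state_id[is.na(st$parent_id)]
  sec <- stats::setNames(rep("S0", nrow(st)), st$state_id)
  kids <- tree_children(tree, root)
  for (j in seq_along(kids)) {
    sub <- c(kids[j], all_descendants(tree, kids[j]))
    sec[sub] <- sprintf("S%d", j)
  }
  sec
}

all_descendants <- function(tree, id) {
  kids <- tree_children(tree, id)
  if (length(kids) == 0L) return(character(0))
  c(kids, unlist(lapply(kids, all_descendants, tree = tree)))
}
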