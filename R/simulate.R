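#' Simulate a branching-differentiation timecourse
#'
#' Samples cells at each point of a fixed time grid from a lineage tree.
#' A cell's latent state is drawn from the growth-weighted branch-mass
#' occupancy at that time (see [state_occupancy()]); its mean expression
#' interpolates linearly from its parent's program at the state's birth to
#' the state's own program at its branch time, so trajectories are
#' transcriptionally continuous; counts are negative-binomial around the
#' mean program scaled to the target depth. Each cell carries analytic
#' ground-truth terminal-fate probabilities: unit mass pushed from the
#' cell's state and time through the tree to the end of the grid under the
#' stated growth rates, with equal splitting at branch points.
#'
#' @param tree A [build_lineage_tree()] result.
#' @param time_grid Strictly increasing vector of days; must not extend
#'   before the root's birth time.
#' @param cells_per_timepoint Cells to sample at each grid point.
#' @param count_depth Target total counts per cell.
#' @param dispersion Negative-binomial dispersion (variance =
#'   `mu + dispersion * mu^2`); 0 gives Poisson noise.
#' @param seed Integer seed; the dataset is deterministic given the seed.
#' @param n_batches Number of batches cells are assigned to (uniformly at
#'   random); batch labels are inert until [inject_batch_effect()].
#' @param section_map Optional named character vector state_id -> section
#'   label; defaults to one section per child-of-root subtree.
#' @return A `timecourse_dataset` with `state_label` in the cell table and
#'   ground-truth `fate_probs`.
#' @export
simulate_timecourse <- function(tree, time_grid, cells_per_timepoint,
                                count_depth = 5000, dispersion = 0.1,
                                seed = 1L, n_batches = 2L,
                                section_map = NULL) {
  if (is.unsorted(time_grid, strictly = TRUE)) {
    stop("time_grid must be strictly increasing.")
  }
  root_birth <- min(tree$states$birth_time)
  if (min(time_grid) < root_birth) {
    stop("time_grid extends before the root birth time (", root_birth, ").")
  }
  if (count_depth <= 0) stop("count_depth must be > 0.")
  rng <- local_rng(seed)
  section_map <- section_map %||% default_section_map(tree)

  n_genes <- ncol(tree$programs)
  genes <- colnames(tree$programs)
  horizon <- max(time_grid)
  terms <- tree$terminal_states

  if (cells_per_timepoint == 0L) {
    empty <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                  dims = c(0, n_genes),
                                  dimnames = list(character(0), genes))
    return(timecourse_dataset(
      empty,
      data.frame(cell_id = character(0), time_point = numeric(0),
                 batch_id = character(0), section_id = character(0),
                 state_label = character(0), stringsAsFactors = FALSE),
      time_grid = time_grid,
      fate_probs = matrix(numeric(0), 0, length(terms),
                          dimnames = list(NULL, terms)),
      ground_truth = list(tree = tree)))
  }

  occ <- state_occupancy(tree, time_grid)
  st <- tree$states
  rows <- list(); meta <- list(); fates <- list()
  cell_counter <- 0L
  for (k in seq_along(time_grid)) {
    t <- time_grid[k]
    states_k <- sample(st$state_id, cells_per_timepoint, replace = TRUE,
                       prob = occ[k, ])
    # one fate row per distinct state at this time
    fate_by_state <- lapply(stats::setNames(unique(states_k), unique(states_k)),
                            terminal_fate_probs, tree = tree, t = t,
                            horizon = horizon)
    mu_by_state <- lapply(stats::setNames(unique(states_k), unique(states_k)),
                          function(s) {
      i <- match(s, st$state_id)
      pid <- st$parent_id[i]
      start <- st$birth_time[i]
      end <- if (is.na(tree$branch_times[[s]])) tree$t_max else tree$branch_times[[s]]
      frac <- if (end > start) min(max((t - start) / (end - start), 0), 1) else 1
      base <- if (is.na(pid)) tree$programs[s, ] else {
        (1 - frac) * tree$programs[pid, ] + frac * tree$programs[s, ]
      }
      base / sum(base) * count_depth
    })
    cnt <- matrix(0L, cells_per_timepoint, n_genes)
    for (c in seq_len(cells_per_timepoint)) {
      mu <- mu_by_state[[states_k[c]]]
      cnt[c, ] <- if (dispersion > 0) {
        stats::rnbinom(n_genes, mu = mu, size = 1 / dispersion)
      } else stats::rpois(n_genes, mu)
    }
    ids <- sprintf("cell%06d", cell_counter + seq_len(cells_per_timepoint))
    cell_counter <- cell_counter + cells_per_timepoint
    rows[[k]] <- cnt
    meta[[k]] <- data.frame(
      cell_id = ids, time_point = t,
      batch_id = sprintf("batch%d", sample.int(n_batches, cells_per_timepoint,
                                               replace = TRUE)),
      section_id = unname(section_map[states_k]),
      state_label = states_k, stringsAsFactors = FALSE)
    fates[[k]] <- do.call(rbind, fate_by_state)[states_k, , drop = FALSE]
  }
  counts <- do.call(rbind, rows)
  cell_table <- do.call(rbind, meta)
  rownames(counts) <- cell_table$cell_id
  colnames(counts) <- genes
  fate_probs <- do.call(rbind, fates)
  rownames(fate_probs) <- cell_table$cell_id

  timecourse_dataset(counts, cell_table, time_grid = time_grid,
                     fate_probs = fate_probs,
                     ground_truth = list(tree = tree),
                     provenance = list(op = "simulate_timecourse", seed = seed,
                                       count_depth = count_depth,
                                       dispersion = dispersion))
}

#' Inject an additive per-batch log-scale expression shift
#'
#' Adds a batch-specific per-gene offset on the log2 scale to every count
#' (counts are re-rounded to integers), emulating the additive batch
#' structure that mutual-nearest-neighbour correction is designed to
#' remove. The first batch (alphabetically) is the reference and gets zero
#' offset; offsets for the others are drawn N(0, magnitude) per gene and
#' stored in `ground_truth$batch_offsets` for oracle checks.
#'
#' @param ds A `timecourse_dataset` with at least two batches.
#' @param magnitude Standard deviation of the per-gene log2 offsets; 0
#'   returns the input unchanged.
#' @param seed Integer seed.
#' @return The perturbed `timecourse_dataset`.
#' @export
inject_batch_effect <- function(ds, magnitude, seed = 1L) {
  batches <- sort(unique(ds$cell_table$batch_id))
  if (length(batches) < 2L) {
    warning("only one batch present; inject_batch_effect is a no-op.")
    return(ds)
  }
  if (magnitude == 0) return(ds)
  rng <- local_rng(seed)
  n_genes <- ncol(ds$counts)
  offsets <- matrix(0, length(batches), n_genes,
                    dimnames = list(batches, colnames(ds$counts)))
  for (b in batches[-1]) {
    offsets[b, ] <- stats::rnorm(n_genes, 0, magnitude)
  }
  counts <- as.matrix(ds$counts)
  for (b in batches[-1]) {
    idx <- ds$cell_table$batch_id == b
    counts[idx, ] <- round(counts[idx, , drop = FALSE] *
                             matrix(2^offsets[b, ], sum(idx), n_genes,
                                    byrow = TRUE))
  }
  ds$counts <- as_sparse_counts(counts)
  ds$ground_truth <- c(ds$ground_truth, list(batch_offsets = offsets))
  ds$provenance$batch_effect <- list(magnitude = magnitude, seed = seed)
  validate_timecourse_dataset(ds)
  ds
}
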