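#' Define terminal target sets
#'
#' Named, pairwise-disjoint sets of cell ids at a reference time point
#' (commonly the end of the timecourse); cells at that time not in any set
#' form the implicit complement, "other_fate".
#'
#' @param reference_time Time label of the target cells.
#' @param ... Named character vectors of cell ids.
#' @return A `target_sets` object.
#' @export
target_sets <- function(reference_time, ...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && is.null(names(sets))) {
    sets <- sets[[1]]
  }
  if (is.null(names(sets)) || any(names(sets) == "")) {
    stop("every target set must be named.")
  }
  ids <- unlist(sets, use.names = FALSE)
  if (anyDuplicated(ids)) {
    stop("target sets must be pairwise disjoint; duplicated ids: ",
         paste(utils::head(unique(ids[duplicated(ids)]), 5), collapse = ", "))
  }
  structure(list(reference_time = reference_time, sets = sets),
            class = "target_sets")
}

#' Build a fate matrix toward terminal target populations
#'
#' For every cell at every time point covered by the map chain, the row of
#' the composed transition matrix to the reference time is summed within
#' each named target set and within the complement ("other_fate"),
#' yielding a row-stochastic cells x fates probability table. Cells at the
#' reference time get indicator rows.
#'
#' @param maps Ordered (earlier to later) list of `transport_map`s ending
#'   at the reference time.
#' @param targets A [target_sets()] over the last map's target cells.
#' @return A `fate_matrix`: list with `probs` (cells x fates, rows sum to
#'   1), `fates`, `reference_time`, and per-cell time bookkeeping.
#' @export
compute_fate_matrix <- function(maps, targets) {
  terminal_ids <- maps[[length(maps)]]$target_ids
  missing <- setdiff(unlist(targets$sets, use.names = FALSE), terminal_ids)
  if (length(missing)) {
    stop("target ids absent from the terminal time point: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (+%d more)", length(missing) - 5))
  }
  fates <- c(names(targets$sets), "other_fate")
  # indicator of fate membership for terminal cells
  Fmat <- matrix(0, length(terminal_ids), length(fates),
                 dimnames = list(terminal_ids, fates))
  assigned <- rep(FALSE, length(terminal_ids))
  for (f in names(targets$sets)) {
    idx <- terminal_ids %in% targets$sets[[f]]
    Fmat[idx, f] <- 1
    assigned <- assigned | idx
  }
  Fmat[!assigned, "other_fate"] <- 1

  blocks <- list(Fmat)   # terminal cells: indicator rows
  for (k in rev(seq_along(maps))) {
    Fmat <- row_normalize(maps[[k]]$gamma) %*% Fmat
    rownames(Fmat) <- maps[[k]]$source_ids
    blocks <- c(list(Fmat), blocks)
  }
  probs <- do.call(rbind, blocks)
  structure(list(probs = probs, fates = fates,
                 reference_time = targets$reference_time,
                 n_intervals = length(maps)),
            class = "fate_matrix")
}

#' Log-odds fate bias
#'
#' `ln(p / (1 - p))` where `p` is each cell's summed probability over the
#' fates of interest; `p` is clipped to `[clip, 1 - clip]` so the log odds
#' stays finite at the simplex boundary. The statistic is 0 exactly at
#' `p = 0.5`, positive for fate-biased cells, and antisymmetric under
#' `p -> 1 - p`.
#'
#' @param fm A `fate_matrix`.
#' @param fate_subset Names of the fates of interest.
#' @param clip Clipping bound in `(0, 0.5)` (default 1e-12).
#' @return A `log_odds_vector`: named numeric vector with attributes
#'   `fates` and `clip`.
#' @export
log_odds <- function(fm, fate_subset, clip = 1e-12) {
  if (length(fate_subset) == 0L) stop("fate_subset must be non-empty.")
  unknown <- setdiff(fate_subset, fm$fates)
  if (length(unknown)) stop("unknown fate name(s): ",
                            paste(unknown, collapse = ", "))
  if (clip <= 0 || clip >= 0.5) stop("clip must lie in (0, 0.5).")
  p <- rowSums(fm$probs[, fate_subset, drop = FALSE])
  p <- pmin(pmax(p, clip), 1 - clip)
  lo <- log(p / (1 - p))
  attr(lo, "fates") <- fate_subset
  attr(lo, "clip") <- clip
  class(lo) <- "log_odds_vector"
  lo
}

#' Select landscape cells by a log-odds threshold
#'
#' Keeps cells with log odds strictly greater than `threshold`
#' (conventional thresholds: 0 for clearly fate-biased cells, relaxed to
#' -0.5 or -1 for complex landscapes where near-threshold cells may still
#' contribute), optionally restricted to an eligible set of state
#' annotations. Masks are nested: lowering the threshold never removes a
#' previously selected cell.
#'
#' @param ds A `timecourse_dataset` whose cells include those in `lo`.
#' @param lo A [log_odds()] vector named by cell id.
#' @param threshold Log-odds cutoff (strict `>`).
#' @param eligible_states Optional character vector of `state_label`
#'   values to which the selection is restricted.
#' @return List with `mask` (named logical over the cells of `lo`) and
#'   `dataset` (the selected subset, metadata carried forward).
#' @export
select_landscape <- function(ds, lo, threshold, eligible_states = NULL) {
  ids <- names(lo) %||% ds$cell_table$cell_id[seq_along(lo)]
  mask <- as.numeric(lo) > threshold
  names(mask) <- ids
  if (!is.null(eligible_states)) {
    st <- ds$cell_table$state_label[match(ids, ds$cell_table$cell_id)]
    mask <- mask & st %in% eligible_states
  }
  keep <- ids[mask & ids %in% ds$cell_table$cell_id]
  if (length(keep) == 0L) {
    stop("no cells pass log-odds threshold ", threshold,
         "; consider lowering it.")
  }
  list(mask = mask, dataset = subset_cells(ds, keep))
}

#' Allocate later cells as descendants of source populations
#'
#' Pushes each named source population's indicator forward through the
#' coupling chain and assigns every later cell to the population giving it
#' maximal pushed mass. Masses are unnormalized by default (each source
#' cell contributes mass 1); `normalize_populations = TRUE` divides by
#' population size instead. Exact ties go to the lexicographically first
#' population name and are flagged.
#'
#' @param maps Ordered list of `transport_map`s starting at the source
#'   population time.
#' @param source_populations Named list of cell-id vectors at the first
#'   map's source time.
#' @param n_intervals How many consecutive maps to push through (default
#'   all); later cells at every pushed-to time point are assigned.
#' @param normalize_populations Compare per-population-normalized masses.
#' @return Data.frame `cell_id`, `time_index`, `population`, `mass`, `tie`.
#' @export
allocate_descendants <- function(maps, source_populations,
                                 n_intervals = length(maps),
                                 normalize_populations = FALSE) {
  if (length(source_populations) == 0L ||
      any(!nzchar(names(source_populations)))) {
    stop("source_populations must be a named list.")
  }
  if (n_intervals > length(maps)) {
    stop("n_intervals (", n_intervals, ") exceeds the available chain of ",
         length(maps), " maps.")
  }
  src_ids <- maps[[1]]$source_ids
  for (pn in names(source_populations)) {
    if (!all(source_populations[[pn]] %in% src_ids)) {
      stop("population '", pn, "' contains ids absent at the source time.")
    }
  }
  pops <- sort(names(source_populations))
  # mass vectors over source cells
  mass <- sapply(pops, function(pn) {
    v <- as.numeric(src_ids %in% source_populations[[pn]])
    if (normalize_populations) v / sum(v) else v
  })
  out <- list()
  for (k in seq_len(n_intervals)) {
    P <- row_normalize(maps[[k]]$gamma)
    mass <- crossprod(P, mass)            # push each population forward
    tgt <- maps[[k]]$target_ids
    winner <- max.col(mass, ties.method = "first")
    best <- mass[cbind(seq_len(nrow(mass)), winner)]
    n_best <- rowSums(mass == best)
    out[[k]] <- data.frame(cell_id = tgt, time_index = k,
                           population = pops[winner], mass = best,
                           tie = n_best > 1L, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
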