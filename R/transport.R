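#' Transport configuration
#'
#' Settings for the unbalanced entropic optimal-transport solver. The
#' defaults (`epsilon = 0.05` on a median-normalized cost,
#' `lambda_source = 1`, `lambda_target = 50`) follow the published
#' defaults of the unbalanced-OT trajectory framework this module
#' implements; `lambda = Inf` makes the corresponding marginal a hard
#' constraint (balanced transport on that side).
#'
#' @param epsilon Entropic regularization strength (> 0).
#' @param lambda_source,lambda_target Marginal relaxation strengths
#'   (> 0; `Inf` = hard constraint).
#' @param max_iterations Maximum scaling iterations.
#' @param tolerance Convergence tolerance on the successive change of the
#'   log scaling vectors.
#' @param growth_iterations Growth-learning iterations (default 3).
#' @param normalize_cost Divide the cost matrix by its median so `epsilon`
#'   is scale-free (default `TRUE`).
#' @return A `transport_config` list.
#' @export
transport_config <- function(epsilon = 0.05, lambda_source = 1,
                             lambda_target = 50, max_iterations = 5000,
                             tolerance = 1e-8, growth_iterations = 3,
                             normalize_cost = TRUE) {
  stopifnot(epsilon > 0, growth_iterations >= 0,
            lambda_source > 0, lambda_target > 0)
  structure(list(epsilon = epsilon, lambda_source = lambda_source,
                 lambda_target = lambda_target,
                 max_iterations = max_iterations, tolerance = tolerance,
                 growth_iterations = growth_iterations,
                 normalize_cost = normalize_cost),
            class = "transport_config")
}

#' Collapse time points into merged labels
#'
#' Relabels cell time points according to `groups` (a named list mapping a
#' merged value to the original time points it absorbs) and updates the
#' declared grid; counts are untouched. Merging non-adjacent time points
#' is allowed but flagged with a warning.
#'
#' @param ds A `timecourse_dataset`.
#' @param groups Named list: `list("0.875" = c(0.75, 1.0))` relabels cells
#'   at days 0.75 and 1.0 to day 0.875.
#' @return The relabelled dataset.
#' @export
collapse_timepoints <- function(ds, groups) {
  if (length(groups) == 0L) return(ds)
  tp <- ds$cell_table$time_point
  grid <- ds$time_grid
  for (lab in names(groups)) {
    members <- groups[[lab]]
    if (!all(members %in% grid)) {
      stop("group '", lab, "' references time points not on the grid: ",
           paste(setdiff(members, grid), collapse = ", "))
    }
    pos <- sort(match(members, sort(grid)))
    if (length(pos) > 1 && any(diff(pos) != 1)) {
      warning("group '", lab, "' merges non-adjacent time points.")
    }
    tp[ds$cell_table$time_point %in% members] <- as.numeric(lab)
    grid <- sort(unique(c(setdiff(grid, members), as.numeric(lab))))
  }
  ds$cell_table$time_point <- tp
  ds$time_grid <- grid
  validate_timecourse_dataset(ds)
  ds
}

#' Squared-Euclidean cost matrix between two embeddings
#'
#' @param emb_t,emb_t1 Matrices (or `embedding` objects) of cells at the
#'   earlier and later time point, same component dimension.
#' @param normalize Divide by the median positive cost so the entropic
#'   scale is dimension-free; recorded in the `"median"` attribute.
#' @return Nonnegative source x target matrix; attribute `median` holds
#'   the normalizing constant (1 when `normalize = FALSE`).
#' @export
cost_matrix <- function(emb_t, emb_t1, normalize = FALSE) {
  X <- if (inherits(emb_t, "embedding")) emb_t$coords else as.matrix(emb_t)
  Y <- if (inherits(emb_t1, "embedding")) emb_t1$coords else as.matrix(emb_t1)
  if (ncol(X) != ncol(Y)) {
    stop("embedding dimensions differ: ", ncol(X), " vs ", ncol(Y), ".")
  }
  C <- cross_dist2(X, Y)
  med <- 1
  if (normalize) {
    med <- stats::median(C[C > 0])
    if (is.na(med) || med <= 0) med <- 1
    C <- C / med
  }
  attr(C, "median") <- med
  C
}

#' Unbalanced entropic optimal transport by Sinkhorn scaling
#'
#' Finds the coupling minimizing
#' `<gamma, C> + epsilon*KL(gamma || a x b) + lambda_s*KL(gamma 1 || a)
#'  + lambda_t*KL(t(gamma) 1 || b)`
#' by alternating scaling updates `u = (a / K v)^(lambda_s/(lambda_s+eps))`
#' (and symmetrically for `v`), where `K = exp(-C/epsilon)`. With
#' `lambda = Inf` the exponent is 1 and the corresponding marginal is
#' matched exactly (classical Sinkhorn). Iterations run in the log domain
#' whenever `epsilon` is small relative to the cost scale (below 1% of the
#' median cost), or when the plain scalings overflow.
#'
#' @param cost Finite source x target cost matrix.
#' @param source_weights,target_weights Positive marginal weights.
#' @param config A [transport_config()].
#' @return A `transport_map`: list with `gamma`, ids, the config, and
#'   convergence diagnostics (`iterations`, `converged`, `marginal_error`
#'   = max relative row-sum deviation in balanced mode).
#' @export
unbalanced_sinkhorn <- function(cost, source_weights, target_weights,
                                config = transport_config()) {
  C <- as.matrix(cost)
  a <- as.numeric(source_weights); b <- as.numeric(target_weights)
  stopifnot(all(is.finite(C)), all(a > 0), all(b > 0),
            length(a) == nrow(C), length(b) == ncol(C))
  eps <- config$epsilon
  med <- attr(cost, "median")
  fs <- if (is.infinite(config$lambda_source)) 1 else
    config$lambda_source / (config$lambda_source + eps)
  ft <- if (is.infinite(config$lambda_target)) 1 else
    config$lambda_target / (config$lambda_target + eps)

  med_c <- stats::median(C[C > 0])
  if (!is.finite(med_c) || med_c <= 0) med_c <- 1
  use_log <- eps < 0.01 * med_c
  la <- log(a); lb <- log(b)
  n <- nrow(C); m <- ncol(C)
  converged <- FALSE; it <- 0L

  if (!use_log) {
    K <- exp(-C / eps)
    u <- rep(1, n); v <- rep(1, m)
    for (it in seq_len(config$max_iterations)) {
      u_old <- u
      Kv <- as.numeric(K %*% v)
      if (any(Kv <= 0) || any(!is.finite(Kv))) { use_log <- TRUE; break }
      u <- (a / Kv)^fs
      Ktu <- as.numeric(crossprod(K, u))
      if (any(Ktu <= 0) || any(!is.finite(Ktu))) { use_log <- TRUE; break }
      v <- (b / Ktu)^ft
      if (max(abs(log(u) - log(u_old))) < config$tolerance) {
        converged <- TRUE; break
      }
      if (max(u, v) > 1e100) { use_log <- TRUE; break }
    }
    if (!use_log) gamma <- sweep(sweep(K, 1, u, "*"), 2, v, "*")
  }
  if (use_log) {
    # potentials phi = eps*log(u), psi = eps*log(v); log-sum-exp updates
    phi <- rep(0, n); psi <- rep(0, m)
    negC <- -C
    lse_rows <- function(M) {
      mx <- apply(M, 1, max)
      mx + log(rowSums(exp(M - mx)))
    }
    converged <- FALSE
    for (it in seq_len(config$max_iterations)) {
      phi_old <- phi
      phi <- fs * eps * (la - lse_rows(sweep(negC, 2, psi, "+") / eps))
      psi <- ft * eps * (lb - lse_rows(t(sweep(negC, 1, phi, "+")) / eps))
      if (max(abs(phi - phi_old)) / eps < config$tolerance) {
        converged <- TRUE; break
      }
    }
    gamma <- exp((negC + outer(phi, psi, "+")) / eps)
  }
  if (any(!is.finite(gamma))) {
    stop("non-finite entries in the transport scaling; try a larger epsilon.")
  }
  marg_err <- if (is.infinite(config$lambda_source)) {
    max(abs(rowSums(gamma) - a) / a)
  } else NA_real_
  if (!converged) {
    warning("sinkhorn did not reach tolerance ", config$tolerance, " in ",
            config$max_iterations, " iterations (returning best iterate).")
  }
  structure(list(gamma = gamma,
                 source_ids = rownames(C) %||% as.character(seq_len(n)),
                 target_ids = colnames(C) %||% as.character(seq_len(m)),
                 config = config, growth = NULL,
                 diagnostics = list(iterations = it, converged = converged,
                                    marginal_error = marg_err,
                                    log_domain = use_log)),
            class = "transport_map")
}

#' Learn per-cell growth rates with a transport coupling
#'
#' Alternates between solving the unbalanced transport problem and updating
#' per-source-cell growth rates from the realized transported mass:
#' source weights are set proportional to `g_i^dt` (normalized), the
#' coupling is solved, and the new rate is
#' `(row_mass_i / mean row mass)^(1/dt)` floored at a small positive
#' constant. The number of alternations is
#' `config$growth_iterations` (default 3).
#'
#' @param cost Source x target cost matrix.
#' @param initial_growth Positive per-source-cell rates per day (default
#'   all 1).
#' @param config A [transport_config()].
#' @param dt Interval length in days (> 0), computed from the declared
#'   time grid by the pipeline.
#' @param target_weights Target marginal (default uniform).
#' @param floor Lower bound on learned rates.
#' @return List with `growth` (rates + `dt`) and `map` (the final
#'   `transport_map`).
#' @export
learn_growth_rates <- function(cost, initial_growth = NULL,
                               config = transport_config(), dt,
                               target_weights = NULL, floor = 0.05) {
  if (dt <= 0) stop("dt must be > 0.")
  n <- nrow(cost); m <- ncol(cost)
  g <- initial_growth %||% rep(1, n)
  stopifnot(all(g > 0), length(g) == n)
  b <- target_weights %||% rep(1 / m, m)
  map <- NULL
  for (iter in seq_len(max(config$growth_iterations, 1L))) {
    a <- g^dt; a <- a / sum(a)
    map <- unbalanced_sinkhorn(cost, a, b, config)
    if (config$growth_iterations == 0L) break
    row_mass <- rowSums(map$gamma)
    g <- pmax((row_mass / mean(row_mass))^(1 / dt), floor)
    if (iter >= config$growth_iterations) break
  }
  if (config$growth_iterations == 0L && is.null(map)) {
    a <- g^dt; a <- a / sum(a)
    map <- unbalanced_sinkhorn(cost, a, b, config)
  }
  growth <- structure(list(rates = g, dt = dt), class = "growth_rates")
  map$growth <- growth
  list(growth = growth, map = map)
}

# Row-normalize a coupling into a transition matrix.
row_normalize <- function(gamma) {
  rs <- rowSums(gamma)
  if (any(rs <= 0)) stop("coupling has an all-zero row; cannot normalize.")
  gamma / rs
}

#' Compose transport maps into a multi-interval transition matrix
#'
#' Each coupling is row-normalized into a transition matrix, then the
#' chain is matrix-multiplied left to right. The composed result is
#' row-stochastic regardless of the input scalings.
#'
#' @param maps List of `transport_map`s whose target ids chain into the
#'   next map's source ids.
#' @return A `transport_map` whose `gamma` is the composed row-stochastic
#'   transition matrix from the first map's sources to the last map's
#'   targets.
#' @export
compose_maps <- function(maps) {
  if (length(maps) == 0L) stop("no maps to compose.")
  for (i in seq_along(maps)[-1]) {
    if (!identical(maps[[i - 1]]$target_ids, maps[[i]]$source_ids)) {
      stop("maps do not chain: targets of map ", i - 1,
           " differ from sources of map ", i, ".")
    }
  }
  P <- row_normalize(maps[[1]]$gamma)
  for (i in seq_along(maps)[-1]) P <- P %*% row_normalize(maps[[i]]$gamma)
  structure(list(gamma = P, source_ids = maps[[1]]$source_ids,
                 target_ids = maps[[length(maps)]]$target_ids,
                 config = maps[[1]]$config, growth = NULL,
                 diagnostics = list(composed_from = length(maps))),
            class = "transport_map")
}

#' Push a cell distribution through transport maps
#'
#' Forward pushing propagates a distribution over the first map's source
#' cells to the last map's targets through the row-normalized chain
#' (descendant distribution); backward pushing propagates a distribution
#' over the last map's targets to the first map's sources through the
#' column-normalized chain in reverse (ancestor distribution). The output
#' always sums to 1.
#'
#' @param distribution Nonnegative vector summing to 1, named by or aligned
#'   with the cells at the starting end.
#' @param maps Ordered (earlier to later) list of `transport_map`s.
#' @param direction `"forward"` or `"backward"`.
#' @return Named probability vector over the cells at the other end.
#' @export
push_distribution <- function(distribution, maps, direction = c("forward",
                                                                "backward")) {
  direction <- match.arg(direction)
  d <- as.numeric(distribution)
  if (any(d < 0)) stop("distribution must be nonnegative.")
  if (abs(sum(d) - 1) > 1e-6) stop("distribution must sum to 1.")
  if (direction == "forward") {
    if (length(d) != length(maps[[1]]$source_ids)) {
      stop("distribution length ", length(d), " does not match the ",
           length(maps[[1]]$source_ids), " source cells of the first map.")
    }
    for (mp in maps) d <- as.numeric(d %*% row_normalize(mp$gamma))
    stats::setNames(d / sum(d), maps[[length(maps)]]$target_ids)
  } else {
    last <- maps[[length(maps)]]
    if (length(d) != length(last$target_ids)) {
      stop("distribution length ", length(d), " does not match the ",
           length(last$target_ids), " target cells of the last map.")
    }
    for (mp in rev(maps)) {
      cs <- colSums(mp$gamma)
      if (any(cs <= 0)) stop("coupling has an all-zero column; cannot normalize.")
      d <- as.numeric((mp$gamma %*% (d / cs)))
    }
    stats::setNames(d / sum(d), maps[[1]]$source_ids)
  }
}

#' Compute transport maps along a whole timecourse
#'
#' For each pair of consecutive (possibly collapsed) time points, builds
#' the squared-Euclidean cost on the batch-corrected embedding, learns
#' growth rates, and returns the per-interval couplings.
#'
#' @param ds A preprocessed `timecourse_dataset` (embedding present).
#' @param config A [transport_config()].
#' @return Ordered list of `transport_map`s, one per interval, named
#'   `"t0->t1"` etc.
#' @export
transport_timecourse <- function(ds, config = transport_config()) {
  if (is.null(ds$embedding)) stop("dataset has no embedding; run preprocess first.")
  grid <- sort(unique(ds$cell_table$time_point))
  if (length(grid) < 2L) stop("need at least two time points.")
  maps <- list()
  for (k in seq_len(length(grid) - 1L)) {
    src <- ds$cell_table$cell_id[ds$cell_table$time_point == grid[k]]
    tgt <- ds$cell_table$cell_id[ds$cell_table$time_point == grid[k + 1]]
    C <- cost_matrix(ds$embedding$coords[src, , drop = FALSE],
                     ds$embedding$coords[tgt, , drop = FALSE],
                     normalize = config$normalize_cost)
    res <- learn_growth_rates(C, config = config, dt = grid[k + 1] - grid[k])
    maps[[sprintf("%g->%g", grid[k], grid[k + 1])]] <- res$map
  }
  maps
}
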