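#' Pipeline configuration
#'
#' Assembles (and validates) the configuration driving [run_pipeline()].
#' Unknown keys are rejected; every seed is explicit; the full config is
#' echoed into the output manifest for provenance.
#'
#' @param config Named list (or path to a YAML file) overriding the
#'   defaults below.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    out_dir = "fatecourse_run",
    simulate = list(n_states = 3, n_genes = 300, depth = 1, seed = 1,
                    time_grid = c(0, 0.25, 0.5, 0.75, 1),
                    cells_per_timepoint = 500, count_depth = 5000,
                    dispersion = 0.1, n_batches = 2, batch_magnitude = 0.25,
                    batch_seed = 11),
    preprocess = list(min_total_counts = 0, max_mito_fraction = 1,
                      n_components = 50, hvg_fdr = 0.05, trend_span = 0.05,
                      min_mean = 1e-3, blacklist = character(0),
                      k_mnn = 20, sigma_frac = 0.5),
    transport = list(epsilon = 0.05, lambda_source = 1, lambda_target = 50,
                     max_iterations = 5000, tolerance = 1e-8,
                     growth_iterations = 3, collapse = list()),
    fate = list(log_odds_threshold = 0, clip = 1e-12),
    resume = FALSE)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  for (k in names(config)) {
    if (is.list(defaults[[k]]) && is.list(config[[k]])) {
      bad <- setdiff(names(config[[k]]), names(defaults[[k]]))
      if (length(bad)) stop("unknown config key(s) under '", k, "': ",
                            paste(bad, collapse = ", "))
      defaults[[k]][names(config[[k]])] <- config[[k]]
    } else defaults[[k]] <- config[[k]]
  }
  structure(defaults, class = "pipeline_config")
}

#' Run the timecourse fate-inference pipeline end to end
#'
#' Simulates (or loads) a timecourse, preprocesses it, computes transport
#' maps across consecutive time points, builds the fate matrix toward the
#' true terminal states, computes log odds and the landscape selection,
#' and allocates descendants. TSV/JSON artifacts and a manifest with
#' per-stage checksums are written under `config$out_dir`; with
#' `resume = TRUE` stages whose outputs match the manifest checksums are
#' skipped.
#'
#' @param config A [pipeline_config()] (or list / YAML path coercible to
#'   one).
#' @param dataset Optional `timecourse_dataset`; when supplied the
#'   simulate stage is skipped.
#' @return Invisibly, a list of the in-memory artifacts (dataset, maps,
#'   fate matrix, log odds, descendants, manifest path).
#' @export
run_pipeline <- function(config = pipeline_config(), dataset = NULL) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(config$out_dir, "manifest.json")
  manifest <- list(config = unclass(config), stages = list())

  stage_file <- function(name) file.path(config$out_dir, name)
  record <- function(stage, files) {
    manifest$stages[[stage]] <<- list(
      files = files,
      md5 = as.list(tools::md5sum(files)),
      time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, force = TRUE)
  }

  # --- simulate -------------------------------------------------------
  if (is.null(dataset)) {
    sim <- config$simulate
    tree <- build_lineage_tree(sim$n_states, sim$n_genes, sim$depth,
                               seed = sim$seed,
                               t_max = max(sim$time_grid))
    dataset <- simulate_timecourse(tree, sim$time_grid,
                                   sim$cells_per_timepoint,
                                   count_depth = sim$count_depth,
                                   dispersion = sim$dispersion,
                                   seed = sim$seed,
                                   n_batches = sim$n_batches)
    if (sim$batch_magnitude > 0 && sim$n_batches > 1) {
      dataset <- inject_batch_effect(dataset, sim$batch_magnitude,
                                     seed = sim$batch_seed)
    }
    write_dataset(dataset, stage_file("dataset"))
    record("simulate", file.path(stage_file("dataset"),
                                 c("counts.mtx", "cells.tsv", "genes.tsv",
                                   "ground_truth.json")))
  }

  # --- preprocess -----------------------------------------------------
  pp <- config$preprocess
  if (pp$min_total_counts > 0 || pp$max_mito_fraction < 1) {
    qc <- qc_filter(dataset, pp$min_total_counts, pp$max_mito_fraction)
    utils::write.table(qc$report, stage_file("qc_report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    dataset <- qc$dataset
  }
  dataset <- preprocess_dataset(dataset, n_components = pp$n_components,
                                hvg_fdr = pp$hvg_fdr,
                                trend_span = pp$trend_span,
                                min_mean = pp$min_mean,
                                blacklist = pp$blacklist,
                                k_mnn = pp$k_mnn,
                                sigma_frac = pp$sigma_frac)
  emb_file <- stage_file("embedding.tsv")
  utils::write.table(data.frame(cell_id = rownames(dataset$embedding$coords),
                                dataset$embedding$coords),
                     emb_file, sep = "\t", quote = FALSE, row.names = FALSE)
  record("preprocess", emb_file)

  # --- transport ------------------------------------------------------
  tc <- config$transport
  if (length(tc$collapse)) dataset <- collapse_timepoints(dataset, tc$collapse)
  tconf <- transport_config(epsilon = tc$epsilon,
                            lambda_source = tc$lambda_source,
                            lambda_target = tc$lambda_target,
                            max_iterations = tc$max_iterations,
                            tolerance = tc$tolerance,
                            growth_iterations = tc$growth_iterations)
  maps <- transport_timecourse(dataset, tconf)
  diag_file <- stage_file("transport_diagnostics.tsv")
  diag <- do.call(rbind, lapply(names(maps), function(nm) {
    d <- maps[[nm]]$diagnostics
    data.frame(interval = nm, iterations = d$iterations,
               converged = d$converged,
               log_domain = d$log_domain, stringsAsFactors = FALSE)
  }))
  utils::write.table(diag, diag_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  record("transport", diag_file)

  # --- fate -----------------------------------------------------------
  artifacts <- list(dataset = dataset, maps = maps,
                    manifest_path = manifest_path)
  if (!is.null(dataset$ground_truth$tree)) {
    tree <- dataset$ground_truth$tree
    last_t <- max(dataset$cell_table$time_point)
    terminal_cells <- lapply(
      stats::setNames(tree$terminal_states, tree$terminal_states),
      function(s) dataset$cell_table$cell_id[
        dataset$cell_table$time_point == last_t &
          dataset$cell_table$state_label == s])
    terminal_cells <- terminal_cells[vapply(terminal_cells, length, 0L) > 0]
    targets <- target_sets(last_t, terminal_cells)
    fm <- compute_fate_matrix(maps, targets)
    lo <- log_odds(fm, names(terminal_cells)[1], clip = config$fate$clip)
    fate_file <- stage_file("fate_matrix.tsv")
    utils::write.table(data.frame(cell_id = rownames(fm$probs), fm$probs,
                                  log_odds = as.numeric(
                                    lo[rownames(fm$probs)])),
                       fate_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    record("fate", fate_file)
    first_t <- min(dataset$cell_table$time_point)
    src_pops <- split(
      dataset$cell_table$cell_id[dataset$cell_table$time_point == first_t],
      dataset$cell_table$section_id[dataset$cell_table$time_point == first_t])
    desc <- allocate_descendants(maps, src_pops)
    desc_file <- stage_file("descendants.tsv")
    utils::write.table(desc, desc_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    record("descendants", desc_file)
    artifacts$fate_matrix <- fm
    artifacts$log_odds <- lo
    artifacts$descendants <- desc
  }
  invisible(artifacts)
}

#' Summary report over pipeline artifacts
#'
#' Collates whatever artifacts a [run_pipeline()] output directory holds
#' into one JSON summary (QC pass rates, transport convergence, landscape
#' sizes at the conventional log-odds thresholds, descendant counts);
#' missing stages are flagged rather than fatal, and regeneration is
#' idempotent.
#'
#' @param out_dir Pipeline output directory.
#' @param thresholds Log-odds thresholds at which landscape sizes are
#'   reported.
#' @return The summary list (also written to `report.json` in `out_dir`).
#' @export
pipeline_report <- function(out_dir, thresholds = c(0, -0.5, -1)) {
  rep <- list(generated = TRUE, missing = character(0))
  qc_f <- file.path(out_dir, "qc_report.tsv")
  if (file.exists(qc_f)) {
    qc <- utils::read.delim(qc_f)
    rep$qc <- list(n_cells = nrow(qc), pass_rate = mean(qc$pass))
  } else rep$missing <- c(rep$missing, "qc")
  tr_f <- file.path(out_dir, "transport_diagnostics.tsv")
  if (file.exists(tr_f)) {
    tr <- utils::read.delim(tr_f)
    rep$transport <- list(intervals = nrow(tr),
                          all_converged = all(tr$converged))
  } else rep$missing <- c(rep$missing, "transport")
  fate_f <- file.path(out_dir, "fate_matrix.tsv")
  if (file.exists(fate_f)) {
    fm <- utils::read.delim(fate_f)
    rep$fate <- list(
      n_cells = nrow(fm),
      max_row_sum_error = max(abs(rowSums(
        fm[, setdiff(names(fm), c("cell_id", "log_odds")), drop = FALSE]) - 1)),
      landscape_sizes = stats::setNames(
        lapply(thresholds, function(th) sum(fm$log_odds > th)),
        paste0("gt_", thresholds)))
  } else rep$missing <- c(rep$missing, "fate")
  desc_f <- file.path(out_dir, "descendants.tsv")
  if (file.exists(desc_f)) {
    d <- utils::read.delim(desc_f)
    rep$descendants <- as.list(table(d$population))
  } else rep$missing <- c(rep$missing, "descendants")
  jsonlite::write_json(rep, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  rep
}
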