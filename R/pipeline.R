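#' Default end-to-end run configuration
#'
#' Returns the configuration list accepted by \code{\link{run_pipeline}},
#' optionally overridden from a YAML file and/or named arguments. Knobs and
#' defaults: \code{alpha_siso = 0.001} (SISO phenotype t-test),
#' \code{alpha_miso = 0.01} (ANOVA/Tukey logic test), \code{k = 2}
#' (compatibility band), \code{expression_threshold = 0.1},
#' \code{global_max_rfu = 75000}, \code{cv = 0.10}, \code{n_replicates = 6},
#' \code{estimator = "min_corner"}, \code{gate_types = c("AND", "NOR")},
#' \code{seed = 1}. \code{catalogue} may be a path to a catalogue file
#' (default: built-in demonstration catalogue). Configurations round-trip
#' losslessly through \code{yaml::write_yaml}.
#'
#' @param path optional YAML file with overrides.
#' @param ... named overrides applied after the file.
#' @return named list.
#' @export
run_config <- function(path = NULL, ...) {
  cfg <- list(seed = 1L, outdir = NULL, catalogue = NULL,
              gate_types = c("AND", "NOR"),
              cv = 0.10, n_replicates = 6L,
              alpha_siso = 0.001, alpha_miso = 0.01, k = 2,
              expression_threshold = 0.1, global_max_rfu = 75000,
              estimator = "min_corner")
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    over <- yaml::read_yaml(path)
    cfg[names(over)] <- over
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  stopifnot(cfg$alpha_siso > 0, cfg$alpha_siso < 1,
            cfg$alpha_miso > 0, cfg$alpha_miso < 1,
            cfg$k >= 0, cfg$cv >= 0, cfg$n_replicates >= 2,
            cfg$expression_threshold > 0, cfg$global_max_rfu > 0,
            all(cfg$gate_types %in% GATE_TYPES_MISO))
  cfg
}

#' Run the full design-predict-validate pipeline on synthetic data
#'
#' Orchestrates every stage end to end: simulate SISO plate data from a
#' ground-truth library, process plates (blank correction, OD normalization,
#' unit scaling), classify phenotypes and extract \eqn{(\epsilon, \sigma)},
#' enumerate and screen SE-PA pair spaces, parameterize corner models for
#' passing pairs, simulate measurements of those two-input gates from the
#' ground truth, and validate predictions (objective-logic tests and fold
#' errors). Deterministic for a fixed \code{seed}. When \code{outdir} is set,
#' every stage's table is written as TSV/JSON so stages can be inspected or
#' rerun independently.
#'
#' @param config list from \code{\link{run_config}} (or a YAML path).
#' @param deviation per-corner deviation factor(s) applied when simulating
#'   the two-input measurements (1 = model-faithful).
#' @return list of class \code{misogate_run}: per-stage tables
#'   (\code{truth}, \code{siso_table}, \code{pairs}, \code{verdicts},
#'   \code{predictions}, \code{validations}, \code{per_corner}), the design
#'   space \code{counts}, and the library \code{report}.
#' @examples
#' \donttest{
#' run <- run_pipeline(run_config(gate_types = "AND", seed = 17))
#' run$counts
#' run$report$mean_error
#' }
#' @export
run_pipeline <- function(config = run_config(), deviation = 1) {
  if (is.character(config)) config <- run_config(config)
  set.seed(config$seed)
  catalogue <- if (is.null(config$catalogue)) default_catalogue()
               else if (inherits(config$catalogue, "gate_catalogue")) config$catalogue
               else read_catalogue(config$catalogue)
  noise <- noise_model(cv = config$cv, n_replicates = config$n_replicates)

  # which SISO regimes do the requested 2-INPUT types need?
  need_types <- unique(unlist(lapply(config$gate_types, miso_slot_phenotypes)))
  siso_types <- c(if ("REPRESSOR" %in% need_types) "BUFFER",
                  if ("ANTIREPRESSOR" %in% need_types) "NOT")

  # stage 1-3: simulate, process, classify each SISO regime
  truth <- list(); wells <- list(); summaries <- list()
  for (st in siso_types) {
    lib <- generate_siso_library(catalogue, st, noise = noise,
                                 global_max_rfu = config$global_max_rfu)
    pp <- process_plate(lib$plate, config$global_max_rfu)
    truth[[st]] <- lib$truth
    wells[[st]] <- pp$wells
    summaries[[st]] <- pp$summaries
  }
  truth <- do.call(rbind, truth); rownames(truth) <- NULL
  wells <- do.call(rbind, wells); rownames(wells) <- NULL
  summaries <- do.call(rbind, summaries); rownames(summaries) <- NULL
  siso_table <- fit_siso_table(wells, config$alpha_siso,
                               config$expression_threshold)

  counts <- list(
    buffer_designs = nrow(enumerate_siso_space(catalogue, "BUFFER")),
    not_designs = nrow(enumerate_siso_space(catalogue, "NOT")))

  # measured phenotypes flow into the design table for tier-1 filtering
  designs <- truth[, c("gate_id", "gate_type", "position", "rcd", "adr")]
  designs$architecture <- "SISO"
  designs$phenotype <- siso_table$phenotype[match(designs$gate_id,
                                                  siso_table$gate_id)]

  pairs_all <- list(); verdicts <- list(); gates <- list()
  validations <- NULL; per_corner <- NULL; positions <- c()
  miso_wells <- list(); miso_summaries <- list()
  for (gt in config$gate_types) {
    putative <- enumerate_sepa_pairs(designs, gt,
                                     apply_functionality_filter = FALSE)
    counts[[paste0(tolower(gt), "_putative_pairs")]] <- nrow(putative)
    screened <- screen_space(
      enumerate_sepa_pairs(designs, gt, apply_functionality_filter = TRUE),
      siso_table, wells = wells, k = config$k, alpha = config$alpha_siso)
    counts[[paste0(tolower(gt), "_passing_pairs")]] <- nrow(screened$passing)
    pairs_all[[gt]] <- putative
    verdicts[[gt]] <- screened$verdicts

    for (i in seq_len(nrow(screened$passing))) {
      p <- screened$passing[i, ]
      px <- as.list(siso_table[siso_table$gate_id == p$siso_a, ])
      py <- as.list(siso_table[siso_table$gate_id == p$siso_b, ])
      g <- miso_gate(px, py, gt, estimator = config$estimator,
                     gate_id = p$gate_id)
      gates[[p$gate_id]] <- g
      positions[p$gate_id] <- p$position
      # stage 6: measure the gate (simulated from ground truth)
      tx <- as.list(truth[truth$gate_id == p$siso_a, ])
      ty <- as.list(truth[truth$gate_id == p$siso_b, ])
      sim <- simulate_miso_measurements(tx, ty, gt, deviation = deviation,
                                        noise = noise,
                                        estimator = config$estimator,
                                        gate_id = p$gate_id,
                                        global_max_rfu = config$global_max_rfu)
      mp <- process_plate(sim$plate, config$global_max_rfu)
      miso_wells[[p$gate_id]] <- mp$wells
      miso_summaries[[p$gate_id]] <- mp$summaries
    }
  }

  result <- list(config = config, counts = counts, truth = truth,
                 siso_table = siso_table,
                 pairs = do.call(rbind, pairs_all),
                 verdicts = do.call(rbind, verdicts),
                 gates = gates)
  if (length(gates)) {
    mw <- do.call(rbind, miso_wells); rownames(mw) <- NULL
    ms <- do.call(rbind, miso_summaries); rownames(ms) <- NULL
    val <- validate_library(gates, mw, ms, positions = positions,
                            alpha = config$alpha_miso)
    result$validations <- val$validations
    result$per_corner <- val$per_corner
    result$report <- val$report
  }
  class(result) <- "misogate_run"

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config$outdir, f)
    utils::write.table(siso_table, out("siso_table.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_design_tsv(result$pairs, out("pairs.tsv"))
    write_verdict_tsv(result$verdicts, out("verdicts.tsv"))
    write_prediction_tsv(gates, out("predictions.tsv"))
    if (!is.null(result$validations))
      utils::write.table(result$validations, out("validations.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(counts = counts,
                              report = result$report %||% NULL),
                         out("report.json"), auto_unbox = TRUE, digits = NA)
  }
  result
}

#' @export
print.misogate_run <- function(x, ...) {
  cat("Transcriptional logic gate pipeline run (seed", x$config$seed, ")\n")
  cat("  SISO designs :", x$counts$buffer_designs %||% 0, "BUFFER,",
      x$counts$not_designs %||% 0, "NOT\n")
  op <- table(x$siso_table$phenotype)
  cat("  phenotypes   :", paste(names(op), op, collapse = ", "), "\n")
  for (gt in x$config$gate_types)
    cat(sprintf("  %-11s: %d putative pairs, %d passed screening\n", gt,
                x$counts[[paste0(tolower(gt), "_putative_pairs")]],
                x$counts[[paste0(tolower(gt), "_passing_pairs")]]))
  if (!is.null(x$report))
    cat(sprintf("  validation   : mean fold error %.3f, %.1f%% corners within 2-fold, %.1f%% objective logic\n",
                x$report$mean_error, x$report$pct_within_2fold_corners,
                x$report$pct_objective_logic))
  invisible(x)
}
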