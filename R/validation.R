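#' Test a measured two-input gate for objective Boolean logic
#'
#' A one-way ANOVA is run across the four inducer conditions, followed by a
#' Tukey honest-significant-difference test (Tukey-Kramer under unbalanced
#' replication) on the condition pairs. The gate shows objective logic when
#' its gate type's designated ON corner is significantly higher (adjusted
#' p < \code{alpha}) than each of the three OFF corners. Wrong truth tables
#' (e.g. two high corners for an AND gate) fail because the ON corner is not
#' separated from the second high corner.
#'
#' When every replicate within each condition is identical the residual
#' variance is zero and F-based p-values are undefined; the test then falls
#' back to exact mean comparison (p = 0 for any difference, 1 otherwise),
#' keeping noise-free closed-loop data well-defined.
#'
#' @param replicates_by_condition named list of numeric replicate vectors,
#'   one per corner condition (\code{"IX=0;IY=0"}, ...), or a well-level
#'   data.frame with \code{condition} and \code{value} columns.
#' @param gate_type one of \code{"AND"}, \code{"NOR"}, \code{"A_NIMPLY_B"},
#'   \code{"B_NIMPLY_A"}.
#' @param alpha significance level for the Tukey comparisons (default 0.01).
#' @return list with \code{anova_p}, \code{tukey_pairs} (named logical:
#'   condition pair significant at \code{alpha}), \code{tukey_p},
#'   \code{objective_logic}.
#' @export
test_objective_logic <- function(replicates_by_condition, gate_type, alpha = 0.01) {
  if (is.data.frame(replicates_by_condition)) {
    df <- data.frame(condition = replicates_by_condition$condition,
                     value = replicates_by_condition$value,
                     stringsAsFactors = FALSE)
  } else {
    df <- data.frame(
      condition = rep(names(replicates_by_condition),
                      lengths(replicates_by_condition)),
      value = unlist(replicates_by_condition, use.names = FALSE),
      stringsAsFactors = FALSE)
  }
  need <- miso_conditions()
  missing <- setdiff(need, unique(df$condition))
  if (length(missing))
    stop("missing condition(s): ", paste(missing, collapse = ", "), call. = FALSE)
  if (any(table(df$condition) < 2))
    stop("each condition needs at least 2 replicates", call. = FALSE)
  df$condition <- factor(df$condition, levels = need)
  means <- tapply(df$value, df$condition, mean)
  resid_var <- sum(tapply(df$value, df$condition,
                          function(v) sum((v - mean(v))^2)))
  pair_names <- utils::combn(need, 2, paste, collapse = "-")
  if (resid_var <= .Machine$double.eps * sum(df$value^2)) {
    # noise-free data: exact comparison of condition means
    anova_p <- if (max(means) - min(means) == 0) 1 else 0
    pm <- utils::combn(need, 2, function(pr) as.numeric(means[pr[1]] == means[pr[2]]))
    tukey_p <- stats::setNames(pm, pair_names)
  } else {
    fit <- stats::aov(value ~ condition, data = df)
    anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- stats::TukeyHSD(fit)$condition
    # TukeyHSD labels pairs "b-a"; renormalize to "a-b" in corner order
    lab <- strsplit(rownames(tk), "-", fixed = TRUE)
    lab <- vapply(lab, function(x) paste(rev(x), collapse = "-"), character(1))
    tukey_p <- stats::setNames(tk[, "p adj"], lab)[pair_names]
  }
  on <- designated_on_corner(gate_type)
  off <- setdiff(need, on)
  on_vs <- vapply(off, function(o) {
    nm <- if (paste(on, o, sep = "-") %in% names(tukey_p))
      paste(on, o, sep = "-") else paste(o, on, sep = "-")
    tukey_p[[nm]]
  }, numeric(1))
  objective <- all(on_vs < alpha) && all(means[on] > means[off])
  list(anova_p = anova_p,
       tukey_pairs = tukey_p < alpha,
       tukey_p = tukey_p,
       objective_logic = objective)
}

#' Fold-error metrology of a predicted truth table against measurements
#'
#' Per corner, the prediction error is the ratio r of measured to predicted
#' output; its fold magnitude is \code{max(r, 1/r)}, so under- and
#' over-predictions of equal size contribute equally. The gate-level mean
#' error is the mean fold magnitude over the four corners; the raw-ratio
#' mean is also reported for transparency.
#'
#' @param measured condition summaries of the measured gate (four corners,
#'   columns \code{condition}, \code{mean_fluor}).
#' @param predicted a \code{\link{miso_gate}} or its truth-table data.frame.
#' @return list: \code{per_corner} (condition, measured, predicted, ratio,
#'   fold), \code{mean_error}, \code{mean_raw_ratio}, \code{frac_ge_2fold}.
#' @export
prediction_error <- function(measured, predicted) {
  tt <- if (inherits(predicted, "miso_gate")) predicted$truth_table else predicted
  m <- measured$mean_fluor[match(tt$condition, measured$condition)]
  if (anyNA(m))
    stop("measured summaries must cover all four corners", call. = FALSE)
  if (any(tt$omega <= 0))
    stop("predicted output is zero at a corner (degenerate model)", call. = FALSE)
  r <- m / tt$omega
  fold <- pmax(r, 1 / r)
  list(per_corner = data.frame(condition = tt$condition, measured = m,
                               predicted = tt$omega, ratio = r, fold = fold,
                               stringsAsFactors = FALSE),
       mean_error = mean(fold),
       mean_raw_ratio = mean(r),
       frac_ge_2fold = mean(fold >= 2))
}

#' Aggregate gate validations into a library report
#'
#' @param validations data.frame with one row per gate: \code{gate_id},
#'   \code{position}, \code{objective_logic}, \code{mean_error},
#'   \code{mean_raw_ratio}, \code{frac_ge_2fold}.
#' @return list: \code{n_gates}; \code{mean_error} (mean fold magnitude over
#'   all gate-corners); \code{mean_raw_ratio}; \code{pct_within_2fold_corners}
#'   (corner-level aggregation) and \code{pct_within_2fold_gates} (gates with
#'   no deviant corner) — both aggregations of the ~2-fold criterion are
#'   emitted; \code{pct_objective_logic}; \code{by_position} strata.
#' @export
summarize_library <- function(validations) {
  stopifnot(nrow(validations) >= 1)
  agg <- function(v) list(
    n_gates = nrow(v),
    mean_error = mean(v$mean_error),
    mean_raw_ratio = mean(v$mean_raw_ratio),
    pct_within_2fold_corners = 100 * (1 - mean(v$frac_ge_2fold)),
    pct_within_2fold_gates = 100 * mean(v$frac_ge_2fold == 0),
    pct_objective_logic = 100 * mean(v$objective_logic))
  out <- agg(validations)
  out$by_position <- lapply(split(validations, validations$position), agg)
  out
}

#' Validate a set of measured two-input gates against their models
#'
#' Runs \code{\link{test_objective_logic}} and \code{\link{prediction_error}}
#' for every gate and tabulates the results.
#'
#' @param gates named list of \code{\link{miso_gate}} objects.
#' @param wells well-level normalized values of the measured gates.
#' @param summaries condition summaries of the measured gates.
#' @param positions optional named character vector gate_id -> operator
#'   position for stratified reporting.
#' @param alpha Tukey significance level.
#' @return list with \code{validations} (per-gate data.frame),
#'   \code{per_corner} (per gate-corner ratios) and \code{report}
#'   (\code{\link{summarize_library}} output).
#' @export
validate_library <- function(gates, wells, summaries, positions = NULL,
                             alpha = 0.01) {
  rows <- list(); corners <- list()
  for (g in gates) {
    w <- wells[wells$gate_id == g$gate_id, ]
    s <- summaries[summaries$gate_id == g$gate_id, ]
    logic <- test_objective_logic(w, g$gate_type, alpha = alpha)
    err <- prediction_error(s, g)
    pos <- if (!is.null(positions)) positions[[g$gate_id]] %||% NA_character_
           else NA_character_
    rows[[g$gate_id]] <- data.frame(
      gate_id = g$gate_id, gate_type = g$gate_type, position = pos,
      anova_p = logic$anova_p, objective_logic = logic$objective_logic,
      mean_error = err$mean_error, mean_raw_ratio = err$mean_raw_ratio,
      frac_ge_2fold = err$frac_ge_2fold, stringsAsFactors = FALSE)
    pc <- err$per_corner
    pc$gate_id <- g$gate_id
    pc$position <- pos
    corners[[g$gate_id]] <- pc
  }
  validations <- do.call(rbind, rows)
  rownames(validations) <- NULL
  list(validations = validations,
       per_corner = do.call(rbind, corners),
       report = summarize_library(validations))
}
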