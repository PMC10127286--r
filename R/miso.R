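#' Estimate corner-model coefficients from two single-input gate fits
#'
#' A two-input SE-PA gate is modeled by the quadratic corner-state form
#' \deqn{\Omega = \alpha_0 + \alpha_1 S_X + \alpha_2 S_Y + \alpha_3 S_X S_Y}
#' where the state functions S take values 0/1. The coefficients are
#' estimated from the member gates' \eqn{(\epsilon, \sigma)} parameters by
#' solving the four corner assumptions: \eqn{\alpha_0} is the minimum output
#' (overall leakiness, the smaller \eqn{\epsilon}); with only slot X active
#' the output is limited by Y's leakiness (\eqn{\alpha_0+\alpha_1 =
#' \epsilon_Y}) and vice versa; the fully active corner is limited by the
#' weaker member's ON state (\eqn{\alpha_0+\alpha_1+\alpha_2+\alpha_3 =
#' \min(\epsilon_X+\sigma_X, \epsilon_Y+\sigma_Y)}). Hence the default
#' \code{"min_corner"} estimator:
#' \deqn{\alpha_0 = \min(\epsilon_X, \epsilon_Y),\;
#'       \alpha_1 = \epsilon_Y - \alpha_0,\;
#'       \alpha_2 = \epsilon_X - \alpha_0,\;
#'       \alpha_3 = \min(\epsilon_X+\sigma_X, \epsilon_Y+\sigma_Y)
#'                  - (\alpha_0+\alpha_1+\alpha_2).}
#' The same coefficient functions serve AND, NOR and both NIMPLY gates; the
#' gate type only changes which state functions are repressor
#' (\eqn{S = I}) versus antirepressor (\eqn{S = 1 - I}).
#'
#' The estimator is pluggable: pass a function
#' \code{f(eps_x, sig_x, eps_y, sig_y)} returning four coefficients to swap
#' in an alternative composition scheme without touching the evaluators.
#'
#' @param params_x,params_y operational \code{\link{siso_fit}} objects or
#'   lists with \code{epsilon} and \code{sigma}.
#' @param estimator \code{"min_corner"} (default) or a function as above.
#' @return named numeric vector \code{(alpha0, alpha1, alpha2, alpha3)}. A
#'   negative \code{alpha3} (ON corner not above the larger leakiness —
#'   a pair that should have failed compatibility screening) is returned
#'   with a warning.
#' @examples
#' estimate_alphas(list(epsilon = .05, sigma = .80),
#'                 list(epsilon = .10, sigma = .70))
#' @export
estimate_alphas <- function(params_x, params_y, estimator = "min_corner") {
  ex <- params_x$epsilon; sx <- params_x$sigma
  ey <- params_y$epsilon; sy <- params_y$sigma
  stopifnot(is.finite(ex), is.finite(sx), is.finite(ey), is.finite(sy))
  if (is.function(estimator)) {
    a <- estimator(ex, sx, ey, sy)
  } else if (identical(estimator, "min_corner")) {
    a0 <- min(ex, ey)
    a1 <- ey - a0
    a2 <- ex - a0
    a3 <- min(ex + sx, ey + sy) - (a0 + a1 + a2)
    a <- c(a0, a1, a2, a3)
  } else {
    stop("unknown alpha estimator: ", estimator, call. = FALSE)
  }
  a <- stats::setNames(as.numeric(a), c("alpha0", "alpha1", "alpha2", "alpha3"))
  if (a["alpha3"] < 0)
    warning("alpha3 < 0: member ON states do not clear both leakiness levels; ",
            "pair is predicted incompatible", call. = FALSE)
  a
}

#' Evaluate the corner-state model over the four binary input corners
#'
#' The gate type fixes each slot's state function: AND pairs two repressors
#' (\eqn{S = I}), NOR two antirepressors (\eqn{S = 1 - I}), A NIMPLY B a
#' repressor on input A with an antirepressor on input B, and B NIMPLY A the
#' converse. Each function therefore has exactly one high corner — the ON
#' corner of its Boolean truth table.
#'
#' @param alphas coefficients from \code{\link{estimate_alphas}}.
#' @param gate_type one of \code{"AND"}, \code{"NOR"}, \code{"A_NIMPLY_B"},
#'   \code{"B_NIMPLY_A"}.
#' @return data.frame with columns \code{IX, IY, condition, omega} (four
#'   rows, truth-table order).
#' @examples
#' a <- estimate_alphas(list(epsilon = .05, sigma = .80),
#'                      list(epsilon = .10, sigma = .70))
#' predict_truth_table(a, "AND")
#' @export
predict_truth_table <- function(alphas, gate_type) {
  ph <- miso_slot_phenotypes(gate_type)
  corners <- expand.grid(IX = 0:1, IY = 0:1)[, c("IX", "IY")]
  corners <- corners[order(corners$IX, corners$IY), ]
  sx <- if (ph[1] == "REPRESSOR") corners$IX else 1 - corners$IX
  sy <- if (ph[2] == "REPRESSOR") corners$IY else 1 - corners$IY
  omega <- alphas[["alpha0"]] + alphas[["alpha1"]] * sx +
    alphas[["alpha2"]] * sy + alphas[["alpha3"]] * sx * sy
  data.frame(IX = corners$IX, IY = corners$IY,
             condition = sprintf("IX=%d;IY=%d", corners$IX, corners$IY),
             omega = omega, row.names = NULL, stringsAsFactors = FALSE)
}

#' Fit a predictive model for a two-input transcriptional logic gate
#'
#' Composes two fitted single-input gates into a corner-state prediction of
#' the two-input gate they would form in the SE-PA architecture. Slot
#' phenotypes must match the gate type (AND: both repressors; NOR: both
#' antirepressors; NIMPLY: one of each, with the repressor on input A for
#' \code{A_NIMPLY_B}).
#'
#' @param x,y member gates: operational \code{\link{siso_fit}} objects (or
#'   lists with \code{epsilon}, \code{sigma} and optionally
#'   \code{phenotype}). \code{x} responds to input A (IX), \code{y} to
#'   input B (IY).
#' @param gate_type one of \code{"AND"}, \code{"NOR"}, \code{"A_NIMPLY_B"},
#'   \code{"B_NIMPLY_A"}.
#' @param estimator coefficient scheme, see \code{\link{estimate_alphas}}.
#' @param gate_id optional identifier.
#' @param source_regime \code{"SE_PA"} (default) or \code{"SERI"} —
#'   records which architectural context supplied the SISO parameters
#'   (SERI gates must be parameterized from SERI-context SISO data).
#' @return object of class \code{miso_gate} with methods \code{print},
#'   \code{summary}, \code{coef}, \code{predict}, \code{plot},
#'   \code{simulate} and \code{residuals}.
#' @examples
#' x <- siso_fit(c(.05, .05, .05), c(.85, .85, .85), "X")
#' y <- siso_fit(c(.10, .10, .10), c(.80, .80, .80), "Y")
#' g <- miso_gate(x, y, "AND")
#' predict(g)
#' @export
miso_gate <- function(x, y, gate_type, estimator = "min_corner",
                      gate_id = NULL, source_regime = c("SE_PA", "SERI")) {
  if (!gate_type %in% GATE_TYPES_MISO)
    stop("unknown gate_type: ", gate_type, call. = FALSE)
  source_regime <- match.arg(source_regime)
  need <- miso_slot_phenotypes(gate_type)
  for (slot in 1:2) {
    p <- list(x, y)[[slot]]
    if (!is.null(p$phenotype) && !identical(p$phenotype, need[slot]))
      stop(sprintf("slot %s of a %s gate requires a %s (got %s)",
                   c("A", "B")[slot], gate_type, need[slot], p$phenotype),
           call. = FALSE)
  }
  alphas <- estimate_alphas(x, y, estimator)
  structure(list(
    gate_id = gate_id %||% paste0(gate_type, "_gate"),
    gate_type = gate_type,
    alphas = alphas,
    members = list(x = x, y = y),
    truth_table = predict_truth_table(alphas, gate_type),
    source_regime = source_regime),
    class = "miso_gate")
}

#' @export
print.miso_gate <- function(x, digits = 4, ...) {
  cat(sprintf("Two-input %s gate model: %s (%s-parameterized)\n",
              x$gate_type, x$gate_id, x$source_regime))
  cat("  alphas:", paste(sprintf("%s = %.*g", names(x$alphas), digits, x$alphas),
                         collapse = ", "), "\n")
  cat("  predicted truth table:\n")
  tt <- x$truth_table
  for (i in seq_len(nrow(tt)))
    cat(sprintf("    (IX=%d, IY=%d) -> %.*g%s\n", tt$IX[i], tt$IY[i],
                digits, tt$omega[i],
                if (tt$condition[i] == designated_on_corner(x$gate_type))
                  "  [ON corner]" else ""))
  invisible(x)
}

#' @export
summary.miso_gate <- function(object, ...) {
  tt <- object$truth_table
  on <- tt$omega[tt$condition == designated_on_corner(object$gate_type)]
  off <- tt$omega[tt$condition != designated_on_corner(object$gate_type)]
  out <- list(gate = object, on_corner = on, max_off = max(off),
              dynamic_range = on / max(off))
  class(out) <- "summary.miso_gate"
  out
}

#' @export
print.summary.miso_gate <- function(x, ...) {
  print(x$gate)
  cat(sprintf("  ON corner %.4g vs max OFF corner %.4g (predicted dynamic range %.3g)\n",
              x$on_corner, x$max_off, x$dynamic_range))
  invisible(x)
}

#' @export
coef.miso_gate <- function(object, ...) object$alphas

#' Predict two-input gate output at binary input corners
#'
#' @param object a \code{miso_gate}.
#' @param newdata optional data.frame with columns \code{IX}, \code{IY}
#'   (binary); defaults to all four corners.
#' @param ... ignored.
#' @return the truth table (or requested subset) with predicted \code{omega}.
#' @export
predict.miso_gate <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$truth_table)
  if (!all(unlist(newdata[, c("IX", "IY")]) %in% c(0, 1)))
    stop("inducer states must be binary (0/1)", call. = FALSE)
  key <- sprintf("IX=%d;IY=%d", newdata$IX, newdata$IY)
  object$truth_table$omega[match(key, object$truth_table$condition)]
}

#' @export
plot.miso_gate <- function(x, measured = NULL, ...) {
  tt <- x$truth_table
  h <- tt$omega
  names(h) <- sprintf("(%d,%d)", tt$IX, tt$IY)
  if (!is.null(measured)) {
    m <- measured$mean_fluor[match(tt$condition, measured$condition)]
    mat <- rbind(predicted = h, measured = m)
    graphics::barplot(mat, beside = TRUE, ylab = "normalized output",
                      xlab = "(IX, IY)", legend.text = rownames(mat),
                      main = sprintf("%s: %s", x$gate_type, x$gate_id), ...)
  } else {
    graphics::barplot(h, ylab = "normalized output", xlab = "(IX, IY)",
                      main = sprintf("%s: %s", x$gate_type, x$gate_id), ...)
  }
  invisible(x)
}

#' Simulate plate-reader measurements from a fitted two-input gate model
#'
#' Emits synthetic raw plate records whose expected normalized outputs equal
#' the model's corner predictions, using the package's measurement-noise
#' model — a convenience wrapper over
#' \code{\link{simulate_miso_measurements}}.
#'
#' @param object a \code{miso_gate}.
#' @param nsim number of simulated plates.
#' @param seed optional RNG seed.
#' @param noise a \code{\link{noise_model}}.
#' @param deviation per-corner multiplicative deviation factors (length 1 or
#'   4) modeling biology the corner model misses.
#' @param ... ignored.
#' @return a plate-record data.frame (\code{nsim} plates).
#' @export
simulate.miso_gate <- function(object, nsim = 1, seed = NULL,
                               noise = noise_model(), deviation = 1, ...) {
  if (!is.null(seed)) set.seed(seed)
  plates <- lapply(seq_len(nsim), function(i) {
    p <- simulate_corner_plate(object$truth_table$omega *
                                 rep(deviation, length.out = 4L),
                               conditions = object$truth_table$condition,
                               gate_id = object$gate_id, noise = noise,
                               plate = sprintf("SIM%d", i))
    p
  })
  do.call(rbind, plates)
}

#' Residual fold deviations of measurements from a gate model
#'
#' @param object a \code{miso_gate}.
#' @param measured condition summaries of the measured gate (four corners).
#' @param ... ignored.
#' @return named numeric vector of log2(measured / predicted) per corner.
#' @export
residuals.miso_gate <- function(object, measured, ...) {
  tt <- object$truth_table
  m <- measured$mean_fluor[match(tt$condition, measured$condition)]
  if (anyNA(m)) stop("measured summaries must cover all four corners", call. = FALSE)
  stats::setNames(log2(m / tt$omega), tt$condition)
}

#' Export predicted truth tables as TSV
#' @param gates list of \code{miso_gate} objects.
#' @param path output file.
#' @export
write_prediction_tsv <- function(gates, path) {
  rows <- lapply(gates, function(g) {
    tt <- g$truth_table
    data.frame(gate_id = g$gate_id, gate_type = g$gate_type,
               condition = tt$condition, omega_pred = tt$omega,
               alpha0 = g$alphas[["alpha0"]], alpha1 = g$alphas[["alpha1"]],
               alpha2 = g$alphas[["alpha2"]], alpha3 = g$alphas[["alpha3"]],
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
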