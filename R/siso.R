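#' Classify a single-input gate phenotype from replicate measurements
#'
#' A two-tailed Welch t-test compares normalized output between the uninduced
#' and induced conditions. Significant gates (p < \code{alpha}) are
#' operational: \code{REPRESSOR} when induction raises output (BUFFER logic),
#' \code{ANTIREPRESSOR} when induction lowers it (NOT logic). Non-significant
#' gates are nonoperational: \code{SUPER_REPRESSOR} when both condition means
#' sit below \code{expression_threshold} (locked repression),
#' \code{NONFUNCTIONAL} otherwise (no repression). Cohen's d (pooled-SD
#' standardized difference, induced minus uninduced) is reported
#' descriptively and never gates the call.
#'
#' When both groups have zero variance the t statistic is undefined; the
#' p-value is then set to 1 for equal means and 0 for distinct means so the
#' classification remains well-defined on noise-free data.
#'
#' @param uninduced,induced numeric replicate vectors (unit-scale
#'   fluorescence), at least 2 values each.
#' @param alpha significance level for the t-test (default 0.001).
#' @param expression_threshold unit-scale cutoff separating super-repressor
#'   from nonfunctional calls (default 0.1).
#' @return list with \code{phenotype}, \code{p_value}, \code{cohens_d}.
#' @export
classify_phenotype <- function(uninduced, induced, alpha = 0.001,
                               expression_threshold = 0.1) {
  stopifnot(length(uninduced) >= 2, length(induced) >= 2)
  s0 <- stats::sd(uninduced); s1 <- stats::sd(induced)
  m0 <- mean(uninduced); m1 <- mean(induced)
  se <- sqrt(s0^2 / length(uninduced) + s1^2 / length(induced))
  if (se < 10 * .Machine$double.eps * max(abs(m0), abs(m1))) {
    # numerically constant data: exact mean comparison replaces the t-test
    p <- if (isTRUE(all.equal(m0, m1))) 1 else 0
  } else {
    p <- stats::t.test(induced, uninduced, alternative = "two.sided",
                       var.equal = FALSE)$p.value
  }
  n0 <- length(uninduced); n1 <- length(induced)
  sp <- sqrt(((n0 - 1) * s0^2 + (n1 - 1) * s1^2) / (n0 + n1 - 2))
  d <- if (sp == 0) ifelse(m1 == m0, 0, sign(m1 - m0) * Inf) else (m1 - m0) / sp
  phenotype <- if (p < alpha) {
    if (m1 > m0) "REPRESSOR" else "ANTIREPRESSOR"
  } else {
    if (m0 < expression_threshold && m1 < expression_threshold)
      "SUPER_REPRESSOR" else "NONFUNCTIONAL"
  }
  list(phenotype = phenotype, p_value = p, cohens_d = d)
}

#' Extract coarse-grained gate parameters from ON/OFF state means
#'
#' The coarse-grained binding model describes a single-input gate by its
#' OFF-state output \eqn{\epsilon} (leakiness) and the ON-minus-OFF increment
#' \eqn{\sigma}: output is \eqn{\epsilon + \sigma \Lambda(I)} where the state
#' function \eqn{\Lambda} is the inducer state I for a repressor and 1 - I
#' for an antirepressor. The phenotype fixes which measured condition is ON:
#' induced for a repressor, uninduced for an antirepressor (for which
#' \eqn{\epsilon} is the output in the presence of inducer).
#'
#' @param mean_on,mean_off normalized mean outputs of the ON and OFF states.
#' @param phenotype \code{"REPRESSOR"} or \code{"ANTIREPRESSOR"}.
#' @return list with \code{epsilon}, \code{sigma}, \code{on_state}
#'   (= epsilon + sigma), \code{phenotype}.
#' @export
estimate_siso_parameters <- function(mean_on, mean_off, phenotype) {
  if (!phenotype %in% OPERATIONAL)
    stop("parameters are defined only for operational phenotypes", call. = FALSE)
  sigma <- mean_on - mean_off
  if (sigma <= 0)
    stop("sigma <= 0: ON state does not exceed OFF state (phenotype/role mismatch)",
         call. = FALSE)
  list(epsilon = mean_off, sigma = sigma, on_state = mean_on,
       phenotype = phenotype)
}

#' Fit the coarse-grained model to one single-input gate
#'
#' Classifies the phenotype from the two replicate sets (see
#' \code{\link{classify_phenotype}}) and, for operational gates, extracts
#' \eqn{\epsilon} and \eqn{\sigma}. Nonoperational gates carry \code{NA}
#' parameters.
#'
#' @param uninduced,induced numeric replicate vectors (unit scale).
#' @param gate_id optional identifier carried through reports.
#' @inheritParams classify_phenotype
#' @return An object of class \code{siso_fit}.
#' @examples
#' g <- siso_fit(uninduced = c(.05, .06, .05), induced = c(.84, .86, .85))
#' coef(g)
#' predict(g, I = c(0, 1))
#' @export
siso_fit <- function(uninduced, induced, gate_id = "siso_gate",
                     alpha = 0.001, expression_threshold = 0.1) {
  cl <- classify_phenotype(uninduced, induced, alpha, expression_threshold)
  m0 <- mean(uninduced); m1 <- mean(induced)
  if (cl$phenotype %in% OPERATIONAL) {
    on_is_induced <- cl$phenotype == "REPRESSOR"
    par <- estimate_siso_parameters(mean_on = if (on_is_induced) m1 else m0,
                                    mean_off = if (on_is_induced) m0 else m1,
                                    phenotype = cl$phenotype)
    fold <- par$on_state / par$epsilon
  } else {
    par <- list(epsilon = NA_real_, sigma = NA_real_, on_state = NA_real_)
    fold <- NA_real_
  }
  structure(list(
    gate_id = gate_id, phenotype = cl$phenotype,
    epsilon = par$epsilon, sigma = par$sigma, on_state = par$on_state,
    p_value = cl$p_value, cohens_d = cl$cohens_d, fold_change = fold,
    data = list(uninduced = uninduced, induced = induced),
    alpha = alpha, expression_threshold = expression_threshold),
    class = "siso_fit")
}

#' @export
print.siso_fit <- function(x, digits = 4, ...) {
  cat("Single-input gate fit:", x$gate_id, "\n")
  cat("  phenotype :", x$phenotype,
      sprintf("(p = %.3g, Cohen's d = %.3g)\n", x$p_value, x$cohens_d))
  if (x$phenotype %in% OPERATIONAL)
    cat(sprintf("  epsilon = %.*g, sigma = %.*g, ON state = %.*g, fold change = %.*g\n",
                digits, x$epsilon, digits, x$sigma, digits, x$on_state,
                digits, x$fold_change))
  invisible(x)
}

#' @export
summary.siso_fit <- function(object, ...) {
  m0 <- mean(object$data$uninduced); m1 <- mean(object$data$induced)
  out <- list(fit = object,
              condition_means = c(uninduced = m0, induced = m1),
              condition_sds = c(uninduced = stats::sd(object$data$uninduced),
                                induced = stats::sd(object$data$induced)),
              n = c(uninduced = length(object$data$uninduced),
                    induced = length(object$data$induced)))
  class(out) <- "summary.siso_fit"
  out
}

#' @export
print.summary.siso_fit <- function(x, ...) {
  print(x$fit)
  cat("  condition means:", sprintf("%.4g", x$condition_means), "\n")
  cat("  condition sds  :", sprintf("%.4g", x$condition_sds), "\n")
  cat("  replicates     :", x$n, "\n")
  invisible(x)
}

#' @export
coef.siso_fit <- function(object, ...) {
  c(epsilon = object$epsilon, sigma = object$sigma)
}

#' Predict single-input gate output at digitized inducer states
#'
#' Corner-state model only: \code{I} must be 0 or 1 (the transition region is
#' out of scope; the model has no graded dose-response).
#'
#' @param object a \code{siso_fit} with operational phenotype.
#' @param I integer vector of inducer states in \{0, 1\}.
#' @param ... ignored.
#' @return numeric vector of predicted unit-scale outputs.
#' @export
predict.siso_fit <- function(object, I = c(0, 1), ...) {
  if (!object$phenotype %in% OPERATIONAL)
    stop("cannot predict from a nonoperational gate", call. = FALSE)
  if (!all(I %in% c(0, 1)))
    stop("inducer states must be binary (0/1); intermediate inputs are not modeled",
         call. = FALSE)
  s <- if (object$phenotype == "REPRESSOR") I else 1 - I
  object$epsilon + object$sigma * s
}

#' @export
fitted.siso_fit <- function(object, ...) {
  c(uninduced = unname(predict(object, 0)), induced = unname(predict(object, 1)))
}

#' @export
residuals.siso_fit <- function(object, ...) {
  f <- fitted(object)
  list(uninduced = object$data$uninduced - f["uninduced"],
       induced = object$data$induced - f["induced"])
}

#' Performance metrology for a single-input gate
#'
#' Reports (i) fold induction (ON/OFF output ratio; for an antirepressor this
#' is the fold anti-induction), (ii) repression strength (unregulated
#' expression level over leakiness \eqn{\epsilon}), and (iii) a two-part
#' traceability score relative to a reference gate: induction units
#' (IU; AIU for antirepressors) = gate fold change / reference fold change,
#' and repression units (RU) = gate repression strength / reference
#' repression strength. The ratio-to-reference definitions are this package's
#' defaults, with the wild-type LacI/O1 system the intended reference.
#'
#' @param params an operational \code{siso_fit} (or list with
#'   \code{epsilon}, \code{on_state}, \code{phenotype}).
#' @param reference_params same shape, the reference system; defaults to the
#'   gate itself (unit scores).
#' @param unregulated_level unit-scale output of the unregulated promoter
#'   (default 1, the nominal global maximum).
#' @return list with \code{fold_induction} (or \code{fold_anti_induction}),
#'   \code{repression_strength}, \code{traceability} (IU/AIU and RU), and an
#'   \code{infinite_repression} flag when \eqn{\epsilon = 0}.
#' @export
compute_metrology <- function(params, reference_params = params,
                              unregulated_level = 1) {
  fold <- function(p) p$on_state / p$epsilon
  rs <- function(p) unregulated_level / p$epsilon
  inf_flag <- params$epsilon == 0
  f <- fold(params); r <- rs(params)
  fr <- fold(reference_params); rr <- rs(reference_params)
  anti <- identical(params$phenotype, "ANTIREPRESSOR")
  out <- list(repression_strength = r,
              traceability = c(iu = f / fr, ru = r / rr),
              infinite_repression = inf_flag)
  names(out$traceability)[1] <- if (anti) "aiu" else "iu"
  out[[if (anti) "fold_anti_induction" else "fold_induction"]] <- f
  out
}

#' Fit every single-input gate in a processed plate
#'
#' Groups normalized well values by gate, fits \code{\link{siso_fit}} to the
#' \code{"I=0"} / \code{"I=1"} condition pair, and tabulates the results.
#'
#' @param wells well-level normalized values (see
#'   \code{\link{normalize_wells}}); only gates whose conditions are
#'   \code{"I=0"} and \code{"I=1"} are fitted.
#' @inheritParams classify_phenotype
#' @return data.frame: \code{gate_id, phenotype, epsilon, sigma, on_state,
#'   p_value, cohens_d, fold_change, mean_uninduced, sd_uninduced,
#'   mean_induced, sd_induced, n}.
#' @export
fit_siso_table <- function(wells, alpha = 0.001, expression_threshold = 0.1) {
  siso <- wells[wells$condition %in% c("I=0", "I=1"), ]
  ids <- unique(siso$gate_id)
  rows <- lapply(ids, function(g) {
    w <- siso[siso$gate_id == g, ]
    u <- w$value[w$condition == "I=0"]; i <- w$value[w$condition == "I=1"]
    fit <- siso_fit(u, i, gate_id = g, alpha = alpha,
                    expression_threshold = expression_threshold)
    data.frame(gate_id = g, phenotype = fit$phenotype, epsilon = fit$epsilon,
               sigma = fit$sigma, on_state = fit$on_state,
               p_value = fit$p_value, cohens_d = fit$cohens_d,
               fold_change = fit$fold_change,
               mean_uninduced = mean(u), sd_uninduced = stats::sd(u),
               mean_induced = mean(i), sd_induced = stats::sd(i),
               n = min(length(u), length(i)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
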