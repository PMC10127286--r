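#' Two-tier compatibility check for an SE-PA transcription-factor pair
#'
#' A pair of single-input gates can compose into an objective two-input gate
#' only if (tier 1) both members are operational, and (tier 2) sufficient
#' inequality separates the ON states from the OFF states: the composed
#' gate's single ON corner is bounded by the smaller member ON state, and its
#' OFF corners by the member leakiness values, so every member ON state must
#' exceed every member OFF state under the separation rule. This covers both
#' cross comparisons (ON of X vs OFF of Y and vice versa) and the own-gate
#' dynamic ranges.
#'
#' Two separation rules are available. When replicate values are present in
#' the fits, each ON-vs-OFF comparison is a one-sided Welch t-test at level
#' \code{alpha}. When only summary means/SDs exist, the fallback band rule
#' requires \code{mean_ON - k*sd_ON > mean_OFF + k*sd_OFF} for every
#' comparison.
#'
#' @param params_x,params_y \code{siso_fit} objects, or lists/rows with
#'   fields \code{phenotype}, \code{mean_uninduced}, \code{sd_uninduced},
#'   \code{mean_induced}, \code{sd_induced} (summary fallback).
#' @param k band half-width multiplier for the summary rule (default 2).
#' @param alpha one-sided test level for the replicate rule (default 0.001).
#' @return list of class \code{compatibility_verdict}: \code{pair},
#'   \code{tier1_pass}, \code{tier2_pass}, \code{pass}, \code{reasons},
#'   \code{margin_used}.
#' @examples
#' x <- siso_fit(c(.05, .06, .05), c(.84, .86, .85), "X")
#' y <- siso_fit(c(.10, .11, .10), c(.78, .80, .82), "Y")
#' check_pair(x, y)$pass
#' @export
check_pair <- function(params_x, params_y, k = 2, alpha = 0.001) {
  states <- function(p) {
    if (inherits(p, "siso_fit")) {
      on_is_induced <- identical(p$phenotype, "REPRESSOR")
      on  <- if (on_is_induced) p$data$induced else p$data$uninduced
      off <- if (on_is_induced) p$data$uninduced else p$data$induced
      list(id = p$gate_id, phenotype = p$phenotype,
           on = on, off = off,
           m_on = mean(on), s_on = stats::sd(on),
           m_off = mean(off), s_off = stats::sd(off),
           has_reps = TRUE)
    } else {
      p <- as.list(p)
      on_is_induced <- identical(p$phenotype, "REPRESSOR")
      list(id = p$gate_id %||% "gate", phenotype = p$phenotype,
           m_on = if (on_is_induced) p$mean_induced else p$mean_uninduced,
           s_on = if (on_is_induced) p$sd_induced else p$sd_uninduced,
           m_off = if (on_is_induced) p$mean_uninduced else p$mean_induced,
           s_off = if (on_is_induced) p$sd_induced else p$sd_uninduced,
           has_reps = FALSE)
    }
  }
  x <- states(params_x); y <- states(params_y)
  reasons <- character()
  tier1 <- x$phenotype %in% OPERATIONAL && y$phenotype %in% OPERATIONAL
  if (!tier1)
    reasons <- c(reasons, paste0("nonoperational member: ",
      paste(c(x$id, y$id)[!c(x$phenotype, y$phenotype) %in% OPERATIONAL],
            collapse = ", ")))
  separated <- function(on, off) {
    if (on$has_reps && off$has_reps) {
      se <- sqrt(stats::sd(on$on)^2 / length(on$on) +
                 stats::sd(off$off)^2 / length(off$off))
      if (se < 10 * .Machine$double.eps * max(abs(on$m_on), abs(off$m_off)))
        return(on$m_on > off$m_off)  # numerically constant data
      stats::t.test(on$on, off$off, alternative = "greater",
                    var.equal = FALSE)$p.value < alpha
    } else {
      on$m_on - k * on$s_on > off$m_off + k * off$s_off
    }
  }
  tier2 <- TRUE
  if (tier1) {
    for (pair in list(list(x, x), list(x, y), list(y, x), list(y, y))) {
      if (!separated(pair[[1]], pair[[2]])) {
        tier2 <- FALSE
        reasons <- c(reasons, sprintf("ON state of %s does not exceed OFF state of %s",
                                      pair[[1]]$id, pair[[2]]$id))
      }
    }
  } else {
    tier2 <- NA
  }
  structure(list(pair = c(x$id, y$id), tier1_pass = tier1,
                 tier2_pass = tier2, pass = isTRUE(tier1) && isTRUE(tier2),
                 reasons = reasons,
                 margin_used = list(k = k, alpha = alpha,
                                    rule = if (x$has_reps && y$has_reps)
                                      "welch_one_sided" else "mean_sd_band")),
            class = "compatibility_verdict")
}

#' @export
print.compatibility_verdict <- function(x, ...) {
  cat(sprintf("Pair %s | %s: tier1 %s, tier2 %s -> %s\n",
              x$pair[1], x$pair[2], x$tier1_pass, x$tier2_pass,
              if (x$pass) "COMPATIBLE" else "REJECTED"))
  for (r in x$reasons) cat("  -", r, "\n")
  invisible(x)
}

#' Screen an enumerated pair space against SISO measurements
#'
#' Applies \code{\link{check_pair}} to every putative SE-PA pair, using the
#' measured SISO table (and replicate wells when supplied) for both decision
#' tiers.
#'
#' @param pairs data.frame from \code{\link{enumerate_sepa_pairs}}.
#' @param siso_table data.frame from \code{\link{fit_siso_table}}.
#' @param wells optional well-level values (see
#'   \code{\link{normalize_wells}}); when given, the replicate t-test rule is
#'   used, otherwise the summary band rule.
#' @inheritParams check_pair
#' @return list with \code{passing} (subset of \code{pairs}) and
#'   \code{verdicts} (one row per pair: tier flags, pass, reasons).
#' @export
screen_space <- function(pairs, siso_table, wells = NULL, k = 2, alpha = 0.001) {
  lookup <- function(gid) {
    row <- siso_table[siso_table$gate_id == gid, ]
    if (nrow(row) == 0L)
      stop("SISO record missing for gate ", gid, call. = FALSE)
    if (!is.null(wells)) {
      w <- wells[wells$gate_id == gid, ]
      fit <- siso_fit(w$value[w$condition == "I=0"],
                      w$value[w$condition == "I=1"], gate_id = gid)
      fit$phenotype <- row$phenotype[1]  # tier-1 authority is the SISO table
      return(fit)
    }
    as.list(row[1, ])
  }
  verdicts <- lapply(seq_len(nrow(pairs)), function(i) {
    v <- check_pair(lookup(pairs$siso_a[i]), lookup(pairs$siso_b[i]),
                    k = k, alpha = alpha)
    data.frame(gate_id = pairs$gate_id[i], siso_a = pairs$siso_a[i],
               siso_b = pairs$siso_b[i], tier1_pass = v$tier1_pass,
               tier2_pass = v$tier2_pass, pass = v$pass,
               reasons = paste(v$reasons, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  verdicts <- if (length(verdicts)) do.call(rbind, verdicts) else
    data.frame(gate_id = character(), siso_a = character(),
               siso_b = character(), tier1_pass = logical(),
               tier2_pass = logical(), pass = logical(),
               reasons = character(), stringsAsFactors = FALSE)
  list(passing = pairs[pairs$gate_id %in% verdicts$gate_id[verdicts$pass], ,
                       drop = FALSE],
       verdicts = verdicts)
}

#' Write a screening verdict table as TSV
#' @param verdicts verdict data.frame from \code{\link{screen_space}}.
#' @param path output file.
#' @export
write_verdict_tsv <- function(verdicts, path) {
  utils::write.table(verdicts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
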