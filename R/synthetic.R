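#' Measurement-noise model for synthetic plate data
#'
#' Phenomenological noise mirroring endpoint plate-reader assays:
#' multiplicative lognormal noise (unit mean, coefficient of variation
#' \code{cv}) on per-cell fluorescence, a lognormal culture-density
#' distribution for OD600, and constant blank-media background added to both
#' channels before blank subtraction, so the correction path is exercised.
#'
#' @param cv lognormal coefficient of variation of per-well fluorescence
#'   (default 0.10).
#' @param background_rfu additive blank fluorescence in RFU (default 500).
#' @param background_od additive blank OD600 (default 0.04).
#' @param od_mean,od_cv culture density mean and lognormal CV (defaults 0.5,
#'   0.05).
#' @param n_replicates replicate wells per condition (default 6).
#' @param utr_cv lognormal CV of a per-gate 5'-UTR expression bias applied to
#'   non-insulated PROXIMAL gates (default 0 = no bias); insulated reporters
#'   remove this bias and halve \code{cv}.
#' @param insulated logical; emulate insulated (RiboJ-type) reporters.
#' @return list of class \code{noise_model}.
#' @export
noise_model <- function(cv = 0.10, background_rfu = 500, background_od = 0.04,
                        od_mean = 0.5, od_cv = 0.05, n_replicates = 6,
                        utr_cv = 0, insulated = FALSE) {
  stopifnot(cv >= 0, n_replicates >= 2, od_mean > 0, utr_cv >= 0)
  if (insulated) {
    cv <- cv / 2
    utr_cv <- 0
  }
  structure(list(cv = cv, background_rfu = background_rfu,
                 background_od = background_od, od_mean = od_mean,
                 od_cv = od_cv, n_replicates = n_replicates,
                 utr_cv = utr_cv, insulated = insulated),
            class = "noise_model")
}

# emit raw wells for one gate given true unit-scale condition means
simulate_corner_plate <- function(true_means, conditions, gate_id,
                                  noise = noise_model(), plate = "P1",
                                  global_max_rfu = 75000, bias = 1) {
  n <- noise$n_replicates
  rows <- list()
  for (ci in seq_along(conditions)) {
    od <- noise$od_mean * rlnorm_cv(n, noise$od_cv)
    unit <- true_means[ci] * bias * rlnorm_cv(n, noise$cv)
    rows[[ci]] <- data.frame(
      well_id = sprintf("%s_%s_c%d_r%d", plate, gate_id, ci, seq_len(n)),
      gate_id = gate_id,
      condition = conditions[ci],
      replicate = seq_len(n),
      od600 = od + noise$background_od,
      gfp = unit * global_max_rfu * od + noise$background_rfu,
      is_blank = FALSE,
      plate = plate,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

blank_wells <- function(noise, plate = "P1", n_blanks = 4) {
  data.frame(well_id = sprintf("%s_blank_r%d", plate, seq_len(n_blanks)),
             gate_id = "blank", condition = "blank",
             replicate = seq_len(n_blanks),
             od600 = noise$background_od, gfp = noise$background_rfu,
             is_blank = TRUE, plate = plate, stringsAsFactors = FALSE)
}

#' Generate a ground-truth single-input gate library with raw plate data
#'
#' Assigns each putative design a phenotype drawn from \code{phenotype_mix}
#' and coarse-grained parameters drawn uniformly from \code{epsilon_range} /
#' \code{sigma_range}, then emits raw OD600/GFP wells for the two inducer
#' conditions (\code{"I=0"}, \code{"I=1"}) plus blank wells, in the exact
#' plate-CSV dialect the processing pipeline consumes. True condition means
#' follow the coarse-grained model: repressors are OFF uninduced,
#' antirepressors OFF induced; super-repressors output their (low) leakiness
#' in both conditions and nonfunctional gates their (high) ON level in both.
#'
#' @param catalogue a \code{\link{gate_catalogue}} (default demonstration
#'   catalogue).
#' @param gate_type \code{"BUFFER"} or \code{"NOT"}.
#' @param phenotype_mix proportions over
#'   (operational, super-repressor, nonfunctional); operational means
#'   repressor for BUFFER designs and antirepressor for NOT designs.
#'   Defaults emulate the observed ~91\% functional BUFFER and ~95\%
#'   functional NOT rates.
#' @param epsilon_range,sigma_range uniform supports of the true leakiness
#'   and dynamic increment on the unit scale.
#' @param noise a \code{\link{noise_model}}.
#' @param seed optional RNG seed (same seed, same library).
#' @param n_designs optionally restrict to the first n designs (desk-scale
#'   runs).
#' @param global_max_rfu unit-scale denominator used when emitting raw RFU.
#' @return list with \code{truth} (gate_id, design columns, phenotype,
#'   epsilon, sigma) and \code{plate} (raw records incl. blanks).
#' @examples
#' lib <- generate_siso_library(n_designs = 3, seed = 7)
#' lib$truth[, c("gate_id", "phenotype", "epsilon", "sigma")]
#' @export
generate_siso_library <- function(catalogue = default_catalogue(),
                                  gate_type = c("BUFFER", "NOT"),
                                  phenotype_mix = NULL,
                                  epsilon_range = c(0.01, 0.12),
                                  sigma_range = c(0.4, 0.85),
                                  noise = noise_model(), seed = NULL,
                                  n_designs = NULL, global_max_rfu = 75000) {
  gate_type <- match.arg(gate_type)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(phenotype_mix))
    phenotype_mix <- if (gate_type == "BUFFER")
      c(operational = 0.9, super_repressor = 0.025, nonfunctional = 0.075)
    else
      c(operational = 0.95, super_repressor = 0.0125, nonfunctional = 0.0375)
  stopifnot(abs(sum(phenotype_mix) - 1) < 1e-8,
            epsilon_range[1] >= 0, epsilon_range[2] <= 1,
            sigma_range[1] >= 0, sigma_range[2] <= 1)
  designs <- enumerate_siso_space(catalogue, gate_type)
  if (!is.null(n_designs)) designs <- designs[seq_len(n_designs), , drop = FALSE]
  k <- nrow(designs)
  operational <- if (gate_type == "BUFFER") "REPRESSOR" else "ANTIREPRESSOR"
  phen <- sample(c(operational, "SUPER_REPRESSOR", "NONFUNCTIONAL"), k,
                 replace = TRUE, prob = phenotype_mix)
  eps <- stats::runif(k, epsilon_range[1], epsilon_range[2])
  sig <- stats::runif(k, sigma_range[1], sigma_range[2])
  sig[phen == "SUPER_REPRESSOR"] <- 0
  # keep super-repressor output safely below the classification threshold
  eps[phen == "SUPER_REPRESSOR"] <- pmin(eps[phen == "SUPER_REPRESSOR"], 0.08)
  truth <- cbind(designs[, c("gate_id", "gate_type", "position", "rcd", "adr")],
                 data.frame(phenotype = phen, epsilon = eps, sigma = sig,
                            stringsAsFactors = FALSE))
  utr <- rep(1, k)
  if (noise$utr_cv > 0 && !noise$insulated) {
    prox <- truth$position == "PROXIMAL"
    utr[prox] <- rlnorm_cv(sum(prox), noise$utr_cv)
  }
  plates <- vector("list", k)
  for (i in seq_len(k)) {
    means <- switch(phen[i],
      REPRESSOR       = c(eps[i], eps[i] + sig[i]),        # I=0, I=1
      ANTIREPRESSOR   = c(eps[i] + sig[i], eps[i]),
      SUPER_REPRESSOR = c(eps[i], eps[i]),
      NONFUNCTIONAL   = c(eps[i] + sig[i], eps[i] + sig[i]))
    plates[[i]] <- simulate_corner_plate(means, c("I=0", "I=1"),
                                         truth$gate_id[i], noise,
                                         global_max_rfu = global_max_rfu,
                                         bias = utr[i])
  }
  plate <- rbind(do.call(rbind, plates), blank_wells(noise))
  rownames(plate) <- NULL
  list(truth = truth, plate = plate)
}

#' Simulate raw measurements of a two-input gate from ground truth
#'
#' Corner means are composed from the members' true \eqn{(\epsilon, \sigma)}
#' via the corner-model coefficient scheme, multiplied by per-corner
#' \code{deviation} factors (biology the corner model misses; 1 = model-
#' faithful), then emitted as noisy raw wells over the four inducer
#' conditions plus blanks.
#'
#' @param truth_x,truth_y rows (or lists) with \code{gate_id},
#'   \code{phenotype}, \code{epsilon}, \code{sigma} for the members; slot
#'   phenotypes must match \code{gate_type}.
#' @param gate_type one of \code{"AND"}, \code{"NOR"}, \code{"A_NIMPLY_B"},
#'   \code{"B_NIMPLY_A"}.
#' @param deviation multiplicative factor(s), length 1 or 4 (truth-table
#'   corner order); must be positive.
#' @param noise a \code{\link{noise_model}}.
#' @param seed optional RNG seed.
#' @param estimator corner composition scheme (see
#'   \code{\link{estimate_alphas}}).
#' @param gate_id identifier for the emitted gate (default derived from
#'   members).
#' @param global_max_rfu unit-scale denominator used when emitting raw RFU.
#' @return list with \code{true_corners} (condition, omega, deviation,
#'   mean) and \code{plate} (raw records incl. blanks).
#' @export
simulate_miso_measurements <- function(truth_x, truth_y, gate_type,
                                       deviation = 1, noise = noise_model(),
                                       seed = NULL, estimator = "min_corner",
                                       gate_id = NULL,
                                       global_max_rfu = 75000) {
  if (!is.null(seed)) set.seed(seed)
  truth_x <- as.list(truth_x); truth_y <- as.list(truth_y)
  need <- miso_slot_phenotypes(gate_type)
  got <- c(truth_x$phenotype, truth_y$phenotype)
  if (!identical(got, need))
    stop(sprintf("%s requires slot phenotypes (%s); got (%s)", gate_type,
                 paste(need, collapse = ", "), paste(got, collapse = ", ")),
         call. = FALSE)
  deviation <- rep(deviation, length.out = 4L)
  stopifnot(all(deviation > 0))
  alphas <- suppressWarnings(estimate_alphas(truth_x, truth_y, estimator))
  tt <- predict_truth_table(alphas, gate_type)
  means <- tt$omega * deviation
  gate_id <- gate_id %||%
    paste(gate_type, paste0(truth_x$gate_id, "|", truth_y$gate_id), sep = "_")
  plate <- rbind(simulate_corner_plate(means, tt$condition, gate_id, noise,
                                       global_max_rfu = global_max_rfu),
                 blank_wells(noise))
  rownames(plate) <- NULL
  list(true_corners = data.frame(condition = tt$condition, omega = tt$omega,
                                 deviation = deviation, mean = means,
                                 stringsAsFactors = FALSE),
       plate = plate)
}
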