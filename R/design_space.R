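#' Enumerate the putative single-input gate design space
#'
#' Every combination of regulatory core domain, DNA recognition function and
#' operator position is a putative SISO gate: BUFFER gates place a repressor
#' (ON with inducer), NOT gates an antirepressor (ON without inducer). The
#' 5-RCD x 8-ADR x 2-position demonstration catalogue therefore yields 80
#' putative BUFFER and 80 putative NOT operations.
#'
#' @param catalogue a \code{\link{gate_catalogue}}.
#' @param gate_type \code{"BUFFER"} or \code{"NOT"}.
#' @return data.frame with one row per design: \code{gate_id, gate_type,
#'   architecture, position, rcd, adr, phenotype}. The phenotype column holds
#'   the design intent (\code{REPRESSOR} for BUFFER, \code{ANTIREPRESSOR} for
#'   NOT) until measurements reclassify it.
#' @examples
#' nrow(enumerate_siso_space(default_catalogue(), "BUFFER"))  # 80
#' @export
enumerate_siso_space <- function(catalogue, gate_type = c("BUFFER", "NOT")) {
  stopifnot(inherits(catalogue, "gate_catalogue"))
  gate_type <- match.arg(gate_type)
  grid <- expand.grid(rcd = catalogue$rcds$rcd_id,
                      adr = catalogue$adrs$adr_id,
                      position = catalogue$positions,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  data.frame(
    gate_id = paste(gate_type, grid$rcd, grid$adr, grid$position, sep = "_"),
    gate_type = gate_type,
    architecture = "SISO",
    position = grid$position,
    rcd = grid$rcd,
    adr = grid$adr,
    phenotype = if (gate_type == "BUFFER") "REPRESSOR" else "ANTIREPRESSOR",
    stringsAsFactors = FALSE)
}

#' Enumerate SE-PA two-input gate pairs from SISO designs
#'
#' In the series-parallel (SE-PA) architecture two transcription factors with
#' the same DNA recognition function are directed to one shared operator, so a
#' two-input gate is a pair of SISO designs agreeing on ADR and position but
#' carrying nonsynonymous (distinct) RCDs — both slots must read different
#' inducers. The gate type dictates slot phenotypes: AND pairs two repressors,
#' NOR two antirepressors, NIMPLY one of each (for A NIMPLY B the slot
#' responding to input A is the repressor; B NIMPLY A swaps them). AND/NOR
#' pairs are unordered (canonicalized by rcd id); NIMPLY pairs are ordered.
#'
#' @param siso_designs data.frame as produced by
#'   \code{\link{enumerate_siso_space}}, with the \code{phenotype} column
#'   holding measured calls when available (\code{REPRESSOR},
#'   \code{ANTIREPRESSOR}, \code{SUPER_REPRESSOR}, \code{NONFUNCTIONAL}).
#' @param gate_type one of \code{"AND"}, \code{"NOR"}, \code{"A_NIMPLY_B"},
#'   \code{"B_NIMPLY_A"}.
#' @param apply_functionality_filter if \code{TRUE}, pairs containing a member
#'   whose phenotype is not the one its slot requires are dropped (the first
#'   tier of the design decision process).
#' @return data.frame with one row per pair: ids of both member SISO gates,
#'   shared adr/position, per-slot rcd and phenotype.
#' @examples
#' siso <- enumerate_siso_space(default_catalogue(), "BUFFER")
#' sum(enumerate_sepa_pairs(siso, "AND")$position == "PROXIMAL")  # 80
#' @export
enumerate_sepa_pairs <- function(siso_designs, gate_type,
                                 apply_functionality_filter = FALSE) {
  if (!gate_type %in% GATE_TYPES_MISO)
    stop("unknown gate_type: ", gate_type, call. = FALSE)
  need <- miso_slot_phenotypes(gate_type)
  source_type <- function(ph) if (ph == "REPRESSOR") "BUFFER" else "NOT"
  cand_a <- siso_designs[siso_designs$gate_type == source_type(need[1]), ]
  cand_b <- siso_designs[siso_designs$gate_type == source_type(need[2]), ]
  if (apply_functionality_filter) {
    cand_a <- cand_a[cand_a$phenotype == need[1], ]
    cand_b <- cand_b[cand_b$phenotype == need[2], ]
  }
  out <- list()
  ordered <- gate_type %in% c("A_NIMPLY_B", "B_NIMPLY_A")
  for (pos in unique(c(cand_a$position, cand_b$position))) {
    for (adr in unique(c(cand_a$adr, cand_b$adr))) {
      a <- cand_a[cand_a$position == pos & cand_a$adr == adr, ]
      b <- cand_b[cand_b$position == pos & cand_b$adr == adr, ]
      if (nrow(a) == 0L || nrow(b) == 0L) next
      pairs <- expand.grid(ia = seq_len(nrow(a)), ib = seq_len(nrow(b)),
                           KEEP.OUT.ATTRS = FALSE)
      pairs <- pairs[a$rcd[pairs$ia] != b$rcd[pairs$ib], , drop = FALSE]
      if (!ordered)  # unordered: keep the lexicographically canonical orientation
        pairs <- pairs[a$rcd[pairs$ia] < b$rcd[pairs$ib], , drop = FALSE]
      if (nrow(pairs) == 0L) next
      out[[length(out) + 1L]] <- data.frame(
        gate_id = paste(gate_type, paste0(a$rcd[pairs$ia], ".", b$rcd[pairs$ib]),
                        adr, pos, sep = "_"),
        gate_type = gate_type,
        architecture = "SE_PA",
        position = pos,
        rcd_a = a$rcd[pairs$ia], adr_a = adr, phenotype_a = a$phenotype[pairs$ia],
        rcd_b = b$rcd[pairs$ib], adr_b = adr, phenotype_b = b$phenotype[pairs$ib],
        siso_a = a$gate_id[pairs$ia], siso_b = b$gate_id[pairs$ib],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(gate_id = character(), gate_type = character(),
                      architecture = character(), position = character(),
                      rcd_a = character(), adr_a = character(),
                      phenotype_a = character(), rcd_b = character(),
                      adr_b = character(), phenotype_b = character(),
                      siso_a = character(), siso_b = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$gate_id), , drop = FALSE]
}

#' Count the networked design space of interconnectable two-input gates
#'
#' Orthogonal DNA recognition functions partition the gate library into
#' independent DNA-binding "bins"; within each bin any unordered pair of
#' nonsynonymous RCDs forms an AND (or NOR) operation, so the AND/NOR network
#' space is \code{adr_bins * choose(rcds, 2)} — e.g. 7 bins x C(5,2) = 70.
#' The \code{"MIXED"} mode additionally counts ordered repressor/antirepressor
#' (NIMPLY) pairings as \code{adr_bins * rcds * (rcds - 1)}; no authoritative
#' enumeration rule exists for mixed network spaces, so that mode is exposed
#' for exploration but flagged non-normative via a warning.
#'
#' @param adr_bins number of orthogonal DNA-binding bins.
#' @param rcds number of nonsynonymous regulatory core domains per bin.
#' @param mode \code{"AND_NOR"} (default) or \code{"MIXED"}.
#' @return integer count; 0 when \code{rcds < 2} (no pairs exist).
#' @export
enumerate_network_space <- function(adr_bins, rcds, mode = c("AND_NOR", "MIXED")) {
  mode <- match.arg(mode)
  stopifnot(adr_bins >= 1, rcds >= 1)
  if (rcds < 2) return(0L)
  if (mode == "AND_NOR") {
    as.integer(adr_bins * choose(rcds, 2))
  } else {
    warning("MIXED network-space formula is non-normative (ordered pair heuristic)",
            call. = FALSE)
    as.integer(adr_bins * rcds * (rcds - 1))
  }
}

#' Export a design list as TSV
#'
#' Writes the standard design-table dialect: columns \code{gate_id, gate_type,
#' architecture, position, rcd_a, adr_a, phenotype_a, rcd_b, adr_b,
#' phenotype_b} (the \code{_b} columns are empty for SISO designs).
#'
#' @param designs data.frame from \code{\link{enumerate_siso_space}} or
#'   \code{\link{enumerate_sepa_pairs}}.
#' @param path output file.
#' @export
write_design_tsv <- function(designs, path) {
  cols <- c("gate_id", "gate_type", "architecture", "position",
            "rcd_a", "adr_a", "phenotype_a", "rcd_b", "adr_b", "phenotype_b")
  d <- designs
  if ("rcd" %in% names(d)) {  # SISO layout -> slot-A columns
    d$rcd_a <- d$rcd; d$adr_a <- d$adr; d$phenotype_a <- d$phenotype
    d$rcd_b <- NA_character_; d$adr_b <- NA_character_; d$phenotype_b <- NA_character_
  }
  utils::write.table(d[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
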