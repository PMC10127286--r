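#' Read a long-format plate-reader table
#'
#' Expected header: \code{well_id,gate_id,condition,replicate,od600,gfp,is_blank}
#' with an optional \code{plate} column (single-plate files get plate "P1").
#' \code{condition} encodes digitized inducer states, e.g. \code{"I=1"} for a
#' single-input gate or \code{"IX=0;IY=1"} for a two-input gate.
#'
#' @param path CSV file path.
#' @return data.frame of plate records.
#' @export
read_plate_csv <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well_id", "gate_id", "condition", "replicate", "od600", "gfp", "is_blank")
  missing <- setdiff(need, names(rec))
  if (length(missing))
    stop("plate CSV missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  if (!"plate" %in% names(rec)) rec$plate <- "P1"
  rec$is_blank <- as.logical(rec$is_blank)
  rec
}

#' @rdname read_plate_csv
#' @param records plate records data.frame.
#' @export
write_plate_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Blank-correct raw plate measurements
#'
#' Subtracts each plate's mean blank OD600 and mean blank fluorescence from
#' every sample well on that plate, then drops the blank wells. Corrected
#' values that fall below zero are clamped to zero with a warning
#' (fluorescence and optical density cannot be negative).
#'
#' @param records plate records (see \code{\link{read_plate_csv}}).
#' @return corrected records, blanks removed.
#' @export
blank_correct <- function(records) {
  if (!"plate" %in% names(records)) records$plate <- "P1"
  out <- list()
  for (pl in unique(records$plate)) {
    r <- records[records$plate == pl, ]
    blanks <- r[r$is_blank, ]
    if (nrow(blanks) == 0L)
      stop("no blank wells on plate ", pl, call. = FALSE)
    samp <- r[!r$is_blank, ]
    samp$od600 <- samp$od600 - mean(blanks$od600)
    samp$gfp <- samp$gfp - mean(blanks$gfp)
    out[[pl]] <- samp
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  n_neg <- sum(out$gfp < 0) + sum(out$od600 < 0)
  if (n_neg > 0) {
    warning(n_neg, " corrected value(s) below zero clamped to 0", call. = FALSE)
    out$gfp <- pmax(out$gfp, 0)
    out$od600 <- pmax(out$od600, 0)
  }
  out
}

#' OD-normalize and unit-scale blank-corrected wells
#'
#' Per well: fluorescence is divided by OD600 (expression per cell proxy) and
#' scaled by a nominal global maximum (default 75,000 RFU), mapping outputs
#' onto a 0-1 scale. Wells with non-positive OD are excluded with a warning.
#'
#' @param records blank-corrected plate records.
#' @param global_max_rfu unit-scale denominator in RFU.
#' @return data.frame of well-level normalized values (\code{value} column).
#' @export
normalize_wells <- function(records, global_max_rfu = 75000) {
  bad <- records$od600 <= 0
  if (any(bad)) {
    warning(sum(bad), " well(s) with non-positive OD600 excluded", call. = FALSE)
    records <- records[!bad, ]
  }
  data.frame(gate_id = records$gate_id,
             condition = records$condition,
             replicate = records$replicate,
             value = (records$gfp / records$od600) / global_max_rfu,
             stringsAsFactors = FALSE)
}

#' Summarize normalized wells per gate and condition
#'
#' Mean and sample standard deviation (n-1 denominator) across replicates.
#' Conditions left with fewer than two replicates raise an error; means above
#' 1 are permitted (the 75,000 RFU maximum is nominal) but flagged.
#'
#' @param wells data.frame from \code{\link{normalize_wells}}.
#' @return data.frame with \code{gate_id, condition, mean_fluor, sd_fluor, n}.
#' @export
condition_summaries <- function(wells) {
  key <- interaction(wells$gate_id, wells$condition, drop = TRUE)
  parts <- split(wells, key)
  res <- do.call(rbind, lapply(parts, function(p) {
    data.frame(gate_id = p$gate_id[1], condition = p$condition[1],
               mean_fluor = mean(p$value), sd_fluor = stats::sd(p$value),
               n = nrow(p), stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  if (any(res$n < 2))
    stop("fewer than 2 replicates for: ",
         paste(res$gate_id[res$n < 2], res$condition[res$n < 2], collapse = "; "),
         call. = FALSE)
  if (any(res$mean_fluor > 1))
    warning(sum(res$mean_fluor > 1),
            " condition mean(s) above the nominal unit scale", call. = FALSE)
  res[order(res$gate_id, res$condition), , drop = FALSE]
}

#' Full plate-processing pipeline
#'
#' Blank-correct, OD-normalize each well, unit-scale, then summarize per
#' (gate, condition) — in that order, so replicate standard deviations
#' reflect per-well fluorescence/OD ratios.
#'
#' @param records raw plate records.
#' @param global_max_rfu unit-scale denominator in RFU.
#' @return list with \code{wells} (normalized replicate values) and
#'   \code{summaries} (condition summaries).
#' @examples
#' lib <- generate_siso_library(n_designs = 4, seed = 1)
#' pp <- process_plate(lib$plate)
#' head(pp$summaries)
#' @export
process_plate <- function(records, global_max_rfu = 75000) {
  wells <- normalize_wells(blank_correct(records), global_max_rfu)
  list(wells = wells, summaries = condition_summaries(wells))
}

#' Write / read condition summaries as TSV
#'
#' Values are written with enough precision to round-trip losslessly to six
#' significant digits.
#' @param summaries condition-summary data.frame.
#' @param path file path.
#' @export
write_summary_tsv <- function(summaries, path) {
  s <- summaries
  s$mean_fluor <- signif(s$mean_fluor, 10)
  s$sd_fluor <- signif(s$sd_fluor, 10)
  utils::write.table(s, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_summary_tsv
#' @export
read_summary_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
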