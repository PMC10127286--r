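#' Component catalogue for transcriptional logic gate design
#'
#' A catalogue bundles the modular parts from which single-input (SISO) and
#' two-input (MISO) transcriptional logic gates are assembled:
#' regulatory core domains (RCDs, the ligand-sensing portion of a
#' LacI-topology transcription factor), alternate DNA recognition functions
#' (ADRs, each paired bijectively with one cognate operator sequence), and
#' operator positions relative to the promoter (\code{"PROXIMAL"},
#' downstream of the promoter, or \code{"CORE"}, between the -35 and -10
#' hexamers).
#'
#' @param rcds data.frame with columns \code{rcd_id} and \code{inducer}
#'   (cognate ligand); ids must be unique, inducers non-empty.
#' @param adrs data.frame with columns \code{adr_id} and \code{operator};
#'   both columns must be duplicate-free (the mapping is a bijection).
#' @param positions character vector drawn from \code{c("PROXIMAL", "CORE")}.
#' @return An object of class \code{gate_catalogue}.
#' @examples
#' cat5x8 <- default_catalogue()
#' cat5x8
#' @export
gate_catalogue <- function(rcds, adrs, positions = c("PROXIMAL", "CORE")) {
  rcds <- as.data.frame(rcds, stringsAsFactors = FALSE)
  adrs <- as.data.frame(adrs, stringsAsFactors = FALSE)
  stopifnot(all(c("rcd_id", "inducer") %in% names(rcds)),
            all(c("adr_id", "operator") %in% names(adrs)))
  if (nrow(rcds) < 1L || nrow(adrs) < 1L || length(positions) < 1L)
    stop("catalogue needs at least one RCD, one ADR and one position", call. = FALSE)
  if (anyDuplicated(rcds$rcd_id))
    stop("duplicate rcd_id in catalogue", call. = FALSE)
  if (any(!nzchar(rcds$inducer)) || anyNA(rcds$inducer))
    stop("every RCD needs a non-empty cognate inducer", call. = FALSE)
  if (anyDuplicated(adrs$adr_id) || anyDuplicated(adrs$operator))
    stop("adr_id <-> operator must be a bijection", call. = FALSE)
  positions <- match.arg(positions, c("PROXIMAL", "CORE"), several.ok = TRUE)
  structure(list(rcds = rcds, adrs = adrs, positions = positions),
            class = "gate_catalogue")
}

#' Default five-RCD, eight-ADR demonstration catalogue
#'
#' Five nonsynonymous regulatory core domains reading distinct sugar/ligand
#' inputs, eight engineered DNA recognition functions with cognate lac-derived
#' operators, and both operator positions. Enumerating BUFFER gates over this
#' catalogue yields the 5 x 8 x 2 = 80-design space used throughout the
#' package documentation.
#'
#' @return A \code{gate_catalogue}.
#' @export
default_catalogue <- function() {
  gate_catalogue(
    rcds = data.frame(
      rcd_id  = c("I", "R", "F", "E", "P"),
      inducer = c("IPTG", "ribose", "fucose", "cellobiose", "fructose"),
      stringsAsFactors = FALSE),
    adrs = data.frame(
      adr_id   = c("WT", "YQR", "HQN", "GKR", "TAN", "NAR", "QAR", "ERN"),
      operator = c("O1", "Oyqr", "Ottg", "Ogac", "Oagg", "Otat", "Ocgc", "Oata"),
      stringsAsFactors = FALSE),
    positions = c("PROXIMAL", "CORE")
  )
}

#' Read / write a component catalogue (YAML or JSON)
#'
#' The on-disk form has top-level keys \code{rcds} (map rcd_id -> inducer),
#' \code{adrs} (map adr_id -> operator) and \code{positions}.
#'
#' @param path file path; format chosen by extension (\code{.json} vs
#'   \code{.yaml}/\code{.yml}).
#' @return \code{read_catalogue} returns a \code{gate_catalogue};
#'   \code{write_catalogue} returns \code{path} invisibly.
#' @export
read_catalogue <- function(path) {
  obj <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  rcds <- data.frame(rcd_id = names(obj$rcds),
                     inducer = unlist(obj$rcds, use.names = FALSE),
                     stringsAsFactors = FALSE)
  adrs <- data.frame(adr_id = names(obj$adrs),
                     operator = unlist(obj$adrs, use.names = FALSE),
                     stringsAsFactors = FALSE)
  gate_catalogue(rcds, adrs, unlist(obj$positions))
}

#' @rdname read_catalogue
#' @param catalogue a \code{gate_catalogue}.
#' @export
write_catalogue <- function(catalogue, path) {
  stopifnot(inherits(catalogue, "gate_catalogue"))
  obj <- list(
    rcds = as.list(stats::setNames(catalogue$rcds$inducer, catalogue$rcds$rcd_id)),
    adrs = as.list(stats::setNames(catalogue$adrs$operator, catalogue$adrs$adr_id)),
    positions = as.list(catalogue$positions))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(obj, path)
  }
  invisible(path)
}

#' @export
print.gate_catalogue <- function(x, ...) {
  cat("Gate component catalogue\n")
  cat("  RCDs     :", paste(x$rcds$rcd_id, collapse = ", "), "\n")
  cat("  ADRs     :", paste(x$adrs$adr_id, collapse = ", "), "\n")
  cat("  positions:", paste(x$positions, collapse = ", "), "\n")
  invisible(x)
}
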