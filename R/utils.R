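# internal helpers shared across modules

# parse a condition label ("I=1" or "IX=0;IY=1") into a named integer vector
parse_condition <- function(cond) {
  parts <- strsplit(cond, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  vals <- vapply(kv, function(x) as.integer(x[2]), integer(1))
  names(vals) <- vapply(kv, `[`, character(1), 1)
  if (anyNA(vals) || !all(vals %in% c(0L, 1L)))
    stop("malformed condition label: ", cond, call. = FALSE)
  vals
}

condition_label <- function(states) {
  paste(paste0(names(states), "=", as.integer(states)), collapse = ";")
}

# condition labels for the four 2-INPUT corners, in truth-table order
miso_conditions <- function() {
  corners <- expand.grid(IX = 0:1, IY = 0:1)[, c("IX", "IY")]
  corners <- corners[order(corners$IX, corners$IY), ]
  apply(corners, 1L, function(r) sprintf("IX=%d;IY=%d", r[1], r[2]))
}

# multiplicative lognormal factors with unit mean and coefficient of variation cv
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

GATE_TYPES_SISO <- c("BUFFER", "NOT")
GATE_TYPES_MISO <- c("AND", "NOR", "A_NIMPLY_B", "B_NIMPLY_A")
PHENOTYPES <- c("REPRESSOR", "ANTIREPRESSOR", "SUPER_REPRESSOR", "NONFUNCTIONAL")
OPERATIONAL <- c("REPRESSOR", "ANTIREPRESSOR")

# slot phenotypes implied by a 2-INPUT gate type (slot A, slot B)
miso_slot_phenotypes <- function(gate_type) {
  switch(gate_type,
    AND        = c("REPRESSOR", "REPRESSOR"),
    NOR        = c("ANTIREPRESSOR", "ANTIREPRESSOR"),
    A_NIMPLY_B = c("REPRESSOR", "ANTIREPRESSOR"),
    B_NIMPLY_A = c("ANTIREPRESSOR", "REPRESSOR"),
    stop("unknown 2-INPUT gate type: ", gate_type, call. = FALSE)
  )
}

# the single ON corner of each Boolean function, as a condition label
designated_on_corner <- function(gate_type) {
  switch(gate_type,
    AND        = "IX=1;IY=1",
    NOR        = "IX=0;IY=0",
    A_NIMPLY_B = "IX=1;IY=0",
    B_NIMPLY_A = "IX=0;IY=1",
    stop("unknown 2-INPUT gate type: ", gate_type, call. = FALSE)
  )
}
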