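# Independent oracles and fixture builders used across the suite.

# count the SISO Cartesian product by explicit loops (not the closed form)
brute_force_siso_count <- function(n_rcd, n_adr, n_pos) {
  count <- 0L
  for (r in seq_len(n_rcd)) for (a in seq_len(n_adr)) for (p in seq_len(n_pos))
    count <- count + 1L
  count
}

# enumerate unordered nonsynonymous pairs per (adr, position) by loops
brute_force_unordered_pairs <- function(rcds, n_adr, n_pos) {
  count <- 0L
  for (a in seq_len(n_adr)) for (p in seq_len(n_pos))
    for (i in seq_along(rcds)) for (j in seq_along(rcds))
      if (i < j) count <- count + 1L
  count
}

# solve the four corner-assumption equations for the alphas directly:
# omega(0,0) = min(eps), omega(1,0) = eps_y, omega(0,1) = eps_x,
# omega(1,1) = min(eps + sigma); design matrix in (1, Sx, Sy, SxSy)
solve_corner_alphas <- function(ex, sx, ey, sy) {
  targets <- c(min(ex, ey), ey, ex, min(ex + sx, ey + sy))
  S <- rbind(c(1, 0, 0, 0),
             c(1, 1, 0, 0),
             c(1, 0, 1, 0),
             c(1, 1, 1, 1))
  as.numeric(solve(S, targets))
}

# small all-operational demonstration catalogue variants
tiny_catalogue <- function(n_rcd = 3, n_adr = 2, positions = c("PROXIMAL", "CORE")) {
  gate_catalogue(
    rcds = data.frame(rcd_id = LETTERS[seq_len(n_rcd)],
                      inducer = paste0("ligand", seq_len(n_rcd))),
    adrs = data.frame(adr_id = paste0("ADR", seq_len(n_adr)),
                      operator = paste0("Op", seq_len(n_adr))),
    positions = positions)
}

# a large synthetic catalogue for parameter-recovery runs (both positions)
big_catalogue <- function(n_rcd = 50, n_adr = 10) {
  gate_catalogue(
    rcds = data.frame(rcd_id = sprintf("R%02d", seq_len(n_rcd)),
                      inducer = sprintf("L%02d", seq_len(n_rcd))),
    adrs = data.frame(adr_id = sprintf("A%02d", seq_len(n_adr)),
                      operator = sprintf("O%02d", seq_len(n_adr))))
}

# ground-truth member gates for two-input simulations
truth_gate <- function(id, phenotype, epsilon, sigma) {
  list(gate_id = id, phenotype = phenotype, epsilon = epsilon, sigma = sigma)
}

noise_free <- function(n = 6) noise_model(cv = 0, od_cv = 0, n_replicates = n)

# replicate vectors with a given mean and small jitter, fixed pattern
jitter_reps <- function(mean, sd = 0.01, n = 6) {
  mean + sd * scale(seq_len(n))[, 1]
}
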