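summary_gate <- function(id, off, on, sd = 0.01, phenotype = "REPRESSOR") {
  if (phenotype == "REPRESSOR")
    list(gate_id = id, phenotype = phenotype,
         mean_uninduced = off, sd_uninduced = sd,
         mean_induced = on, sd_induced = sd)
  else
    list(gate_id = id, phenotype = phenotype,
         mean_uninduced = on, sd_uninduced = sd,
         mean_induced = off, sd_induced = sd)
}

test_that("well-separated pairs pass both tiers under either rule", {
  # summary band rule
  v <- check_pair(summary_gate("X", 0.05, 0.85),
                  summary_gate("Y", 0.10, 0.80))
  expect_true(v$tier1_pass && v$tier2_pass && v$pass)
  # replicate t-test rule
  x <- siso_fit(jitter_reps(0.05), jitter_reps(0.85), "X")
  y <- siso_fit(jitter_reps(0.10), jitter_reps(0.80), "Y")
  vr <- check_pair(x, y)
  expect_true(vr$pass)
  expect_equal(vr$margin_used$rule, "welch_one_sided")
})

test_that("insufficient ON/OFF separation fails tier 2", {
  # ON of Y (0.65) cannot clear the larger leakiness (0.60) at k = 2, sd 0.05
  v <- check_pair(summary_gate("X", 0.05, 0.85, sd = 0.05),
                  summary_gate("Y", 0.60, 0.65, sd = 0.05))
  expect_true(v$tier1_pass)
  expect_false(v$tier2_pass)
  expect_false(v$pass)
  expect_match(paste(v$reasons, collapse = " "), "does not exceed")
})

test_that("identical members with zero spread and ON > OFF are compatible", {
  v <- check_pair(summary_gate("X", 0.05, 0.85, sd = 0),
                  summary_gate("X2", 0.05, 0.85, sd = 0))
  expect_true(v$pass)
})

test_that("nonoperational members fail tier 1 and name the culprit", {
  bad <- summary_gate("DEAD", 0.9, 0.9)
  bad$phenotype <- "NONFUNCTIONAL"
  v <- check_pair(summary_gate("X", 0.05, 0.85), bad)
  expect_false(v$tier1_pass)
  expect_false(v$pass)
  expect_match(v$reasons[1], "DEAD")
})

test_that("check_pair is symmetric in its arguments", {
  set.seed(31)
  for (i in 1:10) {
    x <- summary_gate("X", runif(1, 0, 0.3), runif(1, 0.4, 0.9), sd = 0.03)
    y <- summary_gate("Y", runif(1, 0, 0.3), runif(1, 0.4, 0.9), sd = 0.03)
    expect_equal(check_pair(x, y)$pass, check_pair(y, x)$pass)
  }
})

test_that("screening is monotone in the margin k", {
  set.seed(32)
  gates <- lapply(1:8, function(i)
    summary_gate(paste0("G", i), runif(1, 0.02, 0.35),
                 runif(1, 0.45, 0.9), sd = 0.05))
  passes <- function(k) {
    vapply(utils::combn(8, 2, simplify = FALSE), function(ij)
      check_pair(gates[[ij[1]]], gates[[ij[2]]], k = k)$pass, logical(1))
  }
  prev <- passes(0.5)
  for (k in c(1, 2, 4)) {
    cur <- passes(k)
    expect_true(all(prev | !cur))  # larger k never passes a pair smaller k rejected
    prev <- cur
  }
})

test_that("screen_space recovers a planted incompatible pair exactly", {
  cat_ <- tiny_catalogue(3, 1, "PROXIMAL")
  lib <- generate_siso_library(cat_, "BUFFER", phenotype_mix = c(1, 0, 0),
                               noise = noise_free(), seed = 8)
  # plant: gate C leaks above every partner's ON state, so no partner clears it
  lib$truth$epsilon[3] <- 0.99
  lib$truth$sigma[3] <- 0.005
  pp <- process_plate(lib$plate)
  wells <- pp$wells
  for (i in seq_len(nrow(lib$truth))) {
    g <- lib$truth$gate_id[i]
    wells$value[wells$gate_id == g & wells$condition == "I=0"] <- lib$truth$epsilon[i]
    wells$value[wells$gate_id == g & wells$condition == "I=1"] <-
      lib$truth$epsilon[i] + lib$truth$sigma[i]
  }
  siso <- fit_siso_table(wells)
  designs <- lib$truth[, c("gate_id", "gate_type", "position", "rcd", "adr")]
  designs$phenotype <- siso$phenotype[match(designs$gate_id, siso$gate_id)]
  pairs <- enumerate_sepa_pairs(designs, "AND", apply_functionality_filter = TRUE)
  scr <- screen_space(pairs, siso, k = 2)
  rejected <- scr$verdicts$gate_id[!scr$verdicts$pass]
  planted <- lib$truth$gate_id[3]
  involved <- scr$verdicts$siso_a == planted | scr$verdicts$siso_b == planted
  expect_setequal(rejected, scr$verdicts$gate_id[involved])
  expect_equal(nrow(scr$passing), nrow(pairs) - sum(involved))
})

test_that("screen_space trivial cases and missing records", {
  cat_ <- tiny_catalogue(3, 1, "PROXIMAL")
  lib <- generate_siso_library(cat_, "BUFFER", phenotype_mix = c(1, 0, 0),
                               noise = noise_free(), seed = 12)
  pp <- process_plate(lib$plate)
  siso <- fit_siso_table(pp$wells)
  designs <- lib$truth[, c("gate_id", "gate_type", "position", "rcd", "adr")]
  designs$phenotype <- siso$phenotype[match(designs$gate_id, siso$gate_id)]
  pairs <- enumerate_sepa_pairs(designs, "AND", apply_functionality_filter = TRUE)
  # all pairs operational and well-separated -> screen is a no-op
  scr <- screen_space(pairs, siso, wells = pp$wells)
  expect_equal(scr$passing$gate_id, pairs$gate_id)
  # empty input -> empty output
  empty <- screen_space(pairs[0, ], siso)
  expect_equal(nrow(empty$passing), 0)
  # unknown member gate errors by name
  pairs$siso_a[1] <- "BUFFER_GHOST"
  expect_error(screen_space(pairs, siso), "BUFFER_GHOST")
})
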