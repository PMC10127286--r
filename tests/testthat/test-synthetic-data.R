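test_that("generation is deterministic under a fixed seed", {
  a <- generate_siso_library(tiny_catalogue(2, 2), "BUFFER", seed = 99)
  b <- generate_siso_library(tiny_catalogue(2, 2), "BUFFER", seed = 99)
  expect_identical(a$truth, b$truth)
  expect_identical(a$plate, b$plate)
  path_a <- withr::local_tempfile(fileext = ".csv")
  path_b <- withr::local_tempfile(fileext = ".csv")
  write_plate_csv(a$plate, path_a); write_plate_csv(b$plate, path_b)
  expect_identical(readLines(path_a), readLines(path_b))
})

test_that("zero-noise wells have zero replicate spread after processing", {
  lib <- generate_siso_library(tiny_catalogue(2, 1, "CORE"), "BUFFER",
                               phenotype_mix = c(1, 0, 0),
                               noise = noise_free(), seed = 4)
  s <- process_plate(lib$plate)$summaries
  expect_equal(s$sd_fluor, rep(0, nrow(s)))
})

test_that("phenotype mix drives the operational fraction binomially", {
  lib <- generate_siso_library(default_catalogue(), "BUFFER",
                               phenotype_mix = c(0.875, 0.025, 0.10),
                               seed = 123)
  n_rep <- sum(lib$truth$phenotype == "REPRESSOR")
  # expectation 70 of 80; allow ~4 binomial SDs (sd = 2.96)
  expect_gt(n_rep, 58)
  expect_lt(n_rep, 80)
  # nonoperational gates emit the intended flat profiles
  pp <- process_plate(lib$plate)$summaries
  for (g in lib$truth$gate_id[lib$truth$phenotype == "SUPER_REPRESSOR"])
    expect_lt(max(pp$mean_fluor[pp$gate_id == g]), 0.1)
  for (g in lib$truth$gate_id[lib$truth$phenotype == "NONFUNCTIONAL"])
    expect_gt(min(pp$mean_fluor[pp$gate_id == g]), 0.3)
})

test_that("closed loop: generate -> process -> classify recovers the truth as cv -> 0", {
  lib <- generate_siso_library(big_catalogue(10, 4), "NOT",
                               noise = noise_free(), seed = 17)
  tab <- fit_siso_table(process_plate(lib$plate)$wells)
  ord <- match(tab$gate_id, lib$truth$gate_id)
  expect_equal(tab$phenotype, lib$truth$phenotype[ord])
  op <- tab$phenotype %in% c("REPRESSOR", "ANTIREPRESSOR")
  expect_equal(tab$epsilon[op], lib$truth$epsilon[ord][op])
  expect_equal(tab$sigma[op], lib$truth$sigma[ord][op])
})

test_that("two-input simulation composes corners from ground truth", {
  x <- truth_gate("X", "REPRESSOR", 0.05, 0.80)
  y <- truth_gate("Y", "REPRESSOR", 0.10, 0.70)
  sim <- simulate_miso_measurements(x, y, "AND", noise = noise_free(), seed = 6)
  expect_equal(sim$true_corners$mean, c(0.05, 0.05, 0.10, 0.80),
               tolerance = 1e-12)
  s <- process_plate(sim$plate)$summaries
  expect_equal(s$mean_fluor[match(sim$true_corners$condition, s$condition)],
               sim$true_corners$mean)
  # phenotype mismatches are rejected
  expect_error(simulate_miso_measurements(x, y, "NOR", noise = noise_free()),
               "ANTIREPRESSOR")
})

test_that("planted corner deviations propagate to downstream flags", {
  x <- truth_gate("X", "REPRESSOR", 0.05, 0.80)
  y <- truth_gate("Y", "REPRESSOR", 0.10, 0.70)
  dev <- c(1, 1, 2.5, 1)
  sim <- simulate_miso_measurements(x, y, "AND", deviation = dev,
                                    noise = noise_free(), seed = 7)
  g <- miso_gate(x, y, "AND", gate_id = "planted")
  pe <- prediction_error(process_plate(sim$plate)$summaries, g)
  expect_equal(sort(pe$per_corner$fold), sort(c(1, 1, 2.5, 1)))
  expect_equal(pe$frac_ge_2fold, 0.25)
})

test_that("model-faithful noisy libraries center the error ratio at 1", {
  set.seed(71)
  ratios <- c(); mean_errors <- c()
  for (i in 1:500) {
    x <- truth_gate("X", "REPRESSOR", runif(1, 0.02, 0.12), runif(1, 0.4, 0.85))
    y <- truth_gate("Y", "REPRESSOR", runif(1, 0.02, 0.12), runif(1, 0.4, 0.85))
    sim <- simulate_miso_measurements(x, y, "AND")
    g <- miso_gate(x, y, "AND")
    pe <- prediction_error(process_plate(sim$plate)$summaries, g)
    ratios <- c(ratios, pe$per_corner$ratio)
    mean_errors <- c(mean_errors, pe$mean_error)
  }
  expect_gt(median(ratios), 0.97)
  expect_lt(median(ratios), 1.03)
  # mean fold error of a faithful noisy library sits just above 1
  expect_gt(mean(mean_errors), 1.0)
  expect_lt(mean(mean_errors), 1.15)
})

test_that("insulated mode halves the noise and removes the UTR bias", {
  n0 <- noise_model(cv = 0.10, utr_cv = 0.2)
  n1 <- noise_model(cv = 0.10, utr_cv = 0.2, insulated = TRUE)
  expect_equal(n1$cv, 0.05)
  expect_equal(n1$utr_cv, 0)
  # with a UTR bias, PROXIMAL replicate groups stay internally tight but
  # gate means scatter around the truth; insulated gates do not
  lib <- generate_siso_library(tiny_catalogue(4, 4, "PROXIMAL"), "BUFFER",
                               phenotype_mix = c(1, 0, 0),
                               noise = noise_model(cv = 0, utr_cv = 0.3),
                               seed = 31)
  tab <- fit_siso_table(process_plate(lib$plate)$wells)
  ord <- match(tab$gate_id, lib$truth$gate_id)
  expect_gt(sd(tab$epsilon / lib$truth$epsilon[ord]), 0)
  ins <- generate_siso_library(tiny_catalogue(4, 4, "PROXIMAL"), "BUFFER",
                               phenotype_mix = c(1, 0, 0),
                               noise = noise_model(cv = 0, od_cv = 0,
                                                   utr_cv = 0.3,
                                                   insulated = TRUE),
                               seed = 31)
  ti <- fit_siso_table(process_plate(ins$plate)$wells)
  oi <- match(ti$gate_id, ins$truth$gate_id)
  expect_equal(ti$epsilon, ins$truth$epsilon[oi])
})
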