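worked_x <- list(epsilon = 0.05, sigma = 0.80)
worked_y <- list(epsilon = 0.10, sigma = 0.70)

test_that("alpha estimation matches the brute-force corner-equation oracle", {
  a <- estimate_alphas(worked_x, worked_y)
  expect_equal(unname(a), solve_corner_alphas(0.05, 0.80, 0.10, 0.70))
  expect_equal(unname(a), c(0.05, 0.05, 0.00, 0.70))
  set.seed(41)
  for (i in 1:30) {
    ex <- runif(1, 0, 0.2); sx <- runif(1, 0.1, 0.9)
    ey <- runif(1, 0, 0.2); sy <- runif(1, 0.1, 0.9)
    expect_equal(unname(estimate_alphas(list(epsilon = ex, sigma = sx),
                                        list(epsilon = ey, sigma = sy))),
                 solve_corner_alphas(ex, sx, ey, sy))
  }
})

test_that("identical members give the symmetric coefficient pattern", {
  a <- estimate_alphas(list(epsilon = 0.07, sigma = 0.6),
                       list(epsilon = 0.07, sigma = 0.6))
  expect_equal(unname(a), c(0.07, 0, 0, 0.6))
})

test_that("flat members produce a flagged nonpositive interaction term", {
  expect_warning(
    a <- estimate_alphas(list(epsilon = 0.05, sigma = 0),
                         list(epsilon = 0.12, sigma = 0)),
    "incompatible")
  expect_lte(a[["alpha3"]], 0)
})

test_that("the estimator strategy is pluggable", {
  multiplicative <- function(ex, sx, ey, sy) c(ex * ey, 0, 0, sx * sy)
  a <- estimate_alphas(worked_x, worked_y, estimator = multiplicative)
  expect_equal(unname(a), c(0.005, 0, 0, 0.56))
  expect_error(estimate_alphas(worked_x, worked_y, estimator = "nope"),
               "unknown alpha estimator")
})

test_that("AND truth table equals direct substitution of the worked example", {
  a <- estimate_alphas(worked_x, worked_y)
  tt <- predict_truth_table(a, "AND")
  expect_equal(tt$omega[match(c("IX=0;IY=0", "IX=1;IY=0", "IX=0;IY=1", "IX=1;IY=1"),
                              tt$condition)],
               c(0.05, 0.10, 0.05, 0.80))
  nor <- predict_truth_table(a, "NOR")
  expect_equal(nor$omega[match(c("IX=0;IY=0", "IX=1;IY=0", "IX=0;IY=1", "IX=1;IY=1"),
                               nor$condition)],
               c(0.80, 0.05, 0.10, 0.05))
  anb <- predict_truth_table(a, "A_NIMPLY_B")
  high <- anb$condition[which.max(anb$omega)]
  expect_equal(high, "IX=1;IY=0")
  expect_equal(max(anb$omega), 0.80)
})

test_that("duality and NIMPLY bridge identities hold for arbitrary alphas", {
  set.seed(43)
  flip <- function(tt) {  # lookup omega at inverted inputs
    function(ix, iy) tt$omega[tt$IX == ix & tt$IY == iy]
  }
  for (i in 1:25) {
    a <- c(alpha0 = runif(1, 0, .2), alpha1 = runif(1, 0, .3),
           alpha2 = runif(1, 0, .3), alpha3 = runif(1, 0, .8))
    and <- flip(predict_truth_table(a, "AND"))
    nor <- flip(predict_truth_table(a, "NOR"))
    anb <- flip(predict_truth_table(a, "A_NIMPLY_B"))
    bna <- flip(predict_truth_table(a, "B_NIMPLY_A"))
    for (ix in 0:1) for (iy in 0:1) {
      expect_identical(nor(ix, iy), and(1 - ix, 1 - iy))
      expect_identical(anb(ix, iy), and(ix, 1 - iy))
      expect_identical(bna(ix, iy), and(1 - ix, iy))
    }
  }
})

test_that("corner consistency: alpha0+alpha1+alpha2 = max leakiness", {
  set.seed(44)
  for (i in 1:25) {
    ex <- runif(1, 0, 0.3); ey <- runif(1, 0, 0.3)
    a <- estimate_alphas(list(epsilon = ex, sigma = runif(1, .3, .9)),
                         list(epsilon = ey, sigma = runif(1, .3, .9)))
    expect_equal(a[["alpha0"]] + a[["alpha1"]] + a[["alpha2"]], max(ex, ey))
    expect_gte(a[["alpha0"]], 0)
  }
})

test_that("each gate type has exactly one ON corner, the Boolean one", {
  boole <- list(AND = function(x, y) x & y,
                NOR = function(x, y) !(x | y),
                A_NIMPLY_B = function(x, y) x & !y,
                B_NIMPLY_A = function(x, y) !x & y)
  set.seed(45)
  for (i in 1:10) {
    x <- list(epsilon = runif(1, 0.01, 0.15), sigma = runif(1, 0.4, 0.9))
    y <- list(epsilon = runif(1, 0.01, 0.15), sigma = runif(1, 0.4, 0.9))
    a <- estimate_alphas(x, y)
    for (gt in names(boole)) {
      tt <- predict_truth_table(a, gt)
      expect_true(all(is.finite(tt$omega)) && all(tt$omega >= 0))
      expect_true(all(tt$omega >= min(x$epsilon, y$epsilon) - 1e-12))
      high <- tt$omega > max(x$epsilon, y$epsilon) + 1e-12
      expect_equal(sum(high), 1L)
      expect_true(boole[[gt]](tt$IX[high], tt$IY[high]))
    }
  }
})

test_that("miso_gate validates slot phenotypes and exposes model methods", {
  x <- siso_fit(jitter_reps(0.05), jitter_reps(0.85), "X")
  y <- siso_fit(jitter_reps(0.10), jitter_reps(0.80), "Y")
  g <- miso_gate(x, y, "AND", gate_id = "demo_and")
  expect_s3_class(g, "miso_gate")
  expect_named(coef(g), c("alpha0", "alpha1", "alpha2", "alpha3"))
  expect_equal(nrow(predict(g)), 4)
  expect_equal(predict(g, data.frame(IX = 1, IY = 1)),
               max(g$truth_table$omega))
  expect_error(predict(g, data.frame(IX = 0.5, IY = 1)), "binary")
  expect_error(miso_gate(x, y, "NOR"), "ANTIREPRESSOR")
  anti <- siso_fit(jitter_reps(0.80), jitter_reps(0.10), "XA")
  expect_silent(gn <- miso_gate(anti, anti, "NOR", gate_id = "demo_nor"))
  expect_equal(gn$truth_table$omega[gn$truth_table$condition == "IX=0;IY=0"],
               max(gn$truth_table$omega))
  expect_output(print(g), "ON corner")
  # residuals are log2 measured/predicted
  meas <- data.frame(condition = g$truth_table$condition,
                     mean_fluor = g$truth_table$omega * 2)
  expect_equal(unname(residuals(g, meas)), rep(1, 4))
})
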