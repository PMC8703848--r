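test_that("presets reproduce the printed class counts and ratios", {
  expected <- list(adenot = c(1282L, 310L, 4.1),
                   drugbank = c(2841L, 420L, 6.8),
                   li = c(267L, 133L, 2.0),
                   muehlbacher = c(327L, 35L, 9.3))
  for (nm in names(expected)) {
    cfg <- preset_config(nm, seed = 1)
    expect_equal(c(cfg$n_plus, cfg$n_minus), expected[[nm]][1:2])
  }
  # summary of a simulated preset reports the printed ratio
  s <- dataset_summary(simulate_dataset(preset_config("adenot", seed = 3)))
  expect_equal(c(s$n_plus, s$n_minus, s$ratio), c(1282, 310, 4.1))
})

test_that("largest-remainder rounding realizes a requested ratio", {
  cfg <- synthetic_config(n_total = 100, class_ratio = 3)
  expect_equal(c(cfg$n_plus, cfg$n_minus), c(75L, 25L))
  cfg2 <- synthetic_config(n_total = 101, class_ratio = 3)
  expect_equal(cfg2$n_plus + cfg2$n_minus, 101L)
  # realized ratio rounds back to the requested one at moderate n
  cfg3 <- synthetic_config(n_total = 1000, class_ratio = 4.1)
  expect_equal(round(cfg3$n_plus / cfg3$n_minus, 1), 4.1)
})

test_that("simulation is deterministic and respects invariants", {
  cfg <- synthetic_config(n_total = 300, seed = 17)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  expect_false(identical(
    as.data.frame(simulate_dataset(synthetic_config(n_total = 300, seed = 18))),
    as.data.frame(d1)))
  # hard-sphere truncation keeps geometry total
  expect_true(all(d1$ccs >= pi * nitrogen_gas()$kinetic_radius^2))
  expect_true(all(d1$psa >= 0) && all(d1$mw > 0))
  counts <- c("h_acceptors", "h_donors", "rotatable_bonds")
  for (d in counts) expect_true(all(d1[[d]] == round(d1[[d]]) & d1[[d]] >= 0))
})

test_that("group means are recovered within 3 standard errors", {
  n <- 20000
  ds <- simulate_dataset(synthetic_config(n_plus = n, n_minus = n, seed = 23))
  gm <- group_model()
  for (i in seq_len(nrow(gm$descriptors))) {
    row <- gm$descriptors[i, ]
    if (row$type != "normal" || row$descriptor == "mw") next
    for (side in c("plus", "minus")) {
      mu <- row[[paste0("mean_", side)]]
      sd_ <- row[[paste0("sd_", side)]]
      v <- ds[[row$descriptor]][ds$bbb_label ==
                                  if (side == "plus") "BBB_plus" else "BBB_minus"]
      expect_lt(abs(mean(v) - mu), 3 * sd_ / sqrt(n))
    }
  }
})

test_that("BBB+ CCS sample mean hits 174 within 3 SE at n = 1e5", {
  ds <- simulate_dataset(synthetic_config(n_plus = 1e5, n_minus = 10,
                                          seed = 29))
  m <- mean(ds$ccs[ds$bbb_label == "BBB_plus"])
  expect_lt(abs(m - 174), 3 * 25 / sqrt(1e5))   # +-0.237
})

test_that("CCS-MW rank correlation lands at the configured value", {
  ds <- simulate_dataset(synthetic_config(n_plus = 10000, n_minus = 10000,
                                          seed = 31))
  for (lab in c("BBB_plus", "BBB_minus")) {
    sub <- ds[ds$bbb_label == lab, ]
    rho <- cor(sub$ccs, sub$mw, method = "spearman")
    expect_lt(abs(rho - 0.85), 0.05)
  }
})

test_that("analytic accuracy: closed form matches quadrature and limits", {
  gm <- group_model()
  # independent quadrature oracle over the two Gaussians
  quad <- function(theta, ratio) {
    pp <- ratio / (1 + ratio)
    pp * stats::integrate(function(x) stats::dnorm(x, 174, 25),
                          -Inf, theta)$value +
      (1 - pp) * stats::integrate(function(x) stats::dnorm(x, 230, 40),
                                  theta, Inf)$value
  }
  expect_equal(analytic_accuracy(gm, 200, 4.1), quad(200, 4.1),
               tolerance = 1e-4)
  expect_equal(analytic_accuracy(gm, 150, 2.0), quad(150, 2.0),
               tolerance = 1e-4)
  # theta -> infinity: everything predicted positive
  expect_equal(analytic_accuracy(gm, 1e6, 4.1), 4.1 / 5.1, tolerance = 1e-12)
  # identical group laws: accuracy = p+ Phi(z) + p- (1 - Phi(z))
  same <- group_model(data.frame(
    descriptor = "ccs", mean_plus = 200, sd_plus = 30,
    mean_minus = 200, sd_minus = 30, type = "normal", min = -Inf,
    stringsAsFactors = FALSE), check_directions = FALSE)
  z <- (180 - 200) / 30
  expect_equal(analytic_accuracy(same, 180, 3),
               0.75 * pnorm(z) + 0.25 * (1 - pnorm(z)))
})

test_that("Monte-Carlo rule accuracy converges to the analytic oracle", {
  cfg <- synthetic_config(n_total = 20000, class_ratio = 4.1, seed = 37)
  ds <- simulate_dataset(cfg)
  acc_mc <- mean((ds$ccs < 200) == (ds$bbb_label == "BBB_plus"))
  acc_th <- analytic_accuracy(group_model(), 200, 4.1)
  se <- sqrt(acc_th * (1 - acc_th) / nrow(ds))
  expect_lt(abs(acc_mc - acc_th), 3 * se)
})

test_that("direction constraints and infeasible configs are rejected", {
  bad <- group_model()$descriptors
  bad$mean_plus[bad$descriptor == "ccs"] <- 300
  expect_error(group_model(bad), "direction constraint")
  expect_error(synthetic_config(n_total = 1), "at least 2")
  expect_error(synthetic_config(n_total = 10, class_ratio = -1), "positive")
})

test_that("real-SMILES mode emits parseable drug structures", {
  ds <- simulate_dataset(synthetic_config(n_total = 50, seed = 41,
                                          real_smiles = TRUE))
  expect_true(all(nchar(ds$smiles) > 5))
  expect_true(all(bbbccs:::.smiles_ok(ds$smiles)))
})
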