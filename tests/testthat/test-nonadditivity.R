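test_that("the cycle statistic is plain pActivity arithmetic", {
  expect_equal(nonadditivity_value(5, 6, 7, 6), 0)
  expect_equal(nonadditivity_value(5, 6, 6.5, 5), -0.5)
})

test_that("classification thresholds follow the noise model", {
  nm <- noise_model(0.5)
  expect_equal(nm$t_significant, 1.0)
  expect_equal(as.character(classify_cycles(c(0.9, 1.1, 2.5, -2.5), nm)),
               c("additive", "significant", "strong", "strong"))
  nm3 <- noise_model(0.3)
  expect_equal(nm3$t_significant, 0.6)
  expect_equal(as.character(classify_cycles(0.9, nm3)), "significant")
})

test_that("the theoretical noise density has sd equal to 2 sigma", {
  g <- seq(-4, 4, by = 0.01)
  d5 <- theoretical_noise_density(0.5, g)
  expect_equal(d5, dnorm(g, 0, 1))
  expect_equal(theoretical_noise_density(0.3, g), dnorm(g, 0, 0.6))
})

test_that("noise propagates to cycle variance 4 sigma^2 (Monte Carlo)", {
  set.seed(101)
  sigma <- 0.5
  e <- matrix(rnorm(4e5, 0, sigma), ncol = 4)
  na <- nonadditivity_value(e[, 1], e[, 2], e[, 3], e[, 4])
  expect_equal(sd(na), 2 * sigma, tolerance = 0.02)
})

test_that("a 2x2 block yields one cycle and a 2x3 block three", {
  lib22 <- enumerate_library(small_fw_spec())
  cyc22 <- assemble_cycles(index_pairs(fw_assay(lib22)))
  expect_equal(nrow(cyc22), 1L)
  lib23 <- enumerate_library(small_fw_spec(
    r2 = c("OC", "F", "N"), contrib2 = c(0.2, 0.1, -0.2)))
  cyc23 <- assemble_cycles(index_pairs(fw_assay(lib23)))
  expect_equal(nrow(cyc23), 3L)
  # and they match the designed ground truth as unordered quadruples
  truth <- true_cycles(lib23)
  expect_setequal(
    apply(cyc23[, c("c1", "c2", "c3", "c4")], 1,
          function(r) paste(sort(r), collapse = " ")),
    apply(truth[, c("c1", "c2", "c3", "c4")], 1,
          function(r) paste(sort(r), collapse = " ")))
})

test_that("cycle assembly equals exhaustive quadruple enumeration", {
  for (seed in 1:25) {
    pt <- random_pair_table(seed, n_compounds = 10L + seed %% 5L)
    got <- assemble_cycles(pt)
    expect_identical(cycles_as_keys(got), oracle_as_keys(oracle_cycles(pt)),
                     info = paste("seed", seed))
  }
})

test_that("additive Free-Wilson activities give exactly zero nonadditivity", {
  lib <- enumerate_library(small_fw_spec(
    r1 = c("C", "CC", "Cl"), r2 = c("OC", "F", "N"),
    contrib1 = c(0.4, -0.2, 0.7), contrib2 = c(0.2, 0.1, -0.5)))
  assay <- fw_assay(lib)
  cyc <- cycle_nonadditivity(assemble_cycles(index_pairs(assay)), assay)
  expect_equal(nrow(cyc), 9L)  # C(3,2)^2
  expect_true(all(abs(cyc$nonadditivity) < 1e-9))
})

test_that("an injected interaction is recovered exactly at sigma zero", {
  inj <- na_injection(c("R1", "R2"), c("C", "OC"), delta = 1.5)
  lib <- enumerate_library(small_fw_spec(), injections = list(inj))
  assay <- fw_assay(lib)
  cyc <- cycle_nonadditivity(assemble_cycles(index_pairs(assay)), assay)
  expect_equal(abs(cyc$nonadditivity), 1.5)
})

test_that("per-compound profiles aggregate shifts with null bands", {
  nm <- noise_model(0.5)
  cyc <- data.frame(c1 = "w", c2 = "x", c3 = "y", c4 = "z",
                    nonadditivity = -0.4)
  p <- compound_profiles(cyc, nm)
  expect_equal(p$mean_shift[p$compound_id == "y"], 0.4)
  expect_equal(p$ci_high, rep(1.96 * 1.0, 4))
  expect_false(any(p$significant))
  # four cycles of NA -1.2 through one compound: outside the band
  cyc4 <- data.frame(c1 = paste0("a", 1:4), c2 = paste0("b", 1:4),
                     c3 = "hot", c4 = paste0("d", 1:4),
                     nonadditivity = -1.2)
  p4 <- compound_profiles(cyc4, nm)
  hot <- p4[p4$compound_id == "hot", ]
  expect_equal(hot$n_cycles, 4L)
  expect_equal(hot$mean_shift, 1.2)
  expect_equal(hot$ci_high, 1.96 * 1.0 / 2)
  expect_true(hot$mean_shift > hot$ci_high)
  expect_true(hot$significant)
})

test_that("the interaction-carrying corner shows the largest mean shift", {
  inj <- na_injection(c("R1", "R2"), c("C", "OC"), delta = 2.0)
  lib <- enumerate_library(small_fw_spec(
    r1 = c("C", "CC", "Cl"), r2 = c("OC", "F", "N"),
    contrib1 = c(0.4, -0.2, 0.7), contrib2 = c(0.2, 0.1, -0.5)),
    injections = list(inj))
  assay <- fw_assay(lib)
  cyc <- cycle_nonadditivity(assemble_cycles(index_pairs(assay)), assay)
  prof <- compound_profiles(cyc, noise_model(0.5))
  top <- prof$compound_id[which.max(abs(prof$mean_shift))]
  expect_equal(top, lib$compound_id[lib$injected])
  # and its shift is positive: more potent than additivity predicts
  expect_gt(prof$mean_shift[prof$compound_id == top], 0)
})

test_that("assay summaries count classes consistently", {
  nm <- noise_model(0.5)
  lib <- enumerate_library(small_fw_spec(
    r1 = c("C", "CC", "Cl"), r2 = c("OC", "F", "N"),
    contrib1 = c(0.4, -0.2, 0.7), contrib2 = c(0.2, 0.1, -0.5)))
  assay <- fw_assay(lib)
  cyc <- cycle_nonadditivity(assemble_cycles(index_pairs(assay)), assay)
  s <- assay_summary(cyc, assay, nm)
  expect_equal(s$n_cycles, 9L)
  expect_equal(s$n_cycles_significant, 0L)
  expect_equal(s$n_compounds_significant, 0L)
  expect_true(s$n_cycles_strong <= s$n_cycles_significant)
  # empty cycle set: zero counts, flagged stats
  s0 <- assay_summary(cyc[0, ], assay, nm)
  expect_equal(s0$n_cycles, 0L)
  expect_true(is.na(s0$std))
})

test_that("pure-noise significant fraction matches the normal tail", {
  set.seed(77)
  e <- matrix(rnorm(2e5, 0, 0.5), ncol = 4)
  na <- nonadditivity_value(e[, 1], e[, 2], e[, 3], e[, 4])
  frac <- mean(abs(na) > 1.0)
  expect_equal(frac, 2 * pnorm(-1), tolerance = 0.05)
})

test_that("rank tests behave under identity, the null and a shift", {
  x <- c(1.2, -0.3, 0.8, 0.1, -1.1)
  same <- compare_distributions(x, x)
  expect_equal(same$mann_whitney_p, 1.0, tolerance = 1e-6)
  set.seed(11)
  rej <- replicate(60, {
    a <- rnorm(300); b <- rnorm(300)
    compare_distributions(a, b)$mann_whitney_p < 0.05
  })
  expect_lt(mean(rej), 0.15)
  pow <- replicate(30, {
    a <- rnorm(1000); b <- rnorm(1000, 0.5)
    compare_distributions(a, b)$mann_whitney_p < 0.05
  })
  expect_gt(mean(pow), 0.95)
  deg <- compare_distributions(rep(1, 5), rep(1, 5))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$mann_whitney_p))
})
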