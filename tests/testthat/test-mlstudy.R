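test_that("assay selection enforces the size and cycle criteria", {
  s <- data.frame(assay_id = c("small", "few_cycles", "ok", "no_na"),
                  n_compounds = c(150L, 300L, 400L, 500L),
                  n_cycles = c(80L, 10L, 120L, 0L))
  expect_equal(select_assays(s), "ok")
})

test_that("labels partition compounds and respect the DTC invariant", {
  fx <- ml_fixture(42)
  lab <- fx$lab
  expect_setequal(unique(lab$na_label),
                  c("additive", "nonadditive", "no_dtc"))
  expect_true(all(lab$in_dtc[lab$na_label == "nonadditive"]))
  expect_true(all(!lab$in_dtc[lab$na_label == "no_dtc"]))
  # labels derive from cycle membership at |NA| > 1
  sig <- abs(fx$res$cycles$nonadditivity) > 1
  flagged <- unique(unlist(fx$res$cycles[sig, c("c1", "c2", "c3", "c4")]))
  expect_setequal(lab$compound_id[lab$na_label == "nonadditive"], flagged)
})

test_that("dtc and all splits are stratified, disjoint and reproducible", {
  fx <- ml_fixture(42)
  for (strat in c("dtc", "all")) {
    sp <- make_split(fx$lab, strat, seed = 3)
    expect_length(intersect(sp$train$compound_id,
                            unlist(lapply(sp$tests, `[[`, "compound_id"))),
                  0L)
    pool <- rbind(sp$train, sp$tests$additive)
    expect_equal(nrow(sp$train) / nrow(pool), 0.8, tolerance = 0.02)
    # nonadditive hold-out is all significant compounds, never trained on
    expect_setequal(sp$tests$nonadditive$compound_id,
                    fx$lab$compound_id[fx$lab$na_label == "nonadditive"])
    sp2 <- make_split(fx$lab, strat, seed = 3)
    expect_identical(sp$train$compound_id, sp2$train$compound_id)
    sp3 <- make_split(fx$lab, strat, seed = 4)
    expect_false(identical(sp$train$compound_id, sp3$train$compound_id))
  }
  # stratification: train/test activity deciles stay balanced
  sp <- make_split(fx$lab, "dtc", seed = 3)
  qs <- quantile(c(sp$train$pact, sp$tests$additive$pact),
                 probs = c(0.25, 0.5, 0.75))
  for (q in qs) {
    expect_equal(mean(sp$train$pact <= q), mean(sp$tests$additive$pact <= q),
                 tolerance = 0.1)
  }
  # the all split adds non-DTC compounds to the pool
  sp_all <- make_split(fx$lab, "all", seed = 3)
  expect_gt(nrow(sp_all$train), nrow(sp$train))
})

test_that("the ab split trains on singly-transformed corners only", {
  lib <- enumerate_library(small_fw_spec(
    r1 = c("C", "CC", "Cl", "F", "N"), r2 = c("OC", "F", "N", "Cl", "O"),
    contrib1 = seq(-0.4, 0.4, length.out = 5),
    contrib2 = seq(0.4, -0.4, length.out = 5)))
  assay <- fw_assay(lib)
  cyc <- cycle_nonadditivity(assemble_cycles(index_pairs(assay)), assay)
  lab <- label_compounds(assay, cyc, threshold = 1.0)
  for (seed in c(4, 7)) {
    sp <- make_split(lab, "ab", cycles = cyc, seed = seed)
    expect_length(intersect(sp$train$compound_id,
                            unlist(lapply(sp$tests, `[[`, "compound_id"))),
                  0L)
    ab <- sp$tests$ab_additive$compound_id
    expect_gt(length(ab), 0L)
    # every AB test compound has A and B neighbours in training
    for (cid in ab) {
      rows <- cyc[cyc$c3 == cid, , drop = FALSE]
      ok <- any(rows$c2 %in% sp$train$compound_id &
                  rows$c4 %in% sp$train$compound_id)
      expect_true(ok, info = cid)
    }
  }
  # different seeds start from different cycles
  s4 <- make_split(lab, "ab", cycles = cyc, seed = 4)
  s7 <- make_split(lab, "ab", cycles = cyc, seed = 7)
  expect_false(identical(sort(s4$tests$ab_additive$compound_id),
                         sort(s7$tests$ab_additive$compound_id)))
})

test_that("evaluation metrics satisfy their defining identities", {
  y <- c(4, 4.5, 5.5, 6, 4.8, 5.2)
  expect_equal(dtcna:::.r2(y, y), 1)
  expect_equal(dtcna:::.rmse(y, y), 0)
  expect_equal(dtcna:::.r2(y, rep(mean(y), length(y))), 0)
  truth <- c(0, 0, 1, 1, 0, 1)
  expect_equal(mcc(truth, truth), 1)
  expect_equal(mcc(truth, 1 - truth), -1)
  expect_true(is.na(mcc(truth, rep(1, 6))))
})

test_that("model training learns a noiseless linear response", {
  set.seed(2)
  x <- matrix(rpois(80 * 12, 2), 80, 12)
  colnames(x) <- paste0("fp", 1:12)
  y <- 5 + 0.8 * x[, 1] - 0.3 * x[, 2]
  m <- train_model(x, y, "pls", n_trials = 4L, seed = 1)
  expect_gt(m$cv_r2, 0.99)
  expect_equal(as.numeric(predict(m, x)), y, tolerance = 1e-6)
  expect_error(train_model(x, rep(1, 80), "pls"), "zero variance")
})

test_that("pure-noise responses give non-positive cross-validated R2", {
  set.seed(4)
  r2s <- replicate(5, {
    x <- matrix(rpois(60 * 10, 2), 60, 10)
    colnames(x) <- paste0("fp", 1:10)
    m <- train_model(x, rnorm(60), "pls", n_trials = 2L, seed = 8)
    m$cv_r2
  })
  expect_lt(mean(r2s), 0.05)
})

test_that("mixin draws are nested with a fraction-independent hold-out", {
  fx <- ml_fixture(42)
  pool <- fx$lab[fx$lab$na_label == "nonadditive", ]
  mx1 <- mixin_draws(pool, train_size = 250L, seed = 5)
  mx2 <- mixin_draws(pool, train_size = 250L, seed = 5)
  expect_identical(mx1, mx2)
  expect_equal(lengths(mx1$draws)[["0"]], 0L)
  expect_equal(length(mx1$draws[["0.026"]]), round(0.026 * 250))
  expect_true(all(mx1$draws[["0.006"]] %in% mx1$draws[["0.013"]]))
  expect_true(all(mx1$draws[["0.013"]] %in% mx1$draws[["0.026"]]))
  expect_length(intersect(mx1$holdout$compound_id,
                          unlist(mx1$draws)), 0L)
  expect_error(mixin_draws(pool[1:3, ], train_size = 250L),
               "pool too small")
})
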