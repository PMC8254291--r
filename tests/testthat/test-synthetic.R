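test_that("library enumeration produces valid, additive ground truth", {
  spec <- small_fw_spec()
  lib <- enumerate_library(spec)
  expect_equal(nrow(lib), 4L)
  expect_false(any(is.na(canonical_smiles(lib$smiles))))
  expect_equal(lib$true_pact,
               5 + c(0.5 + 0.2, -0.3 + 0.2, 0.5 + 0.1, -0.3 + 0.1))
  expect_false(any(lib$injected))
  tc <- true_cycles(lib)
  expect_equal(nrow(tc), 1L)
  expect_equal(tc$na_true, 0)
})

test_that("an injection makes exactly the corner-containing cycles nonzero", {
  spec <- small_fw_spec(r1 = c("C", "CC", "Cl"), r2 = c("OC", "F", "N"),
                        contrib1 = c(0.1, 0.2, 0.3),
                        contrib2 = c(0, -0.1, 0.4))
  inj <- na_injection(c("R1", "R2"), c("CC", "F"), delta = 1.5)
  lib <- enumerate_library(spec, list(inj))
  tc <- true_cycles(lib)
  expect_equal(nrow(tc), 9L)
  corner <- lib$compound_id[lib$injected]
  expect_length(corner, 1L)
  touches <- apply(tc[, c("c1", "c2", "c3", "c4")], 1,
                   function(r) corner %in% r)
  expect_equal(sum(touches), 4L)  # (3-1) * (3-1) cycles through the corner
  expect_equal(abs(tc$na_true[touches]), rep(1.5, 4))
  expect_equal(tc$na_true[!touches], rep(0, 5))
})

test_that("invalid substituent chemistry aborts naming the combination", {
  spec <- small_fw_spec(r1 = c("C", "XX"), contrib1 = c(0, 0))
  expect_error(enumerate_library(spec), "invalid chemistry")
})

test_that("noise-free measurement round-trips pActivities exactly", {
  lib <- enumerate_library(small_fw_spec())
  rec <- measure(lib, measurement_spec(sigma = 0, seed = 3))
  expect_equal(to_pactivity(rec$value, rec$unit),
               lib$true_pact[match(rec$compound_id, lib$compound_id)],
               tolerance = 1e-9)
})

test_that("the measurement stream is deterministic given the seed", {
  lib <- enumerate_library(small_fw_spec())
  ms <- measurement_spec(sigma = 0.5, n_replicates = 3L,
                         qualified_fraction = 0.2,
                         duplicate_id_fraction = 0.5, seed = 9)
  expect_identical(measure(lib, ms), measure(lib, ms))
})

test_that("measurement noise has the configured magnitude", {
  spec <- small_fw_spec()
  lib <- enumerate_library(spec)
  rec <- measure(lib, measurement_spec(sigma = 0.5, n_replicates = 2500L,
                                       seed = 5))
  obs <- to_pactivity(rec$value, rec$unit) -
    lib$true_pact[match(rec$compound_id, lib$compound_id)]
  expect_equal(sd(obs), 0.5, tolerance = 0.02)
})

test_that("qualified and duplicate-ID records exercise the curation steps", {
  lib <- enumerate_library(small_fw_spec(
    r1 = c("C", "CC", "Cl", "F", "N"), r2 = c("OC", "F", "N", "Cl", "O"),
    contrib1 = seq(-0.4, 0.4, length.out = 5),
    contrib2 = seq(0.4, -0.4, length.out = 5)))
  rec <- measure(lib, measurement_spec(sigma = 0, qualified_fraction = 0.2,
                                       duplicate_id_fraction = 0.2,
                                       seed = 4))
  expect_equal(mean(rec$qualifier != "="), 0.2, tolerance = 0.05)
  expect_equal(sum(grepl("_dup$", rec$compound_id)), 5L)
  cu <- curate_assay(rec, curation_config(min_assay_size = 5L))
  # duplicate IDs collapse onto unique structures
  expect_lte(nrow(cu$assay), nrow(lib))
  expect_false(any(duplicated(cu$assay$smiles)))
  step2 <- cu$report[cu$report$step == "qualified_or_missing", ]
  expect_equal(step2$records_in - step2$records_out,
               sum(rec$qualifier != "="))
  step6 <- cu$report[cu$report$step == "duplicate_structure", ]
  expect_gte(step6$records_in - step6$records_out, 1L)
})

test_that("the pipeline recovers the designed cycle set at sigma zero", {
  for (seed in c(2, 6)) {
    sim <- simulate_assay(seed = seed, n_series = 3L, occupancy = 0.7,
                          sigma = 0, cycle_na_fraction = 0)
    cu <- curate_assay(sim$records, curation_config(min_assay_size = 5L))
    pairs <- index_pairs(cu$assay)
    cyc <- cycle_nonadditivity(assemble_cycles(pairs), cu$assay)
    truth_keys <- apply(sim$truth_cycles[, c("c1", "c2", "c3", "c4")], 1,
                        function(r) paste(sort(r), collapse = " "))
    got_keys <- apply(cyc[, c("c1", "c2", "c3", "c4")], 1,
                      function(r) paste(sort(r), collapse = " "))
    expect_setequal(got_keys, truth_keys)
    expect_true(all(abs(cyc$nonadditivity) < 1e-9))
  }
})

test_that("the full synthetic assay meets its design conditions", {
  fx <- ml_fixture(42)
  expect_gte(nrow(fx$sim$library), 400L)
  expect_gte(nrow(fx$sim$truth_cycles), 100L)
  inj_frac <- sum(fx$sim$injections$n_cycles_hit) /
    nrow(fx$sim$truth_cycles)
  expect_equal(inj_frac, 0.10, tolerance = 0.035)
  a <- abs(fx$sim$truth_cycles$na_true)
  expect_true(all(a < 1e-9 | abs(a - 2) < 1e-9))
})
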