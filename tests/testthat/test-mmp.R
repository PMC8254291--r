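test_that("fragmentation enumerates exactly the single acyclic bonds", {
  eth <- fragment("CC")
  expect_equal(nrow(eth), 1L)              # symmetric cut collapses
  expect_identical(eth$context, eth$variable)
  expect_equal(nrow(fragment("c1ccccc1")), 0L)  # no acyclic single bond
  # propane: two cuts, orientations give methyl/ethyl both ways
  pro <- fragment("CCC")
  expect_setequal(pro$variable_heavy, c(1L, 2L))
  # heavy-atom bookkeeping: context + variable == parent
  tol <- fragment("Cc1ccccc1")
  expect_true(all(tol$context_heavy + tol$variable_heavy ==
                    tol$parent_heavy))
})

test_that("contexts from different molecules collide on canonical keys", {
  t1 <- fragment("Cc1ccccc1")        # toluene
  t2 <- fragment("CCc1ccccc1")       # ethylbenzene
  shared <- intersect(t1$context, t2$context)
  expect_true(length(shared) >= 1L)  # the phenyl context
  ph <- grep("c1ccccc1|c1ccc\\(cc1\\)", shared, value = TRUE)
  expect_true(length(ph) >= 1L)
})

test_that("pair indexing matches a brute-force pairwise fragment scan", {
  lib <- enumerate_library(small_fw_spec(r1 = c("C", "CC", "Cl"),
                                         r2 = c("OC", "F", "N"),
                                         contrib1 = c(0.1, 0.2, 0.3),
                                         contrib2 = c(0, -0.1, 0.4)))
  assay <- fw_assay(lib)
  got <- index_pairs(assay)
  # oracle: per-molecule fragment() tables, then naive quadratic matching
  frs <- lapply(assay$smiles, fragment)
  ha <- heavy_atoms(assay$smiles)
  expected <- 0L
  for (i in seq_len(nrow(assay) - 1L)) {
    for (j in (i + 1L):nrow(assay)) {
      fi <- frs[[i]]; fj <- frs[[j]]
      fi <- fi[fi$variable_heavy * 3 <= ha[i], ]
      fj <- fj[fj$variable_heavy * 3 <= ha[j], ]
      shared <- intersect(fi$context, fj$context)
      hit <- FALSE
      for (ctx in shared) {
        va <- fi$variable[fi$context == ctx]
        vb <- fj$variable[fj$context == ctx]
        if (any(outer(va, vb, "!="))) hit <- TRUE
      }
      if (hit) expected <- expected + 1L
    }
  }
  # one pair row per (pair, context); count distinct unordered pairs
  upair <- paste(pmin(got$compound_a, got$compound_b),
                 pmax(got$compound_a, got$compound_b))
  expect_equal(length(unique(upair)), expected)
})

test_that("pair indexing is invariant under compound input order", {
  lib <- enumerate_library(small_fw_spec())
  assay <- fw_assay(lib)
  p1 <- index_pairs(assay)
  p2 <- index_pairs(assay[rev(seq_len(nrow(assay))), ])
  key <- function(p) sort(paste(p$compound_a, p$compound_b, p$context,
                                p$var_from, p$var_to))
  expect_identical(key(p1), key(p2))
})

test_that("the transformation-size rule bounds both molecules of a pair", {
  lib <- enumerate_library(small_fw_spec())
  assay <- fw_assay(lib)
  got <- index_pairs(assay)
  frs <- dtcna:::.fragment_table(assay$smiles, assay$compound_id)
  ha <- stats::setNames(heavy_atoms(assay$smiles), assay$compound_id)
  for (r in seq_len(nrow(got))) {
    for (side in c("compound_a", "compound_b")) {
      cid <- got[[side]][r]
      v <- frs$variable_heavy[frs$id == cid & frs$context == got$context[r]]
      expect_true(all(v * 3 <= ha[cid]) || length(v) == 0L)
    }
  }
  # and the amide-bond cuts (half the molecule) never form pairs
  expect_true(all(nchar(got$var_from) < 10))
})
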