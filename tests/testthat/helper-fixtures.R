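# Shared fixtures and independent oracles for the test suite. Expensive
# objects (the simulated ML assay and its analysis) are memoized so several
# test files can share one computation.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# minimal two-site Free-Wilson block on the default scaffold family
small_fw_spec <- function(r1 = c("C", "Cl"), r2 = c("OC", "F"),
                          contrib1 = c(0.5, -0.3), contrib2 = c(0.2, 0.1),
                          baseline = 5) {
  free_wilson_spec(
    "c1cc({R1})ccc1C(=O)Nc1ccc({R2})cc1",
    list(R1 = data.frame(sub = r1, contribution = contrib1),
         R2 = data.frame(sub = r2, contribution = contrib2)),
    baseline = baseline)
}

fw_assay <- function(lib) {
  data.frame(compound_id = lib$compound_id, smiles = lib$smiles,
             pact = lib$true_pact, stringsAsFactors = FALSE)
}

# full synthetic ML assay, curated and analysed; cached per seed
ml_fixture <- function(seed) {
  memo(paste0("ml_", seed), {
    sim <- simulate_assay(seed = seed)
    cu <- curate_assay(sim$records)
    res <- nonadditivity_analysis(cu$assay, noise_model(0.3),
                                  assay_id = "synthetic")
    lab <- label_compounds(cu$assay, res$cycles, threshold = 1.0)
    fp <- ecfp_counts(stats::setNames(lab$smiles, lab$compound_id))
    list(sim = sim, assay = cu$assay, res = res, lab = lab, fp = fp)
  })
}

fp_rows <- function(fx, ids) {
  fx$fp[match(ids, rownames(fx$fp)), , drop = FALSE]
}

# ---- independent cycle oracle ----------------------------------------------
# Exhaustive enumeration over compound quadruples: for every ordered
# (c1, c2, c3, c4) check that edges c1->c2 / c4->c3 share a transformation
# and c1->c4 / c2->c3 share another, then canonicalize and deduplicate.
# Mechanically unrelated to assemble_cycles' edge-pair grouping.
oracle_cycles <- function(pairs) {
  edges <- unique(data.frame(from = pairs$compound_a, to = pairs$compound_b,
                             tf = pairs$var_from, tt = pairs$var_to,
                             stringsAsFactors = FALSE))
  edges$trans <- paste(edges$tf, edges$tt, sep = ">>")
  emap <- split(edges$trans, paste(edges$from, edges$to))
  outn <- lapply(split(edges$to, edges$from), unique)
  cpds <- names(outn)
  recs <- list()
  for (c1 in cpds) {
    for (c2 in outn[[c1]]) for (c4 in outn[[c1]]) {
      if (c2 == c4) next
      o2 <- emap[[paste(c1, c2)]]
      o4 <- emap[[paste(c1, c4)]]
      n2 <- outn[[c2]]; n4 <- outn[[c4]]
      if (is.null(n2) || is.null(n4)) next
      for (c3 in intersect(n2, n4)) {
        if (c3 == c1) next
        tA <- intersect(o2, emap[[paste(c4, c3)]])
        tB <- intersect(o4, emap[[paste(c2, c3)]])
        for (a in tA) for (b in tB) {
          rec <- if (a < b) c(c1, c2, c3, c4, a, b)
          else if (b < a) c(c1, c4, c3, c2, b, a)
          else if (c4 < c2) c(c1, c4, c3, c2, a, b)
          else c(c1, c2, c3, c4, a, b)
          recs[[paste(rec, collapse = "\r")]] <- rec
        }
      }
    }
  }
  if (!length(recs)) {
    return(data.frame(c1 = character(0), c2 = character(0),
                      c3 = character(0), c4 = character(0),
                      trans_a = character(0), trans_b = character(0)))
  }
  m <- do.call(rbind, recs)
  res <- data.frame(c1 = m[, 1], c2 = m[, 2], c3 = m[, 3], c4 = m[, 4],
                    trans_a = m[, 5], trans_b = m[, 6],
                    stringsAsFactors = FALSE)
  res <- res[order(res$c1, res$c2, res$c3, res$c4), , drop = FALSE]
  rownames(res) <- NULL
  res
}

cycles_as_keys <- function(cycles) {
  sort(paste(cycles$c1, cycles$c2, cycles$c3, cycles$c4,
             paste(cycles$trans_a_from, cycles$trans_a_to, sep = ">>"),
             paste(cycles$trans_b_from, cycles$trans_b_to, sep = ">>")))
}

oracle_as_keys <- function(orc) {
  sort(paste(orc$c1, orc$c2, orc$c3, orc$c4, orc$trans_a, orc$trans_b))
}

# abstract random pair tables: compounds share random fragmentation
# contexts with variables drawn from a small alphabet
random_pair_table <- function(seed, n_compounds = 12L, n_contexts = 4L,
                              n_vars = 4L) {
  set.seed(seed)
  cpds <- sprintf("c%02d", seq_len(n_compounds))
  vars <- sprintf("v%d", seq_len(n_vars))
  rows <- list()
  for (ctx in seq_len(n_contexts)) {
    members <- cpds[stats::runif(n_compounds) < 0.6]
    if (length(members) < 2L) next
    assigned <- sample(vars, length(members), replace = TRUE)
    for (i in seq_len(length(members) - 1L)) {
      for (j in (i + 1L):length(members)) {
        if (assigned[i] == assigned[j]) next
        if (assigned[i] < assigned[j]) {
          rows[[length(rows) + 1L]] <- data.frame(
            compound_a = members[i], compound_b = members[j],
            context = paste0("ctx", ctx),
            var_from = assigned[i], var_to = assigned[j])
        } else {
          rows[[length(rows) + 1L]] <- data.frame(
            compound_a = members[j], compound_b = members[i],
            context = paste0("ctx", ctx),
            var_from = assigned[j], var_to = assigned[i])
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(compound_a = character(0), compound_b = character(0),
                      context = character(0), var_from = character(0),
                      var_to = character(0)))
  }
  unique(do.call(rbind, rows))
}
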