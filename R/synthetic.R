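# Synthetic SAR libraries with known additive structure. A library is a
# combinatorial R-group enumeration on a common scaffold; activities follow
# a Free-Wilson model (baseline + independent per-substituent
# contributions) plus optional pairwise interaction terms that inject
# nonadditivity of known magnitude, plus i.i.d. Gaussian measurement noise.

# evaluate expr under a seed without disturbing the caller's RNG stream
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Define a Free-Wilson synthetic library
#'
#' @param scaffold SMILES template containing one `{R...}` placeholder per
#'   substitution site, each written as a branch such as `c1cc({R1})ccc1`.
#'   The placeholder `[H]` for a substituent removes the branch.
#' @param sites named list (names matching the placeholders); each element
#'   is a data frame with columns `sub` (branch SMILES) and `contribution`
#'   (additive pActivity contribution, log units).
#' @param baseline baseline pActivity of the unsubstituted series
#'   (log units).
#' @return object of class `free_wilson_spec`.
#' @export
free_wilson_spec <- function(scaffold, sites, baseline = 5) {
  stopifnot(length(sites) >= 2L, !is.null(names(sites)),
            all(vapply(sites, nrow, 0L) >= 2L))
  for (nm in names(sites)) {
    stopifnot(all(c("sub", "contribution") %in% names(sites[[nm]])),
              grepl(paste0("{", nm, "}"), scaffold, fixed = TRUE))
  }
  structure(list(scaffold = scaffold, sites = sites, baseline = baseline),
            class = "free_wilson_spec")
}

#' Declare a pairwise nonadditivity injection
#'
#' When both named substituents co-occur, `delta` log units are added to
#' the molecule's true pActivity, making every cycle through that corner
#' nonadditive by exactly `delta`.
#'
#' @param site_pair character vector of two site names.
#' @param substituent_pair character vector of the two branch SMILES.
#' @param delta interaction term in log units (nonzero).
#' @return object of class `na_injection`.
#' @export
na_injection <- function(site_pair, substituent_pair, delta) {
  stopifnot(length(site_pair) == 2L, length(substituent_pair) == 2L,
            delta != 0)
  structure(list(site_pair = site_pair,
                 substituent_pair = substituent_pair, delta = delta),
            class = "na_injection")
}

.build_smiles <- function(scaffold, subs) {
  s <- scaffold
  for (nm in names(subs)) {
    ph <- paste0("{", nm, "}")
    s <- if (identical(subs[[nm]], "[H]")) {
      sub(paste0("(", ph, ")"), "", s, fixed = TRUE)
    } else {
      sub(ph, subs[[nm]], s, fixed = TRUE)
    }
  }
  s
}

#' Enumerate a Free-Wilson library with ground truth
#'
#' @param spec a [free_wilson_spec()].
#' @param injections list of [na_injection()] objects.
#' @param id_prefix prefix for generated compound IDs.
#' @param cells optional integer matrix (one row per kept combination, one
#'   column per site, values indexing each site's substituent table) to
#'   enumerate a sparse subset instead of the full grid.
#' @return data frame with `compound_id`, `smiles`, `true_pact`, `injected`
#'   (TRUE when any interaction term applies), and one index column per
#'   site (`<site>_idx`). All structures are validated; enumeration aborts
#'   naming the offending combination if one fails to parse.
#' @export
enumerate_library <- function(spec, injections = list(), id_prefix = "FW",
                              cells = NULL) {
  stopifnot(inherits(spec, "free_wilson_spec"))
  site_names <- names(spec$sites)
  sizes <- vapply(spec$sites, nrow, 0L)
  if (is.null(cells)) {
    cells <- as.matrix(expand.grid(lapply(sizes, seq_len)))
    colnames(cells) <- site_names
  }
  n <- nrow(cells)
  subs <- lapply(seq_len(n), function(i) {
    stats::setNames(
      lapply(seq_along(site_names), function(k)
        spec$sites[[k]]$sub[cells[i, k]]),
      site_names)
  })
  smiles <- vapply(subs, function(s) .build_smiles(spec$scaffold, s), "")
  pact <- spec$baseline + rowSums(vapply(seq_along(site_names), function(k)
    spec$sites[[k]]$contribution[cells[, k]], numeric(n)))
  injected <- logical(n)
  for (inj in injections) {
    hit <- rep(TRUE, n)
    for (q in 1:2) {
      k <- match(inj$site_pair[q], site_names)
      hit <- hit & spec$sites[[k]]$sub[cells[, k]] == inj$substituent_pair[q]
    }
    pact[hit] <- pact[hit] + inj$delta
    injected <- injected | hit
  }
  can <- canonical_smiles(smiles)
  if (anyNA(can)) {
    i <- which(is.na(can))[1L]
    stop("invalid chemistry for combination ",
         paste(vapply(subs[[i]], identity, ""), collapse = " + "),
         " on scaffold ", spec$scaffold)
  }
  out <- data.frame(compound_id = sprintf("%s_%03d", id_prefix, seq_len(n)),
                    smiles = smiles, true_pact = pact, injected = injected,
                    stringsAsFactors = FALSE)
  for (k in seq_along(site_names))
    out[[paste0(site_names[k], "_idx")]] <- cells[, k]
  out
}

#' Ground-truth cycles of a two-site library
#'
#' Enumerates every complete 2x2 sub-block of the (possibly sparse)
#' substituent grid — exactly the double-transformation cycles a correct
#' pipeline should recover — and computes each block's true nonadditivity
#' from the true pActivities.
#'
#' @param lib data frame from [enumerate_library()] (two-site).
#' @param site_names names of the two sites (defaults to the library's
#'   index columns).
#' @return data frame `c1`, `c2`, `c3`, `c4`, `na_true` with c1 and c3 on
#'   the doubly-transformed diagonal.
#' @export
true_cycles <- function(lib, site_names = NULL) {
  idx_cols <- grep("_idx$", names(lib), value = TRUE)
  if (!is.null(site_names)) idx_cols <- paste0(site_names, "_idx")
  stopifnot(length(idx_cols) == 2L)
  i1 <- lib[[idx_cols[1L]]]; i2 <- lib[[idx_cols[2L]]]
  id <- lib$compound_id; p <- lib$true_pact
  key <- paste(i1, i2)
  pos <- stats::setNames(seq_along(key), key)
  out <- list()
  for (a in sort(unique(i1))) for (b in sort(unique(i1))) {
    if (b <= a) next
    for (x in sort(unique(i2))) for (y in sort(unique(i2))) {
      if (y <= x) next
      q <- pos[paste(c(a, b, b, a), c(x, x, y, y))]
      if (anyNA(q)) next
      out[[length(out) + 1L]] <- data.frame(
        c1 = id[q[1L]], c2 = id[q[2L]], c3 = id[q[3L]], c4 = id[q[4L]],
        na_true = (p[q[2L]] - p[q[1L]]) - (p[q[3L]] - p[q[4L]]))
    }
  }
  if (!length(out))
    return(data.frame(c1 = character(0), c2 = character(0),
                      c3 = character(0), c4 = character(0),
                      na_true = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Measurement specification for synthetic assays
#'
#' @param sigma per-measurement Gaussian noise sd in log units (0.3
#'   emulates homogeneous in-house data, 0.5 heterogeneous public data).
#' @param n_replicates measurements per compound (integer, or a function
#'   `function(n)` returning one integer per compound).
#' @param units concentration units to sample raw values in.
#' @param qualified_fraction fraction of records marked with a `<` or `>`
#'   qualifier.
#' @param duplicate_id_fraction fraction of compounds re-emitted under a
#'   second compound ID with a fresh measurement.
#' @param seed RNG seed; the record stream is deterministic given the seed.
#' @return object of class `measurement_spec`.
#' @export
measurement_spec <- function(sigma = 0.5, n_replicates = 1L,
                             units = c("uM", "nM"),
                             qualified_fraction = 0,
                             duplicate_id_fraction = 0, seed = 1L) {
  stopifnot(sigma >= 0, qualified_fraction >= 0, qualified_fraction <= 1,
            duplicate_id_fraction >= 0, duplicate_id_fraction <= 1)
  structure(list(sigma = sigma, n_replicates = n_replicates, units = units,
                 qualified_fraction = qualified_fraction,
                 duplicate_id_fraction = duplicate_id_fraction,
                 seed = seed),
            class = "measurement_spec")
}

#' Simulate raw activity records for a library
#'
#' Draws replicate measurements `N(true_pact, sigma^2)` per molecule,
#' back-converts them to concentrations in sampled units, and optionally
#' injects qualified records and duplicate compound IDs to exercise the
#' curation filters.
#'
#' @param lib data frame from [enumerate_library()].
#' @param mspec a [measurement_spec()].
#' @param assay_id assay label attached to every record.
#' @return data frame in the raw record schema (`compound_id`, `smiles`,
#'   `assay_id`, `value`, `unit`, `qualifier`).
#' @export
measure <- function(lib, mspec = measurement_spec(), assay_id = "synthetic") {
  .with_seed(mspec$seed, {
    n <- nrow(lib)
    reps <- if (is.function(mspec$n_replicates))
      mspec$n_replicates(n) else rep(as.integer(mspec$n_replicates), n)
    idx <- rep(seq_len(n), reps)
    pact <- lib$true_pact[idx] + stats::rnorm(length(idx), 0, mspec$sigma)
    unit <- sample(mspec$units, length(idx), replace = TRUE)
    value <- 10^(-pact) / .unit_factor[unit]
    rec <- data.frame(compound_id = lib$compound_id[idx],
                      smiles = lib$smiles[idx], assay_id = assay_id,
                      value = unname(value), unit = unit, qualifier = "=",
                      stringsAsFactors = FALSE)
    if (mspec$duplicate_id_fraction > 0) {
      k <- round(mspec$duplicate_id_fraction * n)
      if (k > 0) {
        pick <- sample(n, k)
        extra_p <- lib$true_pact[pick] + stats::rnorm(k, 0, mspec$sigma)
        extra_u <- sample(mspec$units, k, replace = TRUE)
        rec <- rbind(rec, data.frame(
          compound_id = paste0(lib$compound_id[pick], "_dup"),
          smiles = lib$smiles[pick], assay_id = assay_id,
          value = unname(10^(-extra_p) / .unit_factor[extra_u]),
          unit = extra_u, qualifier = "=", stringsAsFactors = FALSE))
      }
    }
    if (mspec$qualified_fraction > 0) {
      k <- round(mspec$qualified_fraction * nrow(rec))
      if (k > 0) {
        pick <- sample(nrow(rec), k)
        rec$qualifier[pick] <- sample(c("<", ">"), k, replace = TRUE)
      }
    }
    rownames(rec) <- NULL
    rec
  })
}

# ---- default scaffolds and alphabets ---------------------------------------

# amide-linked diaryl scaffold family; the 5 x 5 aromatic C->N ring-isomer
# patterns are chosen from distinct mirror-symmetry classes of the ring
# (no two templates are the same molecule written in opposite traversal),
# giving 25 distinct series that cannot form cross-series matched pairs
# under single acyclic-bond cuts
.a_cores <- c("c1cc({R1})ccc1", "c1cc({R1})cnc1", "c1nc({R1})ccc1",
              "n1cc({R1})cnc1", "c1nc({R1})ncc1")
.b_cores <- c("c1ccc({R2})cc1", "c1ncc({R2})cc1", "c1cnc({R2})cc1",
              "c1ncc({R2})cn1", "c1cnc({R2})nc1")
.site1_alphabet <- c("C", "CC", "OC", "F", "Cl", "N")
.site2_alphabet <- c("C", "CC", "OC", "Cl", "O", "C#N")

#' Scaffold templates of the default synthetic series
#'
#' @param n number of templates (up to 25).
#' @return character vector of scaffold SMILES templates with `{R1}` and
#'   `{R2}` placeholders.
#' @export
default_scaffolds <- function(n = 25L) {
  all <- as.vector(outer(.a_cores, .b_cores, function(a, b)
    paste0(a, "C(=O)N", b)))
  stopifnot(n <= length(all))
  all[seq_len(n)]
}

#' Simulate a complete synthetic assay with injected nonadditivity
#'
#' Builds a multi-series assay: each series is a two-site Free-Wilson
#' library on its own scaffold with substituent contributions drawn once
#' per series, a sparse occupancy grid (so compounds participate in few
#' cycles, as in public SAR data), and pairwise interaction terms injected
#' at present grid corners until approximately `cycle_na_fraction` of all
#' designed cycles are nonadditive by `delta` log units.
#'
#' @param seed RNG seed controlling every random choice.
#' @param n_series number of scaffold series (max 25).
#' @param n_sub substituents per site (max 6).
#' @param occupancy probability that a grid cell is synthesized.
#' @param delta injected interaction magnitude (log units).
#' @param cycle_na_fraction target fraction of designed cycles made
#'   nonadditive.
#' @param sigma measurement noise sd (log units).
#' @param baseline_mean,baseline_sd distribution of per-series baseline
#'   pActivities.
#' @param contribution_range global per-substituent contributions are
#'   drawn uniformly from this interval (log units); a substituent's
#'   effect is consistent across series, as in real SAR.
#' @param contribution_sd_series sd of the per-series deviation added to
#'   each global substituent contribution (log units).
#' @param mspec optional [measurement_spec()]; its `sigma` and `seed` are
#'   overridden by `sigma` and `seed`.
#' @return list with `library` (with `series` column), `records` (raw
#'   measurements), `truth_cycles` (designed cycles with true
#'   nonadditivity), `injections` (data frame of injected corners) and
#'   `injected_compounds` (IDs of interaction-carrying corner compounds).
#' @export
simulate_assay <- function(seed = 1L, n_series = 25L, n_sub = 6L,
                           occupancy = 0.5, delta = 2.0,
                           cycle_na_fraction = 0.10, sigma = 0.3,
                           baseline_mean = 4.8, baseline_sd = 0.3,
                           contribution_range = c(-0.8, 0.8),
                           contribution_sd_series = 0.1,
                           mspec = NULL) {
  stopifnot(n_sub >= 2L, n_sub <= 6L)
  scaffolds <- default_scaffolds(n_series)
  built <- .with_seed(seed, {
    libs <- list(); truths <- list(); inj_rows <- list()
    glob1 <- stats::runif(n_sub, contribution_range[1],
                          contribution_range[2])
    glob2 <- stats::runif(n_sub, contribution_range[1],
                          contribution_range[2])
    for (s in seq_len(n_series)) {
      sites <- list(
        R1 = data.frame(sub = .site1_alphabet[seq_len(n_sub)],
                        contribution = glob1 +
                          stats::rnorm(n_sub, 0, contribution_sd_series)),
        R2 = data.frame(sub = .site2_alphabet[seq_len(n_sub)],
                        contribution = glob2 +
                          stats::rnorm(n_sub, 0, contribution_sd_series)))
      spec <- free_wilson_spec(scaffolds[s], sites,
                               baseline = stats::rnorm(1, baseline_mean,
                                                       baseline_sd))
      grid <- as.matrix(expand.grid(R1 = seq_len(n_sub),
                                    R2 = seq_len(n_sub)))
      keep <- stats::runif(nrow(grid)) < occupancy
      if (sum(keep) < 4L) keep[sample(which(!keep), 4L - sum(keep))] <- TRUE
      cells <- grid[keep, , drop = FALSE]
      libs[[s]] <- list(spec = spec, cells = cells)
    }
    # designed cycles per series, then greedy injection to the target
    for (s in seq_len(n_series)) {
      lib0 <- enumerate_library(libs[[s]]$spec, list(),
                                id_prefix = sprintf("S%02d", s),
                                cells = libs[[s]]$cells)
      libs[[s]]$lib0 <- lib0
      libs[[s]]$cycles0 <- true_cycles(lib0)
    }
    total_cycles <- sum(vapply(libs, function(l) nrow(l$cycles0), 0L))
    target <- ceiling(cycle_na_fraction * total_cycles)
    got <- 0L
    for (s in sample(n_series)) {
      if (got >= target) break
      l <- libs[[s]]
      # cycles through each present cell when that cell is the injected corner
      cand <- sample(nrow(l$cells))
      for (ci in cand) {
        i <- l$cells[ci, 1L]; j <- l$cells[ci, 2L]
        hits <- sum((l$lib0$R1_idx[match(l$cycles0$c1, l$lib0$compound_id)] == i &
                       l$lib0$R2_idx[match(l$cycles0$c1, l$lib0$compound_id)] == j) |
                      (l$lib0$R1_idx[match(l$cycles0$c2, l$lib0$compound_id)] == i &
                         l$lib0$R2_idx[match(l$cycles0$c2, l$lib0$compound_id)] == j) |
                      (l$lib0$R1_idx[match(l$cycles0$c3, l$lib0$compound_id)] == i &
                         l$lib0$R2_idx[match(l$cycles0$c3, l$lib0$compound_id)] == j) |
                      (l$lib0$R1_idx[match(l$cycles0$c4, l$lib0$compound_id)] == i &
                         l$lib0$R2_idx[match(l$cycles0$c4, l$lib0$compound_id)] == j))
        if (hits == 0L) next
        libs[[s]]$injection <- na_injection(
          c("R1", "R2"),
          c(libs[[s]]$spec$sites$R1$sub[i], libs[[s]]$spec$sites$R2$sub[j]),
          delta)
        inj_rows[[length(inj_rows) + 1L]] <- data.frame(
          series = s, R1_idx = i, R2_idx = j, delta = delta,
          n_cycles_hit = hits)
        got <- got + hits
        break
      }
    }
    list(libs = libs, inj_rows = inj_rows)
  })
  lib_all <- list(); truth_all <- list(); inj_cpds <- character(0)
  for (s in seq_len(n_series)) {
    l <- built$libs[[s]]
    inj <- if (!is.null(l$injection)) list(l$injection) else list()
    lib <- enumerate_library(l$spec, inj, id_prefix = sprintf("S%02d", s),
                             cells = l$cells)
    lib$series <- s
    lib_all[[s]] <- lib
    tc <- true_cycles(lib)
    if (nrow(tc)) tc$series <- s
    truth_all[[s]] <- tc
    inj_cpds <- c(inj_cpds, lib$compound_id[lib$injected])
  }
  lib_all <- do.call(rbind, lib_all)
  truth_all <- do.call(rbind, truth_all[vapply(truth_all, nrow, 0L) > 0])
  if (is.null(mspec)) mspec <- measurement_spec()
  mspec$sigma <- sigma
  mspec$seed <- seed + 1L
  records <- measure(lib_all, mspec, assay_id = "synthetic")
  injections <- if (length(built$inj_rows))
    do.call(rbind, built$inj_rows) else
      data.frame(series = integer(0), R1_idx = integer(0),
                 R2_idx = integer(0), delta = numeric(0),
                 n_cycles_hit = integer(0))
  list(library = lib_all, records = records, truth_cycles = truth_all,
       injections = injections, injected_compounds = inj_cpds)
}
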