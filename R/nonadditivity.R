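# Double-transformation cycles and the nonadditivity statistic.
#
# A cycle links four compounds c1..c4 through two transformations:
#   A: c1 -> c2 and c4 -> c3;   B: c1 -> c4 and c2 -> c3.
# Nonadditivity is ddpAct = (pAct2 - pAct1) - (pAct3 - pAct4); it is zero
# when the two transformations contribute independently, and under pure
# measurement noise of sd sigma per compound it is N(0, (2*sigma)^2).

.trans_key <- function(from, to) paste(from, to, sep = ">>")
.pair_key <- function(x, y) paste(pmin(x, y), pmax(x, y), sep = "|")

#' Assemble double-transformation cycles from matched pairs
#'
#' Finds every quadruple (c1, c2, c3, c4) in which edges c1-c2 and c4-c3
#' carry one transformation and edges c1-c4 and c2-c3 carry another, with
#' all transformation directions consistent. Each cycle is emitted exactly
#' once in canonical orientation: `transformation_A` is the
#' lexicographically smaller of the two transformations, c1 is the corner
#' from which both transformations depart, and when the two transformations
#' are identical the orientation with the smaller c2 is kept.
#'
#' @param pairs data frame from [index_pairs()] (columns `compound_a`,
#'   `compound_b`, `var_from`, `var_to`).
#' @return data frame with columns `c1`..`c4`, `trans_a_from`,
#'   `trans_a_to`, `trans_b_from`, `trans_b_to`.
#' @export
assemble_cycles <- function(pairs) {
  empty <- data.frame(c1 = character(0), c2 = character(0),
                      c3 = character(0), c4 = character(0),
                      trans_a_from = character(0), trans_a_to = character(0),
                      trans_b_from = character(0), trans_b_to = character(0))
  if (is.null(pairs) || nrow(pairs) < 4L) return(empty)
  edges <- data.frame(from = pairs$compound_a, to = pairs$compound_b,
                      tf = pairs$var_from, tt = pairs$var_to,
                      stringsAsFactors = FALSE)
  edges <- unique(edges[, c("from", "to", "tf", "tt")])
  edges$trans <- .trans_key(edges$tf, edges$tt)
  # lookup of directed edges between an unordered compound pair
  pk <- .pair_key(edges$from, edges$to)
  by_pair <- split(seq_len(nrow(edges)), pk)
  by_trans <- split(seq_len(nrow(edges)), edges$trans)
  found <- list()
  for (tA in names(by_trans)) {
    eidx <- by_trans[[tA]]
    m <- length(eidx)
    if (m < 2L) next
    for (ii in seq_len(m - 1L)) {
      for (jj in (ii + 1L):m) {
        e1 <- eidx[ii]; e2 <- eidx[jj]
        u1 <- edges$from[e1]; v1 <- edges$to[e1]
        u2 <- edges$from[e2]; v2 <- edges$to[e2]
        if (length(unique(c(u1, v1, u2, v2))) != 4L) next
        fu <- by_pair[[.pair_key(u1, u2)]]
        fv <- by_pair[[.pair_key(v1, v2)]]
        if (is.null(fu) || is.null(fv)) next
        for (f1 in fu) for (f2 in fv) {
          if (edges$trans[f1] != edges$trans[f2]) next
          tB <- edges$trans[f1]
          # aligned directions: both B edges depart from the same A edge
          if (edges$from[f1] == u1 && edges$from[f2] == v1) {
            cyc <- c(u1, v1, v2, u2)
          } else if (edges$from[f1] == u2 && edges$from[f2] == v2) {
            cyc <- c(u2, v2, v1, u1)
          } else next
          # canonical orientation across the A/B role swap
          if (tA < tB) {
            rec <- c(cyc, strsplit(tA, ">>", fixed = TRUE)[[1]],
                     strsplit(tB, ">>", fixed = TRUE)[[1]])
          } else if (tB < tA) {
            rec <- c(cyc[c(1L, 4L, 3L, 2L)],
                     strsplit(tB, ">>", fixed = TRUE)[[1]],
                     strsplit(tA, ">>", fixed = TRUE)[[1]])
          } else {
            if (cyc[4L] < cyc[2L]) cyc <- cyc[c(1L, 4L, 3L, 2L)]
            rec <- c(cyc, strsplit(tA, ">>", fixed = TRUE)[[1]],
                     strsplit(tB, ">>", fixed = TRUE)[[1]])
          }
          found[[paste(rec, collapse = "\r")]] <- rec
        }
      }
    }
  }
  if (!length(found)) return(empty)
  mat <- do.call(rbind, found)
  res <- data.frame(c1 = mat[, 1L], c2 = mat[, 2L], c3 = mat[, 3L],
                    c4 = mat[, 4L], trans_a_from = mat[, 5L],
                    trans_a_to = mat[, 6L], trans_b_from = mat[, 7L],
                    trans_b_to = mat[, 8L], stringsAsFactors = FALSE)
  res <- res[order(res$c1, res$c2, res$c3, res$c4), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Nonadditivity of a cycle
#'
#' @param pact1,pact2,pact3,pact4 pActivities of the four cycle compounds
#'   (log units); vectorized.
#' @return signed nonadditivity `(pact2 - pact1) - (pact3 - pact4)`.
#' @export
nonadditivity_value <- function(pact1, pact2, pact3, pact4) {
  (pact2 - pact1) - (pact3 - pact4)
}

#' Attach pActivities and nonadditivity values to assembled cycles
#'
#' @param cycles data frame from [assemble_cycles()].
#' @param assay data frame with `compound_id` and `pact`.
#' @return `cycles` with added columns `pact_1`..`pact_4` and
#'   `nonadditivity`.
#' @export
cycle_nonadditivity <- function(cycles, assay) {
  p <- stats::setNames(assay$pact, assay$compound_id)
  cycles$pact_1 <- unname(p[cycles$c1])
  cycles$pact_2 <- unname(p[cycles$c2])
  cycles$pact_3 <- unname(p[cycles$c3])
  cycles$pact_4 <- unname(p[cycles$c4])
  cycles$nonadditivity <- nonadditivity_value(cycles$pact_1, cycles$pact_2,
                                              cycles$pact_3, cycles$pact_4)
  cycles
}

#' Experimental-noise model for nonadditivity significance
#'
#' @param sigma_exp per-measurement experimental uncertainty in log units
#'   (0.3 for homogeneous in-house style data, 0.5 for heterogeneous public
#'   data).
#' @param t_strong threshold for strong nonadditivity (log units).
#' @return object of class `na_noise_model` with `sigma_exp`,
#'   `t_significant` (= 2 * sigma_exp: a cycle propagates each
#'   measurement's error twice) and `t_strong`.
#' @export
noise_model <- function(sigma_exp = 0.5, t_strong = 2.0) {
  stopifnot(sigma_exp > 0, t_strong >= 2 * sigma_exp)
  structure(list(sigma_exp = sigma_exp,
                 t_significant = 2 * sigma_exp,
                 t_strong = t_strong),
            class = "na_noise_model")
}

#' @export
print.na_noise_model <- function(x, ...) {
  cat(sprintf(
    "Noise model: sigma_exp = %.2f, significant |NA| > %.2f, strong |NA| > %.2f\n",
    x$sigma_exp, x$t_significant, x$t_strong))
  invisible(x)
}

#' Classify cycles against the noise model
#'
#' @param na signed nonadditivity values.
#' @param noise an [noise_model()] object.
#' @return factor with levels `additive`, `significant`, `strong`
#'   (strong implies significant; the labels are exclusive).
#' @export
classify_cycles <- function(na, noise) {
  a <- abs(na)
  factor(ifelse(a > noise$t_strong, "strong",
                ifelse(a > noise$t_significant, "significant", "additive")),
         levels = c("additive", "significant", "strong"))
}

#' Theoretical nonadditivity noise density
#'
#' Density of the nonadditivity statistic expected from experimental noise
#' alone: four independent measurement errors of sd `sigma_exp` propagate
#' to a normal with sd `2 * sigma_exp`.
#'
#' @param sigma_exp per-measurement uncertainty (log units).
#' @param grid numeric vector of nonadditivity values.
#' @return numeric density values over `grid`.
#' @export
theoretical_noise_density <- function(sigma_exp, grid) {
  stopifnot(sigma_exp > 0)
  stats::dnorm(grid, mean = 0, sd = 2 * sigma_exp)
}

#' Per-compound additivity-shift profiles
#'
#' Every cycle contributes to all four member compounds. For a focal
#' compound the cycle is re-oriented so the compound sits at the
#' doubly-transformed corner c3, and the shift is the observed pActivity
#' minus the additive expectation from the other three corners
#' (`pact3 - pact2 - pact4 + pact1`); a compound more potent than
#' additivity predicts has a positive shift. The null 95% band is
#' `±1.96 * (2 * sigma_exp) / sqrt(n_cycles)`.
#'
#' @param cycles data frame from [cycle_nonadditivity()].
#' @param noise an [noise_model()] object.
#' @return data frame with one row per compound: `compound_id`, `n_cycles`,
#'   `mean_shift`, `std_shift`, `na_max_abs`, `na_mean_abs`, `ci_low`,
#'   `ci_high`, `significant`.
#' @export
compound_profiles <- function(cycles, noise) {
  if (!nrow(cycles)) {
    return(data.frame(compound_id = character(0), n_cycles = integer(0),
                      mean_shift = numeric(0), std_shift = numeric(0),
                      na_max_abs = numeric(0), na_mean_abs = numeric(0),
                      ci_low = numeric(0), ci_high = numeric(0),
                      significant = logical(0)))
  }
  # corner signs of the shift: c1/c3 on one diagonal, c2/c4 on the other
  long <- rbind(
    data.frame(compound_id = cycles$c3, shift = -cycles$nonadditivity),
    data.frame(compound_id = cycles$c1, shift = -cycles$nonadditivity),
    data.frame(compound_id = cycles$c2, shift = cycles$nonadditivity),
    data.frame(compound_id = cycles$c4, shift = cycles$nonadditivity))
  sp <- split(long$shift, long$compound_id)
  prof <- data.frame(
    compound_id = names(sp),
    n_cycles = vapply(sp, length, integer(1)),
    mean_shift = vapply(sp, mean, numeric(1)),
    std_shift = vapply(sp, function(x)
      if (length(x) > 1L) stats::sd(x) else 0, numeric(1)),
    na_max_abs = vapply(sp, function(x) max(abs(x)), numeric(1)),
    na_mean_abs = vapply(sp, function(x) mean(abs(x)), numeric(1)),
    stringsAsFactors = FALSE)
  half <- 1.96 * 2 * noise$sigma_exp / sqrt(prof$n_cycles)
  prof$ci_low <- -half
  prof$ci_high <- half
  prof$significant <- prof$na_max_abs > noise$t_significant
  rownames(prof) <- NULL
  prof
}

#' Per-assay nonadditivity summary
#'
#' Counts of cycles and compounds by significance class plus descriptive
#' statistics of the signed nonadditivity distribution. Kurtosis is
#' reported as excess kurtosis (0 for a normal distribution); skewness and
#' kurtosis use classical moment estimators. Normality is checked with a
#' Kolmogorov-Smirnov test against N(0, sample sd).
#'
#' @param cycles data frame from [cycle_nonadditivity()].
#' @param assay curated assay data frame (for the compound count).
#' @param noise an [noise_model()] object.
#' @param assay_id optional label.
#' @return one-row data frame of class `na_assay_summary`.
#' @export
assay_summary <- function(cycles, assay, noise, assay_id = "assay") {
  n_cyc <- nrow(cycles)
  if (n_cyc > 0L) {
    cls <- classify_cycles(cycles$nonadditivity, noise)
    prof <- compound_profiles(cycles, noise)
    na <- cycles$nonadditivity
    ks <- if (isTRUE(stats::sd(na) > 0))
      suppressWarnings(stats::ks.test(na, "pnorm", 0, stats::sd(na))$p.value)
    else NA_real_
    out <- data.frame(
      assay_id = assay_id,
      n_compounds = nrow(assay),
      n_compounds_in_dtc = nrow(prof),
      n_cycles = n_cyc,
      n_cycles_significant = sum(cls != "additive"),
      n_cycles_strong = sum(cls == "strong"),
      n_compounds_significant = sum(prof$significant),
      mean = mean(na),
      variance = stats::var(na),
      std = stats::sd(na),
      skewness = e1071::skewness(na, type = 1),
      kurtosis = e1071::kurtosis(na, type = 1),
      ks_p = ks,
      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(assay_id = assay_id, n_compounds = nrow(assay),
                      n_compounds_in_dtc = 0L, n_cycles = 0L,
                      n_cycles_significant = 0L, n_cycles_strong = 0L,
                      n_compounds_significant = 0L, mean = NA_real_,
                      variance = NA_real_, std = NA_real_,
                      skewness = NA_real_, kurtosis = NA_real_,
                      ks_p = NA_real_, stringsAsFactors = FALSE)
  }
  class(out) <- c("na_assay_summary", class(out))
  out
}

#' Compare two nonadditivity distributions
#'
#' Rank-based two-sample comparison: Kruskal-Wallis H test and two-sided
#' Mann-Whitney U test on the signed nonadditivity samples.
#'
#' @param sample_a,sample_b numeric vectors.
#' @return list with `kruskal_wallis_p`, `mann_whitney_p`, and `degenerate`
#'   (TRUE when all pooled values are tied, in which case the p-values are
#'   `NA`).
#' @export
compare_distributions <- function(sample_a, sample_b) {
  stopifnot(length(sample_a) > 0, length(sample_b) > 0)
  pooled <- c(sample_a, sample_b)
  if (length(unique(pooled)) == 1L) {
    return(list(kruskal_wallis_p = NA_real_, mann_whitney_p = NA_real_,
                degenerate = TRUE))
  }
  g <- factor(rep(c("a", "b"), c(length(sample_a), length(sample_b))))
  kw <- stats::kruskal.test(pooled, g)$p.value
  mw <- suppressWarnings(
    stats::wilcox.test(sample_a, sample_b, exact = FALSE)$p.value)
  list(kruskal_wallis_p = kw, mann_whitney_p = mw, degenerate = FALSE)
}

#' Run the full nonadditivity analysis on one curated assay
#'
#' Convenience wrapper: [index_pairs()], [assemble_cycles()],
#' [cycle_nonadditivity()], [compound_profiles()], [assay_summary()].
#'
#' @param assay curated assay data frame (`compound_id`, `smiles`, `pact`).
#' @param noise an [noise_model()] object.
#' @param assay_id optional label.
#' @return list with `pairs`, `cycles`, `profiles`, `summary`, and
#'   `compound_table` (the supplementary-style per-compound table:
#'   compound, SMILES, pActivity, number of cycle occurrences and absolute
#'   nonadditivity aggregates, empty where a compound sits in no cycle).
#' @export
nonadditivity_analysis <- function(assay, noise = noise_model(),
                                   assay_id = "assay") {
  pairs <- index_pairs(assay)
  cycles <- assemble_cycles(pairs)
  cycles <- cycle_nonadditivity(cycles, assay)
  prof <- compound_profiles(cycles, noise)
  summ <- assay_summary(cycles, assay, noise, assay_id = assay_id)
  ct <- merge(assay[, c("compound_id", "smiles", "pact")],
              prof[, c("compound_id", "n_cycles", "na_max_abs",
                       "na_mean_abs")],
              by = "compound_id", all.x = TRUE, sort = TRUE)
  list(pairs = pairs, cycles = cycles, profiles = prof, summary = summ,
       compound_table = ct)
}
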