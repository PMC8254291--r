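# Curation of raw activity measurement tables into per-assay pActivity
# tables. The filter order is fixed and auditable: every step reports the
# number of records entering and leaving it.

.known_units <- c("M", "mM", "uM", "nM", "pM", "fM")
.unit_factor <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9,
                  pM = 1e-12, fM = 1e-15)

#' Curation configuration
#'
#' @param min_assay_size minimum number of unique compounds for an assay to
#'   be kept (default 25).
#' @param max_heavy_atoms maximum molecular size in heavy atoms
#'   (atomic number > 1; default 70).
#' @param replicate_spread_max maximum allowed max-min spread of replicate
#'   pActivities per compound, in log units (default 2.5).
#' @param pact_range open interval of admissible pActivities; the default
#'   `c(2, 11)` keeps values strictly between 10 mM and 10 pM.
#' @return list of class `curation_config`.
#' @export
curation_config <- function(min_assay_size = 25L, max_heavy_atoms = 70L,
                            replicate_spread_max = 2.5,
                            pact_range = c(2, 11)) {
  stopifnot(pact_range[1] < pact_range[2])
  structure(list(min_assay_size = min_assay_size,
                 max_heavy_atoms = max_heavy_atoms,
                 replicate_spread_max = replicate_spread_max,
                 pact_range = pact_range),
            class = "curation_config")
}

#' Convert a raw activity value to pActivity
#'
#' @param value numeric activity readout (must be positive).
#' @param unit concentration unit, one of `"M"`, `"mM"`, `"uM"`, `"nM"`,
#'   `"pM"`, `"fM"`. Records whose value is already logged carry the unit
#'   tag `"logged"` and are rejected upstream, not converted.
#' @return `-log10(value in mol/L)`; `NA` for nonpositive values or unknown
#'   units.
#' @examples
#' to_pactivity(1, "uM")   # 6
#' to_pactivity(10, "nM")  # 8
#' @export
to_pactivity <- function(value, unit) {
  f <- .unit_factor[as.character(unit)]
  out <- suppressWarnings(-log10(as.numeric(value) * unname(f)))
  out[!is.finite(out) | value <= 0] <- NA_real_
  out
}

#' Curate one assay's raw measurements
#'
#' Applies, in order: structure standardization (unparseable structures are
#' dropped); removal of missing, qualified (`<`/`>`) and negative values;
#' removal of undefined units; conversion to pActivity with rejection of
#' values outside the open admissible range and of pre-logged values
#' carrying a unit tag; per-compound replicate handling (compounds whose
#' replicate spread exceeds the limit are dropped, the rest collapse to
#' their median); resolution of distinct compound IDs sharing one
#' standardized structure (the entry with the highest pActivity is kept);
#' the heavy-atom size limit; and the minimum assay size.
#'
#' @param records data frame with columns `compound_id`, `smiles`, `value`,
#'   `unit`, `qualifier` (optional columns `assay_id`, `endpoint` are
#'   carried along). All records must belong to one assay.
#' @param config a [curation_config()].
#' @return list with `assay` (data frame `compound_id`, `smiles`, `pact`,
#'   or `NULL` when the assay fails the size filter), `report` (data frame
#'   `step`, `records_in`, `records_out`) and `rejects` (data frame
#'   `compound_id`, `reason`).
#' @export
curate_assay <- function(records, config = curation_config()) {
  stopifnot(all(c("compound_id", "smiles", "value", "unit") %in%
                  names(records)))
  if (is.null(records$qualifier)) records$qualifier <- "="
  rec <- records
  rejects <- list()
  report <- list()
  note <- function(step, n_in, n_out)
    report[[length(report) + 1L]] <<- data.frame(
      step = step, records_in = n_in, records_out = n_out)
  drop <- function(bad, reason) {
    if (any(bad))
      rejects[[length(rejects) + 1L]] <<- data.frame(
        compound_id = rec$compound_id[bad], reason = reason)
    rec[!bad, , drop = FALSE]
  }

  # standardization (performed up front, as required by duplicate merging)
  n0 <- nrow(rec)
  rec$smiles <- standardize_structure(rec$smiles)
  rec <- drop(is.na(rec$smiles), "unparseable structure")
  note("standardize", n0, nrow(rec))

  # (2) missing values, qualified records, negative values
  n0 <- nrow(rec)
  bad <- is.na(rec$value) | !is.finite(rec$value) | rec$value < 0 |
    (!is.na(rec$qualifier) & rec$qualifier %in% c("<", ">"))
  rec <- drop(bad, "missing/qualified/negative value")
  note("qualified_or_missing", n0, nrow(rec))

  # (3) undefined units ("logged" survives to step 4, where it is rejected
  # as a unit-annotated pre-logged value)
  n0 <- nrow(rec)
  bad <- !(rec$unit %in% c(.known_units, "logged"))
  rec <- drop(bad, "undefined unit")
  note("undefined_unit", n0, nrow(rec))

  # (4) pActivity conversion, admissible range, pre-logged values
  n0 <- nrow(rec)
  bad <- rec$unit == "logged"
  rec <- drop(bad, "pre-logged value with unit annotation")
  rec$pact <- to_pactivity(rec$value, rec$unit)
  bad <- is.na(rec$pact) | rec$pact <= config$pact_range[1] |
    rec$pact >= config$pact_range[2]
  rec <- drop(bad, "pActivity outside admissible range")
  note("pactivity_range", n0, nrow(rec))

  # (5) replicates: drop compounds with excessive spread, keep medians
  n0 <- nrow(rec)
  if (nrow(rec)) {
    sp <- split(seq_len(nrow(rec)), rec$compound_id)
    keep_rows <- integer(0)
    for (idx in sp) {
      p <- rec$pact[idx]
      if (max(p) - min(p) > config$replicate_spread_max) {
        rejects[[length(rejects) + 1L]] <- data.frame(
          compound_id = rec$compound_id[idx[1L]],
          reason = "replicate spread > limit")
      } else {
        keep_rows <- c(keep_rows, idx[1L])
        rec$pact[idx[1L]] <- stats::median(p)
      }
    }
    rec <- rec[sort(keep_rows), , drop = FALSE]
  }
  note("replicate_spread", n0, nrow(rec))

  # (6) distinct IDs with identical structure: keep the highest pActivity
  n0 <- nrow(rec)
  if (nrow(rec)) {
    ord <- order(rec$smiles, -rec$pact, rec$compound_id)
    rec <- rec[ord, , drop = FALSE]
    dup <- duplicated(rec$smiles)
    if (any(dup))
      rejects[[length(rejects) + 1L]] <- data.frame(
        compound_id = rec$compound_id[dup],
        reason = "duplicate structure with lower pActivity")
    rec <- rec[!dup, , drop = FALSE]
  }
  note("duplicate_structure", n0, nrow(rec))

  # (7) molecular size
  n0 <- nrow(rec)
  if (nrow(rec)) {
    ha <- heavy_atoms(rec$smiles)
    rec <- drop(!is.na(ha) & ha > config$max_heavy_atoms,
                "more than max heavy atoms")
  }
  note("heavy_atoms", n0, nrow(rec))

  # (8) assay size
  n0 <- nrow(rec)
  keep_assay <- nrow(rec) >= config$min_assay_size
  note("assay_size", n0, if (keep_assay) nrow(rec) else 0L)

  assay <- if (keep_assay) {
    out <- rec[order(rec$compound_id), c("compound_id", "smiles", "pact")]
    rownames(out) <- NULL
    out
  } else NULL
  rejects <- if (length(rejects)) do.call(rbind, rejects) else
    data.frame(compound_id = character(0), reason = character(0))
  list(assay = assay,
       report = do.call(rbind, report),
       rejects = rejects)
}

#' Represent a curated assay as raw activity records
#'
#' Back-converts curated pActivities to molar concentrations so a curated
#' assay can be fed through [curate_assay()] again; curation is idempotent
#' under this round trip.
#'
#' @param assay curated assay data frame.
#' @return data frame in the raw record schema.
#' @export
curated_as_records <- function(assay) {
  data.frame(compound_id = assay$compound_id, smiles = assay$smiles,
             value = 10^(-assay$pact), unit = "M", qualifier = "=",
             stringsAsFactors = FALSE)
}

#' Curate a multi-assay measurement table
#'
#' Splits a raw table on `assay_id`, optionally restricts it to an endpoint
#' allowlist, and curates each assay independently.
#'
#' @param records data frame with an `assay_id` column (and optionally
#'   `endpoint`).
#' @param config a [curation_config()].
#' @param endpoint_allowlist optional character vector; when given, only
#'   records whose `endpoint` is listed are kept (the manual
#'   endpoint-selection step).
#' @return named list of per-assay results as returned by [curate_assay()].
#' @export
curate_assays <- function(records, config = curation_config(),
                          endpoint_allowlist = NULL) {
  stopifnot("assay_id" %in% names(records))
  if (!is.null(endpoint_allowlist))
    records <- records[records$endpoint %in% endpoint_allowlist, ,
                       drop = FALSE]
  lapply(split(records, records$assay_id), curate_assay, config = config)
}
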