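# Chemistry layer: SMILES standardization, canonicalization and molecular
# graphs. All toolkit calls go through OpenBabel (ChemmineOB) in batch; the
# graph representation used downstream (fragmentation, fingerprints) is a
# plain list parsed from V2000 MOL blocks.

#' Convert a batch of structures between formats via OpenBabel
#'
#' Thin wrapper around [ChemmineOB::convertFormat()] that keeps the
#' one-call-per-batch discipline used throughout the package.
#'
#' @param source character scalar holding the full input payload.
#' @param from,to OpenBabel format identifiers (e.g. `"SMI"`, `"SDF"`,
#'   `"CAN"`).
#' @param options optional data frame of OpenBabel options
#'   (`names`/`args` columns), e.g. the `neutralize` transformation.
#' @return The converted payload as a character scalar.
#' @keywords internal
ob_convert <- function(source, from, to, options = NULL) {
  out <- if (is.null(options)) {
    suppressWarnings(ChemmineOB::convertFormat(from, to, source = source))
  } else {
    suppressWarnings(ChemmineOB::convertFormat(from, to, source = source,
                                               options = options))
  }
  paste(out, collapse = "")
}

# Run a named vector of SMILES through OpenBabel and map results back by
# title, so records OpenBabel fails to parse come back as NA rather than
# silently shifting positions. OpenBabel stops a stream at the first
# unparseable entry, so conversion is retried on the remainder: each retry
# marks the first still-missing entry as failed and resubmits the rest.
.smiles_batch <- function(smiles, to, options = NULL) {
  n <- length(smiles)
  res <- rep(NA_character_, n)
  pending <- seq_len(n)
  while (length(pending)) {
    got <- .smiles_batch_once(smiles[pending], to, options)
    res[pending] <- got
    miss <- which(is.na(got))
    if (!length(miss)) break
    # first missing entry is the genuinely bad one; retry those after it
    pending <- pending[miss[miss > miss[1L]]]
  }
  res
}

.smiles_batch_once <- function(smiles, to, options = NULL) {
  n <- length(smiles)
  if (n == 0L) return(character(0))
  ids <- paste0("m", seq_len(n))
  payload <- paste0(smiles, " ", ids, "\n", collapse = "")
  out <- ob_convert(payload, "SMI", to, options = options)
  res <- rep(NA_character_, n)
  if (!nzchar(out)) return(res)
  if (to %in% c("CAN", "SMI")) {
    lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    got_smi <- vapply(parts, `[`, "", 1L)
    got_id <- vapply(parts, function(p) if (length(p) > 1L) p[2L] else "", "")
    idx <- match(got_id, ids)
    ok <- !is.na(idx)
    res[idx[ok]] <- got_smi[ok]
  } else if (to == "SDF") {
    blocks <- strsplit(out, "\\$\\$\\$\\$\n")[[1]]
    blocks <- blocks[nzchar(trimws(blocks))]
    got_id <- vapply(blocks, function(b)
      strsplit(b, "\n", fixed = TRUE)[[1]][1L], "", USE.NAMES = FALSE)
    idx <- match(trimws(got_id), ids)
    ok <- !is.na(idx)
    res[idx[ok]] <- blocks[ok]
  } else {
    stop("unsupported output format: ", to)
  }
  res
}

#' Canonicalize SMILES strings
#'
#' @param smiles character vector of SMILES.
#' @return character vector of canonical SMILES; `NA` where the input could
#'   not be parsed.
#' @examples
#' \donttest{
#' canonical_smiles(c("C1=CC=CC=C1", "c1ccccc1"))  # identical output
#' }
#' @export
canonical_smiles <- function(smiles) {
  .smiles_batch(as.character(smiles), "CAN")
}

#' Standardize structures for curation
#'
#' Applies the package's open standardization protocol: neutralization of
#' charges (where chemically valid) followed by canonical SMILES generation.
#' The operation is idempotent; unparseable structures yield `NA` so callers
#' can drop them with a logged reason.
#'
#' @param smiles character vector of SMILES.
#' @return character vector of standardized canonical SMILES (or `NA`).
#' @export
standardize_structure <- function(smiles) {
  opts <- data.frame(names = "neutralize", args = "", stringsAsFactors = FALSE)
  .smiles_batch(as.character(smiles), "CAN", options = opts)
}

# ---- MOL block graphs -------------------------------------------------------

# Parse one V2000 MOL block into list(symbols, charges, bonds).
# Bond table columns: a, b, order (1-based atom indices).
.parse_molblock <- function(block) {
  lines <- strsplit(block, "\n", fixed = TRUE)[[1]]
  counts <- lines[4L]
  natoms <- as.integer(substr(counts, 1L, 3L))
  nbonds <- as.integer(substr(counts, 4L, 6L))
  atoms <- lines[4L + seq_len(natoms)]
  symbols <- trimws(substr(atoms, 32L, 34L))
  charges <- integer(natoms)
  if (nbonds > 0L) {
    bl <- lines[4L + natoms + seq_len(nbonds)]
    bonds <- data.frame(
      a = as.integer(substr(bl, 1L, 3L)),
      b = as.integer(substr(bl, 4L, 6L)),
      order = as.integer(substr(bl, 7L, 9L))
    )
  } else {
    bonds <- data.frame(a = integer(0), b = integer(0), order = integer(0))
  }
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
    k <- f[1L]
    for (i in seq_len(k)) charges[f[2L * i]] <- f[2L * i + 1L]
  }
  list(symbols = symbols, charges = charges, bonds = bonds)
}

#' Parse SMILES into molecular graphs
#'
#' @param smiles character vector of SMILES.
#' @return A list of molecular graphs (`symbols`, `charges`, `bonds`), with
#'   `NULL` entries for unparseable input. Hydrogens are implicit; bond
#'   orders are kekulized integers.
#' @export
mol_graphs <- function(smiles) {
  sdf <- .smiles_batch(as.character(smiles), "SDF")
  lapply(sdf, function(b) if (is.na(b)) NULL else .parse_molblock(b))
}

#' Count heavy atoms
#'
#' Heavy atoms are atoms with atomic number greater than 1; attachment-point
#' dummies (`*`) are not counted.
#'
#' @param smiles character vector of SMILES.
#' @return integer vector; `NA` for unparseable structures.
#' @export
heavy_atoms <- function(smiles) {
  g <- mol_graphs(smiles)
  vapply(g, function(m) {
    if (is.null(m)) return(NA_integer_)
    sum(!m$symbols %in% c("H", "*", "D", "T"))
  }, integer(1))
}

# Serialize a fragment of a parsed graph back to a V2000 MOL block, keeping
# the atoms in `keep` and adding one "*" dummy bonded to `attach` (an index
# into the parent atom numbering). Coordinates are irrelevant for
# canonicalization and written as zeros.
.fragment_molblock <- function(g, keep, attach, title = "frag") {
  keep <- sort(keep)
  remap <- integer(length(g$symbols))
  remap[keep] <- seq_along(keep)
  nk <- length(keep)
  natoms <- nk + 1L
  bonds <- g$bonds[g$bonds$a %in% keep & g$bonds$b %in% keep, , drop = FALSE]
  nbonds <- nrow(bonds) + 1L
  hdr <- sprintf("%s\n\n\n%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                 title, natoms, nbonds)
  atom_line <- function(sym)
    sprintf("    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            sym)
  atoms <- c(vapply(g$symbols[keep], atom_line, ""), atom_line("*"))
  bl <- sprintf("%3d%3d%3d  0", remap[bonds$a], remap[bonds$b], bonds$order)
  bl <- c(bl, sprintf("%3d%3d%3d  0", natoms, remap[attach], 1L))
  chg <- which(g$charges[keep] != 0L)
  chg_lines <- if (length(chg)) {
    vapply(chg, function(i)
      sprintf("M  CHG%3d%4d%4d", 1L, remap[keep[i]], g$charges[keep[i]]), "")
  } else character(0)
  paste(c(hdr, atoms, bl, chg_lines, "M  END", "$$$$"), collapse = "\n")
}

#' Canonicalize fragment MOL blocks to SMILES
#'
#' @param molblocks character vector of V2000 MOL blocks (each ending with
#'   `$$$$`).
#' @return character vector of canonical fragment SMILES with `*` attachment
#'   atoms.
#' @keywords internal
.molblocks_to_can <- function(molblocks) {
  n <- length(molblocks)
  if (n == 0L) return(character(0))
  # titles are already frag ids; rewrite them to positional ids
  blocks <- vapply(seq_len(n), function(i)
    sub("^[^\n]*", paste0("f", i), molblocks[i]), "")
  out <- ob_convert(paste0(blocks, "\n", collapse = ""), "SDF", "CAN")
  res <- rep(NA_character_, n)
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  got_smi <- vapply(parts, `[`, "", 1L)
  got_id <- vapply(parts, function(p) if (length(p) > 1L) p[2L] else "", "")
  idx <- match(got_id, paste0("f", seq_len(n)))
  ok <- !is.na(idx)
  res[idx[ok]] <- got_smi[ok]
  res
}
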