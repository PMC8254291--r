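# Matched molecular pair indexing by single acyclic-bond fragmentation
# (Hussain-Rea single cuts). Fragment keys are canonical SMILES with one "*"
# attachment atom, so identical contexts from different molecules collide.

# Enumerate the single-cut fragmentations of one parsed graph.
# Returns a list of cuts; each cut holds the two atom index sets.
.cut_sets <- function(g) {
  heavy <- !g$symbols %in% c("H", "*", "D", "T")
  nb <- nrow(g$bonds)
  if (nb == 0L) return(list())
  ig <- igraph::graph_from_edgelist(as.matrix(g$bonds[, c("a", "b")]),
                                    directed = FALSE)
  if (igraph::vcount(ig) < length(g$symbols))
    ig <- igraph::add_vertices(ig, length(g$symbols) - igraph::vcount(ig))
  bridge_ids <- igraph::bridges(ig)
  cuts <- list()
  for (e in as.integer(bridge_ids)) {
    a <- g$bonds$a[e]; b <- g$bonds$b[e]
    if (g$bonds$order[e] != 1L) next
    if (!heavy[a] || !heavy[b]) next
    g2 <- igraph::delete_edges(ig, e)
    comp <- igraph::components(g2)$membership
    side_a <- which(comp == comp[a])
    side_b <- which(comp == comp[b])
    cuts[[length(cuts) + 1L]] <- list(a = a, b = b,
                                      side_a = side_a, side_b = side_b)
  }
  cuts
}

# Fragmentation table for a vector of molecules, one OpenBabel
# canonicalization call for all fragments. Columns: id, context, variable,
# context_heavy, variable_heavy, parent_heavy.
.fragment_table <- function(smiles, ids = NULL) {
  smiles <- as.character(smiles)
  if (is.null(ids)) ids <- as.character(seq_along(smiles))
  graphs <- mol_graphs(smiles)
  rows <- list(); blocks <- character(0)
  for (i in seq_along(graphs)) {
    g <- graphs[[i]]
    if (is.null(g))
      stop("unparseable structure reached fragmentation: ", smiles[i])
    heavy <- !g$symbols %in% c("H", "*", "D", "T")
    nH <- sum(heavy)
    for (cut in .cut_sets(g)) {
      ha <- sum(heavy[cut$side_a]); hb <- sum(heavy[cut$side_b])
      # two orientations per cut: each side once as the variable part
      blocks <- c(blocks,
                  .fragment_molblock(g, cut$side_a, cut$a),
                  .fragment_molblock(g, cut$side_b, cut$b))
      k <- length(blocks)
      rows[[length(rows) + 1L]] <- data.frame(
        id = ids[i],
        ctx_block = c(k - 1L, k), var_block = c(k, k - 1L),
        context_heavy = c(ha, hb), variable_heavy = c(hb, ha),
        parent_heavy = nH, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(id = character(0), context = character(0),
                      variable = character(0), context_heavy = integer(0),
                      variable_heavy = integer(0), parent_heavy = integer(0)))
  }
  tab <- do.call(rbind, rows)
  keys <- .molblocks_to_can(blocks)
  tab$context <- keys[tab$ctx_block]
  tab$variable <- keys[tab$var_block]
  tab <- tab[, c("id", "context", "variable", "context_heavy",
                 "variable_heavy", "parent_heavy")]
  unique(tab)
}

#' Fragment a molecule at every single acyclic bond
#'
#' Enumerates all Hussain-Rea single-cut fragmentations: each single,
#' acyclic bond between heavy atoms is broken in turn and both resulting
#' (context, variable) orientations are reported with canonical fragment
#' SMILES keys. The transformation-size rule is applied later, when pairs
#' are indexed (see [index_pairs()]), so this enumeration is complete.
#'
#' @param smiles a single SMILES string.
#' @return data frame with columns `context`, `variable`, `context_heavy`,
#'   `variable_heavy`, `parent_heavy`; zero rows for molecules with no
#'   cleavable bond (e.g. benzene).
#' @examples
#' \donttest{
#' fragment("Cc1ccccc1")  # toluene: one cut, two orientations
#' }
#' @export
fragment <- function(smiles) {
  stopifnot(length(smiles) == 1L)
  tab <- .fragment_table(smiles)
  tab$id <- NULL
  rownames(tab) <- NULL
  tab
}

#' Index matched molecular pairs within a curated assay
#'
#' Two compounds form a matched pair when they share a fragmentation
#' context and differ in the attached variable fragment. The transformation
#' is stored in canonical direction (`var_from` lexicographically smaller
#' than `var_to`); `compound_a` carries `var_from`. The transformation-size
#' rule restricts the variable fragment to at most `max_variable_fraction`
#' of each molecule's heavy atoms, enforced on both molecules of a pair.
#'
#' @param assay data frame with columns `compound_id`, `smiles` (and
#'   typically `pact`), one row per unique compound.
#' @param max_variable_fraction maximum fraction of a molecule's heavy
#'   atoms that the variable fragment may contain (default 1/3).
#' @return data frame with columns `compound_a`, `compound_b`, `context`,
#'   `var_from`, `var_to`; at most one row per (pair, context).
#' @export
index_pairs <- function(assay, max_variable_fraction = 1 / 3) {
  stopifnot(all(c("compound_id", "smiles") %in% names(assay)))
  empty <- data.frame(compound_a = character(0), compound_b = character(0),
                      context = character(0), var_from = character(0),
                      var_to = character(0))
  if (nrow(assay) < 2L) return(empty)
  frags <- .fragment_table(assay$smiles, assay$compound_id)
  frags <- frags[frags$variable_heavy <=
                   frags$parent_heavy * max_variable_fraction, , drop = FALSE]
  if (!nrow(frags)) return(empty)
  out <- list()
  for (ctx in unique(frags$context)) {
    sub <- frags[frags$context == ctx, , drop = FALSE]
    cpds <- unique(sub$id)
    if (length(cpds) < 2L) next
    for (i in seq_len(length(cpds) - 1L)) {
      for (j in (i + 1L):length(cpds)) {
        va <- sub$variable[sub$id == cpds[i]]
        vb <- sub$variable[sub$id == cpds[j]]
        combos <- expand.grid(va = va, vb = vb, stringsAsFactors = FALSE)
        combos <- combos[combos$va != combos$vb, , drop = FALSE]
        if (!nrow(combos)) next
        # at most one pair per context: deterministic smallest transformation
        key <- ifelse(combos$va < combos$vb,
                      paste(combos$va, combos$vb, sep = ">>"),
                      paste(combos$vb, combos$va, sep = ">>"))
        pick <- order(key)[1L]
        if (combos$va[pick] < combos$vb[pick]) {
          out[[length(out) + 1L]] <- data.frame(
            compound_a = cpds[i], compound_b = cpds[j], context = ctx,
            var_from = combos$va[pick], var_to = combos$vb[pick])
        } else {
          out[[length(out) + 1L]] <- data.frame(
            compound_a = cpds[j], compound_b = cpds[i], context = ctx,
            var_from = combos$vb[pick], var_to = combos$va[pick])
        }
      }
    }
  }
  if (!length(out)) return(empty)
  res <- unique(do.call(rbind, out))
  rownames(res) <- NULL
  res
}
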