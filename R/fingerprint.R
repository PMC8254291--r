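# Circular substructure count fingerprints (ECFP-style, radius 3 by
# default, i.e. ECFP6) computed on the package's MOL-block graphs, folded
# to a fixed length. Counts, not bits: the number of times an environment
# occurs is retained.

.atomic_number <- c("*" = 0, H = 1, B = 5, C = 6, N = 7, O = 8, F = 9,
                    P = 15, S = 16, Cl = 17, Br = 35, I = 53, Si = 14,
                    Se = 34)
.default_valence <- c(B = 3, C = 4, N = 3, O = 2, P = 3, S = 2, F = 1,
                      Cl = 1, Br = 1, I = 1, Si = 4, Se = 2)

# 32-bit style integer hash of a numeric vector (exact in doubles)
.hash_vec <- function(v) {
  h <- 17
  for (x in v) h <- (h * 31 + (x %% 2147483647)) %% 2147483647
  h
}

# environment identifiers for all atoms of one graph, radius rounds
.ecfp_ids <- function(g, radius) {
  nat <- length(g$symbols)
  if (nat == 0L) return(numeric(0))
  z <- unname(.atomic_number[g$symbols])
  z[is.na(z)] <- 99
  deg <- integer(nat)
  bosum <- integer(nat)
  nbrs <- vector("list", nat)
  if (nrow(g$bonds)) {
    for (r in seq_len(nrow(g$bonds))) {
      a <- g$bonds$a[r]; b <- g$bonds$b[r]; o <- g$bonds$order[r]
      deg[a] <- deg[a] + 1L; deg[b] <- deg[b] + 1L
      bosum[a] <- bosum[a] + o; bosum[b] <- bosum[b] + o
      nbrs[[a]] <- rbind(nbrs[[a]], c(b, o))
      nbrs[[b]] <- rbind(nbrs[[b]], c(a, o))
    }
  }
  dv <- .default_valence[g$symbols]
  nh <- pmax(0, ifelse(is.na(dv), 0, dv) - bosum + g$charges)
  in_ring <- rep(0L, nat)
  if (nrow(g$bonds)) {
    ig <- igraph::graph_from_edgelist(as.matrix(g$bonds[, c("a", "b")]),
                                      directed = FALSE)
    if (igraph::vcount(ig) < nat)
      ig <- igraph::add_vertices(ig, nat - igraph::vcount(ig))
    ring_edge <- setdiff(seq_len(nrow(g$bonds)),
                         as.integer(igraph::bridges(ig)))
    in_ring[unique(c(g$bonds$a[ring_edge], g$bonds$b[ring_edge]))] <- 1L
  }
  ids <- vapply(seq_len(nat), function(i)
    .hash_vec(c(z[i], deg[i], nh[i], g$charges[i], in_ring[i])), numeric(1))
  # an atom stops emitting once its neighborhood no longer grows, so a
  # given substructure environment is counted only once per center
  env <- lapply(seq_len(nat), function(i) i)
  active <- rep(TRUE, nat)
  all_ids <- ids
  cur <- ids
  for (r in seq_len(radius)) {
    if (!any(active)) break
    nxt <- cur
    for (i in which(active)) {
      grown <- unique(c(env[[i]],
                        unlist(lapply(env[[i]], function(j)
                          if (is.null(nbrs[[j]])) integer(0)
                          else nbrs[[j]][, 1L]))))
      if (length(grown) == length(env[[i]])) {
        active[i] <- FALSE
        next
      }
      env[[i]] <- grown
      nb <- nbrs[[i]]
      pairs <- cbind(nb[, 2L], cur[nb[, 1L]])
      ord <- order(pairs[, 1L], pairs[, 2L])
      nxt[i] <- .hash_vec(c(r, cur[i], t(pairs[ord, , drop = FALSE])))
      all_ids <- c(all_ids, nxt[i])
    }
    cur <- nxt
  }
  all_ids
}

#' Circular substructure count fingerprints
#'
#' For every atom, hashed identifiers of its circular neighborhoods of
#' radius 0 up to `radius` are collected (radius 3 corresponds to ECFP6)
#' and their occurrence counts folded into a fixed-length vector.
#'
#' @param smiles character vector of SMILES.
#' @param radius maximum neighborhood radius (default 3).
#' @param n_bits folded vector length (default 2048).
#' @return integer matrix, one row per molecule, `n_bits` columns; row
#'   names are the input SMILES indices' names if given.
#' @export
ecfp_counts <- function(smiles, radius = 3L, n_bits = 2048L) {
  graphs <- mol_graphs(smiles)
  m <- matrix(0L, nrow = length(graphs), ncol = n_bits)
  for (i in seq_along(graphs)) {
    g <- graphs[[i]]
    if (is.null(g)) stop("unparseable structure: ", smiles[i])
    ids <- .ecfp_ids(g, radius)
    tab <- table(ids %% n_bits + 1)
    m[i, as.integer(names(tab))] <- as.integer(tab)
  }
  colnames(m) <- paste0("fp", seq_len(n_bits))
  if (!is.null(names(smiles))) rownames(m) <- names(smiles)
  m
}

#' Tanimoto similarity between count vectors
#'
#' Count-based (min/max) Tanimoto similarity.
#'
#' @param x numeric matrix of count fingerprints (rows = molecules).
#' @param y optional second matrix; defaults to `x`.
#' @return similarity matrix with `nrow(x)` rows and `nrow(y)` columns.
#' @export
tanimoto_counts <- function(x, y = x) {
  out <- matrix(NA_real_, nrow(x), nrow(y))
  for (i in seq_len(nrow(x))) {
    xi <- x[i, ]
    mins <- pmin(matrix(xi, nrow(y), length(xi), byrow = TRUE), y)
    maxs <- pmax(matrix(xi, nrow(y), length(xi), byrow = TRUE), y)
    out[i, ] <- rowSums(mins) / pmax(rowSums(maxs), 1)
  }
  out
}

#' Maximum similarity of each compound to a reference set
#'
#' For every query compound the maximum count-Tanimoto similarity to the
#' reference set is reported, excluding comparisons of a compound with
#' itself (matched by compound ID).
#'
#' @param query_fp,ref_fp count fingerprint matrices.
#' @param query_ids,ref_ids compound ID vectors aligned with the rows.
#' @return numeric vector (length `nrow(query_fp)`); `NA` where no
#'   eligible reference compound exists.
#' @export
similarity_overlap <- function(query_fp, query_ids, ref_fp, ref_ids) {
  sim <- tanimoto_counts(query_fp, ref_fp)
  vapply(seq_len(nrow(sim)), function(i) {
    s <- sim[i, ref_ids != query_ids[i]]
    if (!length(s)) NA_real_ else max(s)
  }, numeric(1))
}
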