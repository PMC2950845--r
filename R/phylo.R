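# Distance trees, congruence statistics and the Fitch-parsimony lower
# bound on horizontal gene transfer. Tree algorithms are delegated to ape
# (neighbor joining) and phangorn (parsimony, Robinson-Foulds); tests
# verify them against independent brute-force oracles.

#' Pairwise p-distance matrix from an alignment
#'
#' d(i, j) is the fraction of differing residues over the columns where
#' neither row has a gap (pairwise deletion). A pair with no comparable
#' columns is an error.
#'
#' @param alignment Character matrix (rows = sequences, rownames = ids).
#' @return Symmetric numeric matrix with zero diagonal, labeled by the
#'   row ids.
#' @export
p_distance <- function(alignment) {
  stopifnot(is.matrix(alignment), nrow(alignment) >= 2L)
  ids <- rownames(alignment) %||% paste0("seq", seq_len(nrow(alignment)))
  n <- nrow(alignment)
  gap <- alignment == "-" | alignment == "." | alignment == "~"
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !gap[i, ] & !gap[j, ]
    if (!any(ok))
      stop("no comparable columns between ", ids[i], " and ", ids[j])
    d[i, j] <- d[j, i] <- mean(alignment[i, ok] != alignment[j, ok])
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining (via \code{ape::nj}); negative
#' branch lengths are clamped to zero with a warning.
#'
#' @param dm Symmetric labeled distance matrix (>= 3 labels).
#' @return Unrooted \code{phylo} tree.
#' @export
neighbor_joining <- function(dm) {
  stopifnot(is.matrix(dm), nrow(dm) >= 3L)
  if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-8)))
    stop("distance matrix is not symmetric")
  tree <- ape::nj(dm)
  if (any(tree$edge.length < 0)) {
    warning("negative branch lengths clamped to zero")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

check_chars <- function(tree, chars) {
  miss <- setdiff(tree$tip.label, names(chars))
  if (length(miss))
    stop("character map is missing leaves: ", paste(miss, collapse = ", "))
  chars[tree$tip.label]
}

#' Is a character state monophyletic on an unrooted tree?
#'
#' TRUE when some edge bipartition isolates exactly the leaves carrying
#' \code{state}.
#'
#' @param tree A \code{phylo} tree.
#' @param chars Named character vector mapping every leaf to a state.
#' @param state The state to test (must be present among the leaves).
#' @return Logical flag.
#' @export
monophyly <- function(tree, chars, state) {
  chars <- check_chars(tree, chars)
  tips <- tree$tip.label[chars == state]
  if (!length(tips)) stop("state '", state, "' not present among leaves")
  if (length(tips) == length(tree$tip.label)) return(TRUE)
  if (length(tips) == 1L) return(TRUE)
  out <- setdiff(tree$tip.label, tips)[1L]
  rooted <- ape::root(tree, outgroup = out, resolve.root = TRUE)
  ape::is.monophyletic(rooted, tips)
}

#' Minimum number of character changes on a tree (Fitch parsimony)
#'
#' The small-parsimony count of state changes required by a leaf
#' character map, computed on an arbitrary rooting (the count is
#' root-invariant). Used as the lower bound on horizontal transfer
#' events when the character is protein-group membership on the species
#' tree.
#'
#' @param tree A \code{phylo} tree.
#' @param chars Named character vector mapping every leaf to a state.
#' @return Integer count (0 when only one state is present).
#' @export
fitch_min_changes <- function(tree, chars) {
  chars <- check_chars(tree, chars)
  states <- unique(chars)
  if (length(states) < 2L) return(0L)
  dat <- phangorn::phyDat(matrix(chars, ncol = 1L,
                                 dimnames = list(names(chars), NULL)),
                          type = "USER", levels = states)
  as.integer(phangorn::parsimony(tree, dat, method = "fitch"))
}

#' Robinson-Foulds distance between two unrooted trees
#'
#' @param t1,t2 \code{phylo} trees over the same taxa.
#' @return Integer count of bipartitions present in one tree but not the
#'   other.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different taxa")
  as.integer(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2)))
}

#' Topological congruence of region trees
#'
#' Builds a neighbor-joining tree on p-distances for each per-region
#' alignment and reports all pairwise Robinson-Foulds distances. Equal
#' taxa are required across regions. Congruent regions (e.g. the
#' glutamate-binding lobes and the channel region having travelled
#' together through evolution) give pairwise distances of zero.
#'
#' @param alignments Named list of character matrices (same rownames).
#' @return List with \code{trees} (named list of phylo) and
#'   \code{rf} (labeled symmetric matrix of RF distances).
#' @export
region_tree_congruence <- function(alignments) {
  stopifnot(is.list(alignments), length(alignments) >= 2L,
            !is.null(names(alignments)))
  ids <- rownames(alignments[[1L]])
  for (nm in names(alignments))
    if (!setequal(rownames(alignments[[nm]]), ids))
      stop("alignment '", nm, "' has mismatched taxa")
  trees <- lapply(alignments, function(a) neighbor_joining(p_distance(a)))
  k <- length(trees)
  rf <- matrix(0L, k, k, dimnames = list(names(trees), names(trees)))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
    rf[i, j] <- rf[j, i] <- rf_distance(trees[[i]], trees[[j]])
  list(trees = trees, rf = rf)
}
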