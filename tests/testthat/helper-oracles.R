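# Independent brute-force oracles used to validate the implementations.
# These deliberately share no code with the package internals.

# Quadratic-space affine-gap Smith-Waterman, score only.
sw_oracle <- function(query, subject, mat = blosum62(), gap_open = 11,
                      gap_extend = 1) {
  qc <- strsplit(query, "")[[1]]
  sc <- strsplit(subject, "")[[1]]
  m <- length(qc); n <- length(sc)
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  F <- matrix(-Inf, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i, j - 1] - gap_open - gap_extend,
                     E[i, j - 1] - gap_extend)
      F[i, j] <- max(H[i - 1, j] - gap_open - gap_extend,
                     F[i - 1, j] - gap_extend)
      H[i, j] <- max(0, H[i - 1, j - 1] + mat[qc[i - 1], sc[j - 1]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# Exhaustive small parsimony: minimize changes over all internal-state
# assignments (feasible for <= 12 leaves, 2-3 states).
brute_fitch <- function(tree, chars) {
  tree <- ape::unroot(tree)
  states <- unique(chars)
  nint <- tree$Nnode
  combos <- expand.grid(rep(list(states), nint), stringsAsFactors = FALSE)
  leaf_states <- chars[tree$tip.label]
  best <- Inf
  for (k in seq_len(nrow(combos))) {
    assign <- c(leaf_states, unlist(combos[k, ], use.names = FALSE))
    best <- min(best, sum(assign[tree$edge[, 1]] != assign[tree$edge[, 2]]))
  }
  best
}

# All-pairs symmetric-difference edge oracle for domain-set graphs.
edges_oracle <- function(sets) {
  ids <- vapply(sets, function(s)
    if (length(s)) paste(sort(s), collapse = "+") else "(none)",
    character(1))
  keep <- !duplicated(ids)
  sets <- sets[keep]; ids <- ids[keep]
  out <- character(0)
  n <- length(sets)
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      sd <- length(setdiff(sets[[i]], sets[[j]])) +
        length(setdiff(sets[[j]], sets[[i]]))
      if (sd == 1)
        out <- c(out, paste(sort(c(ids[i], ids[j])), collapse = "|"))
    }
  }
  sort(out)
}

# Union-find connected components over an edge list of node ids.
components_oracle <- function(node_ids, edges_from, edges_to) {
  parent <- setNames(node_ids, node_ids)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (k in seq_along(edges_from))
    parent[[find(edges_from[k])]] <- find(edges_to[k])
  roots <- vapply(node_ids, find, character(1))
  parts <- split(node_ids, roots)
  parts <- lapply(parts, sort)
  unname(parts[order(vapply(parts, `[`, character(1), 1))])
}

# Breadth-first shortest path length between two nodes (Inf if none).
bfs_oracle <- function(node_ids, edges_from, edges_to, src, dst) {
  if (src == dst) return(0L)
  adj <- lapply(setNames(node_ids, node_ids), function(v)
    c(edges_to[edges_from == v], edges_from[edges_to == v]))
  dist <- setNames(rep(Inf, length(node_ids)), node_ids)
  dist[src] <- 0
  queue <- src
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (is.infinite(dist[w])) {
        dist[w] <- dist[v] + 1
        if (w == dst) return(as.integer(dist[w]))
        queue <- c(queue, w)
      }
    }
  }
  Inf
}

# Canonical unordered key for an edge list, collation-stable.
edge_keys <- function(from, to) {
  sort(vapply(seq_along(from), function(i)
    paste(sort(c(from[i], to[i])), collapse = "|"), character(1)))
}

# Random amino-acid sequence from the 20 standard residues.
random_aa <- function(n) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
               n, replace = TRUE), collapse = "")
}
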