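# Evolutionary Domain Network (EDN): proteins are grouped into nodes by
# their domain composition (the set of domain accessions annotated on
# them); tie lines join compositions that differ by the addition or
# subtraction of exactly one domain. Rows index nodes by set cardinality.

set_id <- function(domains) {
  if (!length(domains)) "(none)" else paste(sort(domains), collapse = "+")
}

#' Build domain compositions from annotations
#'
#' Collapses InterProScan-style annotation rows into one domain set per
#' protein. Composition is a set: duplicate accessions collapse, and
#' overlapping domains are retained as distinct accessions (intervals are
#' ignored). Annotations weaker than \code{evalue_max} are excluded.
#'
#' @param annotations data.frame (protein_id, domain_accession, start,
#'   end, evalue) or a path to such a TSV
#'   (\code{\link{read_domain_annotations}}).
#' @param evalue_max Maximum annotation E-value retained (default 1e-3).
#' @param proteins Optional character vector of protein ids that must all
#'   appear (proteins without surviving annotations get an empty set and
#'   are flagged with a message).
#' @return Named list of class \code{domain_compositions}: protein id ->
#'   sorted character vector of accessions.
#' @export
compose_domains <- function(annotations, evalue_max = 1e-3,
                            proteins = NULL) {
  if (is.character(annotations) && length(annotations) == 1L)
    annotations <- read_domain_annotations(annotations)
  stopifnot(is.data.frame(annotations))
  keep <- annotations[annotations$evalue <= evalue_max, , drop = FALSE]
  comp <- lapply(split(keep$domain_accession, keep$protein_id),
                 function(x) sort(unique(x)))
  if (!is.null(proteins)) {
    unknown <- setdiff(unique(annotations$protein_id), proteins)
    if (length(unknown))
      stop("annotations reference unknown proteins: ",
           paste(unknown, collapse = ", "))
    missing <- setdiff(proteins, names(comp))
    if (length(missing)) {
      message("proteins with empty domain composition: ",
              paste(missing, collapse = ", "))
      comp[missing] <- list(character(0))
    }
    comp <- comp[proteins]
  }
  structure(comp, class = "domain_compositions")
}

#' Build the Evolutionary Domain Network
#'
#' Nodes are the distinct domain sets among the compositions (each input
#' protein belongs to exactly one node); edges join every pair of sets
#' whose symmetric difference has size exactly one, i.e. sets derivable
#' from each other by adding or subtracting a single domain. Rows index
#' nodes by set cardinality. Edges are found by hashing each set minus
#' one element, so endpoints always occupy adjacent rows.
#'
#' @param compositions A \code{domain_compositions} object (or named list
#'   of accession vectors).
#' @return Object of class \code{edn}: list with \code{nodes} (data.frame:
#'   node_id, size, n_proteins plus list-columns domains, proteins),
#'   \code{edges} (data.frame: from, to), \code{rows} (list: cardinality
#'   -> node ids) and \code{graph} (igraph).
#' @export
build_edn <- function(compositions) {
  stopifnot(length(compositions) >= 1L)
  ids <- vapply(compositions, set_id, character(1L))
  uniq <- !duplicated(ids)
  node_id <- ids[uniq]
  domains <- compositions[uniq]
  proteins <- split(names(compositions), ids)[node_id]
  size <- vapply(domains, length, integer(1L))

  # edge discovery: S and S\{x} are adjacent; hash node ids
  have <- seq_along(node_id)
  names(have) <- node_id
  ef <- character(0); et <- character(0)
  for (k in seq_along(node_id)) {
    s <- domains[[k]]
    for (x in s) {
      nb <- set_id(setdiff(s, x))
      if (!is.na(have[nb])) {
        ef <- c(ef, nb); et <- c(et, node_id[k])
      }
    }
  }
  nodes <- data.frame(node_id = node_id, size = size,
                      n_proteins = vapply(proteins, length, integer(1L)),
                      stringsAsFactors = FALSE)
  nodes$domains <- unname(domains)
  nodes$proteins <- unname(proteins)
  edges <- data.frame(from = ef, to = et, stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes[, "node_id",
                                                      drop = FALSE])
  rows <- split(node_id, size)
  structure(list(nodes = nodes, edges = edges, rows = rows, graph = g),
            class = "edn")
}

#' @export
print.edn <- function(x, ...) {
  cat("Evolutionary Domain Network:", nrow(x$nodes), "domain sets,",
      nrow(x$edges), "tie lines,",
      igraph::count_components(x$graph), "components\n")
  invisible(x)
}

#' Connected components of an EDN
#'
#' @param edn An \code{edn} object.
#' @return List of character vectors of node ids, one per component, in a
#'   deterministic order (by the smallest member node id); node ids
#'   within a component are sorted.
#' @export
edn_components <- function(edn) {
  comp <- igraph::components(edn$graph)
  parts <- split(names(comp$membership), comp$membership)
  parts <- lapply(parts, sort)
  parts[order(vapply(parts, `[`, character(1L), 1L))]
}

#' Shortest domain-exchange path between two domain sets
#'
#' Finds the shortest sequence of single-domain additions/removals
#' transforming the source set into the target. With
#' \code{allow_virtual = TRUE} intermediate sets need not be observed
#' nodes (vanished or not-yet-sequenced compositions), and the path
#' length equals the size of the symmetric difference: removals of
#' source-only domains (sorted) followed by additions of target-only
#' domains (sorted). With \code{allow_virtual = FALSE} the path is a
#' breadth-first shortest path over observed nodes only.
#'
#' @param edn An \code{edn} object (only required for observed-only
#'   paths; may be NULL for virtual paths).
#' @param source,target Character vectors of domain accessions (or node
#'   ids containing "+" separators).
#' @param allow_virtual Allow unobserved intermediate sets.
#' @return List with \code{found} (logical), \code{steps} (data.frame:
#'   op ("add"/"remove"), domain), \code{length} and, for observed paths,
#'   \code{nodes} (the node-id sequence).
#' @export
exchange_path <- function(edn, source, target, allow_virtual = TRUE) {
  as_set <- function(x) {
    if (length(x) == 1L && grepl("+", x, fixed = TRUE))
      x <- strsplit(x, "+", fixed = TRUE)[[1L]]
    sort(unique(x))
  }
  src <- as_set(source); tgt <- as_set(target)
  if (!length(src) || !length(tgt))
    stop("source and target sets must be non-empty")
  steps_between <- function(a, b) {
    rem <- sort(setdiff(a, b)); add <- sort(setdiff(b, a))
    data.frame(op = c(rep("remove", length(rem)), rep("add", length(add))),
               domain = c(rem, add), stringsAsFactors = FALSE)
  }
  if (allow_virtual) {
    st <- steps_between(src, tgt)
    return(list(found = TRUE, steps = st, length = nrow(st)))
  }
  sid <- set_id(src); tid <- set_id(tgt)
  vs <- igraph::V(edn$graph)$name
  if (!(sid %in% vs) || !(tid %in% vs))
    stop("source/target not observed in the network: ",
         paste(setdiff(c(sid, tid), vs), collapse = ", "))
  sp <- suppressWarnings(
    igraph::shortest_paths(edn$graph, from = sid, to = tid))
  path <- sp$vpath[[1L]]
  if (sid != tid && length(path) <= 1L)
    return(list(found = FALSE, steps = NULL, length = NA_integer_,
                nodes = character(0)))
  node_ids <- igraph::as_ids(path)
  sets <- edn$nodes$domains[match(node_ids, edn$nodes$node_id)]
  steps <- list()
  for (k in seq_len(length(sets) - 1L))
    steps[[k]] <- steps_between(sets[[k]], sets[[k + 1L]])
  steps <- if (length(steps)) do.call(rbind, steps) else
    data.frame(op = character(0), domain = character(0))
  list(found = TRUE, steps = steps, length = nrow(steps),
       nodes = node_ids)
}

#' Write an EDN as edge-list TSV and DOT
#'
#' @param edn An \code{edn} object.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_edn <- function(edn, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(edn$edges, file.path(dir, "edn_edges.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  nodes <- edn$nodes
  con <- file(file.path(dir, "edn.dot"), "w")
  on.exit(close(con))
  writeLines("graph EDN {", con)
  for (i in seq_len(nrow(nodes)))
    writeLines(sprintf('  "%s" [label="%s\\n(%d proteins)"];',
                       nodes$node_id[i], nodes$node_id[i],
                       nodes$n_proteins[i]), con)
  for (i in seq_len(nrow(edn$edges)))
    writeLines(sprintf('  "%s" -- "%s";', edn$edges$from[i],
                       edn$edges$to[i]), con)
  writeLines("}", con)
  invisible(dir)
}
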