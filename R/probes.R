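# Packaged inputs: the two glutamate-binding probe segments and the
# curated reference tables (annotations of the 100 dual-motif proteins,
# the Group 1/2 gene list, the human iGluR reference list, and the
# per-probe human retrieval ratios).

#' Load the S1 and S2 glutamate-binding probe sequences
#'
#' The two probes are the discontinuous halves of the extracellular
#' glutamate-binding domain of a functionally characterized cyanobacterial
#' glutamate-gated channel: S1 is 57 residues, S2 is 69 residues. They
#' seed the local-alignment screening stage.
#'
#' @return An object of class \code{probe_set}: a list with elements
#'   \code{s1} and \code{s2} (amino-acid strings).
#' @export
#' @examples
#' p <- load_probes()
#' nchar(p$s1)  # 57
load_probes <- function() {
  path <- system.file("extdata", "probes.fasta", package = "gluscreen")
  if (!nzchar(path)) stop("packaged probe file not found; corrupt installation")
  seqs <- read_fasta(path)
  if (!identical(names(seqs), c("S1", "S2")))
    stop("packaged probe file is corrupted: expected records S1 and S2")
  s1 <- unname(seqs["S1"]); s2 <- unname(seqs["S2"])
  if (nchar(s1) != 57L || nchar(s2) != 69L)
    stop("packaged probe file is corrupted: probe lengths must be 57 and 69")
  assert_protein(s1, "S1 probe", allow_x = FALSE)
  assert_protein(s2, "S2 probe", allow_x = FALSE)
  structure(list(s1 = s1, s2 = s2), class = "probe_set")
}

#' @export
print.probe_set <- function(x, ...) {
  cat("probe_set: S1 (", nchar(x$s1), " aa), S2 (", nchar(x$s2), " aa)\n",
      sep = "")
  invisible(x)
}

parse_number_list <- function(x) {
  lapply(strsplit(x, ",", fixed = TRUE),
         function(v) as.integer(trimws(v)))
}

#' Load the packaged reference tables
#'
#' Returns the curated reference tables bundled with the package:
#' \itemize{
#'   \item \code{annotation_table}: database definition-line annotation
#'     categories of the 100 dual-motif prokaryotic proteins, with the
#'     protein numbers in each category and the per-category count.
#'   \item \code{group_table}: the 22 channel-topology proteins with their
#'     Group 1 (potassium-type selectivity filter) or Group 2 (no
#'     recognized filter) assignment, description and accession.
#'   \item \code{human_iglur_table}: the 26 human iGluR reference entries
#'     (subtype, name, accession, length).
#'   \item \code{retrieval_table}: per-probe counts of human iGluR entries
#'     retrieved at E-value < 10, out of the 26-entry reference list.
#' }
#' Integrity invariants (per-row count = length of the protein-number
#' list; group labels in \{1, 2\}; protein numbers within 1..100) are
#' checked on load.
#'
#' @return An object of class \code{reference_tables} (a named list of
#'   data.frames as described above).
#' @export
load_reference_tables <- function() {
  f <- function(name) {
    p <- system.file("extdata", name, package = "gluscreen")
    if (!nzchar(p)) stop("packaged table ", name, " not found")
    read.delim(p, stringsAsFactors = FALSE)
  }
  ann <- f("annotation_categories.tsv")
  ann$protein_numbers <- parse_number_list(ann$protein_numbers)
  if (!all(vapply(ann$protein_numbers, length, 1L) == ann$quantity))
    stop("annotation table corrupted: counts do not match protein lists")
  grp <- f("channel_groups.tsv")
  if (!all(grp$group %in% c(1L, 2L)))
    stop("group table corrupted: group labels must be 1 or 2")
  if (!all(grp$protein_number %in% 1:100))
    stop("group table corrupted: protein numbers must be in 1..100")
  hum <- f("human_iglurs.tsv")
  ret <- f("retrieval_ratios.tsv")
  structure(list(annotation_table = ann, group_table = grp,
                 human_iglur_table = hum, retrieval_table = ret),
            class = "reference_tables")
}

#' @export
print.reference_tables <- function(x, ...) {
  cat("reference_tables:\n",
      "  annotation_table: ", nrow(x$annotation_table), " categories\n",
      "  group_table: ", sum(x$group_table$group == 1L), " Group 1 + ",
      sum(x$group_table$group == 2L), " Group 2 rows\n",
      "  human_iglur_table: ", nrow(x$human_iglur_table), " entries\n",
      "  retrieval_table: ", nrow(x$retrieval_table), " rows\n", sep = "")
  invisible(x)
}

#' Tally annotation categories into broad classes
#'
#' Collapses the definition-line annotation categories into the broad
#' classes used when summarizing the 100 dual-motif proteins: ABC-like
#' (any category mentioning ABC transport), binding protein (categories
#' mentioning binding but not ABC), hypothetical, and other.
#'
#' @param annotation_table The \code{annotation_table} element of
#'   \code{\link{load_reference_tables}} (or a data.frame with
#'   \code{annotation} and \code{quantity} columns).
#' @return Named integer vector with elements \code{abc_like},
#'   \code{binding_protein}, \code{hypothetical} and \code{other}.
#' @export
annotation_class_counts <- function(annotation_table) {
  ann <- annotation_table$annotation
  qty <- annotation_table$quantity
  abc <- grepl("ABC", ann)
  bind <- !abc & grepl("binding", ann, ignore.case = TRUE)
  hypo <- !abc & !bind & grepl("hypothetical", ann, ignore.case = TRUE)
  c(abc_like = sum(qty[abc]),
    binding_protein = sum(qty[bind]),
    hypothetical = sum(qty[hypo]),
    other = sum(qty[!(abc | bind | hypo)]))
}
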