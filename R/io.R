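# Readers and writers for the standard formats the pipeline consumes and
# emits. Sequence I/O goes through Biostrings, trees through ape, Clustal
# alignments through seqinr.

#' Read protein sequences from a FASTA file
#'
#' @param path Path to a (possibly gzipped) FASTA file of amino-acid
#'   sequences.
#' @return Named character vector of sequences; names are the first
#'   whitespace-delimited token of each description line.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  seqs <- as.character(x)
  names(seqs) <- sub("\\s.*$", "", names(x))
  seqs
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  x <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a taxonomy lineage table
#'
#' A lineage table is a TSV with columns \code{protein_id},
#' \code{superkingdom} and optionally \code{phylum}.
#'
#' @param path Path to the TSV file.
#' @return data.frame with at least protein_id and superkingdom columns.
#' @export
read_lineage <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "superkingdom")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("lineage table is missing columns: ", paste(miss, collapse = ", "))
  df
}

#' Read InterProScan-style domain annotations
#'
#' Expected columns: protein_id, domain_accession, start, end, evalue
#' (tab separated, with header). Malformed rows are reported with their
#' line number.
#'
#' @param path Path to the TSV file.
#' @return data.frame of annotations.
#' @export
read_domain_annotations <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "domain_accession", "start", "end", "evalue")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("domain annotation table is missing columns: ",
         paste(miss, collapse = ", "))
  bad <- which(is.na(df$protein_id) | !nzchar(df$protein_id) |
                 is.na(df$domain_accession) | !nzchar(df$domain_accession) |
                 is.na(suppressWarnings(as.numeric(df$evalue))))
  if (length(bad))
    stop("malformed domain annotation row at line ",
         bad[1L] + 1L, " of ", path)
  df$evalue <- as.numeric(df$evalue)
  df
}

#' Read a multiple sequence alignment
#'
#' @param path Path to the alignment file.
#' @param format "fasta" for aligned FASTA or "clustal" for ClustalW
#'   \code{.aln} output (the consensus-symbol line is ignored on read;
#'   sequence names must not contain whitespace).
#' @return Character matrix of single characters; rows are sequences
#'   (rownames = ids), columns are alignment columns. Gaps are "-".
#' @export
read_alignment <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (format == "fasta") {
    x <- Biostrings::readAAStringSet(path)
    seqs <- toupper(as.character(x))
    names(seqs) <- sub("\\s.*$", "", names(x))
  } else {
    lines <- readLines(path)
    if (!length(lines) || !startsWith(lines[1L], "CLUSTAL"))
      stop("not a Clustal alignment: ", path)
    lines <- lines[-1L]
    # sequence lines start with a name; consensus lines with whitespace
    lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s", lines)]
    if (!length(lines)) stop("Clustal alignment has no sequence lines")
    nm <- sub("\\s.*$", "", lines)
    chunk <- toupper(gsub("\\s", "", sub("^\\S+\\s+", "", lines)))
    chunk <- sub("[0-9]+$", "", chunk)  # optional residue counters
    ids <- unique(nm)
    seqs <- vapply(ids, function(id)
      paste(chunk[nm == id], collapse = ""), character(1L))
  }
  n <- nchar(seqs)
  if (length(unique(n)) != 1L)
    stop("alignment rows have unequal lengths")
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(m) <- names(seqs)
  m
}

#' Write a multiple sequence alignment
#'
#' @param aln Character matrix as returned by \code{\link{read_alignment}}.
#' @param path Output path.
#' @param format "fasta" or "clustal". Clustal output regenerates the
#'   ClustalW consensus-symbol line ("*", ":", ".") from the columns.
#' @return \code{path}, invisibly.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  seqs <- apply(aln, 1L, paste, collapse = "")
  if (format == "fasta") return(write_fasta(seqs, path))
  ids <- rownames(aln) %||% paste0("seq", seq_len(nrow(aln)))
  wid <- max(nchar(ids)) + 3L
  cons <- vapply(seq_len(ncol(aln)), function(j) {
    cls <- classify_column(aln[, j])
    switch(cls, identical = "*", strong = ":", weak = ".", " ")
  }, character(1L))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("CLUSTAL W multiple sequence alignment (gluscreen)", con)
  writeLines("", con)
  for (off in seq(1L, ncol(aln), by = 60L)) {
    to <- min(off + 59L, ncol(aln))
    for (i in seq_len(nrow(aln)))
      writeLines(sprintf("%-*s%s", wid, ids[i],
                         substr(seqs[i], off, to)), con)
    writeLines(sprintf("%-*s%s", wid, "",
                       paste(cons[off:to], collapse = "")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read a Newick tree
#' @param path Path to a Newick file.
#' @return An \code{ape} \code{phylo} object.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Write a Newick tree
#' @param tree A \code{phylo} object.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
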