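# A small progressive multiple aligner for synthetic tests: pairwise
# global (Needleman-Wunsch) alignments, a UPGMA guide tree on pairwise
# distances, and profile merging via majority-consensus alignment. It is
# NOT an authoritative aligner; real analyses should supply alignments
# produced by a dedicated MSA tool (aligned FASTA or Clustal input is
# supported by read_alignment()).

msa_consensus <- function(m) {
  apply(m, 2L, function(col) {
    col <- col[col != "-"]
    if (!length(col)) return("A")  # all-gap column: neutral placeholder
    names(sort(table(col), decreasing = TRUE))[1L]
  })
}

# Insert gap columns into alignment matrix m so that its consensus
# follows the gapped pattern `aligned` (characters + "-").
expand_alignment <- function(m, aligned) {
  out <- matrix("-", nrow(m), length(aligned),
                dimnames = list(rownames(m), NULL))
  j <- 0L
  for (k in seq_along(aligned)) {
    if (aligned[k] != "-") {
      j <- j + 1L
      out[, k] <- m[, j]
    }
  }
  stopifnot(j == ncol(m))
  out
}

#' Progressive multiple sequence alignment (non-authoritative)
#'
#' Aligns sequences progressively along a UPGMA guide tree built from
#' pairwise global-alignment distances; profiles are merged by globally
#' aligning their majority-consensus sequences and propagating the gaps.
#' Provided so synthetic benchmarks are self-contained; for real data use
#' a dedicated MSA tool and \code{\link{read_alignment}}.
#'
#' @param seqs Named character vector of sequences (>= 1).
#' @param params A \code{\link{scoring_params}} for the pairwise steps.
#' @return Character matrix (rows = sequences, rownames = ids).
#' @export
align_msa <- function(seqs, params = scoring_params()) {
  stopifnot(length(seqs) >= 1L, !is.null(names(seqs)))
  mats <- lapply(seq_along(seqs), function(i) {
    matrix(seq_chars(seqs[[i]]), nrow = 1L,
           dimnames = list(names(seqs)[i], NULL))
  })
  n <- length(seqs)
  if (n == 1L) return(mats[[1L]])

  nw <- function(a, b) .nw_align(a, b, params$matrix, params$gap_open,
                                 params$gap_extend)
  # guide tree from normalized alignment distance
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    al <- nw(seqs[[i]], seqs[[j]])
    qa <- seq_chars(al$aligned_query); sa <- seq_chars(al$aligned_subject)
    cmp <- qa != "-" & sa != "-"
    d[i, j] <- d[j, i] <- if (any(cmp)) mean(qa[cmp] != sa[cmp]) else 1
  }
  hc <- hclust(as.dist(d), method = "average")

  merge_profiles <- function(a, b) {
    al <- nw(paste(msa_consensus(a), collapse = ""),
             paste(msa_consensus(b), collapse = ""))
    rbind(expand_alignment(a, seq_chars(al$aligned_query)),
          expand_alignment(b, seq_chars(al$aligned_subject)))
  }
  nodes <- vector("list", nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    pick <- function(x) if (x < 0) mats[[-x]] else nodes[[x]]
    nodes[[k]] <- merge_profiles(pick(hc$merge[k, 1L]),
                                 pick(hc$merge[k, 2L]))
  }
  res <- nodes[[nrow(hc$merge)]]
  res[names(seqs), , drop = FALSE]
}
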