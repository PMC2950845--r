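# Probe-based local-alignment search: Smith-Waterman with affine gaps and
# Karlin-Altschul E-values. This is a deterministic, self-contained
# single-pass search; the default lambda/kappa are the standard gapped
# BLOSUM62 (gap open 11, extend 1) calibration constants.

#' Scoring parameters for local-alignment screening
#'
#' @param matrix Substitution matrix: the name "BLOSUM62" or a square
#'   numeric matrix with residue dimnames.
#' @param gap_open Gap opening penalty (a gap of length L costs
#'   \code{gap_open + L * gap_extend}).
#' @param gap_extend Gap extension penalty per residue.
#' @param lambda Karlin-Altschul scale parameter (> 0).
#' @param kappa Karlin-Altschul prefactor (> 0).
#' @param evalue_threshold E-value cutoff for reported hits.
#' @return Object of class \code{scoring_params}.
#' @export
scoring_params <- function(matrix = "BLOSUM62", gap_open = 11,
                           gap_extend = 1, lambda = 0.267, kappa = 0.041,
                           evalue_threshold = 10) {
  if (is.character(matrix)) {
    matrix <- switch(toupper(matrix),
                     BLOSUM62 = blosum62(),
                     stop("unknown substitution matrix name: ", matrix))
  }
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix),
            !is.null(rownames(matrix)),
            identical(rownames(matrix), colnames(matrix)),
            gap_open > 0, gap_extend > 0, lambda > 0, kappa > 0,
            evalue_threshold > 0)
  storage.mode(matrix) <- "double"
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, kappa = kappa,
                 evalue_threshold = evalue_threshold),
            class = "scoring_params")
}

#' Optimal local alignment of two sequences
#'
#' Smith-Waterman local alignment with affine gaps. The traceback is
#' deterministic: on ties the diagonal move is preferred, then the move
#' consuming a query residue, then the move consuming a subject residue.
#' Residues absent from the substitution matrix (e.g. X) score 0 against
#' everything.
#'
#' @param query,subject Amino-acid strings (non-empty).
#' @param params A \code{\link{scoring_params}}.
#' @return List of class \code{alignment_hit} with elements \code{score}
#'   (non-negative), \code{query_interval} and \code{subject_interval}
#'   (0-based half-open integer pairs; empty \code{c(0, 0)} when the best
#'   score is 0).
#' @export
smith_waterman <- function(query, subject, params = scoring_params()) {
  assert_protein(query, "query")
  assert_protein(subject, "subject")
  r <- .sw_align(query, subject, params$matrix, params$gap_open,
                 params$gap_extend)
  structure(list(score = r$score,
                 query_interval = c(r$query_start, r$query_end),
                 subject_interval = c(r$subject_start, r$subject_end)),
            class = "alignment_hit")
}

#' Karlin-Altschul E-value for a raw alignment score
#'
#' E = kappa * m * n * exp(-lambda * score): the expected number of
#' chance local alignments scoring at least \code{raw_score} between a
#' random query of length m and a random database of total length n.
#' Strictly decreasing in the score, linear in m and n.
#'
#' @param raw_score Raw alignment score (>= 0).
#' @param m Query length.
#' @param n Database length (total residues searched).
#' @param params A \code{\link{scoring_params}}.
#' @return The E-value (positive numeric).
#' @export
estimate_evalue <- function(raw_score, m, n, params = scoring_params()) {
  stopifnot(m > 0, n > 0, raw_score >= 0)
  params$kappa * m * n * exp(-params$lambda * raw_score)
}

#' Screen a probe against a sequence database
#'
#' Aligns the probe to every database sequence and reports all hits with
#' E-value below the threshold, sorted by ascending E-value with ties
#' broken by protein id. Following the BLAST convention, the database
#' length n used in the E-value is the total number of residues in the
#' database (overridable via \code{db_length}).
#'
#' @param probe Probe amino-acid string.
#' @param db Named character vector of database sequences.
#' @param params A \code{\link{scoring_params}}.
#' @param probe_label Label recorded in the \code{probe} column (e.g.
#'   "S1").
#' @param db_length Database length for E-values; default is the total
#'   residue count of \code{db}.
#' @return data.frame: protein_id, probe, score, evalue, subject_start,
#'   subject_end, query_start, query_end (0-based half-open).
#' @export
screen_probe <- function(probe, db, params = scoring_params(),
                         probe_label = "probe", db_length = NULL) {
  if (!length(db)) stop("database is empty")
  if (is.null(names(db)) || anyNA(names(db)) || !all(nzchar(names(db))))
    stop("database sequences must be named")
  n <- db_length %||% sum(nchar(db))
  m <- nchar(probe)
  rows <- vector("list", length(db))
  for (i in seq_along(db)) {
    h <- smith_waterman(probe, db[[i]], params)
    e <- estimate_evalue(h$score, m, n, params)
    if (e < params$evalue_threshold)
      rows[[i]] <- data.frame(protein_id = names(db)[i],
                              probe = probe_label,
                              score = h$score, evalue = e,
                              subject_start = h$subject_interval[1L],
                              subject_end = h$subject_interval[2L],
                              query_start = h$query_interval[1L],
                              query_end = h$query_interval[2L],
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(protein_id = character(0), probe = character(0),
                      score = numeric(0), evalue = numeric(0),
                      subject_start = integer(0), subject_end = integer(0),
                      query_start = integer(0), query_end = integer(0))
  out[order(out$evalue, out$protein_id), , drop = FALSE]
}
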