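# Orthology by reciprocal best hits and probe retrieval ratios against a
# reference list, both built on the package's local-alignment search.

# Best hit of `query` among `db`: lowest E-value, ties broken by higher
# raw score then lexicographic id. Returns NULL when nothing clears the
# E-value threshold.
best_db_hit <- function(query, db, params, db_length) {
  m <- nchar(query)
  best <- NULL
  for (id in sort(names(db))) {
    h <- smith_waterman(query, db[[id]], params)
    e <- estimate_evalue(h$score, m, db_length, params)
    if (e >= params$evalue_threshold) next
    if (is.null(best) || e < best$evalue ||
        (e == best$evalue && h$score > best$score))
      best <- list(id = id, score = h$score, evalue = e)
  }
  best
}

#' Reciprocal-best-hit orthologs between two proteomes
#'
#' A pair (a, b) is reported when b is a's best hit in proteome B and a
#' is b's best hit in proteome A (best = lowest E-value, ties broken by
#' highest raw score then lexicographic id; hits must clear the E-value
#' threshold in both directions). Swapping the proteome arguments
#' transposes the pairs.
#'
#' @param proteome_a,proteome_b Named character vectors of sequences.
#' @param params A \code{\link{scoring_params}}.
#' @return Object of class \code{ortholog_report}: data.frame with
#'   columns id_a, id_b, evalue_ab, evalue_ba.
#' @export
reciprocal_best_hits <- function(proteome_a, proteome_b,
                                 params = scoring_params()) {
  stopifnot(length(proteome_a) > 0, length(proteome_b) > 0)
  n_a <- sum(nchar(proteome_a)); n_b <- sum(nchar(proteome_b))
  fwd <- lapply(proteome_a, best_db_hit, db = proteome_b, params = params,
                db_length = n_b)
  rev <- lapply(proteome_b, best_db_hit, db = proteome_a, params = params,
                db_length = n_a)
  rows <- list()
  for (a in sort(names(proteome_a))) {
    f <- fwd[[a]]
    if (is.null(f)) next
    r <- rev[[f$id]]
    if (!is.null(r) && r$id == a)
      rows[[length(rows) + 1L]] <- data.frame(
        id_a = a, id_b = f$id, evalue_ab = f$evalue, evalue_ba = r$evalue,
        stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id_a = character(0), id_b = character(0),
               evalue_ab = numeric(0), evalue_ba = numeric(0))
  class(out) <- c("ortholog_report", class(out))
  out
}

#' Retrieval ratio of a probe against a reference list
#'
#' The fraction of reference entries hit by the probe at
#' E < \code{params$evalue_threshold} (default threshold 10), reported
#' with numerator and denominator. The E-value uses the total residue
#' count of the reference as the database length.
#'
#' @param probe Amino-acid string.
#' @param reference Named character vector of reference sequences.
#' @param params A \code{\link{scoring_params}}.
#' @return List with \code{hits}, \code{reference_size} and \code{ratio}.
#' @export
retrieval_ratio <- function(probe, reference, params = scoring_params()) {
  stopifnot(length(reference) > 0)
  n <- sum(nchar(reference))
  m <- nchar(probe)
  k <- 0L
  for (id in names(reference)) {
    h <- smith_waterman(probe, reference[[id]], params)
    if (estimate_evalue(h$score, m, n, params) < params$evalue_threshold)
      k <- k + 1L
  }
  list(hits = k, reference_size = length(reference),
       ratio = k / length(reference))
}
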