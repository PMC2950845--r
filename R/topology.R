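# Stage 5 and validation: order the annotated regions, find the
# re-entrant pore-loop between the two TM helices, classify the canonical
# channel topology (S1 - M1 - P - M2 - S2), assign Group 1/2 by the
# potassium-channel selectivity filter, and check for signal peptides.

#' Detect the pore-loop between two TM helices
#'
#' The pore-loop presents as a partial-helix hydropathy signal: a
#' sub-threshold candidate segment (see
#' \code{\link{predict_tm_segments}}) whose probability score lies in
#' \code{[p_lo, 0.5)} and whose core falls strictly between the cores of
#' the two flanking TM helices. The highest-scoring such candidate is
#' returned.
#'
#' @param tm_segments Segment data.frame from
#'   \code{\link{predict_tm_segments}} (must contain at least two passing
#'   segments).
#' @param m1,m2 Optional single-row data.frames selecting the flanking
#'   TMs; default the first two passing segments by position.
#' @param p_lo Minimum probability score of a candidate.
#' @return One-row data.frame (region_type, start, end, score) with the
#'   pore-loop core interval, or NULL when no candidate qualifies.
#' @export
detect_pore_loop <- function(tm_segments, m1 = NULL, m2 = NULL,
                             p_lo = 0.25) {
  pass <- tm_segments[tm_segments$passes_test, , drop = FALSE]
  if (nrow(pass) < 2L)
    stop("pore-loop detection requires at least two passing TM segments")
  if (is.null(m1)) m1 <- pass[1L, ]
  if (is.null(m2)) m2 <- pass[2L, ]
  cand <- tm_segments[!tm_segments$passes_test &
                        tm_segments$probability_score >= p_lo &
                        tm_segments$core_start >= m1$core_end &
                        tm_segments$core_end <= m2$core_start, ,
                      drop = FALSE]
  if (!nrow(cand)) return(NULL)
  cand <- cand[order(-cand$probability_score, cand$core_start), ,
               drop = FALSE]
  data.frame(region_type = "P", start = cand$core_start[1L],
             end = cand$core_end[1L], score = cand$probability_score[1L],
             stringsAsFactors = FALSE)
}

#' Detect the potassium-channel selectivity-filter motif
#'
#' Matches the canonical K-channel selectivity-filter signature in a
#' pore-loop sequence: the class pattern [TS]-x-[GA]-[YF]-G, with a
#' fallback acceptance of the bare G-[YF]-G core. Both patterns are
#' configurable.
#'
#' @param pore_sequence Amino-acid string of the pore region.
#' @param pattern Primary regular expression.
#' @param fallback Fallback regular expression (NULL to disable).
#' @return Logical flag.
#' @export
#' @examples
#' detect_k_filter("ILTVGYGLI")  # TRUE
#' detect_k_filter("AAAAA")      # FALSE
detect_k_filter <- function(pore_sequence, pattern = "[TS].[GA][YF]G",
                            fallback = "G[YF]G") {
  if (!nzchar(pore_sequence)) return(FALSE)
  grepl(pattern, pore_sequence) ||
    (!is.null(fallback) && grepl(fallback, pore_sequence))
}

as_interval <- function(x) {
  if (is.data.frame(x)) c(x$start[1L], x$end[1L])
  else if (is.list(x) && !is.null(x$subject_interval)) x$subject_interval
  else as.numeric(x[1:2])
}

#' Classify the channel topology of a screened protein
#'
#' A protein has the channel topology when the regions occur in the
#' canonical order: end(S1) <= start(M1) < end(M1) <= start(P) <
#' end(P) <= start(M2) < end(M2) <= start(S2), where M1/M2 are passing TM
#' segments (their core extents are used) and P is a sub-threshold
#' pore-loop candidate between them. With more than two passing TM
#' segments between S1 and S2 (homologous eukaryotic channels carry an
#' extra C-terminal TM, so extras must not break classification), every
#' consecutive pair is tried and the pair enclosing the best-scoring
#' pore-loop is chosen.
#'
#' @param protein_id Identifier recorded in the profile.
#' @param seq The protein sequence (used to extract the pore-loop
#'   sequence and to test for a signal peptide).
#' @param s1,s2 S1/S2 hit intervals: numeric \code{c(start, end)}
#'   (0-based half-open), a one-row hit data.frame, or an
#'   \code{alignment_hit}.
#' @param tm_segments Segment data.frame from
#'   \code{\link{predict_tm_segments}}.
#' @param pore Optional pre-computed pore-loop row (from
#'   \code{\link{detect_pore_loop}}); by default the pore is searched
#'   between candidate TM pairs.
#' @param p_lo Pore-loop probability floor.
#' @return Object of class \code{topology_profile}: list with
#'   \code{protein_id}, \code{regions} (data.frame: region_type, name,
#'   start, end, score), \code{is_channel}, \code{group} (NA until
#'   \code{\link{assign_groups}}), \code{has_signal_peptide},
#'   \code{pore_seq}.
#' @export
classify_topology <- function(protein_id, seq, s1, s2, tm_segments,
                              pore = NULL, p_lo = 0.25) {
  s1i <- as_interval(s1); s2i <- as_interval(s2)
  if (intervals_overlap(s1i[1L], s1i[2L], s2i[1L], s2i[2L]))
    stop("S1 and S2 hit intervals overlap for protein ", protein_id)
  swapped <- s1i[1L] > s2i[1L]

  has_sig <- if (nchar(seq) >= 30L) detect_signal_peptide(seq) else FALSE

  pass <- tm_segments[tm_segments$passes_test, , drop = FALSE]
  pass <- pass[order(pass$core_start), , drop = FALSE]
  inner <- pass[pass$core_start >= s1i[2L] & pass$core_end <= s2i[1L], ,
                drop = FALSE]

  m1 <- m2 <- p <- NULL
  if (!swapped && nrow(inner) >= 2L) {
    if (!is.null(pore)) {
      m1 <- inner[1L, ]; m2 <- inner[2L, ]; p <- pore
    } else {
      best <- -Inf
      for (k in seq_len(nrow(inner) - 1L)) {
        cand <- detect_pore_loop(tm_segments, inner[k, ], inner[k + 1L, ],
                                 p_lo = p_lo)
        if (!is.null(cand) && cand$score > best) {
          best <- cand$score
          m1 <- inner[k, ]; m2 <- inner[k + 1L, ]; p <- cand
        }
      }
    }
  }

  is_channel <- !swapped && !is.null(p) &&
    s1i[2L] <= m1$core_start && m1$core_start < m1$core_end &&
    m1$core_end <= p$start && p$start < p$end &&
    p$end <= m2$core_start && m2$core_start < m2$core_end &&
    m2$core_end <= s2i[1L]

  regions <- data.frame(region_type = c("S1", "S2"),
                        name = c("S1", "S2"),
                        start = c(s1i[1L], s2i[1L]),
                        end = c(s1i[2L], s2i[2L]),
                        score = NA_real_, stringsAsFactors = FALSE)
  pore_seq <- ""
  if (is_channel) {
    regions <- rbind(regions,
                     data.frame(region_type = c("TM", "P", "TM"),
                                name = c("M1", "P", "M2"),
                                start = c(m1$core_start, p$start,
                                          m2$core_start),
                                end = c(m1$core_end, p$end, m2$core_end),
                                score = c(m1$probability_score, p$score,
                                          m2$probability_score),
                                stringsAsFactors = FALSE))
    pore_seq <- substr(seq, p$start + 1L, p$end)
  }
  regions <- regions[order(regions$start), , drop = FALSE]
  rownames(regions) <- NULL
  structure(list(protein_id = protein_id, regions = regions,
                 is_channel = is_channel, group = NA_integer_,
                 has_signal_peptide = has_sig, pore_seq = pore_seq,
                 suggested_annotation = NA_character_),
            class = "topology_profile")
}

#' @export
print.topology_profile <- function(x, ...) {
  cat("topology_profile ", x$protein_id, ": ",
      if (x$is_channel) "channel" else "non-channel",
      if (!is.na(x$group)) paste0(" (group ", x$group, ")") else "",
      if (x$has_signal_peptide) ", signal peptide" else "", "\n", sep = "")
  invisible(x)
}

#' Assign channel profiles to Group 1 / Group 2
#'
#' Group 1: channel topology with a potassium-type selectivity filter in
#' the pore-loop (suggested annotation "putative glutamate-sensitive
#' potassium channel"). Group 2: channel topology without a recognized
#' filter ("putative glutamate-sensitive ion channel"). Non-channels get
#' no group.
#'
#' @param profiles List of \code{topology_profile} objects (or a single
#'   one).
#' @param pattern,fallback Selectivity-filter patterns (see
#'   \code{\link{detect_k_filter}}).
#' @return The profiles with \code{group} and \code{suggested_annotation}
#'   filled in.
#' @export
assign_groups <- function(profiles, pattern = "[TS].[GA][YF]G",
                          fallback = "G[YF]G") {
  single <- inherits(profiles, "topology_profile")
  if (single) profiles <- list(profiles)
  profiles <- lapply(profiles, function(p) {
    if (isTRUE(p$is_channel)) {
      if (detect_k_filter(p$pore_seq, pattern, fallback)) {
        p$group <- 1L
        p$suggested_annotation <-
          "putative glutamate-sensitive potassium channel"
      } else {
        p$group <- 2L
        p$suggested_annotation <- "putative glutamate-sensitive ion channel"
      }
    } else {
      p$group <- NA_integer_
      p$suggested_annotation <- NA_character_
    }
    p
  })
  if (single) profiles[[1L]] else profiles
}

#' Classify all stage-4 survivors of a screen
#'
#' Convenience wrapper running \code{\link{classify_topology}} and
#' \code{\link{assign_groups}} over every protein that survived stage 4,
#' using each probe's best hit interval and the cached TM segments.
#'
#' @param db Named character vector of sequences.
#' @param screen A \code{screen_result}.
#' @param p_lo Pore-loop probability floor.
#' @param pattern,fallback Selectivity-filter patterns.
#' @return List with \code{profiles} (list of topology_profile) and
#'   \code{table} (data.frame: protein_id, is_channel, group,
#'   has_signal_peptide, suggested_annotation).
#' @export
classify_screen_hits <- function(db, screen, p_lo = 0.25,
                                 pattern = "[TS].[GA][YF]G",
                                 fallback = "G[YF]G") {
  ids <- screen$stages$stage4_both
  profiles <- lapply(ids, function(id) {
    h1 <- best_hit(screen, id, "S1")
    h2 <- best_hit(screen, id, "S2")
    classify_topology(id, db[[id]],
                      c(h1$subject_start, h1$subject_end),
                      c(h2$subject_start, h2$subject_end),
                      screen$tm_segments[[id]], p_lo = p_lo)
  })
  profiles <- assign_groups(profiles, pattern, fallback)
  tab <- do.call(rbind, lapply(profiles, function(p)
    data.frame(protein_id = p$protein_id, is_channel = p$is_channel,
               group = p$group, has_signal_peptide = p$has_signal_peptide,
               suggested_annotation = p$suggested_annotation,
               stringsAsFactors = FALSE)))
  if (is.null(tab))
    tab <- data.frame(protein_id = character(0), is_channel = logical(0),
                      group = integer(0), has_signal_peptide = logical(0),
                      suggested_annotation = character(0))
  list(profiles = profiles, table = tab)
}
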