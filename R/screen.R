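# The five-stage screening cascade: probe hits with E-values (stage 1),
# minimum TM count (stage 2), prokaryote filter (stage 3), S1-and-S2
# intersection (stage 4). Stage 5 (topology) lives in topology.R.

normalize_taxonomy <- function(taxonomy) {
  if (is.data.frame(taxonomy)) {
    if (!all(c("protein_id", "superkingdom") %in% names(taxonomy)))
      stop("taxonomy must have protein_id and superkingdom columns")
    return(setNames(taxonomy$superkingdom, taxonomy$protein_id))
  }
  if (is.character(taxonomy) && !is.null(names(taxonomy))) return(taxonomy)
  stop("taxonomy must be a data.frame or a named character vector")
}

#' Run the staged probe screen over a protein database
#'
#' Stage 1 reports all sequences hit by each probe at
#' E < \code{params$evalue_threshold}. Stage 2 eliminates sequences with
#' fewer than \code{min_tm} passing TM segments. Stage 3 keeps
#' prokaryotes (superkingdom Bacteria or Archaea); a stage-2 survivor
#' with no lineage entry is an error naming the protein. Stage 4 keeps
#' sequences hit by both probes. Survivor sets are nested within each
#' probe across stages.
#'
#' @param db Named character vector of protein sequences.
#' @param taxonomy data.frame (protein_id, superkingdom, ...) or named
#'   character vector mapping protein ids to superkingdoms.
#' @param params A \code{\link{scoring_params}}.
#' @param probes A \code{probe_set} (defaults to the packaged probes).
#' @param min_tm Minimum number of passing TM segments (default 2).
#' @param tm_window,tm_threshold,p_lo TM predictor settings (see
#'   \code{\link{predict_tm_segments}}).
#' @return Object of class \code{screen_result}: list with \code{hits}
#'   (data.frame over both probes), \code{tm_segments} (named list of
#'   per-protein segment data.frames for stage-1 survivors),
#'   \code{stages} (named list of survivor id vectors: stage1_s1,
#'   stage1_s2, stage2_s1, stage2_s2, stage3_s1, stage3_s2, stage4_both)
#'   and \code{counts} (named integer vector of the same keys).
#' @export
run_screen <- function(db, taxonomy, params = scoring_params(),
                       probes = load_probes(), min_tm = 2L,
                       tm_window = 19L, tm_threshold = 1.6, p_lo = 0.25) {
  if (!length(db)) stop("input database is empty")
  lineage <- normalize_taxonomy(taxonomy)

  hits_s1 <- screen_probe(probes$s1, db, params, probe_label = "S1")
  hits_s2 <- screen_probe(probes$s2, db, params, probe_label = "S2")
  stage1 <- list(S1 = hits_s1$protein_id, S2 = hits_s2$protein_id)

  surv1 <- union(stage1$S1, stage1$S2)
  tm <- lapply(db[surv1], predict_tm_segments, window = tm_window,
               threshold = tm_threshold, p_lo = p_lo)
  n_pass <- vapply(tm, function(x) sum(x$passes_test), integer(1L))

  stage2 <- lapply(stage1, function(ids) ids[n_pass[ids] >= min_tm])

  stage3 <- lapply(stage2, function(ids) {
    if (!length(ids)) return(ids)
    miss <- ids[!(ids %in% names(lineage))]
    if (length(miss))
      stop("no taxonomy lineage for surviving protein(s): ",
           paste(miss, collapse = ", "))
    ids[lineage[ids] %in% c("Bacteria", "Archaea")]
  })

  stage4 <- intersect(stage3$S1, stage3$S2)

  stages <- list(stage1_s1 = stage1$S1, stage1_s2 = stage1$S2,
                 stage2_s1 = stage2$S1, stage2_s2 = stage2$S2,
                 stage3_s1 = stage3$S1, stage3_s2 = stage3$S2,
                 stage4_both = stage4)
  structure(list(hits = rbind(hits_s1, hits_s2),
                 tm_segments = tm,
                 stages = stages,
                 counts = vapply(stages, length, integer(1L)),
                 settings = list(min_tm = min_tm, tm_window = tm_window,
                                 tm_threshold = tm_threshold, p_lo = p_lo,
                                 evalue_threshold = params$evalue_threshold)),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("screen_result stage counts:\n")
  print(x$counts)
  invisible(x)
}

# Best (lowest-E) hit of a given probe for a given protein, or NULL.
best_hit <- function(screen_result, protein_id, probe) {
  h <- screen_result$hits
  h <- h[h$protein_id == protein_id & h$probe == probe, , drop = FALSE]
  if (!nrow(h)) return(NULL)
  h[order(h$evalue, -h$score), , drop = FALSE][1L, ]
}
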