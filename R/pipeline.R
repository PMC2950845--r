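# End-to-end orchestration: screen -> classify -> (optional) EDN ->
# conservation -> region trees -> (optional) orthology, with every
# intermediate written in a plain-text format and a machine-readable
# run report.

#' Pipeline configuration
#'
#' @param input_fasta Path to the protein FASTA to screen.
#' @param taxonomy_tsv Path to the lineage TSV (protein_id,
#'   superkingdom, phylum).
#' @param out_dir Output directory.
#' @param domain_tsv Optional InterProScan-style domain TSV; enables the
#'   EDN stage.
#' @param reference_fasta Optional reference proteome FASTA; enables
#'   retrieval ratios and reciprocal-best-hit orthology for the detected
#'   channels.
#' @param probes "packaged" or a path to a FASTA with records S1 and S2.
#' @param evalue Screening E-value threshold.
#' @param min_tm Minimum passing TM segments at stage 2.
#' @param tm_window,tm_threshold TM predictor window and threshold.
#' @param p_lo Pore-loop probability floor.
#' @param k_filter_pattern,k_filter_fallback Selectivity-filter patterns.
#' @param domain_evalue Domain annotation E-value cutoff for the EDN.
#' @param seed Seed recorded in the report (the pipeline itself is
#'   deterministic).
#' @return Object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(input_fasta, taxonomy_tsv, out_dir,
                            domain_tsv = NULL, reference_fasta = NULL,
                            probes = "packaged", evalue = 10,
                            min_tm = 2L, tm_window = 19L,
                            tm_threshold = 1.6, p_lo = 0.25,
                            k_filter_pattern = "[TS].[GA][YF]G",
                            k_filter_fallback = "G[YF]G",
                            domain_evalue = 1e-3, seed = 1L) {
  stopifnot(evalue > 0, min_tm >= 0, tm_window >= 7, tm_threshold > 0,
            p_lo > 0, domain_evalue > 0)
  structure(list(input_fasta = input_fasta, taxonomy_tsv = taxonomy_tsv,
                 out_dir = out_dir, domain_tsv = domain_tsv,
                 reference_fasta = reference_fasta, probes = probes,
                 evalue = evalue, min_tm = as.integer(min_tm),
                 tm_window = as.integer(tm_window),
                 tm_threshold = tm_threshold, p_lo = p_lo,
                 k_filter_pattern = k_filter_pattern,
                 k_filter_fallback = k_filter_fallback,
                 domain_evalue = domain_evalue, seed = as.integer(seed)),
            class = "pipeline_config")
}

stage_log <- function(stage, n_in, n_out, t0) {
  message(sprintf("[%s] in=%s out=%s elapsed=%.2fs", stage,
                  n_in, n_out, as.numeric(proc.time()[3L]) - t0))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full discovery pipeline
#'
#' Executes screen, topology classification and group assignment, then
#' (when inputs allow) the Evolutionary Domain Network, region-wise
#' conservation summaries, region trees with congruence statistics, and
#' reference-proteome orthology. Every intermediate is written as
#' TSV/FASTA/Newick under the configured output directory along with a
#' \code{report.json}. The run is deterministic for a given
#' configuration.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return Object of class \code{run_report} (also serialized to
#'   \code{report.json}).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (f in c(config$input_fasta, config$taxonomy_tsv, config$domain_tsv,
              config$reference_fasta))
    if (!is.null(f) && !file.exists(f)) stop("input file not found: ", f)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- as.numeric(proc.time()[3L])

  db <- read_fasta(config$input_fasta)
  if (!length(db)) stop("stage screen: input FASTA is empty")
  taxonomy <- read_lineage(config$taxonomy_tsv)
  probes <- if (identical(config$probes, "packaged")) load_probes() else {
    p <- read_fasta(config$probes)
    structure(list(s1 = unname(p[["S1"]]), s2 = unname(p[["S2"]])),
              class = "probe_set")
  }
  params <- scoring_params(evalue_threshold = config$evalue)

  screen <- run_screen(db, taxonomy, params, probes,
                       min_tm = config$min_tm,
                       tm_window = config$tm_window,
                       tm_threshold = config$tm_threshold,
                       p_lo = config$p_lo)
  write_tsv(screen$hits, file.path(config$out_dir, "screen_hits.tsv"))
  stage_log("screen", length(db), screen$counts[["stage4_both"]], t0)

  cls <- classify_screen_hits(db, screen, p_lo = config$p_lo,
                              pattern = config$k_filter_pattern,
                              fallback = config$k_filter_fallback)
  write_tsv(cls$table, file.path(config$out_dir, "classification.tsv"))
  regions <- do.call(rbind, lapply(cls$profiles, function(p)
    cbind(protein_id = p$protein_id, p$regions)))
  if (!is.null(regions))
    write_tsv(regions, file.path(config$out_dir, "topology_regions.tsv"))
  channels <- cls$table[cls$table$is_channel, , drop = FALSE]
  stage_log("classify", length(screen$stages$stage4_both), nrow(channels),
            t0)

  edn_stats <- NULL
  if (!is.null(config$domain_tsv)) {
    comp <- compose_domains(config$domain_tsv,
                            evalue_max = config$domain_evalue)
    net <- build_edn(comp)
    write_edn(net, config$out_dir)
    edn_stats <- list(nodes = nrow(net$nodes), edges = nrow(net$edges),
                      components = length(edn_components(net)))
    stage_log("edn", length(comp), edn_stats$nodes, t0)
  }

  conservation <- NULL
  trees <- NULL
  if (nrow(channels) >= 3L) {
    region_seq <- function(p, what) {
      r <- p$regions
      if (what == "channel") {
        i <- which(r$name == "M1"); j <- which(r$name == "M2")
        substr(db[[p$protein_id]], r$start[i] + 1L, r$end[j])
      } else {
        i <- which(r$name == what)
        substr(db[[p$protein_id]], r$start[i] + 1L, r$end[i])
      }
    }
    chan_profiles <- cls$profiles[vapply(cls$profiles,
                                         function(p) p$is_channel, TRUE)]
    alns <- lapply(c(S1 = "S1", channel = "channel", S2 = "S2"),
                   function(w) {
      s <- vapply(chan_profiles, region_seq, character(1L), what = w)
      names(s) <- vapply(chan_profiles, `[[`, character(1L), "protein_id")
      align_msa(s, params)
    })
    joined <- join_alignments(alns)
    conservation <- summarize_conservation(joined)
    write_tsv(conservation,
              file.path(config$out_dir, "conservation.tsv"))
    if (nrow(channels) >= 4L) {
      cong <- region_tree_congruence(alns)
      for (nm in names(cong$trees))
        write_newick(cong$trees[[nm]],
                     file.path(config$out_dir,
                               paste0("tree_", nm, ".nwk")))
      trees <- list(files = paste0("tree_", names(cong$trees), ".nwk"),
                    rf = cong$rf)
      write_tsv(as.data.frame(cong$rf),
                file.path(config$out_dir, "region_tree_rf.tsv"))
    }
    stage_log("conservation", nrow(channels), nrow(conservation), t0)
  }

  orthologs <- NULL
  retrieval <- NULL
  if (!is.null(config$reference_fasta) && nrow(channels) > 0L) {
    ref <- read_fasta(config$reference_fasta)
    chan_seqs <- db[channels$protein_id]
    orthologs <- reciprocal_best_hits(chan_seqs, ref, params)
    write_tsv(as.data.frame(orthologs),
              file.path(config$out_dir, "orthologs.tsv"))
    retrieval <- do.call(rbind, lapply(channels$protein_id, function(id) {
      r <- retrieval_ratio(db[[id]], ref, params)
      data.frame(protein_id = id, hits = r$hits,
                 reference_size = r$reference_size, ratio = r$ratio,
                 stringsAsFactors = FALSE)
    }))
    write_tsv(retrieval, file.path(config$out_dir, "retrieval_ratios.tsv"))
    stage_log("orthologs", nrow(channels), nrow(orthologs), t0)
  }

  report <- structure(list(
    tool = list(package = "gluscreen",
                version = as.character(utils::packageVersion("gluscreen"))),
    config = unclass(config),
    stage_counts = as.list(screen$counts),
    channels = channels,
    n_group1 = sum(channels$group == 1L, na.rm = TRUE),
    n_group2 = sum(channels$group == 2L, na.rm = TRUE),
    edn = edn_stats,
    conservation = conservation,
    trees = if (!is.null(trees))
      list(files = trees$files, rf = as.data.frame(trees$rf)) else NULL,
    orthologs = if (!is.null(orthologs)) as.data.frame(orthologs) else NULL,
    retrieval = retrieval), class = "run_report")
  validate_report(report)
  jsonlite::write_json(unclass(report),
                       file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  report
}

# Internal consistency checks on a run report: monotone stage counts and
# group tallies summing to the channel count.
validate_report <- function(report) {
  sc <- report$stage_counts
  ok <- sc$stage2_s1 <= sc$stage1_s1 && sc$stage2_s2 <= sc$stage1_s2 &&
    sc$stage3_s1 <= sc$stage2_s1 && sc$stage3_s2 <= sc$stage2_s2 &&
    sc$stage4_both <= min(sc$stage3_s1, sc$stage3_s2)
  if (!ok) stop("report validation failed: stage counts are not monotone")
  if (report$n_group1 + report$n_group2 != nrow(report$channels))
    stop("report validation failed: group1 + group2 != channels")
  invisible(TRUE)
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report:\n  stage counts:",
      paste(sprintf("%s=%d", names(x$stage_counts),
                    unlist(x$stage_counts)), collapse = " "),
      "\n  channels:", nrow(x$channels),
      sprintf("(group1=%d, group2=%d)\n", x$n_group1, x$n_group2))
  invisible(x)
}
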