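# Synthetic protein generator with planted channel architectures and known
# ground truth, plus two-clade species scenarios with planted horizontal
# transfers. Every downstream stage of the pipeline is validated against
# the coordinates and labels these functions plant.
#
# Compositional design (see the methods vignette for the arithmetic):
# transmembrane (TM) stretches are strongly hydrophobic; the pore segment
# is drawn so that a full detection window covering it has mean
# Kyte-Doolittle hydropathy inside the sub-threshold band of the TM
# predictor; the short segments flanking the pore are strongly polar so
# that the pore signal is separated from the M1/M2 shoulders; inter-region
# linkers are loop-biased (polar-enriched); decoy filler uses background
# amino-acid frequencies.

# Robinson-Robinson background amino-acid frequencies
.BG_FREQ <- c(A = 0.078, R = 0.051, N = 0.045, D = 0.054, C = 0.019,
              Q = 0.043, E = 0.063, G = 0.074, H = 0.022, I = 0.051,
              L = 0.090, K = 0.057, M = 0.022, F = 0.039, P = 0.052,
              S = 0.071, T = 0.058, W = 0.013, Y = 0.032, V = 0.066)

.LOOP_FREQ <- c(G = 0.12, S = 0.12, T = 0.10, N = 0.10, Q = 0.08,
                D = 0.10, E = 0.10, K = 0.08, R = 0.06, P = 0.06,
                A = 0.05, H = 0.03)

.TM_ALPHABET <- c("A", "I", "L", "F", "V", "M")
.FLANK_ALPHABET <- c("D", "E", "K", "R", "N", "Q")

#' Anchor positions of the key binding residues in the probes
#'
#' The glutamate-binding domain carries two invariant residues: an
#' arginine in S1 that contacts the alpha-carboxy group of L-glutamate
#' and an aspartate in S2 that contacts its alpha-amino group. Within the
#' packaged probes these are the Arg at 0-based position 34 of S1 and the
#' Asp at 0-based position 5 of S2. The synthetic generator can protect
#' these positions from mutation, and conservation checks test them.
#'
#' @return List with elements \code{s1_anchor}, \code{s2_anchor} (0-based
#'   positions) and \code{s1_residue}, \code{s2_residue}.
#' @export
probe_anchors <- function() {
  list(s1_anchor = 34L, s1_residue = "R", s2_anchor = 5L, s2_residue = "D")
}

#' Specification for a synthetic benchmark dataset
#'
#' @param n_channels_group1,n_channels_group2 Number of planted channel
#'   proteins carrying / lacking the potassium-type selectivity filter.
#' @param n_decoys_per_class Number of decoys of each class (soluble
#'   binder, permease, random).
#' @param substitution_rate Per-site substitution probability applied to
#'   the planted S1/S2 probe copies (structural segments are drawn fresh
#'   from their compositional models, not mutated).
#' @param indel_rate Per-site indel probability within the S1/S2 copies
#'   (default 0; region coordinates remain exact for any value because
#'   downstream coordinates are shifted accordingly).
#' @param tm_length Length of each planted TM helix (residues).
#' @param pore_length Length of the planted pore-loop segment.
#' @param flank_length Length of the polar segments flanking the pore.
#' @param linker_length_range Length range (min, max) for inter-region
#'   linkers.
#' @param include_signal_peptide Plant an N-terminal signal peptide on
#'   channel proteins.
#' @param n_signal_free_per_group Number of channels per group generated
#'   without a signal peptide (overrides \code{include_signal_peptide}
#'   for the first such proteins of each group).
#' @param protect_anchors Protect the two key binding residues (see
#'   \code{\link{probe_anchors}}) from mutation.
#' @param rng_seed Integer seed; identical spec + seed gives byte-identical
#'   datasets.
#' @return An object of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(n_channels_group1 = 5L, n_channels_group2 = 5L,
                           n_decoys_per_class = 10L,
                           substitution_rate = 0.05, indel_rate = 0,
                           tm_length = 19L, pore_length = 15L,
                           flank_length = 8L,
                           linker_length_range = c(5L, 30L),
                           include_signal_peptide = TRUE,
                           n_signal_free_per_group = 0L,
                           protect_anchors = TRUE, rng_seed = 1L) {
  stopifnot(n_channels_group1 >= 0, n_channels_group2 >= 0,
            n_decoys_per_class >= 0,
            substitution_rate >= 0, substitution_rate <= 1,
            indel_rate >= 0, indel_rate <= 1,
            tm_length > 0, pore_length > 0, flank_length > 0,
            length(linker_length_range) == 2L,
            linker_length_range[1L] > 0,
            linker_length_range[1L] <= linker_length_range[2L])
  structure(list(n_channels_group1 = as.integer(n_channels_group1),
                 n_channels_group2 = as.integer(n_channels_group2),
                 n_decoys_per_class = as.integer(n_decoys_per_class),
                 substitution_rate = substitution_rate,
                 indel_rate = indel_rate,
                 tm_length = as.integer(tm_length),
                 pore_length = as.integer(pore_length),
                 flank_length = as.integer(flank_length),
                 linker_length_range = as.integer(linker_length_range),
                 include_signal_peptide = isTRUE(include_signal_peptide),
                 n_signal_free_per_group = as.integer(n_signal_free_per_group),
                 protect_anchors = isTRUE(protect_anchors),
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_spec")
}

r_bg <- function(n) sample(names(.BG_FREQ), n, replace = TRUE, prob = .BG_FREQ)

r_loop <- function(n) sample(names(.LOOP_FREQ), n, replace = TRUE,
                             prob = .LOOP_FREQ)

r_linker <- function(range) r_loop(sample(range[1L]:range[2L], 1L))

r_flank <- function(n) sample(.FLANK_ALPHABET, n, replace = TRUE)

# TM helix: 90% hydrophobic alphabet, 10% background; redraw until the
# stretch is unambiguously hydrophobic (mean KD >= 2.5 guarantees the
# window covering it exactly passes the default 1.6 threshold).
r_tm <- function(len) {
  for (i in 1:1000) {
    hydro <- stats::runif(len) < 0.9
    res <- ifelse(hydro, sample(.TM_ALPHABET, len, replace = TRUE), r_bg(len))
    if (mean(.KD_SCALE[res]) >= 2.5) return(res)
  }
  stop("failed to draw a TM stretch")  # unreachable in practice
}

# Target total hydropathy for the pore segment: a full detection window
# (width `window`) covering the pore plus (window - len) polar flank
# residues should average inside [1.2, 1.45] -- within the sub-threshold
# band of the TM predictor but clear of both band edges.
pore_sum_range <- function(len, window = 19L, flank_kd = -3.73) {
  c(1.2, 1.45) * window - flank_kd * (window - len)
}

r_pore <- function(group, len, window = 19L) {
  rng <- pore_sum_range(len, window)
  filt <- c("T", "V", "G", "Y", "G")
  for (i in 1:1000) {
    if (group == 1L) {
      if (len < length(filt) + 4L)
        stop("pore_length too short to host the selectivity filter")
      off <- sample(2:(len - length(filt) - 2L), 1L)
      res <- sample(c("I", "V", "L", "F"), len, replace = TRUE)
      res[(off + 1L):(off + length(filt))] <- filt
    } else {
      res <- sample(c("L", "F", "A", "M"), len, replace = TRUE)
    }
    s <- sum(.KD_SCALE[res])
    if (s < rng[1L] || s > rng[2L]) next
    has_filter <- detect_k_filter(paste(res, collapse = ""))
    if ((group == 1L) == has_filter) return(res)
  }
  stop("failed to draw a pore segment in the target hydropathy band")
}

# Signal peptide: initiator Met, positive n-region, hydrophobic h-region,
# polar c-region; 20 residues total. The h-region is 7 residues: long
# enough for the signal detector's hydrophobic-core window, short enough
# that no 19-residue TM window over the N-terminus comes near the TM
# threshold.
r_signal <- function() {
  c("M", "K", "R", r_bg(2L),
    sample(c("I", "L", "F", "V"), 7L, replace = TRUE),
    sample(c("S", "T", "N", "Q", "G"), 8L, replace = TRUE))
}

# Loop sequence without positively charged residues, used for the
# N-terminus of channels planted without a signal peptide so that the
# absence is a verifiable ground-truth property (no K/R in the n-region).
r_loop_neutral <- function(n) {
  w <- .LOOP_FREQ[setdiff(names(.LOOP_FREQ), c("K", "R"))]
  sample(names(w), n, replace = TRUE, prob = w)
}

# Mutate a planted probe copy: per-site substitution to a uniformly random
# different residue; optional indels. Returns the residue vector.
mutate_seq <- function(res, rate, indel_rate = 0, protect = integer()) {
  n <- length(res)
  hit <- which(stats::runif(n) < rate)
  hit <- setdiff(hit, protect + 1L)
  for (i in hit) {
    res[i] <- sample(setdiff(AA_STANDARD, res[i]), 1L)
  }
  if (indel_rate > 0) {
    keep <- stats::runif(length(res)) >= indel_rate / 2
    keep[protect + 1L] <- TRUE
    res <- res[keep]
    ins <- which(stats::runif(length(res)) < indel_rate / 2)
    if (length(ins)) {
      out <- character(0)
      prev <- 1L
      for (i in ins) {
        out <- c(out, res[prev:i], r_bg(1L))
        prev <- i + 1L
      }
      if (prev <= length(res)) out <- c(out, res[prev:length(res)])
      res <- out
    }
  }
  res
}

#' Generate one synthetic protein with ground truth
#'
#' Channel architectures contain, in order: an optional signal peptide, a
#' mutated copy of the S1 probe, a hydrophobic M1 helix, a polar flank, a
#' pore segment (Group 1: containing the potassium-channel selectivity
#' filter; Group 2: lacking it), a second polar flank, an M2 helix, and a
#' mutated copy of the S2 probe, separated by loop-like linkers. Decoys
#' omit the stated parts: soluble binders have S1+S2 but no membrane
#' segments, permeases have three TM helices but no binding lobes, random
#' proteins are background-frequency sequence.
#'
#' @param spec A \code{\link{synthetic_spec}}.
#' @param architecture One of \code{"channel-g1"}, \code{"channel-g2"},
#'   \code{"soluble-binder"}, \code{"permease"}, \code{"random"}.
#' @param id Protein identifier for the record and ground-truth rows.
#' @param signal Override the spec's signal-peptide setting for this
#'   protein (logical or NULL).
#' @return List with elements \code{record} (list: protein_id,
#'   description, superkingdom, phylum, sequence) and \code{truth}
#'   (data.frame: protein_id, label, region_type, name, start, end;
#'   coordinates 0-based half-open).
#' @export
generate_protein <- function(spec, architecture, id = "protein",
                             signal = NULL) {
  arch <- match.arg(architecture,
                    c("channel-g1", "channel-g2", "soluble-binder",
                      "permease", "random"))
  probes <- load_probes()
  anch <- probe_anchors()
  lr <- spec$linker_length_range
  prot_s1 <- if (spec$protect_anchors) anch$s1_anchor else integer()
  prot_s2 <- if (spec$protect_anchors) anch$s2_anchor else integer()

  parts <- list()   # list of (residues, region_type or NA, name)
  add <- function(res, type = NA_character_, name = NA_character_) {
    parts[[length(parts) + 1L]] <<- list(res = res, type = type, name = name)
  }

  if (arch %in% c("channel-g1", "channel-g2")) {
    grp <- if (arch == "channel-g1") 1L else 2L
    with_sig <- signal %||% spec$include_signal_peptide
    if (isTRUE(with_sig)) {
      add(r_signal(), "SIGNAL", "signal")
      add(r_loop(sample(3:10, 1L)))
    } else {
      add(r_loop_neutral(sample(3:10, 1L)))
    }
    add(mutate_seq(seq_chars(probes$s1), spec$substitution_rate,
                   spec$indel_rate, prot_s1), "S1", "S1")
    add(r_linker(lr))
    add(r_tm(spec$tm_length), "TM", "M1")
    add(r_flank(spec$flank_length))
    add(r_pore(grp, spec$pore_length), "P", "P")
    add(r_flank(spec$flank_length))
    add(r_tm(spec$tm_length), "TM", "M2")
    add(r_linker(lr))
    add(mutate_seq(seq_chars(probes$s2), spec$substitution_rate,
                   spec$indel_rate, prot_s2), "S2", "S2")
    add(r_loop(sample(3:10, 1L)))
    desc <- paste0("synthetic glutamate-gated channel, group ", grp)
  } else if (arch == "soluble-binder") {
    add(r_loop(sample(5:15, 1L)))
    add(mutate_seq(seq_chars(probes$s1), spec$substitution_rate,
                   spec$indel_rate, prot_s1), "S1", "S1")
    add(r_loop(sample(20:40, 1L)))
    add(mutate_seq(seq_chars(probes$s2), spec$substitution_rate,
                   spec$indel_rate, prot_s2), "S2", "S2")
    add(r_loop(sample(5:15, 1L)))
    desc <- "synthetic soluble periplasmic binding protein"
  } else if (arch == "permease") {
    add(r_bg(sample(15:40, 1L)))
    for (k in 1:3) {
      add(r_tm(spec$tm_length), "TM", paste0("TM", k))
      if (k < 3) add(r_loop(15L))
    }
    add(r_bg(sample(15:40, 1L)))
    desc <- "synthetic polytopic permease"
  } else {
    add(r_bg(sample(250:400, 1L)))
    desc <- "synthetic random sequence"
  }

  pos <- 0L
  rows <- list()
  res_all <- character(0)
  for (p in parts) {
    len <- length(p$res)
    if (!is.na(p$type))
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = id, label = arch, region_type = p$type,
        name = p$name, start = pos, end = pos + len,
        stringsAsFactors = FALSE)
    res_all <- c(res_all, p$res)
    pos <- pos + len
  }
  truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protein_id = character(0), label = character(0),
               region_type = character(0), name = character(0),
               start = integer(0), end = integer(0))
  list(record = list(protein_id = id, description = desc,
                     superkingdom = "Bacteria", phylum = "Proteobacteria",
                     sequence = paste(res_all, collapse = "")),
       truth = truth)
}

#' Generate a full synthetic benchmark dataset
#'
#' Draws the numbers of channel and decoy proteins given by the spec,
#' assigns identifiers and taxonomy (all bacterial by default; channel
#' proteins alternate between Cyanobacteria and Proteobacteria phyla), and
#' collects ground truth. Identical spec + seed gives identical output.
#'
#' @param spec A \code{\link{synthetic_spec}}.
#' @return Object of class \code{synthetic_dataset}: list with
#'   \code{spec}, \code{proteins} (data.frame: protein_id, label,
#'   description, sequence), \code{taxonomy} (data.frame: protein_id,
#'   superkingdom, phylum) and \code{truth} (region data.frame).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_rng(spec$rng_seed, {
    plan <- list()
    addp <- function(arch, n, prefix) {
      if (n > 0)
        plan[[length(plan) + 1L]] <<- data.frame(
          arch = arch, id = sprintf("%s_%03d", prefix, seq_len(n)),
          stringsAsFactors = FALSE)
    }
    addp("channel-g1", spec$n_channels_group1, "ch1")
    addp("channel-g2", spec$n_channels_group2, "ch2")
    addp("soluble-binder", spec$n_decoys_per_class, "sol")
    addp("permease", spec$n_decoys_per_class, "perm")
    addp("random", spec$n_decoys_per_class, "rand")
    plan <- if (length(plan)) do.call(rbind, plan) else
      data.frame(arch = character(0), id = character(0))

    sigfree <- c(
      if (spec$n_channels_group1 > 0)
        sprintf("ch1_%03d",
                seq_len(min(spec$n_signal_free_per_group,
                            spec$n_channels_group1))),
      if (spec$n_channels_group2 > 0)
        sprintf("ch2_%03d",
                seq_len(min(spec$n_signal_free_per_group,
                            spec$n_channels_group2))))

    prots <- vector("list", nrow(plan))
    truths <- vector("list", nrow(plan))
    for (i in seq_len(nrow(plan))) {
      sig <- if (plan$id[i] %in% sigfree) FALSE else NULL
      g <- generate_protein(spec, plan$arch[i], id = plan$id[i],
                            signal = sig)
      if (grepl("^ch", plan$id[i]))
        g$record$phylum <- if (i %% 2L == 0L) "Cyanobacteria" else
          "Proteobacteria"
      prots[[i]] <- data.frame(protein_id = g$record$protein_id,
                               label = plan$arch[i],
                               description = g$record$description,
                               sequence = g$record$sequence,
                               superkingdom = g$record$superkingdom,
                               phylum = g$record$phylum,
                               stringsAsFactors = FALSE)
      truths[[i]] <- g$truth
    }
    proteins <- do.call(rbind, prots)
    truth <- do.call(rbind, truths)
    structure(list(spec = spec,
                   proteins = proteins[, c("protein_id", "label",
                                           "description", "sequence")],
                   taxonomy = proteins[, c("protein_id", "superkingdom",
                                           "phylum")],
                   truth = truth),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset:", nrow(x$proteins), "proteins (",
      paste(sprintf("%s=%d", names(table(x$proteins$label)),
                    table(x$proteins$label)), collapse = ", "), ")\n")
  invisible(x)
}

#' Extract the sequences of a synthetic dataset
#' @param dataset A \code{synthetic_dataset}.
#' @return Named character vector of sequences.
#' @export
dataset_sequences <- function(dataset) {
  setNames(dataset$proteins$sequence, dataset$proteins$protein_id)
}

#' Write a synthetic dataset to disk
#'
#' Writes \code{proteins.fasta}, \code{taxonomy.tsv} and
#' \code{ground_truth.tsv} (protein_id, label, region_type, name, start,
#' end) into \code{dir}.
#'
#' @param dataset A \code{synthetic_dataset}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(dataset_sequences(dataset), file.path(dir, "proteins.fasta"))
  write.table(dataset$taxonomy, file.path(dir, "taxonomy.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(dataset$truth, file.path(dir, "ground_truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

# Caterpillar Newick string for labels with given branch lengths.
caterpillar <- function(labels, bl) {
  n <- length(labels)
  fmt <- function(lab, len) sprintf("%s:%.4f", lab, len)
  if (n == 1L) return(fmt(labels, bl[1L]))
  s <- sprintf("(%s,%s)", fmt(labels[n - 1L], bl[n - 1L]),
               fmt(labels[n], bl[n]))
  if (n > 2L)
    for (i in (n - 2L):1L)
      s <- sprintf("(%s,%s:%.4f)", fmt(labels[i], bl[i]), s, 0.1)
  s
}

#' Generate a two-clade species scenario with planted transfers
#'
#' Builds a species tree with two monophyletic clades (A and B) of the
#' requested sizes, assigns protein-group labels by vertical descent
#' (clade A carries Group 1, clade B carries Group 2) and then performs
#' exactly \code{transfers} cross-clade label reassignments. Transfer
#' positions are chosen deterministically (basal leaves first, then
#' isolated interior leaves, alternating clades) so that the Fitch
#' parsimony count of the group character equals the planted number of
#' transfers (for \code{transfers >= 1}; with zero transfers the two
#' groups are perfectly congruent with the clades and the character needs
#' exactly one change, the origin split).
#'
#' @param n_clade_a,n_clade_b Leaf counts of the two clades (>= 2).
#' @param transfers Number of cross-clade reassignments (>= 0).
#' @param rng_seed Integer seed for branch lengths.
#' @return List with \code{tree} (phylo), \code{groups} (named character
#'   vector, leaf -> "group1"/"group2"), \code{newick} (string) and
#'   \code{transfers}.
#' @export
generate_species_scenario <- function(n_clade_a, n_clade_b, transfers = 0L,
                                      rng_seed = NULL) {
  stopifnot(n_clade_a >= 2L, n_clade_b >= 2L, transfers >= 0L)
  la <- sprintf("A%02d", seq_len(n_clade_a))
  lb <- sprintf("B%02d", seq_len(n_clade_b))
  slots_a <- la[seq(1L, n_clade_a - 1L, by = 2L)]
  slots_b <- lb[seq(1L, n_clade_b - 1L, by = 2L)]
  nmax <- length(slots_a) + length(slots_b)
  if (transfers > nmax)
    stop("transfers (", transfers, ") exceeds the ", nmax,
         " reassignable leaves of this scenario")
  with_rng(rng_seed, {
    bla <- stats::runif(n_clade_a, 0.05, 0.3)
    blb <- stats::runif(n_clade_b, 0.05, 0.3)
    nwk <- sprintf("(%s:0.2,%s:0.2);",
                   caterpillar(la, bla), caterpillar(lb, blb))
    tree <- ape::read.tree(text = nwk)
    groups <- setNames(c(rep("group1", n_clade_a), rep("group2", n_clade_b)),
                       c(la, lb))
    if (transfers > 0) {
      picks <- character(0)
      ia <- 0L; ib <- 0L
      for (k in seq_len(transfers)) {
        if ((k %% 2L == 1L && ib < length(slots_b)) || ia >= length(slots_a)) {
          ib <- ib + 1L; picks <- c(picks, slots_b[ib])
        } else {
          ia <- ia + 1L; picks <- c(picks, slots_a[ia])
        }
      }
      groups[picks] <- ifelse(startsWith(picks, "A"), "group2", "group1")
    }
    list(tree = tree, groups = groups,
         newick = ape::write.tree(tree), transfers = as.integer(transfers))
  })
}

#' Simulate an alignment by evolving sequences along a tree
#'
#' A simple Jukes-Cantor-like protein model: the root sequence is drawn
#' from background frequencies (or supplied), and along each branch every
#' site substitutes independently with probability
#' \code{1 - exp(-rate * branch_length)}, to a uniformly random different
#' residue. No indels, so the result is an alignment. Intended for
#' validating tree-building, not for realism.
#'
#' @param tree A \code{phylo} tree with branch lengths.
#' @param n_sites Number of alignment columns.
#' @param rate Substitution rate per unit branch length.
#' @param root_seq Optional root residue vector or string.
#' @param rng_seed Integer seed.
#' @return Character matrix (tips x sites) with tip labels as rownames.
#' @export
simulate_alignment_on_tree <- function(tree, n_sites = 200L, rate = 1,
                                       root_seq = NULL, rng_seed = NULL) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  with_rng(rng_seed, {
    ntip <- length(tree$tip.label)
    root <- ntip + 1L
    seqs <- vector("list", max(tree$edge))
    seqs[[root]] <- if (is.null(root_seq)) r_bg(n_sites) else {
      rs <- if (length(root_seq) == 1L) seq_chars(root_seq) else root_seq
      stopifnot(length(rs) == n_sites)
      rs
    }
    # parents precede children in a preorder edge walk
    ord <- ape::reorder.phylo(tree, "cladewise")
    for (k in seq_len(nrow(ord$edge))) {
      par <- ord$edge[k, 1L]; chi <- ord$edge[k, 2L]
      p <- 1 - exp(-rate * ord$edge.length[k])
      s <- seqs[[par]]
      hit <- which(stats::runif(n_sites) < p)
      for (i in hit) s[i] <- sample(setdiff(AA_STANDARD, s[i]), 1L)
      seqs[[chi]] <- s
    }
    m <- do.call(rbind, seqs[seq_len(ntip)])
    rownames(m) <- tree$tip.label
    m
  })
}
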