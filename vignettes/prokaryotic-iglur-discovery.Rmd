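---
title: "Discovering prokaryotic glutamate receptor-like channels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering prokaryotic glutamate receptor-like channels: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gluscreen)
```

## The problem

Eukaryotic ionotropic glutamate receptors (iGluRs) are ligand-gated cation
channels with a characteristic domain architecture: the extracellular
glutamate-binding domain is split into two discontinuous lobes (S1 and S2)
that flank the channel-forming segment, which itself consists of two
transmembrane helices (M1 and M2) separated by a re-entrant pore-loop (P).
Prokaryotic relatives of these channels exist but are frequently
mis-annotated in sequence databases as ABC transporters or periplasmic
binding proteins, because the binding lobes are homologous to solute-binding
domains. Annotation by overall sequence similarity therefore fails;
identification has to rest on *domain content plus topology*: both binding
lobes present, in the right order, flanking two membrane segments that
bracket a pore-loop.

`gluscreen` implements that strategy as a staged screen:

1. **Probe search.** Local alignment of the packaged S1 (57 aa) and S2
   (69 aa) probe segments against every database sequence, keeping hits
   with E-value below a threshold (default 10, deliberately permissive).
2. **Membrane filter.** Sequences with fewer than two predicted TM helices
   are discarded — two is the minimum for the channel architecture.
3. **Taxonomy filter.** Prokaryotic sequences (superkingdom Bacteria or
   Archaea) are kept; lineage comes from a user-supplied table, and a
   surviving protein without lineage is an error rather than silently
   assumed eukaryotic.
4. **Dual-motif intersection.** Only proteins hit by *both* probes remain.
5. **Topology classification.** A protein is called a channel when
   end(S1) &le; start(M1) < end(M1) &le; start(P) < end(P) &le; start(M2) <
   end(M2) &le; start(S2).

Channels are then split into **Group 1** (pore-loop carries a
potassium-channel selectivity-filter motif; suggested annotation "putative
glutamate-sensitive potassium channel") and **Group 2** (no recognized
filter; "putative glutamate-sensitive ion channel").

## Alignment scoring and E-values

The search is a single-pass Smith–Waterman with affine gaps (BLOSUM62,
gap open 11, gap extend 1; a gap of length L costs `11 + L`). Statistical
significance uses the Karlin–Altschul form

E = &kappa; m n e^(−&lambda; S)

with the standard gapped BLOSUM62/11,1 calibration &lambda; = 0.267,
&kappa; = 0.041, query length m, and — following the BLAST convention —
n equal to the *total* residue count of the database searched. Iterated
profile search would be more sensitive but is not reproducible without the
original database; a deterministic single-pass search is sufficient to
recover planted motifs at the substitution rates the benchmark uses, and
its tie-breaks are pinned down (traceback prefers diagonal, then the move
consuming a query residue; equal E-values order by protein id).

## Transmembrane prediction and the pore-loop band

TM helices are predicted by sliding-window Kyte–Doolittle hydropathy:
window 19 (odd, about one helix turn short of a membrane span), passing
threshold mean &ge; 1.6. The per-segment score is a logistic transform of
the best window mean, anchored so that the threshold maps to 0.5:
`1/(1 + exp(-2 (mean - 1.6)))`.

The pore-loop is *defined* by sub-threshold behaviour: it is a
partial-helix signal, strong enough to stand out from loop background but
too short/polar to pass the TM test. Candidate segments are maximal runs of
windows whose mean falls in the band `[p_lo, threshold)` with
`p_lo = 0.25` on the probability scale (mean hydropathy about 1.05). The
pore call is the highest-scoring candidate whose *core* lies strictly
between the cores of the two flanking TM helices.

Two extents are reported per segment. The **union** of a run's windows
overstates a helix by up to half a window on each side (hydrophobic signal
bleeds into flanking sequence), so ordering regions by unions is fragile.
The **core** — the intersection of the run's windows — is provably
contained inside the true hydrophobic stretch whenever some window covers
it exactly, so the topology predicate uses cores. For the pore-loop, whose
band requires essentially full window coverage, the core reproduces the
planted segment to within one residue on synthetic data.

With more than two passing TM segments between S1 and S2 (eukaryotic
homologues carry an extra C-terminal helix, and spurious hydrophobic
stretches occur), every consecutive TM pair is tried and the pair
bracketing the best-scoring pore candidate wins.

## Selectivity filter and signal peptide

The potassium-channel selectivity filter is matched by the signature class
`[TS]-x-[GA]-[YF]-G`, with fallback acceptance of the bare `G-[YF]-G`
core; both patterns are arguments, since the canonical TVGYG motif admits
natural variation. The signal-peptide check is an explicitly heuristic
stand-in for dedicated predictors: at least one K/R in the first five
residues followed by a 7-residue window of mean hydropathy &ge; 1.8 within
the first 25. It reports presence/absence only.

## The synthetic generator

The generator plants the channel architecture with exact 0-based,
half-open coordinates: optional signal peptide (20 aa: Met, two basic
residues, a 7-residue hydrophobic h-region, polar tail), a mutated copy of
the S1 probe, M1 (19 aa, 90% from {A,I,L,F,V,M}, redrawn until mean
hydropathy &ge; 2.5), an 8-residue strongly polar flank, the pore segment
(15 aa), a second flank, M2, and a mutated S2 copy, separated by loop-like
linkers of random length (default 5–30).

Compositional choices are driven by the detector's arithmetic, not by
residue statistics of any real protein family:

* **Pore.** A full 19-window covering the 15-residue pore includes 4 flank
  residues; the pore is rejection-sampled until that window's mean lands in
  [1.2, 1.45] — inside the sub-threshold band, clear of both edges. Group-1
  pores embed TVGYG and fill up with {I,V,L,F}; Group-2 pores draw from
  {L,F,A,M} and are redrawn if they accidentally match the filter pattern.
  Twelve-residue pores cannot host the (hydrophilic) TVGYG motif and still
  reach the band, which is why the default pore length is 15.
* **Flanks and linkers.** The segments flanking the pore are strongly polar
  ({D,E,K,R,N,Q}) and the inter-region linkers are loop-biased
  (polar-enriched) rather than background-frequency: with background-level
  flanks the M1/M2 hydrophobic shoulders and the pore band signal merge,
  and no detector could separate them. Random decoys and terminal padding
  still use background (Robinson–Robinson) frequencies.
* **Mutation model.** The substitution rate applies to the planted S1/S2
  copies only (per-site substitution to a uniformly random different
  residue; indels optional and off by default). Structural segments are
  drawn fresh from their compositional models for every protein, so the
  benchmark degrades probe detectability without destroying the planted
  topology. The two invariant binding residues (Arg at S1 position 34, Asp
  at S2 position 5) can be protected from mutation, mirroring their
  biological invariance.
* **Signal-free channels** draw their N-terminal loop from a K/R-free
  alphabet so that "no signal peptide" is a verifiable planted property
  rather than a coin flip against the heuristic.

Decoy classes: soluble binders (S1 + S2, no membrane segments), permeases
(three TM helices, no binding lobes), and random background sequence. What
the generator does **not** emulate: real residue composition of any
protein family, indel-rich divergence, compositional bias, or homology
between decoys and probes beyond chance. Passing benchmarks therefore
demonstrates correctness of the machinery under the planted model, not
sensitivity/specificity on real proteomes.

## Evolutionary Domain Network

Proteins are grouped by domain composition — the *set* of domain
accessions annotated on them (duplicates collapse; overlapping domains are
retained as distinct accessions; annotations weaker than E = 1e-3 are
dropped by default, a choice exposed as an argument). Nodes are distinct
sets, rows index nodes by set size, and tie lines join sets whose symmetric
difference is exactly one accession — single-domain gain or loss, a rough
proxy for domain-recombination events. Edges are found by hashing each set
minus one element (O(nk) rather than all-pairs), and connected components
and observed-only exchange paths are delegated to igraph. Exchange paths
may also use *virtual* intermediates (compositions that vanished or have
not been sequenced), in which case the path length equals the symmetric
difference.

## Conservation and key residues

Per-region alignments (S1, channel, S2) are joined column-wise and each
column classified by ClustalX conventions: *identical* (one residue type,
no gaps), *strongly conserved* (all residues within one strong group: STA,
NEQK, NHQK, NDEQ, QHRK, MILV, MILF, HY, FYW), *weakly conserved* (one weak
group: CSA, ATV, SAG, STNK, STPA, SGND, SNDEQK, NDEQHK, NEQHRK, FVLIM,
HFY), else unconserved; any gap makes a column unconserved, since ClustalW
prints no consensus symbol under gaps. The package consumes alignments
(aligned FASTA or Clustal) rather than re-implementing an aligner; the
bundled progressive aligner (pairwise Needleman–Wunsch, UPGMA guide tree,
consensus-based profile merging) exists so synthetic benchmarks are
self-contained and is documented as non-authoritative.

## Trees, congruence, and the transfer lower bound

Region trees are neighbor-joining on p-distances (pairwise gap deletion;
a pair with no comparable columns is an error). NJ, Fitch parsimony and
Robinson–Foulds distances are delegated to ape/phangorn and cross-checked
in the test suite against exhaustive oracles (brute-force DP, all
internal-state assignments on small trees, all-pairs bipartition
enumeration). Congruent region trees — pairwise RF of zero — support the
conclusion that binding and channel regions travelled together through
evolution.

Horizontal transfer is bounded from below by Fitch parsimony: with
protein-group membership as a character on the species tree, the minimum
number of state changes bounds the number of transfer events. The scenario
generator builds two monophyletic clades (caterpillar shape, branch
lengths U(0.05, 0.3)) and plants exactly `k` cross-clade reassignments at
deterministic positions — the basal leaf of each clade first, then
isolated even-index leaves, alternating clades — a construction chosen so
that the Fitch count equals `k` for `k` &ge; 1. One caveat is recorded
rather than hidden: with zero transfers the two groups are perfectly
congruent with the clades, and any two-state character present on both
sides of the root needs exactly one change, so the count is 1, not 0. The
origin split is not a transfer; tests assert monophyly plus a count of one
for that case.

Orthology uses reciprocal best hits: lowest E-value in both directions,
ties broken by raw score then lexicographic id, hits required to clear the
E-value threshold both ways. Retrieval ratios report, for one probe
sequence against a reference list, the fraction of references hit at
E below the threshold (numerator over denominator).

## Numerical and reproducibility choices

* Coordinates are 0-based half-open everywhere; conversions happen only at
  I/O boundaries (`substr` calls).
* All randomness flows through explicit integer seeds; generators restore
  the caller's RNG state. Identical spec + seed gives byte-identical FASTA
  and reports.
* Negative NJ branch lengths are clamped to zero with a warning.
* Residues outside the 20-letter alphabet: `X` scores 0 against everything
  in alignments and 0 in hydropathy; anything else is rejected on input.
* Benchmark problem sizes: the parameter-recovery dataset uses 100 planted
  channels (50 per group) plus 102 decoys at substitution rate 0.05; oracle
  suites use 200 random alignment pairs, 50 random domain-set collections,
  50 random additive matrices, and trees of 6–12 leaves where exhaustive
  enumeration is feasible. Tree-recovery simulations use 8-leaf trees,
  branch lengths U(0.15, 0.4), rate 0.5, 500 sites — enough signal for
  distance methods without saturating p-distances.

## Known limitations

* The hydropathy TM predictor and the signal heuristic are documented
  stand-ins, not re-implementations of HMM-based predictors; their scores
  are package-defined quantities.
* E-value calibration constants are the standard gapped BLOSUM62 values,
  not estimated from the input database.
* The progressive aligner is for synthetic, nearly gap-free families; real
  alignments should come from a dedicated MSA tool.
* Database-scale results (hit counts against public protein databases)
  depend on database snapshots and are outside what the package can or
  tries to reproduce; the packaged tables record printed values for
  fixture-level checks only.
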