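aa_matrix <- function(strings) {
  do.call(rbind, strsplit(strings, ""))
}

mutated_copies <- function(probe, n, rate, protect = integer(), seed = 1) {
  set.seed(seed)
  m <- t(vapply(1:n, function(i)
    gluscreen:::mutate_seq(strsplit(probe, "")[[1]], rate,
                           protect = protect),
    character(nchar(probe))))
  rownames(m) <- paste0("s", 1:n)
  m
}

test_that("joined alignments concatenate in canonical region order", {
  a <- aa_matrix(c("ARNDARNDAR", "ARNDARNDAR"))
  b <- aa_matrix(c("WYVWYVWY", "WYVWYVWY"))
  rownames(a) <- rownames(b) <- c("x", "y")
  j <- join_alignments(list(S1 = a, S2 = b))
  expect_identical(ncol(j$alignment), 18L)
  expect_identical(j$boundaries$S1, c(0L, 10L))
  expect_identical(j$boundaries$S2, c(10L, 18L))
  # shuffled input order still yields S1, channel, S2
  ch <- aa_matrix(c("LLLL", "LLLL")); rownames(ch) <- c("x", "y")
  j2 <- join_alignments(list(S2 = b, channel = ch, S1 = a))
  expect_identical(names(j2$boundaries), c("S1", "channel", "S2"))
  expect_identical(j2$boundaries$channel, c(10L, 14L))
  # single region: identity
  j3 <- join_alignments(list(S1 = a))
  expect_identical(unname(j3$alignment), unname(a))
  # id mismatch names the offenders
  bad <- b; rownames(bad) <- c("x", "z")
  expect_error(join_alignments(list(S1 = a, S2 = bad)), "z")
})

test_that("column classification follows ClustalW conventions", {
  expect_identical(classify_column(c("R", "R", "R")), "identical")
  expect_identical(classify_column(c("M", "I", "L", "V")), "strong")
  expect_identical(classify_column(c("S", "A", "G")), "weak")
  expect_identical(classify_column(c("R", "D")), "none")
  expect_identical(classify_column(c("R", "R", "-")), "none")
  expect_identical(classify_column("Q"), "identical")
})

test_that("conservation summaries count each column exactly once", {
  p <- load_probes()
  m <- mutated_copies(p$s1, 8, 0.2, seed = 5)
  j <- join_alignments(list(S1 = m))
  s <- summarize_conservation(j)
  # per-column loop oracle
  cls <- vapply(seq_len(ncol(m)), function(i) classify_column(m[, i]),
                character(1))
  expect_identical(s$identical, sum(cls == "identical"))
  expect_identical(s$strongly_conserved, sum(cls == "strong"))
  expect_identical(s$weakly_conserved, sum(cls == "weak"))
  expect_lte(s$identical + s$strongly_conserved + s$weakly_conserved,
             s$columns_total)
  # identical rows: everything identical
  ident <- aa_matrix(rep("ARND", 3)); rownames(ident) <- paste0("r", 1:3)
  si <- summarize_conservation(ident)
  expect_identical(si$identical, si$columns_total)
})

test_that("summaries commute with joining", {
  p <- load_probes()
  a <- mutated_copies(p$s1, 6, 0.1, seed = 7)
  b <- mutated_copies(p$s2, 6, 0.1, seed = 8)
  j <- join_alignments(list(S1 = a, S2 = b))
  joint <- summarize_conservation(j)
  sep_a <- summarize_conservation(a)
  sep_b <- summarize_conservation(b)
  expect_identical(joint[joint$region == "S1",
                         c("identical", "strongly_conserved",
                           "weakly_conserved")],
                   sep_a[, c("identical", "strongly_conserved",
                             "weakly_conserved")])
  expect_identical(unlist(joint[joint$region == "S2",
                                c("identical", "weakly_conserved")],
                          use.names = FALSE),
                   unlist(sep_b[, c("identical", "weakly_conserved")],
                          use.names = FALSE))
})

test_that("identical-column counts fall as the mutation rate rises", {
  p <- load_probes()
  counts <- vapply(c(0, 0.05, 0.2, 0.5), function(r) {
    m <- mutated_copies(p$s1, 20, r, seed = 11)
    summarize_conservation(m)$identical
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_identical(counts[1], 57)
})

test_that("protected anchor residues are fully conserved", {
  p <- load_probes()
  anch <- probe_anchors()
  a <- mutated_copies(p$s1, 10, 0.3, protect = anch$s1_anchor, seed = 13)
  b <- mutated_copies(p$s2, 10, 0.3, protect = anch$s2_anchor, seed = 14)
  j <- join_alignments(list(S1 = a, S2 = b))
  chk <- key_residue_check(j, anch$s1_anchor, anch$s2_anchor)
  expect_true(chk[["s1"]])
  expect_true(chk[["s2"]])
  # one mutated row at the anchor breaks full conservation
  a2 <- a; a2[3, anch$s1_anchor + 1] <- "G"
  chk2 <- key_residue_check(join_alignments(list(S1 = a2, S2 = b)),
                            anch$s1_anchor, anch$s2_anchor)
  expect_false(chk2[["s1"]])
  expect_error(key_residue_check(j, 400, anch$s2_anchor), "outside")
})

test_that("the progressive aligner reconstructs gap-free families", {
  p <- load_probes()
  set.seed(15)
  seqs <- setNames(vapply(1:5, function(i)
    paste(gluscreen:::mutate_seq(strsplit(p$s1, "")[[1]], 0.1),
          collapse = ""), character(1)), paste0("s", 1:5))
  aln <- align_msa(seqs)
  expect_identical(dim(aln), c(5L, 57L))
  expect_identical(rownames(aln), names(seqs))
  expect_false(any(aln == "-"))
})

test_that("alignments round-trip through FASTA and Clustal writers", {
  p <- load_probes()
  m <- mutated_copies(p$s1, 4, 0.1, seed = 17)
  fa <- tempfile(fileext = ".fasta")
  write_alignment(m, fa, "fasta")
  expect_identical(read_alignment(fa, "fasta"), m)
  aln <- tempfile(fileext = ".aln")
  write_alignment(m, aln, "clustal")
  back <- read_alignment(aln, "clustal")
  expect_identical(unname(back), unname(m))
  expect_setequal(rownames(back), rownames(m))
})
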