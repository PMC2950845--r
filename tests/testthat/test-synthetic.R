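test_that("identical spec and seed give byte-identical datasets", {
  spec <- synthetic_spec(n_channels_group1 = 2, n_channels_group2 = 2,
                         n_decoys_per_class = 2, rng_seed = 11)
  d1 <- generate_dataset(spec)
  d2 <- generate_dataset(spec)
  expect_identical(d1$proteins, d2$proteins)
  expect_identical(d1$truth, d2$truth)
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_fasta(dataset_sequences(d1), f1)
  write_fasta(dataset_sequences(d2), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("dataset sizes follow the spec and labels are balanced", {
  spec <- synthetic_spec(n_channels_group1 = 5, n_channels_group2 = 5,
                         n_decoys_per_class = 10, rng_seed = 1)
  ds <- generate_dataset(spec)
  expect_identical(nrow(ds$proteins), 40L)
  tab <- table(ds$proteins$label)
  expect_equal(as.integer(tab[c("channel-g1", "channel-g2")]), c(5L, 5L))
  spec0 <- synthetic_spec(n_channels_group1 = 0, n_channels_group2 = 0,
                          n_decoys_per_class = 3, rng_seed = 1)
  ds0 <- generate_dataset(spec0)
  expect_false(any(grepl("^channel", ds0$truth$label)))
})

test_that("unmutated channel copies plant the probes verbatim", {
  spec <- synthetic_spec(substitution_rate = 0, rng_seed = 5)
  p <- load_probes()
  set.seed(5)
  g <- generate_protein(spec, "channel-g1", id = "x")
  tr <- g$truth
  s1 <- tr[tr$name == "S1", ]
  expect_identical(substr(g$record$sequence, s1$start + 1, s1$end), p$s1)
  s2 <- tr[tr$name == "S2", ]
  expect_identical(substr(g$record$sequence, s2$start + 1, s2$end), p$s2)
  # regions are ordered, non-overlapping, within bounds
  expect_true(all(diff(tr$start) > 0))
  expect_true(all(tr$start < tr$end))
  expect_true(all(tr$end[-nrow(tr)] <= tr$start[-1]))
  expect_true(max(tr$end) <= nchar(g$record$sequence))
})

test_that("planted pores match their group's filter status", {
  set.seed(21)
  spec <- synthetic_spec(rng_seed = 21)
  for (i in 1:50) {
    g1 <- generate_protein(spec, "channel-g1", id = "a")
    p1 <- g1$truth[g1$truth$region_type == "P", ]
    pore1 <- substr(g1$record$sequence, p1$start + 1, p1$end)
    expect_true(detect_k_filter(pore1))
    g2 <- generate_protein(spec, "channel-g2", id = "b")
    p2 <- g2$truth[g2$truth$region_type == "P", ]
    pore2 <- substr(g2$record$sequence, p2$start + 1, p2$end)
    expect_false(detect_k_filter(pore2))
  }
})

test_that("unknown architecture labels are rejected", {
  spec <- synthetic_spec()
  expect_error(generate_protein(spec, "not-an-architecture"))
})

test_that("random decoys rarely reach the screening threshold", {
  set.seed(101)
  spec <- synthetic_spec()
  rand <- vapply(1:100, function(i)
    generate_protein(spec, "random", id = "r")$record$sequence,
    character(1))
  names(rand) <- sprintf("r%03d", 1:100)
  p <- load_probes()
  hits <- screen_probe(p$s1, rand, scoring_params(), "S1")
  expect_gte(100 - length(unique(hits$protein_id)), 95)
  strict <- screen_probe(p$s1, rand,
                         scoring_params(evalue_threshold = 1e-3), "S1")
  expect_identical(nrow(strict), 0L)
})

test_that("species scenarios plant the advertised transfer count", {
  sc0 <- generate_species_scenario(6, 6, transfers = 0, rng_seed = 3)
  expect_true(monophyly(sc0$tree, sc0$groups, "group1"))
  expect_true(monophyly(sc0$tree, sc0$groups, "group2"))
  expect_identical(fitch_min_changes(sc0$tree, sc0$groups), 1L)
  for (k in 1:3) {
    sc <- generate_species_scenario(6, 6, transfers = k, rng_seed = 7)
    f <- fitch_min_changes(sc$tree, sc$groups)
    expect_identical(f, k)
    expect_identical(brute_fitch(sc$tree, sc$groups), as.numeric(k))
  }
  # determinism and the reassignable-leaf bound
  a <- generate_species_scenario(5, 4, transfers = 2, rng_seed = 9)
  b <- generate_species_scenario(5, 4, transfers = 2, rng_seed = 9)
  expect_identical(a$newick, b$newick)
  expect_identical(a$groups, b$groups)
  expect_error(generate_species_scenario(4, 4, transfers = 10, rng_seed = 1),
               "reassignable")
})

test_that("written datasets round-trip through the package readers", {
  spec <- synthetic_spec(n_channels_group1 = 2, n_channels_group2 = 1,
                         n_decoys_per_class = 1, rng_seed = 13)
  ds <- generate_dataset(spec)
  dir <- tempfile("ds")
  write_dataset(ds, dir)
  seqs <- read_fasta(file.path(dir, "proteins.fasta"))
  expect_identical(seqs, dataset_sequences(ds))
  tax <- read_lineage(file.path(dir, "taxonomy.tsv"))
  expect_identical(tax$protein_id, ds$taxonomy$protein_id)
})
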