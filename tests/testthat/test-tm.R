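test_that("hydropathy extremes give one passing segment or none", {
  polyL <- strrep("L", 30)
  seg <- predict_tm_segments(polyL)
  expect_identical(nrow(seg), 1L)
  expect_true(seg$passes_test)
  expect_identical(c(seg$start, seg$end), c(0L, 30L))
  expect_gte(seg$probability_score, 0.5)
  polyD <- strrep("D", 30)
  expect_identical(nrow(predict_tm_segments(polyD)), 0L)
  # shorter than the window: no segments
  expect_identical(nrow(predict_tm_segments("LLLL")), 0L)
  expect_error(predict_tm_segments(polyL, window = 10), "odd")
})

test_that("planted channels show two passing TMs and a pore candidate", {
  set.seed(17)
  spec <- synthetic_spec(substitution_rate = 0)
  g <- generate_protein(spec, "channel-g1", id = "x")
  tm <- predict_tm_segments(g$record$sequence)
  pass <- tm[tm$passes_test, ]
  expect_identical(nrow(pass), 2L)
  # exactly one sub-threshold candidate strictly between the TM cores
  mid <- tm[!tm$passes_test &
              tm$core_start >= pass$core_end[1] &
              tm$core_end <= pass$core_start[2], ]
  expect_identical(nrow(mid), 1L)
  expect_lt(mid$probability_score, 0.5)
  expect_gte(mid$probability_score, 0.25)
  # the TM cores sit inside the planted helices
  m1 <- g$truth[g$truth$name == "M1", ]
  m2 <- g$truth[g$truth$name == "M2", ]
  expect_gte(pass$core_start[1], m1$start)
  expect_lte(pass$core_end[1], m1$end)
  expect_gte(pass$core_start[2], m2$start)
  expect_lte(pass$core_end[2], m2$end)
})

test_that("the screen cascade shrinks monotonically and filters decoys", {
  spec <- synthetic_spec(n_channels_group1 = 3, n_channels_group2 = 2,
                         n_decoys_per_class = 5, substitution_rate = 0.05,
                         rng_seed = 23)
  ds <- generate_dataset(spec)
  db <- dataset_sequences(ds)
  scr <- run_screen(db, ds$taxonomy)
  s <- scr$stages
  expect_true(all(s$stage2_s1 %in% s$stage1_s1))
  expect_true(all(s$stage3_s1 %in% s$stage2_s1))
  expect_true(all(s$stage2_s2 %in% s$stage1_s2))
  expect_true(all(s$stage3_s2 %in% s$stage2_s2))
  expect_lte(length(s$stage4_both),
             min(length(s$stage3_s1), length(s$stage3_s2)))
  # soluble binders are eliminated at the TM stage
  sol <- ds$proteins$protein_id[ds$proteins$label == "soluble-binder"]
  expect_length(intersect(sol, s$stage2_s1), 0L)
  expect_length(intersect(sol, s$stage2_s2), 0L)
})

test_that("eukaryote-lineage hits are removed at stage 3", {
  spec <- synthetic_spec(n_channels_group1 = 2, n_channels_group2 = 0,
                         n_decoys_per_class = 0, substitution_rate = 0,
                         rng_seed = 29)
  ds <- generate_dataset(spec)
  tax <- ds$taxonomy
  tax$superkingdom[tax$protein_id == "ch1_001"] <- "Eukaryota"
  scr <- run_screen(dataset_sequences(ds), tax)
  expect_false("ch1_001" %in% scr$stages$stage3_s1)
  expect_true("ch1_002" %in% scr$stages$stage4_both)
  # a surviving protein without lineage is a named error
  tax2 <- tax[tax$protein_id != "ch1_002", ]
  expect_error(run_screen(dataset_sequences(ds), tax2), "ch1_002")
})

test_that("signal peptide heuristic fires on planted signals only", {
  set.seed(37)
  spec <- synthetic_spec(substitution_rate = 0.02)
  with_sig <- generate_protein(spec, "channel-g1", id = "a", signal = TRUE)
  expect_true(detect_signal_peptide(with_sig$record$sequence))
  no_sig <- generate_protein(spec, "channel-g1", id = "b", signal = FALSE)
  expect_false(detect_signal_peptide(no_sig$record$sequence))
  expect_false(detect_signal_peptide(paste0(strrep("D", 30), strrep("L", 20))))
  expect_warning(flag <- detect_signal_peptide("MKRLLLLLLLL"), "shorter")
  expect_false(flag)
})

test_that("signal-free channel counts are recovered exactly", {
  spec <- synthetic_spec(n_channels_group1 = 6, n_channels_group2 = 6,
                         n_decoys_per_class = 0, substitution_rate = 0.02,
                         n_signal_free_per_group = 2, rng_seed = 4)
  ds <- generate_dataset(spec)
  db <- dataset_sequences(ds)
  sig <- vapply(db, detect_signal_peptide, logical(1))
  g1 <- grepl("^ch1", names(db)); g2 <- grepl("^ch2", names(db))
  expect_identical(sum(!sig[g1]), 2L)
  expect_identical(sum(!sig[g2]), 2L)
})
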