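make_channel <- function(arch = "channel-g1", rate = 0.02, seed = 1,
                         signal = NULL) {
  set.seed(seed)
  spec <- synthetic_spec(substitution_rate = rate)
  generate_protein(spec, arch, id = "x", signal = signal)
}

truth_interval <- function(g, name) {
  r <- g$truth[g$truth$name == name, ]
  c(r$start, r$end)
}

test_that("selectivity-filter detection matches the signature patterns", {
  expect_true(detect_k_filter("ILTVGYGLI"))
  expect_true(detect_k_filter("AAGYGAA"))     # bare G-[YF]-G fallback
  expect_false(detect_k_filter("AAAAA"))
  expect_false(detect_k_filter(""))
  expect_false(detect_k_filter("AAGYGAA", fallback = NULL))
})

test_that("the pore-loop is recovered at the planted coordinates", {
  g <- make_channel(rate = 0.02, seed = 3)
  tm <- predict_tm_segments(g$record$sequence)
  p <- detect_pore_loop(tm)
  planted <- truth_interval(g, "P")
  expect_lte(abs(p$start - planted[1]), 2)
  expect_lte(abs(p$end - planted[2]), 2)
  expect_error(detect_pore_loop(tm[!tm$passes_test, ]), "two passing")
})

test_that("two TMs joined by a polar linker have no pore candidate", {
  seq <- paste0(strrep("L", 19), strrep("D", 30), strrep("L", 19))
  tm <- predict_tm_segments(seq)
  expect_identical(sum(tm$passes_test), 2L)
  expect_null(detect_pore_loop(tm))
})

test_that("planted channels classify as channels; decoys do not", {
  g <- make_channel("channel-g1", seed = 7)
  tm <- predict_tm_segments(g$record$sequence)
  prof <- classify_topology("x", g$record$sequence,
                            truth_interval(g, "S1"),
                            truth_interval(g, "S2"), tm)
  expect_true(prof$is_channel)
  prof <- assign_groups(prof)
  expect_identical(prof$group, 1L)
  expect_match(prof$suggested_annotation, "potassium")

  set.seed(7)
  spec <- synthetic_spec()
  sol <- generate_protein(spec, "soluble-binder", id = "d")
  tms <- predict_tm_segments(sol$record$sequence)
  profs <- classify_topology("d", sol$record$sequence,
                             sol$truth[sol$truth$name == "S1",
                                       c("start", "end")],
                             sol$truth[sol$truth$name == "S2",
                                       c("start", "end")], tms)
  expect_false(profs$is_channel)
  expect_true(is.na(assign_groups(profs)$group))
})

test_that("binding lobes in reversed order are not a channel", {
  g <- make_channel(seed = 9)
  tm <- predict_tm_segments(g$record$sequence)
  prof <- classify_topology("x", g$record$sequence,
                            truth_interval(g, "S2"),
                            truth_interval(g, "S1"), tm)
  expect_false(prof$is_channel)
  expect_error(classify_topology("x", g$record$sequence, c(10, 50),
                                 c(30, 90), tm), "overlap")
})

test_that("an extra TM outside the core does not break classification", {
  g <- make_channel(seed = 11)
  set.seed(11)
  extra <- paste(c(rep("D", 10),
                   sample(c("I", "L", "F", "V"), 19, replace = TRUE),
                   rep("D", 10)), collapse = "")
  seq2 <- paste0(g$record$sequence, extra)
  tm <- predict_tm_segments(seq2)
  expect_gte(sum(tm$passes_test), 3L)
  prof <- classify_topology("x", seq2, truth_interval(g, "S1"),
                            truth_interval(g, "S2"), tm)
  expect_true(prof$is_channel)
  # region order invariant: the channel regions remain ordered
  r <- prof$regions
  expect_true(all(diff(r$start) >= 0))
  expect_identical(r$name[r$region_type %in% c("TM", "P")],
                   c("M1", "P", "M2"))
})

test_that("group labels are fully recovered on a seeded dataset", {
  spec <- synthetic_spec(n_channels_group1 = 5, n_channels_group2 = 5,
                         n_decoys_per_class = 3, substitution_rate = 0.02,
                         rng_seed = 19)
  ds <- generate_dataset(spec)
  db <- dataset_sequences(ds)
  scr <- run_screen(db, ds$taxonomy)
  cls <- classify_screen_hits(db, scr)
  tab <- cls$table
  got <- setNames(tab$group, tab$protein_id)
  expect_identical(sum(got[grepl("^ch1", names(got))] == 1L,
                       na.rm = TRUE), 5L)
  expect_identical(sum(got[grepl("^ch2", names(got))] == 2L,
                       na.rm = TRUE), 5L)
  # group implies channel
  expect_true(all(tab$is_channel[!is.na(tab$group)]))
})
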