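test_that("p-distance counts mismatches over comparable columns", {
  a <- do.call(rbind, strsplit(c("ARNDARNDAR", "ARNDARNDAR"), ""))
  rownames(a) <- c("x", "y")
  expect_identical(unname(p_distance(a)["x", "y"]), 0)
  b <- do.call(rbind, strsplit(c("ARNDARNDAR", "AWNDARNDAW"), ""))
  rownames(b) <- c("x", "y")
  expect_identical(unname(p_distance(b)["x", "y"]), 0.2)
  # gapped columns are excluded pairwise
  g <- do.call(rbind, strsplit(c("AR-DA", "AWND-"), ""))
  rownames(g) <- c("x", "y")
  expect_identical(unname(p_distance(g)["x", "y"]), 1 / 3)
  allgap <- do.call(rbind, strsplit(c("A---", "-RRR"), ""))
  rownames(allgap) <- c("x", "y")
  expect_error(p_distance(allgap), "comparable")
  # random alignments match a per-pair loop oracle
  set.seed(3)
  m <- do.call(rbind, lapply(1:5, function(i)
    strsplit(random_aa(40), "")[[1]]))
  rownames(m) <- paste0("t", 1:5)
  d <- p_distance(m)
  for (i in 1:4) for (j in (i + 1):5)
    expect_identical(d[i, j], mean(m[i, ] != m[j, ]))
})

test_that("neighbor joining recovers additive trees exactly", {
  set.seed(19)
  for (i in 1:50) {
    tr <- ape::rtree(sample(6:8, 1))
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 1)
    dm <- cophenetic(tr)
    nj <- neighbor_joining(dm)
    expect_identical(rf_distance(nj, tr), 0L)
  }
  # three taxa resolve to the unique star topology
  tr3 <- neighbor_joining(cophenetic(ape::rtree(3)))
  expect_identical(length(tr3$tip.label), 3L)
  # label order does not change the unrooted topology
  tr <- ape::rtree(7)
  dm <- cophenetic(tr)
  perm <- sample(rownames(dm))
  expect_identical(rf_distance(neighbor_joining(dm),
                               neighbor_joining(dm[perm, perm])), 0L)
  asym <- dm; asym[1, 2] <- asym[1, 2] + 1
  expect_error(neighbor_joining(asym), "symmetric")
})

test_that("monophyly agrees with an exhaustive bipartition oracle", {
  # enumerate the tip set below every edge (pendant edges included) and
  # test whether the target or its complement is exactly one of them
  bipartition_oracle <- function(tree, tips) {
    tree <- ape::unroot(tree)
    ntip <- length(tree$tip.label)
    if (length(tips) %in% c(0L, ntip)) return(length(tips) == ntip)
    below <- function(node) {
      if (node <= ntip) return(node)
      kids <- tree$edge[tree$edge[, 1] == node, 2]
      unlist(lapply(kids, below))
    }
    target <- sort(match(tips, tree$tip.label))
    compl <- sort(setdiff(seq_len(ntip), target))
    for (child in tree$edge[, 2]) {
      s <- sort(below(child))
      if (identical(s, target) || identical(s, compl)) return(TRUE)
    }
    FALSE
  }
  set.seed(23)
  for (i in 1:20) {
    tr <- ape::rtree(sample(6:10, 1))
    states <- setNames(sample(c("a", "b"), length(tr$tip.label),
                              replace = TRUE), tr$tip.label)
    if (length(unique(states)) < 2) states[1] <- "b"
    for (st in c("a", "b")) {
      if (!any(states == st)) next
      expect_identical(monophyly(tr, states, st),
                       bipartition_oracle(tr, names(states)[states == st]))
    }
  }
  sc <- generate_species_scenario(4, 4, transfers = 0, rng_seed = 1)
  expect_true(monophyly(sc$tree, sc$groups, "group1"))
  scattered <- sc$groups
  scattered[c("A01", "B01")] <- c("group2", "group1")
  expect_false(monophyly(sc$tree, scattered, "group1"))
  expect_error(monophyly(sc$tree, sc$groups[-1], "group1"), "missing")
})

test_that("Fitch counts match brute force and ignore the rooting", {
  set.seed(29)
  for (i in 1:10) {
    tr <- ape::rtree(sample(6:10, 1))
    states <- setNames(sample(c("a", "b", "c"), length(tr$tip.label),
                              replace = TRUE), tr$tip.label)
    expect_identical(as.numeric(fitch_min_changes(tr, states)),
                     brute_fitch(tr, states))
  }
  # monophyletic two-state tree: exactly one change
  sc <- generate_species_scenario(5, 5, transfers = 0, rng_seed = 31)
  expect_identical(fitch_min_changes(sc$tree, sc$groups), 1L)
  # single state: zero changes
  one <- setNames(rep("a", length(sc$tree$tip.label)), sc$tree$tip.label)
  expect_identical(fitch_min_changes(sc$tree, one), 0L)
  # root invariance over all rootings of an 8-leaf tree
  tr <- ape::rtree(8)
  states <- setNames(rep(c("a", "b"), each = 4), tr$tip.label)
  ref <- fitch_min_changes(tr, states)
  for (tip in tr$tip.label) {
    rooted <- ape::root(tr, outgroup = tip, resolve.root = TRUE)
    expect_identical(fitch_min_changes(rooted, states), ref)
  }
})

test_that("region trees simulated on one topology are congruent", {
  set.seed(37)
  tr <- ape::rtree(8)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.15, 0.4)
  alns <- list(
    S1 = simulate_alignment_on_tree(tr, 500, rate = 0.5, rng_seed = 1),
    channel = simulate_alignment_on_tree(tr, 500, rate = 0.5, rng_seed = 2),
    S2 = simulate_alignment_on_tree(tr, 500, rate = 0.5, rng_seed = 3))
  cong <- region_tree_congruence(alns)
  expect_true(all(cong$rf == 0))
  expect_identical(rf_distance(cong$trees$S1, cong$trees$S1), 0L)
  # a region simulated on a different topology is incongruent
  tr2 <- ape::rtree(8)
  tr2$tip.label <- tr$tip.label
  tr2$edge.length <- stats::runif(nrow(tr2$edge), 0.15, 0.4)
  while (ape::dist.topo(ape::unroot(tr), ape::unroot(tr2)) == 0) {
    tr2 <- ape::rtree(8); tr2$tip.label <- tr$tip.label
    tr2$edge.length <- stats::runif(nrow(tr2$edge), 0.15, 0.4)
  }
  alns$S2 <- simulate_alignment_on_tree(tr2, 500, rate = 0.5, rng_seed = 4)
  cong2 <- region_tree_congruence(alns)
  expect_gt(cong2$rf["S1", "S2"], 0)
  bad <- alns
  rownames(bad$S2)[1] <- "other"
  expect_error(region_tree_congruence(bad), "mismatched")
})

test_that("newick output round-trips through the package readers", {
  sc <- generate_species_scenario(5, 4, transfers = 1, rng_seed = 41)
  f <- tempfile(fileext = ".nwk")
  write_newick(sc$tree, f)
  back <- read_newick(f)
  expect_setequal(back$tip.label, sc$tree$tip.label)
  expect_identical(rf_distance(back, sc$tree), 0L)
})
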