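# Candidate construction for the basal split, likelihood comparison,
# bootstrap support, and the per-locus tally.

test_that("quartet candidates are the three rooted resolutions", {
  g <- quartet_groups()
  cands <- build_candidate_topologies(g)
  expect_named(cands, c("Tree1", "Tree2", "Tree3"))
  for (tr in cands) {
    expect_true(ape::is.rooted(tr))
    expect_setequal(tr$tip.label, g$taxon)
    expect_equal(length(tr$tip.label), 4L)
  }
  # all three topologies pairwise distinct
  expect_false(ape::all.equal.phylo(cands$Tree1, cands$Tree2,
                                    use.edge.length = FALSE))
  expect_false(ape::all.equal.phylo(cands$Tree2, cands$Tree3,
                                    use.edge.length = FALSE))
})

test_that("candidates differ in exactly one bipartition (RF = 2)", {
  skip_if_not_installed("phangorn")
  g <- quartet_groups()
  cands <- build_candidate_topologies(g)
  rf <- phangorn::RF.dist(cands$Tree1, cands$Tree2)
  expect_equal(rf, 2)
  expect_equal(phangorn::RF.dist(cands$Tree1, cands$Tree3), 2)
  expect_equal(phangorn::RF.dist(cands$Tree2, cands$Tree3), 2)
})

test_that("multi-taxon groups keep identical backbones across candidates", {
  g <- group_assignment(data.frame(
    taxon = c("og1", "og2", "e1", "e2", "o1", "c1"),
    group = c("outgroup", "outgroup", "Elopomorpha", "Elopomorpha",
              "Osteoglossomorpha", "Clupeocephala")))
  cands <- build_candidate_topologies(g)
  for (tr in cands) {
    expect_setequal(tr$tip.label, g$taxon)
    expect_equal(sum(duplicated(tr$tip.label)), 0L)
    # the Elopomorpha pair stays monophyletic in every candidate
    expect_true(ape::is.monophyletic(tr, c("e1", "e2")))
  }
})

test_that("the true topology wins on strongly informative data", {
  set.seed(31)
  m <- load_empirical_model("JTT", alpha = 0.7)
  truth_tree <- quartet_tree("Tree2", delta = 0.05)
  a <- simulate_alignment(truth_tree, m, 5000, seed = 77)
  cands <- build_candidate_topologies(quartet_groups())
  cmp <- compare_topologies(a, cands, m)
  expect_equal(cmp$winner, "Tree2")
  expect_false(cmp$tie)
  # permuting candidate order leaves the winner unchanged
  cmp_perm <- compare_topologies(a, cands[c(3, 1, 2)], m)
  expect_equal(cmp_perm$winner, "Tree2")
  # per-candidate logL equals an independent single-candidate re-fit
  refit <- optimize_branches_and_alpha(a, ape::unroot(cands$Tree1), m)
  expect_equal(cmp$fits$logL[cmp$fits$hypothesis == "Tree1"],
               refit$loglik, tolerance = 1e-4)
})

test_that("RELL bootstrap proportions partition the replicates", {
  set.seed(32)
  m <- load_empirical_model("JTT", alpha = 0.7)
  a <- simulate_alignment(quartet_tree("Tree2", delta = 0.05), m, 3000,
                          seed = 5)
  cands <- build_candidate_topologies(quartet_groups())
  cmp <- compare_topologies(a, cands, m, bootstrap = 50, seed = 9)
  expect_equal(sum(cmp$bp), 1)
  expect_gt(cmp$bp["Tree2"], 0.5)
  expect_error(bootstrap_support(cmp, B = 0), "B must be")
})

test_that("full bootstrap mode re-optimizes and still partitions", {
  set.seed(33)
  m <- load_empirical_model("JTT", alpha = 1, K = 2L)
  a <- simulate_alignment(quartet_tree("Tree2", delta = 0.08), m, 400,
                          seed = 6)
  cands <- build_candidate_topologies(quartet_groups())
  cmp <- compare_topologies(a, cands, m,
                            control = list(tol = 1e-3, max_outer = 1L))
  bp <- bootstrap_support(cmp, B = 5, mode = "full", seed = 10, a = a,
                          control = list(tol = 1e-3, max_outer = 1L))
  expect_equal(sum(bp), 1)
})

test_that("gene tallies conserve locus counts and skip incomplete loci", {
  set.seed(34)
  m <- load_empirical_model("JTT", alpha = 0.7)
  tr <- quartet_tree("Tree2", delta = 0.05)
  loci <- lapply(1:8, function(i)
    simulate_alignment(tr, m, 400, seed = 40 + i))
  # one locus with no Elopomorpha taxon
  loci[[9]] <- extract_taxon_subset(loci[[1]], c("out", "ost", "clu"))
  names(loci) <- paste0("L", 1:9)
  tally <- gene_tree_tally(loci, quartet_groups(), m,
                           control = list(tol = 1e-3, max_outer = 1L))
  expect_equal(sum(tally$counts) + tally$skipped, 9)
  expect_equal(tally$skipped, 1L)
  expect_true(tally$per_locus$skipped[tally$per_locus$locus == "L9"])
  # modal winner is the generating topology
  expect_equal(names(which.max(tally$counts)), "Tree2")
})

test_that("winner recovery improves with sequence length", {
  set.seed(35)
  m <- load_empirical_model("JTT", alpha = 0.7)
  tr <- quartet_tree("Tree2", delta = 0.02)
  cands <- build_candidate_topologies(quartet_groups())
  hits <- vapply(c(300, 3000), function(n) {
    wins <- 0
    for (r in 1:8) {
      a <- simulate_alignment(tr, m, n, seed = 1000 * n + r)
      cmp <- compare_topologies(a, cands, m,
                                control = list(tol = 1e-3, max_outer = 1L))
      wins <- wins + (cmp$winner == "Tree2")
    }
    wins
  }, 0)
  expect_true(hits[2] >= hits[1])
  expect_equal(hits[2], 8)  # 3000 sites with delta 0.02 is decisive
})
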