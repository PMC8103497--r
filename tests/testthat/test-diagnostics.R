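# Locus QC filters, b_R / TBL / composition chi-square diagnostics,
# top-k selection and correlation.

test_that("b_R is the path length from the teleost MRCA", {
  g <- quartet_groups()
  # direct child of the MRCA
  tr <- parse_newick("((elo:0.1,(ost:0.2,clu:0.3):0.05):0.02,out:0.4);")
  expect_equal(branch_length_from_teleost_mrca(tr, g, "elo"), 0.1)
  expect_equal(branch_length_from_teleost_mrca(tr, g, "ost"), 0.25)
  # manual path sum over three edges
  expect_equal(branch_length_from_teleost_mrca(tr, g, "clu"),
               0.05 + 0.3)
  # outgroup path runs through the root
  expect_equal(branch_length_from_teleost_mrca(tr, g, "out"),
               0.02 + 0.4)
  g2 <- group_assignment(data.frame(
    taxon = c("Out", "T1", "T2"),
    group = c("outgroup", "Clupeocephala", "Elopomorpha")))
  tr2 <- parse_newick("(Out:0.5,(T1:0.2,T2:0.2):0.1);")
  expect_equal(branch_length_from_teleost_mrca(tr2, g2, "Out"), 0.6)
  expect_error(branch_length_from_teleost_mrca(tr2, g2, "nope"),
               "not in tree")
  expect_error(branch_length_from_teleost_mrca(ape::unroot(tr), g, "elo"),
               "rooted")
})

test_that("b_R is invariant to within-group tip relabeling", {
  g <- group_assignment(data.frame(
    taxon = c("out", "e1", "e2", "o1", "c1"),
    group = c("outgroup", "Elopomorpha", "Elopomorpha",
              "Osteoglossomorpha", "Clupeocephala")))
  tr <- parse_newick(
    "(((e1:0.1,e2:0.15):0.05,(o1:0.2,c1:0.25):0.03):0.02,out:0.3);")
  before <- branch_length_from_teleost_mrca(tr, g, "o1")
  tr2 <- tr
  tr2$tip.label[match(c("e1", "e2"), tr2$tip.label)] <- c("e2", "e1")
  expect_equal(branch_length_from_teleost_mrca(tr2, g, "o1"), before)
})

test_that("total branch length sums edges and scales linearly", {
  expect_equal(total_branch_length(parse_newick("(A:0.1,B:0.2);")), 0.3)
  tr <- parse_newick(
    "((a:0.11,b:0.23):0.08,((c:0.16,d:0.3):0.05,(e:0.2,f:0.12):0.07):0.01);")
  expect_equal(total_branch_length(tr),
               0.11 + 0.23 + 0.08 + 0.16 + 0.3 + 0.05 + 0.2 + 0.12 +
                 0.07 + 0.01)
  tr2 <- tr
  tr2$edge.length <- tr2$edge.length * 2
  expect_equal(total_branch_length(tr2), 2 * total_branch_length(tr))
})

test_that("mean pairwise chi-square matches hand arithmetic", {
  # identical compositions
  a <- teleo_alignment(c(t1 = "AARRNN", t2 = "RANARN"), "AA20")
  expect_equal(mean_pairwise_chi2(a), 0)
  # 3-state toy counts (10, 0, 10) vs (5, 5, 10): chi2 = 20/3
  s1 <- paste(c(rep("A", 10), rep("N", 10)), collapse = "")
  s2 <- paste(c(rep("A", 5), rep("R", 5), rep("N", 10)), collapse = "")
  a2 <- teleo_alignment(c(t1 = s1, t2 = s2), "AA20")
  expect_equal(mean_pairwise_chi2(a2), 20 / 3, tolerance = 1e-12)
  # symmetry
  a3 <- teleo_alignment(c(t1 = s2, t2 = s1), "AA20")
  expect_equal(mean_pairwise_chi2(a3), mean_pairwise_chi2(a2))
  # taxa with no residues are skipped with a warning
  a4 <- teleo_alignment(c(t1 = s1, t2 = s2,
                          t3 = paste(rep("-", 20), collapse = "")), "AA20")
  expect_warning(v <- mean_pairwise_chi2(a4), "skipped")
  expect_equal(v, 20 / 3, tolerance = 1e-12)
})

test_that("locus filters exclude exactly the planted violations", {
  diags <- tibble::tibble(
    locus = paste0("L", 1:5),
    n_sites = c(300, 300, 60, 300, 300),
    shared_sites = c(120, 49, 55, 200, 150),
    n_taxa = c(6, 6, 6, 5, 6),
    n_groups = c(4, 4, 4, 3, 4),
    tbl = c(1, 2, 1.5, 1, 8),
    max_br = c(0.5, 0.4, 0.6, 0.5, 3.5),
    chi2 = runif(5)
  )
  rep <- apply_locus_filters(diags)
  expect_setequal(rep$surviving, c("L1", "L3"))
  expect_equal(rep$excluded$min_shared_sites, "L2")
  expect_equal(rep$excluded$max_br, "L5")
  expect_equal(rep$excluded$require_all_groups, "L4")
  # conservation: surviving + excluded = input
  expect_equal(length(rep$surviving) + sum(rep$table$excluded),
               nrow(diags))
  expect_error(apply_locus_filters(diags, list(min_sites = 10)),
               "unknown filter rule")
  # a locus excluded by several rules lists all reasons
  diags2 <- diags
  diags2$shared_sites[5] <- 10
  rep2 <- apply_locus_filters(diags2)
  reasons5 <- rep2$table$reasons[[which(rep2$table$locus == "L5")]]
  expect_setequal(reasons5, c("min_shared_sites", "max_br"))
})

test_that("top-k selection sorts ascending with stable ties", {
  diags <- tibble::tibble(locus = c("a", "b", "c"),
                          tbl = c(0.3, 0.1, 0.2),
                          chi2 = c(1, 1, 1))
  expect_equal(select_top_loci(diags, "tbl", 2), c("b", "c"))
  expect_equal(select_top_loci(diags, "tbl", 10), c("b", "c", "a"))
  expect_equal(select_top_loci(diags, "chi2", 3), c("a", "b", "c"))
  expect_error(select_top_loci(diags, "tbl", 0), "k must be")
})

test_that("pearson correlation matches hand computation", {
  expect_equal(pearson_correlation(1:5, 2 * (1:5) + 3)$r, 1,
               tolerance = 1e-12)
  r <- pearson_correlation(c(1, 2, 3), c(2, 1, 4))
  expect_equal(r$r, 2 / sqrt(2 * 42 / 9), tolerance = 1e-4)
  expect_error(pearson_correlation(1:2, 2:3), "n >= 3")
  expect_error(pearson_correlation(c(1, 1, 1), 1:3), "constant")
})

test_that("gene diagnostics assemble per-locus rows with fitted trees", {
  set.seed(21)
  m <- load_empirical_model("JTT", alpha = 0.7)
  tr <- quartet_tree("Tree2")
  loci <- lapply(1:3, function(i)
    simulate_alignment(tr, m, 150, seed = 60 + i))
  names(loci) <- paste0("g", 1:3)
  diags <- gene_diagnostics(loci, quartet_groups(), topology = tr, m = m,
                            control = list(tol = 1e-3, max_outer = 1L))
  expect_equal(nrow(diags), 3L)
  expect_true(all(diags$tbl > 0))
  expect_true(all(diags$max_br > 0))
  expect_true(all(diags$shared_sites == 150))
  expect_true(all(diags$n_groups == 4L))
})
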