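# Synthetic study templates and the multi-locus generator.

test_that("preset templates carry the documented species depths", {
  tpl <- make_study_template("bian_like")
  d <- setNames(tpl$taxa$depth, tpl$taxa$taxon)
  expect_equal(unname(d[c("outgroup_long", "outgroup_short")]),
               c(0.43, 0.21))
  expect_equal(unname(d[c("elopomorpha_eel", "elopomorpha_tarpon")]),
               c(0.18, 0.10))
  expect_true(all(d[grep("^osteoglossomorpha", names(d))] >= 0.17 &
                    d[grep("^osteoglossomorpha", names(d))] <= 0.22))
  expect_true(all(d[grep("^clupeocephala", names(d))] >= 0.23 &
                    d[grep("^clupeocephala", names(d))] <= 0.32))
  expect_equal(make_study_template("chen_like")$taxa$depth[
    make_study_template("chen_like")$taxa$taxon == "outgroup_gar"], 0.14)
})

test_that("template overrides replace fields and reject unknown keys", {
  tpl <- make_study_template("bian_like",
                             list(n_loci = 7L, truth = "Tree3"))
  expect_equal(tpl$n_loci, 7L)
  expect_equal(tpl$truth, "Tree3")
  expect_error(make_study_template("bian_like", list(nloci = 7)),
               "unknown template field")
  expect_error(make_study_template("mystery"))
})

test_that("template trees realize the advertised b_R for every taxon", {
  for (preset in c("bian_like", "chen_like", "hughes_like", "uce_like")) {
    for (truth in c("Tree1", "Tree2", "Tree3")) {
      tpl <- make_study_template(preset, list(truth = truth))
      tr <- template_tree(tpl)
      g <- template_groups(tpl)
      expect_true(ape::is.rooted(tr))
      for (i in seq_len(nrow(tpl$taxa))) {
        expect_equal(
          branch_length_from_teleost_mrca(tr, g, tpl$taxa$taxon[i]),
          tpl$taxa$depth[i], tolerance = 1e-10)
      }
      # the first-diverging group matches the truth label
      mrca <- teleost_mrca(tr, g)
      kids <- tr$edge[tr$edge[, 1] == mrca, 2]
      first_group <- switch(truth, Tree1 = "Clupeocephala",
                            Tree2 = "Elopomorpha",
                            Tree3 = "Osteoglossomorpha")
      solo <- g$taxon[g$group == first_group]
      desc <- lapply(kids, function(k) {
        if (k <= length(tr$tip.label)) tr$tip.label[k]
        else ape::extract.clade(tr, k)$tip.label
      })
      expect_true(any(vapply(desc, setequal, TRUE, solo)))
    }
  }
})

test_that("studies are regenerated byte-identically from the manifest", {
  tpl <- make_study_template("bian_like",
                             list(n_loci = 3L, sites_per_locus = 80L))
  s1 <- generate_synthetic_study(tpl)
  s2 <- generate_synthetic_study(s1$manifest)
  expect_identical(lapply(s1$loci, unclass), lapply(s2$loci, unclass))
  expect_identical(s1$multipliers, s2$multipliers)
  expect_equal(length(s1$loci), 3L)
  expect_true(all(vapply(s1$loci, ncol, 0L) == 80L))
})

test_that("missingness never empties a group", {
  tpl <- make_study_template("hughes_like",
                             list(n_loci = 12L, sites_per_locus = 40L,
                                  missingness = 0.5))
  s <- generate_synthetic_study(tpl)
  g <- s$groups
  for (a in s$loci) {
    gp <- g[g$taxon %in% rownames(a), ]
    expect_equal(length(unique(gp$group)), 4L)
  }
  # some taxa actually dropped at this rate
  expect_true(any(vapply(s$loci, nrow, 0L) < nrow(tpl$taxa)))
})

test_that("perturbed taxa show elevated compositional chi-square", {
  tpl <- make_study_template("bian_like",
                             list(n_loci = 50L, sites_per_locus = 150L,
                                  perturb_eps = 0.3, rate_sigma = 0))
  s <- generate_synthetic_study(tpl)
  pert <- tpl$perturb
  others <- setdiff(rownames(s$loci[[1]]), pert)
  diff_sign <- vapply(s$loci, function(a) {
    mat <- unclass(a)
    chi_pair <- function(t1, t2) {
      sub <- teleo_alignment(mat[c(t1, t2), , drop = FALSE], "AA20")
      mean_pairwise_chi2(sub)
    }
    some <- others[1:4]
    with_pert <- mean(vapply(some, function(o) chi_pair(pert, o), 0))
    without <- mean(c(chi_pair(some[1], some[2]),
                      chi_pair(some[3], some[4])))
    with_pert > without
  }, TRUE)
  bt <- stats::binom.test(sum(diff_sign), length(diff_sign),
                          alternative = "greater")
  expect_lt(bt$p.value, 0.01)
})

test_that("per-locus divergence tracks the drawn rate multipliers", {
  tpl <- make_study_template("bian_like",
                             list(n_loci = 25L, sites_per_locus = 400L))
  s <- generate_synthetic_study(tpl)
  m <- template_model(tpl)
  tbls <- vapply(names(s$loci), function(nm) {
    fit <- optimize_branches_and_alpha(
      s$loci[[nm]], template_tree(tpl), m,
      control = list(tol = 1e-3, max_outer = 1L))
    total_branch_length(fit$tree)
  }, 0)
  expect_gte(pearson_correlation(tbls, s$multipliers)$r, 0.8)
})

test_that("concatenated synthetic data recovers the true topology", {
  tpl <- make_study_template("chen_like",
                             list(n_loci = 40L, sites_per_locus = 500L))
  s <- generate_synthetic_study(tpl)
  cat_aln <- concatenate_loci(s$loci)
  m <- template_model(tpl)
  m <- load_empirical_model(tpl$model_name,
                            freqs = empirical_frequencies(cat_aln),
                            alpha = tpl$alpha, K = tpl$K)
  bbs <- lapply(setNames(unique(s$groups$group), unique(s$groups$group)),
                function(gr) {
    taxa <- s$groups$taxon[s$groups$group == gr]
    if (length(taxa) < 2) return(NULL)
    ape::keep.tip(template_tree(tpl), taxa)
  })
  cands <- build_candidate_topologies(s$groups, backbones = bbs)
  cmp <- compare_topologies(cat_aln, cands, m,
                            control = list(tol = 1e-3, max_outer = 2L))
  expect_equal(cmp$winner, "Tree2")
})
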