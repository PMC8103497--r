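# Pruning likelihood against the exhaustive-enumeration oracle,
# optimization behavior, information criteria and model selection.

test_that("single-tip likelihood is the stationary log-probability", {
  m <- load_empirical_model("JTT", alpha = Inf, K = 1L)
  a <- teleo_alignment(c(t1 = "AR-A"), "AA20")
  tr <- structure(list(edge = matrix(c(2L, 1L), 1, 2),
                       edge.length = 0.4, Nnode = 1L, tip.label = "t1"),
                  class = "phylo")
  ll <- pruning_loglik(a, tr, m)
  # fully missing column contributes 0
  expected <- 2 * log(m$pi[1]) + log(m$pi[2])
  expect_equal(ll, expected, tolerance = 1e-12)
})

test_that("pruning equals exhaustive enumeration on a 4-taxon fixture", {
  set.seed(101)
  m <- load_empirical_model("JTT", alpha = 0.8)
  fx <- random_fixture("AA20", ntip = 4, nsites = 2)
  ll <- pruning_loglik(fx$alignment, fx$tree, m)
  expect_equal(ll, brute_force_loglik(fx$alignment, fx$tree, m),
               tolerance = 1e-8)
})

test_that("pruning equals enumeration across random fixtures (both alphabets)", {
  set.seed(202)
  for (i in 1:12) {
    alphabet <- if (i %% 2 == 0) "AA20" else "NT4"
    m <- random_model(alphabet)
    fx <- random_fixture(alphabet, with_missing = alphabet == "NT4")
    ll <- pruning_loglik(fx$alignment, fx$tree, m)
    expect_equal(ll, brute_force_loglik(fx$alignment, fx$tree, m),
                 tolerance = 1e-8)
  }
})

test_that("all-missing columns contribute exactly zero", {
  set.seed(7)
  m <- load_empirical_model("LG", alpha = 0.5)
  fx <- random_fixture("AA20", ntip = 4, nsites = 3)
  a2 <- teleo_alignment(cbind(unclass(fx$alignment),
                              matrix("?", 4, 2)), "AA20")
  expect_equal(pruning_loglik(a2, fx$tree, m),
               pruning_loglik(fx$alignment, fx$tree, m), tolerance = 1e-10)
})

test_that("likelihood is invariant to row order and rerooting", {
  set.seed(303)
  m <- load_empirical_model("WAG", alpha = 1.2)
  fx <- random_fixture("AA20", ntip = 5, nsites = 3)
  ll <- pruning_loglik(fx$alignment, fx$tree, m)
  perm <- sample(nrow(fx$alignment))
  a_perm <- teleo_alignment(unclass(fx$alignment)[perm, , drop = FALSE],
                            "AA20")
  expect_equal(pruning_loglik(a_perm, fx$tree, m), ll, tolerance = 1e-10)
  un <- ape::unroot(fx$tree)
  ll_un <- pruning_loglik(fx$alignment, un, m)
  re <- ape::root(un, outgroup = fx$tree$tip.label[1], resolve.root = TRUE)
  expect_equal(pruning_loglik(fx$alignment, re, m), ll_un,
               tolerance = 1e-8)
})

test_that("identical sequences drive branch lengths to the lower bound", {
  m <- load_empirical_model("JTT", alpha = Inf, K = 1L)
  mat <- matrix(rep(strsplit("ARNDCQEGHILK", "")[[1]], each = 4), 4, 12,
                dimnames = list(paste0("t", 1:4), NULL))
  a <- teleo_alignment(mat, "AA20")
  star <- ape::read.tree(text = "(t1:0.1,t2:0.1,t3:0.1,t4:0.1);")
  fit <- optimize_branches_and_alpha(a, star, m, optimize_alpha = FALSE)
  expect_true(all(fit$tree$edge.length < 1e-6))
})

test_that("two-taxon ML distance matches the closed form", {
  # Jukes-Cantor: 20% observed differences => t = -3/4 log(1 - 4/3 * 0.2)
  m <- load_empirical_model("GTR", alpha = Inf, K = 1L)  # equal rates/freqs
  m$S[] <- 1; diag(m$S) <- 0
  mat <- rbind(s1 = rep(c("A", "C", "G", "T"), 25),
               s2 = c(rep(c("A", "C", "G", "T"), 20),
                      rep(c("C", "G", "T", "A"), 5)))
  a <- teleo_alignment(mat, "NT4")
  tr <- parse_newick("(s1:0.1,s2:0.1);")
  fit <- optimize_branches_and_alpha(a, tr, m, optimize_alpha = FALSE)
  expect_equal(sum(fit$tree$edge.length), -0.75 * log(1 - 0.2 * 4 / 3),
               tolerance = 1e-3)
})

test_that("branch lengths are recovered from long simulated alignments", {
  set.seed(404)
  m <- load_empirical_model("JTT", alpha = 0.9)
  tr <- parse_newick(
    "((a:0.11,b:0.23):0.08,(c:0.16,d:0.3):0.05,(e:0.2,f:0.12):0.07);")
  a <- simulate_alignment(tr, m, 20000, seed = 99)
  fit <- optimize_branches_and_alpha(a, tr, m)
  expect_true(fit$converged)
  expect_equal(fit$alpha, 0.9, tolerance = 0.15)
  po <- ape::reorder.phylo(tr, "postorder")
  rel_err <- abs(fit$tree$edge.length - po$edge.length) / po$edge.length
  expect_true(all(rel_err < 0.10))
  expect_false(is.unsorted(fit$trace))  # monotone optimization trace
})

test_that("pruning agrees with an independent likelihood implementation", {
  skip_if_not_installed("phangorn")
  set.seed(55)
  m <- load_empirical_model("JTT", alpha = 0.5)
  fx <- random_fixture("AA20", ntip = 5, nsites = 40)
  ll <- pruning_loglik(fx$alignment, fx$tree, m)
  pd <- phangorn::phyDat(unclass(fx$alignment), type = "AA")
  ref <- phangorn::pml(fx$tree, pd, model = "JTT", k = 4, shape = 0.5)
  expect_equal(ll, ref$logLik, tolerance = 1e-6)
})

test_that("information criteria follow the stated formulas", {
  ic <- information_criteria(-1000, 10, 1000)
  expect_identical(ic$AIC, 2020)
  expect_equal(ic$AICc, 2020 + 220 / 989, tolerance = 1e-12)
  expect_equal(ic$BIC, 2000 + 10 * log(1000), tolerance = 1e-12)
  expect_true(is.na(information_criteria(-10, 5, 6)$AICc))
})

test_that("model selection recovers the generating model family", {
  set.seed(606)
  freqs <- empirical_frequencies(
    simulate_alignment(parse_newick("(x:0.5,y:0.5);"),
                       load_empirical_model("LG"), 2000, seed = 3))
  gen <- load_empirical_model("LG", freqs = freqs, alpha = 0.7)
  tr <- parse_newick("((a:0.15,b:0.25):0.1,(c:0.2,d:0.35):0.08);")
  grid <- model_grid(c("JTT", "LG", "WAG"))
  for (g in 1:3) {
    a <- simulate_alignment(tr, gen, 2000, seed = 700 + g)
    sel <- select_model(a, tr, grid)
    expect_match(sel$best_name, "^LG")
    expect_equal(sel$table$AIC, -2 * sel$table$logL + 2 * sel$table$k)
  }
})

test_that("single-candidate selection is returned unconditionally", {
  set.seed(5)
  m <- load_empirical_model("JTT", alpha = 1)
  fx <- random_fixture("AA20", ntip = 4, nsites = 30)
  sel <- select_model(fx$alignment, fx$tree, list(only = m))
  expect_equal(sel$best_name, "only")
  expect_error(select_model(fx$alignment, fx$tree, list()), "empty")
})

test_that("fit objects expose tidy and glance summaries", {
  set.seed(6)
  m <- load_empirical_model("JTT", alpha = 1)
  fx <- random_fixture("AA20", ntip = 4, nsites = 50)
  fit <- optimize_branches_and_alpha(fx$alignment, fx$tree, m)
  td <- tidy(fit)
  expect_equal(nrow(td), nrow(fit$tree$edge))
  gl <- glance(fit)
  expect_equal(gl$AIC, -2 * gl$logLik + 2 * gl$k)
})
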