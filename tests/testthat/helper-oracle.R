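# Independent brute-force likelihood oracle and random fixture generators.
# The oracle never uses the package's pruning path: it builds the generator
# and transition matrices itself (base eigen on the full Q) and sums the
# likelihood over ALL internal-node (and missing-tip) state assignments.

.oracle_alphabet <- function(alphabet) {
  if (alphabet == "AA20")
    list(states = strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]],
         missing = c("-", "?", "X"))
  else
    list(states = c("A", "C", "G", "T"), missing = c("-", "?", "N"))
}

# transition matrix by brute eigen of the full generator (non-symmetric
# route, unlike the package's sqrt(pi) similarity transform)
.oracle_pmat <- function(S, pi, t) {
  Q <- S * rep(pi, each = nrow(S))
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q <- Q / (-sum(pi * diag(Q)))
  e <- eigen(Q)
  P <- Re(e$vectors %*% diag(exp(e$values * t)) %*% solve(e$vectors))
  P[P < 0] <- 0
  P
}

brute_force_loglik <- function(a, tree, m) {
  ab <- .oracle_alphabet(m$alphabet)
  c_states <- length(ab$states)
  rates <- discrete_gamma(m$alpha, m$K)
  K <- length(rates)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  edge <- tree$edge
  el <- tree$edge.length
  root <- setdiff(edge[, 1], edge[, 2])[1]
  obs <- matrix(match(unclass(a)[tree$tip.label, , drop = FALSE],
                      ab$states, nomatch = 0L), ntip, ncol(a))
  total <- 0
  for (site in seq_len(ncol(a))) {
    fixed <- obs[, site]
    free_nodes <- c(which(fixed == 0L), (ntip + 1L):nnode)
    grid <- as.matrix(expand.grid(rep(list(seq_len(c_states)),
                                      length(free_nodes))))
    lik_site <- 0
    for (k in seq_len(K)) {
      Ps <- lapply(seq_len(nrow(edge)), function(e)
        .oracle_pmat(m$S, m$pi, el[e] * rates[k]))
      s_full <- matrix(0L, nrow(grid), nnode)
      for (tp in seq_len(ntip))
        if (fixed[tp] > 0L) s_full[, tp] <- fixed[tp]
      for (j in seq_along(free_nodes)) s_full[, free_nodes[j]] <- grid[, j]
      prob <- m$pi[s_full[, root]]
      for (e in seq_len(nrow(edge))) {
        prob <- prob * Ps[[e]][cbind(s_full[, edge[e, 1]],
                                     s_full[, edge[e, 2]])]
      }
      lik_site <- lik_site + sum(prob) / K
    }
    total <- total + log(lik_site)
  }
  total
}

random_fixture <- function(alphabet = "AA20", ntip = NULL, nsites = NULL,
                           with_missing = FALSE) {
  ab <- .oracle_alphabet(alphabet)
  if (is.null(ntip)) ntip <- sample(2:5, 1)
  if (is.null(nsites)) nsites <- sample(1:3, 1)
  tree <- ape::rtree(ntip, rooted = TRUE)
  tree$edge.length <- runif(nrow(tree$edge), 0.02, 0.8)
  pool <- ab$states
  if (with_missing) pool <- c(pool, ab$missing[1:2])
  mat <- matrix(sample(pool, ntip * nsites, replace = TRUE), ntip, nsites,
                dimnames = list(tree$tip.label, NULL))
  list(alignment = teleo_alignment(mat, alphabet), tree = tree)
}

random_model <- function(alphabet = "AA20", alpha = NULL, K = 4L) {
  if (is.null(alpha)) alpha <- runif(1, 0.3, 2)
  if (alphabet == "AA20") {
    load_empirical_model(sample(c("JTT", "LG", "WAG"), 1), alpha = alpha,
                         K = K)
  } else {
    f <- runif(4, 0.5, 2)
    load_empirical_model("GTR", freqs = f / sum(f), alpha = alpha, K = K)
  }
}

# quartet template: one outgroup + one taxon per teleost group
quartet_tree <- function(truth = "Tree2", og_depth = 0.21,
                         tel_depths = c(Elopomorpha = 0.10,
                                        Osteoglossomorpha = 0.17,
                                        Clupeocephala = 0.23),
                         delta = 0.01, root_gap = 0.02) {
  first <- switch(truth, Tree1 = "Clupeocephala", Tree2 = "Elopomorpha",
                  Tree3 = "Osteoglossomorpha")
  rest <- setdiff(names(tel_depths), first)
  tip <- c(Elopomorpha = "elo", Osteoglossomorpha = "ost",
           Clupeocephala = "clu")
  tel <- sprintf("(%s:%g,(%s:%g,%s:%g):%g)",
                 tip[first], tel_depths[first],
                 tip[rest[1]], tel_depths[rest[1]] - delta,
                 tip[rest[2]], tel_depths[rest[2]] - delta, delta)
  parse_newick(sprintf("(%s:%g,out:%g);", tel, root_gap,
                       og_depth - root_gap))
}

quartet_groups <- function() {
  group_assignment(data.frame(
    taxon = c("out", "elo", "ost", "clu"),
    group = c("outgroup", "Elopomorpha", "Osteoglossomorpha",
              "Clupeocephala")))
}
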