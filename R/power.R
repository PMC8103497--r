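# Sequence simulation along a phylogeny and the correct-topology (N_C)
# power experiment over species subsets.

#' Simulate an alignment along a tree
#'
#' Per site, a discrete-gamma rate category is drawn, the root state is
#' drawn from the model's stationary frequencies, and states evolve along
#' each branch with `P(b * r)`. Terminal branches of taxa listed in
#' `tip_freqs` evolve under a generator rebuilt from the same
#' exchangeabilities but perturbed stationary frequencies, producing
#' compositional heterogeneity in those lineages.
#'
#' @param tree A rooted [ape::phylo] tree with branch lengths (expected
#'   substitutions/site).
#' @param m A [teleo_model]; its `alpha` and `K` define the site-rate
#'   distribution.
#' @param n_sites Number of sites (>= 1).
#' @param seed Optional integer seed; the output is deterministic given the
#'   seed.
#' @param tip_freqs Optional named list mapping taxon names to alternative
#'   stationary frequency vectors for their terminal branches.
#' @return A [teleo_alignment] with one row per tip.
#' @export
simulate_alignment <- function(tree, m, n_sites, seed = NULL,
                               tip_freqs = NULL) {
  stopifnot(n_sites >= 1)
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree has unset branch lengths", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  states <- .alphabets[[m$alphabet]]$states
  c_states <- length(states)
  rates <- .model_rates(m)
  K <- length(rates)
  po <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(po$tip.label)
  nnode <- ntip + po$Nnode
  root <- po$edge[nrow(po$edge), 1L]
  cat_of_site <- sample.int(K, n_sites, replace = TRUE)
  node_states <- matrix(0L, nnode, n_sites)
  node_states[root, ] <- sample.int(c_states, n_sites, replace = TRUE,
                                    prob = m$pi)
  ed <- .model_eigen(m)
  pmat_r <- function(eig, t, r) {
    P <- eig$A %*% (exp(eig$values * t * r) * eig$B)
    P[P < 0] <- 0
    P / rowSums(P)
  }
  eig_tip <- list()
  if (!is.null(tip_freqs)) {
    for (nm in names(tip_freqs)) {
      pf <- tip_freqs[[nm]]
      pf <- pf / sum(pf)
      mprime <- teleo_model(paste0(m$name, "'"), m$S, pf, alpha = m$alpha,
                            K = m$K, plus_F = TRUE, alphabet = m$alphabet)
      eig_tip[[nm]] <- .model_eigen(mprime)
    }
  }
  # preorder: reverse postorder edge ordering
  for (e in rev(seq_len(nrow(po$edge)))) {
    par <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    eig <- ed
    if (ch <= ntip && !is.null(eig_tip[[po$tip.label[ch]]]))
      eig <- eig_tip[[po$tip.label[ch]]]
    for (k in seq_len(K)) {
      idx <- which(cat_of_site == k)
      if (!length(idx)) next
      P <- pmat_r(eig, po$edge.length[e], rates[k])
      ps <- node_states[par, idx]
      out <- integer(length(idx))
      for (s in unique(ps)) {
        sel <- ps == s
        out[sel] <- sample.int(c_states, sum(sel), replace = TRUE,
                               prob = P[s, ])
      }
      node_states[ch, idx] <- out
    }
  }
  mat <- matrix(states[node_states[seq_len(ntip), , drop = FALSE]],
                ntip, n_sites, dimnames = list(po$tip.label, NULL))
  teleo_alignment(mat, m$alphabet)
}

#' Correct-topology power experiment (N_C)
#'
#' Replicated simulation under a model tree carrying a known (true) basal
#' arrangement: per replicate, an alignment is simulated on the full model
#' tree, each requested species subset is extracted, the three candidate
#' topologies (restricted to the subset, within-group backbones taken from
#' the model tree) are fitted, and the winner recorded. `N_C` is the number
#' of replicates in which the true topology wins. Replicate `i` uses seed
#' `seed + i`, so results are reproducible and subsets share the same
#' simulated replicates (paired comparisons).
#'
#' @param model_tree Rooted [ape::phylo] with branch lengths, containing
#'   all taxa; its basal arrangement must equal `truth`.
#' @param truth `"Tree1"`, `"Tree2"` or `"Tree3"`.
#' @param subsets Named list of taxon subsets (each with >= 1 taxon per
#'   group), or a single character vector.
#' @param groups A [group_assignment()] table.
#' @param m A [teleo_model] used both to simulate and to fit.
#' @param n_sites Sites per replicate (default 300).
#' @param n_reps Number of replicates (default 1000).
#' @param seed Base seed.
#' @param optimize_alpha Re-estimate the gamma shape per candidate fit
#'   (default) or keep it fixed at the simulation value.
#' @param control Optimizer control for the per-replicate fits (defaults
#'   lighter than [optimize_branches_and_alpha()]'s: `tol = 1e-4`,
#'   `max_outer = 2`).
#' @return An object of class `teleo_nc_set`: named list (one `teleo_nc`
#'   per subset), each with `wins` (per hypothesis), `n_c`, `ties`,
#'   `truth`, `subset`, `n_sites`, `n_reps`, `seed`.
#' @export
nc_experiment <- function(model_tree, truth = c("Tree1", "Tree2", "Tree3"),
                          subsets, groups, m, n_sites = 300L,
                          n_reps = 1000L, seed = 1L, optimize_alpha = TRUE,
                          control = list()) {
  truth <- match.arg(truth)
  if (is.character(subsets)) subsets <- list(subset1 = subsets)
  if (is.null(names(subsets)))
    names(subsets) <- paste0("subset", seq_along(subsets))
  ctl <- modifyList(list(tol = 1e-3, max_outer = 2L, max_sweeps = 8L,
                         brent_tol = 1e-2), control)
  cands <- lapply(subsets, function(keep) {
    unknown <- setdiff(keep, model_tree$tip.label)
    if (length(unknown))
      stop("subset taxon '", unknown[1L], "' not in model tree",
           call. = FALSE)
    gp <- groups[groups$taxon %in% keep, , drop = FALSE]
    if (length(unique(gp$group)) < 4L)
      stop("subset must contain >= 1 taxon per group", call. = FALSE)
    bbs <- lapply(setNames(.teleo_groups, .teleo_groups), function(g) {
      taxa <- intersect(.group_taxa(groups, g), keep)
      if (length(taxa) < 2L) return(NULL)
      ape::keep.tip(model_tree, taxa)
    })
    build_candidate_topologies(group_assignment(gp), backbones = bbs,
                               within = keep)
  })
  wins <- lapply(subsets, function(...)
    setNames(numeric(3L), .hypothesis_labels))
  ties <- setNames(numeric(length(subsets)), names(subsets))
  for (i in seq_len(n_reps)) {
    a <- simulate_alignment(model_tree, m, n_sites,
                            seed = (seed + i) %% .Machine$integer.max)
    for (s in names(subsets)) {
      sub <- extract_taxon_subset(a, subsets[[s]])
      cmp <- compare_topologies(sub, cands[[s]], m,
                                optimize_alpha = optimize_alpha,
                                control = ctl)
      wins[[s]][cmp$winner] <- wins[[s]][cmp$winner] + 1
      if (cmp$tie) ties[s] <- ties[s] + 1
    }
  }
  out <- lapply(names(subsets), function(s) {
    structure(list(truth = truth, subset = subsets[[s]],
                   subset_name = s, n_sites = n_sites, n_reps = n_reps,
                   seed = seed, wins = wins[[s]],
                   n_c = unname(wins[[s]][truth]), ties = ties[[s]]),
              class = "teleo_nc")
  })
  names(out) <- names(subsets)
  class(out) <- "teleo_nc_set"
  out
}

#' @export
print.teleo_nc <- function(x, ...) {
  cat("<teleo_nc> truth ", x$truth, ", N_C = ", x$n_c, "/", x$n_reps,
      " (wins: ", paste(names(x$wins), x$wins, collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

#' @export
print.teleo_nc_set <- function(x, ...) {
  for (nc in x) {
    cat(format(nc$subset_name, width = 16), " N_C = ", nc$n_c, "/",
        nc$n_reps, "  (truth ", nc$truth, ")\n", sep = "")
  }
  invisible(x)
}

#' Sensitivity of N_C to species divergence (b_R)
#'
#' For each designated contrast of subsets, the difference in b_R of the
#' species changed and the difference in N_C are paired, and their Pearson
#' correlation summarizes whether including less divergent species raises
#' the probability of recovering the true topology.
#'
#' @param nc A [nc_experiment()] result (`teleo_nc_set`) or tibble with
#'   columns `subset_name` and `n_c`.
#' @param b_r Named numeric vector: the b_R value characterizing each
#'   subset (e.g. the outgroup's depth).
#' @param contrasts Optional 2-column matrix of subset-name pairs; default
#'   all unordered pairs. At least 3 contrasts are required.
#' @return An object of class `teleo_sensitivity`: list with `table`
#'   (tibble: contrast, delta_br, delta_nc) and `correlation`
#'   (tibble `r`, `p` from [pearson_correlation()]).
#' @export
nc_sensitivity <- function(nc, b_r, contrasts = NULL) {
  if (inherits(nc, "teleo_nc_set")) {
    tab <- tibble::tibble(
      subset_name = vapply(nc, function(x) x$subset_name, ""),
      n_c = vapply(nc, function(x) x$n_c, 0)
    )
  } else {
    tab <- tibble::as_tibble(nc)
  }
  stopifnot(all(tab$subset_name %in% names(b_r)))
  if (is.null(contrasts)) {
    cmb <- utils::combn(tab$subset_name, 2L)
    contrasts <- t(cmb)
  }
  if (nrow(contrasts) < 3L)
    stop("need >= 3 contrasts", call. = FALSE)
  nc_of <- setNames(tab$n_c, tab$subset_name)
  delta_br <- b_r[contrasts[, 2L]] - b_r[contrasts[, 1L]]
  delta_nc <- nc_of[contrasts[, 2L]] - nc_of[contrasts[, 1L]]
  out <- tibble::tibble(
    from = contrasts[, 1L], to = contrasts[, 2L],
    delta_br = unname(delta_br), delta_nc = unname(delta_nc)
  )
  structure(list(table = out,
                 correlation = pearson_correlation(out$delta_br,
                                                   out$delta_nc)),
            class = "teleo_sensitivity")
}

#' @export
print.teleo_sensitivity <- function(x, ...) {
  cat("<teleo_sensitivity> r = ",
      format(x$correlation$r, digits = 4), " (p = ",
      format(x$correlation$p, digits = 3), ")\n", sep = "")
  print(x$table)
  invisible(x)
}
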