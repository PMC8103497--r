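# The three competing rooted hypotheses for the basal teleost split:
# candidate construction, likelihood comparison, bootstrap support, and a
# per-locus tally.

.teleo_groups <- c("outgroup", "Elopomorpha", "Osteoglossomorpha",
                   "Clupeocephala")
.hypothesis_labels <- c("Tree1", "Tree2", "Tree3")

#' Taxon-to-group assignment
#'
#' Validates a two-column table assigning every analyzed taxon to exactly
#' one of `outgroup`, `Elopomorpha`, `Osteoglossomorpha`, `Clupeocephala`.
#'
#' @param x A data frame with columns `taxon` and `group`.
#' @return A tibble of class `teleo_groups`.
#' @export
group_assignment <- function(x) {
  x <- tibble::as_tibble(x)
  stopifnot(all(c("taxon", "group") %in% names(x)))
  bad <- setdiff(unique(x$group), .teleo_groups)
  if (length(bad))
    stop("unknown group: '", bad[1L], "' (expected ",
         paste(.teleo_groups, collapse = ", "), ")", call. = FALSE)
  if (anyDuplicated(x$taxon))
    stop("taxon assigned more than once: '",
         x$taxon[duplicated(x$taxon)][1L], "'", call. = FALSE)
  class(x) <- c("teleo_groups", class(x))
  x
}

#' @rdname group_assignment
#' @param path Path to a tab-separated file with columns taxon, group (no
#'   header).
#' @export
read_group_table <- function(path) {
  x <- read.table(path, sep = "\t", header = FALSE,
                  col.names = c("taxon", "group"),
                  stringsAsFactors = FALSE)
  group_assignment(x)
}

.group_taxa <- function(groups, g, within = NULL) {
  taxa <- groups$taxon[groups$group == g]
  if (!is.null(within)) taxa <- intersect(taxa, within)
  taxa
}

# newick fragment for one group (no length on the fragment's own stem):
# user backbone, single tip, or a star
.clade_string <- function(taxa, backbone = NULL, blen = 0.1) {
  if (!is.null(backbone)) {
    bb <- backbone
    if (is.null(bb$edge.length)) bb$edge.length <- rep(blen, nrow(bb$edge))
    if (length(bb$tip.label) == 1L) return(bb$tip.label)
    bb$root.edge <- NULL
    return(sub(";$", "", ape::write.tree(bb)))
  }
  if (length(taxa) == 1L) return(taxa)
  paste0("(", paste0(taxa, ":", blen, collapse = ","), ")")
}

#' Build the three candidate rooted topologies
#'
#' Constructs the three rooted resolutions of the basal teleost split, with
#' identical outgroup and within-group backbones across candidates:
#' * Tree1 - Clupeocephala sister to (Elopomorpha, Osteoglossomorpha),
#'   i.e. Clupeocephala diverged first;
#' * Tree2 - Elopomorpha first, sister to (Osteoglossomorpha,
#'   Clupeocephala);
#' * Tree3 - Osteoglossomorpha first, sister to (Elopomorpha,
#'   Clupeocephala).
#'
#' @param groups A [group_assignment()] table; every group must have at
#'   least one taxon (at least one outgroup too).
#' @param backbones Optional named list (`outgroup`, `Elopomorpha`,
#'   `Osteoglossomorpha`, `Clupeocephala`) of [ape::phylo] backbones fixing
#'   the within-group branching pattern; each must contain exactly that
#'   group's taxa. Groups without a backbone and more than one taxon get an
#'   unresolved (star) clade.
#' @param within Optional taxon subset; candidates are built on
#'   `intersect(groups$taxon, within)`.
#' @param blen Starting branch length for edges without a supplied length.
#' @return Named list of three rooted [ape::phylo] trees
#'   (`Tree1`, `Tree2`, `Tree3`).
#' @export
build_candidate_topologies <- function(groups, backbones = NULL,
                                       within = NULL, blen = 0.1) {
  gtaxa <- lapply(setNames(.teleo_groups, .teleo_groups), .group_taxa,
                  groups = groups, within = within)
  for (g in .teleo_groups)
    if (length(gtaxa[[g]]) == 0L)
      stop("group '", g, "' has no taxa", call. = FALSE)
  cl <- list()
  for (g in .teleo_groups) {
    bb <- backbones[[g]]
    if (!is.null(bb)) {
      if (!setequal(bb$tip.label, gtaxa[[g]]))
        stop("backbone for '", g, "' does not match the group's taxa",
             call. = FALSE)
    }
    cl[[g]] <- .clade_string(gtaxa[[g]], bb, blen)
  }
  og <- paste0(cl[["outgroup"]], ":", blen)
  pair <- function(x, y)
    paste0("(", x, ":", blen, ",", y, ":", blen, ")")
  e <- cl[["Elopomorpha"]]; o <- cl[["Osteoglossomorpha"]]
  cc <- cl[["Clupeocephala"]]
  tel <- c(
    Tree1 = pair(cc, pair(e, o)),
    Tree2 = pair(e, pair(o, cc)),
    Tree3 = pair(o, pair(e, cc))
  )
  out <- lapply(tel, function(t)
    parse_newick(paste0("(", og, ",", t, ":", blen, ");")))
  names(out) <- .hypothesis_labels
  out
}

#' Compare the three candidate topologies by maximum likelihood
#'
#' Each candidate is optimized independently (branch lengths and gamma
#' shape) on the same alignment and model; the topology with the highest
#' log-likelihood is the winner. Exact likelihood ties are broken towards
#' the lowest hypothesis index and flagged.
#'
#' @inheritParams optimize_branches_and_alpha
#' @param candidates Named list of three trees from
#'   [build_candidate_topologies()].
#' @param bootstrap Number of bootstrap replicates for support values
#'   (0 = none).
#' @param mode Bootstrap mode, `"rell"` (default) or `"full"`; see
#'   [bootstrap_support()].
#' @param seed Seed for the bootstrap resampling.
#' @param tie_tol Absolute log-likelihood difference treated as a tie.
#' @return An object of class `teleo_comparison`: list with `fits` (tibble:
#'   hypothesis, logL, alpha, k, AIC, converged), `winner`, `tie`,
#'   `bp` (named bootstrap proportions, when requested), and the per-fit
#'   site log-likelihood matrix used by RELL.
#' @export
compare_topologies <- function(a, candidates, m, optimize_alpha = TRUE,
                               control = list(), bootstrap = 0L,
                               mode = c("rell", "full"), seed = NULL,
                               tie_tol = 1e-9) {
  mode <- match.arg(mode)
  stopifnot(length(candidates) >= 2L)
  if (is.null(names(candidates)))
    names(candidates) <- .hypothesis_labels[seq_along(candidates)]
  patterns <- if (inherits(a, "teleo_patterns")) a else compress_patterns(a)
  fits <- lapply(candidates, function(tr)
    optimize_branches_and_alpha(patterns, ape::unroot(tr), m,
                                optimize_alpha = optimize_alpha,
                                control = control))
  ll <- unname(vapply(fits, function(f) f$loglik, 0))
  winner <- which.max(ll)
  tie <- sum(abs(ll - max(ll)) <= tie_tol) > 1L
  if (tie) winner <- which(abs(ll - max(ll)) <= tie_tol)[1L]
  tab <- tibble::tibble(
    hypothesis = names(candidates),
    logL = ll,
    alpha = vapply(fits, function(f) f$alpha, 0),
    k = vapply(fits, function(f) f$k, 0L),
    AIC = vapply(fits, function(f) f$AIC, 0),
    converged = vapply(fits, function(f) f$converged, TRUE)
  )
  out <- structure(list(fits = tab, fit_objects = fits,
                        winner = names(candidates)[winner], tie = tie,
                        site_loglik = vapply(fits, function(f) f$site_loglik,
                                             numeric(length(patterns$weights))),
                        weights = patterns$weights,
                        n_sites = sum(patterns$weights),
                        candidates = candidates, model = m, bp = NULL),
                   class = "teleo_comparison")
  if (bootstrap > 0L) {
    out$bp <- bootstrap_support(out, B = bootstrap, mode = mode,
                                seed = seed, a = a,
                                optimize_alpha = optimize_alpha,
                                control = control)
  }
  out
}

#' @export
print.teleo_comparison <- function(x, ...) {
  cat("<teleo_comparison> winner: ", x$winner,
      if (x$tie) " (tie)", "\n", sep = "")
  print(x$fits)
  if (!is.null(x$bp)) {
    cat("bootstrap proportions:\n")
    print(x$bp)
  }
  invisible(x)
}

#' Bootstrap support for the three topologies
#'
#' Sites are resampled with replacement `B` times; the winning hypothesis is
#' recorded per replicate and the bootstrap proportion (BP) of each
#' hypothesis is its win fraction (ties to the lowest index). In `"rell"`
#' mode the per-site log-likelihood vectors of the original fits are
#' reweighted without re-optimization; `"full"` mode rebuilds the resampled
#' alignment and re-optimizes every candidate (only sensible for small
#' data).
#'
#' @param comparison A [compare_topologies()] result.
#' @param B Number of bootstrap replicates (>= 1).
#' @param mode `"rell"` or `"full"`.
#' @param seed Optional seed for reproducibility.
#' @param a Original alignment, required for `mode = "full"`.
#' @param optimize_alpha,control Passed to the re-fits in `"full"` mode.
#' @return Named numeric vector of bootstrap proportions summing to 1.
#' @export
bootstrap_support <- function(comparison, B, mode = c("rell", "full"),
                              seed = NULL, a = NULL, optimize_alpha = TRUE,
                              control = list()) {
  mode <- match.arg(mode)
  if (B < 1L) stop("B must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  hyp <- comparison$fits$hypothesis
  if (mode == "rell") {
    L <- comparison$site_loglik          # npat x nhyp
    w <- comparison$weights
    n <- comparison$n_sites
    cnt <- rmultinom(B, size = n, prob = w / n)   # npat x B
    scores <- crossprod(cnt, L)                   # B x nhyp
    winners <- max.col(scores, ties.method = "first")
  } else {
    if (is.null(a)) stop("mode 'full' needs the original alignment",
                         call. = FALSE)
    n <- ncol(a)
    winners <- integer(B)
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      ab <- structure(unclass(a)[, idx, drop = FALSE],
                      alphabet = attr(a, "alphabet"),
                      class = c("teleo_alignment", "matrix"))
      cmpb <- compare_topologies(ab, comparison$candidates,
                                 comparison$model,
                                 optimize_alpha = optimize_alpha,
                                 control = control)
      winners[b] <- match(cmpb$winner, hyp)
    }
  }
  bp <- tabulate(winners, nbins = length(hyp)) / B
  names(bp) <- hyp
  bp
}

#' Per-locus three-topology tally
#'
#' A reduced gene-tree summary: every locus is scored against the three
#' candidate topologies restricted to its taxa, and the per-hypothesis win
#' counts are tallied. Loci that do not contain at least one taxon in each
#' of the four groups (outgroup and the three teleost groups) are skipped.
#'
#' @inheritParams compare_topologies
#' @param loci Named list of [teleo_alignment] loci.
#' @param groups A [group_assignment()] table.
#' @param backbones Optional within-group backbones (see
#'   [build_candidate_topologies()]); they are pruned to each locus's taxa.
#' @param min_groups_present Minimum number of groups that must be present
#'   (default 4, i.e. all).
#' @return An object of class `teleo_tally`: list with `counts` (named wins
#'   per hypothesis), `skipped`, and `per_locus` (tibble: locus, winner,
#'   tie, n_taxa).
#' @export
gene_tree_tally <- function(loci, groups, m, backbones = NULL,
                            min_groups_present = 4L, optimize_alpha = TRUE,
                            control = list()) {
  if (is.null(names(loci)) && length(loci))
    names(loci) <- paste0("locus_", seq_along(loci))
  counts <- setNames(numeric(3L), .hypothesis_labels)
  rows <- list()
  skipped <- 0L
  for (nm in names(loci)) {
    a <- loci[[nm]]
    taxa <- rownames(a)
    gp <- groups[groups$taxon %in% taxa, , drop = FALSE]
    present_groups <- unique(gp$group)
    if (length(present_groups) < min_groups_present) {
      skipped <- skipped + 1L
      rows[[nm]] <- tibble::tibble(locus = nm, winner = NA_character_,
                                   tie = NA, n_taxa = length(taxa),
                                   skipped = TRUE)
      next
    }
    bbs <- backbones
    if (!is.null(bbs)) {
      bbs <- lapply(setNames(.teleo_groups, .teleo_groups), function(g) {
        bb <- backbones[[g]]
        if (is.null(bb)) return(NULL)
        keep <- intersect(bb$tip.label, taxa)
        if (length(keep) == 0L) return(NULL)
        if (length(keep) == 1L) return(NULL)
        ape::keep.tip(bb, keep)
      })
    }
    cands <- build_candidate_topologies(group_assignment(gp),
                                        backbones = bbs, within = taxa)
    cmp <- compare_topologies(a, cands, m, optimize_alpha = optimize_alpha,
                              control = control)
    counts[cmp$winner] <- counts[cmp$winner] + 1L
    rows[[nm]] <- tibble::tibble(locus = nm, winner = cmp$winner,
                                 tie = cmp$tie, n_taxa = length(taxa),
                                 skipped = FALSE)
  }
  structure(list(counts = counts, skipped = skipped,
                 per_locus = dplyr::bind_rows(rows)),
            class = "teleo_tally")
}

#' @export
print.teleo_tally <- function(x, ...) {
  cat("<teleo_tally> wins:", paste(names(x$counts), x$counts,
                                   collapse = ", "),
      "| skipped:", x$skipped, "\n")
  invisible(x)
}
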