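# Locus QC filters and divergence/composition diagnostics: b_R, TBL,
# mean pairwise chi-square of residue frequencies, top-k subsetting, and
# Pearson correlation.

#' MRCA node of the teleost taxa
#'
#' @param tree A rooted [ape::phylo] tree.
#' @param groups A [group_assignment()] table.
#' @return Internal node number of the most recent common ancestor of all
#'   non-outgroup tips present in the tree.
#' @export
teleost_mrca <- function(tree, groups) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted", call. = FALSE)
  tel <- groups$taxon[groups$group != "outgroup"]
  tel <- intersect(tree$tip.label, tel)
  if (length(tel) < 2L)
    stop("need >= 2 teleost taxa to define the MRCA", call. = FALSE)
  ape::getMRCA(tree, tel)
}

#' Branch length from the teleost MRCA to a tip (b_R)
#'
#' The species-divergence measure: the sum of branch lengths along the
#' unique path between the most recent common ancestor of all teleost taxa
#' and the named tip. For outgroup tips the path runs through the root.
#'
#' @inheritParams teleost_mrca
#' @param taxon Tip label.
#' @return Numeric path length (expected substitutions/site).
#' @export
branch_length_from_teleost_mrca <- function(tree, groups, taxon) {
  idx <- match(taxon, tree$tip.label)
  if (is.na(idx)) stop("taxon '", taxon, "' not in tree", call. = FALSE)
  mrca <- teleost_mrca(tree, groups)
  .path_length(tree, mrca, idx)
}

#' Mean pairwise chi-square of residue composition
#'
#' For every unordered pair of taxa, residue counts (missing excluded) form
#' a 2 x c contingency table; states with zero pooled count are dropped and
#' the Pearson chi-square statistic is computed with expectations from the
#' pooled margins. The mean over all pairs measures compositional
#' heterogeneity across taxa. Counts (not per-site frequencies) are used.
#'
#' @param a A [teleo_alignment] with >= 2 taxa.
#' @return Mean pairwise chi-square statistic (>= 0).
#' @export
mean_pairwise_chi2 <- function(a) {
  ab <- .alphabets[[attr(a, "alphabet")]]
  counts <- t(apply(unclass(a), 1L, function(row)
    as.numeric(table(factor(row, levels = ab$states)))))
  usable <- rowSums(counts) > 0
  if (any(!usable))
    warning("taxa with no non-missing residues skipped: ",
            paste(rownames(a)[!usable], collapse = ", "), call. = FALSE)
  counts <- counts[usable, , drop = FALSE]
  if (nrow(counts) < 2L)
    stop("need >= 2 taxa with non-missing residues", call. = FALSE)
  pairs <- utils::combn(nrow(counts), 2L)
  stat_one <- function(i, j) {
    tab <- rbind(counts[i, ], counts[j, ])
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    if (ncol(tab) < 2L) return(0)
    suppressWarnings(
      unname(stats::chisq.test(tab, correct = FALSE)$statistic))
  }
  mean(vapply(seq_len(ncol(pairs)),
              function(k) stat_one(pairs[1L, k], pairs[2L, k]), 0))
}

#' Per-locus diagnostics table
#'
#' Computes, for each locus, the quantities the locus filters and gene
#' rankings use: site counts, shared-site count, groups present, total
#' branch length (TBL), the maximum b_R over the locus's taxa, and the mean
#' pairwise composition chi-square. Per-locus trees are either supplied or
#' obtained by optimizing branch lengths on a fixed topology restricted to
#' the taxa present (no per-locus topology search).
#'
#' @param loci Named list of [teleo_alignment] loci.
#' @param groups A [group_assignment()] table.
#' @param trees Optional named list of rooted per-locus trees. When absent,
#'   `topology` and `m` must be given to fit them.
#' @param topology Rooted tree on the full taxon set used (pruned per
#'   locus) when fitting per-locus branch lengths.
#' @param m A [teleo_model] for the per-locus fits.
#' @param control Passed to [optimize_branches_and_alpha()].
#' @return A tibble with one row per locus: `locus`, `n_sites`,
#'   `shared_sites`, `n_taxa`, `n_groups`, `tbl`, `max_br`, `chi2`.
#' @export
gene_diagnostics <- function(loci, groups, trees = NULL, topology = NULL,
                             m = NULL, control = list()) {
  if (is.null(names(loci)) && length(loci))
    names(loci) <- paste0("locus_", seq_along(loci))
  rows <- lapply(names(loci), function(nm) {
    a <- loci[[nm]]
    taxa <- rownames(a)
    gp <- groups[groups$taxon %in% taxa, , drop = FALSE]
    tr <- trees[[nm]]
    if (is.null(tr) && !is.null(topology) && !is.null(m)) {
      sub <- ape::keep.tip(topology, intersect(topology$tip.label, taxa))
      fit <- optimize_branches_and_alpha(a, sub, m, control = control)
      tr <- fit$tree
      # refitting unroots nothing: keep.tip preserves rootedness
    }
    tbl <- if (!is.null(tr)) total_branch_length(tr) else NA_real_
    max_br <- NA_real_
    if (!is.null(tr) && ape::is.rooted(tr) &&
        length(intersect(tr$tip.label,
                         gp$taxon[gp$group != "outgroup"])) >= 2L) {
      max_br <- max(vapply(tr$tip.label, function(tx)
        branch_length_from_teleost_mrca(tr, groups, tx), 0))
    }
    chi2 <- tryCatch(mean_pairwise_chi2(a), error = function(e) NA_real_)
    tibble::tibble(locus = nm, n_sites = ncol(a),
                   shared_sites = shared_site_count(a),
                   n_taxa = length(taxa),
                   n_groups = length(unique(gp$group)),
                   tbl = tbl, max_br = max_br, chi2 = chi2)
  })
  dplyr::bind_rows(rows)
}

#' Locus filter rules
#'
#' The default thresholds: loci with fewer than 50 shared sites are
#' excluded; loci in which some taxon has a branch length from the teleost
#' MRCA above 3 substitutions/site are excluded; loci must contain at least
#' one taxon in each of the four groups.
#'
#' @param min_shared_sites Minimum shared-site count (exclusive lower
#'   bound: loci with fewer are excluded).
#' @param max_br Maximum allowed b_R (exclusive upper bound).
#' @param require_all_groups Require all four groups present.
#' @return Named list of rules.
#' @export
locus_filter_rules <- function(min_shared_sites = 50, max_br = 3,
                               require_all_groups = TRUE) {
  list(min_shared_sites = min_shared_sites, max_br = max_br,
       require_all_groups = require_all_groups)
}

#' Apply the locus QC filters
#'
#' Rules are applied independently to a [gene_diagnostics()] table; a locus
#' excluded by several rules lists all of them.
#'
#' @param diags A [gene_diagnostics()] tibble.
#' @param rules A [locus_filter_rules()] list; unknown rule names are a
#'   configuration error.
#' @return An object of class `teleo_filter_report`: list with `table`
#'   (tibble: locus, excluded, reasons), `surviving` (locus ids), and
#'   `excluded` (named list of locus ids per rule).
#' @export
apply_locus_filters <- function(diags, rules = locus_filter_rules()) {
  known <- names(locus_filter_rules())
  bad <- setdiff(names(rules), known)
  if (length(bad))
    stop("unknown filter rule: '", bad[1L], "'", call. = FALSE)
  rules <- modifyList(locus_filter_rules(), rules)
  per_rule <- list()
  per_rule$min_shared_sites <-
    diags$locus[!is.na(diags$shared_sites) &
                  diags$shared_sites < rules$min_shared_sites]
  per_rule$max_br <-
    diags$locus[!is.na(diags$max_br) & diags$max_br > rules$max_br]
  per_rule$require_all_groups <-
    if (isTRUE(rules$require_all_groups))
      diags$locus[diags$n_groups < 4L] else character(0)
  reasons <- lapply(diags$locus, function(l)
    names(per_rule)[vapply(per_rule, function(v) l %in% v, TRUE)])
  excluded <- lengths(reasons) > 0L
  structure(list(
    table = tibble::tibble(locus = diags$locus, excluded = excluded,
                           reasons = reasons),
    surviving = diags$locus[!excluded],
    excluded = per_rule
  ), class = "teleo_filter_report")
}

#' @export
print.teleo_filter_report <- function(x, ...) {
  cat("<teleo_filter_report> ", length(x$surviving), " surviving / ",
      nrow(x$table), " loci\n", sep = "")
  for (r in names(x$excluded))
    cat("  ", r, ": ", length(x$excluded[[r]]), " excluded\n", sep = "")
  invisible(x)
}

#' Select the top-k loci by a diagnostic key
#'
#' Loci are sorted ascending by the key (low divergence / low heterogeneity
#' first) with a stable tie-break on locus id, and the first `k` are
#' returned — the construction of top-10/-50/-100 low-divergence gene sets.
#'
#' @param diags A [gene_diagnostics()] tibble.
#' @param key `"tbl"` or `"chi2"`.
#' @param k Number of loci to keep (>= 1); capped at the number of loci.
#' @return Character vector of locus ids in selection order.
#' @export
select_top_loci <- function(diags, key = c("tbl", "chi2"), k) {
  key <- match.arg(key)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  vals <- diags[[key]]
  ord <- order(vals, seq_len(nrow(diags)))
  head(diags$locus[ord], min(k, nrow(diags)))
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y Numeric vectors of equal length >= 3; neither may be
#'   constant.
#' @return A one-row tibble with `r` and the two-sided `p` value.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("lengths differ", call. = FALSE)
  if (length(x) < 3L) stop("need n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input", call. = FALSE)
  ct <- cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value)
}
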