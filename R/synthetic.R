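# Synthetic multi-locus study generator: templates emulating the structure
# of published teleost phylogenomic datasets (species depths from the
# teleost MRCA, wide per-locus rate spread, compositional perturbation of
# selected taxa, per-locus taxon missingness).

.template_fields <- c("preset", "taxa", "truth", "delta_basal",
                      "within_internal", "outgroup_spacing", "rate_sigma",
                      "perturb", "perturb_eps", "missingness", "n_loci",
                      "sites_per_locus", "model_name", "plus_F", "alpha",
                      "K", "base_seed")

.preset_taxa <- function(preset) {
  tb <- function(taxon, group, depth) tibble::tibble(taxon = taxon,
                                                     group = group,
                                                     depth = depth)
  switch(preset,
    bian_like = dplyr::bind_rows(
      tb(c("outgroup_short", "outgroup_long"), "outgroup", c(0.21, 0.43)),
      tb(c("elopomorpha_tarpon", "elopomorpha_eel"), "Elopomorpha",
         c(0.10, 0.18)),
      tb(paste0("osteoglossomorpha_", 1:3), "Osteoglossomorpha",
         c(0.17, 0.19, 0.22)),
      tb(paste0("clupeocephala_", 1:5), "Clupeocephala",
         c(0.23, 0.25, 0.28, 0.30, 0.32))
    ),
    chen_like = dplyr::bind_rows(
      tb(c("outgroup_gar", "outgroup_sturgeon", "outgroup_bichir",
           "outgroup_coelacanth"), "outgroup", c(0.14, 0.17, 0.30, 0.40)),
      tb("elopomorpha_1", "Elopomorpha", 0.12),
      tb("osteoglossomorpha_1", "Osteoglossomorpha", 0.13),
      tb(paste0("clupeocephala_", 1:9), "Clupeocephala",
         seq(0.15, 0.25, length.out = 9))
    ),
    hughes_like = dplyr::bind_rows(
      tb(c(paste0("outgroup_holostei_", 1:4),
           paste0("outgroup_acipenser_", 1:2),
           paste0("outgroup_polypterus_", 1:3),
           "outgroup_coelacanth", "outgroup_lungfish", "outgroup_frog"),
         "outgroup",
         c(0.24, 0.25, 0.26, 0.27, 0.28, 0.30, 0.33, 0.34, 0.36,
           0.43, 0.46, 0.56)),
      tb(c("elopomorpha_tarpon", paste0("elopomorpha_eel_", 1:3)),
         "Elopomorpha", c(0.20, 0.27, 0.28, 0.29)),
      tb(paste0("osteoglossomorpha_", 1:6), "Osteoglossomorpha",
         c(0.25, 0.26, 0.27, 0.28, 0.29, 0.31)),
      tb(paste0("clupeocephala_", 1:9), "Clupeocephala",
         seq(0.23, 0.32, length.out = 9))
    ),
    uce_like = dplyr::bind_rows(
      tb(c("outgroup_gar", "outgroup_bowfin", "outgroup_sturgeon",
           "outgroup_bichir"), "outgroup", c(0.09, 0.10, 0.12, 0.20)),
      tb(c("elopomorpha_megalops", "elopomorpha_moray"), "Elopomorpha",
         c(0.06, 0.11)),
      tb(c("osteoglossomorpha_arawana", "osteoglossomorpha_butterflyfish"),
         "Osteoglossomorpha", c(0.11, 0.15)),
      tb(paste0("clupeocephala_", 1:19), "Clupeocephala",
         seq(0.08, 0.20, length.out = 19))
    ),
    stop("unknown preset: '", preset, "'", call. = FALSE)
  )
}

#' Build a synthetic study template
#'
#' A template describes a group-level rooted model tree (species depths
#' from the teleost MRCA, outgroup attachment order, the basal arrangement
#' given by the truth topology) plus the per-locus generative settings:
#' lognormal rate multipliers, compositional perturbation of designated
#' taxa, taxonwise-per-locus missingness, locus count and length. Presets
#' emulate the structure of four published teleost datasets: a 12-species
#' 412-gene set with two outgroups of contrasting depth (`bian_like`), a
#' 15-species set with four outgroups and a single taxon in each of
#' Elopomorpha/Osteoglossomorpha (`chen_like`), a 30-species set with 12
#' outgroups and substantial per-locus missingness (`hughes_like`), and a
#' nucleotide UCE-like set of low divergence (`uce_like`).
#'
#' @param preset One of `"bian_like"`, `"chen_like"`, `"hughes_like"`,
#'   `"uce_like"`.
#' @param overrides Named list replacing template fields (e.g. `n_loci`,
#'   `sites_per_locus`, `truth`, `base_seed`, `taxa`); an unknown name is
#'   an error.
#' @return An object of class `teleo_template` (a named list).
#' @examples
#' tpl <- make_study_template("bian_like", list(n_loci = 4))
#' tpl$taxa
#' @export
make_study_template <- function(preset = c("bian_like", "chen_like",
                                           "hughes_like", "uce_like"),
                                overrides = list()) {
  preset <- match.arg(preset)
  tpl <- list(
    preset = preset,
    taxa = .preset_taxa(preset),
    truth = "Tree2",
    delta_basal = 0.01,
    within_internal = 0.01,
    outgroup_spacing = 0.02,
    rate_sigma = 0.6,
    perturb = switch(preset,
      bian_like = "osteoglossomorpha_2",
      chen_like = "outgroup_gar",
      hughes_like = "osteoglossomorpha_6",
      uce_like = "elopomorpha_moray"),
    perturb_eps = 0.15,
    missingness = switch(preset, hughes_like = 0.15, uce_like = 0.10, 0),
    n_loci = switch(preset, bian_like = 412L, chen_like = 772L,
                    hughes_like = 1062L, uce_like = 278L),
    sites_per_locus = switch(preset, bian_like = 350L, uce_like = 400L,
                             300L),
    model_name = if (preset == "uce_like") "GTR" else "JTT",
    plus_F = TRUE,
    alpha = 0.7,
    K = 4L,
    base_seed = 1L
  )
  unknown <- setdiff(names(overrides), .template_fields)
  if (length(unknown))
    stop("unknown template field: '", unknown[1L], "'", call. = FALSE)
  ov_taxa <- overrides$taxa
  overrides$taxa <- NULL
  tpl <- modifyList(tpl, overrides)
  if (!is.null(ov_taxa)) {
    tpl$taxa <- tibble::as_tibble(ov_taxa)
    stopifnot(all(c("taxon", "group", "depth") %in% names(tpl$taxa)))
    tpl$perturb <- intersect(tpl$perturb, tpl$taxa$taxon)
  }
  if (tpl$perturb_eps < 0 || tpl$perturb_eps >= 1)
    stop("perturb_eps must be in [0, 1)", call. = FALSE)
  if (tpl$missingness < 0 || tpl$missingness > 1)
    stop("missingness must be a probability", call. = FALSE)
  structure(tpl, class = "teleo_template")
}

#' @export
print.teleo_template <- function(x, ...) {
  cat("<teleo_template> ", x$preset, ": ", nrow(x$taxa), " taxa, ",
      x$n_loci, " loci x ", x$sites_per_locus, " sites, truth ", x$truth,
      "\n", sep = "")
  invisible(x)
}

#' @rdname make_study_template
#' @param tpl A `teleo_template`.
#' @return `template_groups()`: the [group_assignment()] table of the
#'   template's taxa.
#' @export
template_groups <- function(tpl) {
  group_assignment(tpl$taxa[, c("taxon", "group")])
}

# ladder clade for one group: tips attach successively; terminal edges
# chosen so each tip's distance to the group ancestor equals depth - d_anc
.ladder_clade <- function(taxa, depths, d_anc, w) {
  n <- length(taxa)
  rel <- depths - d_anc
  if (n == 1L) return(list(str = taxa, stem_extra = rel))
  # shrink the internal spacing when the group is too shallow for it
  pos <- c(seq_len(n - 1L) - 1L, n - 2L)
  if (any(pos > 0))
    w <- min(w, 0.5 * min(rel[pos > 0] / pos[pos > 0]))
  q <- pos * w
  term <- rel - q
  if (any(term <= 0))
    stop("within-group depths incompatible with the ladder construction",
         call. = FALSE)
  # innermost pair first
  s <- paste0("(", taxa[n - 1L], ":", term[n - 1L], ",", taxa[n], ":",
              term[n], ")")
  for (i in rev(seq_len(n - 2L)))
    s <- paste0("(", taxa[i], ":", term[i], ",", s, ":", w, ")")
  list(str = s, stem_extra = 0)
}

#' Rooted model tree of a template
#'
#' Builds the rooted tree the template describes: the teleost MRCA splits
#' according to the truth topology with a basal internode of
#' `delta_basal`; each group's ancestor sits at half the group's minimum
#' tip depth, with a ladder backbone inside the group; outgroups attach
#' successively below the teleost MRCA (shallowest first) at
#' `outgroup_spacing` intervals. Tip distances from the teleost MRCA equal
#' the template's `depth` column exactly.
#'
#' @param tpl A [make_study_template()] template.
#' @return A rooted [ape::phylo] tree.
#' @export
template_tree <- function(tpl) {
  tx <- tpl$taxa
  w <- tpl$within_internal
  delta <- tpl$delta_basal
  clade <- function(g, base_offset) {
    rows <- tx[tx$group == g, ]
    rows <- rows[order(rows$depth), ]
    d_anc <- min(rows$depth) / 2
    stem <- d_anc - base_offset
    if (stem <= 0)
      stop("group '", g, "' too shallow for the basal internode",
           call. = FALSE)
    cl <- .ladder_clade(rows$taxon, rows$depth, d_anc, w)
    paste0(cl$str, ":", stem + cl$stem_extra)
  }
  first <- switch(tpl$truth, Tree1 = "Clupeocephala", Tree2 = "Elopomorpha",
                  Tree3 = "Osteoglossomorpha")
  rest <- setdiff(c("Elopomorpha", "Osteoglossomorpha", "Clupeocephala"),
                  first)
  tel <- paste0("(", clade(first, 0), ",(", clade(rest[1L], delta), ",",
                clade(rest[2L], delta), "):", delta, ")")
  og <- tx[tx$group == "outgroup", ]
  og <- og[order(og$depth), ]
  v <- tpl$outgroup_spacing
  s <- tel
  for (i in seq_len(nrow(og))) {
    term <- og$depth[i] - i * v
    if (term <= 0)
      stop("outgroup '", og$taxon[i], "' too shallow for its attachment",
           call. = FALSE)
    s <- paste0("(", s, ":", v, ",", og$taxon[i], ":", term, ")")
  }
  parse_newick(paste0(s, ";"))
}

# perturbed stationary frequencies: boost the 4 most common states
.perturbed_freqs <- function(pi, eps) {
  delta <- numeric(length(pi))
  top <- order(pi, decreasing = TRUE)[1:4]
  delta[top] <- pi[top] / sum(pi[top])
  (1 - eps) * pi + eps * delta
}

#' Template substitution model
#'
#' @rdname make_study_template
#' @return `template_model()`: the [teleo_model] the template simulates
#'   under.
#' @export
template_model <- function(tpl) {
  load_empirical_model(tpl$model_name, alpha = tpl$alpha, K = tpl$K)
}

#' Generate a synthetic multi-locus study
#'
#' Per locus: a lognormal rate multiplier (mean 1, sdlog `rate_sigma`)
#' scales the template tree; sequences are simulated under the template
#' model, with perturbed taxa evolving their terminal branches under
#' frequencies shifted towards the commonest residues
#' (`pi' = (1 - eps) pi + eps delta`); taxa are then dropped independently
#' with the missingness probability, never emptying a group. Locus `i`
#' uses seed `base_seed + i`, so the study is regenerable byte-identically
#' from its manifest.
#'
#' @param tpl A [make_study_template()] template.
#' @return An object of class `teleo_study`: list with `loci` (named list
#'   of [teleo_alignment]), `trees` (true per-locus trees, scaled),
#'   `multipliers`, `groups`, `truth`, `model`, and `manifest` (the
#'   template).
#' @export
generate_synthetic_study <- function(tpl) {
  base_tree <- template_tree(tpl)
  m <- template_model(tpl)
  groups <- template_groups(tpl)
  tip_freqs <- NULL
  if (length(tpl$perturb) && tpl$perturb_eps > 0) {
    pf <- .perturbed_freqs(m$pi, tpl$perturb_eps)
    tip_freqs <- setNames(rep(list(pf), length(tpl$perturb)), tpl$perturb)
  }
  sigma <- tpl$rate_sigma
  loci <- list()
  trees <- list()
  mult <- numeric(tpl$n_loci)
  for (i in seq_len(tpl$n_loci)) {
    set.seed((tpl$base_seed + i) %% .Machine$integer.max)
    mult[i] <- if (sigma > 0) rlnorm(1, meanlog = -sigma^2 / 2,
                                     sdlog = sigma) else 1
    tr <- base_tree
    tr$edge.length <- tr$edge.length * mult[i]
    a <- simulate_alignment(tr, m, tpl$sites_per_locus,
                            tip_freqs = tip_freqs)
    if (tpl$missingness > 0) {
      drop <- runif(nrow(a)) < tpl$missingness
      names(drop) <- rownames(a)
      for (g in unique(groups$group)) {
        members <- intersect(rownames(a), .group_taxa(groups, g))
        if (length(members) && all(drop[members])) {
          keep_one <- members[sample.int(length(members), 1L)]
          drop[keep_one] <- FALSE
        }
      }
      a <- extract_taxon_subset(a, rownames(a)[!drop])
    }
    nm <- sprintf("locus_%04d", i)
    loci[[nm]] <- a
    trees[[nm]] <- tr
  }
  structure(list(loci = loci, trees = trees, multipliers = mult,
                 groups = groups, truth = tpl$truth, model = m,
                 manifest = tpl),
            class = "teleo_study")
}

#' @export
print.teleo_study <- function(x, ...) {
  cat("<teleo_study> ", x$manifest$preset, ": ", length(x$loci),
      " loci, truth ", x$truth, "\n", sep = "")
  invisible(x)
}

#' Concatenate loci into a supermatrix
#'
#' Taxa absent from a locus are filled with missing symbols.
#'
#' @param loci Named list of [teleo_alignment] loci over a common
#'   alphabet.
#' @return A [teleo_alignment] over the union of taxa.
#' @export
concatenate_loci <- function(loci) {
  stopifnot(length(loci) >= 1L)
  alphabet <- attr(loci[[1L]], "alphabet")
  taxa <- unique(unlist(lapply(loci, rownames)))
  blocks <- lapply(loci, function(a) {
    out <- matrix("?", length(taxa), ncol(a), dimnames = list(taxa, NULL))
    out[rownames(a), ] <- unclass(a)
    out
  })
  teleo_alignment(do.call(cbind, blocks), alphabet)
}
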