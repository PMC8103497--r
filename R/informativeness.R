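# Site-rate estimation, strict-clock (ultrametric) tree fitting, and
# phylogenetic-informativeness profiles with TBL-ratio rate scaling.

#' Estimate per-site substitution rates
#'
#' The rate of each site is the posterior mean over the discrete-gamma
#' categories: `lambda_i = sum_k r_k P(k | site i)`, with
#' `P(k | site) proportional to (1/K) L_k(site)` from the pruning
#' likelihood. Rates are normalized so their average over sites with data
#' is exactly 1 (the model's mean rate); sites that are missing in every
#' taxon get rate 0 with a warning.
#'
#' @inheritParams pruning_loglik
#' @param tree Fitted tree (branch lengths set) on the alignment's taxa.
#' @return An object of class `teleo_site_rates`: numeric vector of
#'   per-site rates with attributes `method` (`"gamma_posterior_mean"`) and
#'   `alpha`.
#' @export
estimate_site_rates <- function(a, tree, m) {
  patterns <- if (inherits(a, "teleo_patterns")) a else compress_patterns(a)
  pd <- .plik_data(patterns, tree)
  ed <- .model_eigen(m)
  rates <- .model_rates(m)
  res <- plik_cpp(pd$edge, pd$el, pd$ntip, pd$nnode, pd$tips,
                  patterns$weights, ed$A, ed$B, ed$values, m$pi,
                  rates, TRUE)
  catll <- res$cat_loglik                      # npat x K (log scale)
  mx <- apply(catll, 1L, max)
  post <- exp(catll - mx)
  post <- post / rowSums(post)
  lam_pat <- as.numeric(post %*% rates)
  all_missing <- colSums(patterns$states > 0L) == 0L
  if (any(all_missing)) {
    warning(sum(patterns$weights[all_missing]),
            " all-missing site(s) assigned rate 0", call. = FALSE)
    lam_pat[all_missing] <- 0
  }
  lam <- lam_pat[patterns$index]
  informative <- lam > 0
  if (any(informative)) lam[informative] <- lam[informative] /
      mean(lam[informative])
  structure(lam, method = "gamma_posterior_mean", alpha = m$alpha,
            class = "teleo_site_rates")
}

#' @export
print.teleo_site_rates <- function(x, ...) {
  cat("<teleo_site_rates> ", length(x), " sites, mean ",
      format(mean(x), digits = 4), " (", attr(x, "method"), ")\n", sep = "")
  invisible(x)
}

# node ages from a rooted tree parametrization: root height + per-node
# proportions of the parent's age, traversed preorder
.ages_to_lengths <- function(tree, ages) {
  el <- numeric(nrow(tree$edge))
  ntip <- length(tree$tip.label)
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    age_ch <- if (ch <= ntip) 0 else ages[ch - ntip]
    el[e] <- ages[par - ntip] - age_ch
  }
  el
}

#' Fit a strict molecular clock tree
#'
#' Node ages are optimized by maximum likelihood under a strict clock
#' (branch length = age difference, one global rate absorbed in the ages),
#' yielding an ultrametric tree: all root-to-tip path lengths are equal.
#' The data need not be clock-like; the fit is then simply the best
#' clock-constrained approximation (the log-likelihood is reported, not
#' enforced).
#'
#' @inheritParams pruning_loglik
#' @param rooted_topology A rooted [ape::phylo] topology.
#' @return An object of class `teleo_clock_tree`: list with `tree`
#'   (ultrametric [ape::phylo]), `ages` (internal-node ages), `loglik`, and
#'   `root_depth`.
#' @export
fit_clock_tree <- function(a, rooted_topology, m) {
  if (!ape::is.rooted(rooted_topology))
    stop("topology must be rooted", call. = FALSE)
  tr <- rooted_topology
  patterns <- if (inherits(a, "teleo_patterns")) a else compress_patterns(a)
  ntip <- length(tr$tip.label)
  nint <- tr$Nnode
  root <- ntip + 1L
  # preorder list of internal nodes (parents before children)
  pre <- ape::reorder.phylo(tr, "cladewise")
  int_order <- unique(pre$edge[, 1L])
  parent_of <- setNames(pre$edge[, 1L], pre$edge[, 2L])
  ed <- .model_eigen(m)
  rates <- .model_rates(m)
  # parameters: log root height, logit proportion per non-root internal
  par_to_ages <- function(p) {
    ages <- numeric(nint)
    ages[root - ntip] <- exp(p[1L])
    i <- 2L
    for (nd in int_order) {
      if (nd == root) next
      frac <- 1 / (1 + exp(-p[i]))
      ages[nd - ntip] <- frac * ages[parent_of[as.character(nd)] - ntip]
      i <- i + 1L
    }
    ages
  }
  pd <- .plik_data(patterns, tr)
  obj <- function(p) {
    ages <- par_to_ages(p)
    el <- .ages_to_lengths(pd$po, ages)
    if (any(el < 0)) return(1e10)
    el[el < 1e-9] <- 1e-9
    -plik_cpp(pd$edge, el, pd$ntip, pd$nnode, pd$tips, patterns$weights,
              ed$A, ed$B, ed$values, m$pi, rates, FALSE)$loglik
  }
  # start: root height from the mean tip depth of an additive guess
  p0 <- c(log(0.5), rep(0.7, nint - 1L))
  op <- optim(p0, obj, method = "BFGS",
              control = list(maxit = 500, reltol = 1e-10))
  ages <- par_to_ages(op$par)
  fit_tree <- tr
  fit_tree$edge.length <- .ages_to_lengths(tr, ages)
  structure(list(tree = fit_tree, ages = ages, loglik = -op$value,
                 root_depth = ages[1L]),
            class = "teleo_clock_tree")
}

#' @export
print.teleo_clock_tree <- function(x, ...) {
  cat("<teleo_clock_tree> root depth ", format(x$root_depth, digits = 5),
      ", logL ", format(x$loglik, digits = 8), "\n", sep = "")
  invisible(x)
}

#' Phylogenetic-informativeness profile
#'
#' The net informativeness at depth `T` is the sum over sites of the
#' per-site form `f(lambda, T) = 16 lambda^2 T exp(-4 lambda T)`, which is
#' zero at `T = 0`, non-negative, and has its unique interior maximum at
#' `T* = 1 / (4 lambda)` — so faster sites peak at shallower depths. Site
#' rates are first multiplied by the scaling ratio `r`, the ratio of the
#' TBL of the ultrametric tree of a gene subset to that of the total set,
#' which converts the subset's rates to the total set's depth axis.
#'
#' @param rates A [estimate_site_rates()] result (or numeric vector of
#'   non-negative site rates).
#' @param grid Strictly increasing depth grid starting at 0; default 512
#'   uniform points from 0 to `max_depth`.
#' @param r Positive TBL scaling ratio (default 1).
#' @param max_depth Root depth defining the default grid (required when
#'   `grid` is absent).
#' @return An object of class `teleo_pi_profile`: tibble with columns
#'   `depth` and `pi`, plus attributes `r` and `n_sites`.
#' @export
pi_profile <- function(rates, grid = NULL, r = 1, max_depth = NULL) {
  if (r <= 0) stop("scaling ratio r must be > 0", call. = FALSE)
  lam <- as.numeric(rates) * r
  if (any(lam < 0)) stop("negative site rate", call. = FALSE)
  if (is.null(grid)) {
    if (is.null(max_depth))
      stop("supply either grid or max_depth", call. = FALSE)
    grid <- seq(0, max_depth, length.out = 512L)
  }
  if (any(diff(grid) <= 0) || grid[1L] != 0)
    stop("grid must increase strictly from 0", call. = FALSE)
  pi_vals <- vapply(grid, function(T)
    sum(16 * lam^2 * T * exp(-4 * lam * T)), 0)
  out <- tibble::tibble(depth = grid, pi = pi_vals)
  attr(out, "r") <- r
  attr(out, "n_sites") <- length(lam)
  class(out) <- c("teleo_pi_profile", class(out))
  out
}

#' Depth of the informativeness peak
#'
#' The grid depth maximizing the profile; plateau ties resolve to the
#' smallest depth. An all-zero profile has no peak and returns `NA`.
#'
#' @param profile A [pi_profile()] result.
#' @return Numeric depth, or `NA` for a degenerate profile.
#' @export
profile_peak_depth <- function(profile) {
  if (all(profile$pi == 0)) return(NA_real_)
  profile$depth[which.max(profile$pi)]
}
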