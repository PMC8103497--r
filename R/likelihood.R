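# Pruning log-likelihood, branch-length/shape optimization on a fixed
# topology, and information-criterion model selection.

# prepare C++ inputs: postorder edge matrix and tip states aligned to labels
.plik_data <- function(patterns, tree) {
  missing_tips <- setdiff(tree$tip.label, patterns$taxa)
  if (length(missing_tips))
    stop("taxon '", missing_tips[1L], "' in tree but not in alignment",
         call. = FALSE)
  po <- ape::reorder.phylo(tree, "postorder")
  if (is.null(po$edge.length) || anyNA(po$edge.length))
    stop("tree has unset branch lengths", call. = FALSE)
  tips <- patterns$states[match(po$tip.label, patterns$taxa), , drop = FALSE]
  list(edge = po$edge, el = po$edge.length, ntip = length(po$tip.label),
       nnode = length(po$tip.label) + po$Nnode, tips = tips, po = po)
}

.model_rates <- function(m) discrete_gamma(m$alpha, m$K)

#' Felsenstein pruning log-likelihood
#'
#' Computes the log-likelihood of an alignment on a fixed tree under a
#' reversible model with discrete-gamma rate variation, by postorder pruning
#' over compressed site patterns with per-pattern rescaling. Gap and missing
#' symbols contribute a partial likelihood of 1 for every state, so a column
#' that is missing in every taxon contributes exactly 0.
#'
#' @param a A [teleo_alignment] or [compress_patterns()] result.
#' @param tree An [ape::phylo] tree whose tip labels are a subset of the
#'   alignment's taxa, with branch lengths set.
#' @param m A [teleo_model].
#' @param per_site Return the per-site log-likelihood vector as attribute
#'   `"site_loglik"` (used by RELL resampling).
#' @return The total log-likelihood (numeric scalar).
#' @export
pruning_loglik <- function(a, tree, m, per_site = FALSE) {
  patterns <- if (inherits(a, "teleo_patterns")) a else compress_patterns(a)
  if (length(tree$tip.label) < length(patterns$taxa)) {
    # restrict patterns to the tree's taxa (recompress to merge patterns)
    keep <- match(tree$tip.label, patterns$taxa)
    if (anyNA(keep))
      stop("taxon '", tree$tip.label[which(is.na(keep))[1L]],
           "' in tree but not in alignment", call. = FALSE)
  }
  if (length(tree$tip.label) == 1L) {
    idx <- match(tree$tip.label, patterns$taxa)
    s <- patterns$states[idx, ]
    ll_pat <- ifelse(s > 0L, log(m$pi[pmax(s, 1L)]), 0)
    ll <- sum(patterns$weights * ll_pat)
    if (per_site) attr(ll, "site_loglik") <- ll_pat[patterns$index]
    return(ll)
  }
  pd <- .plik_data(patterns, tree)
  ed <- .model_eigen(m)
  res <- plik_cpp(pd$edge, pd$el, pd$ntip, pd$nnode, pd$tips,
                  patterns$weights, ed$A, ed$B, ed$values, m$pi,
                  .model_rates(m), FALSE)
  ll <- res$loglik
  if (per_site) attr(ll, "site_loglik") <- res$site_loglik[patterns$index]
  ll
}

#' Optimize branch lengths and gamma shape on a fixed topology
#'
#' Branch lengths are optimized by Brent coordinate sweeps (on a log scale,
#' bounded to \[1e-8, 10\]) with cached partial likelihoods; the gamma shape
#' is optimized on a log scale in \[0.02, 100\], alternating with branch
#' sweeps until the joint improvement per round falls below `tol`. The
#' log-likelihood trace is non-decreasing. Failure to converge within
#' `max_sweeps` sets a warning flag on the result rather than erroring.
#'
#' @inheritParams pruning_loglik
#' @param topology An [ape::phylo] tree; absent branch lengths start at 0.1.
#' @param optimize_alpha Re-estimate the gamma shape (default) or keep the
#'   model's value fixed.
#' @param control List overriding `tol` (sweep convergence, log-units,
#'   default 1e-6), `max_sweeps` (100), `min_blen`, `max_blen`, `brent_tol`,
#'   `max_outer` (branch/alpha alternations, 10).
#' @return An object of class `teleo_fit`: list with the optimized `tree`,
#'   `loglik`, `alpha`, `k` (free parameters), `n_sites`, `AIC`, `AICc`,
#'   `BIC`, `converged`, `model`, and per-pattern site log-likelihoods.
#' @export
optimize_branches_and_alpha <- function(a, topology, m,
                                        optimize_alpha = TRUE,
                                        control = list()) {
  ctl <- modifyList(list(tol = 1e-6, max_sweeps = 100L, min_blen = 1e-8,
                         max_blen = 10, brent_tol = 1e-4, max_outer = 10L),
                    control)
  patterns <- if (inherits(a, "teleo_patterns")) a else compress_patterns(a)
  tr <- topology
  if (is.null(tr$edge.length) || anyNA(tr$edge.length))
    tr$edge.length <- rep(0.1, nrow(tr$edge))
  tr$edge.length[tr$edge.length <= 0] <- ctl$min_blen
  pd <- .plik_data(patterns, tr)
  ed <- .model_eigen(m)
  alpha <- m$alpha
  prev <- -Inf
  res <- NULL
  converged <- TRUE
  trace <- numeric(0)
  for (outer in seq_len(ctl$max_outer)) {
    rates <- discrete_gamma(alpha, m$K)
    res <- optimize_blen_cpp(pd$edge, pd$el, pd$ntip, pd$nnode, pd$tips,
                             patterns$weights, ed$A, ed$B, ed$values, m$pi,
                             rates, ctl$min_blen, ctl$max_blen, ctl$tol,
                             ctl$max_sweeps, ctl$brent_tol)
    pd$el <- as.numeric(res$edge_length)
    trace <- c(trace, res$trace)
    converged <- isTRUE(res$converged)
    ll <- res$loglik
    if (optimize_alpha && !is.infinite(alpha) && m$K > 1L) {
      f <- function(la) {
        plik_cpp(pd$edge, pd$el, pd$ntip, pd$nnode, pd$tips,
                 patterns$weights, ed$A, ed$B, ed$values, m$pi,
                 discrete_gamma(exp(la), m$K), FALSE)$loglik
      }
      op <- optimize(f, interval = log(c(0.02, 100)), maximum = TRUE,
                     tol = 1e-3)
      if (op$objective > ll) {
        alpha <- exp(op$maximum)
        ll <- op$objective
        trace <- c(trace, ll)
      }
    }
    if (ll - prev < ctl$tol) break
    prev <- ll
    if (!optimize_alpha) break
  }
  fit_tree <- pd$po
  fit_tree$edge.length <- pd$el
  # final per-site vector under the optimized parameters
  fin <- plik_cpp(pd$edge, pd$el, pd$ntip, pd$nnode, pd$tips,
                  patterns$weights, ed$A, ed$B, ed$values, m$pi,
                  discrete_gamma(alpha, m$K), FALSE)
  mfit <- m
  mfit$alpha <- alpha
  n <- sum(patterns$weights)
  c_states <- length(.alphabets[[m$alphabet]]$states)
  k <- nrow(fit_tree$edge) +
    (optimize_alpha && !is.infinite(m$alpha) && m$K > 1L) +
    if (m$plus_F) c_states - 1L else 0L
  ic <- information_criteria(fin$loglik, k, n)
  structure(list(tree = fit_tree, loglik = fin$loglik, alpha = alpha,
                 k = k, n_sites = n, AIC = ic$AIC, AICc = ic$AICc,
                 BIC = ic$BIC, converged = converged, trace = trace,
                 model = mfit, site_loglik = as.numeric(fin$site_loglik),
                 weights = patterns$weights, site_index = patterns$index),
            class = "teleo_fit")
}

#' @export
print.teleo_fit <- function(x, ...) {
  cat("<teleo_fit> logL = ", format(x$loglik, digits = 8), ", alpha = ",
      format(x$alpha, digits = 4), ", k = ", x$k, ", n = ", x$n_sites,
      if (!x$converged) " (NOT converged)", "\n", sep = "")
  invisible(x)
}

#' Information criteria
#'
#' `AIC = -2L + 2k`; `AICc = -2L + 2k + 2k(k+1)/(n-k-1)` (reported as `NA`
#' when `n <= k + 1`); `BIC = -2L + k log(n)`.
#'
#' @param L Log-likelihood.
#' @param k Number of free parameters (>= 1).
#' @param n Number of sites (>= 1).
#' @return A one-row [tibble::tibble] with columns `AIC`, `AICc`, `BIC`.
#' @examples
#' information_criteria(-1000, 10, 1000)
#' @export
information_criteria <- function(L, k, n) {
  stopifnot(k >= 1, n >= 1)
  aic <- -2 * L + 2 * k
  aicc <- if (n > k + 1) aic + 2 * k * (k + 1) / (n - k - 1) else NA_real_
  bic <- -2 * L + k * log(n)
  tibble::tibble(AIC = aic, AICc = aicc, BIC = bic)
}

#' Select the best-fitting substitution model for an alignment
#'
#' Fits every candidate on the same fixed topology (branch lengths and gamma
#' shape re-optimized per candidate; +F candidates use the alignment's
#' empirical frequencies) and ranks them by an information criterion. Ties
#' are broken by grid order.
#'
#' @inheritParams optimize_branches_and_alpha
#' @param candidates Named list of [teleo_model] objects, e.g. from
#'   [model_grid()].
#' @param criterion `"AIC"` (default), `"AICc"` or `"BIC"`.
#' @param control Passed to [optimize_branches_and_alpha()].
#' @return An object of class `teleo_model_selection`: list with `table`
#'   (tibble of per-candidate fits), `best_name`, `best_model` (fitted), and
#'   `best_fit`.
#' @export
select_model <- function(a, topology, candidates, criterion = "AIC",
                         control = list()) {
  criterion <- match.arg(criterion, c("AIC", "AICc", "BIC"))
  if (length(candidates) == 0L)
    stop("empty candidate list", call. = FALSE)
  if (is.null(names(candidates)))
    names(candidates) <- vapply(candidates, function(m) m$name, "")
  patterns <- if (inherits(a, "teleo_patterns")) a else compress_patterns(a)
  fits <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    m <- candidates[[i]]
    if (m$plus_F) {
      freqs <- empirical_frequencies(a)
      m <- teleo_model(m$name, m$S, freqs, alpha = m$alpha, K = m$K,
                       plus_F = TRUE, alphabet = m$alphabet)
    }
    fits[[i]] <- optimize_branches_and_alpha(patterns, topology, m,
                                             control = control)
  }
  tab <- tibble::tibble(
    model = names(candidates),
    logL = vapply(fits, function(f) f$loglik, 0),
    alpha = vapply(fits, function(f) f$alpha, 0),
    k = vapply(fits, function(f) f$k, 0L),
    AIC = vapply(fits, function(f) f$AIC, 0),
    AICc = vapply(fits, function(f) f$AICc, 0),
    BIC = vapply(fits, function(f) f$BIC, 0)
  )
  score <- tab[[criterion]]
  best <- which.min(score)
  structure(list(table = tab, criterion = criterion,
                 best_name = names(candidates)[best],
                 best_model = fits[[best]]$model, best_fit = fits[[best]]),
            class = "teleo_model_selection")
}

#' @export
print.teleo_model_selection <- function(x, ...) {
  cat("<teleo_model_selection> best by ", x$criterion, ": ", x$best_name,
      "\n", sep = "")
  print(x$table)
  invisible(x)
}

#' Fit nucleotide GTR exchangeabilities by maximum likelihood
#'
#' Optimizes the five free exchangeabilities (GT fixed at 1, log scale)
#' jointly with branch lengths and shape: each candidate set of
#' exchangeabilities is scored after a branch-length/shape re-optimization.
#' Amino-acid exchangeabilities are never re-estimated; empirical matrices
#' are used as published.
#'
#' @inheritParams optimize_branches_and_alpha
#' @param m A `"GTR"` [teleo_model] supplying starting exchangeabilities and
#'   frequencies (typically empirical).
#' @return A `teleo_fit` whose `model` carries the fitted exchangeabilities;
#'   `k` includes the 5 free exchangeabilities.
#' @export
fit_gtr <- function(a, topology, m, optimize_alpha = TRUE,
                    control = list()) {
  stopifnot(m$alphabet == "NT4")
  patterns <- if (inherits(a, "teleo_patterns")) a else compress_patterns(a)
  lt <- lower.tri(matrix(0, 4, 4))
  start <- m$S[lt]
  start <- start / start[6L]
  inner_ctl <- modifyList(list(tol = 1e-4, max_outer = 3L), control)
  make_model <- function(logx) {
    S <- matrix(0, 4, 4)
    S[lt] <- c(exp(logx), 1)
    S <- S + t(S)
    teleo_model("GTR", S, m$pi, alpha = m$alpha, K = m$K,
                plus_F = m$plus_F, alphabet = "NT4")
  }
  obj <- function(logx) {
    f <- optimize_branches_and_alpha(patterns, topology, make_model(logx),
                                     optimize_alpha = optimize_alpha,
                                     control = inner_ctl)
    -f$loglik
  }
  op <- optim(log(start[1:5]), obj, method = "Nelder-Mead",
              control = list(maxit = 200, reltol = 1e-7))
  mhat <- make_model(op$par)
  fit <- optimize_branches_and_alpha(patterns, topology, mhat,
                                     optimize_alpha = optimize_alpha,
                                     control = control)
  fit$k <- fit$k + 5L
  ic <- information_criteria(fit$loglik, fit$k, fit$n_sites)
  fit$AIC <- ic$AIC; fit$AICc <- ic$AICc; fit$BIC <- ic$BIC
  fit
}
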