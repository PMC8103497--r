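# broom-style tidiers for fitted objects.

#' Tidy a fixed-topology fit
#'
#' @param x A `teleo_fit`.
#' @param ... Unused.
#' @return One row per edge: parent, child node numbers and branch length.
#' @method tidy teleo_fit
#' @export
tidy.teleo_fit <- function(x, ...) {
  tibble::tibble(parent = x$tree$edge[, 1L], child = x$tree$edge[, 2L],
                 branch_length = x$tree$edge.length)
}

#' @rdname tidy.teleo_fit
#' @return `glance()`: a one-row model summary.
#' @method glance teleo_fit
#' @export
glance.teleo_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, alpha = x$alpha, k = x$k,
                 n_sites = x$n_sites, AIC = x$AIC, AICc = x$AICc,
                 BIC = x$BIC, converged = x$converged)
}

#' Tidy a three-topology comparison
#'
#' @param x A `teleo_comparison`.
#' @param ... Unused.
#' @return Per-hypothesis fit table with bootstrap proportions when
#'   available.
#' @method tidy teleo_comparison
#' @export
tidy.teleo_comparison <- function(x, ...) {
  out <- x$fits
  if (!is.null(x$bp)) out$bp <- unname(x$bp[out$hypothesis])
  out$winner <- out$hypothesis == x$winner
  out
}

#' @rdname tidy.teleo_comparison
#' @method glance teleo_comparison
#' @export
glance.teleo_comparison <- function(x, ...) {
  tibble::tibble(winner = x$winner, tie = x$tie, n_sites = x$n_sites,
                 delta_logL = max(x$fits$logL) -
                   sort(x$fits$logL, decreasing = TRUE)[2L])
}

#' Tidy a model-selection table
#'
#' @param x A `teleo_model_selection`.
#' @param ... Unused.
#' @method tidy teleo_model_selection
#' @export
tidy.teleo_model_selection <- function(x, ...) {
  out <- x$table
  out$best <- out$model == x$best_name
  out
}

#' Tidy a power-simulation result set
#'
#' @param x A `teleo_nc_set`.
#' @param ... Unused.
#' @return One row per subset with per-hypothesis wins, `n_c` and tie
#'   count.
#' @method tidy teleo_nc_set
#' @export
tidy.teleo_nc_set <- function(x, ...) {
  dplyr::bind_rows(lapply(unclass(x), function(nc) {
    tibble::tibble(subset = nc$subset_name, truth = nc$truth,
                   n_sites = nc$n_sites, n_reps = nc$n_reps,
                   Tree1 = unname(nc$wins["Tree1"]),
                   Tree2 = unname(nc$wins["Tree2"]),
                   Tree3 = unname(nc$wins["Tree3"]),
                   n_c = nc$n_c, ties = nc$ties)
  }))
}

#' Tidy a locus filter report
#'
#' @param x A `teleo_filter_report`.
#' @param ... Unused.
#' @method tidy teleo_filter_report
#' @export
tidy.teleo_filter_report <- function(x, ...) {
  out <- x$table
  out$reasons <- vapply(out$reasons, paste, "", collapse = ";")
  out
}
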