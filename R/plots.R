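# ggplot2 displays for the main result types.

#' Plot bootstrap support for the three hypotheses
#'
#' @param object A `teleo_comparison` with bootstrap proportions.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot teleo_comparison
#' @export
autoplot.teleo_comparison <- function(object, ...) {
  df <- tidy.teleo_comparison(object)
  if (is.null(df$bp)) df$bp <- as.numeric(df$winner)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hypothesis, y = .data$bp,
                                   fill = .data$winner)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2166ac",
                                          `FALSE` = "grey65")) +
    ggplot2::labs(x = NULL, y = "bootstrap proportion") +
    ggplot2::theme_minimal()
}

#' Plot correct-topology counts across subsets
#'
#' @param object A `teleo_nc_set`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot teleo_nc_set
#' @export
autoplot.teleo_nc_set <- function(object, ...) {
  df <- tidy.teleo_nc_set(object)
  long <- tidyr::pivot_longer(df, c("Tree1", "Tree2", "Tree3"),
                              names_to = "hypothesis", values_to = "wins")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$subset, y = .data$wins,
                                     fill = .data$hypothesis)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "replicates won",
                  fill = NULL,
                  title = paste("truth:", df$truth[1L])) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Plot a phylogenetic-informativeness profile
#'
#' @param object A `teleo_pi_profile`.
#' @param ... Further profiles to overlay, named.
#' @return A ggplot of net informativeness against depth.
#' @method autoplot teleo_pi_profile
#' @export
autoplot.teleo_pi_profile <- function(object, ...) {
  extra <- list(...)
  dfs <- c(list(profile = object), extra[vapply(extra, inherits, TRUE,
                                                "teleo_pi_profile")])
  if (is.null(names(dfs)) || any(names(dfs) == ""))
    names(dfs) <- paste0("profile_", seq_along(dfs))
  df <- dplyr::bind_rows(lapply(dfs, tibble::as_tibble), .id = "set")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$depth, y = .data$pi,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "depth (substitutions/site)",
                  y = "net informativeness", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter of composition heterogeneity against gene divergence
#'
#' @param diags A [gene_diagnostics()] tibble.
#' @return A ggplot of mean pairwise chi-square against TBL per locus.
#' @export
plot_gene_diagnostics <- function(diags) {
  ggplot2::ggplot(diags, ggplot2::aes(x = .data$tbl, y = .data$chi2)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "#b2182b") +
    ggplot2::labs(x = "total branch length",
                  y = "mean pairwise chi-square") +
    ggplot2::theme_minimal()
}
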