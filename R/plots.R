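#' Plot the simulation null distribution of convergence counts
#'
#' Histogram of per-replicate convergent-site counts with the observed count
#' marked; the empirical p-value is shown in the subtitle.
#'
#' @param object A `null_distribution` from [convergence_null_test()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.null_distribution <- function(object, ...) {
  obs <- attr(object, "observed")
  p <- attr(object, "empirical_p")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n_convergent_sites)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = obs, colour = "darkgreen",
                        linewidth = 1) +
    ggplot2::labs(
      x = "convergent sites per simulated replicate", y = "replicates",
      title = "Simulation null of convergence counts",
      subtitle = sprintf("observed = %d, empirical p = %.4g", obs, p)
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-site selection posteriors
#'
#' Points per site, with convergent sites highlighted and the upper
#' percentile threshold drawn.
#'
#' @param posteriors Tibble from [site_posteriors()].
#' @param conv_sites Optional convergent-site coordinates to highlight.
#' @param percentile Percentile line to draw (default 90).
#' @return A ggplot object.
#' @export
plot_site_posteriors <- function(posteriors, conv_sites = NULL,
                                 percentile = 90) {
  df <- posteriors
  df$convergent <- if (is.null(conv_sites)) FALSE else df$site %in% conv_sites
  thr <- stats::quantile(df$posterior, percentile / 100, type = 5)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$site, y = .data$posterior,
                                   colour = .data$convergent)) +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::geom_hline(yintercept = thr, linetype = 2, colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "darkgreen")) +
    ggplot2::labs(x = "site (0-based)", y = "P(positive selection)",
                  colour = "convergent") +
    ggplot2::theme_minimal()
}

#' Plot per-branch dN/dS from a free-ratio or partition fit
#'
#' @param object A `codon_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.codon_fit <- function(object, ...) {
  df <- tidy(object)
  df$branch <- factor(df$branch, levels = df$branch[order(df$omega)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$branch, y = .data$omega,
                                   fill = .data$tag)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "dN/dS") +
    ggplot2::theme_minimal()
}
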