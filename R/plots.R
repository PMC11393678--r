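#' Plot a lineage stability profile
#'
#' Mean largest Jacobian eigenvalue per window with a +/- one standard
#' deviation ribbon (over the subsampling iterations), against the window's
#' lineage position. Values above zero mark unstable (tipping) regions.
#'
#' @param object A [scan_lineage()] result.
#' @param metric One of `"largest_real"`, `"n_positive"`, `"frac_positive"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lineage_scan <- function(object, metric = "largest_real", ...) {
  metric <- match.arg(metric, c("largest_real", "n_positive", "frac_positive"))
  df <- object$summary
  m <- df[[paste0(metric, "_mean")]]
  s <- df[[paste0(metric, "_sd")]]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = m)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = m - s, ymax = m + s), alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey40") +
    ggplot2::labs(
      x = "lineage position",
      y = switch(metric,
        largest_real = "largest Re(eigenvalue)",
        n_positive = "positive eigenvalues",
        frac_positive = "fraction of positive eigenvalues"
      )
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-cell instability scores along the lineage
#'
#' @param scores Tibble from [instability_score()].
#' @return A ggplot object.
#' @export
plot_instability <- function(scores) {
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$ordering, y = .data$score)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.7) +
    ggplot2::labs(x = "lineage ordering", y = "instability score") +
    ggplot2::theme_minimal()
}

#' Plot the GRN community count along the lineage
#'
#' @param trajectory Tibble from [community_trajectory()].
#' @return A ggplot object.
#' @export
plot_community_trajectory <- function(trajectory) {
  ggplot2::ggplot(
    trajectory,
    ggplot2::aes(x = .data$position, y = .data$n_communities,
                 colour = .data$algorithm)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.9) +
    ggplot2::labs(x = "lineage position", y = "GRN communities",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
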