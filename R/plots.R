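#' Histogram of the permutation null with the observed distance
#'
#' @param result an `amsd_result` from [amsd_test()].
#' @param bins histogram bin count.
#' @return a ggplot object.
#' @export
plot_amsd_null <- function(result, bins = 40) {
  df <- data.frame(distance = result$null_distances)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70",
                            colour = "grey40") +
    ggplot2::geom_vline(xintercept = result$observed_distance,
                        colour = "firebrick", linewidth = 1) +
    ggplot2::labs(
      x = paste(result$distance_name, "distance between aggregates"),
      y = "permutations",
      title = sprintf("AMSD null (%d permutations), observed = %.4g, p = %.3g",
                      result$n_permutations, result$observed_distance,
                      result$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Volcano plot of a screen
#'
#' Observed aggregate distance against `-log10(p)` per comparison, with
#' the Bonferroni line and, when available, the regression-estimated BH
#' line.
#'
#' @param screen a `screen_table` from [run_screen()].
#' @return a ggplot object.
#' @export
plot_screen_volcano <- function(screen) {
  df <- screen$records
  df$neglogp <- -log10(df$raw_p)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$observed_distance,
                                        y = .data$neglogp)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = screen$bonferroni_threshold,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "observed aggregate spectrum distance",
                  y = expression(-log[10](italic(p))),
                  title = "AMSD screen") +
    ggplot2::theme_minimal()
  if (!is.null(screen$bh_regression)) {
    p <- p + ggplot2::geom_hline(yintercept = screen$bh_regression$threshold,
                                 linetype = "dotted", colour = "steelblue")
  }
  p
}

#' Volcano plot of per-channel rank-sum results
#'
#' @param tab data.frame from [per_channel_wilcoxon()].
#' @return a ggplot object.
#' @export
plot_channel_volcano <- function(tab) {
  tab$neglogp <- -log10(tab$raw_p)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$mean_freq_diff,
                                    y = .data$neglogp)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "mean frequency difference (A - B)",
                  y = expression(-log[10](italic(p))),
                  title = "Per-channel rank-sum comparison") +
    ggplot2::theme_minimal()
}
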