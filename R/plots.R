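#' Boxplot of read-length distributions by library
#'
#' @param reads Read tibble with `length` and `library` columns.
#' @param log_scale Log10 y axis (default TRUE; long-read length
#'   distributions are right-skewed).
#' @return A ggplot object.
#' @export
plot_read_lengths <- function(reads, log_scale = TRUE) {
  p <- ggplot2::ggplot(reads,
                       ggplot2::aes(x = .data$library, y = .data$length,
                                    fill = .data$library)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.2, show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "Read length (bp)") +
    ggplot2::theme_minimal()
  if (log_scale) p <- p + ggplot2::scale_y_log10()
  p
}

#' Rank-abundance curve with the top decile highlighted
#'
#' @param abundance Abundance tibble from [rank_abundance()].
#' @param populations Optional population summary ([population_summary()]);
#'   when given, bars are coloured by shared vs unique status.
#' @return A ggplot object.
#' @export
plot_rank_abundance <- function(abundance, populations = NULL) {
  df <- abundance
  if (!is.null(populations)) {
    df <- df |>
      left_join(populations[c("rep_id", "unique_to")], by = "rep_id") |>
      mutate(status = ifelse(is.na(.data$unique_to), "shared", "unique"))
  } else {
    df$status <- "population"
  }
  cutoff <- floor(nrow(df) / 10)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$abundance,
                                        fill = .data$status)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Population rank", y = "Abundance (mean depth / M reads)",
                  fill = NULL) +
    ggplot2::theme_minimal()
  if (cutoff >= 1) {
    p <- p + ggplot2::geom_vline(xintercept = cutoff + 0.5, linetype = "dashed")
  }
  p
}

#' Boxplots of per-contig microdiversity by group
#'
#' @param df Tibble with columns `group` and `pi`.
#' @return A ggplot object.
#' @export
plot_microdiversity <- function(df) {
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$pi,
                                   fill = .data$group)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = expression(pi)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.median_ci <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$median)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = c(object$ci_low, object$ci_high),
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$median, colour = "red") +
    ggplot2::labs(x = "Bootstrap median (bp)", y = "Replicates") +
    ggplot2::theme_minimal()
}
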