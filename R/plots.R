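# ggplot2 displays for the main result types.

#' @importFrom ggplot2 ggplot aes geom_col geom_line geom_point geom_ribbon
#'   geom_errorbar labs theme_minimal scale_fill_brewer facet_grid
#'   geom_hline element_text theme
NULL

#' Plot an indel spectrum
#'
#' @param object An `indel_spectrum`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot indel_spectrum
#' @export
autoplot.indel_spectrum <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(
      category = factor(.data$category, levels = .data$category),
      class = sub("^([0-9]+:[A-Za-z]+:[A-Z]+):.*$", "\\1", .data$category)
    )
  ggplot(df, aes(x = .data$category, y = .data$count, fill = .data$class)) +
    geom_col(show.legend = FALSE) +
    labs(x = NULL, y = "count",
         title = paste0("Indel spectrum (", attr(object, "scheme"), ")")) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5, hjust = 1,
                                     size = 5))
}

#' Plot a sequence logo matrix
#'
#' Stacked per-position bit contributions by base.
#'
#' @param logo A `logo_matrix` from [build_logo()].
#' @return A ggplot.
#' @export
plot_logo <- function(logo) {
  df <- as_tibble(unclass(logo)) |>
    mutate(position = dplyr::row_number()) |>
    tidyr::pivot_longer(dplyr::all_of(DNA_BASES), names_to = "base",
                        values_to = "bits")
  ggplot(df, aes(x = .data$position, y = .data$bits, fill = .data$base)) +
    geom_col() +
    scale_fill_brewer(palette = "Set1") +
    labs(y = "information (bits)", x = "position") +
    theme_minimal()
}

#' Plot signal-decile relative deletion rates
#'
#' @param rates Output of [signal_decile_rates()].
#' @return A ggplot.
#' @export
plot_decile_rates <- function(rates) {
  ggplot(rates, aes(x = .data$decile, y = .data$relative_rate)) +
    geom_ribbon(aes(ymin = .data$ci_low, ymax = .data$ci_high),
                fill = "grey80") +
    geom_line() + geom_point() +
    geom_hline(yintercept = 1, linetype = 2) +
    labs(x = "signal decile", y = "relative deletion rate") +
    theme_minimal()
}

#' Plot per-stratum deletion rates with bootstrap CIs
#'
#' @param rates Output of [stratum_rates()].
#' @return A ggplot.
#' @export
plot_stratum_rates <- function(rates) {
  df <- mutate(rates, group = factor(.data$group, levels = .data$group))
  ggplot(df, aes(x = .data$group, y = .data$rate)) +
    geom_errorbar(aes(ymin = .data$ci_low, ymax = .data$ci_high),
                  width = 0.2) +
    geom_point() +
    labs(x = "expression group", y = "deletions / bp / genome") +
    theme_minimal()
}

#' @export
plot.spectra_clust <- function(x, ...) {
  plot(x$hclust, sub = "", xlab = "",
       main = "Complete-linkage clustering (cosine distance)", ...)
}

#' Tidy a spectra clustering: one row per internal join
#'
#' @param x A `spectra_clust`.
#' @param ... Unused.
#' @return Tibble `join`, `height`, `members`, `support_pct`.
#' @method tidy spectra_clust
#' @export
tidy.spectra_clust <- function(x, ...) {
  clades <- hclust_clades(x$hclust)
  tibble(
    join = seq_along(x$support),
    height = x$hclust$height,
    members = unlist(clades),
    support_pct = x$support
  )
}
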