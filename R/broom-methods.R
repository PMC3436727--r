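#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a composite map into one row per composite position
#'
#' @param x A `composite_map`.
#' @param ... Unused.
#' @return Tibble: `linkage_group`, `marker`, `position`, `marker_type`,
#'   `n_support`, `support` (list-column of map ids), `added_in_round`,
#'   `is_multicopy`.
#' @method tidy composite_map
#' @export
tidy.composite_map <- function(x, ...) {
  x$loci |>
    dplyr::mutate(n_support = lengths(.data$support)) |>
    dplyr::select("linkage_group", "marker", "position", "marker_type",
                  "n_support", "support", "added_in_round", "is_multicopy")
}

#' One-row summary of a composite map
#'
#' @param x A `composite_map`.
#' @param ... Unused.
#' @return One-row tibble: `n_lgs`, `length_cM`, `n_markers` (distinct),
#'   `n_positions`, `n_multicopy_markers`, `n_multicopy_positions`,
#'   `n_unique_loci` (positions after collapsing co-located markers),
#'   `mean_interval_cM`, `n_merge_rounds`, `n_trimmed`.
#' @method glance composite_map
#' @export
glance.composite_map <- function(x, ...) {
  acc <- multicopy_accounting(x)
  st <- summary_table(x)
  tot <- st[st$linkage_group == "Total", ]
  tibble::tibble(
    n_lgs = nrow(st) - 1L,
    length_cM = tot$length_cM,
    n_markers = acc$n_markers,
    n_positions = acc$n_positions,
    n_multicopy_markers = acc$n_multicopy,
    n_multicopy_positions = acc$n_multicopy_positions,
    n_unique_loci = tot$unique_loci,
    mean_interval_cM = tot$mean_interval_cM,
    n_merge_rounds = nrow(x$merge_log),
    n_trimmed = if (is.null(x$trimmed)) 0L else nrow(x$trimmed))
}

#' Tidy the per-group table of a multicopy chi-square test
#' @param x An `mc_chisq`.
#' @param ... Unused.
#' @return Tibble with per-group `dart_positions`, `observed`, `expected`
#'   and the Pearson `residual`.
#' @method tidy mc_chisq
#' @export
tidy.mc_chisq <- function(x, ...) {
  dplyr::mutate(x$table,
                residual = (.data$observed - .data$expected) /
                  sqrt(.data$expected))
}

#' One-row summary of a multicopy chi-square test
#' @param x An `mc_chisq`.
#' @param ... Unused.
#' @return Tibble: `statistic`, `df`, `p_value`.
#' @method glance mc_chisq
#' @export
glance.mc_chisq <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_value = x$p_value)
}

#' Plot a composite map as linkage-group bars with marker ticks
#'
#' One vertical bar per linkage group, a tick per composite position;
#' multicopy positions are highlighted.
#'
#' @param object A `composite_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot composite_map
#' @export
autoplot.composite_map <- function(object, ...) {
  loci <- object$loci
  loci$linkage_group <- factor(
    loci$linkage_group,
    levels = unique(loci$linkage_group[order(nchar(loci$linkage_group),
                                             loci$linkage_group)]))
  ggplot2::ggplot(loci, ggplot2::aes(x = .data$linkage_group,
                                     y = .data$position)) +
    ggplot2::geom_linerange(
      ggplot2::aes(xmin = as.integer(.data$linkage_group) - 0.3,
                   xmax = as.integer(.data$linkage_group) + 0.3,
                   colour = .data$is_multicopy),
      linewidth = 0.2, show.legend = c(colour = TRUE)) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey30", `TRUE` = "red"),
      labels = c(`FALSE` = "single-copy", `TRUE` = "multicopy"),
      name = NULL) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "Linkage group", y = "Position (cM)") +
    ggplot2::theme_minimal()
}

#' Heatmap of composite vs component order correlations
#'
#' @param corr_table Output of [correlation_table()].
#' @return A ggplot tile map of signed Spearman rho per (linkage group,
#'   component map) cell.
#' @export
plot_correlation_table <- function(corr_table) {
  ggplot2::ggplot(corr_table,
                  ggplot2::aes(x = .data$map_id, y = .data$linkage_group,
                               fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$rho), "", sprintf("%.2f", .data$rho))),
      size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "steelblue",
                                  mid = "white", high = "firebrick",
                                  na.value = "grey90") +
    ggplot2::labs(x = "Component map", y = "Composite linkage group",
                  fill = "rho") +
    ggplot2::theme_minimal()
}
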