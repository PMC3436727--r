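#' Composite vs component marker-order correlation table
#'
#' For every (composite linkage group, component map) cell with at least
#' two shared markers, the signed Spearman correlation of shared-marker
#' orders. This is the primary post-hoc quality check of a composite map:
#' groups whose order was used in construction should correlate near 1.
#'
#' @param composite A `composite_map`.
#' @param maps Long marker table of the component maps.
#' @param min_common Minimum shared markers for a defined cell (default 2).
#' @return Tibble: `linkage_group`, `map_id`, `n_common`, `rho`,
#'   `used_in_build` (the map contributed a merge round to that group).
#'   Undefined cells carry `NA` rho. Row/column averages are available via
#'   [correlation_averages()].
#' @export
correlation_table <- function(composite, maps, min_common = 2) {
  loci <- composite$loci
  used <- dplyr::distinct(composite$merge_log, .data$building_lg,
                          .data$component_map_id)
  cells <- tidyr::expand_grid(
    linkage_group = unique(loci$linkage_group),
    map_id = unique(maps$map_id))
  per_cell <- purrr::pmap(cells, function(linkage_group, map_id) {
    comp_lg <- loci[loci$linkage_group == linkage_group, ]
    cmp <- maps[maps$map_id == map_id, ]
    anchors <- dplyr::inner_join(
      dplyr::select(comp_lg, "marker", pos_composite = "position"),
      dplyr::select(cmp, "marker", "linkage_group", pos_component = "position"),
      by = "marker", relationship = "many-to-many")
    # a multicopy marker pairs once per component placement; correlate
    # against the component LG sharing the most markers with this group
    if (nrow(anchors) > 0) {
      main_lg <- names(sort(table(anchors$linkage_group),
                            decreasing = TRUE))[1]
      anchors <- anchors[anchors$linkage_group == main_lg, ]
    }
    n <- nrow(anchors)
    tibble::tibble(
      linkage_group = linkage_group, map_id = map_id, n_common = n,
      rho = if (n >= min_common)
        spearman_rho(anchors$pos_composite, anchors$pos_component)
      else NA_real_)
  }) |> dplyr::bind_rows()
  per_cell |>
    dplyr::left_join(
      dplyr::mutate(used, used_in_build = TRUE),
      by = c(linkage_group = "building_lg", map_id = "component_map_id")) |>
    dplyr::mutate(used_in_build = dplyr::coalesce(.data$used_in_build, FALSE))
}

#' Row and column averages of a correlation table
#'
#' @param corr_table Output of [correlation_table()].
#' @param used_only Average only over cells whose map contributed to the
#'   build of that group (`TRUE`) or over all defined cells (`FALSE`).
#' @return List with `by_lg` and `by_map` tibbles of mean rho.
#' @export
correlation_averages <- function(corr_table, used_only = FALSE) {
  tbl <- corr_table[!is.na(corr_table$rho), ]
  if (used_only) tbl <- tbl[tbl$used_in_build, ]
  list(
    by_lg = tbl |> dplyr::group_by(.data$linkage_group) |>
      dplyr::summarise(mean_rho = mean(.data$rho), n_cells = dplyr::n(),
                       .groups = "drop"),
    by_map = tbl |> dplyr::group_by(.data$map_id) |>
      dplyr::summarise(mean_rho = mean(.data$rho), n_cells = dplyr::n(),
                       .groups = "drop"))
}

#' Per-linkage-group composite map summary
#'
#' Length, marker counts by type, multicopy counts, unique locus count
#' (distinct positions after collapsing co-located markers) and average
#' marker interval per linkage group, with a totals row. Average interval
#' is length / (unique loci - 1) per group; the totals-row interval is
#' total length / (total unique loci - number of groups).
#'
#' @param composite A `composite_map` (or its loci tibble).
#' @return Tibble with one row per linkage group plus a `"Total"` row;
#'   columns `linkage_group`, `length_cM`, `dart`, `ssr`, `gene`, `other`,
#'   `total`, `unique_loci`, `mean_interval_cM`, `multicopy_dart`,
#'   `pct_multicopy_of_total`, `pct_multicopy_of_dart`. Groups with fewer
#'   than two unique loci carry `NA` interval.
#' @export
summary_table <- function(composite) {
  loci <- if (inherits(composite, "composite_map")) composite$loci else
    tibble::as_tibble(composite)
  per_lg <- loci |>
    dplyr::group_by(.data$linkage_group) |>
    dplyr::summarise(
      length_cM = max(.data$position) - min(.data$position),
      dart = sum(.data$marker_type == "DArT"),
      ssr = sum(.data$marker_type == "SSR"),
      gene = sum(.data$marker_type == "gene"),
      other = sum(.data$marker_type == "other"),
      total = dplyr::n(),
      unique_loci = dplyr::n_distinct(.data$position),
      multicopy_dart = sum(.data$is_multicopy & .data$marker_type == "DArT"),
      .groups = "drop") |>
    dplyr::mutate(
      mean_interval_cM = dplyr::if_else(
        .data$unique_loci >= 2,
        .data$length_cM / (.data$unique_loci - 1), NA_real_),
      pct_multicopy_of_total = 100 * .data$multicopy_dart / .data$total,
      pct_multicopy_of_dart = 100 * .data$multicopy_dart / .data$dart)
  totals <- per_lg |>
    dplyr::summarise(
      linkage_group = "Total",
      length_cM = sum(.data$length_cM),
      dplyr::across(c("dart", "ssr", "gene", "other", "total", "unique_loci",
                      "multicopy_dart"), sum),
      mean_interval_cM = sum(.data$length_cM) /
        (sum(.data$unique_loci) - dplyr::n()),
      pct_multicopy_of_total = 100 * sum(.data$multicopy_dart) /
        sum(.data$total),
      pct_multicopy_of_dart = 100 * sum(.data$multicopy_dart) /
        sum(.data$dart))
  dplyr::bind_rows(per_lg, totals)
}

#' Chi-square test of multicopy marker distribution across linkage groups
#'
#' Tests whether multicopy DArT marker positions are spread across linkage
#' groups in proportion to DArT marker content. The expected count for
#' group *i* is `(total multicopy positions / total DArT positions) *
#' DArT positions on group i`; the statistic is the usual
#' `sum((obs - exp)^2 / exp)` with `df = groups - 1` and an upper-tail
#' p-value. Only DArT positions enter either side of the formula.
#'
#' @param dart_positions Integer vector: DArT marker positions per group.
#' @param multicopy_positions Integer vector: multicopy DArT positions per
#'   group (same order).
#' @param linkage_groups Optional group labels.
#' @return Object of class `mc_chisq` (list: `statistic`, `df`, `p_value`,
#'   and a `table` tibble of observed/expected per group). [tidy()] and
#'   [glance()] methods are provided.
#' @export
multicopy_chisquare <- function(dart_positions, multicopy_positions,
                                linkage_groups = NULL) {
  stopifnot(length(dart_positions) == length(multicopy_positions),
            length(dart_positions) >= 2,
            all(dart_positions >= 0), all(multicopy_positions >= 0))
  if (is.null(linkage_groups)) {
    linkage_groups <- as.character(seq_along(dart_positions))
  }
  expected <- sum(multicopy_positions) / sum(dart_positions) * dart_positions
  if (any(expected == 0)) {
    stop("expected count of zero (a linkage group has no DArT positions)",
         call. = FALSE)
  }
  stat <- sum((multicopy_positions - expected)^2 / expected)
  df <- length(dart_positions) - 1L
  structure(
    list(statistic = stat, df = df,
         p_value = stats::pchisq(stat, df, lower.tail = FALSE),
         table = tibble::tibble(linkage_group = linkage_groups,
                                dart_positions = dart_positions,
                                observed = multicopy_positions,
                                expected = expected)),
    class = "mc_chisq")
}

#' Chi-square test computed from a built composite map
#'
#' Convenience wrapper: counts DArT and multicopy-DArT positions per
#' linkage group from the composite loci and runs [multicopy_chisquare()].
#'
#' @param composite A `composite_map`.
#' @return An `mc_chisq` object.
#' @export
composite_multicopy_test <- function(composite) {
  tab <- summary_table(composite)
  tab <- tab[tab$linkage_group != "Total", ]
  multicopy_chisquare(tab$dart, tab$multicopy_dart, tab$linkage_group)
}

#' @export
print.mc_chisq <- function(x, ...) {
  cat(sprintf(
    "Multicopy marker distribution chi-square test\n  X-squared = %.2f, df = %d, p-value = %.2f\n",
    x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Multicopy accounting for a composite map
#'
#' Reports the identity `total positions = distinct markers +
#' sum(copies - 1)` over multicopy markers, plus the histogram of copy
#' numbers (how many markers occupy 1, 2, 3, ... linkage groups).
#'
#' @param composite A `composite_map` (or its loci tibble).
#' @return List: `n_positions`, `n_markers` (distinct), `n_multicopy`
#'   (markers on >= 2 groups), `n_multicopy_positions`, `copies` (tibble
#'   `n_lgs`, `n_markers`).
#' @export
multicopy_accounting <- function(composite) {
  loci <- if (inherits(composite, "composite_map")) composite$loci else
    tibble::as_tibble(composite)
  per_marker <- loci |>
    dplyr::group_by(.data$marker) |>
    dplyr::summarise(n_lgs = dplyr::n_distinct(.data$linkage_group),
                     .groups = "drop")
  copies <- per_marker |> dplyr::count(.data$n_lgs, name = "n_markers")
  mc <- per_marker[per_marker$n_lgs >= 2, ]
  list(
    n_positions = nrow(dplyr::distinct(loci, .data$marker,
                                       .data$linkage_group)),
    n_markers = nrow(per_marker),
    n_multicopy = nrow(mc),
    n_multicopy_positions = sum(mc$n_lgs),
    copies = copies)
}

#' Flag candidate redundant marker groups
#'
#' Redundant markers (identical clones under different names) should land
#' at the same position on every linkage group where both occur. This
#' flags groups of two or more markers whose placements co-locate, within
#' `tolerance_cM`, on identical linkage-group sets — candidates for
#' sequence-level confirmation, which this package does not perform.
#'
#' @param composite A `composite_map` (or its loci tibble).
#' @param tolerance_cM Maximum position difference counted as co-located
#'   (default 0, exact).
#' @return Tibble: `group` id, `marker`, `n_lgs`; zero rows when nothing
#'   co-locates.
#' @export
flag_redundant <- function(composite, tolerance_cM = 0.0) {
  loci <- if (inherits(composite, "composite_map")) composite$loci else
    tibble::as_tibble(composite)
  # signature per marker: its (LG, position-cluster) placements; markers
  # sharing a signature co-locate everywhere they occur. Clusters chain
  # positions whose successive gaps are <= tolerance within one LG.
  loci <- loci[order(loci$linkage_group, loci$position), ]
  cluster <- unlist(tapply(loci$position, loci$linkage_group, function(p) {
    cumsum(c(TRUE, diff(p) > tolerance_cM))
  }, simplify = FALSE), use.names = FALSE)
  sig <- tapply(paste(loci$linkage_group, cluster, sep = "@"), loci$marker,
                function(s) paste(sort(s), collapse = "|"))
  groups <- split(names(sig), unname(sig))
  groups <- groups[lengths(groups) >= 2]
  if (length(groups) == 0) {
    return(tibble::tibble(group = integer(), marker = character(),
                          n_lgs = integer()))
  }
  n_lgs <- lengths(strsplit(names(groups), "|", fixed = TRUE))
  purrr::imap(groups, function(mk, nm) {
    tibble::tibble(marker = mk,
                   n_lgs = length(strsplit(nm, "|", fixed = TRUE)[[1]]))
  }) |>
    dplyr::bind_rows(.id = "sig") |>
    dplyr::mutate(group = match(.data$sig, unique(.data$sig))) |>
    dplyr::select("group", "marker", "n_lgs") |>
    dplyr::arrange(.data$group, .data$marker)
}
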