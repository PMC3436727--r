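#' Published per-linkage-group counts for the Eucalyptus composite map
#'
#' The per-linkage-group summary of the published 11-group Eucalyptus
#' composite reference map (map length, DArT/SSR/gene marker positions,
#' total positions, mean marker interval, multicopy DArT positions),
#' shipped as a plain TSV. These counts are the standard worked example
#' for [multicopy_chisquare()] and the accounting identities of
#' [multicopy_accounting()].
#'
#' @return Tibble with one row per linkage group and columns
#'   `linkage_group`, `length_cM`, `dart`, `ssr`, `gene`, `total`,
#'   `mean_interval_cM`, `multicopy_dart`.
#' @examples
#' counts <- eucalyptus_composite_counts()
#' multicopy_chisquare(counts$dart, counts$multicopy_dart,
#'                     counts$linkage_group)
#' @export
eucalyptus_composite_counts <- function() {
  path <- system.file("extdata", "eucalyptus_composite_counts.tsv",
                      package = "compositemap", mustWork = TRUE)
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE) |>
    dplyr::mutate(linkage_group = as.character(.data$linkage_group))
}
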