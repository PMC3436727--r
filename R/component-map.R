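#' Assemble a component linkage map from a data frame
#'
#' A component map is one independently constructed genetic linkage map:
#' a set of linkage groups, each an ordered list of markers at centiMorgan
#' (cM) positions. `component_map()` validates a plain data frame of marker
#' records and returns it as a canonical tibble, sorted by position within
#' linkage group.
#'
#' @param x A data frame with columns `linkage_group`, `marker`, `position`
#'   and optionally `marker_type` (one of `"DArT"`, `"SSR"`, `"gene"`,
#'   `"other"`) and `map_id`.
#' @param map_id Identifier for the map; overrides any `map_id` column.
#' @param family_size Number of progeny in the mapping pedigree (optional;
#'   used only for seed-map tie-breaking and reporting).
#' @param default_type Marker type assigned where none is given. DArT
#'   markers dominate the maps this method was developed for, so the
#'   default is `"DArT"`; a message notes when defaulting occurs because
#'   type-stratified statistics (the multicopy chi-square test) depend on it.
#'
#' @return A tibble of class `component_map` with columns `map_id`,
#'   `linkage_group`, `marker`, `position`, `marker_type`, sorted by
#'   position within linkage group, carrying a `family_size` attribute.
#'
#' @details Positions must be finite and non-negative. A marker may appear
#'   at most once per linkage group within one map; a marker on two
#'   different linkage groups of the same map is kept as two distinct loci
#'   (that is how multicopy markers enter component maps). Positions are
#'   preserved verbatim: per-group re-basing to 0 is applied only by the
#'   merge engine, never on construction or read.
#'
#' @examples
#' component_map(
#'   data.frame(linkage_group = "LG1", marker = c("mA", "mB"),
#'              position = c(0, 12.5)),
#'   map_id = "M1"
#' )
#' @export
component_map <- function(x, map_id = NULL, family_size = NA_integer_,
                          default_type = "DArT") {
  stopifnot(is.data.frame(x))
  required <- c("linkage_group", "marker", "position")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x <- tibble::as_tibble(x)
  if (!is.null(map_id)) {
    x$map_id <- as.character(map_id)
  } else if (!"map_id" %in% names(x)) {
    stop("`map_id` must be given as an argument or a column", call. = FALSE)
  }
  if (length(unique(x$map_id)) > 1) {
    stop("a component map must have a single map_id; got: ",
         paste(unique(x$map_id), collapse = ", "), call. = FALSE)
  }
  if (!"marker_type" %in% names(x)) {
    x$marker_type <- NA_character_
  }
  n_default <- sum(is.na(x$marker_type))
  if (n_default > 0) {
    x$marker_type[is.na(x$marker_type)] <- default_type
    attr(x, "types_defaulted") <- TRUE
  }
  bad_type <- setdiff(unique(x$marker_type), marker_types())
  if (length(bad_type) > 0) {
    stop("unknown marker_type(s): ", paste(bad_type, collapse = ", "),
         call. = FALSE)
  }
  x$linkage_group <- as.character(x$linkage_group)
  x$marker <- as.character(x$marker)
  x$position <- as.double(x$position)
  if (any(!nzchar(x$marker)) || anyNA(x$marker)) {
    stop("marker names must be non-empty", call. = FALSE)
  }
  if (anyNA(x$position) || any(!is.finite(x$position))) {
    stop("positions must be finite numbers", call. = FALSE)
  }
  if (any(x$position < 0)) {
    stop("positions must be non-negative (cM)", call. = FALSE)
  }
  dup <- duplicated(x[, c("linkage_group", "marker")])
  if (any(dup)) {
    first <- x[dup, , drop = FALSE][1, ]
    stop(sprintf("duplicate locus: marker '%s' occurs twice on %s",
                 first$marker, first$linkage_group), call. = FALSE)
  }
  x <- dplyr::arrange(x, .data$linkage_group, .data$position, .data$marker)
  x <- x[, c("map_id", "linkage_group", "marker", "position", "marker_type")]
  attr(x, "family_size") <- as.integer(family_size)
  class(x) <- c("component_map", class(x))
  x
}

#' Recognised marker types
#' @return Character vector of valid `marker_type` values.
#' @export
marker_types <- function() c("DArT", "SSR", "gene", "other")

#' Bind several component maps into one long marker table
#'
#' Most multi-map operations ([match_linkage_groups()], [classify_markers()],
#' [build_composite()]) take a single long tibble with one row per
#' (map, linkage group, marker) placement. `bind_maps()` concatenates
#' component maps and records their family sizes.
#'
#' @param ... `component_map` objects (or a single list of them).
#' @return A tibble with the five canonical columns and a `family_sizes`
#'   attribute (named integer vector by `map_id`).
#' @export
bind_maps <- function(...) {
  maps <- list(...)
  if (length(maps) == 1 && is.list(maps[[1]]) && !is.data.frame(maps[[1]])) {
    maps <- maps[[1]]
  }
  fam <- purrr::map_int(maps, ~ {
    fs <- attr(.x, "family_size")
    if (is.null(fs)) NA_integer_ else fs
  })
  out <- dplyr::bind_rows(maps)
  ids <- purrr::map_chr(maps, ~ .x$map_id[1])
  if (anyDuplicated(ids)) {
    stop("duplicate map_id across maps: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(fam) <- ids
  attr(out, "family_sizes") <- fam
  out
}

#' Family sizes recorded on a bound marker table
#' @param maps A tibble produced by [bind_maps()].
#' @return Named integer vector (may contain `NA` where unknown).
#' @export
family_sizes <- function(maps) {
  fs <- attr(maps, "family_sizes")
  if (is.null(fs)) {
    ids <- unique(maps$map_id)
    fs <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  }
  fs
}

# Split a long marker table into a named list of per-map tibbles.
split_maps <- function(maps) {
  split(maps, maps$map_id)
}

#' Shift every linkage group so its smallest position is zero
#'
#' @param x A marker table (any tibble with `linkage_group` and `position`;
#'   grouping also respects `map_id` when present).
#' @return The table with per-group minimum position subtracted.
#' @export
rebase_positions <- function(x) {
  keys <- intersect(c("map_id", "linkage_group"), names(x))
  x |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::mutate(position = .data$position - min(.data$position)) |>
    dplyr::ungroup()
}
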