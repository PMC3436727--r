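#' Standardise marker names across maps
#'
#' Applies an alias table (raw name to canonical name) so that the same
#' locus genotyped under different names in different pedigrees becomes a
#' shared anchor. With no alias table the input is returned unchanged.
#'
#' @param maps Long marker table ([bind_maps()]) or a single map.
#' @param alias_table Data frame with columns `raw` and `canonical`, or
#'   `NULL`.
#' @return The table with `marker` replaced by its canonical name.
#'   Renaming that makes two distinct raw markers collide on the same
#'   linkage group of the same map is an error (the aliases are
#'   contradictory), reported with both raw names.
#' @export
standardize_names <- function(maps, alias_table = NULL) {
  if (is.null(alias_table)) return(maps)
  stopifnot(all(c("raw", "canonical") %in% names(alias_table)))
  idx <- match(maps$marker, alias_table$raw)
  new <- ifelse(is.na(idx), maps$marker, alias_table$canonical[idx])
  key <- paste(maps$map_id, maps$linkage_group, new, sep = "\r")
  d <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
  if (length(d) > 0) {
    grp <- split(maps$marker[d], key[d])
    pair <- grp[[which(lengths(grp) >= 2)[1]]]
    stop(sprintf(
      "alias collision: raw markers '%s' and '%s' map to the same canonical name on one linkage group",
      pair[1], pair[2]), call. = FALSE)
  }
  maps$marker <- new
  maps
}

#' Paired positions of markers shared by two linkage groups
#'
#' The anchor set for one pair of linkage groups: exactly the markers named
#' on both, with their position on each.
#'
#' @param lg_a,lg_b Marker tables for one linkage group each (columns
#'   `marker`, `position`; extra columns ignored).
#' @return Tibble with columns `marker`, `position_a`, `position_b`; zero
#'   rows when the groups share no marker.
#' @export
find_shared_markers <- function(lg_a, lg_b) {
  dplyr::inner_join(
    dplyr::select(tibble::as_tibble(lg_a), "marker", position_a = "position"),
    dplyr::select(tibble::as_tibble(lg_b), "marker", position_b = "position"),
    by = "marker"
  ) |>
    dplyr::arrange(.data$position_a, .data$marker)
}

#' Assign linkage groups of other maps to homologous reference groups
#'
#' Homology is decided from shared (anchor) loci: each linkage group of
#' each non-reference map is assigned to the reference linkage group with
#' which it shares the most markers. Assignments supported by fewer than
#' `min_anchors` shared markers, or tied between two reference groups, are
#' flagged unassigned rather than guessed.
#'
#' @param maps Long marker table containing the reference map and at least
#'   one other map.
#' @param reference_map_id `map_id` of the reference (seed) map.
#' @param min_anchors Minimum shared-marker evidence for an assignment
#'   (default 3, the merge eligibility minimum).
#' @return Tibble with one row per (map, linkage group) of the other maps:
#'   `map_id`, `linkage_group`, `assigned_lg` (`NA` when unassigned),
#'   `n_shared` (with the best reference group), `tie` (logical).
#' @export
match_linkage_groups <- function(maps, reference_map_id, min_anchors = 3) {
  stopifnot(reference_map_id %in% maps$map_id)
  ref <- maps[maps$map_id == reference_map_id, c("linkage_group", "marker")]
  oth <- maps[maps$map_id != reference_map_id, ]
  counts <- dplyr::inner_join(
    dplyr::select(oth, "map_id", "linkage_group", "marker"),
    dplyr::rename(ref, ref_lg = "linkage_group"),
    by = "marker", relationship = "many-to-many"
  ) |>
    dplyr::count(.data$map_id, .data$linkage_group, .data$ref_lg,
                 name = "n_shared")
  all_lgs <- dplyr::distinct(oth, .data$map_id, .data$linkage_group)
  best <- counts |>
    dplyr::group_by(.data$map_id, .data$linkage_group) |>
    dplyr::summarise(
      best = which.max(.data$n_shared),
      tie = sum(.data$n_shared == max(.data$n_shared)) > 1,
      assigned_lg = .data$ref_lg[.data$best],
      n_shared = max(.data$n_shared),
      .groups = "drop"
    ) |>
    dplyr::select(-"best")
  out <- dplyr::left_join(all_lgs, best,
                          by = c("map_id", "linkage_group")) |>
    dplyr::mutate(
      n_shared = dplyr::coalesce(.data$n_shared, 0L),
      tie = dplyr::coalesce(.data$tie, FALSE),
      assigned_lg = dplyr::if_else(
        .data$tie | .data$n_shared < min_anchors,
        NA_character_, .data$assigned_lg)
    ) |>
    dplyr::arrange(.data$map_id, .data$linkage_group)
  out
}

# Homology classes for every (map, LG): the reference map's own LGs are
# their own class; other maps' LGs use the match_linkage_groups assignment.
lg_classes <- function(maps, reference_map_id, homology) {
  ref_lgs <- unique(maps$linkage_group[maps$map_id == reference_map_id])
  dplyr::bind_rows(
    tibble::tibble(map_id = reference_map_id, linkage_group = ref_lgs,
                   lg_class = ref_lgs),
    dplyr::select(homology, "map_id", "linkage_group",
                  lg_class = "assigned_lg")
  )
}

#' Classify every marker placement as bridging, unique or multicopy
#'
#' A placement is one (marker, map, linkage group) record. Markers mapped
#' on homologous linkage groups in two or more maps are bridging (they can
#' serve as anchors); markers mapped in a single map only are unique.
#' Orthogonally, a marker whose placements fall on two or more distinct
#' homologous linkage-group classes is multicopy (a putatively duplicated
#' locus); a marker can be both bridging and multicopy through different
#' copies.
#'
#' @param maps Long marker table.
#' @param homology Output of [match_linkage_groups()].
#' @param reference_map_id The reference map used for `homology`.
#' @return List with `placements` (one row per placement with its homology
#'   class and `category` bridging/unique), `markers` (one row per marker:
#'   `n_placements`, `n_lg_classes`, `is_multicopy`) and `totals`
#'   (placements, bridging, unique, multicopy marker count) satisfying
#'   placements = bridging + unique.
#' @export
classify_markers <- function(maps, homology, reference_map_id) {
  cls <- lg_classes(maps, reference_map_id, homology)
  pl <- dplyr::left_join(maps, cls, by = c("map_id", "linkage_group"))
  # unassigned LGs form their own private class so their placements count
  # as unique rather than silently joining a homology class
  pl$lg_class <- dplyr::coalesce(
    pl$lg_class, paste0(pl$map_id, ":", pl$linkage_group))
  pl <- pl |>
    dplyr::group_by(.data$marker, .data$lg_class) |>
    dplyr::mutate(category = dplyr::if_else(dplyr::n_distinct(.data$map_id) >= 2,
                                            "bridging", "unique")) |>
    dplyr::ungroup()
  mk <- pl |>
    dplyr::group_by(.data$marker) |>
    dplyr::summarise(
      n_placements = dplyr::n(),
      n_lg_classes = dplyr::n_distinct(.data$lg_class),
      is_multicopy = .data$n_lg_classes >= 2,
      .groups = "drop"
    )
  # a placement is one (marker, lg_class) map position in merge accounting:
  # the same marker in k maps on one homologous LG is one bridging position
  pos <- dplyr::distinct(pl, .data$marker, .data$lg_class, .data$category)
  totals <- list(
    placements = nrow(pos),
    bridging = sum(pos$category == "bridging"),
    unique = sum(pos$category == "unique"),
    multicopy_markers = sum(mk$is_multicopy)
  )
  list(placements = pl, markers = mk, totals = totals)
}

#' Pre-screen component linkage groups for colinearity
#'
#' Before merging, each candidate linkage group is correlated (Spearman,
#' on shared-marker positions) against every reference linkage group it
#' overlaps. Groups whose best absolute correlation falls below
#' `min_rho` despite adequate anchoring show substantial non-colinearity
#' and are flagged for exclusion. Exclusion is advisory: the report lists
#' every pairwise correlation for review, mirroring a visual inspection
#' workflow, and [build_composite()] only drops groups you pass to it.
#'
#' @param maps Long marker table.
#' @param reference_map_id Reference map against which to screen.
#' @param min_rho Exclusion threshold on |rho| (default 0.90; retained
#'   groups in well-behaved map sets correlate above this, discordant ones
#'   far below).
#' @param min_anchors Minimum shared markers for a correlation to count
#'   (default 3).
#' @return Tibble with one row per (map, LG, reference LG) overlap:
#'   `n_common`, `rho`, `orientation`, plus per-(map, LG) `best_abs_rho`
#'   and `decision` (`"pass"`, `"excluded"`, or `"insufficient"` when no
#'   reference overlap reaches `min_anchors`).
#' @export
screen_colinearity <- function(maps, reference_map_id, min_rho = 0.90,
                               min_anchors = 3) {
  ref <- maps[maps$map_id == reference_map_id, ]
  oth <- maps[maps$map_id != reference_map_id, ]
  ref_split <- split(ref, ref$linkage_group)
  rows <- oth |>
    dplyr::group_by(.data$map_id, .data$linkage_group) |>
    dplyr::group_map(function(lg, key) {
      per_ref <- purrr::map(ref_split, function(rlg) {
        anchors <- find_shared_markers(lg, rlg)
        if (nrow(anchors) == 0) return(NULL)
        rho <- spearman_rho(anchors$position_a, anchors$position_b)
        tibble::tibble(
          map_id = key$map_id, linkage_group = key$linkage_group,
          reference_lg = rlg$linkage_group[1],
          n_common = nrow(anchors), rho = rho,
          orientation = dplyr::case_when(
            is.na(rho) ~ NA_character_,
            rho < 0 ~ "reversed",
            TRUE ~ "forward")
        )
      })
      dplyr::bind_rows(per_ref)
    }) |>
    dplyr::bind_rows()
  if (nrow(rows) == 0) return(rows)
  rows |>
    dplyr::group_by(.data$map_id, .data$linkage_group) |>
    dplyr::mutate(
      best_abs_rho = {
        ok <- .data$n_common >= min_anchors & !is.na(.data$rho)
        if (any(ok)) max(abs(.data$rho[ok])) else NA_real_
      },
      decision = dplyr::case_when(
        is.na(.data$best_abs_rho) ~ "insufficient",
        .data$best_abs_rho < min_rho ~ "excluded",
        TRUE ~ "pass"
      )
    ) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$map_id, .data$linkage_group, .data$reference_lg)
}
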