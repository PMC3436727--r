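#' Spearman rank correlation of two anchor position vectors
#'
#' Marker-order agreement between two linkage groups is measured as the
#' Spearman rank correlation of the positions of their shared markers.
#' Ties take mean ranks. The coefficient is signed: a perfectly colinear
#' but reversed group scores -1.
#'
#' @param a,b Numeric position vectors of equal length (one entry per
#'   shared marker, paired).
#' @return Signed correlation in `[-1, 1]`, or `NA` when fewer than two
#'   pairs are given or either side has zero rank variance.
#' @export
spearman_rho <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) < 2) return(NA_real_)
  if (stats::sd(rank(a)) == 0 || stats::sd(rank(b)) == 0) return(NA_real_)
  stats::cor(a, b, method = "spearman")
}

#' Fit value: a heuristic score for ranking candidate linkage groups
#'
#' `fit_value = |rho| * log(n_common)`. The log term rewards the number
#' of shared anchor markers with diminishing returns, so a moderately
#' correlated group anchored by many markers can outrank a near-perfectly
#' correlated group anchored by few. The absolute correlation is used
#' because linkage-group orientation is arbitrary across independently
#' built maps; reversed groups are flipped before projection instead of
#' being penalised. Ranking is invariant to the logarithm base (a positive
#' rescaling of all scores); base 10 is the reporting default.
#'
#' @param rho Spearman order correlation (signed or absolute).
#' @param n_common Number of shared markers (>= 1; 0 gives `NA`).
#' @param log_base Base of the logarithm (default 10).
#' @return Non-negative score; 0 when `n_common` is 1; `NA` when
#'   `n_common` is 0 or `rho` is `NA`.
#' @export
fit_value <- function(rho, n_common, log_base = 10) {
  out <- abs(rho) * log(n_common, base = log_base)
  out[n_common == 1] <- 0
  out[n_common == 0] <- NA_real_
  out
}

# Compare each unconsumed candidate LG against the current building LG.
# building: list(marker=chr, position=dbl); candidates: list of tibbles.
compare_candidates <- function(building, candidates, log_base) {
  purrr::imap(candidates, function(cand, i) {
    idx <- match(cand$marker, building$marker)
    hit <- !is.na(idx)
    n <- sum(hit)
    rho <- if (n >= 2) spearman_rho(building$position[idx[hit]],
                                    cand$position[hit]) else NA_real_
    tibble::tibble(
      candidate = i,
      component_map_id = cand$map_id[1],
      component_lg = cand$linkage_group[1],
      n_common = n,
      rho = rho,
      orientation = dplyr::case_when(is.na(rho) ~ NA_character_,
                                     rho < 0 ~ "reversed",
                                     TRUE ~ "forward"),
      fit = fit_value(rho, n, log_base)
    )
  }) |> dplyr::bind_rows()
}

#' Select the best eligible component linkage group for the next merge round
#'
#' Candidates must share at least `min_anchors` markers with the building
#' composite group and have absolute order correlation `>= min_rho`; among
#' eligible candidates the one with the highest fit value wins. Ties are
#' broken by larger shared-marker count, then by candidate input order, so
#' the build is deterministic.
#'
#' @param building_lg Tibble of the current building linkage group
#'   (columns `marker`, `position`).
#' @param candidates List of candidate component linkage-group tibbles
#'   (columns `map_id`, `linkage_group`, `marker`, `position`).
#' @param min_anchors Minimum shared markers (default 3).
#' @param min_rho Minimum |Spearman rho| (default 0.50).
#' @param log_base Log base of the fit value (selection is base-invariant).
#' @return One-row tibble (`component_map_id`, `component_lg`, `n_common`,
#'   `rho`, `orientation`, `fit`, `candidate` index), or `NULL` when no
#'   candidate is eligible.
#' @export
select_best_component <- function(building_lg, candidates, min_anchors = 3,
                                  min_rho = 0.50, log_base = 10) {
  if (length(candidates) == 0) return(NULL)
  cmp <- compare_candidates(
    list(marker = building_lg$marker, position = building_lg$position),
    candidates, log_base)
  ok <- cmp$n_common >= min_anchors & !is.na(cmp$rho) &
    abs(cmp$rho) >= min_rho
  if (!any(ok)) return(NULL)
  el <- cmp[ok, ]
  el <- el[order(-el$fit, -el$n_common, el$candidate), ]
  el[1, ]
}

#' Fit the anchor regression projecting component onto composite positions
#'
#' Ordinary least squares of composite positions (`pc`) on component
#' positions (`pi`): `pc = m * pi + c`. The fitted line transfers the
#' positions of markers unique to the component group onto the building
#' composite group.
#'
#' @param anchors Data frame with columns `pc` (position on the building
#'   composite group) and `pi` (position on the component group, already
#'   orientation-resolved).
#' @return List of class `map_projection`: `slope`, `intercept`,
#'   `residual_rmse` (root mean squared residual, cM), `n_anchors`.
#' @export
fit_projection <- function(anchors) {
  pc <- anchors$pc
  pi_ <- anchors$pi
  if (length(pc) < 2) stop("need at least 2 anchors to fit", call. = FALSE)
  if (diff(range(pi_)) == 0) {
    stop("degenerate fit: all component anchor positions identical",
         call. = FALSE)
  }
  fit <- stats::lm(pc ~ pi_)
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         residual_rmse = sqrt(mean(stats::residuals(fit)^2)),
         n_anchors = length(pc)),
    class = "map_projection")
}

#' Evaluate a projection at component positions
#' @param projection A `map_projection`.
#' @param pi_ Component-map positions (cM).
#' @return Projected composite positions `slope * pi + intercept`.
#' @export
project_positions <- function(projection, pi_) {
  projection$slope * pi_ + projection$intercept
}

#' Project a component group's unique markers onto the building group
#'
#' Markers of `component_lg` absent from `building_lg` are placed at their
#' regression position; markers already present are skipped, their support
#' set gaining the component map's id. Projected positions may fall below
#' zero or beyond the current ends — the build re-bases each finished
#' group, so no clipping is applied here.
#'
#' @param component_lg Component linkage-group tibble (orientation already
#'   resolved in `position`).
#' @param building_lg Building composite group tibble (columns `marker`,
#'   `position`, `marker_type`, `support`, `added_in_round`).
#' @param projection A `map_projection` from [fit_projection()].
#' @param round Merge round number recorded on added markers.
#' @return List: `building_lg` (updated), `n_added`, `n_skipped`.
#' @export
project_unique_markers <- function(component_lg, building_lg, projection,
                                   round = 1L) {
  map_id <- component_lg$map_id[1]
  shared_idx <- match(component_lg$marker, building_lg$marker)
  is_new <- is.na(shared_idx)
  hit <- shared_idx[!is_new]
  building_lg$support[hit] <- purrr::map(building_lg$support[hit],
                                         ~ union(.x, map_id))
  if (any(is_new)) {
    add <- component_lg[is_new, ]
    new_rows <- tibble::tibble(
      marker = add$marker,
      position = project_positions(projection, add$position),
      marker_type = add$marker_type,
      support = purrr::map(add$marker, ~ map_id),
      added_in_round = as.integer(round)
    )
    building_lg <- dplyr::bind_rows(building_lg, new_rows)
  }
  list(building_lg = building_lg, n_added = sum(is_new),
       n_skipped = sum(!is_new))
}

empty_merge_log <- function() {
  tibble::tibble(
    building_lg = character(), round = integer(),
    component_map_id = character(), component_lg = character(),
    n_common = integer(), rho = double(), orientation = character(),
    fit_value = double(), slope = double(), intercept = double(),
    residual_rmse = double(), markers_added = integer(),
    markers_skipped = integer())
}

#' Build one composite linkage group from a fixed seed group
#'
#' The iterative core of composite construction. The seed group is the
#' fixed backbone: its marker positions never move (apart from the final
#' rigid shift to a zero minimum). Each round, every unconsumed candidate
#' component group is compared to the *current* building group — so anchors
#' include markers projected in earlier rounds — the best eligible
#' candidate (see [select_best_component()]) is merged via
#' [fit_projection()] and [project_unique_markers()], and the process
#' repeats until no candidate is eligible.
#'
#' @param seed_lg Seed linkage-group tibble (columns `map_id`,
#'   `linkage_group`, `marker`, `position`, `marker_type`).
#' @param component_lgs List of candidate component linkage-group tibbles
#'   (same columns). Each is consumed at most once.
#' @inheritParams select_best_component
#' @return List: `lg` — the composite group tibble (`marker`, `position`,
#'   `marker_type`, `support`, `added_in_round`), sorted, min position 0;
#'   `log` — one merge-log row per round.
#' @export
build_linkage_group <- function(seed_lg, component_lgs, min_anchors = 3,
                                min_rho = 0.50, log_base = 10) {
  building <- tibble::tibble(
    marker = seed_lg$marker,
    position = seed_lg$position,
    marker_type = seed_lg$marker_type,
    support = purrr::map(seed_lg$marker, ~ seed_lg$map_id[1]),
    added_in_round = 0L
  )
  lg_id <- seed_lg$linkage_group[1]
  log <- empty_merge_log()
  remaining <- component_lgs
  round <- 0L
  while (length(remaining) > 0) {
    sel <- select_best_component(building, remaining, min_anchors, min_rho,
                                 log_base)
    if (is.null(sel)) break
    round <- round + 1L
    cand <- remaining[[sel$candidate]]
    if (sel$orientation == "reversed") {
      cand$position <- max(cand$position) - cand$position
    }
    idx <- match(cand$marker, building$marker)
    hit <- !is.na(idx)
    proj <- fit_projection(data.frame(pc = building$position[idx[hit]],
                                      pi = cand$position[hit]))
    res <- project_unique_markers(cand, building, proj, round = round)
    building <- res$building_lg
    log <- dplyr::bind_rows(log, tibble::tibble(
      building_lg = lg_id, round = round,
      component_map_id = sel$component_map_id,
      component_lg = sel$component_lg,
      n_common = sel$n_common, rho = sel$rho,
      orientation = sel$orientation, fit_value = sel$fit,
      slope = proj$slope, intercept = proj$intercept,
      residual_rmse = proj$residual_rmse,
      markers_added = res$n_added, markers_skipped = res$n_skipped))
    remaining <- remaining[-sel$candidate]
  }
  building$position <- building$position - min(building$position)
  building <- building[order(building$position, building$marker), ]
  list(lg = building, log = log)
}

#' Trim poorly supported markers from linkage-group ends
#'
#' Markers at the distal ends of a composite group that sit a large
#' interval (`>= gap_threshold` cM) from their neighbour and are supported
#' by too few component maps (fewer than `min_support`) are likely
#' projection artefacts and are removed. Trimming repeats from both ends
#' until stable, then the group is re-based to a zero minimum. The
#' operation is idempotent.
#'
#' @param composite_lg Composite group tibble with `marker`, `position`
#'   and a `support` list-column.
#' @param gap_threshold Terminal gap in cM at or above which a marker is a
#'   trim candidate (default 5).
#' @param min_support Markers supported by at least this many maps are
#'   never trimmed (default 2, i.e. single-map support is "poor").
#' @return List: `lg` (trimmed, re-based), `removed` (rows trimmed, with a
#'   `trim_gap` column).
#' @export
trim_ends <- function(composite_lg, gap_threshold = 5.0, min_support = 2) {
  lg <- composite_lg[order(composite_lg$position, composite_lg$marker), ]
  removed <- lg[0, ]
  removed$trim_gap <- double(0)
  repeat {
    n <- nrow(lg)
    if (n < 2) break
    gaps <- diff(lg$position)
    cut <- NULL
    if (gaps[1] >= gap_threshold && length(lg$support[[1]]) < min_support) {
      cut <- 1L; gap <- gaps[1]
    } else if (gaps[n - 1] >= gap_threshold &&
               length(lg$support[[n]]) < min_support) {
      cut <- n; gap <- gaps[n - 1]
    }
    if (is.null(cut)) break
    row <- lg[cut, ]
    row$trim_gap <- gap
    removed <- dplyr::bind_rows(removed, row)
    lg <- lg[-cut, ]
  }
  if (nrow(lg) > 0) lg$position <- lg$position - min(lg$position)
  list(lg = lg, removed = removed)
}

#' Choose the seed (backbone) map
#'
#' The seed map is the component map with the most mapped markers; ties
#' break by larger family size, then lexical map id.
#'
#' @param maps Long marker table.
#' @return The chosen `map_id`.
#' @export
select_seed_map <- function(maps) {
  fam <- family_sizes(maps)
  counts <- maps |>
    dplyr::count(.data$map_id, name = "n_markers") |>
    dplyr::mutate(family_size = unname(fam[.data$map_id]))
  counts <- counts[order(-counts$n_markers,
                         -ifelse(is.na(counts$family_size), -Inf,
                                 counts$family_size),
                         counts$map_id), ]
  counts$map_id[1]
}

#' Build a composite map from two or more component maps
#'
#' End-to-end merge: choose (or accept) the seed map, establish linkage
#' group homology from shared markers, then for each seed group run the
#' iterative fit-value merge ([build_linkage_group()]) followed by distal
#' trimming ([trim_ends()]). Markers ending up on two or more composite
#' groups are flagged multicopy.
#'
#' @param maps Long marker table from [bind_maps()] (>= 2 maps).
#' @param seed_map_id Seed map; `NULL` selects automatically
#'   ([select_seed_map()]).
#' @param exclusions Optional data frame (`map_id`, `linkage_group`) of
#'   component groups to leave out, e.g. the `"excluded"` rows of a
#'   [screen_colinearity()] report.
#' @param min_anchors,min_rho Merge eligibility thresholds (defaults 3
#'   and 0.50).
#' @param trim Logical; run end trimming (default `TRUE`).
#' @param trim_gap,trim_min_support Trimming parameters (defaults 5 cM
#'   and 2 maps); see [trim_ends()].
#' @param log_base Fit-value log base (default 10; selection is
#'   base-invariant).
#' @return A `composite_map` object: list with `loci` (tibble:
#'   `linkage_group`, `marker`, `position`, `marker_type`, `support`
#'   list-column, `added_in_round`, `is_multicopy`), `merge_log`,
#'   `trimmed`, `seed_map_id`, `homology`, `config`. Methods: [tidy()],
#'   [glance()], [summary_table()], [autoplot()], `print()`.
#' @export
build_composite <- function(maps, seed_map_id = NULL, exclusions = NULL,
                            min_anchors = 3, min_rho = 0.50, trim = TRUE,
                            trim_gap = 5.0, trim_min_support = 2,
                            log_base = 10) {
  map_order <- unique(maps$map_id)
  if (length(map_order) < 2) {
    stop("need at least two component maps to build a composite",
         call. = FALSE)
  }
  if (is.null(seed_map_id)) seed_map_id <- select_seed_map(maps)
  stopifnot(seed_map_id %in% map_order)
  if (!is.null(exclusions) && nrow(exclusions) > 0) {
    drop_key <- paste(exclusions$map_id, exclusions$linkage_group, sep = "\r")
    maps <- maps[!(paste(maps$map_id, maps$linkage_group, sep = "\r") %in%
                     drop_key), ]
  }
  homology <- match_linkage_groups(maps, seed_map_id,
                                   min_anchors = min_anchors)
  seed <- maps[maps$map_id == seed_map_id, ]
  seed_lgs <- unique(seed$linkage_group)
  other <- maps[maps$map_id != seed_map_id, ]
  other_split <- split(other, paste(other$map_id, other$linkage_group,
                                    sep = "\r"))
  # candidate lists per seed LG, in map input order (deterministic ties)
  hom <- homology[!is.na(homology$assigned_lg), ]
  hom <- hom[order(match(hom$map_id, map_order), hom$linkage_group), ]
  loci <- list()
  log <- empty_merge_log()
  trimmed <- list()
  for (lg in seed_lgs) {
    seed_lg <- seed[seed$linkage_group == lg, ]
    cand_keys <- paste(hom$map_id, hom$linkage_group, sep = "\r")[
      hom$assigned_lg == lg]
    cands <- unname(other_split[cand_keys])
    built <- build_linkage_group(seed_lg, cands, min_anchors = min_anchors,
                                 min_rho = min_rho, log_base = log_base)
    out_lg <- built$lg
    if (trim && nrow(out_lg) > 0) {
      tr <- trim_ends(out_lg, gap_threshold = trim_gap,
                      min_support = trim_min_support)
      out_lg <- tr$lg
      if (nrow(tr$removed) > 0) {
        tr$removed$linkage_group <- lg
        trimmed[[lg]] <- tr$removed
      }
    }
    out_lg$linkage_group <- lg
    loci[[lg]] <- out_lg
    log <- dplyr::bind_rows(log, built$log)
  }
  loci <- dplyr::bind_rows(loci) |>
    dplyr::select("linkage_group", "marker", "position", "marker_type",
                  "support", "added_in_round")
  lg_per_marker <- tapply(loci$linkage_group, loci$marker,
                          function(g) length(unique(g)))
  loci$is_multicopy <- as.vector(lg_per_marker[loci$marker] >= 2)
  trimmed <- if (length(trimmed) > 0) dplyr::bind_rows(trimmed) else NULL
  new_composite_map(
    loci, merge_log = log, trimmed = trimmed,
    config = list(seed_map_id = seed_map_id, min_anchors = min_anchors,
                  min_rho = min_rho, trim = trim, trim_gap = trim_gap,
                  trim_min_support = trim_min_support, log_base = log_base),
    seed_map_id = seed_map_id, homology = homology)
}

new_composite_map <- function(loci, merge_log, trimmed, config,
                              seed_map_id = NA_character_, homology = NULL) {
  structure(
    list(loci = loci, merge_log = merge_log, trimmed = trimmed,
         seed_map_id = seed_map_id, homology = homology, config = config),
    class = "composite_map")
}

#' @export
print.composite_map <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "A composite linkage map: %d linkage groups, %.1f cM\n", g$n_lgs,
    g$length_cM))
  cat(sprintf(
    "  %d markers at %d positions (%d multicopy markers), %d unique loci\n",
    g$n_markers, g$n_positions, g$n_multicopy_markers, g$n_unique_loci))
  cat(sprintf("  seed map: %s; %d merge rounds; mean interval %.2f cM\n",
              x$seed_map_id, nrow(x$merge_log), g$mean_interval_cM))
  invisible(x)
}
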