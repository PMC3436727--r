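#' Configuration for the synthetic map generator
#'
#' Defaults emulate a seven-pedigree Eucalyptus-style map set: 11 linkage
#' groups of roughly 80-140 cM, ~4400 markers on the true map, per-map
#' marker retention between ~10% and ~53% (so the largest component
#' carries ~2300 markers and the smallest ~500), per-map length scale
#' factors 0.93-1.14, 1 cM position noise, ~2% multicopy markers and a
#' couple of redundant clone pairs.
#'
#' @param n_lgs Number of linkage groups (default 11).
#' @param markers_per_lg Markers per linkage group on the true map
#'   (default 400).
#' @param lg_length_range Range (cM) from which true group lengths are
#'   drawn uniformly (default `c(80, 140)`).
#' @param n_maps Number of component maps (default 7).
#' @param retention Per-map marker retention probabilities (recycled /
#'   truncated to `n_maps`).
#' @param length_scale Per-map map-length scale factors.
#' @param family_size Per-map progeny counts (reporting and seed
#'   tie-breaks only).
#' @param noise_sd Gaussian position noise, cM (default 1).
#' @param swap_rate Probability that each adjacent marker pair is swapped
#'   after noising (extra local order error; default 0.02).
#' @param multicopy_fraction Fraction of true markers duplicated onto a
#'   second linkage group (default 0.02).
#' @param redundant_pairs Number of redundant clone pairs injected
#'   (co-located duplicate markers under a second name; default 2).
#' @param seed Random seed; mandatory, for byte-identical regeneration.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_lgs = 11, markers_per_lg = 400,
                         lg_length_range = c(80, 140), n_maps = 7,
                         retention = c(0.53, 0.42, 0.24, 0.13, 0.11, 0.14,
                                       0.16),
                         length_scale = c(1.00, 1.11, 1.04, 0.93, 1.03,
                                          0.95, 1.14),
                         family_size = c(547, 177, 503, 184, 184, 183, 172),
                         noise_sd = 1.0, swap_rate = 0.02,
                         multicopy_fraction = 0.02, redundant_pairs = 2,
                         seed) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  stopifnot(n_lgs >= 1, markers_per_lg >= 2,
            all(lg_length_range > 0), n_maps >= 1,
            all(retention > 0 & retention <= 1),
            all(length_scale > 0), noise_sd >= 0,
            swap_rate >= 0, swap_rate <= 1,
            multicopy_fraction >= 0, multicopy_fraction <= 1)
  structure(list(
    n_lgs = n_lgs, markers_per_lg = markers_per_lg,
    lg_length_range = lg_length_range, n_maps = n_maps,
    retention = rep_len(retention, n_maps),
    length_scale = rep_len(length_scale, n_maps),
    family_size = rep_len(family_size, n_maps),
    noise_sd = noise_sd, swap_rate = swap_rate,
    multicopy_fraction = multicopy_fraction,
    redundant_pairs = redundant_pairs, seed = as.integer(seed)),
    class = "synth_config")
}

#' Generate a true map with known marker positions
#'
#' Markers are placed uniformly at random along each linkage group and
#' sorted; this is the ground truth that component maps are sampled from
#' and recovery is scored against.
#'
#' @param config A [synth_config()].
#' @return Tibble: `linkage_group` (`"LG1"`...), `marker` (`"mk00001"`...),
#'   `position`, `marker_type` (all `"DArT"`).
#' @export
generate_true_map <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  lengths <- stats::runif(config$n_lgs, config$lg_length_range[1],
                          config$lg_length_range[2])
  n_total <- config$n_lgs * config$markers_per_lg
  tibble::tibble(
    linkage_group = rep(paste0("LG", seq_len(config$n_lgs)),
                        each = config$markers_per_lg),
    marker = sprintf("mk%05d", seq_len(n_total)),
    position = unlist(purrr::map(lengths, ~ stats::runif(
      config$markers_per_lg, 0, .x))),
    marker_type = "DArT"
  ) |>
    dplyr::group_by(.data$linkage_group) |>
    dplyr::mutate(position = .data$position - min(.data$position)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$linkage_group, .data$position, .data$marker)
}

#' Sample one component map from a true map
#'
#' Each marker is retained independently with probability `retention`;
#' retained positions are scaled by a per-map length factor, perturbed
#' with Gaussian noise, optionally locally shuffled by adjacent swaps,
#' re-based to a zero minimum per group and re-sorted. This reproduces,
#' in map-distance space, the error structure of independently estimated
#' maps: local order uncertainty among tightly linked markers and
#' map-length differences between pedigrees.
#'
#' @param true_map Output of [generate_true_map()].
#' @param map_id Identifier for the sampled map.
#' @param retention Per-marker retention probability.
#' @param length_scale Map length scale factor.
#' @param noise_sd Gaussian position noise, cM.
#' @param swap_rate Adjacent-pair swap probability.
#' @param family_size Progeny count recorded on the map.
#' @return A `component_map` tibble. Linkage groups left with fewer than
#'   two retained markers are dropped with a warning.
#' @export
sample_component_map <- function(true_map, map_id, retention,
                                 length_scale = 1, noise_sd = 0,
                                 swap_rate = 0, family_size = NA_integer_) {
  keep <- stats::runif(nrow(true_map)) < retention
  smp <- true_map[keep, ]
  n_lg <- table(smp$linkage_group)
  thin <- names(n_lg)[n_lg < 2]
  if (length(thin) > 0) {
    warning("dropping linkage group(s) with < 2 retained markers: ",
            paste(thin, collapse = ", "), call. = FALSE)
    smp <- smp[!smp$linkage_group %in% thin, ]
  }
  if (nrow(smp) == 0) {
    return(component_map(as.data.frame(smp), map_id = map_id,
                         family_size = family_size))
  }
  smp <- smp |>
    dplyr::group_by(.data$linkage_group) |>
    dplyr::group_modify(function(lg, key) {
      pos <- lg$position * length_scale
      if (noise_sd > 0) pos <- pos + stats::rnorm(length(pos), 0, noise_sd)
      ord <- order(pos)
      pos <- pos[ord]
      lg <- lg[ord, ]
      if (swap_rate > 0 && nrow(lg) >= 2) {
        # swap marker identities of adjacent pairs, keeping positions
        for (i in which(stats::runif(nrow(lg) - 1) < swap_rate)) {
          lg[c(i, i + 1), ] <- lg[c(i + 1, i), ]
        }
      }
      lg$position <- pos - min(pos)
      lg
    }) |>
    dplyr::ungroup()
  component_map(as.data.frame(smp), map_id = map_id,
                family_size = family_size)
}

#' Duplicate a fraction of markers onto a second linkage group
#'
#' Emulates multicopy loci: each selected marker name is added at a
#' uniform-random position on a different linkage group of one randomly
#' chosen component map that does not already carry the name there.
#'
#' @param maps List of `component_map` tibbles.
#' @param fraction Fraction of distinct marker names to duplicate.
#' @return List: `maps` (updated) and `injected` (tibble `marker`,
#'   `map_id`, `linkage_group` of each injected copy).
#' @export
inject_multicopy <- function(maps, fraction) {
  all_markers <- unique(unlist(purrr::map(maps, "marker")))
  n_dup <- round(length(all_markers) * fraction)
  injected <- tibble::tibble(marker = character(), map_id = character(),
                             linkage_group = character(),
                             position = double())
  if (n_dup == 0) return(list(maps = maps, injected = injected))
  chosen <- sample(all_markers, n_dup)
  for (mk in chosen) {
    has_mk <- which(purrr::map_lgl(maps, ~ mk %in% .x$marker))
    m_i <- if (length(has_mk) > 0) sample(has_mk, 1) else sample(length(maps), 1)
    mp <- maps[[m_i]]
    home_lgs <- unique(mp$linkage_group[mp$marker == mk])
    target_lgs <- setdiff(unique(mp$linkage_group), home_lgs)
    if (length(target_lgs) == 0) next
    lg <- sample(target_lgs, 1)
    lg_pos <- mp$position[mp$linkage_group == lg]
    new_pos <- stats::runif(1, 0, max(lg_pos))
    new_row <- mp[1, ]
    new_row$linkage_group <- lg
    new_row$marker <- mk
    new_row$position <- new_pos
    new_row$marker_type <- "DArT"
    mp <- dplyr::bind_rows(mp, new_row) |>
      dplyr::arrange(.data$linkage_group, .data$position, .data$marker)
    attr(mp, "family_size") <- attr(maps[[m_i]], "family_size")
    class(mp) <- class(maps[[m_i]])
    maps[[m_i]] <- mp
    injected <- dplyr::bind_rows(injected, tibble::tibble(
      marker = mk, map_id = mp$map_id[1], linkage_group = lg,
      position = new_pos))
  }
  list(maps = maps, injected = injected)
}

#' Randomly permute the marker order of one linkage group
#'
#' Emulates a discordant (non-colinear) linkage group: marker identities
#' are reassigned to positions by a random permutation, destroying order
#' agreement with the true map while keeping the marker set and position
#' spectrum intact. Such groups should be caught by
#' [screen_colinearity()].
#'
#' @param map A `component_map`.
#' @param lg Linkage group to scramble.
#' @return The map with `lg` permuted.
#' @export
inject_discordant_lg <- function(map, lg) {
  stopifnot(lg %in% map$linkage_group)
  rows <- which(map$linkage_group == lg)
  map$marker[rows] <- map$marker[rows][sample(length(rows))]
  map
}

#' Generate a full synthetic map set with ground truth
#'
#' Runs the whole generator: true map, one component map per configured
#' pedigree, multicopy injection, redundant clone pairs, and optional
#' discordant-group injections. Everything is reproducible from the
#' config seed.
#'
#' @param config A [synth_config()].
#' @param discordant Optional tibble (`map_index`, `linkage_group`) of
#'   groups to scramble.
#' @return List: `true_map`, `maps` (list of `component_map`s, ids
#'   `"sim1"`...), `truth` (list: `injected_multicopy`,
#'   `redundant_pairs`, `discordant` bookkeeping).
#' @export
simulate_map_set <- function(config, discordant = NULL) {
  stopifnot(inherits(config, "synth_config"))
  true_map <- generate_true_map(config)  # seeds the RNG
  maps <- purrr::map(seq_len(config$n_maps), function(i) {
    sample_component_map(
      true_map, map_id = paste0("sim", i),
      retention = config$retention[i],
      length_scale = config$length_scale[i],
      noise_sd = config$noise_sd, swap_rate = config$swap_rate,
      family_size = config$family_size[i])
  })
  mc <- inject_multicopy(maps, config$multicopy_fraction)
  maps <- mc$maps
  redundant <- tibble::tibble(marker = character(), clone = character())
  if (config$redundant_pairs > 0) {
    # clone markers from the largest map: same positions, new name, so the
    # pair co-locates wherever the original occurs in that map
    big <- which.max(purrr::map_int(maps, nrow))
    mp <- maps[[big]]
    originals <- sample(unique(mp$marker), config$redundant_pairs)
    for (k in seq_along(originals)) {
      src <- mp[mp$marker == originals[k], ]
      src$marker <- sprintf("%s_clone", originals[k])
      mp <- dplyr::bind_rows(mp, src) |>
        dplyr::arrange(.data$linkage_group, .data$position, .data$marker)
      redundant <- dplyr::bind_rows(redundant, tibble::tibble(
        marker = originals[k], clone = sprintf("%s_clone", originals[k])))
    }
    attr(mp, "family_size") <- attr(maps[[big]], "family_size")
    class(mp) <- class(maps[[big]])
    maps[[big]] <- mp
  }
  disc_log <- NULL
  if (!is.null(discordant) && nrow(discordant) > 0) {
    for (r in seq_len(nrow(discordant))) {
      i <- discordant$map_index[r]
      maps[[i]] <- inject_discordant_lg(maps[[i]],
                                        discordant$linkage_group[r])
    }
    disc_log <- discordant
  }
  list(true_map = true_map, maps = maps,
       truth = list(injected_multicopy = mc$injected,
                    redundant_pairs = redundant, discordant = disc_log))
}

#' Score a composite map against the generator's true map
#'
#' Per linkage group, the Spearman correlation between composite marker
#' positions and true positions (shared markers), plus the maximum
#' absolute position error after the optimal rigid shift (meaningful for
#' noise-free runs, where recovery should be exact).
#'
#' @param composite A `composite_map` built from simulated maps.
#' @param true_map The generator's true map.
#' @return Tibble: `linkage_group`, `n_scored`, `rho`,
#'   `max_abs_error_cM`.
#' @export
score_recovery <- function(composite, true_map) {
  loci <- composite$loci
  purrr::map(unique(loci$linkage_group), function(lg) {
    comp <- loci[loci$linkage_group == lg & !loci$is_multicopy, ]
    tr <- true_map[true_map$linkage_group == lg, ]
    shared <- dplyr::inner_join(
      dplyr::select(comp, "marker", pos_comp = "position"),
      dplyr::select(tr, "marker", pos_true = "position"), by = "marker")
    rho <- spearman_rho(shared$pos_comp, shared$pos_true)
    # optimal rigid shift = mean offset; orientation assumed forward
    shift <- mean(shared$pos_comp - shared$pos_true)
    tibble::tibble(
      linkage_group = lg, n_scored = nrow(shared), rho = rho,
      max_abs_error_cM = max(abs(shared$pos_comp - shared$pos_true - shift)))
  }) |> dplyr::bind_rows()
}
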