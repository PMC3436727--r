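#' Read a component linkage map from a delimited text file
#'
#' Accepts tab- or comma-delimited files, with or without a header line,
#' with `#` comment lines, and either LF or CRLF line endings. Expected
#' columns (by header name, or by order when headerless):
#' `linkage_group`, `marker`, `position`, and optionally `marker_type`.
#'
#' @param path File to read.
#' @param map_id Map identifier; defaults to the file name without extension.
#' @param family_size Optional progeny count for the pedigree.
#' @inheritParams component_map
#' @return A `component_map` tibble (see [component_map()]); positions are
#'   preserved exactly as written (no re-basing on read).
#' @export
read_component_map <- function(path, map_id = NULL, family_size = NA_integer_,
                               default_type = "DArT") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(map_id)) {
    map_id <- sub("\\.[^.]*$", "", basename(path))
  }
  raw <- readLines(path, warn = FALSE)
  raw <- sub("\r$", "", raw)
  keep <- !grepl("^\\s*(#|$)", raw)
  lines <- raw[keep]
  if (length(lines) == 0) stop("empty map file: ", path, call. = FALSE)
  delim <- if (grepl("\t", lines[1])) "\t" else ","
  fields <- strsplit(lines, delim, fixed = TRUE)
  fields <- purrr::map(fields, trimws)
  header_names <- tolower(fields[[1]])
  has_header <- any(c("marker", "position", "linkage_group", "lg") %in%
                      header_names)
  col_names <- c("linkage_group", "marker", "position", "marker_type")
  if (has_header) {
    header_names[header_names == "lg"] <- "linkage_group"
    body <- fields[-1]
    line_no <- which(keep)[-1]
    idx <- match(col_names, header_names)
    if (anyNA(idx[1:3])) {
      stop("header must name linkage_group (or LG), marker and position",
           call. = FALSE)
    }
  } else {
    body <- fields
    line_no <- which(keep)
    idx <- c(1L, 2L, 3L, if (length(fields[[1]]) >= 4) 4L else NA_integer_)
  }
  if (length(body) == 0) stop("no data rows in: ", path, call. = FALSE)
  pick <- function(i) purrr::map_chr(body, ~ if (is.na(i) || length(.x) < i)
    NA_character_ else .x[[i]])
  df <- tibble::tibble(
    linkage_group = pick(idx[1]),
    marker = pick(idx[2]),
    position_raw = pick(idx[3]),
    marker_type = pick(idx[4])
  )
  pos <- suppressWarnings(as.double(df$position_raw))
  bad <- which(is.na(pos) | !is.finite(pos) | pos < 0)
  if (length(bad) > 0) {
    stop(sprintf("bad position '%s' at line %d of %s",
                 df$position_raw[bad[1]], line_no[bad[1]], path),
         call. = FALSE)
  }
  df$position <- pos
  df$position_raw <- NULL
  component_map(df, map_id = map_id, family_size = family_size,
                default_type = default_type)
}

#' Write a composite map to disk
#'
#' @param composite A `composite_map` object from [build_composite()], or a
#'   loci tibble in the same layout.
#' @param path Output file.
#' @param format `"tsv"` writes one row per composite position with full
#'   precision positions plus support count, multicopy flag and the merge
#'   round in which each marker was added; `"mapchart"` writes
#'   MapChart-style chart text (`group <LG>` blocks of marker/position
#'   pairs, positions to 1 decimal cM).
#' @return `path`, invisibly.
#' @export
write_composite_map <- function(composite, path, format = c("tsv", "mapchart")) {
  format <- match.arg(format)
  loci <- if (inherits(composite, "composite_map")) composite$loci else
    tibble::as_tibble(composite)
  loci <- dplyr::arrange(loci, .data$linkage_group, .data$position,
                         .data$marker)
  if (format == "tsv") {
    out <- loci |>
      dplyr::mutate(
        support = purrr::map_chr(.data$support, paste, collapse = ","),
        n_support = lengths(loci$support)
      ) |>
      dplyr::select("linkage_group", "marker", "position", "marker_type",
                    "n_support", "support", "is_multicopy", "added_in_round")
    readr::write_tsv(out, path)
  } else {
    con <- file(path, open = "wb")
    on.exit(close(con))
    lines <- character(0)
    for (lg in unique(loci$linkage_group)) {
      sub <- loci[loci$linkage_group == lg, ]
      lines <- c(lines,
                 paste("group", lg),
                 sprintf("%s\t%.1f", sub$marker, sub$position),
                 "")
    }
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

#' Read back a composite map written in TSV format
#'
#' Inverse of `write_composite_map(..., format = "tsv")`; the round trip
#' preserves every field at full precision.
#'
#' @param path A TSV written by [write_composite_map()].
#' @return A `composite_map` object (with an empty merge log).
#' @export
read_composite_map <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  loci <- df |>
    dplyr::mutate(
      linkage_group = as.character(.data$linkage_group),
      support = strsplit(as.character(.data$support), ",", fixed = TRUE),
      is_multicopy = as.logical(.data$is_multicopy),
      added_in_round = as.integer(.data$added_in_round)
    ) |>
    dplyr::select("linkage_group", "marker", "position", "marker_type",
                  "support", "added_in_round", "is_multicopy") |>
    dplyr::arrange(.data$linkage_group, .data$position, .data$marker)
  new_composite_map(loci, merge_log = empty_merge_log(),
                    trimmed = NULL, config = list())
}

#' Write the merge log of a composite build
#'
#' One row per merge round: which component linkage group was chosen for
#' which building group, its fit value, the fitted projection, and how many
#' markers were added or skipped. Deterministic ordering (build order).
#'
#' @param composite A `composite_map` object.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_merge_log <- function(composite, path) {
  log <- if (inherits(composite, "composite_map")) composite$merge_log else
    tibble::as_tibble(composite)
  readr::write_tsv(log, path)
  invisible(path)
}
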