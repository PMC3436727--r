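# Fixture builders shared across test files. All maps are constructed in
# code; nothing is read from disk except where file I/O itself is under
# test.

# A minimal map tibble from parallel vectors.
toy_map <- function(map_id, lg, marker, position, type = NULL,
                    family_size = NA_integer_) {
  df <- data.frame(linkage_group = lg, marker = marker, position = position)
  if (!is.null(type)) df$marker_type <- type
  component_map(df, map_id = map_id, family_size = family_size)
}

# One linkage group with evenly spaced markers m1..mN at 0, step, 2*step...
even_lg <- function(map_id, n, step = 10, lg = "LG1", prefix = "m") {
  toy_map(map_id, lg, paste0(prefix, seq_len(n)), (seq_len(n) - 1) * step)
}

# Two identical two-LG maps under different ids: the canonical
# "identity merge" fixture.
identical_pair <- function() {
  mk <- function(id) toy_map(
    id,
    rep(c("LG1", "LG2"), each = 5),
    c(paste0("a", 1:5), paste0("b", 1:5)),
    rep(c(0, 10, 25, 40, 60), 2))
  list(mk("M1"), mk("M2"))
}

# A composite-shaped loci tibble for QC tests (support as list-column).
make_loci <- function(lg, marker, position, type = "DArT", support = 1,
                      round = 0L, multicopy = FALSE) {
  n <- length(marker)
  tibble::tibble(
    linkage_group = rep_len(lg, n), marker = marker, position = position,
    marker_type = rep_len(type, n),
    support = purrr::map(rep_len(support, n),
                         ~ paste0("M", seq_len(.x))),
    added_in_round = rep_len(as.integer(round), n),
    is_multicopy = rep_len(multicopy, n))
}

# Independent Spearman oracle: mean ranks + explicit Pearson formula.
spearman_oracle <- function(a, b) {
  ra <- rank(a); rb <- rank(b)
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}
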