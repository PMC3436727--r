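test_that("spearman_rho matches the explicit rank-Pearson oracle", {
  expect_equal(spearman_rho(c(0, 5, 10), c(2, 4, 9)), 1)
  expect_equal(spearman_rho(c(0, 5, 10), c(9, 4, 2)), -1)

  # one adjacent swap among six anchors
  a <- c(0, 4, 9, 15, 22, 30)
  b <- c(1, 5, 12, 10, 24, 33)
  expect_equal(spearman_rho(a, b), spearman_oracle(a, b))

  # random vectors, with and without ties
  set.seed(9)
  for (i in 1:20) {
    n <- sample(3:40, 1)
    x <- runif(n, 0, 100)
    y <- x + rnorm(n, 0, 20)
    if (i %% 3 == 0) y[1:2] <- y[2:1] * 0 + 5  # inject ties
    expect_equal(spearman_rho(x, y), spearman_oracle(x, y),
                 tolerance = 1e-12)
  }
})

test_that("spearman_rho flags undefined cases", {
  expect_true(is.na(spearman_rho(1, 2)))
  expect_true(is.na(spearman_rho(numeric(0), numeric(0))))
  expect_true(is.na(spearman_rho(c(5, 5, 5), c(1, 2, 3))))
})

test_that("fit_value rewards anchors with diminishing returns", {
  expect_equal(fit_value(0.97, 1), 0)
  expect_equal(fit_value(1.0, 10), 1.0)  # base-10 default
  # many moderate anchors beat few excellent ones
  expect_equal(fit_value(0.80, 100), 1.600)
  expect_equal(fit_value(0.99, 5), 0.99 * log10(5))
  expect_gt(fit_value(0.80, 100), fit_value(0.99, 5))
  # reversed orientation scores by magnitude
  expect_equal(fit_value(-0.9, 10), 0.9)
  expect_true(is.na(fit_value(0.9, 0)))
})

test_that("candidate selection enforces eligibility thresholds", {
  building <- even_lg("B", 10)
  # n_common = 2 -> ineligible
  weak <- toy_map("W", "LG1", c("m1", "m2", "z1", "z2"), c(0, 10, 20, 30))
  expect_null(select_best_component(building, list(weak)))
  # |rho| = 0.45 < 0.50 -> ineligible (constructed low-correlation set)
  set.seed(2)
  repeat {
    perm <- sample(10)
    r <- spearman_rho(seq(0, 90, 10), perm * 7)
    if (abs(r) < 0.5) break
  }
  low <- toy_map("L", "LG1", paste0("m", 1:10), perm * 7)
  expect_null(select_best_component(building, list(low)))
})

test_that("selection picks the larger fit value and is base-invariant", {
  building <- even_lg("B", 200, step = 1)
  # A: 5 perfectly ordered anchors; B: 100 anchors with mild noise
  a_mk <- paste0("m", seq(1, 200, 40))
  cand_a <- toy_map("A", "LG1", a_mk, seq_along(a_mk) * 10)
  set.seed(4)
  b_mk <- paste0("m", 1:100)
  pos_b <- (1:100) + rnorm(100, 0, 8)
  cand_b <- toy_map("B", "LG1", b_mk, pos_b - min(pos_b))
  rho_b <- spearman_rho(1:100, cand_b$position[match(b_mk, cand_b$marker)])
  stopifnot(abs(rho_b) < 1, abs(rho_b) > 0.8)

  for (base in c(10, exp(1), 2)) {
    sel <- select_best_component(building, list(cand_a, cand_b),
                                 log_base = base)
    expect_equal(sel$component_map_id, "B")
    # hand-computed fit of the winner
    expect_equal(sel$fit, abs(rho_b) * log(100, base))
  }
})

test_that("fit ties break by anchor count, then input order", {
  building <- even_lg("B", 16)
  # both perfectly colinear; same fit only if same n -> vary n
  c1 <- toy_map("C1", "LG1", paste0("m", 1:8), seq(0, 70, 10))
  c2 <- toy_map("C2", "LG1", paste0("m", 1:10), seq(0, 90, 10))
  sel <- select_best_component(building, list(c1, c2))
  expect_equal(sel$component_map_id, "C2")  # rho 1 both, larger n wins
  sel2 <- select_best_component(building, list(c2, c2))
  expect_equal(sel2$candidate, 1L)  # exact tie -> first in input order
})

test_that("fit_projection reproduces the normal-equation oracle", {
  # identity
  p <- fit_projection(data.frame(pc = c(0, 50, 100), pi = c(0, 50, 100)))
  expect_equal(p$slope, 1)
  expect_equal(p$intercept, 0)
  expect_equal(p$residual_rmse, 0)
  # two-point line
  p2 <- fit_projection(data.frame(pc = c(10, 110), pi = c(0, 100)))
  expect_equal(p2$slope, 1)
  expect_equal(p2$intercept, 10)
  # closed-form OLS on the spec of anchors (pc, pi)
  anchors <- data.frame(pc = c(0, 10, 20), pi = c(0, 4, 12))
  p3 <- fit_projection(anchors)
  ols <- function(x, y) {
    m <- (sum(x * y) - length(x) * mean(x) * mean(y)) /
      (sum(x^2) - length(x) * mean(x)^2)
    c(m, mean(y) - m * mean(x))
  }
  expect_equal(c(p3$slope, p3$intercept), ols(anchors$pi, anchors$pc),
               tolerance = 1e-9)
  # random anchor sets
  set.seed(8)
  for (i in 1:15) {
    n <- sample(2:30, 1)
    pi_ <- runif(n, 0, 120)
    if (diff(range(pi_)) == 0) next
    pc <- 0.9 * pi_ + 3 + rnorm(n, 0, 2)
    pf <- fit_projection(data.frame(pc = pc, pi = pi_))
    expect_equal(c(pf$slope, pf$intercept), ols(pi_, pc), tolerance = 1e-9)
  }
  expect_error(fit_projection(data.frame(pc = c(0, 1), pi = c(5, 5))),
               "degenerate")
  expect_error(fit_projection(data.frame(pc = 1, pi = 1)), "at least 2")
})

test_that("project_unique_markers adds new markers and grows support", {
  building <- tibble::tibble(
    marker = c("m1", "m2"), position = c(0, 50),
    marker_type = "DArT", support = list("S", "S"), added_in_round = 0L)
  comp <- toy_map("C", "LG1", c("m1", "u1", "m2"), c(0, 25, 50))
  idproj <- fit_projection(data.frame(pc = c(0, 50), pi = c(0, 50)))
  res <- project_unique_markers(comp, building, idproj)
  expect_equal(res$n_added, 1L)
  expect_equal(res$n_skipped, 2L)
  expect_equal(res$building_lg$position[res$building_lg$marker == "u1"], 25)
  expect_setequal(res$building_lg$support[[1]], c("S", "C"))

  # scaling projection: m=2, c=0 puts pi=5 at 10
  sc <- fit_projection(data.frame(pc = c(0, 20), pi = c(0, 10)))
  res2 <- project_unique_markers(toy_map("C", "LG1", "u9", 5), building, sc)
  expect_equal(res2$building_lg$position[res2$building_lg$marker == "u9"], 10)
})

test_that("build_linkage_group with no eligible candidates returns the seed", {
  seed <- even_lg("S", 5)
  out <- build_linkage_group(seed, list())
  expect_equal(out$lg$marker, seed$marker)
  expect_equal(out$lg$position, seed$position)
  expect_equal(nrow(out$log), 0L)
})

test_that("a single extra marker is interpolated at its regression position", {
  seed <- toy_map("S", "LG1", c("m1", "m2", "m3", "m4"), c(0, 10, 20, 30))
  # component identical to seed but scaled x2, plus one marker at pi = 25
  comp <- toy_map("C", "LG1", c("m1", "m2", "extra", "m3", "m4"),
                  c(0, 20, 50, 40, 60))
  out <- build_linkage_group(seed, list(comp))
  # seed positions unchanged
  expect_equal(out$lg$position[match(paste0("m", 1:4), out$lg$marker)],
               c(0, 10, 20, 30))
  # regression is pc = 0.5 * pi, so "extra" lands at 25
  expect_equal(out$lg$position[out$lg$marker == "extra"], 25)
  expect_equal(out$log$markers_added, 1L)
  expect_equal(out$log$markers_skipped, 4L)
})

test_that("markers chain through intermediate maps across rounds", {
  # map B shares markers only with map A (not the seed); B merges in
  # round 2 via anchors projected in round 1
  seed <- toy_map("S", "LG1", c("s1", "s2", "s3", "s4"), c(0, 10, 20, 30))
  map_a <- toy_map("A", "LG1",
                   c("s1", "a1", "s2", "a2", "s3", "a3", "s4"),
                   c(0, 5, 10, 15, 20, 25, 30))
  map_b <- toy_map("B", "LG1", c("a1", "a2", "a3", "b1"),
                   c(5, 15, 25, 20))
  out <- build_linkage_group(seed, list(map_b, map_a))
  expect_equal(out$log$component_map_id, c("A", "B"))
  expect_equal(out$log$round, 1:2)
  expect_true("b1" %in% out$lg$marker)
  expect_equal(out$lg$position[out$lg$marker == "b1"], 20)
})

test_that("reversed component groups are flipped before projection", {
  seed <- toy_map("S", "LG1", c("m1", "m2", "m3", "m4"), c(0, 10, 20, 30))
  comp <- toy_map("C", "LG1", c("m4", "u1", "m3", "m2", "m1"),
                  c(0, 5, 10, 20, 30))
  out <- build_linkage_group(seed, list(comp))
  expect_equal(out$log$orientation, "reversed")
  # flipped pi: m1..m4 at 0,10,20,30; u1 at 30-5=25 -> identity projection
  expect_equal(out$lg$position[out$lg$marker == "u1"], 25)
  expect_equal(out$lg$position[match(paste0("m", 1:4), out$lg$marker)],
               c(0, 10, 20, 30))
})

test_that("monotone projection preserves component order", {
  set.seed(14)
  seed_pos <- sort(runif(12, 0, 100))
  seed <- toy_map("S", "LG1", paste0("s", 1:12), seed_pos)
  comp_pos <- 1.2 * seed_pos + 4
  extra <- runif(8, min(comp_pos), max(comp_pos))
  comp <- toy_map("C", "LG1", c(paste0("s", 1:12), paste0("u", 1:8)),
                  c(comp_pos, extra) - min(c(comp_pos, extra)))
  out <- build_linkage_group(seed, list(comp))
  ord_comp <- comp$marker[order(comp$position)]
  ord_built <- out$lg$marker[order(out$lg$position)]
  expect_equal(match(ord_comp, ord_built), sort(match(ord_comp, ord_built)))
})

test_that("trim_ends removes exactly poorly supported distal outliers", {
  lg <- make_loci("LG1", c("t1", "m1", "m2", "m3", "t2"),
                  c(0, 6, 10, 14, 20.5),
                  support = c(1, 2, 3, 2, 1))
  tr <- trim_ends(lg, gap_threshold = 5, min_support = 2)
  expect_setequal(tr$removed$marker, c("t1", "t2"))
  expect_equal(min(tr$lg$position), 0)
  expect_equal(tr$lg$marker, c("m1", "m2", "m3"))

  # well-supported terminal marker survives a big gap
  lg2 <- make_loci("LG1", c("t1", "m1", "m2"), c(0, 6, 10),
                   support = c(3, 2, 2))
  tr2 <- trim_ends(lg2)
  expect_equal(nrow(tr2$removed), 0L)
  # sub-threshold gap survives poor support
  lg3 <- make_loci("LG1", c("t1", "m1", "m2"), c(0, 4.9, 10),
                   support = c(1, 2, 2))
  expect_equal(nrow(trim_ends(lg3)$removed), 0L)
})

test_that("trimming cascades and is idempotent", {
  # after removing the outermost marker, the next becomes terminal and
  # is itself 5+ cM out with single-map support
  lg <- make_loci("LG1", c("t1", "t2", "m1", "m2"), c(0, 6, 12, 14),
                  support = c(1, 1, 2, 2))
  tr <- trim_ends(lg)
  expect_equal(tr$lg$marker, c("m1", "m2"))
  twice <- trim_ends(tr$lg)
  expect_equal(twice$lg, tr$lg)
  expect_equal(nrow(twice$removed), 0L)
})

test_that("merging two identical maps returns the seed unchanged", {
  maps <- bind_maps(identical_pair())
  cm <- build_composite(maps, seed_map_id = "M1")
  seed <- maps[maps$map_id == "M1", ]
  expect_equal(nrow(cm$loci), nrow(seed))
  expect_equal(cm$loci$position,
               seed$position[match(paste(cm$loci$linkage_group,
                                         cm$loci$marker),
                                   paste(seed$linkage_group, seed$marker))])
  expect_equal(nrow(cm$merge_log), 2L)  # one round per LG
  expect_equal(sum(cm$merge_log$markers_added), 0L)
  # every shared marker supported by both maps
  expect_true(all(lengths(cm$loci$support) == 2))
})

test_that("backbone immutability: seed positions survive the merge", {
  cfg <- synth_config(seed = 5, n_lgs = 4, markers_per_lg = 80, n_maps = 4,
                      retention = c(0.8, 0.5, 0.4, 0.3), noise_sd = 1,
                      multicopy_fraction = 0.02, redundant_pairs = 1)
  s <- simulate_map_set(cfg)
  maps <- bind_maps(s$maps)
  cm <- build_composite(maps, seed_map_id = "sim1", trim = FALSE)
  seed <- maps[maps$map_id == "sim1", ]
  joined <- dplyr::inner_join(
    cm$loci[cm$loci$added_in_round == 0L, ],
    seed, by = c("linkage_group", "marker"),
    suffix = c("_comp", "_seed"))
  # rigid per-LG shift only
  shifts <- tapply(joined$position_comp - joined$position_seed,
                   joined$linkage_group, function(d) diff(range(d)))
  expect_true(all(shifts < 1e-9))
})

test_that("build_composite rejects a single map and unknown seeds", {
  one <- bind_maps(list(even_lg("A", 5)))
  expect_error(build_composite(one), "at least two")
  maps <- bind_maps(identical_pair())
  expect_error(build_composite(maps, seed_map_id = "nope"))
})

test_that("noise-free subsampled components are recovered exactly", {
  cfg <- synth_config(seed = 31, n_lgs = 5, markers_per_lg = 120,
                      n_maps = 4, retention = c(0.7, 0.45, 0.35, 0.3),
                      length_scale = 1, noise_sd = 0, swap_rate = 0,
                      multicopy_fraction = 0, redundant_pairs = 0)
  s <- simulate_map_set(cfg)
  maps <- bind_maps(s$maps)
  cm <- build_composite(maps, trim = FALSE)
  # composite contains the union of component markers
  expect_setequal(cm$loci$marker, unique(maps$marker))
  sc <- score_recovery(cm, s$true_map)
  expect_equal(sc$rho, rep(1, nrow(sc)), tolerance = 1e-12)
  expect_true(all(sc$max_abs_error_cM <= 1e-6))
})
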