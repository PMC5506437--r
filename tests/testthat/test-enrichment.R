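test_that("enrichment matches the closed form and the pmf-summation oracle", {
  universe <- sprintf("g%03d", 1:100)
  gene_set <- list(ten = universe[1:10])
  selected <- c(universe[1:5], universe[51:65])  # 20 selected, overlap 5
  out <- hypergeom_enrich(selected, gene_set, universe)
  expect_equal(out$genes_in_overlap, 5L)
  expect_equal(out$expected, 20 * 10 / 100)     # 2.0
  expect_equal(out$ratio_of_enrichment, 2.5)
  expect_equal(out$p, oracle_hyper_tail(5, 10, 100, 20), tolerance = 1e-12)
})

test_that("degenerate selections behave as the tail demands", {
  universe <- sprintf("g%03d", 1:100)
  sets <- list(a = universe[1:10], b = universe[11:40])
  # selected = universe: every ratio 1, p = 1
  full <- hypergeom_enrich(universe, sets, universe)
  expect_equal(full$ratio_of_enrichment, c(1, 1))
  expect_equal(full$p, c(1, 1))
  # zero overlap: ratio 0, p ~ 1
  none <- hypergeom_enrich(universe[41:60], list(a = universe[1:10]), universe)
  expect_equal(none$ratio_of_enrichment, 0)
  expect_equal(none$p, 1, tolerance = 1e-12)
})

test_that("input hygiene: duplicates, out-of-universe genes, empty sets", {
  universe <- sprintf("g%03d", 1:50)
  expect_warning(
    out <- hypergeom_enrich(c(universe[1:5], "alien"),
                            list(s = universe[1:10]), universe),
    "outside")
  expect_equal(out$genes_in_overlap, 5L)
  # duplicated genes are deduplicated before counting
  dup <- hypergeom_enrich(rep(universe[1:5], 3),
                          list(s = rep(universe[1:10], 2)), universe)
  expect_equal(dup$genes_in_overlap, 5L)
  expect_equal(dup$set_size, 10L)
  # a set fully outside the universe is skipped with a warning
  expect_warning(
    skipped <- hypergeom_enrich(universe[1:5],
                                list(out = c("x1", "x2"), s = universe[1:10]),
                                universe),
    "no universe members")
  expect_equal(skipped$set_name, "s")
  expect_error(hypergeom_enrich(universe[1], list(s = universe[1:2]),
                                character(0)), "universe")
})

test_that("custom pathway lists use the identical machinery", {
  set.seed(71)
  universe <- sprintf("g%04d", 1:1000)
  selected <- sample(universe, 100)
  aging <- c(sample(selected, 30), sample(setdiff(universe, selected), 20))
  other <- sample(universe, 50)
  out <- enrich_custom_pathways(selected, list(aging_like = aging,
                                               background = other), universe)
  expect_equal(out$set_name[1], "aging_like")  # planted list ranks first by p
  expect_lt(out$p[1], 1e-6)
  same <- hypergeom_enrich(selected, list(aging_like = aging,
                                          background = other), universe)
  expect_equal(out, same)
})

test_that("q-values across sets are BH and results sort by p", {
  set.seed(72)
  universe <- sprintf("g%04d", 1:500)
  sets <- lapply(1:8, function(i) sample(universe, 40))
  names(sets) <- sprintf("s%d", 1:8)
  sets$planted <- c(sample(universe[1:60], 30), sample(universe, 10))
  out <- hypergeom_enrich(universe[1:60], sets, universe)
  expect_false(is.unsorted(out$p))
  expect_equal(out$q, brute_force_bh(out$p)[order(order(out$p))])
  expect_equal(out$set_name[1], "planted")
})
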