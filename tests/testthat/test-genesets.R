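test_that("read_gmt parses, dedups and rejects malformed lines", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc A\tg1\tg2\tg3",
               "setB\tdesc B\tg2\tg2\tg4"), f)
  coll <- read_gmt(f)
  expect_length(coll$sets, 2L)
  expect_equal(coll$sets$setB, c("g2", "g4"))     # duplicate stored once
  writeLines(c("setA\tdesc A\tg1", "setB\tonly desc"), f)
  expect_error(read_gmt(f), "line 2")
  # GMT round-trip
  f2 <- withr::local_tempfile(fileext = ".gmt")
  coll2 <- gene_set_collection(list(s1 = c("a", "b"), s2 = "c"),
                               source = "toy")
  write_gmt(coll2, f2)
  back <- read_gmt(f2)
  expect_equal(back$sets, coll2$sets)
  expect_error(gene_set_collection(list(s1 = character(0))), "empty")
})

test_that("filter_min_size restricts to the universe before filtering", {
  universe <- sprintf("g%02d", 1:50)
  coll <- gene_set_collection(list(
    nine = sprintf("g%02d", 1:9),          # 9 in-universe -> dropped
    ten = sprintf("g%02d", 1:10),          # exactly 10 -> kept
    big_out = c(sprintf("g%02d", 1:8), sprintf("x%d", 1:7))  # 15 raw, 8 in
  ), source = "toy")
  filt <- filter_min_size(coll, 10, universe)
  expect_equal(names(filt$sets), "ten")
  # raw counting mode keeps the 15-gene set
  filt_raw <- filter_min_size(coll, 10, universe, count = "raw")
  expect_setequal(names(filt_raw$sets), c("ten", "big_out"))
  expect_equal(filt_raw$sets$big_out, sprintf("g%02d", 1:8))  # restricted
})

test_that("eval_set_mannwhitney: separation, medians, skip behaviour", {
  vals <- setNames(c(10, 11, 12, 1, 2, 3, 4, 5), sprintf("g%d", 1:8))
  r <- eval_set_mannwhitney(c("g1", "g2", "g3"), vals)
  expect_equal(r$statistic, 15)          # n1 * n2, complete separation
  expect_gt(r$effect, 0)
  expect_lt(r$p, 0.05)
  # median arithmetic: in-set {5,5}, rest {1,9} -> effect 0
  v2 <- setNames(c(5, 5, 1, 9), c("a", "b", "c", "d"))
  r2 <- eval_set_mannwhitney(c("a", "b"), v2)
  expect_equal(r2$effect, 0)
  expect_warning(r0 <- eval_set_mannwhitney("g1", vals), "skipped")
  expect_null(r0)
})

test_that("Mann-Whitney set p-values are uniform under a null draw", {
  set.seed(47)
  vals <- setNames(rnorm(300), sprintf("g%03d", 1:300))
  ps <- replicate(500, {
    eval_set_mannwhitney(sample(names(vals), 20), vals)$p
  })
  expect_lt(ks_distance_uniform(ps), 0.08)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})

test_that("eval_set_fisher: proportional, degenerate and zero-attr tables", {
  universe <- sprintf("g%03d", 1:110)
  labels <- setNames(rep(FALSE, 110), universe)
  # table [[5,5],[50,50]] -> OR 1, p 1
  labels[c(1:5, 11:60)] <- TRUE          # 5 in-set attr, 50 out attr
  r <- eval_set_fisher(universe[1:10], labels)
  expect_equal(unname(r$table), matrix(c(5, 5, 50, 50), 2, byrow = TRUE))
  expect_equal(r$p, 1)
  expect_equal(r$odds_ratio, 1, tolerance = 1e-6)
  # zero duplicated genes in the set -> OR 0
  labels2 <- setNames(c(rep(FALSE, 10), rep(TRUE, 30), rep(FALSE, 70)),
                      universe)
  r2 <- eval_set_fisher(universe[1:10], labels2)
  expect_equal(r2$odds_ratio, 0)
  # degenerate margin: nobody has the attribute
  r3 <- eval_set_fisher(universe[1:10],
                        setNames(rep(FALSE, 110), universe))
  expect_true(r3$degenerate)
  expect_equal(r3$p, 1)
})

test_that("Fisher p equals the hypergeometric enumeration oracle (margins <= 10)", {
  # spot-check here; the exhaustive sweep is in test-acceptance.R
  for (tab in list(matrix(c(8, 2, 2, 8), 2, byrow = TRUE),
                   matrix(c(1, 9, 5, 5), 2, byrow = TRUE),
                   matrix(c(0, 7, 3, 4), 2, byrow = TRUE))) {
    expect_equal(stats::fisher.test(tab)$p.value, oracle_fisher_p(tab),
                 tolerance = 1e-12)
  }
})

test_that("evaluate_collection: determinism, BH families, single-set identity", {
  set.seed(53)
  w <- generate_world(generator_config(
    n_genes = 300, n_modules = 8, module_size = 25, n_datasets = 8,
    conditions_per_dataset = 10, seed = 61))
  ma <- build_coexpression_map(w$datasets_a, "A")
  mb <- build_coexpression_map(w$datasets_b, "B")
  ccg <- ccg_all_pairs(ma, mb, w$homology, percent = 10)
  na <- build_directed_network(ma, 2); nb <- build_directed_network(mb, 2)
  dk <- diffk_table(na, nb, w$homology)
  coll <- filter_min_size(w$sets, 10, w$homology$universe_a)
  rep1 <- evaluate_collection(coll, ccg, dk, w$homology)
  rep2 <- evaluate_collection(coll, ccg, dk, w$homology)
  expect_identical(rep1, rep2)                      # no hidden randomness
  expect_true(all(rep1$fdr >= rep1$p))              # BH bounded below by p
  expect_true(all(c("ccg_conservation", "differential_connectivity",
                    "duplication_ratio", "nonhomolog_ratio") %in%
                    rep1$parameter))
  expect_true(all(c("all", "one2one") %in%
                    rep1$homology_mode[rep1$parameter == "ccg_conservation"]))
  # BH is monotone within each family
  fam <- paste(rep1$parameter, rep1$homology_mode)
  for (f in unique(fam)) {
    sub <- rep1[fam == f, ]
    o <- order(sub$p)
    expect_true(all(diff(sub$fdr[o]) >= -1e-12))
  }
  # single-set collection: fdr == p
  single <- gene_set_collection(list(only = coll$sets[[1]]), source = "x")
  rs <- evaluate_collection(single, ccg, dk, w$homology)
  expect_equal(rs$fdr, rs$p)
})

test_that("planted conserved set is recovered with positive effect", {
  w <- generate_world(recovery_config(71))
  ma <- build_coexpression_map(w$datasets_a, "A")
  mb <- build_coexpression_map(w$datasets_b, "B")
  ccg <- ccg_all_pairs(ma, mb, w$homology)
  na <- build_directed_network(ma, 1); nb <- build_directed_network(mb, 1)
  dk <- diffk_table(na, nb, w$homology)
  coll <- filter_min_size(w$sets, 10, w$homology$universe_a)
  rep1 <- evaluate_collection(coll, ccg, dk, w$homology)
  r <- rep1[rep1$parameter == "ccg_conservation" &
              rep1$homology_mode == "all", ]
  cons <- r[r$set == "planted_conserved", ]
  expect_gt(cons$effect, 0)
  expect_true(cons$significant)
  div <- r[r$set == "planted_diverged", ]
  expect_lt(div$effect, 0)
  expect_true(div$significant)
})
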