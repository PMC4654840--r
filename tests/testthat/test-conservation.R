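one2one_table <- function(genes_a, genes_b) {
  homology_table(data.frame(gene_a = genes_a, gene_b = genes_b,
                            dn = 0.1, ds = 1, stringsAsFactors = FALSE),
                 universe_a = genes_a, universe_b = genes_b)
}

test_that("ccg_count implements the homolog-overlap rule", {
  # identity-homology universe of 10 genes per species
  ga <- sprintf("a%02d", 1:10); gb <- sprintf("b%02d", 1:10)
  tab <- one2one_table(ga, gb)
  mk_top <- function(gene, partners, percent = 30) {
    structure(list(gene = gene, percent = percent, partners = partners),
              class = "top_list")
  }
  # top_a = {a2,a3,a4}; homologs of a3,a4 in top_b -> 2
  ta <- mk_top("a01", c("a02", "a03", "a04"))
  tb <- mk_top("b01", c("b03", "b04", "b05"))
  expect_equal(ccg_count("a01", "b01", ta, tb, tab), 2L)
  expect_equal(ccg_count("a01", "b01", ta, tb, tab, return_genes = TRUE),
               c("a03", "a04"))
  # disjoint mapped lists -> 0
  tb0 <- mk_top("b01", c("b07", "b08", "b09"))
  expect_equal(ccg_count("a01", "b01", ta, tb0, tab), 0L)
  # species vs itself with identity homology -> full list length
  taa <- one2one_table(ga, ga)
  ta2 <- mk_top("a01", c("a02", "a03", "a04"))
  expect_equal(ccg_count("a01", "a01", ta2, ta2, taa), 3L)
})

test_that("ccg_count errors on unknown pair and mismatched percents", {
  ga <- sprintf("a%02d", 1:5); gb <- sprintf("b%02d", 1:5)
  tab <- one2one_table(ga, gb)
  mk_top <- function(gene, partners, percent) {
    structure(list(gene = gene, percent = percent, partners = partners),
              class = "top_list")
  }
  ta <- mk_top("a01", "a02", 5); tb <- mk_top("b01", "b02", 5)
  expect_error(ccg_count("a01", "b09", ta, tb, tab), "not in the homology")
  tb10 <- mk_top("b01", "b02", 10)
  expect_error(ccg_count("a01", "b01", ta, tb10, tab), "percent")
})

test_that("multi-homolog top-list members contribute once", {
  ga <- sprintf("a%02d", 1:10); gb <- sprintf("b%02d", 1:10)
  pairs <- data.frame(gene_a = c("a01", "a05", "a05", "a06"),
                      gene_b = c("b01", "b05", "b06", "b07"),
                      dn = 0.1, ds = 1, stringsAsFactors = FALSE)
  tab <- homology_table(pairs, universe_a = ga, universe_b = gb)
  mk_top <- function(gene, partners) {
    structure(list(gene = gene, percent = 30, partners = partners),
              class = "top_list")
  }
  # a05 has homologs b05 and b06, both in top_b: counts once
  ta <- mk_top("a01", c("a05", "a06", "a09"))
  tb <- mk_top("b01", c("b05", "b06", "b08"))
  expect_equal(ccg_count("a01", "b01", ta, tb, tab), 1L)
})

test_that("ccg_all_pairs matches the brute-force oracle on toy worlds", {
  set.seed(17)
  for (i in 1:10) {
    w <- generate_random_toy_world(n_a = 20, n_b = 22, seed = 1000 + i)
    ccg <- ccg_all_pairs(w$map_a, w$map_b, w$table, percent = 20)
    for (k in sample(nrow(ccg$pairs), min(8, nrow(ccg$pairs)))) {
      expect_equal(ccg$pairs$ccg_count[k],
                   oracle_ccg(ccg$pairs$gene_a[k], ccg$pairs$gene_b[k],
                              w$map_a, w$map_b, w$table, 20))
    }
  }
})

test_that("CCG invariants: symmetry for one2one homology, bounds,
           gene-level aggregation", {
  set.seed(23)
  m <- 30
  map_a <- random_map(m, "A", "a")
  map_b <- random_map(m, "B", "b")
  tab <- one2one_table(map_a$genes, map_b$genes)
  ccg <- ccg_all_pairs(map_a, map_b, tab, percent = 20)
  # swap species: transpose the homology table
  tab_t <- homology_table(
    data.frame(gene_a = tab$pairs$gene_b, gene_b = tab$pairs$gene_a,
               dn = 0.1, ds = 1, stringsAsFactors = FALSE),
    universe_a = map_b$genes, universe_b = map_a$genes)
  ccg_sw <- ccg_all_pairs(map_b, map_a, tab_t, percent = 20)
  key <- paste(ccg$pairs$gene_a, ccg$pairs$gene_b)
  key_sw <- paste(ccg_sw$pairs$gene_b, ccg_sw$pairs$gene_a)
  expect_equal(ccg$pairs$ccg_count, ccg_sw$pairs$ccg_count[match(key, key_sw)])
  # bound: never exceeds list length
  expect_true(all(ccg$pairs$ccg_count <= ccg$top_length_a))
  # gene-level: single-pair genes equal their pair value (all one2one here)
  expect_equal(unname(ccg$gene_level_a[ccg$pairs$gene_a]),
               as.numeric(ccg$pairs$ccg_count))
})

test_that("gene-level aggregation rule: max default, mean optional", {
  ga <- c("a1", "a1", "a2"); gb <- c("b1", "b2", "b3")
  ua <- c("a1", "a2"); ub <- c("b1", "b2", "b3")
  tab <- homology_table(data.frame(gene_a = ga, gene_b = gb, dn = 0.1,
                                   ds = 1, stringsAsFactors = FALSE),
                        universe_a = ua, universe_b = ub)
  # craft maps where the two pairs of a1 score 3 and 7 overlaps is hard by
  # hand; instead check the aggregation arithmetic directly
  pairs <- data.frame(gene_a = c("a1", "a1", "a2"), ccg_count = c(3L, 7L, 5L),
                      stringsAsFactors = FALSE)
  expect_equal(unname(coexcons:::aggregate_gene_level(pairs, "gene_a", "max")),
               c(7, 5))
  expect_equal(unname(coexcons:::aggregate_gene_level(pairs, "gene_a", "mean")),
               c(5, 5))
})

test_that("random-overlap CCG matches the hypergeometric expectation", {
  # shuffled labels: expected CCG per pair ~ L_a * (L_b / N_b) * hom share;
  # with full one2one homology that is L^2 / N
  set.seed(29)
  N <- 80
  reps <- 40
  counts <- numeric(0)
  for (i in seq_len(reps)) {
    map_a <- random_map(N, "A", "a")
    map_b <- random_map(N, "B", "b")
    tab <- one2one_table(map_a$genes, map_b$genes)
    ccg <- ccg_all_pairs(map_a, map_b, tab, percent = 10)
    counts <- c(counts, ccg$pairs$ccg_count)
  }
  L <- top_list_length(N, 10)
  expected <- L * L / N            # 0.8 per pair
  expect_equal(mean(counts), expected, tolerance = 0.15)
})

test_that("spearman_permutation: exact cases and p-value floor", {
  x <- as.numeric(1:20)   # large enough that no permutation ties |rho| = 1
  r1 <- spearman_permutation(x, x, B = 200, seed = 1)
  expect_equal(r1$rho, 1)
  expect_equal(r1$p_empirical, 1 / 201)
  expect_equal(r1$bound, "<0.005")
  r2 <- spearman_permutation(c(1, 2, 3), c(3, 2, 1), B = 50, seed = 1)
  expect_equal(r2$rho, -1)
  expect_error(spearman_permutation(x, rep(1, 20)), "constant")
  expect_error(spearman_permutation(x, c(NA, x[-1])), "finite")
  # reproducibility under a fixed seed
  set.seed(8); a <- rnorm(30); b <- rnorm(30)
  expect_identical(spearman_permutation(a, b, B = 100, seed = 4)$p_empirical,
                   spearman_permutation(a, b, B = 100, seed = 4)$p_empirical)
})

test_that("rank_select_extremes: floor sizing and tie rules", {
  v <- setNames(rnorm(100), sprintf("g%03d", 1:100))
  ex <- rank_select_extremes(v, 5)
  expect_length(ex$top, 5); expect_length(ex$bottom, 5)
  expect_equal(ex$top, names(sort(v, decreasing = TRUE))[1:5])
  # n = 41 -> floor gives 2 + 2
  v41 <- setNames(rnorm(41), sprintf("g%02d", 1:41))
  ex41 <- rank_select_extremes(v41, 5)
  expect_length(ex41$top, 2); expect_length(ex41$bottom, 2)
  # all-equal values: lexicographically first / last
  ve <- setNames(rep(1, 100), sprintf("g%03d", 1:100))
  exe <- rank_select_extremes(ve, 5)
  expect_equal(exe$top, sprintf("g%03d", 1:5))
  expect_equal(exe$bottom, sprintf("g%03d", 100:96))
  expect_error(rank_select_extremes(setNames(rnorm(10), letters[1:10]), 5))
})

test_that("distribution_summary: skewness and normality diagnostics", {
  expect_equal(distribution_summary(c(-2, -1, 0, 1, 2, -2, -1, 0, 1, 2))$skewness, 0)
  cst <- distribution_summary(rep(3, 10))
  expect_equal(cst$skewness, 0)
  expect_false(cst$normality_defined)
  set.seed(41)
  ex <- distribution_summary(rexp(5000))
  expect_equal(ex$skewness, 2, tolerance = 0.2)
  # normal data: p > 0.01 in >= 95 % of seeds
  ok <- vapply(1:60, function(s) {
    set.seed(s)
    distribution_summary(rnorm(1000))$shapiro_p > 0.01
  }, logical(1))
  expect_gte(mean(ok), 0.95)
  # n > 5000 takes the flagged systematic subsample branch
  set.seed(2)
  big <- distribution_summary(rnorm(12000))
  expect_true(big$subsampled)
  expect_true(is.finite(big$shapiro_p))
})
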