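# Independent oracles used by the unit and acceptance tests.  These are
# deliberately naive re-derivations from first principles; they never call
# into the code paths they check.

# Bipartite component classification by brute-force set expansion.
oracle_classify <- function(pairs) {
  n <- nrow(pairs)
  labels <- character(n)
  for (i in seq_len(n)) {
    # grow the connected component of pair i
    a_set <- pairs$gene_a[i]
    b_set <- pairs$gene_b[i]
    repeat {
      in_comp <- pairs$gene_a %in% a_set | pairs$gene_b %in% b_set
      na <- unique(pairs$gene_a[in_comp])
      nb <- unique(pairs$gene_b[in_comp])
      if (length(na) == length(a_set) && length(nb) == length(b_set)) break
      a_set <- na
      b_set <- nb
    }
    in_comp <- pairs$gene_a %in% a_set | pairs$gene_b %in% b_set
    mult_a <- any(table(pairs$gene_a[in_comp]) > 1)
    mult_b <- any(table(pairs$gene_b[in_comp]) > 1)
    labels[i] <- if (mult_a && mult_b) "many2many"
                 else if (mult_a || mult_b) "one2many" else "one2one"
  }
  labels
}

# Top-percent partner list by explicit sort on (-score, gene ID).
oracle_top_list <- function(map, gene, percent) {
  s <- map$values[, gene]
  s <- s[names(s) != gene]
  df <- data.frame(g = names(s), s = unname(s), stringsAsFactors = FALSE)
  df <- df[order(-df$s, df$g), ]
  df$g[seq_len(floor(percent / 100 * length(map$genes)))]
}

# CCG by literal set logic: members of a's top list with >= 1 homolog
# inside b's top list.
oracle_ccg <- function(gene_a, gene_b, map_a, map_b, table, percent) {
  ta <- oracle_top_list(map_a, gene_a, percent)
  tb <- oracle_top_list(map_b, gene_b, percent)
  sum(vapply(ta, function(g) {
    partners <- table$pairs$gene_b[table$pairs$gene_a == g]
    length(partners) > 0 && any(partners %in% tb)
  }, logical(1)))
}

# Directed adjacency by recomputation from per-gene sorted score lists.
oracle_adjacency <- function(map, percent) {
  m <- length(map$genes)
  A <- matrix(0L, m, m, dimnames = list(map$genes, map$genes))
  for (g in map$genes) A[oracle_top_list(map, g, percent), g] <- 1L
  A
}

# Two-sided Fisher p by hypergeometric enumeration over all tables with the
# observed margins (sum of table probabilities <= observed, with the
# standard relative tolerance).
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(support, r1, r2, c1)
  p_obs <- dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Mann-Whitney U statistic from midranks (first sample vs second).
oracle_u_stat <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

# Kolmogorov-Smirnov distance of a sample against the Uniform(0, 1) cdf.
ks_distance_uniform <- function(p) {
  p <- sort(p)
  n <- length(p)
  max(abs(c(seq_len(n) / n - p, p - (seq_len(n) - 1) / n)))
}

# Small convenience: build a coexpression map from an explicit symmetric
# matrix with gene names.
make_map <- function(values, genes = NULL, species = "S") {
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(values)))
  coexpression_map(species, genes, values)
}

# Random symmetric score matrix in [0, 1].
random_map <- function(m, species = "S", prefix = "g") {
  v <- matrix(0, m, m)
  v[upper.tri(v)] <- runif(m * (m - 1) / 2)
  v <- v + t(v)
  make_map(v, genes = sprintf("%s%03d", prefix, seq_len(m)),
           species = species)
}

# The scaled-down planted-set world used by the recovery tests (see the
# methods vignette for the rationale: module genes dominate the universe so
# "diverged" differs from background).
recovery_config <- function(seed) {
  generator_config(n_genes = 600L, n_modules = 20L, module_size = 25L,
                   n_datasets = 20L, conditions_per_dataset = 10L,
                   noise_sigma = 1, seed = seed)
}
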