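# Map species-A gene index -> integer vector of species-B partner indices,
# restricted to genes present in both maps.  Used by the CCG counting core.
homolog_index_map <- function(table, genes_a, genes_b) {
  p <- table$pairs
  ia <- match(p$gene_a, genes_a)
  ib <- match(p$gene_b, genes_b)
  ok <- !is.na(ia) & !is.na(ib)
  out <- vector("list", length(genes_a))
  if (any(ok)) {
    sp <- split(ib[ok], ia[ok])
    out[as.integer(names(sp))] <- sp
  }
  out
}

# Core of the CCG statistic: the species-A genes of top list `top_a_idx`
# (indices into genes_a) that have at least one homolog inside the species-B
# membership vector `memb_b`.  A top-list gene with several matched homologs
# contributes once.
ccg_overlap_core <- function(top_a_idx, memb_b, hmap) {
  qual <- logical(length(top_a_idx))
  for (i in seq_along(top_a_idx)) {
    hb <- hmap[[top_a_idx[i]]]
    qual[i] <- length(hb) > 0L && any(memb_b[hb])
  }
  top_a_idx[qual]
}

#' Commonly co-expressed genes (CCG) of one homolog pair
#'
#' For a homolog pair (a, b), CCG counts the species-A genes in a's top list
#' that have at least one homolog (any relationship class) inside b's top
#' list.  Non-homologous list members can never contribute, and a list
#' member with several matched homologs contributes once.
#'
#' @param gene_a,gene_b the homolog pair (must occur in `table`).
#' @param top_a,top_b [top_percent_list()] results for `gene_a` in species A
#'   and `gene_b` in species B, computed at the same percent.
#' @param table a [homology_table()].
#' @param return_genes return the overlapping species-A genes instead of the
#'   count.
#' @return integer CCG count (or character vector of overlap genes).
#' @export
ccg_count <- function(gene_a, gene_b, top_a, top_b, table,
                      return_genes = FALSE) {
  stopifnot(inherits(top_a, "top_list"), inherits(top_b, "top_list"),
            inherits(table, "homology_table"))
  if (top_a$percent != top_b$percent)
    stop("top lists were computed at different percent thresholds")
  p <- table$pairs
  if (!any(p$gene_a == gene_a & p$gene_b == gene_b))
    stop("pair (", gene_a, ", ", gene_b, ") is not in the homology table")
  genes_a <- sort(unique(c(table$universe_a, top_a$partners)), method = "radix")
  genes_b <- sort(unique(c(table$universe_b, top_b$partners)), method = "radix")
  hmap <- homolog_index_map(table, genes_a, genes_b)
  memb_b <- logical(length(genes_b))
  memb_b[match(top_b$partners, genes_b)] <- TRUE
  top_a_idx <- match(top_a$partners, genes_a)
  ov <- ccg_overlap_core(top_a_idx, memb_b, hmap)
  if (return_genes) genes_a[ov] else length(ov)
}

#' CCG for all homolog pairs of two co-expression maps
#'
#' Computes the top-`percent` lists of every gene in both maps, then one CCG
#' count per homolog pair whose two genes are present in their species' map.
#' Gene-level CCG aggregates a gene's pair counts (default: max, i.e. a gene
#' is ranked by its best-conserved relationship; `"mean"` is available).
#' The actual overlapping genes per pair are retained for the downstream
#' candidate-association analysis.
#'
#' @param map_a,map_b [coexpression_map()] objects for species A and B.
#' @param table a [homology_table()].
#' @param percent top-list percentage threshold (default 5).
#' @param aggregate gene-level aggregation rule, `"max"` or `"mean"`.
#' @return object of class `ccg_table`: list with `pairs` (data.frame
#'   `pair_id`, `gene_a`, `gene_b`, `relationship`, `dnds`, `ccg_count`),
#'   `overlaps` (list of per-pair overlap gene vectors, names = pair_id),
#'   `gene_level_a`, `gene_level_b` (named numeric), `percent`,
#'   `top_length_a`, `top_length_b`, `aggregate`.
#' @export
ccg_all_pairs <- function(map_a, map_b, table, percent = 5,
                          aggregate = c("max", "mean")) {
  stopifnot(inherits(map_a, "coexpression_map"),
            inherits(map_b, "coexpression_map"),
            inherits(table, "homology_table"))
  aggregate <- match.arg(aggregate)
  TA <- top_lists_all(map_a, percent)
  TB <- top_lists_all(map_b, percent)
  genes_a <- map_a$genes
  genes_b <- map_b$genes
  hmap <- homolog_index_map(table, genes_a, genes_b)

  p <- table$pairs
  keep <- p$gene_a %in% genes_a & p$gene_b %in% genes_b
  p <- p[keep, , drop = FALSE]
  np <- nrow(p)
  if (np == 0L) stop("no homolog pair has both genes present in the maps")
  ia <- match(p$gene_a, genes_a)
  ib <- match(p$gene_b, genes_b)

  counts <- integer(np)
  overlaps <- vector("list", np)
  memb_b <- logical(length(genes_b))
  for (k in seq_len(np)) {
    bl <- TB[, ib[k]]
    memb_b[bl] <- TRUE
    ov <- ccg_overlap_core(TA[, ia[k]], memb_b, hmap)
    memb_b[bl] <- FALSE
    counts[k] <- length(ov)
    overlaps[[k]] <- genes_a[ov]
  }
  pair_id <- paste(p$gene_a, p$gene_b, sep = "|")
  names(overlaps) <- pair_id
  pairs <- data.frame(pair_id = pair_id, gene_a = p$gene_a,
                      gene_b = p$gene_b, relationship = p$relationship,
                      dnds = p$dnds, ccg_count = counts,
                      stringsAsFactors = FALSE)
  structure(list(pairs = pairs, overlaps = overlaps,
                 gene_level_a = aggregate_gene_level(pairs, "gene_a", aggregate),
                 gene_level_b = aggregate_gene_level(pairs, "gene_b", aggregate),
                 percent = percent,
                 top_length_a = nrow(TA), top_length_b = nrow(TB),
                 aggregate = aggregate),
            class = "ccg_table")
}

aggregate_gene_level <- function(pairs, side, aggregate) {
  f <- if (aggregate == "max") max else mean
  v <- tapply(pairs$ccg_count, pairs[[side]], f)
  out <- as.numeric(v)
  names(out) <- names(v)
  out
}

#' @export
print.ccg_table <- function(x, ...) {
  cat("ccg_table:", nrow(x$pairs), "homolog pairs at top", x$percent,
      "% (list lengths", x$top_length_a, "/", x$top_length_b, ")\n")
  cat("median CCG:", stats::median(x$pairs$ccg_count), "| aggregate:",
      x$aggregate, "\n")
  invisible(x)
}

#' Write a CCG table as TSV
#'
#' @param ccg a [ccg_all_pairs()] result.
#' @param path TSV file path.
#' @return `path`, invisibly.
#' @export
write_ccg_table <- function(ccg, path) {
  stopifnot(inherits(ccg, "ccg_table"))
  dt <- data.table::as.data.table(ccg$pairs)
  dt$gene_level_a <- ccg$gene_level_a[dt$gene_a]
  dt$gene_level_b <- ccg$gene_level_b[dt$gene_b]
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Spearman correlation with a permutation empirical p-value
#'
#' Spearman's rho via midranks; the null distribution is built by permuting
#' the second vector `B` times and the two-sided empirical p-value uses the
#' add-one convention p = (1 + #\{|rho_perm| >= |rho_obs|\}) / (B + 1), so
#' p >= 1/(B+1) always.  When no permutation reaches the observed value the
#' paper-style bound string `"<1/B"` is reported alongside.
#'
#' @param x,y equal-length finite numeric vectors, n >= 3, non-constant.
#' @param B number of permutations (default 10000).
#' @param seed optional RNG seed for reproducible permutations.
#' @return object of class `permutation_association`: list with `rho`, `B`,
#'   `p_empirical`, `bound` (string or NA), `seed`.
#' @export
spearman_permutation <- function(x, y, B = 10000L, seed = NULL) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3L, B >= 1L)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("x and y must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("rho undefined for constant input")
  if (!is.null(seed)) set.seed(seed)
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  a <- abs(rho)
  cnt <- 0L
  for (b in seq_len(B)) {
    if (abs(stats::cor(rx, sample(ry))) >= a) cnt <- cnt + 1L
  }
  p <- (1 + cnt) / (B + 1)
  structure(list(rho = rho, B = as.integer(B), p_empirical = p,
                 bound = if (cnt == 0L) sprintf("<%g", 1 / B) else NA_character_,
                 seed = seed),
            class = "permutation_association")
}

#' @export
print.permutation_association <- function(x, ...) {
  cat(sprintf("Spearman rho = %.4f, empirical p = %.4g (B = %d)%s\n",
              x$rho, x$p_empirical, x$B,
              if (!is.na(x$bound)) paste0(" [", x$bound, "]") else ""))
  invisible(x)
}

#' Select the top and bottom extremes of a ranked gene list
#'
#' Takes `floor(percent/100 * n)` genes from each end of the ranking by
#' `values`.  Ties at the top cut are broken by ascending gene ID and ties
#' at the bottom cut by descending gene ID, so with all-equal values the top
#' list holds the lexicographically first genes and the bottom list the
#' last, and the two lists never overlap.  Intended for export to external
#' enrichment tools (one ID per line, see `write_gene_list`).
#'
#' @param values named finite numeric vector (names = gene IDs).
#' @param percent extreme size in percent (default 5).
#' @return list with character vectors `top` (highest values) and `bottom`.
#' @export
rank_select_extremes <- function(values, percent = 5) {
  n <- length(values)
  if (is.null(names(values))) stop("values must be named by gene ID")
  if (any(!is.finite(values))) stop("values must be finite")
  L <- floor(percent / 100 * n)
  if (L < 1L || 2L * L > n)
    stop("need n >= 2 * 100/percent values for non-overlapping extremes")
  ids <- names(values)
  top_ord <- order(-values, ids, method = "radix")
  bot_ord <- order(values, ids, method = "radix",
                   decreasing = c(FALSE, TRUE))
  list(top = ids[top_ord[seq_len(L)]],
       bottom = ids[bot_ord[seq_len(L)]])
}

#' Write a plain gene list (one ID per line)
#'
#' @param genes character vector of gene IDs.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' Distribution diagnostics: skewness and normality
#'
#' Adjusted Fisher-Pearson sample skewness
#' G1 = g1 * sqrt(n(n-1)) / (n-2) with g1 = m3 / m2^(3/2), and a
#' Shapiro-Wilk normality test.  `shapiro.test` supports at most 5000
#' observations; larger samples are tested on a deterministic systematic
#' subsample (flagged in the result).  A constant vector returns skewness 0
#' with the normality p flagged undefined.  Diagnostics only; nothing in the
#' pipeline gates on them.
#'
#' @param values numeric vector, n >= 8.
#' @return list with `n`, `skewness`, `shapiro_W`, `shapiro_p`,
#'   `normality_defined`, `subsampled`.
#' @export
distribution_summary <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 8L) stop("need at least 8 finite values")
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 == 0) {
    return(list(n = n, skewness = 0, shapiro_W = NA_real_,
                shapiro_p = NA_real_, normality_defined = FALSE,
                subsampled = FALSE))
  }
  g1 <- mean((values - m)^3) / m2^1.5
  G1 <- g1 * sqrt(n * (n - 1)) / (n - 2)
  sub <- n > 5000L
  v <- if (sub) values[seq(1L, n, by = ceiling(n / 5000))] else values
  st <- stats::shapiro.test(v)
  list(n = n, skewness = G1, shapiro_W = unname(st$statistic),
       shapiro_p = st$p.value, normality_defined = TRUE, subsampled = sub)
}
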