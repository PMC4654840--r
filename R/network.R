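#' Extract a directed co-expression network at a percentage threshold
#'
#' An arc i -> j is drawn iff gene i appears in the top-`percent`
#' co-expression list of gene j, so every gene owns an incoming top list of
#' exactly `floor(percent/100 * m)` arcs and the total arc count is
#' `m * floor(percent/100 * m)` by construction.  Self arcs are impossible
#' (the focal gene is excluded from its own list).
#'
#' @param map a [coexpression_map()].
#' @param percent percentage threshold (default 1).
#' @return object of class `directed_coexpr_network`: list with `genes`,
#'   `percent`, `list_length` and `in_lists` (integer matrix, column j =
#'   indices of the genes with an arc into j, i.e. j's top list).
#' @export
build_directed_network <- function(map, percent = 1) {
  stopifnot(inherits(map, "coexpression_map"))
  m <- length(map$genes)
  L <- top_list_length(m, percent)
  if (L < 1L) stop("percent = ", percent, " yields an empty top list for m = ", m)
  structure(list(genes = map$genes, percent = percent, list_length = L,
                 in_lists = top_lists_all(map, percent)),
            class = "directed_coexpr_network")
}

#' @export
print.directed_coexpr_network <- function(x, ...) {
  m <- length(x$genes)
  cat("directed_coexpr_network:", m, "genes,", x$percent,
      "% threshold,", m * x$list_length, "arcs\n")
  invisible(x)
}

#' Dense adjacency matrix of a directed network
#'
#' `A[i, j] = 1` iff there is an arc i -> j (i is in j's top list).  Meant
#' for small networks and tests; the network object itself stores only the
#' top lists.
#'
#' @param net a [build_directed_network()] result.
#' @return m x m 0/1 integer matrix with gene dimnames.
#' @export
adjacency_matrix <- function(net) {
  stopifnot(inherits(net, "directed_coexpr_network"))
  m <- length(net$genes)
  A <- matrix(0L, m, m, dimnames = list(net$genes, net$genes))
  js <- rep(seq_len(m), each = net$list_length)
  A[cbind(as.vector(net$in_lists), js)] <- 1L
  A
}

#' Connectivity (degree) vector of a directed network
#'
#' k_i = sum_j A(i, j): the number of other genes whose top-percent lists
#' contain gene i.  Under the fixed-size in-list construction the total
#' connectivity is exactly m * floor(percent/100 * m).
#'
#' @param net a [build_directed_network()] result.
#' @return named integer vector of per-gene connectivity.
#' @export
connectivity <- function(net) {
  stopifnot(inherits(net, "directed_coexpr_network"))
  k <- tabulate(net$in_lists, nbins = length(net$genes))
  names(k) <- net$genes
  k
}

#' Normalize connectivity between two networks of different size
#'
#' Networks built with a percentage threshold have total arc counts that
#' scale with their size, so raw degrees are not comparable across species.
#' Species-2 degrees are rescaled by the ratio of list lengths
#' `floor(percent/100 * m1) / floor(percent/100 * m2)` onto the species-1
#' scale; species-1 degrees are returned unchanged.  After rescaling the
#' mean normalized connectivity equals the species-1 list length in both
#' species.
#'
#' @param k1,k2 connectivity vectors of the two networks.
#' @param m1,m2 network sizes (gene counts).
#' @param percent the common percentage threshold.
#' @return list with numeric vectors `k1n`, `k2n` and the `factor` applied.
#' @export
normalize_connectivity <- function(k1, k2, m1, m2, percent) {
  L1 <- top_list_length(m1, percent)
  L2 <- top_list_length(m2, percent)
  factor <- L1 / L2
  list(k1n = as.numeric(k1), k2n = as.numeric(k2) * factor, factor = factor)
}

#' Folded differential connectivity (DiffK)
#'
#' For normalized connectivities k1n, k2n of a homolog pair the raw ratio is
#' r = (k1n + 10) / (k2n + 10); the pseudocount of 10 damps disproportionate
#' fold changes between poorly connected genes.  Ratios in (0, 1) are
#' replaced by their negative reciprocal and finally 1 is subtracted from
#' positive and added to negative values, folding the ratio scale so that 0
#' means equal connectivity, positive values mean more connected in species
#' 1 and negative values more connected in species 2.  The transform is
#' exactly antisymmetric under swapping the species.
#'
#' @param k1n,k2n non-negative normalized connectivity values (vectorized).
#' @return numeric vector of folded DiffK values.
#' @export
differential_connectivity <- function(k1n, k2n) {
  if (any(k1n < 0) || any(k2n < 0)) stop("connectivity values must be >= 0")
  r <- (k1n + 10) / (k2n + 10)
  v <- ifelse(r >= 1, r, -1 / r)
  ifelse(v > 0, v - 1, v + 1)
}

#' DiffK table for all homolog pairs of two networks
#'
#' Computes raw connectivities in both networks, rescales species 2 onto the
#' species-1 scale with [normalize_connectivity()] and applies
#' [differential_connectivity()] to every homolog pair with both genes
#' present.
#'
#' @param net1,net2 [build_directed_network()] results (same percent).
#' @param table a [homology_table()].
#' @return object of class `diffk_result`: data.frame with `pair_id`,
#'   `gene_a`, `gene_b`, `relationship`, `k1`, `k2`, `k1n`, `k2n`,
#'   `raw_ratio`, `folded`.
#' @export
diffk_table <- function(net1, net2, table) {
  stopifnot(inherits(net1, "directed_coexpr_network"),
            inherits(net2, "directed_coexpr_network"),
            inherits(table, "homology_table"))
  if (net1$percent != net2$percent)
    stop("networks were built at different percent thresholds")
  k1 <- connectivity(net1)
  k2 <- connectivity(net2)
  nk <- normalize_connectivity(k1, k2, length(net1$genes),
                               length(net2$genes), net1$percent)
  p <- table$pairs
  keep <- p$gene_a %in% net1$genes & p$gene_b %in% net2$genes
  p <- p[keep, , drop = FALSE]
  if (nrow(p) == 0L) stop("no homolog pair has both genes in the networks")
  i1 <- match(p$gene_a, net1$genes)
  i2 <- match(p$gene_b, net2$genes)
  k1n <- nk$k1n[i1]
  k2n <- nk$k2n[i2]
  out <- data.frame(
    pair_id = paste(p$gene_a, p$gene_b, sep = "|"),
    gene_a = p$gene_a, gene_b = p$gene_b,
    relationship = p$relationship,
    k1 = as.numeric(k1[i1]), k2 = as.numeric(k2[i2]),
    k1n = k1n, k2n = k2n,
    raw_ratio = (k1n + 10) / (k2n + 10),
    folded = differential_connectivity(k1n, k2n),
    stringsAsFactors = FALSE
  )
  class(out) <- c("diffk_result", class(out))
  out
}

#' Log-log least-squares fit of the degree distribution
#'
#' Diagnostic for scale-free behaviour P(k) ~ k^-gamma: least-squares slope
#' of log frequency against log degree over degrees k >= 1.  Requires at
#' least 20 distinct positive degrees, otherwise the fit is flagged
#' undefined.  A near-zero R-squared flags low confidence (e.g. uniform
#' degrees).  This is a diagnostic, not an inferential power-law claim.
#'
#' @param k connectivity vector (e.g. from [connectivity()]).
#' @param min_distinct minimum number of distinct positive degrees.
#' @return list with `defined`, `slope`, `r_squared`, `low_confidence`,
#'   `n_distinct`.
#' @export
degree_distribution_fit <- function(k, min_distinct = 20L) {
  kk <- k[k >= 1]
  tab <- table(kk)
  nd <- length(tab)
  if (nd < min_distinct) {
    return(list(defined = FALSE, slope = NA_real_, r_squared = NA_real_,
                low_confidence = TRUE, n_distinct = nd))
  }
  deg <- as.numeric(names(tab))
  freq <- as.numeric(tab)
  lf <- log(freq)
  if (stats::sd(lf) == 0) {  # constant frequencies: slope 0, nothing explained
    return(list(defined = TRUE, slope = 0, r_squared = 0,
                low_confidence = TRUE, n_distinct = nd))
  }
  fit <- stats::lm(lf ~ log(deg))
  r2 <- summary(fit)$r.squared
  if (!is.finite(r2)) r2 <- 0
  list(defined = TRUE, slope = unname(stats::coef(fit)[2L]),
       r_squared = r2, low_confidence = r2 < 0.5, n_distinct = nd)
}

#' Write network edge list, connectivity and DiffK tables as TSV
#'
#' @param net a [build_directed_network()] result.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "directed_coexpr_network"))
  m <- length(net$genes)
  dt <- data.table::data.table(
    source = net$genes[as.vector(net$in_lists)],
    target = net$genes[rep(seq_len(m), each = net$list_length)]
  )
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @param k named connectivity vector.
#' @rdname write_edge_list
#' @export
write_connectivity <- function(k, path) {
  data.table::fwrite(
    data.table::data.table(gene = names(k), k = as.numeric(k)),
    path, sep = "\t")
  invisible(path)
}

#' @param diffk a [diffk_table()] result.
#' @rdname write_edge_list
#' @export
write_diffk <- function(diffk, path) {
  data.table::fwrite(data.table::as.data.table(unclass(diffk)), path,
                     sep = "\t")
  invisible(path)
}
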