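#' Construct an expression dataset
#'
#' A gene-by-condition real matrix for one dataset of a compendium.  Gene IDs
#' must be unique and at least two conditions are required (a single
#' condition carries no co-regulation information under a median split).
#'
#' @param values numeric matrix, genes in rows, conditions in columns.
#' @param genes,conditions character IDs; default to the dimnames.
#' @param name optional dataset label.
#' @return object of class `expression_dataset`.
#' @export
expression_dataset <- function(values, genes = rownames(values),
                               conditions = colnames(values), name = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("values must be numeric")
  if (is.null(genes)) stop("gene IDs required (rownames or 'genes')")
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("duplicate gene IDs in dataset")
  if (length(genes) != nrow(values)) stop("genes/rows length mismatch")
  if (ncol(values) < 2L) stop("need >= 2 conditions")
  if (is.null(conditions)) conditions <- paste0("c", seq_len(ncol(values)))
  conditions <- as.character(conditions)
  dimnames(values) <- list(genes, conditions)
  structure(list(name = name, genes = genes, conditions = conditions,
                 values = values),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("expression_dataset", if (!is.null(x$name)) paste0("'", x$name, "'"),
      ":", length(x$genes), "genes x", length(x$conditions), "conditions\n")
  invisible(x)
}

#' Construct a co-expression map
#'
#' All-pairs co-expression scores in \[0, 1\] over an ordered gene universe.
#' The matrix is symmetric, the diagonal (self pairs) is `NA` and never
#' returned by downstream operations.  Genes are stored in ascending ID
#' order, which is what makes the deterministic tie rules of
#' [top_percent_list()] reproducible.
#'
#' @param species species label.
#' @param genes character gene IDs.
#' @param values symmetric numeric matrix in \[0, 1\] matching `genes`.
#' @return object of class `coexpression_map`.
#' @export
coexpression_map <- function(species, genes, values) {
  genes <- as.character(genes)
  values <- as.matrix(values)
  stopifnot(length(genes) == nrow(values), nrow(values) == ncol(values))
  if (anyDuplicated(genes)) stop("duplicate gene IDs in map")
  ord <- order(genes, method = "radix")
  genes <- genes[ord]
  values <- values[ord, ord, drop = FALSE]
  diag(values) <- NA_real_
  off <- values[upper.tri(values)]
  if (any(!is.na(off) & (off < 0 | off > 1)))
    stop("co-expression scores must lie in [0, 1]")
  if (!isTRUE(all.equal(values, t(values))))
    stop("co-expression map must be symmetric")
  dimnames(values) <- list(genes, genes)
  structure(list(species = species, genes = genes, values = values),
            class = "coexpression_map")
}

#' @export
print.coexpression_map <- function(x, ...) {
  cat("coexpression_map [", x$species, "]: ", length(x$genes),
      " genes\n", sep = "")
  invisible(x)
}

#' Build a vote-counting co-expression map from expression datasets
#'
#' Within each dataset every gene's expression is discretized per condition
#' to up / down / neutral relative to that gene's within-dataset median
#' (neutral when within `neutral_epsilon` of the median; the default 0 is a
#' strict sign split, so only exact median values are neutral).  Pooling all
#' conditions of all datasets, for each gene pair C counts conditions where
#' both genes move in the same direction and D counts conditions where both
#' are non-neutral but move in opposite directions.  The co-expression score
#' is the co-regulation frequency C / (C + D), set to 0 when C + D = 0
#' (including genes never observed in a common dataset).  A gene constant
#' within a dataset is all-neutral there and simply contributes nothing.
#'
#' The map is invariant to the order of datasets and to permuting conditions
#' within a dataset.
#'
#' @param datasets an [expression_dataset()] or list thereof.
#' @param species species label for the map.
#' @param neutral_epsilon half-width of the neutral band around the median.
#' @return a [coexpression_map()] over the union of dataset genes.
#' @export
build_coexpression_map <- function(datasets, species = "species",
                                   neutral_epsilon = 0) {
  if (inherits(datasets, "expression_dataset")) datasets <- list(datasets)
  stopifnot(length(datasets) >= 1L,
            all(vapply(datasets, inherits, logical(1), "expression_dataset")),
            neutral_epsilon >= 0)
  universe <- sort(unique(unlist(lapply(datasets, `[[`, "genes"))),
                   method = "radix")
  n <- length(universe)
  ncond <- vapply(datasets, function(d) ncol(d$values), integer(1))
  total <- sum(ncond)
  U <- matrix(0, n, total)   # 1 = up in that pooled condition
  D <- matrix(0, n, total)   # 1 = down
  off <- 0L
  for (d in datasets) {
    v <- d$values
    med <- apply(v, 1L, stats::median)
    ridx <- match(d$genes, universe)
    cols <- off + seq_len(ncol(v))
    U[ridx, cols] <- (v > med + neutral_epsilon) + 0
    D[ridx, cols] <- (v < med - neutral_epsilon) + 0
    off <- off + ncol(v)
  }
  C <- tcrossprod(U) + tcrossprod(D)
  X <- tcrossprod(U, D)
  Dis <- X + t(X)
  tot <- C + Dis
  score <- C
  nz <- tot > 0
  score[nz] <- C[nz] / tot[nz]
  score[!nz] <- 0
  coexpression_map(species, universe, score)
}

#' Length of a top-percent list
#'
#' The number of partners retained at a percentage threshold over a gene
#' universe of size `n`: `floor(percent/100 * n)`.  Over the 22,766-gene
#' mouse universe the 5 % rule yields 1138 partners.
#'
#' @param n universe size.
#' @param percent percentage threshold in (0, 100].
#' @return integer list length.
#' @export
top_list_length <- function(n, percent) {
  stopifnot(n >= 1, percent > 0, percent <= 100)
  as.integer(floor(percent / 100 * n))
}

#' Top co-expressed partners of one gene
#'
#' Returns the `floor(percent/100 * N)` genes with the highest co-expression
#' score with the focal gene (N is the full map universe size, non-homologs
#' included).  The focal gene itself is excluded; ties at the cut are broken
#' by ascending gene ID.
#'
#' @param map a [coexpression_map()].
#' @param gene focal gene ID (must be in the map).
#' @param percent percentage threshold (default 5).
#' @return object of class `top_list`: list with `gene`, `percent`,
#'   `partners` (ordered character vector).
#' @export
top_percent_list <- function(map, gene, percent = 5) {
  stopifnot(inherits(map, "coexpression_map"))
  j <- match(gene, map$genes)
  if (is.na(j)) stop("gene '", gene, "' is not in the map")
  L <- top_list_length(length(map$genes), percent)
  if (L < 1L) stop("percent threshold yields an empty list")
  idx <- top_partner_indices(map$values[, j], j, L)
  structure(list(gene = gene, percent = percent,
                 partners = map$genes[idx]),
            class = "top_list")
}

# Indices of the L top-scoring partners for one score column.  Genes are in
# ascending ID order in the map, and base radix order is stable, so ranking
# by descending score breaks ties by ascending gene ID.  The self entry is
# NA on the diagonal and sorts last.
top_partner_indices <- function(scores, self, L) {
  o <- order(-scores, method = "radix", na.last = TRUE)
  o <- o[o != self]
  o[seq_len(L)]
}

# All top lists of a map at once, as an L x m integer index matrix
# (column j = partners of gene j, best first).
top_lists_all <- function(map, percent) {
  m <- length(map$genes)
  L <- top_list_length(m, percent)
  if (L < 1L) stop("percent threshold yields an empty list")
  out <- matrix(0L, L, m)
  for (j in seq_len(m)) {
    out[, j] <- top_partner_indices(map$values[, j], j, L)
  }
  dimnames(out) <- list(NULL, map$genes)
  out
}

#' Write / read a co-expression map as long-form TSV
#'
#' Interchange format: one row per unordered gene pair (`gene_a` < `gene_b`)
#' with the score.  `read_coexpression_map` reconstructs the symmetric
#' matrix; pairs absent from the file get score 0.
#'
#' @param map a [coexpression_map()].
#' @param path TSV file path.
#' @param drop_zero omit zero-score pairs when writing (default TRUE).
#' @return `write_coexpression_map` returns `path` invisibly;
#'   `read_coexpression_map` returns a [coexpression_map()].
#' @export
write_coexpression_map <- function(map, path, drop_zero = TRUE) {
  stopifnot(inherits(map, "coexpression_map"))
  ut <- which(upper.tri(map$values), arr.ind = TRUE)
  dt <- data.table::data.table(
    gene_a = map$genes[ut[, 1L]],
    gene_b = map$genes[ut[, 2L]],
    score = map$values[ut]
  )
  if (drop_zero) dt <- dt[dt$score > 0, ]
  data.table::setorderv(dt, c("gene_a", "gene_b"))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @param species species label for the map read back.
#' @param genes optional full universe for `read_coexpression_map` (needed
#'   when zero-score genes were dropped on write).
#' @rdname write_coexpression_map
#' @export
read_coexpression_map <- function(path, species = "species", genes = NULL) {
  dt <- data.table::fread(path, sep = "\t", colClasses = list(
    character = c("gene_a", "gene_b")))
  if (!all(c("gene_a", "gene_b", "score") %in% names(dt)))
    stop("map file must have columns gene_a, gene_b, score")
  universe <- sort(unique(c(dt$gene_a, dt$gene_b, genes)), method = "radix")
  n <- length(universe)
  v <- matrix(0, n, n)
  ia <- match(dt$gene_a, universe)
  ib <- match(dt$gene_b, universe)
  v[cbind(ia, ib)] <- dt$score
  v[cbind(ib, ia)] <- dt$score
  coexpression_map(species, universe, v)
}

#' Write / read an expression dataset TSV (gene x condition with header)
#'
#' @param dataset an [expression_dataset()].
#' @param path TSV file path.
#' @return `write_expression_dataset` returns `path` invisibly;
#'   `read_expression_dataset` returns an [expression_dataset()].
#' @export
write_expression_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "expression_dataset"))
  dt <- data.table::data.table(gene = dataset$genes)
  dt <- cbind(dt, data.table::as.data.table(dataset$values))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @param name dataset label for the dataset read back.
#' @rdname write_expression_dataset
#' @export
read_expression_dataset <- function(path, name = NULL) {
  dt <- data.table::fread(path, sep = "\t", colClasses = list(character = "gene"))
  if (names(dt)[1L] != "gene") stop("first column must be 'gene'")
  genes <- dt$gene
  v <- as.matrix(dt[, -1L, drop = FALSE])
  expression_dataset(v, genes = genes, conditions = colnames(v),
                     name = if (is.null(name)) basename(path) else name)
}
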