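#' Construct a homology table
#'
#' A homology table holds cross-species homologous gene pairs together with
#' their orthology relationship class (`one2one`, `one2many`, `many2many`),
#' molecular evolution rates dN and dS, and the full gene universes of both
#' species (homologs and non-homologs alike).  The dN/dS ratio is computed
#' where dS > 0; pairs with dS = 0 or missing rates are kept but flagged, so
#' homology counts are never silently reduced by undefined ratios.
#'
#' @param pairs data.frame with columns `gene_a`, `gene_b` and optionally
#'   `dn`, `ds`, `relationship`.  Duplicate (gene_a, gene_b) rows are
#'   collapsed to one.  When `relationship` is absent it is inferred from
#'   pair multiplicity via [classify_relationships()].
#' @param universe_a,universe_b character vectors of all gene IDs per species;
#'   default to the genes occurring in `pairs`.  Every paired gene must be a
#'   member of its species' universe.
#' @return An object of class `homology_table`: a list with elements `pairs`
#'   (data.frame with `gene_a`, `gene_b`, `relationship`, `dn`, `ds`, `dnds`,
#'   `dnds_defined`), `universe_a` and `universe_b`.
#' @seealso [read_homology_table()], [dnds_by_class()]
#' @export
homology_table <- function(pairs, universe_a = NULL, universe_b = NULL) {
  stopifnot(is.data.frame(pairs))
  for (col in c("gene_a", "gene_b")) {
    if (is.null(pairs[[col]])) stop("pairs must have a '", col, "' column")
    pairs[[col]] <- as.character(pairs[[col]])
    if (anyNA(pairs[[col]]) || any(!nzchar(pairs[[col]])))
      stop("empty gene ID in column '", col, "'")
  }
  if (is.null(pairs$dn)) pairs$dn <- NA_real_
  if (is.null(pairs$ds)) pairs$ds <- NA_real_
  pairs$dn <- as.numeric(pairs$dn)
  pairs$ds <- as.numeric(pairs$ds)
  if (any(pairs$dn < 0, na.rm = TRUE) || any(pairs$ds < 0, na.rm = TRUE))
    stop("dn and ds must be non-negative")

  # collapse duplicated pairs
  key <- paste(pairs$gene_a, pairs$gene_b, sep = "\r")
  keep <- !duplicated(key)
  pairs <- pairs[keep, , drop = FALSE]
  rownames(pairs) <- NULL

  if (is.null(pairs$relationship) || all(is.na(pairs$relationship))) {
    pairs$relationship <- classify_relationships(pairs)
  } else {
    pairs$relationship <- as.character(pairs$relationship)
    bad <- setdiff(unique(pairs$relationship),
                   c("one2one", "one2many", "many2many"))
    if (length(bad))
      stop("unknown relationship label(s): ", paste(bad, collapse = ", "))
  }

  pairs$dnds <- ifelse(!is.na(pairs$ds) & pairs$ds > 0 & !is.na(pairs$dn),
                       pairs$dn / pairs$ds, NA_real_)
  pairs$dnds_defined <- !is.na(pairs$dnds)

  if (is.null(universe_a)) universe_a <- sort(unique(pairs$gene_a))
  if (is.null(universe_b)) universe_b <- sort(unique(pairs$gene_b))
  universe_a <- sort(unique(as.character(universe_a)))
  universe_b <- sort(unique(as.character(universe_b)))
  if (!all(pairs$gene_a %in% universe_a))
    stop("some gene_a values are not in universe_a")
  if (!all(pairs$gene_b %in% universe_b))
    stop("some gene_b values are not in universe_b")

  structure(list(pairs = pairs, universe_a = universe_a,
                 universe_b = universe_b),
            class = "homology_table")
}

#' @export
print.homology_table <- function(x, ...) {
  cat("homology_table:", nrow(x$pairs), "pairs |",
      length(x$universe_a), "species-A genes |",
      length(x$universe_b), "species-B genes\n")
  print(table(x$pairs$relationship))
  nd <- sum(!x$pairs$dnds_defined)
  if (nd) cat(nd, "pair(s) with undefined dN/dS (missing rates or dS = 0)\n")
  invisible(x)
}

#' Read a homology table from a Biomart-style TSV file
#'
#' The file must be tab-separated with a header naming at least `gene_a`,
#' `gene_b`, `dn` and `ds`; an optional `relationship` column is honoured,
#' otherwise relationship classes are inferred from pair multiplicity.
#' Duplicate rows are collapsed.  Rows with the wrong number of fields or
#' non-numeric rate entries raise an error that names the offending line;
#' empty rate fields are retained as missing (the pair is kept, its dN/dS
#' flagged undefined).
#'
#' @param path path to a UTF-8 TSV file.
#' @return A [homology_table()].
#' @export
read_homology_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 1L) stop("empty homology file: ", path)
  lines <- lines[nzchar(lines)]
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  required <- c("gene_a", "gene_b", "dn", "ds")
  missing_cols <- setdiff(required, header)
  if (length(missing_cols))
    stop("homology file missing column(s): ",
         paste(missing_cols, collapse = ", "))
  nfield <- length(header)
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  lens <- lengths(body)
  bad <- which(lens != nfield)
  if (length(bad))
    stop("malformed homology row at line ", bad[[1L]] + 1L,
         " (expected ", nfield, " fields, found ", lens[bad[[1L]]], ")")
  mat <- do.call(rbind, body)
  colnames(mat) <- header
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  for (col in c("dn", "ds")) {
    raw <- df[[col]]
    empty <- !nzchar(raw) | raw %in% c("NA", "na", "NaN")
    val <- suppressWarnings(as.numeric(raw))
    malformed <- which(is.na(val) & !empty)
    if (length(malformed))
      stop("malformed ", col, " value at line ", malformed[[1L]] + 1L,
           ": '", raw[malformed[[1L]]], "'")
    df[[col]] <- val
  }
  keep <- intersect(c("gene_a", "gene_b", "dn", "ds", "relationship"), header)
  homology_table(df[, keep, drop = FALSE])
}

#' Classify homolog pairs as one2one / one2many / many2many
#'
#' Classification operates on connected components of the bipartite pair
#' graph: a pair is `many2many` when its component contains a multiplied gene
#' on *both* species sides, `one2many` when exactly one side is multiplied
#' anywhere in the component, and `one2one` when both genes of the pair occur
#' in exactly one pair.  The component-level rule means e.g. the three pairs
#' (h1,m1), (h1,m2), (h2,m1) are all `many2many` even though (h2,m1) alone
#' would look `one2many`.  Labels are invariant to row order and to swapping
#' the species sides.
#'
#' @param x a `homology_table` or a data.frame with `gene_a`, `gene_b`.
#' @return character vector of class labels, one per pair.
#' @export
classify_relationships <- function(x) {
  pairs <- if (inherits(x, "homology_table")) x$pairs else x
  n <- nrow(pairs)
  if (n == 0L) return(character(0))
  a <- paste0("A\r", pairs$gene_a)
  b <- paste0("B\r", pairs$gene_b)
  nodes <- unique(c(a, b))
  ia <- match(a, nodes)
  ib <- match(b, nodes)

  # union-find over the bipartite pair graph
  parent <- seq_along(nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(n)) {
    ra <- find(ia[k]); rb <- find(ib[k])
    if (ra != rb) parent[rb] <- ra
  }
  comp <- vapply(seq_along(nodes), find, integer(1))

  mult_a <- table(pairs$gene_a)[pairs$gene_a] > 1L
  mult_b <- table(pairs$gene_b)[pairs$gene_b] > 1L
  pair_comp <- comp[ia]
  comp_mult_a <- tapply(mult_a, pair_comp, any)
  comp_mult_b <- tapply(mult_b, pair_comp, any)
  ka <- unname(comp_mult_a[as.character(pair_comp)])
  kb <- unname(comp_mult_b[as.character(pair_comp)])
  as.character(ifelse(ka & kb, "many2many",
                      ifelse(ka | kb, "one2many", "one2one")))
}

#' Compare dN/dS distributions across homology classes
#'
#' Reproduces the class-wise comparison of molecular evolution rates:
#' a Kruskal-Wallis omnibus test over the per-class dN/dS distributions
#' followed by post-hoc pairwise two-sided Mann-Whitney tests with Bonferroni
#' correction (p multiplied by the number of comparisons, capped at 1).
#' Only pairs with a defined dN/dS enter; classes with fewer than two defined
#' ratios are excluded with a warning.
#'
#' @param table a [homology_table()].
#' @return list of class `dnds_by_class` with elements `ratios` (named list
#'   of per-class dN/dS vectors), `kruskal` (`statistic`, `df`, `p.value`)
#'   and `pairwise` (data.frame `class1`, `class2`, `U`, `p_raw`,
#'   `p_bonferroni`).
#' @export
dnds_by_class <- function(table) {
  stopifnot(inherits(table, "homology_table"))
  p <- table$pairs[table$pairs$dnds_defined, , drop = FALSE]
  ratios <- split(p$dnds, p$relationship)
  small <- names(ratios)[lengths(ratios) < 2L]
  if (length(small)) {
    warning("excluding class(es) with < 2 defined dN/dS ratios: ",
            paste(small, collapse = ", "))
    ratios <- ratios[lengths(ratios) >= 2L]
  }
  if (length(ratios) < 2L)
    stop("need at least two classes with >= 2 defined dN/dS ratios")
  cls <- rep(names(ratios), lengths(ratios))
  val <- unlist(ratios, use.names = FALSE)
  kw <- stats::kruskal.test(val, factor(cls))

  combs <- utils::combn(names(ratios), 2L)
  m <- ncol(combs)
  pw <- data.frame(class1 = combs[1L, ], class2 = combs[2L, ],
                   U = NA_real_, p_raw = NA_real_,
                   p_bonferroni = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(m)) {
    x <- ratios[[combs[1L, i]]]
    y <- ratios[[combs[2L, i]]]
    wt <- mann_whitney(x, y)
    pw$U[i] <- wt$statistic
    pw$p_raw[i] <- wt$p.value
  }
  pw$p_bonferroni <- pmin(pw$p_raw * m, 1)
  structure(list(ratios = ratios,
                 kruskal = list(statistic = unname(kw$statistic),
                                df = unname(kw$parameter),
                                p.value = kw$p.value),
                 pairwise = pw),
            class = "dnds_by_class")
}

# Two-sided Mann-Whitney wrapper: exact enumeration when both groups are
# small (<= 20) and untied, midrank normal approximation otherwise
# (stats::wilcox.test falls back itself when ties are present).
mann_whitney <- function(x, y) {
  exact <- length(x) <= 20L && length(y) <= 20L
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = TRUE)
  )
  list(statistic = unname(wt$statistic), p.value = wt$p.value)
}

#' Assign values to equally sized quantile bins
#'
#' Elements are ranked by `(value, id)` (a stable order, so boundary ties are
#' broken by ascending ID) and split into `k` contiguous bins whose sizes
#' differ by at most one; when `n` is not a multiple of `k` the leftover
#' elements go to the lowest bins (largest-remainder rule: n = 10, k = 4
#' gives sizes 3, 3, 2, 2).  Bin 1 holds the smallest values.
#'
#' @param values finite numeric vector.
#' @param k number of bins (default 4, i.e. quartiles).
#' @param ids optional character IDs used to break ties; defaults to
#'   `names(values)` or the element index.
#' @return integer vector of bin indices in `1:k`, same length as `values`.
#' @export
quartile_bins <- function(values, k = 4L, ids = NULL) {
  n <- length(values)
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("values must be finite numeric")
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  if (n < k) stop("need at least k = ", k, " values, got ", n)
  if (is.null(ids)) {
    ids <- if (!is.null(names(values))) names(values)
           else sprintf("%0*d", nchar(n), seq_len(n))
  }
  stopifnot(length(ids) == n)
  ord <- order(values, as.character(ids), method = "radix")
  base <- n %/% k
  sizes <- rep.int(base, k)
  rem <- n %% k
  if (rem > 0L) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  bins <- integer(n)
  bins[ord] <- rep.int(seq_len(k), sizes)
  bins
}
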