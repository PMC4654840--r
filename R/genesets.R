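#' Construct a gene set collection
#'
#' @param sets named list of character gene ID vectors (species-A IDs).
#'   Names must be unique; duplicate members within a set are dropped; empty
#'   sets are rejected.
#' @param source collection label (e.g. "tissue", "pathway", "disease").
#' @param descriptions optional named character descriptions.
#' @return object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, source = "gene_sets",
                                descriptions = NULL) {
  stopifnot(is.list(sets))
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("all sets must be named")
  if (anyDuplicated(names(sets))) stop("set names must be unique")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0L)) stop("empty gene sets are not allowed")
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  }
  structure(list(sets = sets, source = source,
                 descriptions = descriptions),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection [", x$source, "]: ", length(x$sets),
      " sets, sizes ", min(lengths(x$sets)), "-", max(lengths(x$sets)),
      "\n", sep = "")
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated fields `name`,
#' `description`, then member gene IDs.  Lines with fewer than three fields
#' (i.e. no members) raise an error naming the line; duplicate members
#' within a set are stored once.
#'
#' @param path GMT file path.
#' @param source collection label.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path, source = basename(path)) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop("GMT line ", bad[[1L]], " has fewer than 3 fields")
  nm <- vapply(fields, `[[`, character(1), 1L)
  desc <- vapply(fields, `[[`, character(1), 2L)
  sets <- lapply(fields, function(f) {
    g <- f[-(1:2)]
    g[nzchar(g)]
  })
  names(sets) <- nm
  gene_set_collection(sets, source = source,
                      descriptions = stats::setNames(desc, nm))
}

#' Write a gene set collection as GMT
#'
#' @param collection a [gene_set_collection()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Filter gene sets by minimum size
#'
#' Sets are first restricted to the analysis universe, then sets with fewer
#' than `min_genes` remaining members are dropped (strict "less than", so a
#' 10-gene set survives the default).  With `count = "raw"` the raw set size
#' is used for the filter instead of the in-universe size, but members are
#' still restricted to the universe afterwards.
#'
#' @param collection a [gene_set_collection()].
#' @param min_genes minimum member count (default 10).
#' @param universe character vector of species-A gene IDs in the analysis.
#' @param count size definition: `"in_universe"` (default) or `"raw"`.
#' @return the filtered [gene_set_collection()].
#' @export
filter_min_size <- function(collection, min_genes = 10L, universe,
                            count = c("in_universe", "raw")) {
  stopifnot(inherits(collection, "gene_set_collection"))
  count <- match.arg(count)
  raw_sizes <- lengths(collection$sets)
  restricted <- lapply(collection$sets, intersect, universe)
  sizes <- if (count == "raw") raw_sizes else lengths(restricted)
  keep <- sizes >= min_genes & lengths(restricted) > 0L
  gene_set_collection(restricted[keep], source = collection$source,
                      descriptions = collection$descriptions[names(
                        restricted[keep])])
}

#' Mann-Whitney conservation test of one gene set
#'
#' Two-sided Mann-Whitney U test of the scored values of a gene set against
#' the values of all remaining scored genes, with the median difference
#' median(in-set) - median(remaining) as effect size.  Used for the CCG
#' conservation and differential connectivity parameters.
#'
#' @param set_genes character gene IDs of the set.
#' @param gene_values named numeric vector of per-gene scores (e.g.
#'   gene-level CCG or folded DiffK).
#' @return list with `n_set`, `n_rest`, `statistic` (U), `effect`, `p`;
#'   or NULL (with a warning) when fewer than 2 set genes are scored.
#' @export
eval_set_mannwhitney <- function(set_genes, gene_values) {
  if (is.null(names(gene_values))) stop("gene_values must be named")
  inset <- intersect(set_genes, names(gene_values))
  if (length(inset) < 2L) {
    warning("set has < 2 scored genes; skipped")
    return(NULL)
  }
  x <- gene_values[inset]
  y <- gene_values[setdiff(names(gene_values), inset)]
  if (length(y) < 2L) {
    warning("fewer than 2 remaining genes; skipped")
    return(NULL)
  }
  wt <- mann_whitney(x, y)
  list(n_set = length(x), n_rest = length(y),
       statistic = wt$statistic,
       effect = stats::median(x) - stats::median(y),
       p = wt$p.value)
}

#' Fisher's exact test of a binary gene attribute in a set
#'
#' Builds the 2x2 table \[in-set vs out\] x \[attribute vs not\] over the
#' given universe and returns the conditional odds ratio with a two-sided
#' exact p-value.  Degenerate margins (no gene, or every gene, carrying the
#' attribute) are flagged and return p = 1.
#'
#' @param set_genes character gene IDs of the set.
#' @param gene_labels named logical vector: the attribute per universe gene
#'   (e.g. "duplicated homolog", "non-homologous").
#' @return list with `table` (2x2), `odds_ratio`, `p`, `degenerate`.
#' @export
eval_set_fisher <- function(set_genes, gene_labels) {
  if (is.null(names(gene_labels)) || !is.logical(gene_labels))
    stop("gene_labels must be a named logical vector")
  universe <- names(gene_labels)
  inset <- universe %in% set_genes
  tab <- matrix(c(sum(inset & gene_labels), sum(inset & !gene_labels),
                  sum(!inset & gene_labels), sum(!inset & !gene_labels)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("in_set", "out"), c("attr", "no_attr")))
  degenerate <- any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)
  if (degenerate) {
    or <- if (sum(tab[, "attr"]) == 0L) 0 else Inf
    return(list(table = tab, odds_ratio = or, p = 1, degenerate = TRUE))
  }
  ft <- stats::fisher.test(tab)
  list(table = tab, odds_ratio = unname(ft$estimate), p = ft$p.value,
       degenerate = FALSE)
}

#' Evaluate a gene-set collection with the four conservation parameters
#'
#' For every set the report holds, per homology mode:
#' * `ccg_conservation` - Mann-Whitney of gene-level CCG of the set vs the
#'   remaining scored homologs (modes `all` and `one2one`);
#' * `differential_connectivity` - Mann-Whitney of per-gene folded DiffK
#'   (modes `all` and `one2one`);
#' * `duplication_ratio` - Fisher's exact test of the proportion of
#'   duplicated homologs (one2many/many2many) in the set vs the remaining
#'   homologous genes (mode `all` only);
#' * `nonhomolog_ratio` - Fisher's exact test of the proportion of
#'   non-homologous genes in the set vs the remaining species-A map genes
#'   (mode `all` only).
#'
#' Benjamini-Hochberg correction is applied across sets separately for each
#' (parameter, homology mode) family; significance is flagged at
#' `fdr < alpha`.  Rows are ordered by the ccg_conservation effect
#' (most conserved first) within parameter blocks.  The evaluation is fully
#' deterministic.
#'
#' @param collection a [gene_set_collection()] of species-A gene sets.
#' @param ccg a [ccg_all_pairs()] result.
#' @param diffk a [diffk_table()] result.
#' @param table a [homology_table()].
#' @param universe_a species-A analysis universe (default: the map genes
#'   recorded in `table$universe_a`).
#' @param alpha FDR significance threshold (default 0.05).
#' @return object of class `conservation_report`: data.frame with columns
#'   `set`, `parameter`, `homology_mode`, `n_set`, `statistic`, `effect`,
#'   `p`, `fdr`, `significant`, `direction`.
#' @export
evaluate_collection <- function(collection, ccg, diffk, table,
                                universe_a = NULL, alpha = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"),
            inherits(ccg, "ccg_table"),
            inherits(diffk, "diffk_result"),
            inherits(table, "homology_table"))
  if (is.null(universe_a)) universe_a <- table$universe_a

  p <- ccg$pairs
  one2one <- p$relationship == "one2one"
  ccg_all <- ccg$gene_level_a
  ccg_o2o <- aggregate_gene_level(p[one2one, , drop = FALSE], "gene_a",
                                  ccg$aggregate)
  dk_all <- tapply(diffk$folded, diffk$gene_a, mean)
  dk_all <- stats::setNames(as.numeric(dk_all), names(dk_all))
  d1 <- diffk[diffk$relationship == "one2one", , drop = FALSE]
  dk_o2o <- tapply(d1$folded, d1$gene_a, mean)
  dk_o2o <- stats::setNames(as.numeric(dk_o2o), names(dk_o2o))

  homolog_a <- unique(table$pairs$gene_a)
  dup_a <- unique(table$pairs$gene_a[table$pairs$relationship != "one2one"])
  hom_universe <- intersect(universe_a, homolog_a)
  dup_labels <- stats::setNames(hom_universe %in% dup_a, hom_universe)
  nonhom_labels <- stats::setNames(!(universe_a %in% homolog_a), universe_a)

  mw_specs <- list(
    list(parameter = "ccg_conservation", mode = "all", values = ccg_all),
    list(parameter = "ccg_conservation", mode = "one2one", values = ccg_o2o),
    list(parameter = "differential_connectivity", mode = "all",
         values = dk_all),
    list(parameter = "differential_connectivity", mode = "one2one",
         values = dk_o2o)
  )
  fisher_specs <- list(
    list(parameter = "duplication_ratio", mode = "all", labels = dup_labels),
    list(parameter = "nonhomolog_ratio", mode = "all", labels = nonhom_labels)
  )

  rows <- list()
  for (sp in mw_specs) {
    for (nm in names(collection$sets)) {
      r <- withCallingHandlers(
        eval_set_mannwhitney(collection$sets[[nm]], sp$values),
        warning = function(w) invokeRestart("muffleWarning"))
      if (is.null(r)) next
      rows[[length(rows) + 1L]] <- data.frame(
        set = nm, parameter = sp$parameter, homology_mode = sp$mode,
        n_set = r$n_set, statistic = r$statistic, effect = r$effect,
        p = r$p, stringsAsFactors = FALSE)
    }
  }
  for (sp in fisher_specs) {
    for (nm in names(collection$sets)) {
      r <- eval_set_fisher(collection$sets[[nm]], sp$labels)
      rows[[length(rows) + 1L]] <- data.frame(
        set = nm, parameter = sp$parameter, homology_mode = sp$mode,
        n_set = sum(names(sp$labels) %in% collection$sets[[nm]]),
        statistic = r$odds_ratio, effect = r$odds_ratio, p = r$p,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no set could be evaluated")
  rep_df <- do.call(rbind, rows)

  fam <- paste(rep_df$parameter, rep_df$homology_mode, sep = "/")
  rep_df$fdr <- NA_real_
  for (f in unique(fam)) {
    idx <- fam == f
    rep_df$fdr[idx] <- stats::p.adjust(rep_df$p[idx], method = "BH")
  }
  rep_df$significant <- rep_df$fdr < alpha
  rep_df$direction <- ifelse(
    rep_df$parameter %in% c("duplication_ratio", "nonhomolog_ratio"),
    ifelse(rep_df$effect > 1, "enriched",
           ifelse(rep_df$effect < 1, "depleted", "none")),
    ifelse(rep_df$effect > 0, "higher",
           ifelse(rep_df$effect < 0, "lower", "none")))

  # rank sets by conservation of co-expression (all-homolog mode)
  eff <- rep_df$effect[rep_df$parameter == "ccg_conservation" &
                         rep_df$homology_mode == "all"]
  names(eff) <- rep_df$set[rep_df$parameter == "ccg_conservation" &
                             rep_df$homology_mode == "all"]
  rank_key <- -eff[rep_df$set]
  rank_key[is.na(rank_key)] <- Inf
  ord <- order(rep_df$parameter, rep_df$homology_mode, rank_key, rep_df$set,
               method = "radix")
  rep_df <- rep_df[ord, , drop = FALSE]
  rownames(rep_df) <- NULL
  class(rep_df) <- c("conservation_report", class(rep_df))
  rep_df
}

#' @export
print.conservation_report <- function(x, ...) {
  cat("conservation_report:", length(unique(x$set)), "sets x",
      length(unique(paste(x$parameter, x$homology_mode))),
      "parameter/mode families;",
      sum(x$significant), "significant entries\n")
  NextMethod()
}

#' Write a conservation report as TSV
#'
#' @param report an [evaluate_collection()] result.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_conservation_report <- function(report, path) {
  data.table::fwrite(data.table::as.data.table(unclass(report)), path,
                     sep = "\t")
  invisible(path)
}
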