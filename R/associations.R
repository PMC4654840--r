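# Pair ids of a species-A gene set: every homolog pair whose gene_a is a
# set member and that carries a CCG overlap record.
set_pair_ids <- function(set_genes, ccg) {
  ccg$pairs$pair_id[ccg$pairs$gene_a %in% set_genes]
}

#' Candidate genes recurrently co-expressed with a gene set's homologs
#'
#' For every species-A gene that appears in the CCG overlaps of the set's
#' homolog pairs, counts in how many of those pairs' overlaps it occurs and
#' reports the relative frequency count / (number of set pairs).  Set
#' members themselves are excluded from candidacy by default (they trivially
#' co-occur with their own set).
#'
#' @param set_genes character species-A gene IDs of the set.
#' @param ccg a [ccg_all_pairs()] result (its per-pair overlap gene lists
#'   are the substrate).
#' @param exclude_set_members drop candidates that are set members.
#' @return data.frame with `gene`, `count`, `rel_freq`, ordered by
#'   decreasing rel_freq then gene ID, with attribute `n_set_pairs`.  Empty
#'   (with a warning) when the set has no homolog pairs.
#' @export
candidate_frequencies <- function(set_genes, ccg,
                                  exclude_set_members = TRUE) {
  stopifnot(inherits(ccg, "ccg_table"))
  pid <- set_pair_ids(set_genes, ccg)
  empty <- data.frame(gene = character(0), count = integer(0),
                      rel_freq = numeric(0), stringsAsFactors = FALSE)
  if (!length(pid)) {
    warning("gene set has no homolog pairs in the CCG table")
    attr(empty, "n_set_pairs") <- 0L
    return(empty)
  }
  ov <- ccg$overlaps[pid]
  genes <- unlist(ov, use.names = FALSE)
  if (exclude_set_members) genes <- genes[!(genes %in% set_genes)]
  if (!length(genes)) {
    attr(empty, "n_set_pairs") <- length(pid)
    return(empty)
  }
  tab <- table(genes)
  out <- data.frame(gene = names(tab), count = as.integer(tab),
                    rel_freq = as.integer(tab) / length(pid),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$rel_freq, out$gene, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_set_pairs") <- length(pid)
  out
}

#' Permutation significance of candidate-gene associations
#'
#' The null model redraws, `B` times, a uniform random subset of homolog
#' pairs of the same size as the set's pair list and recomputes each
#' candidate's relative frequency over it; resampling pairs (not genes)
#' preserves the one2many structure in the null.  The one-sided empirical
#' p-value per candidate is (1 + #\{perm rel_freq >= observed\}) / (B + 1)
#' ("at least as extreme" read as enrichment), followed by a
#' Benjamini-Hochberg correction across the set's candidates.
#'
#' @param set_genes character species-A gene IDs of the set.
#' @param ccg a [ccg_all_pairs()] result.
#' @param B number of permutations (default 1000; below 100 a resolution
#'   warning is emitted).
#' @param seed optional RNG seed.
#' @param exclude_set_members drop candidates that are set members.
#' @return object of class `association_result`: data.frame with `gene`,
#'   `count`, `rel_freq`, `p_empirical`, `fdr`, sorted by fdr then
#'   decreasing rel_freq; attributes `n_set_pairs`, `B`, `seed`.
#' @export
permutation_significance <- function(set_genes, ccg, B = 1000L, seed = NULL,
                                     exclude_set_members = TRUE) {
  stopifnot(inherits(ccg, "ccg_table"), B >= 1L)
  if (B < 100L) warning("B < 100 permutations: p-value resolution is coarse")
  freqs <- candidate_frequencies(set_genes, ccg,
                                 exclude_set_members = exclude_set_members)
  n_set_pairs <- attr(freqs, "n_set_pairs")
  if (!nrow(freqs)) {
    freqs$p_empirical <- numeric(0)
    freqs$fdr <- numeric(0)
    class(freqs) <- c("association_result", class(freqs))
    return(freqs)
  }
  if (!is.null(seed)) set.seed(seed)

  all_ids <- ccg$pairs$pair_id
  n_pairs <- length(all_ids)
  # candidate x pair incidence over all pairs
  M <- matrix(FALSE, nrow(freqs), n_pairs,
              dimnames = list(freqs$gene, all_ids))
  for (j in seq_len(n_pairs)) {
    hit <- match(ccg$overlaps[[j]], freqs$gene)
    hit <- hit[!is.na(hit)]
    if (length(hit)) M[hit, j] <- TRUE
  }
  storage.mode(M) <- "double"
  obs <- freqs$count
  exceed <- integer(nrow(freqs))
  for (b in seq_len(B)) {
    idx <- sample.int(n_pairs, n_set_pairs)
    perm_counts <- rowSums(M[, idx, drop = FALSE])
    exceed <- exceed + (perm_counts >= obs)
  }
  freqs$p_empirical <- (1 + exceed) / (B + 1)
  freqs$fdr <- stats::p.adjust(freqs$p_empirical, method = "BH")
  freqs <- freqs[order(freqs$fdr, -freqs$rel_freq, freqs$gene,
                       method = "radix"), , drop = FALSE]
  rownames(freqs) <- NULL
  attr(freqs, "n_set_pairs") <- n_set_pairs
  attr(freqs, "B") <- as.integer(B)
  attr(freqs, "seed") <- seed
  class(freqs) <- c("association_result", class(freqs))
  freqs
}

#' Write candidate-gene associations for a collection as one TSV
#'
#' Runs [permutation_significance()] for every set of a collection and
#' writes the stacked results (columns `set`, `gene`, `count`, `rel_freq`,
#' `p_empirical`, `fdr`).
#'
#' @param collection a [gene_set_collection()].
#' @param ccg a [ccg_all_pairs()] result.
#' @param path output TSV path.
#' @param B,seed passed to [permutation_significance()]; per-set seeds are
#'   derived deterministically from `seed`.
#' @return the stacked data.frame, invisibly.
#' @export
associate_collection <- function(collection, ccg, path = NULL, B = 1000L,
                                 seed = 1L) {
  stopifnot(inherits(collection, "gene_set_collection"))
  out <- list()
  nms <- names(collection$sets)
  for (i in seq_along(nms)) {
    res <- withCallingHandlers(
      permutation_significance(collection$sets[[i]], ccg, B = B,
                               seed = seed + i),
      warning = function(w) invokeRestart("muffleWarning"))
    if (!nrow(res)) next
    res_df <- as.data.frame(res)
    res_df <- cbind(set = nms[i], res_df, stringsAsFactors = FALSE)
    out[[length(out) + 1L]] <- res_df
  }
  stacked <- if (length(out)) do.call(rbind, out) else
    data.frame(set = character(0), gene = character(0), count = integer(0),
               rel_freq = numeric(0), p_empirical = numeric(0),
               fdr = numeric(0), stringsAsFactors = FALSE)
  rownames(stacked) <- NULL
  if (!is.null(path))
    data.table::fwrite(data.table::as.data.table(stacked), path, sep = "\t")
  invisible(stacked)
}
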