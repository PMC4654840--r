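#' Pipeline configuration
#'
#' Collects every threshold, permutation size and seed of the analysis in
#' one validated object.  Defaults follow the reference analysis: top 5 %
#' lists for CCG, 1 % threshold for the directed networks, 5 % ranked
#' extremes, minimum gene-set size 10, FDR 0.05, 10,000 Spearman
#' permutations and 1000 association permutations.  A resolved copy of the
#' configuration is written next to every run's outputs.
#'
#' @param out_dir output directory (created if missing).
#' @param generator a [generator_config()] for synthetic mode, or NULL.
#' @param map_a_path,map_b_path,homology_path,gmt_paths input files for real
#'   mode (long-form map TSVs, homology TSV, named character vector of GMT
#'   paths).
#' @param top_percent_ccg,top_percent_network,extremes_percent thresholds.
#' @param min_set_size gene-set size filter.
#' @param fdr_alpha significance threshold.
#' @param B_spearman,B_assoc permutation sizes.
#' @param ccg_aggregate gene-level CCG rule, `"max"` or `"mean"`.
#' @param seed master seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            generator = NULL,
                            map_a_path = NULL, map_b_path = NULL,
                            homology_path = NULL, gmt_paths = NULL,
                            top_percent_ccg = 5, top_percent_network = 1,
                            extremes_percent = 5, min_set_size = 10L,
                            fdr_alpha = 0.05, B_spearman = 10000L,
                            B_assoc = 1000L,
                            ccg_aggregate = c("max", "mean"), seed = 1L) {
  ccg_aggregate <- match.arg(ccg_aggregate)
  cfg <- list(out_dir = out_dir, generator = generator,
              map_a_path = map_a_path, map_b_path = map_b_path,
              homology_path = homology_path, gmt_paths = gmt_paths,
              top_percent_ccg = top_percent_ccg,
              top_percent_network = top_percent_network,
              extremes_percent = extremes_percent,
              min_set_size = as.integer(min_set_size),
              fdr_alpha = fdr_alpha,
              B_spearman = as.integer(B_spearman),
              B_assoc = as.integer(B_assoc),
              ccg_aggregate = ccg_aggregate, seed = as.integer(seed))
  for (pp in c("top_percent_ccg", "top_percent_network", "extremes_percent"))
    if (cfg[[pp]] <= 0 || cfg[[pp]] > 100)
      stop(pp, " must lie in (0, 100]", call. = FALSE)
  if (cfg$fdr_alpha <= 0 || cfg$fdr_alpha >= 1)
    stop("fdr_alpha must lie in (0, 1)", call. = FALSE)
  if (cfg$B_spearman < 1L || cfg$B_assoc < 1L)
    stop("permutation sizes must be positive", call. = FALSE)
  if (!is.null(generator)) validate_generator_config(generator)
  structure(cfg, class = "pipeline_config")
}

resolved_config_json <- function(cfg, path) {
  out <- cfg
  class(out) <- NULL
  if (!is.null(out$generator)) class(out$generator) <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

log_line <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S "), paste0(...))
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

run_stage <- function(name, expr, con = NULL) {
  log_line(con, "stage ", name, " ...")
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Simulate a synthetic world and write it to disk
#'
#' Writes per-dataset expression TSVs for both species, the homology TSV,
#' the planted gene sets as GMT, the ground truth table and a JSON manifest
#' recording the seed and an MD5 hash per file.  Identical seeds yield
#' byte-identical files and manifests.
#'
#' @param generator a [generator_config()].
#' @param out_dir output directory (created if missing).
#' @param seed RNG seed (default `generator$seed`).
#' @return invisibly, the manifest list.
#' @export
cmd_simulate <- function(generator = generator_config(), out_dir,
                         seed = generator$seed) {
  validate_generator_config(generator)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  world <- generate_world(generator, seed = seed)
  files <- character(0)
  for (side in c("a", "b")) {
    ds_list <- world[[paste0("datasets_", side)]]
    for (i in seq_along(ds_list)) {
      f <- file.path(out_dir,
                     sprintf("expr_%s_ds%03d.tsv", toupper(side), i))
      write_expression_dataset(ds_list[[i]], f)
      files <- c(files, f)
    }
  }
  f <- file.path(out_dir, "homology.tsv")
  data.table::fwrite(data.table::as.data.table(
    world$homology$pairs[, c("gene_a", "gene_b", "dn", "ds", "relationship")]),
    f, sep = "\t")
  files <- c(files, f)
  f <- file.path(out_dir, "gene_sets.gmt")
  write_gmt(world$sets, f)
  files <- c(files, f)
  f <- file.path(out_dir, "truth.tsv")
  data.table::fwrite(data.table::data.table(
    gene = names(world$truth$module_a),
    module = as.integer(world$truth$module_a),
    z = as.numeric(world$truth$z_gene_a),
    class = as.character(world$truth$class_a)), f, sep = "\t")
  files <- c(files, f)
  manifest <- list(seed = seed,
                   n_files = length(files),
                   files = as.list(stats::setNames(
                     unname(tools::md5sum(files)), basename(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Run the full conservation analysis end-to-end
#'
#' Orchestrates all stages on either a synthetic world (when
#' `config$generator` is set) or on real-mode input files: builds the two
#' vote-counting co-expression maps, the CCG table, the Spearman/permutation
#' association of CCG with dN/dS, the 1 % directed networks with
#' connectivity and DiffK, the ranked-extreme exports, the four-parameter
#' gene-set conservation report and the candidate-gene associations.  Every
#' artifact is written as plain TSV into `config$out_dir` together with the
#' resolved configuration and a log; any stage failure aborts with the
#' stage name.  Reruns with the same seed are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the main in-memory results.
#' @export
cmd_run <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  con <- file(file.path(cfg$out_dir, "run.log"), open = "wt")
  on.exit(close(con), add = TRUE)
  resolved_config_json(cfg, file.path(cfg$out_dir, "resolved_config.json"))
  log_line(con, "seed = ", cfg$seed,
           "; top_percent_ccg = ", cfg$top_percent_ccg,
           "; top_percent_network = ", cfg$top_percent_network,
           "; extremes_percent = ", cfg$extremes_percent,
           "; min_set_size = ", cfg$min_set_size,
           "; fdr_alpha = ", cfg$fdr_alpha,
           "; B_spearman = ", cfg$B_spearman,
           "; B_assoc = ", cfg$B_assoc)

  inputs <- run_stage("load_inputs", {
    if (!is.null(cfg$generator)) {
      world <- generate_world(cfg$generator, seed = cfg$seed)
      list(datasets_a = world$datasets_a, datasets_b = world$datasets_b,
           homology = world$homology, collections = list(
             synthetic = world$sets))
    } else {
      if (is.null(cfg$homology_path))
        stop("real mode requires homology_path")
      collections <- lapply(cfg$gmt_paths, read_gmt)
      if (is.null(names(collections)))
        names(collections) <- basename(unlist(cfg$gmt_paths))
      list(maps = list(
             a = read_coexpression_map(cfg$map_a_path, species = "A"),
             b = read_coexpression_map(cfg$map_b_path, species = "B")),
           homology = read_homology_table(cfg$homology_path),
           collections = collections)
    }
  }, con)

  maps <- run_stage("build_maps", {
    if (!is.null(inputs$maps)) inputs$maps
    else list(a = build_coexpression_map(inputs$datasets_a, "A"),
              b = build_coexpression_map(inputs$datasets_b, "B"))
  }, con)

  hom <- inputs$homology
  ccg <- run_stage("ccg", {
    res <- ccg_all_pairs(maps$a, maps$b, hom,
                         percent = cfg$top_percent_ccg,
                         aggregate = cfg$ccg_aggregate)
    write_ccg_table(res, file.path(cfg$out_dir, "ccg.tsv"))
    res
  }, con)

  assoc_dnds <- run_stage("spearman_ccg_dnds", {
    ok <- is.finite(ccg$pairs$dnds)
    if (sum(ok) >= 3L) {
      sp <- spearman_permutation(ccg$pairs$ccg_count[ok],
                                 ccg$pairs$dnds[ok],
                                 B = cfg$B_spearman, seed = cfg$seed)
      log_line(con, sprintf("Spearman(CCG, dN/dS): rho = %.4f, p = %.4g",
                            sp$rho, sp$p_empirical))
      sp
    } else NULL
  }, con)

  nets <- run_stage("networks", {
    n1 <- build_directed_network(maps$a, percent = cfg$top_percent_network)
    n2 <- build_directed_network(maps$b, percent = cfg$top_percent_network)
    write_edge_list(n1, file.path(cfg$out_dir, "network_a_edges.tsv"))
    write_edge_list(n2, file.path(cfg$out_dir, "network_b_edges.tsv"))
    write_connectivity(connectivity(n1),
                       file.path(cfg$out_dir, "connectivity_a.tsv"))
    write_connectivity(connectivity(n2),
                       file.path(cfg$out_dir, "connectivity_b.tsv"))
    list(a = n1, b = n2)
  }, con)

  diffk <- run_stage("diffk", {
    dk <- diffk_table(nets$a, nets$b, hom)
    write_diffk(dk, file.path(cfg$out_dir, "diffk.tsv"))
    dk
  }, con)

  run_stage("extremes", {
    ex <- rank_select_extremes(ccg$gene_level_a,
                               percent = cfg$extremes_percent)
    write_gene_list(ex$top, file.path(cfg$out_dir, "ccg_top_genes.txt"))
    write_gene_list(ex$bottom, file.path(cfg$out_dir, "ccg_bottom_genes.txt"))
    dk_gene <- tapply(diffk$folded, diffk$gene_a, mean)
    dk_gene <- stats::setNames(as.numeric(dk_gene), names(dk_gene))
    exd <- rank_select_extremes(dk_gene, percent = cfg$extremes_percent)
    write_gene_list(exd$top, file.path(cfg$out_dir, "diffk_top_genes.txt"))
    write_gene_list(exd$bottom,
                    file.path(cfg$out_dir, "diffk_bottom_genes.txt"))
  }, con)

  reports <- run_stage("evaluate", {
    out <- list()
    for (nm in names(inputs$collections)) {
      coll <- filter_min_size(inputs$collections[[nm]],
                              min_genes = cfg$min_set_size,
                              universe = hom$universe_a)
      rep_df <- evaluate_collection(coll, ccg, diffk, hom,
                                    alpha = cfg$fdr_alpha)
      write_conservation_report(
        rep_df, file.path(cfg$out_dir, paste0("report_", nm, ".tsv")))
      out[[nm]] <- rep_df
    }
    out
  }, con)

  assoc <- run_stage("associate", {
    out <- list()
    for (nm in names(inputs$collections)) {
      coll <- filter_min_size(inputs$collections[[nm]],
                              min_genes = cfg$min_set_size,
                              universe = hom$universe_a)
      out[[nm]] <- associate_collection(
        coll, ccg, path = file.path(cfg$out_dir,
                                    paste0("associations_", nm, ".tsv")),
        B = cfg$B_assoc, seed = cfg$seed)
    }
    out
  }, con)

  run_stage("diagnostics", {
    k1 <- connectivity(nets$a)
    fit <- degree_distribution_fit(k1)
    diag_df <- data.table::data.table(
      metric = c("ccg_skewness", "degree_fit_slope", "degree_fit_r2"),
      value = c(distribution_summary(ccg$pairs$ccg_count)$skewness,
                fit$slope, fit$r_squared))
    data.table::fwrite(diag_df, file.path(cfg$out_dir, "diagnostics.tsv"),
                       sep = "\t")
  }, con)

  log_line(con, "done")
  invisible(list(maps = maps, ccg = ccg, spearman_dnds = assoc_dnds,
                 networks = nets, diffk = diffk, reports = reports,
                 associations = assoc))
}
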