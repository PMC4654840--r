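#' Configuration for the synthetic two-species world generator
#'
#' The generator plants shared co-expression modules in two gene universes
#' linked by a mixed homology map and couples molecular evolution rates to a
#' per-module latent divergence, so that conservation of co-expression
#' connectivity is negatively associated with dN/dS by construction.
#'
#' Defaults describe the standard world used for end-to-end recovery:
#' 2000 genes per species organized in 40 modules of 25 genes (the rest is
#' unstructured background), expression over 50 datasets of 10 conditions
#' with unit Gaussian noise on a unit-variance module latent, a homology mix
#' of 70 % one2one / 8 % one2many / 6 % many2many / 16 % non-homologous
#' (roughly the human-mouse proportions), and per-module divergence z spread
#' evenly over \[0.05, 0.95\].
#'
#' @param n_genes genes per species (species B is padded/truncated by the
#'   homology draw; its universe size is close to `n_genes`).
#' @param n_modules,module_size module count and size;
#'   `n_modules * module_size <= n_genes`.
#' @param n_datasets,conditions_per_dataset expression compendium shape.
#' @param noise_sigma sd of the per-gene Gaussian noise on the module latent
#'   (the latent itself has sd 1).
#' @param module_divergence numeric vector in \[0, 1\], length `n_modules`:
#'   probability that a species-B homolog of a module gene loses the module.
#'   Default: evenly spaced over \[0.05, 0.95\].
#' @param p_one2one,p_one2many,p_many2many,p_nonhomolog homology class mix
#'   for species-A genes; must sum to 1.
#' @param duplication_mean_extra one2many partner count is
#'   2 + Poisson(`duplication_mean_extra`).
#' @param dnds_base,dnds_slope,dnds_shape dN/dS of a pair is Gamma with
#'   shape `dnds_shape` and mean
#'   `dnds_base + dnds_slope * z + class offset`.
#' @param class_offset_one2many,class_offset_many2many additive dN/dS mean
#'   offsets reproducing the one2one < one2many < many2many ordering.
#' @param ds_shape,ds_rate Gamma parameters of the dS draw (dN = ratio * dS).
#' @param n_null_sets,null_set_size number/size of planted null gene sets.
#' @param dup_set_size size of the planted duplication-enriched set.
#' @param seed default RNG seed of [generate_world()].
#' @return object of class `generator_config` (a validated list).
#' @export
generator_config <- function(n_genes = 2000L, n_modules = 40L,
                             module_size = 25L, n_datasets = 50L,
                             conditions_per_dataset = 10L, noise_sigma = 1,
                             module_divergence = NULL,
                             p_one2one = 0.70, p_one2many = 0.08,
                             p_many2many = 0.06, p_nonhomolog = 0.16,
                             duplication_mean_extra = 0.5,
                             dnds_base = 0.10, dnds_slope = 0.15,
                             dnds_shape = 2,
                             class_offset_one2many = 0.05,
                             class_offset_many2many = 0.10,
                             ds_shape = 4, ds_rate = 10,
                             n_null_sets = 20L, null_set_size = 25L,
                             dup_set_size = 30L, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_modules = as.integer(n_modules),
              module_size = as.integer(module_size),
              n_datasets = as.integer(n_datasets),
              conditions_per_dataset = as.integer(conditions_per_dataset),
              noise_sigma = noise_sigma,
              module_divergence = module_divergence,
              p_one2one = p_one2one, p_one2many = p_one2many,
              p_many2many = p_many2many, p_nonhomolog = p_nonhomolog,
              duplication_mean_extra = duplication_mean_extra,
              dnds_base = dnds_base, dnds_slope = dnds_slope,
              dnds_shape = dnds_shape,
              class_offset_one2many = class_offset_one2many,
              class_offset_many2many = class_offset_many2many,
              ds_shape = ds_shape, ds_rate = ds_rate,
              n_null_sets = as.integer(n_null_sets),
              null_set_size = as.integer(null_set_size),
              dup_set_size = as.integer(dup_set_size),
              seed = as.integer(seed))
  if (is.null(cfg$module_divergence)) {
    cfg$module_divergence <- seq(0.05, 0.95, length.out = cfg$n_modules)
  }
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  with(cfg, {
    if (n_genes < 1L || n_modules < 1L || module_size < 1L ||
        n_datasets < 1L || conditions_per_dataset < 2L)
      stop("generator counts must be positive (>= 2 conditions)")
    if (n_modules * module_size > n_genes)
      stop("module sizes exceed the gene universe")
    if (noise_sigma < 0) stop("noise_sigma must be >= 0")
    mix <- c(p_one2one, p_one2many, p_many2many, p_nonhomolog)
    if (any(mix < 0) || abs(sum(mix) - 1) > 1e-8)
      stop("homology mix probabilities must be non-negative and sum to 1")
    if (length(module_divergence) != n_modules ||
        any(module_divergence < 0 | module_divergence > 1))
      stop("module_divergence must be length n_modules with values in [0, 1]")
  })
  invisible(cfg)
}

#' Generate a synthetic two-species world
#'
#' Species-A genes are partitioned into co-expression modules plus an
#' unstructured background.  A homology class is drawn per A gene; species-B
#' partners are created accordingly (one2many genes receive 2+ duplicated
#' copies, many2many genes are paired up into 2x2 fully connected blocks
#' within a module).  Each B homolog keeps its source module with
#' probability 1 - z(module) and is otherwise reassigned uniformly over all
#' modules and the background; duplicated copies retain independently.
#' Non-homologous genes of both species live in the background.
#'
#' Expression per dataset and condition is the module latent activity
#' (standard normal, drawn independently per species) plus Gaussian noise
#' (sd `noise_sigma`); background genes are pure noise.  dN/dS per pair is
#' Gamma distributed with mean increasing linearly in the gene's divergence
#' z and by class offsets (one2one < one2many < many2many); dN = ratio * dS
#' with dS drawn from a Gamma.  Background homologs get an unrelated latent
#' divergence z ~ Uniform(0, 1).
#'
#' Planted gene sets (species-A IDs, GMT-compatible): `planted_conserved`
#' (genes of the two lowest-z modules), `planted_diverged` (two highest-z
#' modules), `planted_dup` (a draw of duplicated homologs) and
#' `n_null_sets` random draws of homologous genes (`null_01`, ...).
#'
#' The output is byte-deterministic given (`config`, `seed`).
#'
#' @param config a [generator_config()].
#' @param seed RNG seed (default `config$seed`).
#' @return list of class `synthetic_world` with elements `datasets_a`,
#'   `datasets_b` (lists of [expression_dataset()]), `homology`
#'   (a [homology_table()]), `sets` (a [gene_set_collection()]) and `truth`
#'   (module/divergence assignments and planted-set labels).
#' @export
generate_world <- function(config = generator_config(), seed = config$seed) {
  validate_generator_config(config)
  set.seed(seed)
  cf <- config
  n <- cf$n_genes
  nm <- cf$n_modules * cf$module_size
  genes_a <- sprintf("HSA%05d", seq_len(n))
  module_a <- c(rep(seq_len(cf$n_modules), each = cf$module_size),
                rep(0L, n - nm))
  z_mod <- cf$module_divergence
  z_gene_a <- ifelse(module_a > 0L, c(NA_real_, z_mod)[module_a + 1L],
                     stats::runif(n))

  cls <- sample(c("one2one", "one2many", "many2many", "none"), n,
                replace = TRUE,
                prob = c(cf$p_one2one, cf$p_one2many, cf$p_many2many,
                         cf$p_nonhomolog))

  # pair up many2many genes into 2x2 blocks within module (leftover genes
  # fall back to one2many with 2 copies)
  mm <- which(cls == "many2many")
  mm <- mm[order(module_a[mm], mm)]
  blocks <- list()
  if (length(mm)) {
    by_mod <- split(mm, module_a[mm])
    leftovers <- integer(0)
    for (g in by_mod) {
      nb <- length(g) %/% 2L
      if (nb) for (i in seq_len(nb))
        blocks[[length(blocks) + 1L]] <- g[c(2L * i - 1L, 2L * i)]
      if (length(g) %% 2L) leftovers <- c(leftovers, g[length(g)])
    }
    nb <- length(leftovers) %/% 2L
    if (nb) for (i in seq_len(nb))
      blocks[[length(blocks) + 1L]] <- leftovers[c(2L * i - 1L, 2L * i)]
    if (length(leftovers) %% 2L)
      cls[leftovers[length(leftovers)]] <- "one2many"
  }

  pair_a <- integer(0)   # A gene index per pair
  src_mod_b <- integer(0) # source module of the B gene of that pair
  b_of_pair <- integer(0) # B gene serial per pair
  b_serial <- 0L
  new_b <- function(k) {
    out <- b_serial + seq_len(k)
    b_serial <<- b_serial + k
    out
  }
  o2o <- which(cls == "one2one")
  if (length(o2o)) {
    bs <- new_b(length(o2o))
    pair_a <- c(pair_a, o2o)
    b_of_pair <- c(b_of_pair, bs)
    src_mod_b <- c(src_mod_b, module_a[o2o])
  }
  o2m <- which(cls == "one2many")
  for (a in o2m) {
    k <- 2L + stats::rpois(1L, cf$duplication_mean_extra)
    bs <- new_b(k)
    pair_a <- c(pair_a, rep.int(a, k))
    b_of_pair <- c(b_of_pair, bs)
    src_mod_b <- c(src_mod_b, rep.int(module_a[a], k))
  }
  for (blk in blocks) {
    bs <- new_b(2L)           # 2 A genes x 2 B genes, 4 pairs
    pair_a <- c(pair_a, rep(blk, each = 2L))
    b_of_pair <- c(b_of_pair, rep(bs, times = 2L))
    src_mod_b <- c(src_mod_b, module_a[rep(blk, each = 2L)])
  }

  # B gene module retention: per B gene (copies independent), keep the
  # source module with prob 1 - z, else uniform over modules + background
  n_b_hom <- b_serial
  first_pair <- match(seq_len(n_b_hom), b_of_pair)
  src_mod <- src_mod_b[first_pair]
  z_src <- ifelse(src_mod > 0L, c(0, z_mod)[src_mod + 1L], 0)
  lose <- stats::runif(n_b_hom) < z_src
  module_b_hom <- src_mod
  if (any(lose))
    module_b_hom[lose] <- sample(0:cf$n_modules, sum(lose), replace = TRUE)

  n_b_extra <- round(cf$p_nonhomolog * n)
  genes_b <- sprintf("MMU%05d", seq_len(n_b_hom + n_b_extra))
  module_b <- c(module_b_hom, rep(0L, n_b_extra))

  # dN/dS coupled to the A gene's divergence plus class offsets
  z_pair <- z_gene_a[pair_a]
  offset <- c(one2one = 0, one2many = cf$class_offset_one2many,
              many2many = cf$class_offset_many2many)
  cls_pair <- cls[pair_a]
  mean_r <- cf$dnds_base + cf$dnds_slope * z_pair + offset[cls_pair]
  ratio <- stats::rgamma(length(pair_a), shape = cf$dnds_shape,
                         rate = cf$dnds_shape / mean_r)
  ds <- stats::rgamma(length(pair_a), shape = cf$ds_shape, rate = cf$ds_rate)
  dn <- ratio * ds

  pairs <- data.frame(gene_a = genes_a[pair_a],
                      gene_b = genes_b[b_of_pair],
                      dn = dn, ds = ds, stringsAsFactors = FALSE)
  homology <- homology_table(pairs, universe_a = genes_a,
                             universe_b = genes_b)

  datasets_a <- gen_expression_datasets(genes_a, module_a, cf, "A")
  datasets_b <- gen_expression_datasets(genes_b, module_b, cf, "B")

  sets <- planted_sets(genes_a, module_a, z_mod, cls, cf)

  truth <- list(module_a = stats::setNames(module_a, genes_a),
                module_b = stats::setNames(module_b, genes_b),
                z_module = z_mod,
                z_gene_a = stats::setNames(z_gene_a, genes_a),
                class_a = stats::setNames(cls, genes_a),
                planted = attr(sets, "planted_labels"))

  structure(list(datasets_a = datasets_a, datasets_b = datasets_b,
                 homology = homology, sets = sets, truth = truth,
                 config = cf, seed = seed),
            class = "synthetic_world")
}

gen_expression_datasets <- function(genes, module, cf, prefix) {
  n <- length(genes)
  nc <- cf$conditions_per_dataset
  lapply(seq_len(cf$n_datasets), function(d) {
    lat <- matrix(stats::rnorm(cf$n_modules * nc), cf$n_modules, nc)
    vals <- matrix(stats::rnorm(n * nc, 0, max(cf$noise_sigma, 1e-8)), n, nc)
    idx <- module > 0L
    if (any(idx)) vals[idx, ] <- vals[idx, ] + lat[module[idx], ]
    expression_dataset(vals, genes = genes,
                       conditions = sprintf("c%02d", seq_len(nc)),
                       name = sprintf("%s_ds%03d", prefix, d))
  })
}

planted_sets <- function(genes_a, module_a, z_mod, cls, cf) {
  ord <- order(z_mod)
  low2 <- ord[seq_len(min(2L, length(ord)))]
  high2 <- rev(ord)[seq_len(min(2L, length(ord)))]
  sets <- list(
    planted_conserved = genes_a[module_a %in% low2],
    planted_diverged = genes_a[module_a %in% high2]
  )
  labels <- c(planted_conserved = "conserved", planted_diverged = "diverged")
  dup_pool <- genes_a[cls %in% c("one2many", "many2many")]
  if (length(dup_pool) >= 10L) {
    sets$planted_dup <- sample(dup_pool,
                               min(cf$dup_set_size, length(dup_pool)))
    labels["planted_dup"] <- "duplication-enriched"
  }
  hom_pool <- genes_a[cls != "none"]
  for (i in seq_len(cf$n_null_sets)) {
    nm <- sprintf("null_%02d", i)
    sets[[nm]] <- sample(hom_pool, min(cf$null_set_size, length(hom_pool)))
    labels[nm] <- "null"
  }
  out <- gene_set_collection(sets, source = "synthetic")
  attr(out, "planted_labels") <- labels
  out
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("synthetic_world (seed", x$seed, "):",
      length(x$truth$module_a), "A genes /",
      length(x$truth$module_b), "B genes,",
      nrow(x$homology$pairs), "homolog pairs,",
      length(x$datasets_a), "datasets x",
      x$config$conditions_per_dataset, "conditions\n")
  invisible(x)
}

#' Fast direct-map toy world (shortcut generator)
#'
#' Skips the expression layer and synthesizes two random co-expression maps
#' plus a random homology table directly; intended for fast unit tests and
#' brute-force oracle comparisons, not for exercising the vote-counting map
#' builder.
#'
#' @param n_a,n_b gene universe sizes.
#' @param p_nonhomolog fraction of species-A genes with no partner.
#' @param p_extra_partner probability that a homologous A gene gets a second
#'   B partner (creating one2many/many2many structure).
#' @param seed RNG seed.
#' @return list with `map_a`, `map_b` ([coexpression_map()]) and `table`
#'   (a [homology_table()]).
#' @export
generate_random_toy_world <- function(n_a = 50L, n_b = 50L,
                                      p_nonhomolog = 0.2,
                                      p_extra_partner = 0.15, seed = 1L) {
  set.seed(seed)
  genes_a <- sprintf("a%03d", seq_len(n_a))
  genes_b <- sprintf("b%03d", seq_len(n_b))
  rand_map <- function(genes, species) {
    m <- length(genes)
    v <- matrix(0, m, m)
    v[upper.tri(v)] <- stats::runif(m * (m - 1) / 2)
    v <- v + t(v)
    coexpression_map(species, genes, v)
  }
  hom_a <- genes_a[stats::runif(n_a) > p_nonhomolog]
  pa <- character(0); pb <- character(0)
  for (g in hom_a) {
    k <- 1L + stats::rbinom(1L, 1L, p_extra_partner)
    pb <- c(pb, sample(genes_b, k))
    pa <- c(pa, rep(g, k))
  }
  keep <- !duplicated(paste(pa, pb))
  pairs <- data.frame(gene_a = pa[keep], gene_b = pb[keep],
                      dn = stats::runif(sum(keep), 0, 0.5),
                      ds = stats::runif(sum(keep), 0.1, 1),
                      stringsAsFactors = FALSE)
  list(map_a = rand_map(genes_a, "A"), map_b = rand_map(genes_b, "B"),
       table = homology_table(pairs, universe_a = genes_a,
                              universe_b = genes_b))
}
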