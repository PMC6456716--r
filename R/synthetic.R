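#' Configuration for the synthetic study generator
#'
#' Defines the shape and statistical structure of a simulated MeRIP-seq
#' study: genes fall into latent co-regulated modules sharing a per-module
#' condition factor, m6A sites inherit the module of their host gene, and
#' diseases attach to the genes of one or two modules. Defaults mirror a
#' desk-scale version of the real study design (38 experimental
#' conditions).
#'
#' @param n_diseases,n_genes,n_sites,n_conditions,n_modules Counts; the
#'   condition count defaults to 38.
#' @param corr_strength Target within-module Pearson correlation of the
#'   latent profiles, in (0, 1).
#' @param noise_sd Scale of the idiosyncratic noise relative to the
#'   factor-implied level; at 1 the within-module correlation equals
#'   `corr_strength` exactly in expectation.
#' @param frac_disease_genes Fraction of a module's genes linked to a
#'   disease that carries the module.
#' @param mesh_vocab_size,terms_per_disease MeSH vocabulary size and terms
#'   drawn per disease.
#' @param n_replicated_conditions How many leading conditions emit two
#'   technical replicate columns (exercises replicate merging).
#' @param rng_seed Integer seed; all outputs are reproducible from it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_diseases = 50L, n_genes = 300L, n_sites = 800L,
                         n_conditions = 38L, n_modules = 10L,
                         corr_strength = 0.8, noise_sd = 1,
                         frac_disease_genes = 0.5,
                         mesh_vocab_size = 150L, terms_per_disease = 8L,
                         n_replicated_conditions = 6L, rng_seed = 7L) {
  cfg <- list(
    n_diseases = as.integer(n_diseases), n_genes = as.integer(n_genes),
    n_sites = as.integer(n_sites), n_conditions = as.integer(n_conditions),
    n_modules = as.integer(n_modules), corr_strength = corr_strength,
    noise_sd = noise_sd, frac_disease_genes = frac_disease_genes,
    mesh_vocab_size = as.integer(mesh_vocab_size),
    terms_per_disease = as.integer(terms_per_disease),
    n_replicated_conditions = as.integer(n_replicated_conditions),
    rng_seed = as.integer(rng_seed)
  )
  counts <- c(cfg$n_diseases, cfg$n_genes, cfg$n_sites, cfg$n_conditions,
              cfg$n_modules)
  if (any(counts < 1)) abort("all counts must be >= 1")
  if (cfg$n_modules > cfg$n_genes) abort("more modules than genes is infeasible")
  if (!(corr_strength > 0 && corr_strength < 1)) abort("corr_strength must lie in (0, 1)")
  if (!(frac_disease_genes > 0 && frac_disease_genes <= 1)) {
    abort("frac_disease_genes must lie in (0, 1]")
  }
  if (noise_sd <= 0) abort("noise_sd must be > 0")
  structure(cfg, class = "synth_config")
}

pad_ids <- function(prefix, n) sprintf("%s%0*d", prefix, nchar(n), seq_len(n))

#' Simulate a seeded synthetic methylation study
#'
#' Generates all inputs the pipeline consumes — site IP/Input RPKM tables,
#' a gene RPKM table (with replicate columns and a replicate map), a site
#' annotation table, a disease-gene association list with over/under
#' labels, a disease-MeSH term table — plus the planted truth: the
#' disease-site pairs whose host-gene modules match the disease's modules.
#' Everything is reproducible from `config$rng_seed`.
#'
#' @param config A [synth_config()].
#' @return A `synth_study` list of tibbles: `site_ip`, `site_input`,
#'   `gene_rpkm`, `sites`, `replicate_map`, `disease_gene`,
#'   `disease_terms`, `truth`, and the `config`.
#' @export
simulate_study <- function(config = synth_config()) {
  if (!inherits(config, "synth_config")) abort("`config` must come from synth_config()")
  set.seed(config$rng_seed)
  K <- config$n_modules
  C <- config$n_conditions
  rho <- config$corr_strength

  conditions <- pad_ids("C", C)
  gene_ids <- pad_ids("G", config$n_genes)
  site_ids <- pad_ids("S", config$n_sites)
  disease_ids <- pad_ids("D", config$n_diseases)

  gene_module <- sample(rep_len(seq_len(K), config$n_genes))
  FF <- matrix(rnorm(K * C), K, C)

  latent <- function(mod, n) {
    sqrt(rho) * FF[mod, , drop = FALSE] +
      sqrt(1 - rho) * config$noise_sd * matrix(rnorm(n * C), n, C)
  }
  z_gene <- latent(gene_module, config$n_genes)
  mu_gene <- runif(config$n_genes, log(5), log(50))
  gene_rpkm_core <- exp(mu_gene + 0.5 * z_gene)

  host <- sample(config$n_genes, config$n_sites, replace = TRUE)
  site_module <- gene_module[host]
  mu_site <- rnorm(config$n_sites, 0, 0.7)
  m_target <- mu_site + latent(site_module, config$n_sites)
  input_core <- exp(runif(config$n_sites, log(5), log(50)) +
                      0.3 * matrix(rnorm(config$n_sites * C), config$n_sites, C))
  ip_core <- (input_core + 0.1) * 2^m_target - 0.1
  ip_core[ip_core < 0] <- 0

  # replicate columns: the first n_replicated_conditions conditions appear
  # twice with multiplicative log-normal jitter
  n_rep <- min(config$n_replicated_conditions, C)
  rep_cols <- c(
    if (n_rep > 0) paste0(conditions[seq_len(n_rep)], "_r1"),
    if (n_rep > 0) paste0(conditions[seq_len(n_rep)], "_r2"),
    if (C > n_rep) conditions[(n_rep + 1):C]
  )
  rep_group <- c(
    if (n_rep > 0) conditions[seq_len(n_rep)],
    if (n_rep > 0) conditions[seq_len(n_rep)],
    if (C > n_rep) conditions[(n_rep + 1):C]
  )
  ord <- order(match(rep_group, conditions))
  rep_cols <- rep_cols[ord]
  rep_group <- rep_group[ord]
  expand <- function(core) {
    out <- core[, match(rep_group, conditions), drop = FALSE]
    jitter <- matrix(exp(rnorm(length(out), 0, 0.05)), nrow(out), ncol(out))
    dup <- rep_cols %in% paste0(conditions[seq_len(n_rep)], "_r2") |
      rep_cols %in% paste0(conditions[seq_len(n_rep)], "_r1")
    out[, dup] <- out[, dup] * jitter[, dup]
    colnames(out) <- rep_cols
    out
  }
  site_ip <- expand(ip_core)
  site_input <- expand(input_core)
  gene_rpkm <- expand(gene_rpkm_core)

  support <- ifelse(runif(config$n_sites) < 0.9,
                    rpois(config$n_sites, 25), rpois(config$n_sites, 6))
  start <- sample.int(2e8, config$n_sites)
  sites <- tibble(
    site_id = site_ids,
    chrom = paste0("chr", sample(1:22, config$n_sites, replace = TRUE)),
    start = start,
    end = start + 101L,
    strand = sample(c("+", "-"), config$n_sites, replace = TRUE),
    host_gene = gene_ids[host],
    support_count = as.integer(support)
  )

  modules_per_disease <- sample(1:2, config$n_diseases, replace = TRUE)
  disease_modules <- lapply(seq_len(config$n_diseases), function(i) {
    sample(K, modules_per_disease[i])
  })
  # within each module a third of the genes are "recurrently implicated":
  # diseases carrying the module pick them with 9-fold higher odds, so
  # related diseases share specific genes (not just a module), as curated
  # disease-gene resources do
  gene_popularity <- numeric(config$n_genes)
  for (k in seq_len(K)) {
    idx <- which(gene_module == k)
    hot <- sample(idx, max(1, round(length(idx) / 3)))
    gene_popularity[idx] <- 1
    gene_popularity[hot] <- 9
  }
  dg <- purrr::list_rbind(lapply(seq_len(config$n_diseases), function(i) {
    genes <- unlist(lapply(disease_modules[[i]], function(k) {
      idx <- which(gene_module == k)
      n_pick <- max(1, round(config$frac_disease_genes * length(idx)))
      gene_ids[sample(idx, n_pick, prob = gene_popularity[idx])]
    }))
    genes <- unique(genes)
    tibble(disease = disease_ids[i], gene = genes,
           regulation = sample(c("over", "under"), length(genes), replace = TRUE))
  }))

  vocab <- sprintf("MESH%03d", seq_len(config$mesh_vocab_size))
  module_pool <- lapply(seq_len(K), function(k) sample(vocab, 12))
  global_pool <- sample(vocab, min(30, config$mesh_vocab_size))
  n_mod_terms <- max(1, round(0.6 * config$terms_per_disease))
  disease_terms <- purrr::list_rbind(lapply(seq_len(config$n_diseases), function(i) {
    pool <- unique(unlist(module_pool[disease_modules[[i]]]))
    terms <- unique(c(
      sample(pool, min(n_mod_terms, length(pool))),
      sample(global_pool, config$terms_per_disease - n_mod_terms)
    ))
    tibble(disease = disease_ids[i], term = terms)
  }))

  truth <- purrr::list_rbind(lapply(seq_len(config$n_diseases), function(i) {
    tibble(disease = disease_ids[i],
           site_id = site_ids[site_module %in% disease_modules[[i]]])
  }))

  as_table <- function(m, idcol, ids) {
    out <- dplyr::bind_cols(tibble(id = ids), as_tibble(m))
    names(out)[1] <- idcol
    out
  }
  structure(
    list(
      site_ip = as_table(site_ip, "site_id", site_ids),
      site_input = as_table(site_input, "site_id", site_ids),
      gene_rpkm = as_table(gene_rpkm, "gene_id", gene_ids),
      sites = sites,
      replicate_map = tibble(condition_id = rep_cols, group = rep_group),
      disease_gene = dg,
      disease_terms = disease_terms,
      truth = truth,
      gene_module = tibble(gene = gene_ids, module = gene_module),
      config = config
    ),
    class = "synth_study"
  )
}

#' @export
print.synth_study <- function(x, ...) {
  cat("<synth_study: ", x$config$n_diseases, " diseases, ",
      x$config$n_genes, " genes, ", x$config$n_sites, " sites, ",
      x$config$n_conditions, " conditions (seed ", x$config$rng_seed, ")>\n",
      sep = "")
  invisible(x)
}

#' Write a synthetic study to TSV files
#'
#' Emits every table of a [simulate_study()] result in the formats the
#' readers of the other modules expect.
#'
#' @param study A `synth_study`.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(site_ip = "site_ip_rpkm.tsv", site_input = "site_input_rpkm.tsv",
             gene_rpkm = "gene_rpkm.tsv", sites = "sites.tsv",
             replicate_map = "replicate_map.tsv",
             disease_gene = "disease_gene.tsv",
             disease_terms = "disease_terms.tsv", truth = "truth.tsv")
  for (nm in names(files)) {
    readr::write_tsv(study[[nm]], file.path(dir, files[nm]))
  }
  jsonlite::write_json(unclass(study$config), file.path(dir, "synth_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
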