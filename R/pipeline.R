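#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end pipeline with the method's
#' published defaults: strict support filter > 10 experiments, mean-level
#' 70th percentile, top-80-percentile variance, Bonferroni-adjusted
#' correlation cut-off 0.05 with top/bottom 10 percentile band, restart
#' probability 0.75, convergence threshold 1e-10, 100 random networks with
#' 10 attempted swaps per edge, and a prediction report of the top 100
#' sites at empirical significance 0.1.
#'
#' @param input_dir Directory holding the input TSVs (as written by
#'   [write_study()]).
#' @param ... Overrides for any default listed above.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir, ...) {
  cfg <- list(
    input_dir = input_dir,
    min_support = 10, level_pct = 70, var_pct = 80, level_rule = "le_pct",
    alpha = 0.05, pct = 10,
    r = 0.75, tol = 1e-10, max_iter = 1000L,
    n_networks = 100L, swaps_per_edge = 10,
    column_policy = "redistribute",
    top_k = 100L, sig_level = 0.1,
    run_significance = TRUE, run_evaluation = TRUE,
    cv_folds = 10L,
    rng_seed = 1L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) abort(paste0("unknown config field(s): ",
                                    paste(unknown, collapse = ", ")))
  structure(modifyList(cfg, overrides), class = "pipeline_config")
}

#' Build the five association networks from input tables
#'
#' Runs the profile stage (replicate merging, M-value computation, quantile
#' normalization, site filtering) and derives the correlation networks
#' (site-site, gene-gene, gene-site), the MeSH disease similarity network
#' and the disease-gene bipartite network.
#'
#' @param study A `synth_study` or a named list with elements `site_ip`,
#'   `site_input`, `gene_rpkm`, `sites`, `replicate_map` (or `NULL`),
#'   `disease_gene`, `disease_terms`.
#' @param config A [pipeline_config()] (input_dir unused here).
#' @return Named list: the five `assoc_net`s (`dd`, `gg`, `ss`, `dg`,
#'   `sg`), plus the filtered `meth` profile and the `expr` profile.
#' @export
build_networks <- function(study, config = pipeline_config(NULL)) {
  meth <- build_methylation_profile(study$site_ip, study$site_input,
                                    study$sites,
                                    replicate_map = study$replicate_map)
  meth <- filter_sites(meth, min_support = config$min_support,
                       level_pct = config$level_pct, var_pct = config$var_pct,
                       level_rule = config$level_rule)
  expr <- build_expression_profile(study$gene_rpkm,
                                   replicate_map = study$replicate_map)
  ss <- build_correlation_network(meth, alpha = config$alpha, pct = config$pct,
                                  layer_pair = "SS")
  gg <- build_correlation_network(expr, alpha = config$alpha, pct = config$pct,
                                  layer_pair = "GG")
  sg <- build_correlation_network(meth, expr, alpha = config$alpha,
                                  pct = config$pct, layer_pair = "SG")
  dd <- build_disease_network(study$disease_terms)
  dg <- load_disease_gene(study$disease_gene)
  list(dd = dd, gg = gg, ss = ss, dg = dg, sg = sg, meth = meth, expr = expr)
}

read_study_dir <- function(dir) {
  need <- c(site_ip = "site_ip_rpkm.tsv", site_input = "site_input_rpkm.tsv",
            gene_rpkm = "gene_rpkm.tsv", sites = "sites.tsv",
            disease_gene = "disease_gene.tsv", disease_terms = "disease_terms.tsv")
  paths <- file.path(dir, need)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    abort(paste0("missing input file(s): ", paste(missing, collapse = ", ")))
  }
  rep_path <- file.path(dir, "replicate_map.tsv")
  list(
    site_ip = read_rpkm_table(paths[1]),
    site_input = read_rpkm_table(paths[2]),
    gene_rpkm = read_rpkm_table(paths[3]),
    sites = read_site_table(paths[4]),
    disease_gene = utils::read.delim(paths[5], colClasses = "character"),
    disease_terms = read_disease_terms(paths[6]),
    replicate_map = if (file.exists(rep_path)) read_replicate_map(rep_path) else NULL
  )
}

#' Run the full prioritisation pipeline
#'
#' Orchestrates: input reading, profile construction and filtering,
#' association-network building, transition-matrix assembly, per-disease
#' restart walks with site ranking, optional permutation significance and
#' methylation-direction calls, optional cross-validated evaluation, and a
#' reproducibility manifest. Every stage logs to `stderr`.
#'
#' @param config A [pipeline_config()] whose `input_dir` holds the input
#'   TSVs.
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly. Outputs: `network/` (serialized
#'   heterogeneous network), `predictions/<disease>.tsv` (ranked sites with
#'   empirical p and direction), `evaluation/report.json` and ROC point
#'   TSVs, `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  stage <- function(msg) inform(paste0("[methylwalk] ", msg))
  stage(paste0("reading inputs from ", config$input_dir))
  study <- read_study_dir(config$input_dir)

  stage("building profiles and association networks")
  nets <- build_networks(study, config)

  stage("assembling heterogeneous network")
  het <- assemble_hetnet(nets$dd, nets$gg, nets$ss, nets$dg, nets$sg,
                         column_policy = config$column_policy)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_hetnet(het, file.path(out_dir, "network"))

  diseases <- het$registry$node[het$registry$layer == "disease"]
  stage(paste0("ranking sites for ", length(diseases), " diseases"))
  sig <- NULL
  if (config$run_significance && config$n_networks > 0) {
    stage(paste0("permutation significance over ", config$n_networks,
                 " random networks"))
    sig <- rwr_significance(nets, diseases, n_networks = config$n_networks,
                            rng_seed = config$rng_seed,
                            swaps_per_edge = config$swaps_per_edge,
                            r = config$r, tol = config$tol,
                            column_policy = config$column_policy)
  }
  reg_attr <- attr(nets$dg, "regulation")
  sign_map <- if (!is.null(reg_attr)) {
    setNames(reg_attr$regulation, paste(reg_attr$disease, reg_attr$gene))
  }
  pred_dir <- file.path(out_dir, "predictions")
  dir.create(pred_dir, showWarnings = FALSE)
  for (d in diseases) {
    if (is.null(sig)) {
      res <- rwr(het, d, r = config$r, tol = config$tol,
                 max_iter = config$max_iter)
      ranked <- rank_sites(res)
      ranked$empirical_p <- NA_real_
    } else {
      ranked <- sig[sig$disease == d, c("site_id", "probability", "empirical_p")]
      ranked$rank <- seq_len(nrow(ranked))
    }
    top <- head(ranked, config$top_k)
    d_genes <- nets$dg$to[nets$dg$from == d]
    gsign <- if (!is.null(sign_map)) {
      setNames(unname(sign_map[paste(d, d_genes)]), d_genes)
    }
    dirs <- purrr::list_rbind(lapply(top$site_id, function(s) {
      if (!(s %in% nets$meth$ids)) {
        return(tibble(direction = NA_character_, median_corr = NA_real_))
      }
      direction_of_association(nets$meth$values[s, ], d_genes, nets$expr, gsign)
    }))
    out <- dplyr::bind_cols(top, dirs)
    out$significant <- !is.na(out$empirical_p) & out$empirical_p < config$sig_level
    readr::write_tsv(out, file.path(pred_dir, paste0(d, ".tsv")))
  }

  if (config$run_evaluation) {
    stage(paste0(config$cv_folds, "-fold cross-validated evaluation"))
    plan <- make_folds(nets$dg, k = config$cv_folds, rng_seed = config$rng_seed)
    cv <- cross_validate(nets, plan, r = config$r, tol = config$tol,
                         rng_seed = config$rng_seed,
                         column_policy = config$column_policy)
    eval_dir <- file.path(out_dir, "evaluation")
    dir.create(eval_dir, showWarnings = FALSE)
    jsonlite::write_json(
      list(overall = glance(cv), per_disease = tidy(cv)),
      file.path(eval_dir, "report.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows"
    )
    for (m in names(cv$roc)) {
      readr::write_tsv(tidy(cv$roc[[m]]),
                       file.path(eval_dir, paste0("roc_", m, ".tsv")))
    }
  }

  manifest <- list(
    package = "methylwalk",
    version = as.character(utils::packageVersion("methylwalk")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    rng_seed = config$rng_seed,
    config = unclass(config),
    config_hash = rlang::hash(unclass(config))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  stage("done")
  invisible(out_dir)
}
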