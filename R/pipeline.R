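#' Validate a pipeline configuration
#'
#' Schema and cross-field checks for [run_pipeline()]: a seed is mandatory
#' (no unseeded stage runs), stage dependencies are enforced (the proxy
#' stage needs the meQTL stage; the response stage needs the proxy stage for
#' patterns containing proxyDNAm), and numeric fields must be in range.
#'
#' @param config list (or path to a YAML file) with elements `seed`,
#'   `sim` (arguments for [sim_config()]), `stages` (character vector of
#'   stage names to run) and optional per-stage parameter lists.
#' @return the normalized config, invisibly; violations abort with the full
#'   list of problems.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  problems <- character()
  if (is.null(config$seed)) problems <- c(problems, "missing `seed`")
  all_stages <- c("simulate", "outcomes", "risk_scores", "dmr", "meqtl",
                  "coloc", "ewas", "refine", "proxy", "response")
  stages <- config$stages %||% all_stages
  unknown <- setdiff(stages, all_stages)
  if (length(unknown)) {
    problems <- c(problems, paste0("unknown stage(s): ",
                                   paste(unknown, collapse = ", ")))
  }
  if ("proxy" %in% stages && !"meqtl" %in% stages) {
    problems <- c(problems, "proxy stage requires the meqtl stage")
  }
  if ("response" %in% stages && !"proxy" %in% stages) {
    problems <- c(problems, "response stage requires the proxy stage")
  }
  if (length(problems)) {
    abort(paste0("invalid pipeline config:\n- ",
                 paste(problems, collapse = "\n- ")))
  }
  config$stages <- stages
  invisible(config)
}

#' Run the analysis pipeline end to end
#'
#' Orchestrates simulation (or supplied data), outcome derivation, risk
#' scoring, differential methylation/DMRs, the meQTL scan, colocalization,
#' EWAS, candidate refinement, proxy-model training and the
#' combination-pattern response models with decision curves. Per-stage
#' result tables are written under `outdir` (TSV) when it is given, and a
#' manifest records stages, seeds and timing. Fully deterministic under the
#' config seed.
#'
#' @param config see [validate_config()]; `config$sim` is passed to
#'   [sim_config()].
#' @param outdir optional output directory for per-stage TSVs.
#' @return list of stage outputs plus `manifest`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  config <- validate_config(config)
  seed <- check_seed(config$seed)
  t0 <- Sys.time()
  stages <- config$stages
  out <- list()
  sim_args <- config$sim %||% list()
  sim_args$seed <- seed
  cfg <- do.call(sim_config, sim_args)
  cohort <- simulate_cohort(cfg)
  out$cohort <- cohort
  ph <- cohort$phenotypes
  cases <- which(ph$is_case)
  covars <- dplyr::select(ph, "age", "sex")

  if ("risk_scores" %in% stages) {
    pcs <- genotype_pcs(cohort$genotypes, 0.95)
    n_pc <- min(ncol(pcs), 10L)
    prs <- prs_score(cohort$summary_stats, cohort$genotypes,
                     as.integer(ph$is_case),
                     covariates = pcs[, seq_len(n_pc), drop = FALSE],
                     n_permutations = config$prs_permutations %||% 100,
                     seed = seed + 10)
    out$prs <- prs
  }
  if ("dmr" %in% stages) {
    site_risk <- site_dm_test(cohort$methylome, ph$is_case,
                              covariates = covars, contrast = "risk")
    risk_dmrs <- dmr_detect(site_risk, cohort$methylome$cpg_meta)
    res_ph <- ph[cases, ]
    site_res <- site_dm_test(
      subset_methylome(cohort$methylome, cases),
      res_ph$res_label, covariates = covars[cases, ], contrast = "response"
    )
    res_dmrs <- dmr_detect(site_res, cohort$methylome$cpg_meta)
    out$site_risk <- site_risk
    out$risk_dmrs <- risk_dmrs
    out$res_dmrs <- res_dmrs
  }
  if ("meqtl" %in% stages) {
    out$meqtls <- meqtl_scan(cohort$genotypes, cohort$methylome,
                             covariates = covars,
                             threshold = config$meqtl_threshold %||% 1e-8)
  }
  if ("ewas" %in% stages) {
    out$ewas <- ewas_scan(subset_methylome(cohort$methylome, cases),
                          ph$scaled_rate[cases],
                          covariates = covars[cases, ])
  }
  if ("refine" %in% stages && all(c("dmr", "meqtl") %in% stages)) {
    out$asm_genes <- asm_gene_set(out$meqtls, out$risk_dmrs, out$res_dmrs,
                                  cohort$methylome$cpg_meta)
  }
  if ("proxy" %in% stages) {
    split <- split_cohort(ph$sample_id, 0.7, seed + 20)
    tr <- match(split$train, ph$sample_id)
    te <- match(split$test, ph$sample_id)
    sig <- out$meqtls[out$meqtls$is_meqtl, ]
    target_cpgs <- head(unique(sig$cpg_id), config$max_proxies %||% 5L)
    models <- purrr::map(target_cpgs, function(cg) {
      train_proxy(subset_genotypes(cohort$genotypes, tr),
                  subset_methylome(cohort$methylome, tr),
                  covars[tr, ], cg, sig, algorithm = "rf",
                  search_budget = config$search_budget %||% 5,
                  cv_folds = 5, seed = seed + 30)
    })
    sel <- evaluate_and_select(models,
                               subset_genotypes(cohort$genotypes, te),
                               subset_methylome(cohort$methylome, te),
                               covars[te, ])
    out$proxy <- sel
  }
  if ("response" %in% stages) {
    proxy_feats <- impute_methylation(out$proxy$kept, cohort$genotypes,
                                      covars)
    prs_tbl <- out$prs$scores
    names(prs_tbl)[2] <- "scz"
    grs_tbl <- grs_score(
      dplyr::transmute(cohort$truth$disease_snps,
                       snp_id = .data$snp_id,
                       effect_allele = cohort$genotypes$snp_meta$effect_allele[
                         match(.data$snp_id, cohort$genotypes$snp_meta$snp_id)],
                       weight = .data$weight),
      cohort$genotypes
    )
    fs <- assemble_features(ph, prs = prs_tbl, grs = grs_tbl,
                            proxydnam = proxy_feats, pattern = "C+PGM")
    model <- train_response_model(fs, algorithm = "rf",
                                  search_budget = config$search_budget %||% 5,
                                  cv_folds = 5, seed = seed + 40)
    out$response_model <- model
    out$response_eval <- evaluate_model(model, fs)
  }
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(out$meqtls)) write_table(out$meqtls,
                                          file.path(outdir, "meqtls.tsv"))
    if (!is.null(out$risk_dmrs)) {
      write_table(dplyr::select(out$risk_dmrs, -"cpgs"),
                  file.path(outdir, "risk_dmrs.tsv"))
    }
    if (!is.null(out$ewas)) write_table(out$ewas,
                                        file.path(outdir, "ewas.tsv"))
  }
  out$manifest <- tibble::tibble(
    stage = stages, seed = seed,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  out
}

#' Subset containers by sample index
#' @param genotypes a [genotype_matrix()].
#' @param idx integer or logical sample index.
#' @return the subset container.
#' @export
subset_genotypes <- function(genotypes, idx) {
  genotype_matrix(genotypes$dosages[idx, , drop = FALSE],
                  genotypes$snp_meta)
}

#' @rdname subset_genotypes
#' @param methylome a [methylation_matrix()].
#' @export
subset_methylome <- function(methylome, idx) {
  methylation_matrix(methylome$betas[idx, , drop = FALSE],
                     methylome$cpg_meta)
}
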