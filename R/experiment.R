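#' Discovery-to-validation combination-pattern experiment
#'
#' Runs the full external-validation protocol on synthetic cohorts with
#' planted mediation of treatment response through meQTL-driven CpGs:
#' a discovery and a validation cohort are drawn as disjoint sample sets
#' from one generative population; PRS weights/threshold, GRS, proxy
#' methylation models and the response models are all fitted using
#' discovery data only, and the validation cohort is scored untouched.
#' Compared patterns: clinical + PRS (`C+P`) versus
#' clinical + PRS + GRS + proxyDNAm (`C+PGM`).
#'
#' @param seed integer seed driving the whole replicate.
#' @param n_discovery,n_validation cohort sizes (cases only; both cohorts
#'   are randomized-trial cases).
#' @param n_snps,n_cpgs panel sizes.
#' @param search_budget random-search draws per model fit.
#' @param cv_folds CV folds for tuning.
#' @param thresholds DCA threshold grid.
#' @return tibble with one row: validation AUCs and standardized net
#'   benefit summaries for both patterns, plus discovery CV diagnostics.
#' @export
external_validation_experiment <- function(seed, n_discovery = 800,
                                           n_validation = 400,
                                           n_snps = 300, n_cpgs = 150,
                                           search_budget = 3, cv_folds = 5,
                                           thresholds = seq(0.1, 0.9,
                                                            by = 0.1)) {
  seed <- check_seed(seed)
  cfg <- sim_config(
    n_cases = n_discovery + n_validation, n_controls = 0,
    n_snps = n_snps, n_cpgs = n_cpgs,
    n_meqtl = 20, meqtl_beta = 1.0,
    n_response_cpgs = 6, response_cpg_effect = -8, sigma_r = 15,
    seed = seed
  )
  co <- simulate_cohort(cfg)
  ph <- co$phenotypes
  idx_d <- seq_len(n_discovery)
  idx_v <- n_discovery + seq_len(n_validation)
  g_d <- subset_genotypes(co$genotypes, idx_d)
  g_v <- subset_genotypes(co$genotypes, idx_v)
  m_d <- subset_methylome(co$methylome, idx_d)
  ph_d <- ph[idx_d, ]
  ph_v <- ph[idx_v, ]
  covars <- dplyr::select(ph, "age", "sex")

  # PRS: threshold chosen on discovery, scores for everyone at that
  # threshold (the score itself is phenotype-free)
  pr_d <- prs_score(co$summary_stats, g_d, ph_d$scaled_rate,
                    n_permutations = 0, seed = seed + 1)
  pr_all <- prs_score(co$summary_stats, co$genotypes, ph$scaled_rate,
                      thresholds = pr_d$best_threshold,
                      n_permutations = 0, seed = seed + 1)
  prs_tbl <- dplyr::rename(pr_all$scores, scz = "score")

  # GRS: fixed external weight panel (the planted liability SNPs)
  grs_tbl <- grs_score(
    tibble::tibble(
      snp_id = co$truth$disease_snps$snp_id,
      effect_allele = co$genotypes$snp_meta$effect_allele[
        match(co$truth$disease_snps$snp_id, co$genotypes$snp_meta$snp_id)],
      weight = co$truth$disease_snps$weight),
    co$genotypes)

  # proxy models: meQTL scan and training on discovery only; selection on
  # a held-out discovery split; imputation for every sample
  mq <- meqtl_scan(g_d, m_d, covariates = covars[idx_d, ])
  sig <- mq[mq$is_meqtl, ]
  targets <- intersect(co$truth$response_cpgs$cpg_id, unique(sig$cpg_id))
  sp <- split_cohort(ph_d$sample_id, 0.7, seed + 2)
  tr <- match(sp$train, ph_d$sample_id)
  te <- match(sp$test, ph_d$sample_id)
  models <- purrr::map(targets, function(cg) {
    train_proxy(subset_genotypes(g_d, tr), subset_methylome(m_d, tr),
                covars[idx_d, ][tr, ], cg, sig, algorithm = "rf",
                search_budget = search_budget, cv_folds = cv_folds,
                seed = seed + 3)
  })
  sel <- evaluate_and_select(models, subset_genotypes(g_d, te),
                             subset_methylome(m_d, te),
                             covars[idx_d, ][te, ])
  px <- impute_methylation(sel$kept, co$genotypes, covars)

  fit_eval <- function(pattern) {
    fs_d <- assemble_features(ph_d, prs = prs_tbl, grs = grs_tbl,
                              proxydnam = px, pattern = pattern)
    fs_v <- assemble_features(ph_v, prs = prs_tbl, grs = grs_tbl,
                              proxydnam = px, pattern = pattern)
    mod <- train_response_model(fs_d, "rf", search_budget = search_budget,
                                cv_folds = cv_folds, seed = seed + 4)
    ev <- evaluate_model(mod, fs_v)
    dc <- decision_curve(scaled_to_probability(predict(mod, fs_v)),
                         fs_v$res, thresholds = thresholds)
    list(model = mod, eval = ev, curve = dc)
  }
  cp <- fit_eval("C+P")
  cpgm <- fit_eval("C+PGM")
  nb_cp <- cp$curve$net_benefit[cp$curve$model == "model"]
  nb_cpgm <- cpgm$curve$net_benefit[cpgm$curve$model == "model"]
  tibble::tibble(
    seed = seed,
    n_proxies = length(sel$kept),
    auc_cp = cp$eval$overall$auc,
    auc_cpgm = cpgm$eval$overall$auc,
    r2_cp = cp$eval$overall$r_squared,
    r2_cpgm = cpgm$eval$overall$r_squared,
    snb_win_frac = mean(nb_cpgm >= nb_cp - 1e-12),
    cv_r2_cp = cp$model$cv_r2,
    cv_r2_cpgm = cpgm$model$cv_r2
  )
}
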