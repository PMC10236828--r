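#' Simulation configuration for a synthetic trial cohort
#'
#' Builds the configuration object consumed by the `simulate_*` generators.
#' The defaults emulate, at desk scale, the statistical structure of a
#' randomized antipsychotic trial with a case-control methylation arm:
#' LD-structured biallelic genotypes; CpG methylation with additive cis-meQTL,
#' age and sex effects on the M-value scale; schizophrenia liability driven by
#' genotype and methylation; and randomized-arm PANSS outcomes whose reduction
#' rate depends on the drug arm, genetic burden, causal CpG methylation and
#' age. The default per-arm mean reduction rates reflect the spread
#' observed across antipsychotic trial arms (olanzapine 55.9 through
#' perphenazine 49.2 percentage points); PANSS baselines are drawn from
#' N(90, 15^2) truncated at 61 (inclusion floor of > 60).
#'
#' @param n_cases,n_controls cohort sizes.
#' @param n_snps,n_cpgs panel sizes.
#' @param ld_block_size SNPs per LD block.
#' @param ld_rho within-block latent haplotype correlation, in `[0, 1)`.
#' @param maf_range range the per-SNP minor-allele frequency is drawn from.
#' @param n_meqtl number of planted cis SNP-CpG pairs (used when `meqtl_map`
#'   is not supplied).
#' @param meqtl_beta M-value change per effect allele for planted meQTLs.
#' @param meqtl_map optional tibble (`snp_id`, `cpg_id`, `beta`) overriding
#'   the automatic assignment.
#' @param n_disease_snps,disease_snp_sd count and effect-size SD of liability
#'   SNPs.
#' @param n_disease_cpgs,disease_cpg_sd count and effect-size SD of liability
#'   CpGs (effects on the M-value scale).
#' @param n_response_cpgs,response_cpg_effect causal CpGs for treatment
#'   response and their per-M-unit effect on the reduction rate (percentage
#'   points).
#' @param response_genetic_effect per-allele effect of each disease SNP on
#'   the reduction rate (percentage points); negative means higher genetic
#'   burden predicts poorer response.
#' @param b_age effect of one year of age on the reduction rate.
#' @param arms named numeric vector of per-arm mean reduction rates.
#' @param sigma_m residual SD of CpG M-values.
#' @param sigma_r residual SD of the reduction rate (percentage points).
#' @param age_effect_sd,sex_effect_sd SDs of per-CpG age (per year) and sex
#'   effects on M-values.
#' @param seed mandatory integer seed; every generator is fully deterministic
#'   given the config.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_cases = 500, n_controls = 250,
                       n_snps = 400, n_cpgs = 300,
                       ld_block_size = 10, ld_rho = 0.8,
                       maf_range = c(0.05, 0.5),
                       n_meqtl = 30, meqtl_beta = 1.0, meqtl_map = NULL,
                       n_disease_snps = 40, disease_snp_sd = 0.25,
                       n_disease_cpgs = 20, disease_cpg_sd = 0.3,
                       n_response_cpgs = 6, response_cpg_effect = -6,
                       response_genetic_effect = -0.4,
                       b_age = -0.3,
                       arms = c(olanzapine = 55.9, aripiprazole = 47.8,
                                risperidone = 55.3, quetiapine = 48.2,
                                haloperidol = 53.4, ziprasidone = 46.6,
                                perphenazine = 49.2),
                       sigma_m = 0.6, sigma_r = 18,
                       age_effect_sd = 0.01, sex_effect_sd = 0.1,
                       seed) {
  seed <- check_seed(seed)
  stopifnot(n_cases > 0, n_controls >= 0, n_snps > 0, n_cpgs > 0,
            ld_block_size > 0, ld_rho >= 0, ld_rho < 1,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5)
  cfg <- list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    n_snps = as.integer(n_snps), n_cpgs = as.integer(n_cpgs),
    ld_block_size = as.integer(ld_block_size), ld_rho = ld_rho,
    maf_range = maf_range,
    n_meqtl = as.integer(n_meqtl), meqtl_beta = meqtl_beta,
    meqtl_map = meqtl_map,
    n_disease_snps = as.integer(n_disease_snps),
    disease_snp_sd = disease_snp_sd,
    n_disease_cpgs = as.integer(n_disease_cpgs),
    disease_cpg_sd = disease_cpg_sd,
    n_response_cpgs = as.integer(n_response_cpgs),
    response_cpg_effect = response_cpg_effect,
    response_genetic_effect = response_genetic_effect,
    b_age = b_age, arms = arms,
    sigma_m = sigma_m, sigma_r = sigma_r,
    age_effect_sd = age_effect_sd, sex_effect_sd = sex_effect_sd,
    seed = seed
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate LD-structured genotype dosages
#'
#' Haplotypes are generated by thresholding block-correlated latent Gaussians
#' (compound-symmetry correlation `ld_rho` within blocks of `ld_block_size`
#' SNPs) at the MAF-matched quantile; the dosage is the sum over two
#' independent haplotypes, so marginal allele frequencies match the target
#' MAF and adjacent SNPs within a block are correlated.
#'
#' @param config a [sim_config()].
#' @param n_samples optional override of `n_cases + n_controls`.
#' @return a [genotype_matrix()]; SNPs are placed on chromosome 1 at 5 kb
#'   spacing so every block spans well under the default cis window.
#' @export
simulate_genotypes <- function(config, n_samples = NULL) {
  n <- n_samples %||% (config$n_cases + config$n_controls)
  p <- config$n_snps
  set.seed(config$seed)
  maf <- runif(p, config$maf_range[1], config$maf_range[2])
  rho <- config$ld_rho
  bs <- config$ld_block_size
  block <- rep(seq_len(ceiling(p / bs)), each = bs)[seq_len(p)]
  thr <- qnorm(maf)
  hap <- function() {
    # shared + idiosyncratic latent gives compound-symmetry rho within block
    shared <- matrix(rnorm(n * max(block)), n, max(block))
    z <- sqrt(rho) * shared[, block, drop = FALSE] +
      sqrt(1 - rho) * matrix(rnorm(n * p), n, p)
    sweep(z, 2, thr, "<") * 1
  }
  dos <- hap() + hap()
  sample_ids <- sprintf("S%04d", seq_len(n))
  snp_ids <- sprintf("rs%05d", seq_len(p))
  rownames(dos) <- sample_ids
  colnames(dos) <- snp_ids
  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, p, replace = TRUE)
  eff <- vapply(ref, function(a) sample(setdiff(alleles, a), 1), character(1))
  meta <- tibble::tibble(
    snp_id = snp_ids, chrom = "1", pos = 10000L + 5000L * (seq_len(p) - 1L),
    ref_allele = unname(ref), effect_allele = unname(eff)
  )
  # stored maf is the realized one (container invariant); the sampling
  # target is kept as an attribute for calibration checks
  g <- genotype_matrix(dos, meta)
  attr(g, "target_maf") <- maf
  g
}

#' Simulate baseline covariates (age, sex)
#'
#' Age ~ N(31, 8^2) truncated to the trial's 18-45 inclusion window; sex is
#' balanced Bernoulli, coded 0/1.
#'
#' @param config a [sim_config()].
#' @param sample_ids sample identifiers.
#' @return tibble `sample_id`, `age`, `sex`.
#' @export
simulate_covariates <- function(config, sample_ids) {
  n <- length(sample_ids)
  set.seed(config$seed + 1L)
  age <- round(pmin(pmax(rnorm(n, 31, 8), 18), 45), 1)
  sex <- rbinom(n, 1, 0.5)
  tibble::tibble(sample_id = sample_ids, age = age, sex = sex)
}

# Resolve the planted meQTL map: n_meqtl (snp_i, cpg_i) pairs, matched by
# index so each pair is cis (same chromosome, nearby positions).
resolve_meqtl_map <- function(config, snp_ids, cpg_ids) {
  if (!is.null(config$meqtl_map)) return(tibble::as_tibble(config$meqtl_map))
  k <- min(config$n_meqtl, floor(length(snp_ids) / 2),
           floor(length(cpg_ids) / 2))
  idx <- seq_len(k)
  tibble::tibble(snp_id = snp_ids[idx * 2L],
                 cpg_id = cpg_ids[idx * 2L],
                 beta = config$meqtl_beta)
}

#' Simulate a methylome with planted meQTL, age and sex effects
#'
#' Per CpG, M-values follow
#' `M = mu + beta_meqtl * G + gamma_age * age + gamma_sex * sex + N(0, sigma_m^2)`
#' and betas are the inverse-logit `2^M / (2^M + 1)`, hence in (0, 1).
#' CpG positions interleave the SNP grid so planted pairs are cis.
#'
#' @param genotypes a [genotype_matrix()].
#' @param covars tibble from [simulate_covariates()] (columns `age`, `sex`).
#' @param config a [sim_config()].
#' @return a [methylation_matrix()] whose `cpg_meta` carries gene, context
#'   and island annotations (genes `GENE0001`... shared by neighbouring
#'   CpG triplets).
#' @export
simulate_methylome <- function(genotypes, covars, config) {
  n <- nrow(genotypes$dosages)
  p <- config$n_cpgs
  cpg_ids <- sprintf("cg%06d", seq_len(p))
  map <- resolve_meqtl_map(config, genotypes$snp_meta$snp_id, cpg_ids)
  bad <- setdiff(map$snp_id, genotypes$snp_meta$snp_id)
  if (length(bad) || length(setdiff(map$cpg_id, cpg_ids))) {
    abort("meqtl_map references unknown SNP or CpG ids")
  }
  set.seed(config$seed + 2L)
  mu <- runif(p, -2, 2)
  g_age <- rnorm(p, 0, config$age_effect_sd)
  g_sex <- rnorm(p, 0, config$sex_effect_sd)
  M <- matrix(rnorm(n * p, 0, config$sigma_m), n, p)
  M <- sweep(M, 2, mu, "+")
  M <- M + outer(covars$age - mean(covars$age), g_age)
  M <- M + outer(covars$sex - 0.5, g_sex)
  for (i in seq_len(nrow(map))) {
    j <- match(map$cpg_id[i], cpg_ids)
    M[, j] <- M[, j] + map$beta[i] * genotypes$dosages[, map$snp_id[i]]
  }
  betas <- m_to_beta(M)
  rownames(betas) <- rownames(genotypes$dosages)
  colnames(betas) <- cpg_ids
  # CpGs interleave SNP positions (offset 2500 within the 5 kb SNP grid)
  pos <- 10000L + 5000L * (seq_len(p) - 1L) + 2500L
  contexts <- c("TSS1500", "TSS200", "5'UTR", "1stExon", "Body", "3'UTR",
                "Intergenic")
  islands <- c("Island", "Shore", "Shelf", "OpenSea")
  meta <- tibble::tibble(
    cpg_id = cpg_ids, chrom = "1", pos = pos,
    gene = sprintf("GENE%04d", (seq_len(p) - 1L) %/% 3L + 1L),
    context = sample(contexts, p, replace = TRUE),
    island = sample(islands, p, replace = TRUE)
  )
  methylation_matrix(betas, meta)
}

#' Simulate case-control status from a liability model
#'
#' Liability is a weighted sum of disease-SNP dosages and disease-CpG
#' M-values plus standard normal noise; the top fraction (matching the
#' requested case:control ratio) are cases. Controls carry no PANSS fields.
#'
#' @param genotypes a [genotype_matrix()].
#' @param methylome a [methylation_matrix()].
#' @param covars covariate tibble (for sample ids / age / sex passthrough).
#' @param config a [sim_config()].
#' @return list with `phenotypes` (partial trial phenotype tibble) and
#'   `truth` (planted SNP/CpG effects and the latent liability).
#' @export
simulate_case_control <- function(genotypes, methylome, covars, config) {
  n <- nrow(genotypes$dosages)
  set.seed(config$seed + 3L)
  snp_idx <- sample(config$n_snps, min(config$n_disease_snps, config$n_snps))
  w <- rnorm(length(snp_idx), 0, config$disease_snp_sd)
  cpg_idx <- sample(config$n_cpgs, min(config$n_disease_cpgs, config$n_cpgs))
  v <- rnorm(length(cpg_idx), 0, config$disease_cpg_sd)
  M <- beta_to_m(methylome$betas)
  liab <- as.vector(genotypes$dosages[, snp_idx, drop = FALSE] %*% w) +
    as.vector(scale(M[, cpg_idx, drop = FALSE], scale = FALSE) %*% v) +
    rnorm(n)
  case_frac <- config$n_cases / (config$n_cases + config$n_controls)
  is_case <- rank(-liab, ties.method = "first") <= round(n * case_frac)
  ph <- tibble::tibble(
    sample_id = rownames(genotypes$dosages),
    age = covars$age, sex = covars$sex,
    cohort = "synthetic",
    arm = NA_character_,
    panss_baseline = NA_real_, panss_endpoint = NA_real_,
    is_case = is_case,
    reduction_rate = NA_real_, res_label = NA_character_
  )
  truth <- list(disease_snps = tibble::tibble(
                  snp_id = genotypes$snp_meta$snp_id[snp_idx], weight = w),
                disease_cpgs = tibble::tibble(
                  cpg_id = methylome$cpg_meta$cpg_id[cpg_idx], weight = v),
                liability = liab)
  list(phenotypes = ph, truth = truth)
}

#' Simulate randomized-arm PANSS outcomes
#'
#' Cases are assigned uniformly at random to the configured arms. Baseline
#' PANSS totals are `round(N(90, 15^2))` truncated at 61; the generating
#' reduction rate is
#' `arm_effect + b_g * genetic_burden + b_m * causal CpG M + b_age * (age - 30) + N(0, sigma_r^2)`,
#' truncated above at 100, and the endpoint is back-computed as
#' `round(baseline - rate/100 * (baseline - 30))` floored at 30 (so the
#' recorded rate differs from the generating rate only by rounding).
#'
#' @param cc output of [simulate_case_control()].
#' @param genotypes,methylome the simulated omics matrices.
#' @param config a [sim_config()].
#' @return list `phenotypes` (complete trial phenotype tibble with derived
#'   outcomes) and `truth` (adds response CpG/SNP effects and generating
#'   rates to the case-control truth).
#' @export
simulate_trial_outcomes <- function(cc, genotypes, methylome, config) {
  ph <- cc$phenotypes
  n_case <- sum(ph$is_case)
  set.seed(config$seed + 4L)
  arms <- config$arms
  arm_of <- sample(names(arms), n_case, replace = TRUE)
  baseline <- pmax(round(rnorm(n_case, 90, 15)), 61)
  M <- beta_to_m(methylome$betas)
  # causal response CpGs are drawn from the meQTL targets first (the
  # mediation structure proxy models rely on), topped up at random
  map <- resolve_meqtl_map(config, genotypes$snp_meta$snp_id,
                           methylome$cpg_meta$cpg_id)
  k <- min(config$n_response_cpgs, config$n_cpgs)
  pool <- match(map$cpg_id, methylome$cpg_meta$cpg_id)
  resp_idx <- if (length(pool) >= k) sample(pool, k) else {
    c(pool, sample(setdiff(seq_len(config$n_cpgs), pool), k - length(pool)))
  }
  resp_cpgs <- methylome$cpg_meta$cpg_id[resp_idx]
  m_part <- rowSums(scale(M[ph$is_case, resp_idx, drop = FALSE],
                          scale = FALSE)) * config$response_cpg_effect
  gen_burden <- as.vector(
    genotypes$dosages[ph$is_case, cc$truth$disease_snps$snp_id, drop = FALSE] %*%
      sign(cc$truth$disease_snps$weight)
  )
  g_part <- config$response_genetic_effect * (gen_burden - mean(gen_burden))
  rate <- unname(arms[arm_of]) + g_part + m_part +
    config$b_age * (ph$age[ph$is_case] - 30) +
    rnorm(n_case, 0, config$sigma_r)
  rate <- pmin(rate, 100)
  endpoint <- pmax(round(baseline - rate / 100 * (baseline - 30)), 30)
  ph$arm[ph$is_case] <- arm_of
  ph$panss_baseline[ph$is_case] <- baseline
  ph$panss_endpoint[ph$is_case] <- endpoint
  ph <- derive_outcomes(ph)
  truth <- cc$truth
  truth$response_cpgs <- tibble::tibble(cpg_id = resp_cpgs,
                                        effect = config$response_cpg_effect)
  truth$generating_rate <- rate
  list(phenotypes = validate_trial_phenotypes(ph), truth = truth)
}

#' Fabricate GWAS summary statistics for the simulated panel
#'
#' Either regresses a simulated reference phenotype on each SNP
#' (`mode = "regression"`) or draws effects analytically
#' (`mode = "analytic"`): `beta_hat ~ N(beta_true, se^2)` with
#' `se = 1 / sqrt(2 n maf (1 - maf))` and a two-sided normal p, the standard
#' large-sample approximation for a standardized trait.
#'
#' @param genotypes a [genotype_matrix()] supplying the SNP panel.
#' @param true_effects tibble (`snp_id`, `beta`) of true per-allele effects;
#'   SNPs absent from it are null.
#' @param n_ref GWAS reference sample size.
#' @param mode `"analytic"` or `"regression"`.
#' @param seed integer seed.
#' @return a [summary_stats()] tibble covering every panel SNP.
#' @export
make_summary_stats <- function(genotypes, true_effects = NULL, n_ref = 10000,
                               mode = c("analytic", "regression"), seed) {
  mode <- match.arg(mode)
  seed <- check_seed(seed)
  meta <- genotypes$snp_meta
  beta_true <- rep(0, nrow(meta))
  if (!is.null(true_effects)) {
    i <- match(true_effects$snp_id, meta$snp_id)
    beta_true[i[!is.na(i)]] <- true_effects$beta[!is.na(i)]
  }
  set.seed(seed)
  if (mode == "analytic") {
    se <- 1 / sqrt(2 * n_ref * meta$maf * (1 - meta$maf))
    beta_hat <- rnorm(nrow(meta), beta_true, se)
  } else {
    # small simulated reference population, per-SNP OLS
    nref <- min(n_ref, 2000)
    ref_cfg <- modifyList(unclass_config(genotypes, nref),
                          list(seed = seed + 1L))
    ref <- simulate_genotypes(ref_cfg, n_samples = nref)
    y <- as.vector(ref$dosages %*% beta_true) + rnorm(nref)
    fits <- purrr::map(seq_len(ncol(ref$dosages)), function(j) {
      fast_ols(matrix(y), cbind(1, ref$dosages[, j]))
    }) |> purrr::list_rbind()
    beta_hat <- fits$estimate
    se <- fits$se
  }
  z <- beta_hat / se
  summary_stats(tibble::tibble(
    snp_id = meta$snp_id,
    effect_allele = meta$effect_allele, other_allele = meta$ref_allele,
    beta = beta_hat, se = se,
    p = pmax(2 * pnorm(abs(z), lower.tail = FALSE), 1e-300),
    freq = ifelse(meta$maf <= 0.5, meta$maf, 1 - meta$maf),
    n = n_ref
  ))
}

# reconstruct a minimal config matching a genotype panel (regression mode)
unclass_config <- function(genotypes, n) {
  p <- ncol(genotypes$dosages)
  sim_config(n_cases = n, n_controls = 0, n_snps = p, n_cpgs = 1, seed = 1)
}

#' Simulate a full cohort in one call
#'
#' Runs genotype, covariate, methylome, case-control and trial-outcome
#' generation in order and also fabricates case-control GWAS summary
#' statistics whose true effects are the planted liability SNP weights.
#'
#' @param config a [sim_config()].
#' @return list with `genotypes`, `methylome`, `phenotypes`, `summary_stats`,
#'   `meqtl_map` (the planted cis pairs) and `truth`.
#' @export
simulate_cohort <- function(config) {
  g <- simulate_genotypes(config)
  cov <- simulate_covariates(config, rownames(g$dosages))
  m <- simulate_methylome(g, cov, config)
  cc <- simulate_case_control(g, m, cov, config)
  out <- simulate_trial_outcomes(cc, g, m, config)
  ss <- make_summary_stats(
    g, true_effects = dplyr::rename(out$truth$disease_snps,
                                    beta = "weight"),
    n_ref = 20000, seed = config$seed + 5L
  )
  list(genotypes = g, methylome = m, phenotypes = out$phenotypes,
       summary_stats = ss,
       meqtl_map = resolve_meqtl_map(config, g$snp_meta$snp_id,
                                     m$cpg_meta$cpg_id),
       truth = out$truth)
}
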