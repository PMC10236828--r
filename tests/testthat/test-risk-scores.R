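test_that("clumping applies the greedy rule on forced fixtures", {
  # two perfectly correlated SNPs: only the smaller-p one survives
  d <- cbind(rs1 = c(0, 1, 2, 1, 0, 2), rs2 = c(0, 1, 2, 1, 0, 2))
  rownames(d) <- paste0("S", 1:6)
  g <- genotype_matrix(d, tibble::tibble(
    snp_id = c("rs1", "rs2"), chrom = "1", pos = c(100L, 200L),
    ref_allele = "A", effect_allele = "G"))
  ss <- summary_stats(tibble::tibble(
    snp_id = c("rs1", "rs2"), effect_allele = "G", other_allele = "A",
    beta = c(0.5, 0.3), se = 0.1, p = c(1e-8, 1e-4)))
  kept <- ld_clump(ss, g, r2_threshold = 0.5, window_kb = 1)
  expect_equal(kept$snp_id, "rs1")

  # mutually independent SNPs all survive
  set.seed(4)
  d2 <- matrix(rbinom(600, 2, 0.3), 200, 3,
               dimnames = list(NULL, paste0("rs", 1:3)))
  g2 <- genotype_matrix(d2, tibble::tibble(
    snp_id = paste0("rs", 1:3), chrom = "1", pos = c(100L, 200L, 300L),
    ref_allele = "A", effect_allele = "G"))
  ss2 <- summary_stats(tibble::tibble(
    snp_id = paste0("rs", 1:3), effect_allele = "G", other_allele = "A",
    beta = 0.1, se = 0.1, p = c(1e-5, 1e-4, 1e-3)))
  expect_equal(sort(ld_clump(ss2, g2, 0.2, 250)$snp_id),
               paste0("rs", 1:3))
})

test_that("clumping matches the brute-force verifier on random instances", {
  for (s in 1:25) {
    cfg <- sim_config(n_cases = 120, n_controls = 0,
                      n_snps = sample(8:25, 1), n_cpgs = 2,
                      ld_block_size = 4, ld_rho = runif(1, 0, 0.95),
                      seed = 1000 + s)
    set.seed(s)
    g <- simulate_genotypes(cfg)
    ss <- make_summary_stats(g, n_ref = 3000, seed = 2000 + s)
    r2t <- sample(c(0.1, 0.3, 0.6), 1)
    win <- sample(c(5, 15, 250), 1)
    got <- sort(ld_clump(ss, g, r2t, win)$snp_id)
    expect_equal(got, clump_oracle(ss, g, r2t, win))
  }
})

test_that("PRS is the harmonized weighted allele sum", {
  d <- cbind(rs1 = c(2, 0), rs2 = c(1, 2))
  rownames(d) <- c("S1", "S2")
  g <- genotype_matrix(d, tibble::tibble(
    snp_id = c("rs1", "rs2"), chrom = "1", pos = c(1000L, 500000L),
    ref_allele = c("A", "C"), effect_allele = c("G", "T")))
  ss <- summary_stats(tibble::tibble(
    snp_id = c("rs1", "rs2"), effect_allele = c("G", "T"),
    other_allele = c("A", "C"), beta = c(0.2, -0.1), se = 0.05,
    p = c(1e-10, 1e-9)))
  pr <- prs_score(ss, g, phenotype = c(1, 0), n_permutations = 3, seed = 1,
                  thresholds = 1)
  expect_equal(pr$scores$score, c(2 * 0.2 + 1 * -0.1, 0 * 0.2 + 2 * -0.1))
})

test_that("SNP counts grow monotonically with the p threshold", {
  co <- small_cohort()
  pr <- prs_score(co$summary_stats, co$genotypes,
                  as.integer(co$phenotypes$is_case),
                  n_permutations = 3, seed = 5)
  tb <- tidy(pr)
  expect_true(all(diff(tb$n_snps[order(tb$threshold)]) >= 0))
  expect_gte(pr$empirical_p, 1 / (3 + 1))
  expect_lte(pr$empirical_p, 1)
})

test_that("a planted architecture yields a liability-correlated PRS", {
  cfg <- sim_config(n_cases = 300, n_controls = 300, n_snps = 100,
                    n_cpgs = 10, n_disease_snps = 50, disease_snp_sd = 0.35,
                    n_disease_cpgs = 0, seed = 31)
  co <- simulate_cohort(cfg)
  pr <- prs_score(co$summary_stats, co$genotypes,
                  as.integer(co$phenotypes$is_case),
                  n_permutations = 19, seed = 6)
  ct <- cor.test(pr$scores$score, co$truth$liability)
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})

test_that("genotype PCs honour rank and variance-target edge cases", {
  set.seed(9)
  base <- rnorm(50)
  d <- outer(base, rep(1, 10)) + 1    # rank-1 after centering
  d <- pmin(pmax(d, 0), 2)
  g <- genotype_matrix(d, tibble::tibble(
    snp_id = paste0("rs", 1:10), chrom = "1",
    pos = seq(100L, 1000L, 100L), ref_allele = "A", effect_allele = "G"))
  expect_equal(ncol(genotype_pcs(g, 0.95)), 1L)

  co <- small_cohort()
  pcs <- genotype_pcs(co$genotypes, 1.0)
  expect_equal(ncol(pcs), qr(scale(co$genotypes$dosages))$rank)
  pcs95 <- genotype_pcs(co$genotypes, 0.95)
  expect_gte(sum(attr(pcs95, "explained")), 0.95)
})

test_that("GRS is a harmonized weighted sum, invariant to allele flips", {
  co <- small_cohort()
  g <- co$genotypes
  w <- tibble::tibble(snp_id = g$snp_meta$snp_id[1:5],
                      effect_allele = g$snp_meta$effect_allele[1:5],
                      weight = c(1, -0.5, 0.2, 0, 2))
  s1 <- grs_score(w, g)
  manual <- as.vector(g$dosages[, w$snp_id] %*% w$weight)
  expect_equal(s1$score, manual)

  w_flip <- dplyr::mutate(w, effect_allele = g$snp_meta$ref_allele[1:5],
                          weight = -weight)
  expect_equal(grs_score(w_flip, g)$score, s1$score)

  w0 <- dplyr::mutate(w, weight = 0)
  expect_equal(grs_score(w0, g)$score, rep(0, nrow(g$dosages)))
  expect_error(grs_score(dplyr::mutate(w, snp_id = paste0("x", snp_id)), g),
               "overlap")
})

test_that("single-SNP GRS with weight 1 returns the dosage", {
  d <- cbind(rs1 = c(2, 1, 0))
  rownames(d) <- paste0("S", 1:3)
  g <- genotype_matrix(d, tibble::tibble(
    snp_id = "rs1", chrom = "1", pos = 100L,
    ref_allele = "A", effect_allele = "G"))
  w <- tibble::tibble(snp_id = "rs1", effect_allele = "G", weight = 1)
  expect_equal(grs_score(w, g)$score, c(2, 1, 0))
})

test_that("PMS separates a separable fixture and stays out of fold", {
  set.seed(41)
  n <- 120
  driver <- matrix(rnorm(n * 4), n, 4)
  y <- as.integer(rowMeans(driver) > 0)
  noise <- matrix(rnorm(n * 6), n, 6)
  betas <- m_to_beta(cbind(driver * 3, noise))
  colnames(betas) <- paste0("cg", 1:10)
  rownames(betas) <- paste0("S", 1:n)
  meta <- tibble::tibble(cpg_id = paste0("cg", 1:10), chrom = "1",
                         pos = seq(100L, 1000L, 100L))
  meth <- methylation_matrix(betas, meta)
  pw <- list(signal = paste0("cg", 1:4), noise = paste0("cg", 5:10))
  pms <- pms_fit_score(meth, y, pw, n_bootstrap = 5, cv_folds = 5, seed = 2)
  expect_gt(pms$auc, 0.9)
  expect_true(all(pms$scores$pms >= 0 & pms$scores$pms <= 1))

  # permuted labels give chance-level out-of-fold AUC
  aucs <- sapply(1:5, function(s) {
    set.seed(s)
    pms_fit_score(meth, sample(y), pw, n_bootstrap = 3, cv_folds = 5,
                  seed = s)$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.12)

  # pathways with no mapped CpGs are dropped; all dropped is an error
  expect_warning(
    pms_fit_score(meth, y, c(pw, list(empty = "cgX")), n_bootstrap = 2,
                  cv_folds = 5, seed = 3),
    "no mapped CpGs")
  expect_error(
    suppressWarnings(pms_fit_score(meth, y, list(empty = "cgX"),
                                   n_bootstrap = 2, cv_folds = 5, seed = 3)),
    "every pathway")
})

test_that("linear clock recovers a planted aging signal", {
  set.seed(51)
  n <- 150
  age <- runif(n, 20, 70)
  betas <- sapply(1:8, function(j) {
    pmin(pmax(0.2 + 0.008 * age * (j %% 2 == 0) + rnorm(n, 0, 0.02), 0), 1)
  })
  colnames(betas) <- paste0("cg", 1:8)
  rownames(betas) <- paste0("S", 1:n)
  meth <- methylation_matrix(betas, tibble::tibble(
    cpg_id = paste0("cg", 1:8), chrom = "1", pos = seq(100L, 800L, 100L)))

  flat <- dnam_age(meth, tibble::tibble(cpg_id = paste0("cg", 1:8),
                                        weight = 0), intercept = 40)
  expect_equal(flat$dnam_age, rep(40, n))

  co <- tibble::tibble(cpg_id = paste0("cg", c(2, 4, 6, 8)), weight = 125)
  da <- dnam_age(meth, co, intercept = -100)
  expect_gt(cor(da$dnam_age, age), 0.9)

  # the inverse log-linear map is the identity on its linear branch when
  # the adult threshold is 0, so transform on/off agree there
  one <- methylation_matrix(matrix(0.5, 1, 1,
                                   dimnames = list("S1", "cg1")),
                            tibble::tibble(cpg_id = "cg1", chrom = "1",
                                           pos = 100L))
  co1 <- tibble::tibble(cpg_id = "cg1", weight = 0)
  expect_equal(dnam_age(one, co1, intercept = 20,
                        transform_mode = "adult-log",
                        adult_age = 0)$dnam_age,
               dnam_age(one, co1, intercept = 20)$dnam_age)
  # and inverts the forward log-linear transform above the threshold
  fwd <- (35 - 20) / (1 + 20)
  expect_equal(dnam_age(one, co1, intercept = fwd,
                        transform_mode = "adult-log")$dnam_age, 35)
})

test_that("age acceleration is a zero-mean OLS residual that finds a planted shift", {
  set.seed(61)
  n <- 200
  age <- runif(n, 20, 60)
  da <- age + rnorm(n, 0, 2)
  sub <- seq_len(50)
  da[sub] <- da[sub] + 5
  acc <- age_acceleration(da, age)
  expect_equal(mean(acc), 0, tolerance = 1e-9)
  sub_mean <- mean(acc[sub])
  se <- sd(acc[sub]) / sqrt(length(sub))
  # planted +5 shift partially absorbed by the fit; recovered within 2 SE
  # of the attenuated expectation 5 * (1 - 50/200)
  expect_lt(abs(sub_mean - 5 * 0.75), 2.5 * se + 1)

  expect_equal(age_acceleration(age, age), rep(0, n), tolerance = 1e-9)
  expect_error(age_acceleration(da, rep(30, n)), "constant")
})
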