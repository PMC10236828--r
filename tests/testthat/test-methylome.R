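make_meth <- function(M, prefix = "cg", chrom = "1", spacing = 100L) {
  p <- ncol(M)
  betas <- m_to_beta(M)
  colnames(betas) <- sprintf("%s%03d", prefix, seq_len(p))
  rownames(betas) <- sprintf("S%03d", seq_len(nrow(M)))
  methylation_matrix(betas, tibble::tibble(
    cpg_id = colnames(betas), chrom = chrom,
    pos = spacing * seq_len(p), gene = paste0("G", seq_len(p))))
}

test_that("site test without covariates equals the two-sample t statistic", {
  set.seed(71)
  M <- matrix(rnorm(60 * 8), 60, 8)
  meth <- make_meth(M)
  grp <- rep(c(0, 1), each = 30)
  got <- site_dm_test(meth, grp)
  for (j in c(1, 4, 8)) {
    tt <- t.test(beta_to_m(meth$betas[grp == 1, j]),
                 beta_to_m(meth$betas[grp == 0, j]), var.equal = TRUE)
    expect_equal(got$statistic[j], unname(tt$statistic), tolerance = 1e-9)
    expect_equal(got$p[j], tt$p.value, tolerance = 1e-9)
  }
  # and with covariates it equals lm()
  cov <- data.frame(age = rnorm(60))
  got2 <- site_dm_test(meth, grp, covariates = cov)
  fit <- summary(lm(beta_to_m(meth$betas[, 2]) ~ grp + cov$age))
  expect_equal(got2$effect[2], unname(coef(fit)[2, 1]), tolerance = 1e-9)
  expect_equal(got2$p[2], unname(coef(fit)[2, 4]), tolerance = 1e-9)
})

test_that("planted group differences are detected and nulls calibrated", {
  set.seed(72)
  n <- 200
  grp <- rep(c(0, 1), each = n / 2)
  M <- matrix(rnorm(n * 60, 0, 0.5), n, 60)
  M[grp == 1, 1:20] <- M[grp == 1, 1:20] + 1.0
  meth <- make_meth(M)
  got <- site_dm_test(meth, grp)
  expect_gte(sum(got$p_adj[1:20] < 0.05), 18)

  nulls <- got$p[21:60]
  ks <- suppressWarnings(ks.test(nulls, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("age-confounded signal vanishes when groups are age-matched", {
  set.seed(73)
  n <- 200
  age <- rnorm(n, 40, 10)
  grp <- rep(c(0, 1), n / 2)            # alternating: independent of age
  M <- matrix(0.05 * age + rnorm(n * 5, 0, 0.5), n, 5)
  meth <- make_meth(M)
  got <- site_dm_test(meth, grp, covariates = data.frame(age = age))
  expect_true(all(got$p > 0.001))
})

test_that("constant CpGs are flagged with p = 1", {
  M <- cbind(rep(0, 30), rnorm(30))
  meth <- make_meth(M)
  grp <- rep(c(0, 1), each = 15)
  expect_warning(got <- site_dm_test(meth, grp), "constant")
  expect_equal(got$p[1], 1)
})

test_that("DMR seed-and-extend applies the gap and size rules", {
  p_vec <- c(0.5, 0.9, 1e-6, 1e-6, 1e-6, 1e-6, 1e-6, 0.8, 0.6)
  pos <- c(100L, 200L, 300L, 350L, 400L, 450L, 500L, 600L, 700L)
  sites <- tibble::tibble(cpg_id = paste0("cg", 1:9), contrast = "risk",
                          effect = 1, se = 1, statistic = 1, p = p_vec,
                          p_adj = p_vec)
  meta <- tibble::tibble(cpg_id = paste0("cg", 1:9), chrom = "7", pos = pos,
                         gene = "GENE1")
  dm <- dmr_detect(sites, meta, seed_p = 0.05, max_gap_bp = 200, min_cpgs = 3)
  expect_equal(nrow(dm), 1L)
  expect_equal(dm$n_cpgs, 5L)
  expect_equal(dm$start, 300L)
  expect_equal(dm$end, 500L)
  expect_setequal(dm$cpgs[[1]], paste0("cg", 3:7))
  expect_lt(dm$combined_p, 1e-6)

  # gap below inter-CpG spacing: no region reaches min_cpgs
  dm0 <- dmr_detect(sites, meta, seed_p = 0.05, max_gap_bp = 10,
                    min_cpgs = 3)
  expect_equal(nrow(dm0), 0L)
})

test_that("DMRs are disjoint and invariant to relabeling/translation", {
  set.seed(74)
  p <- 300
  p_vec <- runif(p)
  p_vec[sample(p, 40)] <- 10^runif(40, -8, -2)
  sites <- tibble::tibble(cpg_id = paste0("cg", 1:p), contrast = "risk",
                          effect = rnorm(p), se = 1, statistic = 0,
                          p = p_vec, p_adj = p_vec)
  meta <- tibble::tibble(cpg_id = paste0("cg", 1:p), chrom = "1",
                         pos = sort(sample(1:100000, p)), gene = "G")
  dm <- dmr_detect(sites, meta)
  ids <- unlist(dm$cpgs)
  expect_equal(anyDuplicated(ids), 0L)

  meta2 <- dplyr::mutate(meta, chrom = "X", pos = pos + 123456L)
  dm2 <- dmr_detect(sites, meta2)
  expect_equal(dm2$combined_p, dm$combined_p)
  expect_equal(dm2$start, dm$start + 123456L)
})

test_that("null DMR counts match a permutation oracle within Poisson error", {
  set.seed(75)
  p <- 1000
  pos <- sort(sample(1:500000, p))
  meta <- tibble::tibble(cpg_id = paste0("cg", 1:p), chrom = "1", pos = pos,
                         gene = "G")
  n_obs <- sapply(1:8, function(r) {
    pv <- runif(p)
    sites <- tibble::tibble(cpg_id = meta$cpg_id, contrast = "risk",
                            effect = rnorm(p), se = 1, statistic = 0,
                            p = pv, p_adj = pv)
    nrow(dmr_detect(sites, meta))
  })
  # permutation oracle: same detection geometry on permuted position maps
  n_perm <- sapply(1:8, function(r) {
    pv <- runif(p)
    sites <- tibble::tibble(cpg_id = meta$cpg_id, contrast = "risk",
                            effect = rnorm(p), se = 1, statistic = 0,
                            p = pv, p_adj = pv)
    meta_p <- dplyr::mutate(meta, pos = sort(sample(1:500000, p)))
    nrow(dmr_detect(sites, meta_p))
  })
  expect_lt(abs(mean(n_obs) - mean(n_perm)),
            3 * sqrt(mean(n_obs) / 8 + mean(n_perm) / 8) + 1)
})

test_that("EWAS finds a planted causal CpG as the top hit", {
  set.seed(76)
  n <- 400
  M <- matrix(rnorm(n * 50), n, 50)
  y <- 0.65 * M[, 7] + rnorm(n)         # R2 ~ 0.3
  meth <- make_meth(M)
  got <- ewas_scan(meth, y)
  expect_equal(got$cpg_id[which.min(got$p)], "cg007")
  expect_true(got$genome_wide[7])

  # duplicated CpG columns give identical statistics
  M2 <- cbind(M[, 1:3], M[, 3])
  meth2 <- make_meth(M2)
  got2 <- ewas_scan(meth2, y)
  expect_equal(got2$statistic[3], got2$statistic[4], tolerance = 1e-12)

  expect_error(ewas_scan(meth, rep(1, n)), "constant")
})

test_that("EWAS on a null methylome has no genome-wide hits", {
  set.seed(77)
  hits <- sapply(1:20, function(r) {
    M <- matrix(rnorm(100 * 40), 100, 40)
    sum(ewas_scan(make_meth(M), rnorm(100))$genome_wide)
  })
  expect_equal(sum(hits), 0L)
})

test_that("context annotation cross-tab sums to one", {
  meta <- tibble::tibble(cpg_id = paste0("cg", 1:6), chrom = "1",
                         pos = 1:6 * 100L,
                         context = c("TSS200", "TSS200", "Body", "5'UTR",
                                     "Body", "TSS1500"),
                         island = c("Island", "Island", "OpenSea", "Shore",
                                    "Shelf", "Island"))
  recs <- tibble::tibble(cpg_id = meta$cpg_id)
  tab <- annotate_cpg_context(recs, meta)
  expect_equal(sum(tab$fraction), 1, tolerance = 1e-12)

  single <- annotate_cpg_context(recs[1:2, ], meta)
  expect_equal(nrow(single), 1L)
  expect_equal(single$fraction, 1)
  expect_equal(single$context, "TSS200")
})
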