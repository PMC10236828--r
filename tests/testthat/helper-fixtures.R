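# Shared fixtures and independent oracles. Fixtures are built in code at
# test time; the small cohort is memoized so several files can reuse it.

the_fixture_cache <- new.env(parent = emptyenv())

small_cohort <- function(seed = 101) {
  key <- paste0("cohort_", seed)
  if (!exists(key, the_fixture_cache)) {
    cfg <- sim_config(n_cases = 150, n_controls = 75, n_snps = 80,
                      n_cpgs = 40, seed = seed)
    assign(key, simulate_cohort(cfg), the_fixture_cache)
  }
  get(key, the_fixture_cache)
}

# Brute-force greedy clumping verifier: replays the greedy rule decision by
# decision using direct pairwise correlations, independent of ld_clump()'s
# bookkeeping.
clump_oracle <- function(stats, genotypes, r2_threshold, window_kb) {
  meta <- genotypes$snp_meta
  st <- merge(as.data.frame(stats)[c("snp_id", "p")],
              as.data.frame(meta)[c("snp_id", "chrom", "pos")],
              by = "snp_id")
  st <- st[order(st$p, st$snp_id), ]
  removed <- character()
  kept <- character()
  for (i in seq_len(nrow(st))) {
    id <- st$snp_id[i]
    if (id %in% removed) next
    kept <- c(kept, id)
    for (j in seq_len(nrow(st))) {
      jd <- st$snp_id[j]
      if (jd == id || jd %in% removed || jd %in% kept) next
      if (st$chrom[j] != st$chrom[i]) next
      if (abs(st$pos[j] - st$pos[i]) > window_kb * 1000) next
      r <- suppressWarnings(cor(genotypes$dosages[, id],
                                genotypes$dosages[, jd]))
      if (!is.na(r) && r^2 >= r2_threshold) removed <- c(removed, jd)
    }
  }
  sort(kept)
}

# Exhaustive single-causal-variant colocalization enumeration: loops over
# every causal-SNP configuration explicitly, on the log scale so extreme
# Bayes factors cannot overflow.
coloc_oracle <- function(stats_a, stats_b, p1 = 1e-4, p2 = 1e-4,
                         p12 = 1e-5, sd_a = 0.15, sd_b = 0.20) {
  shared <- intersect(stats_a$snp_id, stats_b$snp_id)
  a <- stats_a[match(shared, stats_a$snp_id), ]
  b <- stats_b[match(shared, stats_b$snp_id), ]
  labf <- function(beta, se, w) {
    r <- w^2 / (w^2 + se^2)
    0.5 * (log1p(-r) + r * (beta / se)^2)
  }
  lse <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }
  la <- labf(a$beta, a$se, sd_a)
  lb <- labf(b$beta, b$se, sd_b)
  k <- length(shared)
  l3_terms <- numeric(0)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i != j) l3_terms <- c(l3_terms, la[i] + lb[j])
  }
  l4_terms <- numeric(0)
  for (i in seq_len(k)) l4_terms <- c(l4_terms, la[i] + lb[i])
  ls <- c(0,
          log(p1) + lse(la),
          log(p2) + lse(lb),
          log(p1) + log(p2) + lse(l3_terms),
          log(p12) + lse(l4_terms))
  setNames(exp(ls - lse(ls)), c("pp0", "pp1", "pp2", "pp3", "pp4"))
}

# Pairwise-concordance AUC oracle.
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + (p > n) + 0.5 * (p == n)
  }
  tot / (length(pos) * length(neg))
}

# Region summary stats with one causal SNP per trait, LD-propagated:
# z_j = r_j,causal * z_causal + noise, the standard single-causal model.
region_stats <- function(R, causal, z_causal, n = 10000, maf = 0.3,
                         snp_ids = paste0("rs", seq_len(nrow(R)))) {
  se <- rep(1 / sqrt(2 * n * maf * (1 - maf)), nrow(R))
  z <- as.vector(R[, causal] * z_causal) + rnorm(nrow(R))
  summary_stats(tibble::tibble(
    snp_id = snp_ids, effect_allele = "A", other_allele = "G",
    beta = z * se, se = se,
    p = pmax(2 * pnorm(abs(z), lower.tail = FALSE), 1e-300),
    freq = maf, n = n
  ))
}

ar1_ld <- function(k, rho = 0.8) {
  R <- outer(seq_len(k), seq_len(k), function(i, j) rho^abs(i - j))
  dimnames(R) <- list(paste0("rs", seq_len(k)), paste0("rs", seq_len(k)))
  R
}

write_test_vcf <- function(path, n_multi = 0) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                  "S1\tS2\tS3"))
  recs <- c("1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
            "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t0/1\t0/1\t0/0",
            "1\t300\trs3\tG\tA\t.\tPASS\t.\tGT\t1/1\t0/0\t0/1",
            "1\t400\trs4\tT\tC\t.\tPASS\t.\tGT\t0/0\t0/0\t0/1",
            "1\t500\trs5\tA\tC\t.\tPASS\t.\tGT\t0/1\t1/1\t0/0")
  if (n_multi > 0) {
    recs[2] <- "1\t200\trs2\tC\tT,G\t.\tPASS\t.\tGT\t0/1\t0/2\t0/0"
  }
  writeLines(c(hdr, recs), path)
  path
}
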