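#' Bayesian colocalization by approximate Bayes factors
#'
#' Single-causal-variant colocalization of two traits over a region:
#' per-SNP Wakefield approximate Bayes factors are computed from (beta, se)
#' with a prior effect SD per trait, and the five hypothesis posteriors are
#' formed by summing ABF products over causal-SNP configurations —
#' H0 no association, H1/H2 one trait only, H3 two distinct causal SNPs,
#' H4 a shared causal SNP. All sums are carried in log space; the posterior
#' vector sums to one.
#'
#' @param stats_a,stats_b `summary_stats` tibbles restricted to the region;
#'   SNPs are matched on `snp_id` (at least 2 shared SNPs required).
#' @param p1,p2 prior probability a SNP is causal for trait A / B only.
#' @param p12 prior probability a SNP is causal for both.
#' @param sd_a,sd_b Wakefield prior effect SDs (0.15 suits log-odds effects
#'   of a binary trait; use ~0.2 x phenotype SD for a quantitative trait).
#' @return tibble of class `coloc_result`: `n_snps`, `pp0`..`pp4`, priors.
#' @export
coloc_abf <- function(stats_a, stats_b, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      sd_a = 0.15, sd_b = 0.20) {
  shared <- intersect(stats_a$snp_id, stats_b$snp_id)
  if (length(shared) < 2) abort("need at least 2 shared SNPs in the region")
  a <- stats_a[match(shared, stats_a$snp_id), ]
  b <- stats_b[match(shared, stats_b$snp_id), ]
  if (!all(is.finite(a$beta)) || !all(is.finite(b$beta)) ||
      !all(is.finite(a$se)) || !all(is.finite(b$se))) {
    abort("non-finite beta/se in region")
  }
  la <- wakefield_labf(a$beta, a$se, sd_a)
  lb <- wakefield_labf(b$beta, b$se, sd_b)
  lsum_a <- logsumexp(la)
  lsum_b <- logsumexp(lb)
  lsum_ab <- logsumexp(la + lb)
  # log(sum_{i != j} ABF_a[i] ABF_b[j]) = log(S_a S_b - S_ab)
  l_h3_sum <- logdiff(lsum_a + lsum_b, lsum_ab)
  lh <- c(
    h0 = 0,
    h1 = log(p1) + lsum_a,
    h2 = log(p2) + lsum_b,
    h3 = log(p1) + log(p2) + l_h3_sum,
    h4 = log(p12) + lsum_ab
  )
  pp <- exp(lh - logsumexp(lh))
  out <- tibble::tibble(
    n_snps = length(shared),
    pp0 = pp[["h0"]], pp1 = pp[["h1"]], pp2 = pp[["h2"]],
    pp3 = pp[["h3"]], pp4 = pp[["h4"]],
    p1 = p1, p2 = p2, p12 = p12
  )
  class(out) <- c("coloc_result", class(out))
  out
}

wakefield_labf <- function(beta, se, prior_sd) {
  z2 <- (beta / se)^2
  r <- prior_sd^2 / (prior_sd^2 + se^2)
  0.5 * (log(1 - r) + r * z2)
}

# log(exp(a) - exp(b)) for a >= b, clamped at -Inf when equal
logdiff <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

#' SMR and HEIDI tests
#'
#' Summary-based Mendelian randomization of a methylation exposure on an
#' outcome: at the top exposure SNP (smallest exposure p, required to pass
#' the instrument threshold), the putative effect is
#' `b_xy = b_outcome / b_exposure`, and the SMR statistic is
#' `T = z_exp^2 z_out^2 / (z_exp^2 + z_out^2)`, chi-squared with 1 df.
#' HEIDI tests heterogeneity in dependent instruments: for up to
#' `max_heidi_snps` SNPs in intermediate LD with the top SNP
#' (`r2_range[1] < r^2 < r2_range[2]`), the deviations
#' `d_i = b_xy(i) - b_xy(top)` are combined with their delta-method LD
#' covariance into a sum-of-chi-squares statistic whose null distribution is
#' approximated by Satterthwaite moment matching. A HEIDI p above 0.01
#' supports a single shared causal variant; fewer than 3 eligible SNPs leave
#' the HEIDI p undefined (flagged `NA`).
#'
#' @param exposure,outcome `summary_stats` tibbles over the region's SNPs
#'   (exposure: SNP-on-methylation; outcome: SNP-on-trait).
#' @param ld correlation matrix (r, not r-squared) of region SNP dosages,
#'   dimnames = SNP ids; compute from a [genotype_matrix()] with [ld_matrix()].
#' @param instrument_p instrument threshold for the top SNP (default 5e-8).
#' @param heidi_p_exp exposure-p ceiling for HEIDI SNPs.
#' @param r2_range LD window for HEIDI SNPs relative to the top SNP.
#' @param max_heidi_snps cap on HEIDI SNPs (strongest exposure first).
#' @param probe optional CpG/probe label.
#' @param gene optional gene label.
#' @return tibble of class `smr_result`: `probe`, `gene`, `top_snp`, `b_xy`,
#'   `se_xy`, `t_smr`, `p_smr`, `p_heidi`, `n_heidi_snps`.
#' @export
smr_heidi <- function(exposure, outcome, ld, instrument_p = 5e-8,
                      heidi_p_exp = 1.6e-3, r2_range = c(0.05, 0.9),
                      max_heidi_snps = 20, probe = NA_character_,
                      gene = NA_character_) {
  shared <- Reduce(intersect, list(exposure$snp_id, outcome$snp_id,
                                   colnames(ld)))
  ex <- exposure[match(shared, exposure$snp_id), ]
  ou <- outcome[match(shared, outcome$snp_id), ]
  R <- ld[shared, shared, drop = FALSE]
  top <- which.min(ex$p)
  if (length(top) == 0 || ex$p[top] > instrument_p) {
    abort("no valid instrument: top exposure p exceeds the threshold")
  }
  z_exp <- ex$beta / ex$se
  z_out <- ou$beta / ou$se
  b_xy <- ou$beta / ex$beta
  t_smr <- (z_exp[top]^2 * z_out[top]^2) / (z_exp[top]^2 + z_out[top]^2)
  p_smr <- pchisq(t_smr, df = 1, lower.tail = FALSE)
  se_xy <- abs(b_xy[top]) * sqrt(ou$se[top]^2 / ou$beta[top]^2 +
                                   ex$se[top]^2 / ex$beta[top]^2)
  r2_top <- R[, top]^2
  elig <- which(r2_top > r2_range[1] & r2_top < r2_range[2] &
                  ex$p < heidi_p_exp & seq_along(shared) != top)
  elig <- elig[order(ex$p[elig])]
  if (length(elig) > max_heidi_snps) elig <- elig[seq_len(max_heidi_snps)]
  p_heidi <- NA_real_
  if (length(elig) >= 3) {
    idx <- c(top, elig)
    C <- heidi_cov(ex$beta[idx], ex$se[idx], ou$beta[idx], ou$se[idx],
                   R[idx, idx])
    k <- length(elig)
    Vd <- matrix(NA_real_, k, k)
    for (i in seq_len(k)) for (j in seq_len(k)) {
      Vd[i, j] <- C[i + 1, j + 1] - C[i + 1, 1] - C[j + 1, 1] + C[1, 1]
    }
    d <- b_xy[elig] - b_xy[top]
    sdd <- sqrt(diag(Vd))
    z <- d / sdd
    corr <- Vd / outer(sdd, sdd)
    lambda <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
    lambda <- pmax(lambda, 0)
    stat <- sum(z^2)
    a <- sum(lambda^2) / sum(lambda)
    dfree <- sum(lambda)^2 / sum(lambda^2)
    p_heidi <- pchisq(stat / a, df = dfree, lower.tail = FALSE)
  }
  out <- tibble::tibble(
    probe = probe, gene = gene, top_snp = shared[top],
    b_xy = b_xy[top], se_xy = se_xy,
    t_smr = t_smr, p_smr = p_smr,
    p_heidi = p_heidi, n_heidi_snps = length(elig)
  )
  class(out) <- c("smr_result", class(out))
  out
}

# Delta-method covariance of b_xy across SNPs, exposure and outcome GWAS
# treated as independent samples; index 1 is the top SNP.
heidi_cov <- function(b_exp, se_exp, b_out, se_out, R) {
  cov_out <- R * outer(se_out, se_out)
  cov_exp <- R * outer(se_exp, se_exp)
  term1 <- cov_out / outer(b_exp, b_exp)
  term2 <- outer(b_out, b_out) * cov_exp / outer(b_exp^2, b_exp^2)
  term1 + term2
}

#' LD correlation matrix from genotypes
#'
#' @param genotypes a [genotype_matrix()].
#' @param snp_ids optional subset of SNPs.
#' @return correlation matrix (r) of dosages with SNP-id dimnames.
#' @export
ld_matrix <- function(genotypes, snp_ids = NULL) {
  d <- genotypes$dosages
  if (!is.null(snp_ids)) d <- d[, snp_ids, drop = FALSE]
  suppressWarnings(cor(d))
}
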