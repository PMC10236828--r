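#' Beta-value / M-value transforms
#'
#' Illumina-style methylation beta values (methylated fraction, in `[0, 1]`)
#' are mapped to M-values `M = log2(beta / (1 - beta))` for linear modelling,
#' and back. Betas are clipped to `[eps, 1 - eps]` before the logit so M stays
#' finite; the default `eps = 1e-6` moves no realistic array value.
#'
#' @param beta numeric vector or matrix of beta values.
#' @param m numeric vector or matrix of M-values.
#' @param eps clipping constant applied to beta before the log-ratio.
#' @return numeric object of the same shape.
#' @examples
#' beta_to_m(0.5)      # 0
#' m_to_beta(2)        # 0.8
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' @rdname beta_to_m
#' @export
m_to_beta <- function(m) {
  # 2^m / (2^m + 1), computed stably for large |m|
  1 / (1 + 2^(-m))
}

logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Harmonize summary-statistic alleles to a genotype panel
#'
#' Matches summary-statistic records to panel SNPs on the allele pair. Records
#' whose (effect, other) alleles are swapped relative to the panel's
#' (effect, ref) coding have their effect sign flipped and frequency
#' complemented; records with an incompatible allele pair are dropped.
#' Strand-ambiguous A/T and C/G SNPs are dropped by default since strand
#' cannot be resolved from the alleles alone.
#'
#' @param stats a `summary_stats` tibble (see [load_summary_stats()]).
#' @param snp_meta tibble with columns `snp_id`, `ref_allele`, `effect_allele`.
#' @param drop_ambiguous drop A/T and C/G palindromic SNPs (default `TRUE`).
#' @return the harmonized subset of `stats`, effect alleles aligned to the
#'   panel's `effect_allele`.
#' @export
harmonize_alleles <- function(stats, snp_meta, drop_ambiguous = TRUE) {
  joined <- dplyr::inner_join(
    stats,
    dplyr::select(snp_meta, "snp_id", panel_ref = "ref_allele",
                  panel_eff = "effect_allele"),
    by = "snp_id"
  )
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  if (drop_ambiguous) {
    ambig <- joined$effect_allele == comp[joined$other_allele]
    ambig[is.na(ambig)] <- FALSE
    joined <- joined[!ambig, , drop = FALSE]
  }
  same <- joined$effect_allele == joined$panel_eff &
    joined$other_allele == joined$panel_ref
  flip <- joined$effect_allele == joined$panel_ref &
    joined$other_allele == joined$panel_eff
  out <- joined[same | flip, , drop = FALSE]
  fl <- flip[same | flip]
  out$beta[fl] <- -out$beta[fl]
  if ("freq" %in% names(out)) out$freq[fl] <- 1 - out$freq[fl]
  tmp <- out$effect_allele[fl]
  out$effect_allele[fl] <- out$other_allele[fl]
  out$other_allele[fl] <- tmp
  dplyr::select(out, -"panel_ref", -"panel_eff")
}

# Vectorized OLS of each column of Y on a shared design X.
# Returns per-column coefficient, SE, t and two-sided p for the column of X
# named by `term` (index). Unit-checked against lm() in the test suite.
fast_ols <- function(Y, X, term = 2L) {
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  n <- nrow(X)
  qr_x <- qr(X)
  r <- qr_x$rank
  if (r < ncol(X)) abort("design matrix is rank deficient")
  coefs <- qr.coef(qr_x, Y)                 # p x k
  fitted <- X %*% coefs
  rss <- colSums((Y - fitted)^2)
  df <- n - r
  sigma2 <- rss / df
  xtx_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(outer(diag(xtx_inv), sigma2))  # p x k
  tval <- coefs / se
  tibble::tibble(
    estimate = unname(coefs[term, ]),
    se = unname(se[term, ]),
    statistic = unname(tval[term, ]),
    p = unname(2 * pt(abs(tval[term, ]), df, lower.tail = FALSE)),
    df = df
  )
}

# Residualize columns of a matrix on covariates (with intercept).
residualize <- function(Y, covariates = NULL) {
  Y <- as.matrix(Y)
  X <- cbind(1, covariates_matrix(covariates, nrow(Y)))
  qr_x <- qr(X)
  Y - X %*% qr.coef(qr_x, Y)
}

covariates_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(numeric(0), nrow = n, ncol = 0))
  cm <- as.matrix(as.data.frame(covariates))
  storage.mode(cm) <- "double"
  if (nrow(cm) != n) abort("covariate rows do not match sample count")
  cm
}

check_seed <- function(seed) {
  if (is.null(seed) || !is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort("an explicit integer `seed` is required")
  }
  as.integer(seed)
}
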