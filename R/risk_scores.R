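#' Greedy LD clumping
#'
#' Standard PRS clumping: visit SNPs in ascending association p; retain the
#' SNP and remove every not-yet-processed SNP within `window_kb` whose
#' genotype r-squared with it is at least `r2_threshold`. The retained set is
#' mutually independent at the threshold within the window.
#'
#' @param stats a `summary_stats` tibble.
#' @param genotypes a [genotype_matrix()] providing LD.
#' @param r2_threshold r-squared above which a nearby SNP is clumped away
#'   (default 0.1).
#' @param window_kb physical window in kilobases (default 250).
#' @return tibble of retained SNPs: `snp_id`, `p`, `chrom`, `pos`.
#' @export
ld_clump <- function(stats, genotypes, r2_threshold = 0.1, window_kb = 250) {
  meta <- genotypes$snp_meta
  shared <- intersect(stats$snp_id, meta$snp_id)
  if (length(shared) == 0) abort("no overlap between summary stats and genotypes")
  st <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(stats), "snp_id", "p"),
    dplyr::select(meta, "snp_id", "chrom", "pos"), by = "snp_id"
  ) |> dplyr::arrange(.data$p, .data$snp_id)
  dos <- genotypes$dosages[, st$snp_id, drop = FALSE]
  window <- window_kb * 1000
  alive <- rep(TRUE, nrow(st))
  keep <- logical(nrow(st))
  for (i in seq_len(nrow(st))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[i] <- FALSE
    cand <- which(alive & st$chrom == st$chrom[i] &
                    abs(st$pos - st$pos[i]) <= window)
    if (length(cand)) {
      r <- suppressWarnings(cor(dos[, i], dos[, cand, drop = FALSE]))
      r[is.na(r)] <- 0
      alive[cand[r^2 >= r2_threshold]] <- FALSE
    }
  }
  st[keep, , drop = FALSE]
}

#' Polygenic risk scoring with threshold scan and permutation empirical P
#'
#' Scores each sample as the harmonized weighted allele sum over clumped
#' SNPs with GWAS `p` at or below each threshold; the best threshold
#' maximizes the incremental association R-squared of the score against the
#' phenotype on top of the covariates (Nagelkerke pseudo-R2 from a logistic
#' fit for binary phenotypes, OLS R2 otherwise). The empirical P is the
#' add-one permutation rule
#' `(1 + #\{permuted best-model p <= observed best-model p\}) / (B + 1)`,
#' permuting phenotype labels, so it is never zero.
#'
#' @param stats a `summary_stats` tibble.
#' @param genotypes a [genotype_matrix()].
#' @param phenotype numeric vector (binary 0/1 or continuous), one per sample.
#' @param covariates optional data frame of covariates (e.g. PCs, batch).
#' @param thresholds p-value threshold grid.
#' @param n_permutations permutation count B (default 1000; configurable up to
#'   10,000 for a confirmatory run).
#' @param r2_threshold,window_kb clumping parameters, see [ld_clump()].
#' @param seed integer seed for the permutations.
#' @return object of class `prs_result`: list with `scores` (tibble
#'   `sample_id`, `score` at the best threshold), `by_threshold` (tibble
#'   `threshold`, `n_snps`, `estimate`, `p`, `r2`), `best_threshold`,
#'   `empirical_p`.
#' @export
prs_score <- function(stats, genotypes, phenotype, covariates = NULL,
                      thresholds = c(5e-8, 1e-6, 1e-4, 1e-3, 0.01, 0.05,
                                     0.1, 0.5, 1),
                      n_permutations = 1000, r2_threshold = 0.1,
                      window_kb = 250, seed = 1) {
  seed <- check_seed(seed)
  clumped <- ld_clump(stats, genotypes, r2_threshold, window_kb)
  harm <- harmonize_alleles(tibble::as_tibble(stats)[stats$snp_id %in%
                                                       clumped$snp_id, ],
                            genotypes$snp_meta)
  if (nrow(harm) == 0) abort("no SNPs left after clumping/harmonization")
  thresholds <- sort(thresholds)
  dos <- genotypes$dosages[, harm$snp_id, drop = FALSE]
  binary <- all(phenotype %in% c(0, 1))
  cm <- covariates_matrix(covariates, length(phenotype))
  score_at <- function(thr) {
    use <- harm$p <= thr
    if (!any(use)) return(NULL)
    list(score = as.vector(dos[, use, drop = FALSE] %*% harm$beta[use]),
         n_snps = sum(use))
  }
  assoc <- function(score, y) {
    X0 <- if (ncol(cm)) cbind(1, cm) else matrix(1, length(y), 1)
    X1 <- cbind(X0, score)
    if (binary) {
      f0 <- glm.fit(X0, y, family = binomial())
      f1 <- glm.fit(X1, y, family = binomial())
      n <- length(y)
      # Nagelkerke pseudo-R2 of the score on top of covariates
      r2_cs <- 1 - exp((f1$deviance - f0$deviance) / n)
      r2 <- r2_cs / (1 - exp(-f0$null.deviance / n))
      z <- coef_z_glm(f1, X1)
      list(estimate = f1$coefficients[ncol(X1)], p = z$p, r2 = r2)
    } else {
      fit <- fast_ols(matrix(y), X1, term = ncol(X1))
      rss1 <- sum((y - X1 %*% qr.coef(qr(X1), y))^2)
      rss0 <- sum((y - X0 %*% qr.coef(qr(X0), y))^2)
      list(estimate = fit$estimate, p = fit$p, r2 = (rss0 - rss1) / rss0)
    }
  }
  eval_grid <- function(y) {
    purrr::map(thresholds, function(thr) {
      s <- score_at(thr)
      if (is.null(s)) return(NULL)
      a <- assoc(s$score, y)
      tibble::tibble(threshold = thr, n_snps = s$n_snps,
                     estimate = a$estimate, p = a$p, r2 = a$r2)
    }) |> purrr::list_rbind()
  }
  grid <- eval_grid(phenotype)
  if (is.null(grid) || nrow(grid) == 0) {
    abort("zero SNPs pass every p-value threshold")
  }
  best <- grid[which.max(grid$r2), ]
  obs_p <- best$p
  set.seed(seed)
  perm_hits <- 0L
  for (b in seq_len(n_permutations)) {
    yb <- sample(phenotype)
    gb <- eval_grid(yb)
    if (min(gb$p) <= obs_p) perm_hits <- perm_hits + 1L
  }
  empirical_p <- (1 + perm_hits) / (n_permutations + 1)
  sc <- score_at(best$threshold)
  structure(list(
    scores = tibble::tibble(sample_id = rownames(genotypes$dosages),
                            score = sc$score),
    by_threshold = grid,
    best_threshold = best$threshold,
    empirical_p = empirical_p,
    n_permutations = n_permutations,
    binary = binary
  ), class = "prs_result")
}

coef_z_glm <- function(fit, X) {
  # Wald z for the last coefficient of a glm.fit result
  w <- fit$weights
  XtWX <- crossprod(X * sqrt(w))
  vc <- tryCatch(chol2inv(chol(XtWX)), error = function(e) MASS_ginv(XtWX))
  se <- sqrt(diag(vc))
  z <- fit$coefficients / se
  k <- length(z)
  list(z = z[k], p = 2 * pnorm(abs(z[k]), lower.tail = FALSE))
}

MASS_ginv <- function(X) {
  s <- svd(X)
  pos <- s$d > max(s$d) * 1e-12
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' @export
print.prs_result <- function(x, ...) {
  cat(sprintf("<prs_result> best threshold %g (%d SNPs), empirical P = %.4g\n",
              x$best_threshold,
              x$by_threshold$n_snps[x$by_threshold$threshold == x$best_threshold],
              x$empirical_p))
  invisible(x)
}

#' @export
tidy.prs_result <- function(x, ...) x$by_threshold

#' @export
glance.prs_result <- function(x, ...) {
  best <- x$by_threshold[which.max(x$by_threshold$r2), ]
  tibble::tibble(best_threshold = x$best_threshold, n_snps = best$n_snps,
                 r2 = best$r2, p = best$p, empirical_p = x$empirical_p,
                 n_permutations = x$n_permutations)
}

#' Genotype principal components
#'
#' PCs of the standardized dosage matrix; returns the smallest number of
#' components whose cumulative explained variance reaches `variance_target`
#' (default 95%), the set used as PRS covariates.
#'
#' @param genotypes a [genotype_matrix()].
#' @param variance_target cumulative explained-variance target in (0, 1].
#' @return matrix of PC scores (samples x k) with a `"explained"` attribute.
#' @export
genotype_pcs <- function(genotypes, variance_target = 0.95) {
  X <- genotypes$dosages
  sds <- apply(X, 2, sd)
  X <- X[, sds > 0, drop = FALSE]
  pc <- prcomp(X, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  k <- which(cumsum(ev) >= variance_target - 1e-12)[1]
  out <- pc$x[, seq_len(k), drop = FALSE]
  attr(out, "explained") <- ev[seq_len(k)]
  out
}

#' Fixed-weight genetic risk score
#'
#' Weighted allele sum for an externally supplied weight file (e.g. a
#' previously reported biomarker panel), with allele harmonization: flipping
#' a weight file's alleles and negating its weights leaves scores unchanged.
#'
#' @param weights tibble (`snp_id`, `effect_allele`, `weight`); an optional
#'   `other_allele` column enables full harmonization, otherwise the effect
#'   allele is matched against the panel's two alleles.
#' @param genotypes a [genotype_matrix()].
#' @return tibble `sample_id`, `score`; SNPs absent from the panel are
#'   reported and skipped; zero overlap is an error.
#' @export
grs_score <- function(weights, genotypes) {
  w <- tibble::as_tibble(weights)
  meta <- genotypes$snp_meta
  w <- dplyr::inner_join(w, dplyr::select(meta, "snp_id",
                                          panel_ref = "ref_allele",
                                          panel_eff = "effect_allele"),
                         by = "snp_id")
  n_missing <- length(setdiff(weights$snp_id, meta$snp_id))
  if (nrow(w) == 0) abort("no weight-file SNPs overlap the genotype panel")
  if (n_missing > 0) {
    inform(sprintf("grs_score: %d weight-file SNP(s) absent from panel",
                   n_missing))
  }
  sign_flip <- ifelse(toupper(w$effect_allele) == w$panel_eff, 1,
                      ifelse(toupper(w$effect_allele) == w$panel_ref, -1, NA))
  if (anyNA(sign_flip)) {
    inform(sprintf("grs_score: dropped %d SNP(s) with unmatched alleles",
                   sum(is.na(sign_flip))))
    w <- w[!is.na(sign_flip), , drop = FALSE]
    sign_flip <- sign_flip[!is.na(sign_flip)]
    if (nrow(w) == 0) abort("no weight-file SNPs with matching alleles")
  }
  dos <- genotypes$dosages[, w$snp_id, drop = FALSE]
  # sign-flip harmonization: weights are re-expressed on the panel's effect
  # allele, so a weight file with swapped alleles and negated weights scores
  # identically
  score <- as.vector(dos %*% (w$weight * sign_flip))
  tibble::tibble(sample_id = rownames(genotypes$dosages), score = score)
}

#' Two-stage polymethylation score (PMS)
#'
#' Stage 1 fits, per pathway, a ridge-penalized logistic classifier on the
#' pathway's CpG M-values and records strictly out-of-fold case
#' probabilities, averaged over `n_bootstrap` bootstrap refits. Stage 2 fits
#' a probability forest on the stage-1 pathway-score matrix, again scored
#' out of fold. The PMS is the stage-2 out-of-fold case probability, a
#' quantified score in `[0, 1]` for the likelihood of being a case; no
#' sample's score is ever produced by a model that saw it.
#'
#' @param methylome a [methylation_matrix()].
#' @param case_labels binary vector (1 = case), one per sample.
#' @param pathway_map named list: pathway -> character vector of CpG ids.
#' @param n_bootstrap bootstrap refits per stage-1 fold model (the source
#'   protocol used 1000; default here is desk-scale).
#' @param cv_folds fold count for the out-of-fold scheme.
#' @param seed integer seed.
#' @return object of class `pms_result`: `scores` tibble (`sample_id`,
#'   `pms`), `pathway_scores` matrix, `auc` (out-of-fold).
#' @export
pms_fit_score <- function(methylome, case_labels, pathway_map,
                          n_bootstrap = 25, cv_folds = 5, seed = 1) {
  seed <- check_seed(seed)
  M <- beta_to_m(methylome$betas)
  present <- purrr::map(pathway_map, ~ intersect(.x, colnames(M)))
  empty <- purrr::map_int(present, length) == 0
  if (any(empty)) {
    warn(sprintf("dropping %d pathway(s) with no mapped CpGs", sum(empty)))
    present <- present[!empty]
  }
  if (length(present) == 0) abort("every pathway had zero mapped CpGs")
  y <- as.integer(case_labels)
  n <- length(y)
  set.seed(seed)
  folds <- sample(rep(seq_len(cv_folds), length.out = n))
  oof_pathway <- matrix(NA_real_, n, length(present),
                        dimnames = list(rownames(M), names(present)))
  for (k in seq_along(present)) {
    Xp <- M[, present[[k]], drop = FALSE]
    for (f in seq_len(cv_folds)) {
      tr <- folds != f
      preds <- matrix(0, sum(!tr), n_bootstrap)
      for (b in seq_len(n_bootstrap)) {
        idx <- sample(which(tr), sum(tr), replace = TRUE)
        # ensure both classes present in the bootstrap resample
        if (length(unique(y[idx])) < 2) idx <- which(tr)
        fit <- glmnet::glmnet(cbind(Xp[idx, , drop = FALSE], 0), y[idx],
                              family = "binomial", alpha = 0,
                              lambda = 0.1)
        preds[, b] <- predict(fit,
                              cbind(Xp[!tr, , drop = FALSE], 0),
                              type = "response")[, 1]
      }
      oof_pathway[!tr, k] <- rowMeans(preds)
    }
  }
  pms <- rep(NA_real_, n)
  for (f in seq_len(cv_folds)) {
    tr <- folds != f
    fit <- ranger::ranger(
      x = as.data.frame(oof_pathway[tr, , drop = FALSE]),
      y = factor(y[tr], levels = c(0, 1)),
      probability = TRUE, num.trees = 300, seed = seed + f
    )
    pms[!tr] <- predict(fit,
                        data = as.data.frame(oof_pathway[!tr, , drop = FALSE])
    )$predictions[, "1"]
  }
  structure(list(
    scores = tibble::tibble(sample_id = rownames(M), pms = pms),
    pathway_scores = oof_pathway,
    auc = auc_rank(pms, y),
    n_bootstrap = n_bootstrap, cv_folds = cv_folds
  ), class = "pms_result")
}

#' @export
print.pms_result <- function(x, ...) {
  cat(sprintf("<pms_result> %d samples, %d pathways, out-of-fold AUC %.3f\n",
              nrow(x$scores), ncol(x$pathway_scores), x$auc))
  invisible(x)
}

#' @export
tidy.pms_result <- function(x, ...) x$scores

#' Linear epigenetic clock age
#'
#' Applies a linear clock (intercept + per-CpG weights on beta values) and,
#' in `"adult-log"` mode, the standard inverse log-linear age transform
#' (log scale below the adult threshold of 20 years, linear above).
#'
#' @param methylome a [methylation_matrix()].
#' @param coefficients tibble (`cpg_id`, `weight`).
#' @param intercept clock intercept.
#' @param transform_mode `"none"` or `"adult-log"`.
#' @param adult_age threshold of the log-linear transform.
#' @return tibble `sample_id`, `dnam_age`.
#' @export
dnam_age <- function(methylome, coefficients, intercept = 0,
                     transform_mode = c("none", "adult-log"),
                     adult_age = 20) {
  transform_mode <- match.arg(transform_mode)
  co <- tibble::as_tibble(coefficients)
  shared <- intersect(co$cpg_id, colnames(methylome$betas))
  if (length(shared) == 0) abort("no clock CpGs present in the methylome")
  w <- co$weight[match(shared, co$cpg_id)]
  lin <- intercept + as.vector(methylome$betas[, shared, drop = FALSE] %*% w)
  age <- if (transform_mode == "adult-log") {
    ifelse(lin < 0, (1 + adult_age) * exp(lin) - 1,
           (1 + adult_age) * lin + adult_age)
  } else lin
  tibble::tibble(sample_id = rownames(methylome$betas), dnam_age = age)
}

#' Epigenetic age acceleration
#'
#' Residuals of an OLS regression of methylation age on chronological age;
#' by construction the residual mean over the fitted set is zero.
#'
#' @param dnam_age numeric vector of methylation ages.
#' @param chron_age numeric vector of chronological ages.
#' @return numeric vector of residuals (years).
#' @export
age_acceleration <- function(dnam_age, chron_age) {
  if (length(dnam_age) < 3) abort("need at least 3 samples")
  if (sd(chron_age) == 0) abort("chronological age is constant; regression degenerate")
  unname(resid(lm(dnam_age ~ chron_age)))
}
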