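#' Deterministic train/test split
#'
#' Disjoint, exhaustive partition of the sample ids with
#' `round(n * ratio)` training samples, drawn without replacement under the
#' seed.
#'
#' @param sample_ids character vector of ids.
#' @param ratio training fraction in (0, 1); default 7:3.
#' @param seed integer seed.
#' @return list with `train` and `test` id vectors.
#' @export
split_cohort <- function(sample_ids, ratio = 0.7, seed) {
  seed <- check_seed(seed)
  n <- length(sample_ids)
  if (n < 10) abort("need at least 10 samples to split")
  if (ratio <= 0 || ratio >= 1) abort("ratio must be in (0, 1)")
  set.seed(seed)
  n_train <- round(n * ratio)
  tr <- sample(sample_ids, n_train)
  list(train = tr, test = setdiff(sample_ids, tr))
}

#' Leakage-safe feature preprocessor
#'
#' Fits, on training data only, a per-feature rank-based inverse-normal
#' (Gaussian) mapping followed by standardization with the training moments
#' of the mapped values, so applying the preprocessor to its own training
#' data gives exactly mean 0, SD 1 per feature. Unseen test values are
#' mapped through linear interpolation of the training empirical CDF with
#' boundary clamping — no test statistic ever enters the fit.
#' Zero-variance features are passed through unchanged with a warning.
#'
#' @param train data frame or matrix of numeric training features.
#' @return object of class `preprocessor`.
#' @export
fit_preprocessor <- function(train) {
  X <- as.matrix(train)
  storage.mode(X) <- "double"
  feats <- purrr::map(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    if (sd(x) == 0) return(list(constant = TRUE))
    sx <- sort(x)
    px <- (seq_along(sx) - 0.5) / length(sx)
    # collapse tied knots for interpolation
    agg <- tapply(px, sx, mean)
    knots_x <- as.numeric(names(agg))
    knots_p <- as.numeric(agg)
    z <- qnorm(approx(knots_x, knots_p, xout = x, rule = 2,
                      ties = "ordered")$y)
    list(constant = FALSE, knots_x = knots_x, knots_p = knots_p,
         mu = mean(z), sigma = sd(z))
  })
  n_const <- sum(purrr::map_lgl(feats, "constant"))
  if (n_const > 0) {
    warn(sprintf("%d zero-variance feature(s) passed through unchanged",
                 n_const))
  }
  structure(list(features = setNames(feats, colnames(X)),
                 names = colnames(X)),
            class = "preprocessor")
}

#' @rdname fit_preprocessor
#' @param pre a fitted `preprocessor`.
#' @param newdata data frame or matrix with the training columns.
#' @export
apply_preprocessor <- function(pre, newdata) {
  X <- as.matrix(newdata)[, pre$names, drop = FALSE]
  storage.mode(X) <- "double"
  for (j in seq_along(pre$features)) {
    f <- pre$features[[j]]
    if (f$constant) next
    z <- qnorm(approx(f$knots_x, f$knots_p, xout = X[, j], rule = 2,
                      ties = "ordered")$y)
    X[, j] <- (z - f$mu) / f$sigma
  }
  X
}

#' Train a per-CpG proxy methylation model
#'
#' Regresses a CpG's M-value on its significant cis-meQTL SNP dosages
#' (clumped at r-squared 0.8 to remove duplicated columns) plus age and sex.
#' Features are preprocessed leakage-safely ([fit_preprocessor()]);
#' hyperparameters are tuned by random search over repeated k-fold CV
#' (LOOCV below 30 training samples) and the best setting refit on all
#' training data.
#'
#' @param genotypes training-cohort [genotype_matrix()].
#' @param methylome training-cohort [methylation_matrix()].
#' @param covars tibble with `age` and `sex` aligned to the samples.
#' @param cpg_id target CpG.
#' @param meqtls meQTL table from [meqtl_scan()]; rows with `is_meqtl` for
#'   this CpG supply the feature SNPs.
#' @param algorithm `"qrf"`, `"rf"` or `"svmPoly"`.
#' @param search_budget random-search draws (default 25).
#' @param cv_folds,cv_repeats CV scheme (10 x tenfold for a confirmatory
#'   run; smaller folds suit simulation loops).
#' @param seed integer seed.
#' @return object of class `proxy_model`.
#' @export
train_proxy <- function(genotypes, methylome, covars, cpg_id, meqtls,
                        algorithm = c("qrf", "rf", "svmPoly"),
                        search_budget = 25, cv_folds = 10, cv_repeats = 1,
                        seed = 1) {
  algorithm <- match.arg(algorithm)
  seed <- check_seed(seed)
  snps <- unique(meqtls$snp_id[meqtls$cpg_id == cpg_id &
                                 (meqtls$is_meqtl %||% TRUE)])
  snps <- intersect(snps, genotypes$snp_meta$snp_id)
  if (length(snps) == 0) abort(paste0("no meQTL SNPs for ", cpg_id))
  # drop duplicated-information SNPs (pairwise r2 >= 0.8), keeping the
  # first of each correlated pair in meQTL order
  if (length(snps) > 1) {
    r2 <- suppressWarnings(cor(genotypes$dosages[, snps, drop = FALSE]))^2
    keep <- rep(TRUE, length(snps))
    for (i in seq_along(snps)[-1]) {
      if (any(r2[i, seq_len(i - 1)][keep[seq_len(i - 1)]] >= 0.8,
              na.rm = TRUE)) keep[i] <- FALSE
    }
    snps <- snps[keep]
  }
  X <- cbind(genotypes$dosages[, snps, drop = FALSE],
             age = covars$age, sex = covars$sex)
  y <- beta_to_m(methylome$betas[, cpg_id])
  pre <- fit_preprocessor(X)
  Xp <- apply_preprocessor(pre, X)
  tuned <- random_search_cv(Xp, y, algorithm, search_budget,
                            cv_folds, cv_repeats, seed)
  structure(list(
    cpg_id = cpg_id, snps = snps, algorithm = algorithm,
    preprocessor = pre, fit = tuned$fit, params = tuned$params,
    cv_rmse = tuned$cv_rmse, cv_r2 = tuned$cv_r2,
    cv = list(folds = cv_folds, repeats = cv_repeats,
              n_folds = tuned$n_folds),
    seed = seed,
    pearson_r = NA_real_, pearson_p = NA_real_, selected = NA
  ), class = "proxy_model")
}

#' @export
print.proxy_model <- function(x, ...) {
  cat(sprintf("<proxy_model> %s (%s, %d SNPs + age + sex), CV R2 %.3f\n",
              x$cpg_id, x$algorithm, length(x$snps), x$cv_r2))
  invisible(x)
}

#' Predict with a proxy model
#' @param object a `proxy_model`.
#' @param genotypes a [genotype_matrix()].
#' @param covars tibble with `age`, `sex`.
#' @param ... unused.
#' @return numeric vector of predicted M-values.
#' @export
predict.proxy_model <- function(object, genotypes, covars, ...) {
  missing_snps <- setdiff(object$snps, genotypes$snp_meta$snp_id)
  if (length(missing_snps)) {
    abort(sprintf("model %s: SNP(s) %s absent from genotypes",
                  object$cpg_id, paste(missing_snps, collapse = ", ")))
  }
  X <- cbind(genotypes$dosages[, object$snps, drop = FALSE],
             age = covars$age, sex = covars$sex)
  predict_learner(object$fit, apply_preprocessor(object$preprocessor, X),
                  object$algorithm)
}

#' Evaluate proxy models on held-out data and select
#'
#' Per model, the Pearson correlation between observed and predicted
#' M-values on the test set with its two-sided p; models with
#' `pearson_p <= p_gate` are selected, and when several algorithms model the
#' same CpG the selected model with the highest r is kept. Constant
#' predictions leave r undefined and the model unselected (with a warning).
#'
#' @param models list of `proxy_model` objects.
#' @param genotypes,methylome,covars the held-out test cohort (must be
#'   disjoint from training).
#' @param p_gate selection threshold on the Pearson p (default 0.05).
#' @return list: `models` (with `pearson_r`, `pearson_p`, `selected`
#'   filled), `kept` (best selected model per CpG), `summary` tibble.
#' @export
evaluate_and_select <- function(models, genotypes, methylome, covars,
                                p_gate = 0.05) {
  models <- purrr::map(models, function(m) {
    pred <- predict(m, genotypes, covars)
    obs <- beta_to_m(methylome$betas[, m$cpg_id])
    if (sd(pred) == 0 || sd(obs) == 0) {
      warn(sprintf("model %s: constant predictions; not selected", m$cpg_id))
      m$pearson_r <- NA_real_; m$pearson_p <- NA_real_; m$selected <- FALSE
    } else {
      ct <- cor.test(obs, pred)
      m$pearson_r <- unname(ct$estimate)
      m$pearson_p <- ct$p.value
      m$selected <- ct$p.value <= p_gate
    }
    m
  })
  smry <- purrr::map(models, function(m) tibble::tibble(
    cpg_id = m$cpg_id, algorithm = m$algorithm, n_snps = length(m$snps),
    cv_r2 = m$cv_r2, pearson_r = m$pearson_r, pearson_p = m$pearson_p,
    selected = m$selected
  )) |> purrr::list_rbind()
  kept <- smry |>
    dplyr::filter(.data$selected) |>
    dplyr::group_by(.data$cpg_id) |>
    dplyr::slice_max(.data$pearson_r, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  kept_models <- purrr::keep(models, function(m) {
    any(kept$cpg_id == m$cpg_id & kept$algorithm == m$algorithm)
  })
  list(models = models, kept = kept_models, summary = smry)
}

#' Impute proxy methylation features
#'
#' One column of predicted methylation (M-value scale) per selected proxy
#' model, for any cohort carrying the model's SNPs plus age and sex.
#'
#' @param models list of selected `proxy_model` objects.
#' @param genotypes a [genotype_matrix()].
#' @param covars tibble with `age`, `sex`.
#' @return numeric matrix (samples x CpGs), `proxy_` column prefix; a
#'   zero-column matrix with a warning when no model is supplied.
#' @export
impute_methylation <- function(models, genotypes, covars) {
  if (length(models) == 0) {
    warn("no selected proxy models; returning empty matrix")
    return(matrix(numeric(0), nrow = nrow(genotypes$dosages), ncol = 0,
                  dimnames = list(rownames(genotypes$dosages), NULL)))
  }
  cols <- purrr::map(models, predict, genotypes = genotypes, covars = covars)
  out <- do.call(cbind, cols)
  colnames(out) <- paste0("proxy_", purrr::map_chr(models, "cpg_id"))
  rownames(out) <- rownames(genotypes$dosages)
  out
}

#' Filter candidate CpGs by brain-blood methylation correlation
#'
#' Retains CpGs whose blood methylation correlates with brain methylation
#' in an external correlation table (`p <= p_threshold` and
#' `|r| >= r_threshold`); CpGs absent from the table are excluded with a
#' warning.
#'
#' @param candidate_cpgs character vector.
#' @param correlation_table tibble (`cpg_id`, `r`, `p`).
#' @param r_threshold minimum `|r|` (default 0).
#' @param p_threshold maximum p (default 0.05).
#' @return character vector of retained CpGs.
#' @export
brain_blood_filter <- function(candidate_cpgs, correlation_table,
                               r_threshold = 0, p_threshold = 0.05) {
  tab <- tibble::as_tibble(correlation_table)
  absent <- setdiff(candidate_cpgs, tab$cpg_id)
  if (length(absent)) {
    warn(sprintf("%d candidate CpG(s) absent from the correlation table",
                 length(absent)))
  }
  hit <- tab[tab$cpg_id %in% candidate_cpgs &
               tab$p <= p_threshold & abs(tab$r) >= r_threshold, ]
  hit$cpg_id
}

#' @export
tidy.proxy_model <- function(x, ...) {
  tibble::tibble(cpg_id = x$cpg_id, algorithm = x$algorithm,
                 n_snps = length(x$snps), cv_rmse = x$cv_rmse,
                 cv_r2 = x$cv_r2, pearson_r = x$pearson_r,
                 pearson_p = x$pearson_p, selected = x$selected)
}
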