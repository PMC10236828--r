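#' Rank-based AUC
#'
#' Area under the ROC curve computed as the normalized Mann-Whitney U
#' statistic (probability a random positive outscores a random negative,
#' ties counted half).
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (1/TRUE = positive) or a factor/character
#'   whose second sorted level is positive.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  y <- as_binary_labels(labels)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) abort("numeric labels must be 0/1")
    return(as.integer(labels))
  }
  f <- factor(labels)
  if (nlevels(f) > 2) abort("labels must be binary")
  # convention: "RES" is the positive class when present
  pos <- if ("RES" %in% levels(f)) "RES" else levels(f)[nlevels(f)]
  as.integer(f == pos)
}

#' DeLong confidence interval for an AUC
#'
#' Deterministic variance estimate from the placement values of DeLong,
#' DeLong and Clarke-Pearson; the CI is on the logit scale when the AUC is
#' interior, clamped to `[0, 1]`.
#'
#' @param scores,labels as in [auc_rank()].
#' @param conf confidence level.
#' @return tibble `auc`, `ci_lo`, `ci_hi`, `se`.
#' @export
auc_delong_ci <- function(scores, labels, conf = 0.95) {
  y <- as_binary_labels(labels)
  xs <- scores[y == 1]
  ys <- scores[y == 0]
  m <- length(xs); n <- length(ys)
  if (m == 0 || n == 0) {
    return(tibble::tibble(auc = NA_real_, ci_lo = NA_real_,
                          ci_hi = NA_real_, se = NA_real_))
  }
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  V10 <- vapply(xs, function(x) mean(psi(x, ys)), numeric(1))
  V01 <- vapply(ys, function(yv) mean(psi(xs, yv)), numeric(1))
  auc <- mean(V10)
  s2 <- var(V10) / m + var(V01) / n
  se <- sqrt(s2)
  zq <- qnorm(1 - (1 - conf) / 2)
  tibble::tibble(auc = auc,
                 ci_lo = max(0, auc - zq * se),
                 ci_hi = min(1, auc + zq * se),
                 se = se)
}

#' Regression error metrics
#'
#' MAE, RMSE, MAPE (targets with `|y| < 1e-8` excluded, count reported as an
#' attribute), R-squared (`1 - SSres/SStot`, may be negative) and Pearson r
#' with a Fisher-z confidence interval.
#'
#' @param y observed values.
#' @param y_hat predicted values.
#' @param conf confidence level of the Pearson CI.
#' @return tibble `mae`, `rmse`, `mape`, `r_squared`, `pearson_r`,
#'   `pearson_lo`, `pearson_hi`, `n`, `n_mape_excluded`.
#' @export
regression_metrics <- function(y, y_hat, conf = 0.95) {
  err <- y - y_hat
  mae <- mean(abs(err))
  rmse <- sqrt(mean(err^2))
  ok <- abs(y) >= 1e-8
  mape <- if (any(ok)) mean(abs(err[ok]) / abs(y[ok])) else NA_real_
  r2 <- 1 - sum(err^2) / sum((y - mean(y))^2)
  pr <- pearson_fisher_ci(y, y_hat, conf)
  tibble::tibble(mae = mae, rmse = rmse, mape = mape, r_squared = r2,
                 pearson_r = pr$r, pearson_lo = pr$lo, pearson_hi = pr$hi,
                 n = length(y), n_mape_excluded = sum(!ok))
}

pearson_fisher_ci <- function(x, y, conf = 0.95) {
  if (sd(x) == 0 || sd(y) == 0) return(list(r = NA_real_, lo = NA_real_,
                                            hi = NA_real_))
  r <- cor(x, y)
  n <- length(x)
  if (n < 4) return(list(r = r, lo = NA_real_, hi = NA_real_))
  z <- atanh(min(max(r, -1 + 1e-12), 1 - 1e-12))
  sz <- 1 / sqrt(n - 3)
  zq <- qnorm(1 - (1 - conf) / 2)
  list(r = r, lo = tanh(z - zq * sz), hi = tanh(z + zq * sz))
}

#' Correlation of a risk score with an outcome
#'
#' Pearson correlation with Fisher-z CI; when covariates are supplied, the
#' partial correlation is computed by residualizing both variables on the
#' covariates (with intercept), with degrees of freedom reduced accordingly.
#'
#' @param score,outcome numeric vectors (n of at least 10).
#' @param covariates optional covariate data frame (e.g. drug, sex, age).
#' @param conf confidence level.
#' @return tibble `r`, `ci_lo`, `ci_hi`, `p`, `n`, `partial`.
#' @export
score_outcome_association <- function(score, outcome, covariates = NULL,
                                      conf = 0.95) {
  if (length(score) < 10) abort("need at least 10 samples")
  if (sd(score) == 0 || sd(outcome) == 0) abort("constant input")
  k <- 0L
  if (!is.null(covariates)) {
    cm <- covariates_matrix(covariates, length(score))
    k <- ncol(cm)
    score <- residualize(matrix(score), cm)[, 1]
    outcome <- residualize(matrix(outcome), cm)[, 1]
  }
  n <- length(score)
  if (sd(score) < 1e-12 || sd(outcome) < 1e-12) {
    return(tibble::tibble(r = 0, ci_lo = NA_real_, ci_hi = NA_real_, p = 1,
                          n = n, partial = k > 0))
  }
  r <- cor(score, outcome)
  df <- n - 2L - k
  tstat <- r * sqrt(df / (1 - r^2))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  z <- atanh(min(max(r, -1 + 1e-12), 1 - 1e-12))
  sz <- 1 / sqrt(n - 3 - k)
  zq <- qnorm(1 - (1 - conf) / 2)
  tibble::tibble(r = r, ci_lo = tanh(z - zq * sz), ci_hi = tanh(z + zq * sz),
                 p = p, n = n, partial = k > 0)
}
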