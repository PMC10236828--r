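#' Assemble a feature matrix for one combination pattern
#'
#' Builds the design for the four combination patterns:
#' `C+P` (clinical + PRS), `C+G` (clinical + GRS), `C+M`
#' (clinical + proxyDNAm) and `C+PGM` (all blocks). The clinical block is
#' PANSS baseline, age, sex and a full drug-arm one-hot (dummies sum to 1
#' per sample); the target is the scaled reduction rate and the binary
#' target the RES label. Samples missing any requested block are dropped
#' with a message. Column order is deterministic.
#'
#' @param phenotypes trial phenotype tibble (cases; needs `sample_id`,
#'   `panss_baseline`, `age`, `sex`, `arm`, `scaled_rate`, `res_label` —
#'   run [derive_outcomes()] first).
#' @param prs optional tibble/matrix of PRS columns with `sample_id` (e.g.
#'   scores for several psychiatric traits).
#' @param grs optional tibble `sample_id`, `score`.
#' @param proxydnam optional matrix from [impute_methylation()] (rownames =
#'   sample ids).
#' @param pattern one of `"C+P"`, `"C+G"`, `"C+M"`, `"C+PGM"`.
#' @return list of class `feature_set`: `x` (numeric matrix), `y` (scaled
#'   rate), `res` (labels), `sample_id`, `pattern`.
#' @export
assemble_features <- function(phenotypes, prs = NULL, grs = NULL,
                              proxydnam = NULL,
                              pattern = c("C+PGM", "C+P", "C+G", "C+M")) {
  pattern <- match.arg(pattern)
  need_p <- pattern %in% c("C+P", "C+PGM")
  need_g <- pattern %in% c("C+G", "C+PGM")
  need_m <- pattern %in% c("C+M", "C+PGM")
  if (need_p && is.null(prs)) abort(paste0(pattern, " requires a PRS block"))
  if (need_g && is.null(grs)) abort(paste0(pattern, " requires a GRS block"))
  if (need_m && is.null(proxydnam)) {
    abort(paste0(pattern, " requires a proxyDNAm block"))
  }
  ph <- dplyr::filter(tibble::as_tibble(phenotypes),
                      !is.na(.data$scaled_rate), !is.na(.data$arm))
  arms <- sort(unique(ph$arm))
  arm_oh <- outer(ph$arm, arms, "==") * 1
  colnames(arm_oh) <- paste0("arm_", arms)
  X <- cbind(panss_baseline = ph$panss_baseline, age = ph$age, sex = ph$sex,
             arm_oh)
  rownames(X) <- ph$sample_id
  add_block <- function(X, block, prefix) {
    if (is.matrix(block)) {
      b <- block
    } else {
      bt <- tibble::as_tibble(block)
      b <- as.matrix(bt[setdiff(names(bt), "sample_id")])
      rownames(b) <- bt$sample_id
    }
    if (ncol(b) > 0 && is.null(colnames(b))) {
      colnames(b) <- paste0(prefix, seq_len(ncol(b)))
    }
    colnames(b) <- ifelse(grepl(paste0("^", prefix), colnames(b)),
                          colnames(b), paste0(prefix, colnames(b)))
    shared <- intersect(rownames(X), rownames(b))
    dropped <- setdiff(rownames(X), shared)
    if (length(dropped)) {
      inform(sprintf("assemble_features: dropped %d sample(s) missing the %s block",
                     length(dropped), prefix))
    }
    cbind(X[shared, , drop = FALSE], b[shared, , drop = FALSE])
  }
  if (need_p) X <- add_block(X, prs, "prs_")
  if (need_g) X <- add_block(X, grs, "grs_")
  if (need_m) X <- add_block(X, proxydnam, "proxy_")
  ids <- rownames(X)
  ph <- ph[match(ids, ph$sample_id), ]
  structure(list(x = X, y = ph$scaled_rate, res = ph$res_label,
                 arm = ph$arm, sex = ph$sex,
                 sample_id = ids, pattern = pattern),
            class = "feature_set")
}

#' Train a treatment-response model
#'
#' One regression model per combination pattern on the scaled reduction
#' rate; the continuous prediction doubles as the classification score for
#' ROC analysis. Features go through the leakage-safe preprocessor; the
#' learner (`"rf"`, `"qrf"` or `"svmRadial"`) is tuned by random search over
#' repeated k-fold CV (LOOCV under 30 samples) and refit on all training
#' data.
#'
#' @param features a `feature_set` from [assemble_features()].
#' @param algorithm learner tag.
#' @param search_budget random-search draws.
#' @param cv_folds,cv_repeats CV scheme.
#' @param seed integer seed.
#' @return object of class `response_model`.
#' @export
train_response_model <- function(features,
                                 algorithm = c("rf", "qrf", "svmRadial"),
                                 search_budget = 25, cv_folds = 10,
                                 cv_repeats = 1, seed = 1) {
  algorithm <- match.arg(algorithm)
  seed <- check_seed(seed)
  y <- features$y
  if (length(y) < 50 && length(y) >= 30) {
    inform("fewer than 50 samples: k-fold CV may be unstable")
  }
  if (sd(y) == 0) abort("degenerate target: scaled rate is constant")
  pre <- fit_preprocessor(features$x)
  Xp <- apply_preprocessor(pre, features$x)
  tuned <- random_search_cv(Xp, y, algorithm, search_budget, cv_folds,
                            cv_repeats, seed)
  structure(list(
    pattern = features$pattern, algorithm = algorithm,
    feature_names = colnames(features$x),
    preprocessor = pre, fit = tuned$fit, params = tuned$params,
    cv_rmse = tuned$cv_rmse, cv_r2 = tuned$cv_r2,
    cv = list(folds = cv_folds, repeats = cv_repeats,
              n_folds = tuned$n_folds),
    seed = seed
  ), class = "response_model")
}

#' @export
print.response_model <- function(x, ...) {
  cat(sprintf("<response_model> %s (%s), %d features, CV R2 %.3f\n",
              x$pattern, x$algorithm, length(x$feature_names), x$cv_r2))
  invisible(x)
}

#' @export
#' @param object a `response_model`.
#' @param features a `feature_set` with the model's columns.
#' @param ... unused.
#' @rdname train_response_model
predict.response_model <- function(object, features, ...) {
  X <- features$x[, object$feature_names, drop = FALSE]
  predict_learner(object$fit, apply_preprocessor(object$preprocessor, X),
                  object$algorithm)
}

#' Evaluate a response model
#'
#' Classification (AUC with DeLong CI, continuous prediction as the score)
#' and regression (MAE, RMSE, MAPE, R-squared, Pearson r with Fisher CI) on
#' an evaluation set that must be disjoint from training, with per-arm and
#' per-sex strata. Single-class strata carry `NA` AUC.
#'
#' @param model a `response_model`.
#' @param features evaluation `feature_set`.
#' @return object of class `eval_report`: `overall` tibble and `strata`
#'   tibble.
#' @export
evaluate_model <- function(model, features) {
  y_hat <- predict(model, features)
  y <- features$y
  res01 <- as_binary_labels(features$res)
  one_stratum <- function(idx, label) {
    m <- regression_metrics(y[idx], y_hat[idx])
    a <- if (length(unique(res01[idx])) == 2) {
      auc_delong_ci(y_hat[idx], res01[idx])
    } else {
      tibble::tibble(auc = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                     se = NA_real_)
    }
    dplyr::bind_cols(tibble::tibble(stratum = label), a, m)
  }
  overall <- one_stratum(seq_along(y), "all")
  strata <- purrr::list_rbind(c(
    purrr::map(sort(unique(features$arm)),
               ~ one_stratum(which(features$arm == .x), paste0("arm:", .x))),
    purrr::map(sort(unique(features$sex)),
               ~ one_stratum(which(features$sex == .x), paste0("sex:", .x)))
  ))
  structure(list(pattern = model$pattern, algorithm = model$algorithm,
                 overall = overall, strata = strata,
                 predictions = tibble::tibble(
                   sample_id = features$sample_id, y = y, y_hat = y_hat,
                   res = features$res)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  o <- x$overall
  cat(sprintf("<eval_report> %s: AUC %.3f (%.3f-%.3f), R2 %.3f, RMSE %.3f\n",
              x$pattern, o$auc, o$ci_lo, o$ci_hi, o$r_squared, o$rmse))
  invisible(x)
}

#' @export
tidy.eval_report <- function(x, ...) {
  dplyr::bind_rows(x$overall, x$strata) |>
    dplyr::mutate(pattern = x$pattern, .before = 1)
}

#' @export
glance.eval_report <- function(x, ...) {
  dplyr::mutate(x$overall, pattern = x$pattern, .before = 1) |>
    dplyr::select(-"stratum")
}

#' Compare combination patterns
#'
#' Metric table over patterns evaluated on the same samples, plus whether
#' any pattern's decision curve dominates every other across the full
#' threshold grid.
#'
#' @param reports named list of `eval_report`s (one per pattern).
#' @param curves optional named list of [decision_curve()] outputs on the
#'   same samples.
#' @return list: `metrics` tibble (one row per pattern, ranked by AUC),
#'   `nb_dominant` (name of the pattern whose model net benefit is at least
#'   every other's at every threshold, or `NA`).
#' @export
compare_patterns <- function(reports, curves = NULL) {
  metrics <- purrr::imap(reports, function(r, nm) {
    dplyr::mutate(glance(r), pattern = nm)
  }) |> purrr::list_rbind() |>
    dplyr::arrange(dplyr::desc(.data$auc))
  nb_dominant <- NA_character_
  if (!is.null(curves) && length(curves) >= 2) {
    nb <- purrr::imap(curves, function(cv, nm) {
      m <- dplyr::filter(cv, .data$model == "model")
      tibble::tibble(pattern = nm, threshold = m$threshold,
                     net_benefit = m$net_benefit)
    }) |> purrr::list_rbind() |>
      tidyr::pivot_wider(names_from = "pattern", values_from = "net_benefit")
    mat <- as.matrix(nb[-1])
    dom <- vapply(seq_len(ncol(mat)), function(j) {
      all(mat[, j] >= apply(mat, 1, max) - 1e-12)
    }, logical(1))
    if (any(dom)) nb_dominant <- colnames(mat)[which(dom)[1]]
  }
  list(metrics = metrics, nb_dominant = nb_dominant)
}

#' Permutation variable importance
#'
#' Mean degradation of the evaluation RMSE over `n_repeats` random
#' shuffles of each feature column, on the supplied data.
#'
#' @param model a `response_model`.
#' @param features a `feature_set`.
#' @param n_repeats shuffles per feature.
#' @param seed integer seed.
#' @return tibble `feature`, `importance` (RMSE increase), `sd`.
#' @export
variable_importance <- function(model, features, n_repeats = 5, seed = 1) {
  seed <- check_seed(seed)
  X <- features$x[, model$feature_names, drop = FALSE]
  y <- features$y
  base_rmse <- sqrt(mean((y - predict(model, features))^2))
  set.seed(seed)
  out <- purrr::map(colnames(X), function(f) {
    deltas <- purrr::map_dbl(seq_len(n_repeats), function(r) {
      Xp <- X
      Xp[, f] <- sample(Xp[, f])
      fs <- list(x = Xp, y = y, pattern = features$pattern)
      sqrt(mean((y - predict(model, fs))^2)) - base_rmse
    })
    tibble::tibble(feature = f, importance = mean(deltas), sd = sd(deltas))
  }) |> purrr::list_rbind()
  dplyr::arrange(out, dplyr::desc(.data$importance))
}
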