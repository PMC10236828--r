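# Random-search hyperparameter tuning over repeated k-fold CV (or LOOCV),
# shared by the proxy-methylation and response models. Scheme: draw
# `search_budget` parameter settings from the documented spaces, score each
# by mean CV RMSE, refit the best on the full training data. Deterministic
# under `seed`.

tune_spaces <- list(
  rf = function() list(
    num.trees = sample(seq(100L, 1000L, by = 50L), 1),
    max.depth = sample(2:20, 1),
    min.node.size = sample(1:10, 1),
    mtry_frac = runif(1, 0.3, 1)
  ),
  qrf = function() list(
    num.trees = sample(seq(100L, 1000L, by = 50L), 1),
    max.depth = sample(2:20, 1),
    min.node.size = sample(1:10, 1),
    mtry_frac = runif(1, 0.3, 1)
  ),
  svmPoly = function() list(
    cost = 10^runif(1, -2, 2),
    degree = sample(2:4, 1),
    gamma = 10^runif(1, -3, 0),
    coef0 = runif(1, 0, 1)
  ),
  svmRadial = function() list(
    cost = 10^runif(1, -2, 2),
    gamma = 10^runif(1, -3, 0)
  )
)

fit_learner <- function(X, y, algorithm, par, seed) {
  X <- as.data.frame(X)
  switch(algorithm,
    rf = ranger::ranger(
      x = X, y = y, num.trees = par$num.trees, max.depth = par$max.depth,
      min.node.size = par$min.node.size,
      mtry = max(1L, floor(par$mtry_frac * ncol(X))), seed = seed
    ),
    qrf = ranger::ranger(
      x = X, y = y, num.trees = par$num.trees, max.depth = par$max.depth,
      min.node.size = par$min.node.size,
      mtry = max(1L, floor(par$mtry_frac * ncol(X))),
      quantreg = TRUE, seed = seed
    ),
    svmPoly = e1071::svm(x = as.matrix(X), y = y, kernel = "polynomial",
                         cost = par$cost, degree = par$degree,
                         gamma = par$gamma, coef0 = par$coef0, scale = FALSE),
    svmRadial = e1071::svm(x = as.matrix(X), y = y, kernel = "radial",
                           cost = par$cost, gamma = par$gamma, scale = FALSE),
    abort(paste0("unknown algorithm: ", algorithm))
  )
}

predict_learner <- function(fit, X, algorithm) {
  X <- as.data.frame(X)
  if (algorithm == "qrf") {
    # quantile forest scored at the median
    as.vector(predict(fit, data = X, type = "quantiles",
                      quantiles = 0.5)$predictions)
  } else if (algorithm == "rf") {
    predict(fit, data = X)$predictions
  } else {
    as.vector(predict(fit, as.matrix(X)))
  }
}

make_folds <- function(n, cv_folds, cv_repeats) {
  if (n < 30 || cv_folds >= n) {
    # LOOCV for small training sets
    list(purrr::map(seq_len(n), ~ .x))
  } else {
    purrr::map(seq_len(cv_repeats), function(r) {
      f <- sample(rep(seq_len(cv_folds), length.out = n))
      purrr::map(seq_len(cv_folds), ~ which(f == .x))
    }) |> purrr::flatten()
  }
}

random_search_cv <- function(X, y, algorithm, search_budget = 25,
                             cv_folds = 10, cv_repeats = 1, seed = 1) {
  seed <- check_seed(seed)
  X <- as.matrix(X)
  n <- nrow(X)
  set.seed(seed)
  draws <- purrr::map(seq_len(search_budget), ~ tune_spaces[[algorithm]]())
  folds <- make_folds(n, cv_folds, cv_repeats)
  cv_rmse <- purrr::map_dbl(seq_along(draws), function(d) {
    par <- draws[[d]]
    errs <- purrr::map(folds, function(test_idx) {
      tr <- setdiff(seq_len(n), test_idx)
      fit <- fit_learner(X[tr, , drop = FALSE], y[tr], algorithm, par,
                         seed = seed + d)
      predict_learner(fit, X[test_idx, , drop = FALSE], algorithm) -
        y[test_idx]
    })
    sqrt(mean(unlist(errs)^2))
  })
  best <- which.min(cv_rmse)
  final <- fit_learner(X, y, algorithm, draws[[best]], seed = seed)
  list(fit = final, algorithm = algorithm, params = draws[[best]],
       cv_rmse = cv_rmse[best], cv_rmse_all = cv_rmse,
       cv_r2 = 1 - cv_rmse[best]^2 / mean((y - mean(y))^2),
       n_folds = length(folds), search_budget = search_budget, seed = seed)
}
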