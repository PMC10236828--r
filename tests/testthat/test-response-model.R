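test_that("feature assembly builds the documented pattern schemas", {
  co <- small_cohort()
  ph <- co$phenotypes
  n <- nrow(ph)
  prs <- tibble::tibble(sample_id = ph$sample_id, scz = rnorm(n),
                        bp = rnorm(n))
  grs <- tibble::tibble(sample_id = ph$sample_id, score = rnorm(n))
  px <- matrix(rnorm(n * 2), n, 2,
               dimnames = list(ph$sample_id, c("proxy_cg1", "proxy_cg2")))
  arms <- sort(unique(ph$arm[!is.na(ph$arm)]))

  cp <- assemble_features(ph, prs = prs, pattern = "C+P")
  expect_equal(colnames(cp$x),
               c("panss_baseline", "age", "sex", paste0("arm_", arms),
                 "prs_scz", "prs_bp"))
  # drug-arm one-hot sums to 1 per sample
  expect_equal(unname(rowSums(cp$x[, paste0("arm_", arms)])),
               rep(1, nrow(cp$x)))

  all4 <- assemble_features(ph, prs = prs, grs = grs, proxydnam = px,
                            pattern = "C+PGM")
  for (p in c("C+P", "C+G", "C+M")) {
    sub <- assemble_features(ph, prs = prs, grs = grs, proxydnam = px,
                             pattern = p)
    expect_true(all(colnames(sub$x) %in% colnames(all4$x)))
  }
  expect_error(assemble_features(ph, pattern = "C+G"), "GRS")

  # samples missing a block are dropped with a message
  drop_ids <- head(ph$sample_id[!is.na(ph$scaled_rate)], 5)
  grs_part <- grs[!grs$sample_id %in% drop_ids, ]
  expect_message(
    part <- assemble_features(ph, grs = grs_part, pattern = "C+G"),
    "dropped 5")
  expect_equal(nrow(part$x), sum(!is.na(ph$scaled_rate)) - 5L)
})

test_that("rank AUC equals brute-force pairwise concordance", {
  set.seed(121)
  for (r in 1:50) {
    n <- sample(8:25, 1)
    s <- sample(round(runif(n, 0, 1), 2))   # with ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    expect_equal(auc_rank(s, y), auc_oracle(s, y), tolerance = 1e-12)
  }
  expect_equal(auc_rank(c(0.9, 0.1), c("RES", "non-RES")), 1)
  expect_equal(auc_rank(c(0.1, 0.9), c("RES", "non-RES")), 0)
})

test_that("DeLong CI agrees with the reference implementation", {
  set.seed(122)
  for (r in 1:5) {
    y <- rbinom(60, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- rnorm(60) + y
    got <- auc_delong_ci(s, y)
    ref <- suppressMessages(pROC::ci.auc(y, s, method = "delong"))
    expect_equal(got$auc, as.numeric(ref[2]), tolerance = 1e-12)
    expect_equal(got$ci_lo, max(0, as.numeric(ref[1])), tolerance = 1e-9)
    expect_equal(got$ci_hi, min(1, as.numeric(ref[3])), tolerance = 1e-9)
  }
})

test_that("regression metrics obey their identities", {
  set.seed(123)
  y <- rnorm(100)
  expect_equal(regression_metrics(y, y)$mae, 0)
  expect_equal(regression_metrics(y, y)$rmse, 0)
  expect_equal(regression_metrics(y, y)$r_squared, 1)
  for (r in 1:20) {
    yh <- y + rnorm(100, 0, runif(1, 0.1, 2))
    m <- regression_metrics(y, yh)
    expect_gte(m$rmse, m$mae)
  }
  # R2 equals squared Pearson r for least-squares affine predictions
  x <- rnorm(100)
  fit <- lm(y ~ x)
  m <- regression_metrics(y, fitted(fit))
  expect_equal(m$r_squared, unname(cor(y, x)^2), tolerance = 1e-9)
})

test_that("decision curve reproduces the worked net-benefit example", {
  # N = 100, threshold 0.2 with TP = 30, FP = 10:
  # NB = (30 - 10 * 0.2/0.8) / 100 = 0.275
  y <- c(rep(1, 40), rep(0, 60))
  scores <- c(rep(0.9, 30), rep(0.1, 10),   # positives: 30 above t
              rep(0.9, 10), rep(0.1, 50))   # negatives: 10 above t
  dc <- decision_curve(scores, y, thresholds = 0.2)
  nb <- dc$net_benefit[dc$model == "model"]
  expect_equal(nb, 0.275)
  # treat-all closed form at the same threshold
  prev <- 0.4
  expect_equal(dc$net_benefit[dc$model == "treat_all"],
               prev - (1 - prev) * 0.2 / 0.8)
  expect_equal(dc$net_benefit[dc$model == "treat_none"], 0)
})

test_that("a perfect classifier attains NB = prevalence at all thresholds", {
  y <- rep(c(1, 0), c(30, 70))
  dc <- decision_curve(ifelse(y == 1, 1, 0), y)
  m <- dc[dc$model == "model", ]
  expect_equal(m$net_benefit, rep(0.3, nrow(m)))
  expect_equal(m$standardized_nb, rep(1, nrow(m)))
})

test_that("random scores do not beat the reference envelope", {
  set.seed(124)
  viol <- 0
  for (r in 1:50) {
    y <- rbinom(80, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- runif(80)
    dc <- decision_curve(s, y)
    wide <- tidyr::pivot_wider(dc[, c("threshold", "model", "net_benefit")],
                               names_from = "model",
                               values_from = "net_benefit")
    envelope <- pmax(wide$treat_all, 0)
    # binomial SE of the NB estimate at n = 80
    viol <- viol + any(wide$model > envelope + 2 * sqrt(0.25 / 80) + 0.05)
  }
  expect_lte(viol, 5)
})

response_fixture <- function(n = 200, seed = 125) {
  set.seed(seed)
  x1 <- rnorm(n)
  x2 <- rnorm(n)
  y <- pmin(pmax(0.6 * x1 + rnorm(n, 0, 0.4), -1), 1)
  fs <- list(
    x = cbind(panss_baseline = rnorm(n, 90, 10), age = runif(n, 20, 45),
              sex = rbinom(n, 1, 0.5), x1 = x1, x2 = x2),
    y = y, res = ifelse(y >= 0.5, "RES", "non-RES"),
    arm = sample(c("olz", "ris"), n, TRUE), sex = rbinom(n, 1, 0.5),
    sample_id = sprintf("S%03d", 1:n), pattern = "C+P"
  )
  class(fs) <- "feature_set"
  fs
}

test_that("response model trains, evaluates and stays deterministic", {
  fs <- response_fixture()
  m1 <- train_response_model(fs, "rf", search_budget = 4, cv_folds = 5,
                             seed = 17)
  m2 <- train_response_model(fs, "rf", search_budget = 4, cv_folds = 5,
                             seed = 17)
  expect_identical(m1$params, m2$params)
  expect_equal(predict(m1, fs), predict(m2, fs))
  expect_gt(m1$cv_r2, 0.2)

  ev <- evaluate_model(m1, fs)
  expect_s3_class(glance(ev), "tbl_df")
  expect_gte(ev$overall$rmse, ev$overall$mae)
  expect_true(ev$overall$auc > 0.5)
  expect_true(any(grepl("^arm:", ev$strata$stratum)))
  expect_true(any(grepl("^sex:", ev$strata$stratum)))

  expect_error(train_response_model(
    structure(list(x = fs$x, y = rep(0.5, 200), pattern = "C+P"),
              class = "feature_set"), "rf", seed = 1), "degenerate")
})

test_that("permuted targets give non-positive CV R2 almost always", {
  fs <- response_fixture()
  r2s <- sapply(1:10, function(s) {
    set.seed(s)
    fsp <- fs
    fsp$y <- sample(fs$y)
    train_response_model(fsp, "rf", search_budget = 2, cv_folds = 5,
                         seed = s)$cv_r2
  })
  expect_gte(mean(r2s <= 0.05), 0.9)
})

test_that("pattern comparison tabulates metrics and NB dominance", {
  fs <- response_fixture()
  m <- train_response_model(fs, "rf", search_budget = 3, cv_folds = 5,
                            seed = 19)
  ev <- evaluate_model(m, fs)
  p <- scaled_to_probability(predict(m, fs))
  # dominance flag: a perfect classifier (NB = prevalence everywhere)
  # dominates a treat-no-one score (NB = 0 everywhere)
  y01 <- as.integer(fs$res == "RES")
  dc_good <- decision_curve(ifelse(y01 == 1, 1, 0), fs$res)
  dc_bad <- decision_curve(rep(0, length(fs$y)), fs$res)
  cmp <- compare_patterns(list(good = ev, flat = ev),
                          curves = list(good = dc_good, flat = dc_bad))
  expect_equal(nrow(cmp$metrics), 2L)
  expect_equal(cmp$nb_dominant, "good")
})

test_that("variable importance ranks the driving feature first", {
  fs <- response_fixture()
  m <- train_response_model(fs, "rf", search_budget = 3, cv_folds = 5,
                            seed = 23)
  vi <- variable_importance(m, fs, n_repeats = 3, seed = 29)
  expect_equal(vi$feature[1], "x1")
  # column order must not matter
  fs2 <- fs
  fs2$x <- fs$x[, rev(colnames(fs$x))]
  vi2 <- variable_importance(m, fs2, n_repeats = 3, seed = 29)
  expect_equal(vi2$feature[1], "x1")
})

test_that("score-outcome association handles plain and partial correlation", {
  set.seed(126)
  x <- rnorm(200)
  expect_equal(score_outcome_association(x, x)$r, 1)
  got <- score_outcome_association(x, x)
  expect_true(got$ci_lo > 0)

  # partialling a variable on itself leaves ~zero correlation
  y <- x + rnorm(200, 0, 0.5)
  prt <- score_outcome_association(x, y, covariates = data.frame(c1 = x))
  expect_lt(abs(prt$r), 0.1)

  # planted r = 0.3 recovered within 2 SE at n = 500
  n <- 500
  a <- rnorm(n)
  b <- 0.3 * a + sqrt(1 - 0.09) * rnorm(n)
  est <- score_outcome_association(a, b)
  expect_lt(abs(est$r - 0.3), 2 / sqrt(n - 3) * 2)
  expect_error(score_outcome_association(rep(1, 20), rnorm(20)), "constant")
})
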