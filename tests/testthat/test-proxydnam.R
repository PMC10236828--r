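test_that("cohort split is a deterministic exhaustive partition", {
  ids <- sprintf("S%03d", 1:10)
  sp <- split_cohort(ids, 0.7, seed = 3)
  expect_equal(length(sp$train), 7L)
  expect_equal(length(sp$test), 3L)
  expect_setequal(c(sp$train, sp$test), ids)
  expect_equal(length(intersect(sp$train, sp$test)), 0L)
  expect_identical(sp, split_cohort(ids, 0.7, seed = 3))
  expect_false(identical(sp$train, split_cohort(ids, 0.7, seed = 4)$train))
})

test_that("preprocessor standardizes its own training data exactly", {
  set.seed(111)
  X <- cbind(a = rexp(80), b = rnorm(80, 5, 2), c = runif(80))
  pre <- fit_preprocessor(X)
  Z <- apply_preprocessor(pre, X)
  expect_equal(unname(colMeans(Z)), rep(0, 3), tolerance = 1e-9)
  expect_equal(unname(apply(Z, 2, sd)), rep(1, 3), tolerance = 1e-9)

  # Gaussian mapping of uniform variates is not rejected as non-normal
  U <- matrix(runif(200), ncol = 1, dimnames = list(NULL, "u"))
  Zu <- apply_preprocessor(fit_preprocessor(U), U)
  expect_gt(shapiro.test(Zu[, 1])$p.value, 0.01)

  expect_warning(fit_preprocessor(cbind(k = rep(1, 10))), "zero-variance")
})

test_that("preprocessor parameters come from training data only", {
  set.seed(112)
  train <- cbind(x = rnorm(60))
  test <- cbind(x = rnorm(40, 3, 2))       # shifted test distribution
  pre_train <- fit_preprocessor(train)
  pre_leaky <- fit_preprocessor(rbind(train, test))
  z_ok <- apply_preprocessor(pre_train, test)
  z_leak <- apply_preprocessor(pre_leaky, test)
  expect_false(isTRUE(all.equal(z_ok, z_leak)))
  # perturbing test data must not change the train-fitted transform
  z_ref <- apply_preprocessor(pre_train, train)
  pre_after <- fit_preprocessor(train)
  expect_identical(apply_preprocessor(pre_after, train), z_ref)
})

linear_proxy_fixture <- function(n = 300, seed = 113) {
  set.seed(seed)
  dos <- cbind(rs1 = rbinom(n, 2, 0.4), rs2 = rbinom(n, 2, 0.3))
  rownames(dos) <- sprintf("S%03d", 1:n)
  g <- genotype_matrix(dos, tibble::tibble(
    snp_id = c("rs1", "rs2"), chrom = "1", pos = c(1000L, 2000L),
    ref_allele = "A", effect_allele = "G"))
  covars <- tibble::tibble(age = runif(n, 20, 45), sex = rbinom(n, 1, 0.5))
  M <- 0.5 * dos[, "rs1"] + 0.3 * dos[, "rs2"] - 1 + rnorm(n, 0, 0.1)
  betas <- matrix(m_to_beta(M), ncol = 1,
                  dimnames = list(rownames(dos), "cg001"))
  meth <- methylation_matrix(betas, tibble::tibble(
    cpg_id = "cg001", chrom = "1", pos = 1500L))
  mq <- tibble::tibble(snp_id = c("rs1", "rs2"), cpg_id = "cg001",
                       is_meqtl = TRUE)
  list(g = g, meth = meth, covars = covars, mq = mq)
}

test_that("all three proxy learners recover a linear genotype signal", {
  fx <- linear_proxy_fixture()
  for (alg in c("rf", "qrf", "svmPoly")) {
    m <- train_proxy(fx$g, fx$meth, fx$covars, "cg001", fx$mq,
                     algorithm = alg, search_budget = 6, cv_folds = 5,
                     seed = 21)
    expect_gt(m$cv_r2, 0.8)
  }
})

test_that("proxy training is deterministic under a fixed seed", {
  fx <- linear_proxy_fixture()
  m1 <- train_proxy(fx$g, fx$meth, fx$covars, "cg001", fx$mq,
                    algorithm = "rf", search_budget = 4, cv_folds = 5,
                    seed = 9)
  m2 <- train_proxy(fx$g, fx$meth, fx$covars, "cg001", fx$mq,
                    algorithm = "rf", search_budget = 4, cv_folds = 5,
                    seed = 9)
  expect_identical(m1$params, m2$params)
  expect_equal(predict(m1, fx$g, fx$covars), predict(m2, fx$g, fx$covars))
})

test_that("a pure-noise target gives near-zero CV R2", {
  set.seed(114)
  fx <- linear_proxy_fixture()
  r2s <- sapply(1:8, function(s) {
    betas <- matrix(m_to_beta(rnorm(300)), ncol = 1,
                    dimnames = list(rownames(fx$g$dosages), "cg001"))
    meth <- methylation_matrix(betas, fx$meth$cpg_meta)
    train_proxy(fx$g, meth, fx$covars, "cg001", fx$mq, algorithm = "rf",
                search_budget = 3, cv_folds = 5, seed = s)$cv_r2
  })
  expect_gte(mean(r2s <= 0.05), 0.9)
})

test_that("selection keeps the best significant model per CpG", {
  fx <- linear_proxy_fixture()
  sp <- split_cohort(rownames(fx$g$dosages), 0.7, seed = 31)
  tr <- match(sp$train, rownames(fx$g$dosages))
  te <- match(sp$test, rownames(fx$g$dosages))
  models <- purrr::map(c("rf", "svmPoly"), function(a) {
    train_proxy(subset_genotypes(fx$g, tr), subset_methylome(fx$meth, tr),
                fx$covars[tr, ], "cg001", fx$mq, algorithm = a,
                search_budget = 4, cv_folds = 5, seed = 7)
  })
  sel <- evaluate_and_select(models, subset_genotypes(fx$g, te),
                             subset_methylome(fx$meth, te), fx$covars[te, ])
  expect_true(all(sel$summary$selected))
  expect_equal(length(sel$kept), 1L)
  expect_equal(sel$kept[[1]]$pearson_r, max(sel$summary$pearson_r))
})

test_that("the selection gate is calibrated near 0.05 under the null", {
  # quick version at 60 CpGs; the 200-CpG version runs in the acceptance
  # suite
  set.seed(115)
  n <- 60
  fx <- linear_proxy_fixture(n = 80, seed = 116)
  sp <- split_cohort(rownames(fx$g$dosages), 0.7, seed = 41)
  tr <- match(sp$train, rownames(fx$g$dosages))
  te <- match(sp$test, rownames(fx$g$dosages))
  hits <- sapply(seq_len(n), function(s) {
    betas <- matrix(m_to_beta(rnorm(80)), ncol = 1,
                    dimnames = list(rownames(fx$g$dosages), "cg001"))
    meth <- methylation_matrix(betas, fx$meth$cpg_meta)
    m <- train_proxy(subset_genotypes(fx$g, tr),
                     subset_methylome(meth, tr), fx$covars[tr, ],
                     "cg001", fx$mq, algorithm = "rf", search_budget = 1,
                     cv_folds = 5, seed = s)
    sel <- evaluate_and_select(list(m), subset_genotypes(fx$g, te),
                               subset_methylome(meth, te), fx$covars[te, ])
    sel$summary$selected
  })
  expect_lt(abs(mean(hits) - 0.05), 0.08)
})

test_that("imputation reproduces model predictions and fails on missing SNPs", {
  fx <- linear_proxy_fixture()
  m <- train_proxy(fx$g, fx$meth, fx$covars, "cg001", fx$mq,
                   algorithm = "rf", search_budget = 3, cv_folds = 5,
                   seed = 13)
  px <- impute_methylation(list(m), fx$g, fx$covars)
  expect_equal(colnames(px), "proxy_cg001")
  expect_equal(px[, 1], setNames(predict(m, fx$g, fx$covars),
                                 rownames(fx$g$dosages)))
  # correlation with truth collapses under genotype permutation
  set.seed(117)
  perm <- sample(nrow(fx$g$dosages))
  g_perm <- genotype_matrix(fx$g$dosages[perm, ], fx$g$snp_meta)
  rownames(g_perm$dosages) <- rownames(fx$g$dosages)
  px_perm <- impute_methylation(list(m), g_perm, fx$covars)
  truth <- beta_to_m(fx$meth$betas[, 1])
  expect_gt(abs(cor(px[, 1], truth)), 0.5)
  expect_lt(abs(cor(px_perm[, 1], truth)), 0.15)

  g_missing <- subset_genotypes(fx$g, seq_len(nrow(fx$g$dosages)))
  g_missing$dosages <- g_missing$dosages[, 1, drop = FALSE]
  g_missing$snp_meta <- g_missing$snp_meta[1, ]
  expect_error(predict(m, g_missing, fx$covars), "rs2")

  expect_warning(empty <- impute_methylation(list(), fx$g, fx$covars),
                 "no selected")
  expect_equal(ncol(empty), 0L)
})

test_that("brain-blood filtering applies both gates", {
  tab <- tibble::tibble(cpg_id = c("cgX", "cgY", "cgZ"),
                        r = c(0.8, 0.8, 0.1), p = c(1e-4, 0.2, 1e-4))
  expect_equal(brain_blood_filter(c("cgX", "cgY"), tab), "cgX")
  expect_equal(brain_blood_filter(c("cgX", "cgZ"), tab, r_threshold = 0.5),
               "cgX")
  expect_warning(got <- brain_blood_filter(c("cgX", "cgQ"), tab), "absent")
  expect_equal(got, "cgX")
  expect_warning(none <- brain_blood_filter("cgA", tab[0, ]), "absent")
  expect_equal(length(none), 0L)
})
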