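mk_features <- function(seed = 1, n = 400, n_prot = 40) {
  gen_feature_table(sim_config(seed = seed, n_feature_sites = n,
                               n_feature_proteins = n_prot,
                               class_imbalance = 5))$table
}

test_that("preprocessing transforms, imputes and standardizes as specified", {
  x <- mk_features()
  prep <- preprocess_features(x)
  params <- attr(prep, "ubifunc_prep")
  feats <- functional_score_features()
  # standardized columns
  for (f in feats) {
    expect_lt(abs(mean(prep[[f]])), 1e-8)
    expect_lt(abs(sd(prep[[f]]) - 1), 1e-8)
  }
  # count features with zeros use log1p, zero-free positive ones plain log
  expect_equal(unname(params$log_fun[["n_regulations"]]), "log1p")
  expect_equal(unname(params$log_fun[["protein_length"]]), "log")
  # rows missing a non-conservation feature are dropped ...
  expect_equal(nrow(prep), sum(!is.na(x$rsa)))
  # ... while missing conservation is mean-imputed from the full table
  expect_false(anyNA(prep$conservation_level))
  expect_equal(params$impute_conservation,
               mean(x$conservation_level, na.rm = TRUE))
  # log1p at zero is zero before scaling
  expect_equal(log1p(0), 0)
})

test_that("preprocessing is idempotent once fitted", {
  x <- mk_features(2)
  once <- preprocess_features(x)
  twice <- preprocess_features(once)
  expect_equal(twice, once, tolerance = 1e-12)
  # zero-variance feature is an error naming the column
  bad <- x
  bad$in_hotspot <- 0
  expect_error(preprocess_features(bad), "in_hotspot")
})

test_that("the excluded protein leaves training but keeps predictions", {
  x <- mk_features(3)
  x$protein_ac[1:19] <- "P13010"
  out <- exclude_training_protein(x)
  expect_equal(sum(out$protein_ac == "P13010"), 0L)
  expect_identical(exclude_training_protein(out), out)  # absent: unchanged
  fit <- train_functional_score(x, seed = 1)
  expect_true(any(fit$scores$protein_ac == "P13010"))
  expect_true(all(fit$scores$functional_score >= 0 &
                    fit$scores$functional_score <= 1))
})

test_that("fold plans group proteins, balance positives and obey the seed", {
  # 10 proteins x 1 site, 5 folds: exactly two proteins per fold
  x <- data.frame(protein_ac = sprintf("P%02d", 1:10), label = 1)
  plan <- build_fold_plan(x, k = 5, repeats = 2, seed = 1)
  expect_true(all(table(plan[, 1]) == 2))
  expect_true(all(table(plan[, 2]) == 2))
  # all sites of one protein stay together
  x2 <- data.frame(protein_ac = c(rep("BIG", 100), sprintf("P%02d", 1:10)),
                   label = c(rep(0, 100), rep(1, 10)))
  plan2 <- build_fold_plan(x2, k = 5, repeats = 3, seed = 2)
  for (r in 1:3) {
    expect_equal(length(unique(plan2[x2$protein_ac == "BIG", r])), 1L)
  }
  # seeds change the assignment but not the invariants
  p_a <- build_fold_plan(x2, k = 5, repeats = 1, seed = 3)
  p_b <- build_fold_plan(x2, k = 5, repeats = 1, seed = 4)
  expect_false(identical(p_a, p_b))
  expect_error(build_fold_plan(data.frame(protein_ac = c("a", "b"),
                                          label = c(1, 1)), k = 5),
               "fewer positive-bearing")
})

test_that("weighted logistic fit matches independent optimizers", {
  set.seed(13)
  # monotone 1-D data: positive weight
  X1 <- matrix(c(-2, -1, 1, 2), ncol = 1)
  f1 <- fit_weighted_logistic(X1, c(0, 0, 1, 1))
  expect_gt(f1$coef[2], 0)
  # perfectly balanced classes reduce to the unweighted fit (vs glm)
  n <- 200
  X <- matrix(rnorm(2 * n), ncol = 2)
  y <- rbinom(n, 1, plogis(X[, 1] - 0.5 * X[, 2]))
  y[1:(n / 2)] <- rep(c(0, 1), n / 4)  # force exact balance
  y <- c(rep(0, n / 2), rep(1, n / 2))
  g <- glm(y ~ X, family = binomial)
  f <- fit_weighted_logistic(X, y, lambda = 0)
  expect_equal(unname(f$coef), unname(coef(g)), tolerance = 1e-6)
  # small imbalanced problems match a brute-force BFGS oracle
  for (seed in 1:5) {
    set.seed(seed)
    Xs <- matrix(rnorm(16), ncol = 2)
    ys <- c(1, rep(0, 7))[sample(8)]
    fit <- fit_weighted_logistic(Xs, ys, lambda = 1e-2)
    oracle <- oracle_logistic(Xs, ys, lambda = 1e-2)
    expect_equal(unname(fit$coef), oracle, tolerance = 1e-5)
  }
  expect_error(fit_weighted_logistic(X1, c(1, 1, 1, 1)), "both classes")
})

test_that("ensemble scores are per-site medians with weight summaries", {
  mods <- lapply(1:25, function(i) {
    structure(list(coef = c(`(Intercept)` = 0, a = 0)),
              class = "ubifunc_logit")
  })
  X <- matrix(rnorm(10), ncol = 1, dimnames = list(NULL, "a"))
  ens <- score_ensemble(mods, X)
  expect_true(all(ens$scores == 0.5))
  expect_equal(ens$weights$sd, c(0, 0))
  expect_error(score_ensemble(mods[1:10], X), "expected 25")
  # median of an arithmetic probability grid is the 13th order statistic
  expect_equal(median(seq(0.02, 0.50, by = 0.02)), 0.26)
  # scores stay in [0, 1] under random weights
  set.seed(20)
  wild <- lapply(1:25, function(i) {
    structure(list(coef = rnorm(2, sd = 10)), class = "ubifunc_logit")
  })
  s <- score_ensemble(wild, X)$scores
  expect_true(all(s >= 0 & s <= 1))
})

test_that("rank-based AUC equals brute-force pair counting", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(roc_auc(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_true(is.na(roc_auc(c(0.5, 0.6), c(1, 1))))
  set.seed(21)
  for (i in 1:200) {
    n <- sample(2:6, 1)
    scores <- sample(seq(0, 1, 0.25), n, replace = TRUE)  # ties likely
    labels <- rbinom(n, 1, 0.5)
    expect_identical(is.na(roc_auc(scores, labels)),
                     is.na(oracle_auc(scores, labels)))
    if (!is.na(oracle_auc(scores, labels))) {
      expect_equal(roc_auc(scores, labels), oracle_auc(scores, labels))
    }
  }
})

test_that("architecture evaluation yields 25 held-out AUCs above chance", {
  x <- mk_features(5, n = 800, n_prot = 80)
  ev <- evaluate_architecture(x, seed = 2)
  expect_equal(nrow(ev$auc), 25L)
  expect_gt(ev$mean_auc, 0.6)  # informative planted model
  # labels independent of features: AUC concentrates at 1/2
  nulls <- vapply(1:5, function(seed) {
    cfg <- sim_config(seed = seed + 50, n_feature_sites = 2000,
                      n_feature_proteins = 150, class_imbalance = 5,
                      planted_weights = setNames(
                        rep(0, 16), functional_score_features()))
    tab <- gen_feature_table(cfg)$table
    evaluate_architecture(tab, seed = seed)$mean_auc
  }, numeric(1))
  expect_lt(abs(mean(nulls) - 0.5), 0.05)
})

test_that("score variance of the ensemble is below single-model variance", {
  x <- mk_features(6, n = 600, n_prot = 60)
  runs <- lapply(1:6, function(seed) {
    fit <- train_functional_score(x, seed = seed)
    list(score = fit$scores$functional_score,
         single = predict(fit$models[[1]],
                          as.matrix(fit$prepared[,
                            functional_score_features()])))
  })
  med_mat <- sapply(runs, `[[`, "score")
  one_mat <- sapply(runs, `[[`, "single")
  expect_lte(mean(apply(med_mat, 1, var)), mean(apply(one_mat, 1, var)))
})
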