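test_that("gini impurity matches hand values", {
  expect_equal(gini_impurity(c(5, 0)), 0)
  expect_equal(gini_impurity(c(5, 5)), 0.5)
  expect_equal(gini_impurity(c(3, 1)), 0.375)   # 1 - 0.75^2 - 0.25^2
  expect_error(gini_impurity(c(0, 0)), class = "codephen_input_error")
})

test_that("single-tree importance equals exhaustive brute-force enumeration", {
  # whole-data single tree, all features at every node, so the oracle can
  # enumerate every split the implementation may take
  for (s in 1:12) {
    fm <- random_fm(n = 8, p = 2, seed = 200 + s)
    fit <- fit_forest(fm, forest_config(n_trees = 1, train_fraction = 1,
                                        features_per_split = 2, seed = 1))
    oracle <- oracle_tree_importance(fm$values, as.character(fm$labels))
    got <- setNames(fit$importance$importance, fit$importance$feature)
    expect_equal(got[names(oracle)], oracle, tolerance = 1e-10)
  }
})

test_that("brute-force oracle is invariant to patient order", {
  fm <- random_fm(n = 8, p = 2, seed = 77)
  perm <- sample(nrow(fm$values))
  imp1 <- oracle_tree_importance(fm$values, as.character(fm$labels))
  imp2 <- oracle_tree_importance(fm$values[perm, ],
                                 as.character(fm$labels)[perm])
  expect_equal(imp1, imp2)
})

test_that("forests are deterministic under a fixed seed", {
  fm <- random_fm(n = 30, p = 4, seed = 5)
  cfg <- forest_config(n_trees = 15, seed = 42)
  f1 <- fit_forest(fm, cfg)
  f2 <- fit_forest(fm, cfg)
  expect_identical(f1$importance, f2$importance)
  expect_identical(f1$oob_accuracy, f2$oob_accuracy)
  f3 <- fit_forest(fm, forest_config(n_trees = 15, seed = 43))
  expect_false(identical(f1$importance$importance,
                         f3$importance$importance))
})

test_that("all-constant features yield zero importance and majority-vote accuracy", {
  X <- matrix(2L, nrow = 20, ncol = 3,
              dimnames = list(sprintf("p%02d", 1:20), c("a", "b", "c")))
  fm <- feature_matrix(X, c(rep("RA", 6), rep("nonRA", 14)))
  fit <- fit_forest(fm, forest_config(n_trees = 20, seed = 1))
  expect_equal(fit$importance$importance, rep(0, 3))
  # every tree predicts its subsample majority; votes track the 70% class
  expect_gt(fit$oob_accuracy, 0.5)
})

test_that("a perfectly separating feature outranks noise in nearly all seeds", {
  hits <- 0L
  for (s in 1:20) {
    set.seed(400 + s)
    n <- 200
    y <- rep(c("RA", "nonRA"), each = n / 2)
    X <- matrix(rpois(n * 11, 1), n, 11,
                dimnames = list(sprintf("p%03d", 1:n),
                                c("signal", sprintf("noise%02d", 1:10))))
    X[, "signal"] <- ifelse(y == "RA", rpois(n, 1) + 2L, rpois(n, 0.3))
    fit <- fit_forest(feature_matrix(X, y),
                      forest_config(n_trees = 15, seed = s))
    hits <- hits + (fit$importance$feature[1] == "signal")
  }
  expect_gte(hits / 20, 0.95)
  # k = 1 returns that planted feature; k = n is the identity ordering
  set.seed(401)
  y <- rep(c("RA", "nonRA"), each = 100)
  X <- matrix(rpois(200 * 5, 1), 200, 5,
              dimnames = list(sprintf("p%03d", 1:200),
                              c("signal", paste0("n", 1:4))))
  X[, "signal"] <- ifelse(y == "RA", rpois(200, 1) + 2L, rpois(200, 0.3))
  fit <- fit_forest(feature_matrix(X, y), forest_config(n_trees = 15, seed = 1))
  expect_equal(select_top(fit, 1), "signal")
  expect_equal(select_top(fit, 5), fit$importance$feature)
  expect_identical(select_top(fit, 3), select_top(fit, 3))
  expect_error(select_top(fit, 0), class = "codephen_input_error")
  expect_error(select_top(fit, 6), class = "codephen_input_error")
})

test_that("out-of-bag accuracy clears 0.9 on the planted benchmark", {
  cfg <- benchmark_sim_config(seed = 8)
  d <- simulate_ehr(cfg)
  fm <- build_feature_matrix(build_records(d$events, d$labels))
  fit <- fit_forest(fm, forest_config(n_trees = 25, seed = 8))
  expect_gte(fit$oob_accuracy, 0.9)
})

test_that("importance ranking broadly agrees with an established forest", {
  skip_if_not_installed("randomForest")
  cfg <- benchmark_sim_config(seed = 14, n_patients = 800)
  d <- simulate_ehr(cfg)
  fm <- build_feature_matrix(build_records(d$events, d$labels))
  fit <- fit_forest(fm, forest_config(n_trees = 25, seed = 14))
  rf <- randomForest::randomForest(
    x = as.data.frame(fm$values), y = fm$labels, ntree = 100)
  rf_rank <- rank(-rf$importance[, "MeanDecreaseGini"])
  planted <- intersect(planted_member_codes(cfg), fm$feature_names)
  noise <- setdiff(fm$feature_names, planted)
  ours <- setNames(fit$importance$rank, fit$importance$feature)
  # both rankers separate the planted signal from the noise on average
  expect_lt(mean(ours[planted]), mean(ours[noise]))
  expect_lt(mean(rf_rank[planted]), mean(rf_rank[noise]))
})
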