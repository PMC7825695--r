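small_grid <- function() {
  build_grid(
    n_top = c(2, 3), trees = 50, shrinkage = 0.1, depth = 2,
    min_node = 5, bag_fraction = 1
  )
}

test_that("the hyperparameter grid is the full Cartesian product", {
  g <- build_grid()
  expect_equal(nrow(g), 8 * 4 * 3 * 3 * 3 * 3) # 2592
  expect_equal(nrow(unique(g)), nrow(g))
  expect_equal(sort(unique(g$n_top)), 3:10)
  g1 <- build_grid(
    n_top = 5, trees = 100, shrinkage = 0.1, depth = 2,
    min_node = 10, bag_fraction = 1
  )
  expect_equal(nrow(g1), 1)
  expect_error(build_grid(trees = numeric(0)), "trees")
})

test_that("AUC equals exhaustive pair counting, including ties", {
  expect_equal(compute_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(compute_auc(c(0.9, 0.2, 0.8, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_equal(compute_auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(compute_auc(1:3, c(1, 1, 1)), "both classes")

  set.seed(14)
  for (i in 1:300) {
    n <- sample(4:12, 1)
    s <- sample(seq(0, 1, 0.1), n, replace = TRUE) # frequent ties
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    expect_identical(compute_auc(s, y), oracle_auc(s, y))
  }
})

test_that("PRAUC is average precision with tie grouping", {
  expect_equal(compute_prauc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0)), 1)
  # constant scores: precision equals prevalence at full recall
  expect_equal(compute_prauc(rep(0.7, 10), c(rep(1, 3), rep(0, 7))), 0.3)
  # hand-enumerated steps for scores (0.9, 0.8, 0.2, 0.1), labels (1,0,1,0):
  # recall steps at 1/2 (prec 1) and 1 (prec 2/3) -> 0.5*1 + 0.5*2/3
  expect_equal(
    compute_prauc(c(0.9, 0.8, 0.2, 0.1), c(1, 0, 1, 0)),
    0.5 * 1 + 0.5 * 2 / 3
  )
  expect_error(compute_prauc(1:4, rep(0, 4)), "positive")
})

test_that("the boosted scorer separates separable data and is deterministic", {
  set.seed(3)
  n <- 60
  x <- matrix(stats::rnorm(n), ncol = 1)
  y <- as.integer(x[, 1] > 0)
  st <- list(trees = 50, shrinkage = 0.3, depth = 2, min_node = 5, bag_fraction = 0.8)
  sc <- fit_gbm(x, y, st, seed = 5)
  expect_gte(compute_auc(sc(x), y), 0.99)
  sc2 <- fit_gbm(x, y, st, seed = 5)
  expect_identical(sc(x), sc2(x))
  expect_error(fit_gbm(x, rep(1L, n), st), "single class")
})

test_that("held-out scores on label-independent features sit near chance", {
  set.seed(21)
  aucs <- replicate(40, {
    x <- matrix(stats::rnorm(80 * 3), 80, 3)
    y <- sample(rep(0:1, 40))
    fold <- radsig:::.stratified_folds(y, 2)
    st <- list(trees = 40, shrinkage = 0.1, depth = 2, min_node = 5, bag_fraction = 1)
    sc <- fit_gbm(x[fold == 1, ], y[fold == 1], st, seed = 2)
    compute_auc(sc(x[fold == 2, ]), y[fold == 2])
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("cross-validation emits exactly rounds x folds leak-free records", {
  ft <- generate_feature_table(table_spec(
    n_patients = 45, n_features = 30, n_informative = 3, effect = 1.3,
    block_size = 1, prevalence = 0.4, seed = 6
  ))
  ranked <- colnames(ft$table)[1:5]
  cv <- cross_validate(ft$table, ft$labels, ranked, small_grid(),
    rounds = 7, folds = 3, seed = 10
  )
  expect_equal(nrow(cv$records), 21)
  expect_equal(nrow(cv$records), length(cv$chosen))
  expect_true(all(cv$records$auc >= 0 & cv$records$auc <= 1))
  expect_true(all(cv$records$prauc >= 0 & cv$records$prauc <= 1))
  # summary is recomputable from the records
  expect_equal(unname(cv$summary["mean_auc"]), mean(cv$records$auc))
  expect_equal(unname(cv$summary["sd_auc"]), stats::sd(cv$records$auc))
  # planted signal is detected
  expect_gt(cv$summary[["mean_auc"]], 0.65)
  # reproducible under the master seed
  cv2 <- cross_validate(ft$table, ft$labels, ranked, small_grid(),
    rounds = 7, folds = 3, seed = 10
  )
  expect_identical(cv$records, cv2$records)

  # degenerate folds are refused
  expect_error(
    cross_validate(ft$table, ft$labels, ranked, small_grid(),
      rounds = 1, folds = 45, seed = 1
    ),
    "folds"
  )
})

test_that("validation AUC on permuted labels centres at chance (no leakage)", {
  ft <- generate_feature_table(table_spec(
    n_patients = 90, n_features = 25, n_informative = 0, block_size = 1,
    prevalence = 0.5, seed = 13
  ))
  set.seed(99)
  y <- sample(ft$labels)
  cv <- cross_validate(ft$table, y, colnames(ft$table)[1:4], small_grid(),
    rounds = 34, folds = 3, seed = 2
  )
  expect_gte(nrow(cv$records), 100)
  expect_lt(abs(mean(cv$records$auc) - 0.5), 0.05)
})

test_that("ROC averaging is idempotent and respects perfect/null extremes", {
  perfect <- list(scores = c(0.9, 0.8, 0.2, 0.1), labels = c(1, 1, 0, 0))
  r1 <- average_roc(list(perfect))
  expect_equal(r1$tpr[r1$fpr == 0], 1) # hugs the (0,1) corner
  expect_equal(r1$tpr[101], 1)
  expect_equal(r1$tpr[1], 1)
  r2 <- average_roc(list(perfect, perfect))
  expect_equal(r1, r2)
  expect_false(is.unsorted(r1$tpr))

  # hand-checked two-curve average at a grid point: curve A has TPR 1 at
  # FPR 0; curve B (reversed scores) has TPR 0 until FPR 0.5
  worst <- list(scores = c(0.1, 0.2, 0.8, 0.9), labels = c(1, 1, 0, 0))
  rb <- average_roc(list(perfect, worst))
  expect_equal(rb$tpr[rb$fpr == 0], 0.5)
  expect_equal(rb$tpr[rb$fpr == 0.75], 0.5)
  expect_equal(rb$tpr[101], 1)
})

test_that("negative_control validates prevalence and returns the full protocol output", {
  ft <- generate_feature_table(table_spec(
    n_patients = 40, n_features = 25, n_informative = 0, block_size = 1,
    prevalence = 0.5, seed = 3
  ))
  expect_error(
    negative_control(ft$table, prevalence = 0, rounds = 1),
    "prevalence"
  )
  nc <- negative_control(ft$table,
    prevalence = 0.4,
    selection = selection_config(rounds = 2, seed = 5),
    grid = small_grid(), rounds = 3, folds = 3, seed = 5
  )
  expect_equal(sum(nc$labels), 16)
  expect_equal(nrow(nc$validation$records), 9)
  expect_s3_class(nc$selection, "selection_result")
})
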