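#' Hyperparameter grid for the gradient-boosting classifier
#'
#' Full Cartesian product of the six tuned dimensions, with level counts
#' 8 x 4 x 3 x 3 x 3 x 3 = 2592: number of top-ranked features
#' (3-10), number of trees, shrinkage, interaction depth, minimum node size
#' and bag fraction.
#'
#' @param n_top candidate signature sizes.
#' @param trees number-of-tree levels.
#' @param shrinkage learning-rate levels.
#' @param depth interaction-depth levels.
#' @param min_node minimum-node-size levels.
#' @param bag_fraction subsampling-fraction levels.
#' @return A data.frame with one row per setting, in deterministic order.
#' @export
build_grid <- function(n_top = 3:10, trees = c(50, 100, 150, 200),
                       shrinkage = c(0.01, 0.05, 0.1), depth = 1:3,
                       min_node = c(5, 10, 20), bag_fraction = c(0.5, 0.75, 1)) {
  args <- list(
    n_top = n_top, trees = trees, shrinkage = shrinkage,
    depth = depth, min_node = min_node, bag_fraction = bag_fraction
  )
  bad <- names(args)[lengths(args) == 0L]
  if (length(bad) > 0) {
    stop("empty level list for: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(unlist(args) <= 0)) stop("all grid levels must be positive", call. = FALSE)
  expand.grid(args, KEEP.OUT.ATTRS = FALSE)
}

# shared mapping from a settings row to xgboost parameters; min_node counts
# training samples and the logistic hessian is ~1/4 per sample, so it is
# converted to xgboost's hessian-weight units
.gbm_params <- function(setting, seed) {
  list(
    objective = "binary:logistic",
    max_depth = as.integer(setting$depth),
    eta = setting$shrinkage,
    subsample = setting$bag_fraction,
    min_child_weight = setting$min_node / 4,
    nthread = 1,
    seed = as.integer(seed)
  )
}

#' Fit the gradient-boosting classifier
#'
#' Trains a boosted-tree classifier (xgboost backend) with the given
#' setting and returns a scorer: a function mapping a feature matrix to
#' positive-class probabilities. Training is deterministic given `seed`.
#'
#' @param x training feature matrix.
#' @param y 0/1 training labels (both classes required).
#' @param setting list/row with `trees`, `shrinkage`, `depth`, `min_node`,
#'   `bag_fraction`.
#' @param seed integer seed.
#' @return A scoring function `function(newx) -> probabilities`.
#' @export
fit_gbm <- function(x, y, setting, seed = 1) {
  .assert_binary(y)
  if (length(unique(y)) < 2) {
    stop("training data contain a single class; cannot fit a classifier", call. = FALSE)
  }
  x <- as.matrix(x)
  params <- .gbm_params(setting, seed)
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  booster <- xgboost::xgb.train(
    params = params, data = dtrain,
    nrounds = as.integer(setting$trees), verbose = 0
  )
  nc <- ncol(x)
  function(newx) {
    newx <- matrix(as.numeric(newx), ncol = nc)
    stats::predict(booster, xgboost::xgb.DMatrix(newx, nthread = 1))
  }
}

#' Area under the ROC curve
#'
#' The Mann-Whitney U statistic normalised by `n1 * n0`, with ties counted
#' one half (midrank method).
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels 0/1 labels (both classes required).
#' @return AUC in `[0, 1]`.
#' @export
compute_auc <- function(scores, labels) {
  .assert_binary(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("AUC requires both classes among the labels", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise (non-interpolated) average precision: the sum over score
#' thresholds of the recall increment times the precision at that
#' threshold, with tied scores grouped into one threshold.
#'
#' @inheritParams compute_auc
#' @return PRAUC in `(0, 1]`.
#' @export
compute_prauc <- function(scores, labels) {
  .assert_binary(labels)
  npos <- sum(labels == 1)
  if (npos == 0) stop("PRAUC requires at least one positive label", call. = FALSE)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  grp <- cumsum(!duplicated(s)) # tie group per descending threshold
  tp <- cumsum(y)
  n <- seq_along(y)
  last <- !duplicated(grp, fromLast = TRUE) # last index of each tie group
  tp_g <- tp[last]
  n_g <- n[last]
  prec <- tp_g / n_g
  rec <- tp_g / npos
  sum(diff(c(0, rec)) * prec)
}

#' Repeated stratified k-fold cross-validation with nested tuning
#'
#' For each of `rounds` random stratified `folds`-fold partitions and each
#' held-out fold: the hyperparameter setting (including how many of the
#' ranked features to use) is chosen by an inner cross-validated AUC on the
#' training portion only, the model is refit on the training portion, and
#' AUC/PRAUC are measured on the held-out fold — `rounds * folds`
#' validation records in total (500 x 3 = 1500 with the defaults).
#'
#' @param table patients x features matrix.
#' @param labels 0/1 vector.
#' @param ranked_features feature names in rank order (at least
#'   `max(grid$n_top)` of them).
#' @param grid data.frame from [build_grid()] (use a reduced grid for
#'   small studies).
#' @param rounds number of repeated partitions (default 500).
#' @param folds folds per partition (default 3).
#' @param inner_folds folds of the nested tuning CV.
#' @param seed master seed.
#' @return A `validation_result`: `records` (round, fold, auc, prauc),
#'   `summary` (means/sds), `mean_roc` (101-point averaged ROC),
#'   `chosen` (per-test chosen settings).
#' @export
cross_validate <- function(table, labels, ranked_features, grid = build_grid(),
                           rounds = 500, folds = 3, inner_folds = 3, seed = 1) {
  .assert_binary(labels)
  stopifnot(nrow(table) == length(labels))
  ranked_features <- ranked_features[ranked_features %in% colnames(table)]
  maxk <- max(grid$n_top)
  if (length(ranked_features) < min(grid$n_top)) {
    stop("fewer ranked features than the smallest grid signature size", call. = FALSE)
  }
  grid$n_top <- pmin(grid$n_top, length(ranked_features))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (min(n1, n0) < folds) {
    stop("folds must allow both classes in every fold; reduce 'folds'", call. = FALSE)
  }
  records <- vector("list", rounds * folds)
  chosen <- vector("list", rounds * folds)
  pairs <- vector("list", rounds * folds)
  k <- 0L
  for (r in seq_len(rounds)) {
    set.seed(substream_seed(seed, r, "cv-round"))
    fold <- .stratified_folds(labels, folds)
    for (f in seq_len(folds)) {
      k <- k + 1L
      tr <- fold != f
      xtr <- table[tr, , drop = FALSE]
      ytr <- labels[tr]
      best <- .tune_setting(xtr, ytr, ranked_features, grid, inner_folds,
        seed = substream_seed(seed, r * folds + f, "cv-tune")
      )
      feats <- ranked_features[seq_len(best$n_top)]
      scorer <- fit_gbm(xtr[, feats, drop = FALSE], ytr, best, seed = 11L)
      sc <- scorer(table[!tr, feats, drop = FALSE])
      yte <- labels[!tr]
      records[[k]] <- data.frame(
        round = r, fold = f,
        auc = compute_auc(sc, yte), prauc = compute_prauc(sc, yte)
      )
      chosen[[k]] <- best
      pairs[[k]] <- list(scores = sc, labels = yte)
    }
  }
  records <- do.call(rbind, records)
  structure(
    list(
      records = records,
      summary = c(
        mean_auc = mean(records$auc), sd_auc = stats::sd(records$auc),
        mean_prauc = mean(records$prauc), sd_prauc = stats::sd(records$prauc)
      ),
      mean_roc = average_roc(pairs),
      chosen = chosen
    ),
    class = "validation_result"
  )
}

# choose the grid row with the best inner-CV AUC on the training portion
.tune_setting <- function(xtr, ytr, ranked_features, grid, inner_folds, seed) {
  if (nrow(grid) == 1L) return(as.list(grid[1L, ]))
  set.seed(seed)
  fold <- .stratified_folds(ytr, inner_folds)
  best <- NULL
  best_auc <- -Inf
  for (gi in seq_len(nrow(grid))) {
    st <- as.list(grid[gi, ])
    feats <- ranked_features[seq_len(st$n_top)]
    auc <- .subset_cv_auc(xtr[, feats, drop = FALSE], ytr, fold, st)
    if (auc > best_auc) {
      best_auc <- auc
      best <- st
    }
  }
  best
}

#' Vertically averaged ROC curve
#'
#' Interpolates each test's ROC curve onto a fixed 101-point FPR grid and
#' averages the TPR values, giving a monotone mean curve through (0,0) and
#' (1,1).
#'
#' @param pairs list of `list(scores=, labels=)` per validation test.
#' @return A data.frame with `fpr` and mean `tpr`.
#' @export
average_roc <- function(pairs) {
  if (length(pairs) == 0L) stop("no validation tests to average", call. = FALSE)
  grid <- seq(0, 1, by = 0.01)
  tprs <- vapply(pairs, function(p) {
    .roc_at(p$scores, p$labels, grid)
  }, numeric(length(grid)))
  data.frame(fpr = grid, tpr = rowMeans(tprs))
}

# TPR of the empirical ROC step curve at given FPR values
.roc_at <- function(scores, labels, fpr_grid) {
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]
  s <- scores[o]
  grp <- cumsum(!duplicated(s))
  last <- !duplicated(grp, fromLast = TRUE)
  tp <- cumsum(y)[last]
  fp <- cumsum(1 - y)[last]
  tpr <- c(0, tp / max(sum(labels), 1))
  fpr <- c(0, fp / max(sum(1 - labels), 1))
  vapply(fpr_grid, function(g) max(tpr[fpr <= g + 1e-12]), numeric(1))
}

#' Negative-control evaluation
#'
#' Runs the full selection + evaluation protocol against labels that are
#' (by construction or assumption) independent of the features — the
#' ACEI-style control. A sound pipeline should return validation AUCs near
#' chance here; systematically high control AUCs indicate selection or
#' evaluation leakage.
#'
#' @param table patients x features matrix.
#' @param null_labels 0/1 labels independent of the features; if `NULL`,
#'   generated at `prevalence` with `seed`.
#' @param prevalence prevalence used when generating labels (default
#'   35/91, the ACEI rate).
#' @param selection a [selection_config()].
#' @param grid hyperparameter grid for evaluation.
#' @param rounds,folds evaluation protocol size.
#' @param seed master seed.
#' @return A list with the `selection_result`, the `validation_result` and
#'   the labels used.
#' @export
negative_control <- function(table, null_labels = NULL, prevalence = 35 / 91,
                             selection = selection_config(),
                             grid = build_grid(), rounds = 500, folds = 3,
                             seed = 1) {
  if (is.null(null_labels)) {
    if (prevalence <= 0 || prevalence >= 1) {
      stop("prevalence must lie strictly between 0 and 1", call. = FALSE)
    }
    set.seed(substream_seed(seed, 0L, "null-labels"))
    null_labels <- integer(nrow(table))
    null_labels[sample.int(nrow(table), round(prevalence * nrow(table)))] <- 1L
  }
  .assert_binary(null_labels)
  sel <- run_selection(table, null_labels, selection)
  ranked <- suppressWarnings(top_features(sel, selection$top_k))
  if (length(ranked) < min(grid$n_top)) {
    # the control selected (almost) nothing: fall back to the global
    # frequency ranking so the evaluation stage can still be exercised
    ranked <- utils::head(sel$ranked, max(grid$n_top))
  }
  ev <- cross_validate(table, null_labels, ranked, grid, rounds, folds, seed = seed)
  list(selection = sel, validation = ev, labels = null_labels)
}
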