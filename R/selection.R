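#' Selection configuration
#'
#' Parameters of the resampling feature-selection procedure: 1000 rounds of
#' two-thirds subsampling; per round a univariate ANOVA screen, a lenient
#' Benjamini-Hochberg filter at adjusted p < 0.5, correlation clustering at
#' |r| > 0.8 keeping the lowest-p representative, and sequential floating
#' forward selection (SFFS) with a gradient-boosting learner that keeps only
#' features improving the internal cross-validated AUC by more than 0.01.
#'
#' @param rounds number of resampling rounds.
#' @param subsample_fraction fraction of patients drawn (without
#'   replacement, stratified) per round.
#' @param fdr_threshold BH-adjusted p cutoff.
#' @param correlation_threshold |Pearson r| above which features are
#'   clustered.
#' @param delta_auc minimum AUC improvement for SFFS to keep a feature.
#' @param top_k number of features in the final ranked signature.
#' @param learner list of gradient-boosting settings used inside SFFS
#'   (`trees`, `shrinkage`, `depth`, `min_node`, `bag_fraction`); the
#'   default is a deliberately light configuration because this model is
#'   refit thousands of times per selection run.
#' @param inner_folds folds of the CV that scores subsets inside SFFS.
#' @param seed master seed.
#' @return A `selection_config` list.
#' @export
selection_config <- function(rounds = 1000, subsample_fraction = 2 / 3,
                             fdr_threshold = 0.5, correlation_threshold = 0.8,
                             delta_auc = 0.01, top_k = 10,
                             learner = list(
                               trees = 30, shrinkage = 0.15, depth = 2,
                               min_node = 5, bag_fraction = 1
                             ),
                             inner_folds = 3, seed = 1) {
  stopifnot(
    rounds >= 1, subsample_fraction > 0, subsample_fraction < 1,
    fdr_threshold > 0, fdr_threshold <= 1,
    correlation_threshold > 0, correlation_threshold <= 1,
    top_k >= 1
  )
  structure(
    list(
      rounds = as.integer(rounds), subsample_fraction = subsample_fraction,
      fdr_threshold = fdr_threshold, correlation_threshold = correlation_threshold,
      delta_auc = delta_auc, top_k = as.integer(top_k), learner = learner,
      inner_folds = as.integer(inner_folds), seed = as.integer(seed)
    ),
    class = "selection_config"
  )
}

#' Univariate ANOVA screen
#'
#' One-way two-group ANOVA F-test p-value for every feature (equivalent to
#' the two-sided pooled-variance t-test). Features with zero within-group
#' variance and equal means get p = 1 by convention.
#'
#' @param table numeric matrix, patients x features.
#' @param labels 0/1 vector.
#' @return Named numeric vector of p-values.
#' @export
anova_screen <- function(table, labels) {
  .assert_binary(labels)
  n <- nrow(table)
  if (n < 3) stop("need at least 3 samples for the ANOVA screen", call. = FALSE)
  n1 <- sum(labels == 1)
  n0 <- n - n1
  if (n1 == 0 || n0 == 0) {
    stop("both label classes must be present in the sample", call. = FALSE)
  }
  m1 <- colMeans(table[labels == 1, , drop = FALSE])
  m0 <- colMeans(table[labels == 0, , drop = FALSE])
  gm <- (n1 * m1 + n0 * m0) / n
  ssb <- n1 * (m1 - gm)^2 + n0 * (m0 - gm)^2
  sst <- colSums(sweep(table, 2, gm)^2)
  ssw <- pmax(sst - ssb, 0)
  f <- (ssb / 1) / (ssw / (n - 2))
  p <- stats::pf(f, 1, n - 2, lower.tail = FALSE)
  p[ssw == 0 & ssb == 0] <- 1 # zero-variance features carry no evidence
  p[ssw == 0 & ssb > 0] <- 0 # perfect separation with zero within-group spread
  stats::setNames(p, colnames(table))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: `p_(i) * m / i`, cumulative minimum from the
#' largest rank down, capped at 1.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order and names as the input.
#' @export
fdr_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  if (m == 0L) return(p)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(p[o] * m / seq(m, 1)))
  out <- p
  out[o] <- adj
  out
}

#' Cluster correlated features and keep one representative per cluster
#'
#' Builds a graph with an edge wherever two surviving features have
#' `|Pearson r| >` the threshold; each connected component is a cluster and
#' its representative is the feature with the lowest screening p-value
#' (ties broken by name). Zero-variance features correlate with nothing.
#'
#' @param table patients x features matrix (the current subsample).
#' @param features character vector of surviving feature names.
#' @param p named p-values from [anova_screen()].
#' @param threshold |r| cutoff (default 0.8).
#' @return Character vector of representative feature names.
#' @export
cluster_correlated <- function(table, features, p, threshold = 0.8) {
  if (length(features) == 0L) stop("no surviving features to cluster", call. = FALSE)
  if (length(features) == 1L) return(features)
  x <- table[, features, drop = FALSE]
  suppressWarnings(r <- stats::cor(x))
  r[!is.finite(r)] <- 0 # zero-variance features
  adj <- abs(r) > threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  unname(vapply(split(features, comp), function(cl) {
    cl[order(p[cl], cl)][1]
  }, character(1)))
}

# k-fold CV AUC of the boosting learner on a feature subset. This is the
# innermost hot loop of SFFS and of the nested tuner, so it calls the
# booster directly (same parameter mapping as fit_gbm) instead of going
# through the scorer-closure interface; a failed fit scores chance.
.subset_cv_auc <- function(x, y, fold, learner) {
  k <- max(fold)
  params <- .gbm_params(learner, seed = 7L)
  nrounds <- as.integer(learner$trees)
  aucs <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold != f
    ytr <- y[tr]
    yte <- y[!tr]
    if (length(unique(ytr)) < 2 || length(unique(yte)) < 2) {
      aucs[f] <- 0.5
      next
    }
    p <- tryCatch(
      {
        dtr <- xgboost::xgb.DMatrix(x[tr, , drop = FALSE], label = ytr, nthread = 1)
        m <- xgboost::xgb.train(params = params, data = dtr, nrounds = nrounds, verbose = 0)
        stats::predict(m, xgboost::xgb.DMatrix(x[!tr, , drop = FALSE], nthread = 1))
      },
      error = function(e) NULL
    )
    if (is.null(p)) {
      aucs[f] <- 0.5
    } else {
      n1 <- sum(yte == 1)
      r <- rank(p)
      aucs[f] <- (sum(r[yte == 1]) - n1 * (n1 + 1) / 2) / (n1 * (length(yte) - n1))
    }
  }
  mean(aucs)
}

#' Sequential floating forward selection
#'
#' Classic SFFS on a candidate set: repeatedly add the feature whose
#' addition gives the best cross-validated AUC of the gradient-boosting
#' learner, provided the gain exceeds `delta_auc`; after every addition,
#' conditionally remove any feature (other than the newest) whose removal
#' improves on the best score recorded for the smaller subset size. The
#' empty set scores 0.5 (chance). Deterministic given the seed; candidate
#' ties break lexicographically.
#'
#' @param table patients x features matrix (the round's subsample).
#' @param labels 0/1 vector.
#' @param candidates character vector of candidate feature names.
#' @param delta_auc minimum improvement to accept an addition.
#' @param learner gradient-boosting settings (see [selection_config()]).
#' @param inner_folds CV folds used to score subsets.
#' @param seed integer seed (controls the fold split).
#' @return Character vector of selected feature names (possibly empty).
#' @export
sffs_select <- function(table, labels, candidates, delta_auc = 0.01,
                        learner = selection_config()$learner,
                        inner_folds = 3, seed = 1) {
  if (length(candidates) == 0L) stop("candidate set is empty", call. = FALSE)
  candidates <- sort(candidates)
  set.seed(seed)
  fold <- .stratified_folds(labels, inner_folds)
  memo <- new.env(parent = emptyenv())
  score <- function(set) {
    if (length(set) == 0L) return(0.5)
    key <- paste(sort(set), collapse = "\r")
    if (!is.null(memo[[key]])) return(memo[[key]])
    memo[[key]] <- .subset_cv_auc(table[, set, drop = FALSE], labels, fold, learner)
    memo[[key]]
  }
  selected <- character(0)
  current <- 0.5
  best_by_size <- c(`0` = 0.5) # best score seen for each subset size
  repeat {
    remaining <- setdiff(candidates, selected)
    if (length(remaining) == 0L) break
    gains <- vapply(remaining, function(f) score(c(selected, f)), numeric(1))
    bi <- which.max(gains) # ties: first in sorted order
    if (gains[bi] <= current + delta_auc) break
    selected <- c(selected, remaining[bi])
    current <- gains[bi]
    newest <- remaining[bi]
    best_by_size[as.character(length(selected))] <-
      max(current, best_by_size[as.character(length(selected))], na.rm = TRUE)
    # floating backward step
    while (length(selected) > 2L) {
      drops <- vapply(
        setdiff(selected, newest),
        function(f) score(setdiff(selected, f)), numeric(1)
      )
      sz <- as.character(length(selected) - 1L)
      prev_best <- if (sz %in% names(best_by_size)) best_by_size[[sz]] else 0.5
      if (max(drops) > prev_best) {
        worst <- names(drops)[which.max(drops)]
        selected <- setdiff(selected, worst)
        current <- max(drops)
        best_by_size[[sz]] <- current
      } else {
        break
      }
    }
  }
  selected
}

#' Run the full resampling feature-selection procedure
#'
#' Per round: draw a stratified subsample of `ceiling(fraction * n)`
#' patients, screen every feature by ANOVA, keep BH-adjusted p below the
#' threshold, collapse correlated clusters to their lowest-p
#' representative, and run SFFS; accumulate how often each feature is
#' selected across rounds.
#'
#' @param table patients x features matrix.
#' @param labels 0/1 vector.
#' @param config a [selection_config()].
#' @return A `selection_result` list: `frequency` (named counts), `ranked`
#'   (names by decreasing frequency, ties lexicographic), `rounds`,
#'   `log` (per-round selected sets and stage sizes).
#' @export
run_selection <- function(table, labels, config = selection_config()) {
  .assert_binary(labels)
  stopifnot(nrow(table) == length(labels))
  if (is.null(colnames(table))) {
    colnames(table) <- sprintf("f%04d", seq_len(ncol(table)))
  }
  freq <- stats::setNames(integer(ncol(table)), colnames(table))
  m <- ceiling(config$subsample_fraction * nrow(table))
  log <- vector("list", config$rounds)
  for (r in seq_len(config$rounds)) {
    set.seed(substream_seed(config$seed, r, "selection-round"))
    idx <- .stratified_sample(labels, m)
    sub <- table[idx, , drop = FALSE]
    suby <- labels[idx]
    p <- anova_screen(sub, suby)
    padj <- fdr_adjust(p)
    surv <- names(padj)[padj < config$fdr_threshold]
    sel <- character(0)
    reps <- character(0)
    if (length(surv) > 0) {
      reps <- cluster_correlated(sub, surv, p, config$correlation_threshold)
      sel <- sffs_select(
        sub, suby, reps,
        delta_auc = config$delta_auc, learner = config$learner,
        inner_folds = config$inner_folds,
        seed = substream_seed(config$seed, r, "sffs")
      )
      freq[sel] <- freq[sel] + 1L
    }
    log[[r]] <- list(
      round = r, n_screened = length(surv), n_clustered = length(reps),
      selected = sel
    )
  }
  ranked <- names(freq)[order(-freq, names(freq))]
  structure(
    list(frequency = freq, ranked = ranked, rounds = config$rounds, log = log),
    class = "selection_result"
  )
}

#' Top-k features by selection frequency
#'
#' @param result a `selection_result` from [run_selection()].
#' @param k signature size (default 10).
#' @return Character vector of at most `k` names, decreasing frequency,
#'   ties lexicographic; warns if fewer than `k` features were ever
#'   selected.
#' @export
top_features <- function(result, k = 10) {
  stopifnot(inherits(result, "selection_result"), k >= 1)
  nz <- result$frequency[result$frequency > 0]
  if (length(nz) < k) {
    warning(sprintf(
      "only %d features were ever selected; returning all of them", length(nz)
    ), call. = FALSE)
    k <- length(nz)
  }
  ranked_nz <- names(nz)[order(-nz, names(nz))]
  f <- result$frequency[ranked_nz]
  if (k >= 1 && k < length(ranked_nz) && f[k] == f[k + 1]) {
    warning("tie at the top-k boundary broken lexicographically", call. = FALSE)
  }
  utils::head(ranked_nz, k)
}
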