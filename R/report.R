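#' Run the full signature-discovery pipeline for one drug/ROI combination
#'
#' Executes select -> evaluate on a feature table and labels (the table may
#' come from [extract_feature_table()] on images or from
#' [generate_feature_table()]), and writes the artifacts of the run:
#' selection frequencies, the ranked signature, per-test validation
#' metrics, the averaged ROC curve and a machine-readable JSON report. The
#' report echoes the configuration and master seed, so a re-run with the
#' same inputs is byte-identical.
#'
#' @param table patients x features matrix.
#' @param labels data.frame with `patient_id` and one column per drug.
#' @param drug name of the label column to model.
#' @param out_dir output directory.
#' @param selection a [selection_config()].
#' @param grid evaluation hyperparameter grid.
#' @param rounds,folds evaluation protocol size.
#' @param seed master seed for the whole run.
#' @param make_figures also write the heatmap and mean-ROC figure.
#' @return The report list, invisibly.
#' @export
run_pipeline <- function(table, labels, drug, out_dir,
                         selection = selection_config(),
                         grid = build_grid(), rounds = 500, folds = 3,
                         seed = 1, make_figures = FALSE) {
  if (!drug %in% colnames(labels)) {
    stop(sprintf("drug column '%s' not found in the labels table", drug), call. = FALSE)
  }
  y <- labels[[drug]]
  .assert_binary(y, drug)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  selection$seed <- seed

  stage <- "feature selection"
  res <- tryCatch(
    {
      sel <- run_selection(table, y, selection)
      ranked <- suppressWarnings(top_features(sel, selection$top_k))
      if (length(ranked) < min(grid$n_top)) {
        ranked <- utils::head(sel$ranked, max(grid$n_top))
      }
      stage <- "model evaluation"
      ev <- cross_validate(table, y, ranked, grid, rounds, folds, seed = seed)
      list(sel = sel, ranked = ranked, ev = ev)
    },
    error = function(e) {
      stop(sprintf("pipeline failed during %s: %s", stage, conditionMessage(e)), call. = FALSE)
    }
  )

  freq_df <- data.frame(
    feature = names(res$sel$frequency),
    frequency = as.integer(res$sel$frequency)
  )
  utils::write.csv(freq_df, file.path(out_dir, "selection_frequency.csv"), row.names = FALSE)
  writeLines(res$ranked, file.path(out_dir, "signature.txt"))
  utils::write.csv(res$ev$records, file.path(out_dir, "validation_metrics.csv"), row.names = FALSE)
  utils::write.csv(res$ev$mean_roc, file.path(out_dir, "mean_roc.csv"), row.names = FALSE)

  files <- c(
    "selection_frequency.csv", "signature.txt",
    "validation_metrics.csv", "mean_roc.csv"
  )
  if (make_figures) {
    make_heatmap(table, labels, file.path(out_dir, "heatmap.png"))
    plot_mean_roc(res$ev, file.path(out_dir, "mean_roc.png"))
    files <- c(files, "heatmap.png", "mean_roc.png")
  }
  report <- list(
    drug = drug,
    seed = seed,
    n_patients = nrow(table),
    n_features = ncol(table),
    selection = list(
      rounds = selection$rounds,
      subsample_fraction = selection$subsample_fraction,
      fdr_threshold = selection$fdr_threshold,
      correlation_threshold = selection$correlation_threshold,
      delta_auc = selection$delta_auc,
      top_k = selection$top_k
    ),
    evaluation = list(
      rounds = rounds, folds = folds, n_tests = nrow(res$ev$records),
      grid_size = nrow(grid)
    ),
    signature = res$ranked,
    metrics = as.list(res$ev$summary),
    files = files
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(report)
}

#' Feature-pattern heatmap with drug-usage annotation
#'
#' Columns (features) are z-scored; patients and features are ordered by
#' hierarchical clustering (Euclidean distance, average linkage) and the
#' drug-usage flags are drawn as annotation bars. For display only,
#' z-scores are clipped at +/-4 so single extreme patients cannot flatten
#' the colour scale — analysis data are never clipped.
#'
#' @param table patients x features matrix.
#' @param labels data.frame with `patient_id` and binary drug columns.
#' @param path output figure path (`.png`).
#' @param clip display clipping for z-scores.
#' @return `path`, invisibly.
#' @export
make_heatmap <- function(table, labels, path, clip = 4) {
  sds <- apply(table, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping %d zero-variance features from the heatmap", sum(sds == 0)))
    table <- table[, sds > 0, drop = FALSE]
  }
  if (ncol(table) == 0L) stop("no non-constant features to draw", call. = FALSE)
  z <- scale(table)
  z[z > clip] <- clip
  z[z < -clip] <- -clip
  ann_cols <- intersect(c("statin", "omega3", "acei"), colnames(labels))
  ann <- as.data.frame(lapply(labels[ann_cols], function(v) factor(v, c(0, 1), c("no", "yes"))))
  rownames(ann) <- rownames(z) <- if (!is.null(labels$patient_id)) labels$patient_id else rownames(z)
  grDevices::png(path, width = 1400, height = 900, res = 120)
  on.exit(grDevices::dev.off(), add = TRUE)
  pheatmap::pheatmap(
    t(z),
    clustering_method = "average",
    clustering_distance_rows = "euclidean",
    clustering_distance_cols = "euclidean",
    annotation_col = ann,
    show_rownames = ncol(table) <= 60,
    show_colnames = nrow(table) <= 60,
    main = "Radiomic feature pattern (column z-scores)"
  )
  invisible(path)
}

#' Plot the averaged ROC curve of a validation result
#'
#' @param result a `validation_result` from [cross_validate()].
#' @param path output figure path (`.png`).
#' @return `path`, invisibly.
#' @export
plot_mean_roc <- function(result, path) {
  stopifnot(inherits(result, "validation_result"))
  grDevices::png(path, width = 700, height = 700, res = 120)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::plot(
    result$mean_roc$fpr, result$mean_roc$tpr,
    type = "l", lwd = 2, col = "#0072B2",
    xlab = "False positive rate", ylab = "True positive rate",
    main = "Average ROC over validation tests", xlim = c(0, 1), ylim = c(0, 1)
  )
  graphics::abline(0, 1, lty = 2, col = "grey50")
  graphics::legend(
    "bottomright",
    legend = sprintf("mean AUC = %.2f", result$summary[["mean_auc"]]),
    bty = "n"
  )
  invisible(path)
}

#' Hierarchical patient clustering of a feature table
#'
#' Average-linkage clustering of z-scored features into `k` groups; used to
#' compare unsupervised patient structure with the drug labels.
#'
#' @param table patients x features matrix.
#' @param k number of clusters.
#' @return Integer cluster assignment per patient.
#' @export
cluster_patients <- function(table, k = 2) {
  sds <- apply(table, 2, stats::sd)
  z <- scale(table[, sds > 0, drop = FALSE])
  stats::cutree(stats::hclust(stats::dist(z), method = "average"), k = k)
}
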