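#' Confusion counts for binary predictions
#'
#' Counts with positive class = 1: TP (true 1 predicted 1), TN (true 0
#' predicted 0), FP (true 0 predicted 1), FN (true 1 predicted 0).
#'
#' @param y_true,y_pred Equal-length vectors with values in `{0, 1}`.
#' @return A list of class `confusion_counts` with integer `TP`, `FP`,
#'   `TN`, `FN`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("length mismatch: ", length(y_true), " vs ", length(y_pred),
         call. = FALSE)
  }
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1))) {
    stop("labels must be binary 0/1", call. = FALSE)
  }
  structure(list(TP = sum(y_true == 1 & y_pred == 1),
                 FP = sum(y_true == 0 & y_pred == 1),
                 TN = sum(y_true == 0 & y_pred == 0),
                 FN = sum(y_true == 1 & y_pred == 0)),
            class = "confusion_counts")
}

#' Accuracy, sensitivity, specificity and precision from counts
#'
#' The four standard ratios: accuracy `(TP+TN)/(TP+FN+FP+TN)`, sensitivity
#' `TP/(TP+FN)`, specificity `TN/(TN+FP)`, precision `TP/(TP+FP)`. A zero
#' denominator yields `NA` and the metric's name is recorded in
#' `undefined`, never a silent zero.
#'
#' @param counts A [confusion()] result.
#' @return A list of class `metrics_report` with the four metrics, the
#'   counts and an `undefined` character vector.
#' @export
metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tot <- counts$TP + counts$FP + counts$TN + counts$FN
  if (tot == 0L) stop("all-zero confusion counts", call. = FALSE)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  out <- list(accuracy = (counts$TP + counts$TN) / tot,
              sensitivity = ratio(counts$TP, counts$TP + counts$FN),
              specificity = ratio(counts$TN, counts$TN + counts$FP),
              precision = ratio(counts$TP, counts$TP + counts$FP),
              counts = counts)
  out$undefined <- names(which(vapply(out[1:4], is.na, logical(1))))
  structure(out, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.4f", v)
  cat("<metrics_report> accuracy ", fmt(x$accuracy),
      ", sensitivity ", fmt(x$sensitivity),
      ", specificity ", fmt(x$specificity),
      ", precision ", fmt(x$precision), "\n", sep = "")
  cat("  counts: TP=", x$counts$TP, " FP=", x$counts$FP,
      " TN=", x$counts$TN, " FN=", x$counts$FN, "\n", sep = "")
  invisible(x)
}

# one split -> selection on the training fold -> classifier -> test metrics
.run_once <- function(fm, config, split_seed, selected_global = NULL,
                      split = NULL) {
  sp <- if (is.null(split)) stratified_split(fm$labels, 0.75, split_seed) else
    split
  train_fm <- feature_matrix(fm$values[sp$train, , drop = FALSE],
                             fm$labels[sp$train])
  selected <- if (!is.null(selected_global)) {
    selected_global
  } else {
    recursive_select(train_fm, k_final = config$k_final,
                     n_trees = config$n_trees, seed = split_seed)$selected
  }
  tr_cfg <- config$train
  tr_cfg$seed <- split_seed
  model <- if (config$classifier == "cnn") {
    build_cnn(cnn_spec(input_len = length(selected)), seed = split_seed)
  } else {
    build_svm()
  }
  fit <- if (config$classifier == "cnn") {
    .cnn_fit(model, train_fm$values[, selected, drop = FALSE],
             train_fm$labels, tr_cfg)
  } else {
    .svm_fit(model, train_fm$values[, selected, drop = FALSE],
             train_fm$labels, tr_cfg)
  }
  pred <- predict(fit, fm$values[sp$test, selected, drop = FALSE])
  m <- metrics(confusion(fm$labels[sp$test], as.integer(pred$labels)))
  list(metrics = m, selected = selected, model = fit,
       test_idx = sp$test, train_idx = sp$train)
}

#' Run one classification case end to end
#'
#' For each repeat: fresh seeded stratified 3:1 split, recursive feature
#' selection fit on the training fold only (unless
#' `selection_scope = "global"`), classifier training on the selected
#' training-fold features, and metrics on the held-out fold. Selection and
#' training never see test-fold rows.
#'
#' @param segments Labeled [eeg_segment()]s (e.g. from [assemble_case()] or
#'   [generate_dataset()]). Alternatively pass `case_id` together with
#'   `segments_by_set`.
#' @param config A [pipeline_config()].
#' @param n_repeats Number of repeated splits (default 10).
#' @param seed Master seed; repeat `i` uses `seed + i - 1` for its split.
#' @param case_id,segments_by_set Optional: resolve the segment list via
#'   [assemble_case()].
#' @param shuffle_labels Permute all labels once (seeded) before running --
#'   a chance-level control for leak checking.
#' @return A list of class `case_report`: `case_id`, mean metrics
#'   (`accuracy`, `sensitivity`, `specificity`, `precision`), `sd_accuracy`,
#'   `per_repeat` data frame, `n_repeats`, and the selected features of
#'   each repeat.
#' @export
run_case <- function(segments = NULL, config = pipeline_config(),
                     n_repeats = 10, seed = 0, case_id = NULL,
                     segments_by_set = NULL, shuffle_labels = FALSE) {
  if (is.null(segments)) {
    if (is.null(case_id) || is.null(segments_by_set)) {
      stop("provide either `segments` or both `case_id` and `segments_by_set`",
           call. = FALSE)
    }
    segments <- assemble_case(case_id, segments_by_set)
  }
  stopifnot(n_repeats >= 1)
  fm <- segments_to_features(segments, config)
  if (isTRUE(shuffle_labels)) {
    set.seed(seed + 990001L)
    fm$labels <- fm$labels[sample.int(length(fm$labels))]
  }
  selected_global <- if (config$selection_scope == "global") {
    recursive_select(fm, k_final = config$k_final, n_trees = config$n_trees,
                     seed = seed)$selected
  } else NULL
  runs <- lapply(seq_len(n_repeats), function(i) {
    .run_once(fm, config, split_seed = seed + i - 1L,
              selected_global = selected_global)
  })
  per <- do.call(rbind, lapply(seq_along(runs), function(i) {
    m <- runs[[i]]$metrics
    data.frame(repeat_id = i, accuracy = m$accuracy,
               sensitivity = m$sensitivity, specificity = m$specificity,
               precision = m$precision, stringsAsFactors = FALSE)
  }))
  structure(list(case_id = if (is.null(case_id)) "custom" else case_id,
                 accuracy = mean(per$accuracy),
                 sensitivity = mean(per$sensitivity),
                 specificity = mean(per$specificity),
                 precision = mean(per$precision),
                 sd_accuracy = stats::sd(per$accuracy),
                 per_repeat = per, n_repeats = n_repeats,
                 selected = lapply(runs, `[[`, "selected"),
                 shuffled = isTRUE(shuffle_labels)),
            class = "case_report")
}

#' @export
print.case_report <- function(x, ...) {
  cat("<case_report> ", x$case_id, if (x$shuffled) " (labels shuffled)",
      ": mean accuracy ", sprintf("%.4f", x$accuracy),
      " +/- ", sprintf("%.4f", if (is.na(x$sd_accuracy)) 0 else x$sd_accuracy),
      " over ", x$n_repeats, " repeats\n", sep = "")
  invisible(x)
}

#' Serialize / restore a case report as JSON
#'
#' The JSON round trip is lossless for every numeric field.
#'
#' @param report A [run_case()] report.
#' @param path Output (input) JSON path.
#' @return `write_case_report()` returns `path` invisibly;
#'   `read_case_report()` the restored `case_report`.
#' @export
write_case_report <- function(report, path) {
  stopifnot(inherits(report, "case_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_case_report
#' @export
read_case_report <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  obj$per_repeat <- as.data.frame(obj$per_repeat)
  # undo jsonlite's simplification of the per-repeat selection lists
  obj$selected <- if (is.matrix(obj$selected)) {
    lapply(seq_len(nrow(obj$selected)), function(i) obj$selected[i, ])
  } else if (is.atomic(obj$selected)) {
    list(as.character(obj$selected))
  } else {
    lapply(obj$selected, as.character)
  }
  structure(obj, class = "case_report")
}
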