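# End-to-end pipeline: load a labeled CSV feature table, split, fit bins
# on the training rows only, run the Tabu reducer on the discretized
# training table, then benchmark the classifiers on the raw continuous
# features with and without the selection. Reports are written as JSON;
# reruns with the same config reproduce them byte for byte.

coerce_labels <- function(data, label) {
  if (!label %in% names(data)) {
    stop(sprintf("label column '%s' not found; available: %s",
                 label, paste(names(data), collapse = ", ")), call. = FALSE)
  }
  feats <- data[setdiff(names(data), label)]
  not_num <- names(feats)[!vapply(feats, is.numeric, logical(1))]
  if (length(not_num)) {
    stop("non-numeric feature column(s): ", paste(not_num, collapse = ", "),
         call. = FALSE)
  }
  raw <- data[[label]]
  if (is.numeric(raw) && all(raw %in% c(0, 1))) {
    labels <- as.integer(raw)
    mapping <- c(`0` = 0L, `1` = 1L)
  } else {
    f <- factor(raw)
    if (nlevels(f) != 2L) {
      stop(sprintf("label column must be binary; found %d distinct values",
                   nlevels(f)), call. = FALSE)
    }
    labels <- as.integer(f) - 1L
    mapping <- stats::setNames(0:1, levels(f))
  }
  list(features = tibble::as_tibble(feats), labels = labels, mapping = mapping)
}

#' Load a labeled feature table from CSV
#'
#' Reads a header CSV, drops any requested identifier columns, maps the
#' binary label to 0/1 (recording the mapping: levels in sorted order, so
#' e.g. "B" -> 0, "M" -> 1), and rejects rows with missing values by row
#' number.
#'
#' @param path CSV path.
#' @param label Label column name (default `"label"`).
#' @param drop Character vector of columns to discard (e.g. an id column).
#' @return A list: `features` (tibble of numeric columns), `labels`
#'   (0/1 integer vector), `mapping` (named 0/1 vector recording the label
#'   encoding), `feature_names`.
#' @export
load_feature_table <- function(path, label = "label", drop = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0L) stop("empty feature table: ", path, call. = FALSE)
  if (length(drop)) df <- df[setdiff(names(df), drop)]
  bad <- which(!stats::complete.cases(df))
  if (length(bad)) {
    stop("missing values in row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- coerce_labels(as.data.frame(df), label)
  out$feature_names <- names(out$features)
  out
}

#' Run the full selection-and-benchmark pipeline
#'
#' Splits the data, discretizes the training features (bins fitted on
#' training rows only), runs the Tabu-search reducer on the discretized
#' training decision table, and evaluates all requested classifiers on
#' the raw continuous features with and without the selected columns,
#' on the identical partition.
#'
#' @inheritParams evaluate_classifiers
#' @param bins,strategy Discretizer settings for the rough-set stage
#'   (see [fit_bins()]); `strategy = "none"` asserts already-integer
#'   features and skips binning.
#' @param tabu A [tabu_config()]; its seed is reset to `seed` so one seed
#'   drives the whole run.
#' @return A `tabu_pipeline` list: `reduct` (the [tabu_reduce()] result,
#'   with attribute names from the feature table), `report` (the
#'   [evaluate_classifiers()] report), `selected` (feature names), and
#'   the resolved settings.
#' @examples
#' sim <- simulate_classification(150, n_informative = 2, n_noise = 8,
#'                                effect_size = 2, seed = 3)
#' pl <- run_pipeline(sim$data, classifiers = c("knn", "lr"), seed = 3)
#' pl$selected
#' @export
run_pipeline <- function(data, label = "label", split = split_holdout(),
                         bins = 3L, strategy = c("quantile", "width", "none"),
                         tabu = tabu_config(),
                         classifiers = classifier_codes,
                         positive = 1, seed = 1L) {
  strategy <- match.arg(strategy)
  seed <- as.integer(seed)
  tabu$seed <- seed
  loaded <- coerce_labels(data, label)
  part <- resolve_split(split, loaded$labels, seed)
  train_feats <- loaded$features[part$train, , drop = FALSE]
  if (strategy == "none") {
    coded <- train_feats
    if (any(as.matrix(coded) != round(as.matrix(coded)))) {
      stop("strategy 'none' requires integer-coded features", call. = FALSE)
    }
  } else {
    model <- fit_bins(train_feats, strategy = strategy, n_bins = bins)
    coded <- bin_apply(model, train_feats)
  }
  coded$label <- loaded$labels[part$train]
  train_table <- decision_table(as.data.frame(coded), label = "label")
  reduct <- tabu_reduce(train_table, tabu)
  selected <- reduct$selected_names
  report <- evaluate_classifiers(
    data, label = label, split = split_indices(part$train, part$test),
    classifiers = classifiers,
    selected = if (length(selected)) selected else NULL,
    positive = positive, seed = seed
  )
  structure(
    list(reduct = reduct, report = report, selected = selected,
         split = part, bins = bins, strategy = strategy, seed = seed),
    class = "tabu_pipeline"
  )
}

#' @export
print.tabu_pipeline <- function(x, ...) {
  cat(sprintf("<tabu_pipeline> %d feature(s) selected of %d, gamma %.4f (full %.4f)\n",
              length(x$selected), x$reduct$n_attributes, x$reduct$gamma,
              x$reduct$gamma_full))
  print(tidy(x$report), n = Inf)
  invisible(x)
}

#' Serialize a reduction result or pipeline report to JSON
#'
#' Writes a machine-readable record (selected attributes, dependency
#' degrees, per-classifier metrics, config echo, seeds) with stable
#' key order and fixed precision so identical runs produce identical
#' bytes.
#'
#' @param x A `tabu_reduct`, `eval_report` or `tabu_pipeline`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  payload <- report_payload(x)
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = 10,
                           pretty = TRUE, null = "null")
  writeLines(json, path)
  invisible(path)
}

report_payload <- function(x) {
  if (inherits(x, "tabu_reduct")) {
    list(
      kind = "reduct",
      selected = as.list(x$selected_names),
      selected_indices = x$selected,
      gamma = x$gamma,
      gamma_full = x$gamma_full,
      shaken = x$shaken,
      config = unclass(x$config),
      trace = x$trace
    )
  } else if (inherits(x, "eval_report")) {
    list(
      kind = "evaluation",
      seed = x$seed,
      n_train = length(x$split$train),
      n_test = length(x$split$test),
      label_mapping = as.list(x$label_mapping),
      selected = as.list(x$selected %||% character()),
      metrics = tidy(x)
    )
  } else if (inherits(x, "tabu_pipeline")) {
    list(
      kind = "pipeline",
      seed = x$seed,
      bins = x$bins,
      strategy = x$strategy,
      reduct = report_payload(x$reduct),
      evaluation = report_payload(x$report)
    )
  } else {
    stop("no JSON serialization for class ", paste(class(x), collapse = "/"),
         call. = FALSE)
  }
}

#' Score a feature selection against generator metadata
#'
#' Precision and recall of a selected feature set with respect to the
#' ground-truth roles recorded by the synthetic generators (planted or
#' informative features count as relevant; injective recodings of planted
#' attributes count as relevant too, since either member of such a pair
#' is a valid substitute).
#'
#' @param selected Character vector of selected attribute names.
#' @param metadata Metadata tibble from [simulate_decision_table()] or
#'   [simulate_classification()].
#' @return A one-row tibble: `n_selected`, `n_relevant`, `precision`,
#'   `recall`.
#' @export
score_selection <- function(selected, metadata) {
  name_col <- if ("attribute" %in% names(metadata)) "attribute" else "feature"
  relevant <- metadata[[name_col]][metadata$role %in%
                                     c("planted", "redundant", "informative")]
  hits <- intersect(selected, relevant)
  tibble::tibble(
    n_selected = length(selected),
    n_relevant = length(relevant),
    precision = if (length(selected)) length(hits) / length(selected) else NA_real_,
    recall = if (length(relevant)) length(hits) / length(relevant) else NA_real_
  )
}
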