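# The with/without-selection benchmarking harness: identical train/test
# partitions in both arms, five classifiers, five metrics per classifier.

#' Train/test split specification
#'
#' Either a stratified holdout (`split_holdout`) or explicit train/test
#' index lists (`split_indices`, for datasets shipped with a fixed split,
#' e.g. samples from one centre for training and another for testing).
#'
#' @param test_prop Proportion of rows held out per class (default 0.3).
#' @return A `split_spec`.
#' @export
split_holdout <- function(test_prop = 0.3) {
  stopifnot(test_prop > 0, test_prop < 1)
  structure(list(kind = "holdout", test_prop = test_prop), class = "split_spec")
}

#' @rdname split_holdout
#' @param train,test Integer row indices.
#' @export
split_indices <- function(train, test) {
  train <- as.integer(train); test <- as.integer(test)
  if (!length(train) || !length(test)) {
    stop("train and test index sets must be nonempty", call. = FALSE)
  }
  if (length(intersect(train, test))) {
    stop("train and test indices overlap", call. = FALSE)
  }
  structure(list(kind = "indices", train = train, test = test),
            class = "split_spec")
}

resolve_split <- function(split, labels, seed) {
  if (split$kind == "indices") {
    return(list(train = split$train, test = split$test))
  }
  idx <- withr::with_seed(seed, {
    unlist(lapply(base::split(seq_along(labels), labels), function(rows) {
      n_test <- max(1L, round(split$test_prop * length(rows)))
      if (n_test >= length(rows)) {
        stop("a class would have no training rows; reduce test_prop", call. = FALSE)
      }
      sample(rows, n_test)
    }), use.names = FALSE)
  })
  list(train = setdiff(seq_along(labels), idx), test = sort(idx))
}

#' Benchmark classifiers with and without a feature selection
#'
#' Fits each requested classifier on the training rows -- once on all
#' features and, when `selected` is given, once restricted to the selected
#' features -- and scores accuracy, precision, sensitivity, F1 and ROC AUC
#' on the held-out rows. Both arms share the identical partition, and the
#' whole run is reproducible from `seed`.
#'
#' @param data Data frame: numeric feature columns plus a binary label
#'   column. Classifiers consume the features as-is (discretization is
#'   only ever used by the rough-set selector).
#' @param label Label column name (default `"label"`).
#' @param split A [split_holdout()] or [split_indices()] spec.
#' @param classifiers Subset of `c("knn", "gnb", "lr", "et", "ab")`.
#' @param selected Optional character vector (or integer indices) of
#'   feature columns defining the selected-feature arm.
#' @param positive Positive label value after 0/1 mapping (default 1).
#' @param seed RNG seed for the split and the stochastic learners.
#' @return An `eval_report`: tibble `metrics` with one row per classifier
#'   x arm (`features` = "all" or "selected") carrying the confusion
#'   counts and the five metrics, plus the split, selection and seed.
#' @examples
#' sim <- simulate_classification(120, n_informative = 2, n_noise = 3,
#'                                effect_size = 3, seed = 2)
#' ev <- evaluate_classifiers(sim$data, classifiers = c("knn", "lr"), seed = 2)
#' tidy(ev)
#' @export
evaluate_classifiers <- function(data, label = "label", split = split_holdout(),
                                 classifiers = classifier_codes,
                                 selected = NULL, positive = 1, seed = 1L) {
  stopifnot(is.data.frame(data))
  classifiers <- match.arg(classifiers, classifier_codes, several.ok = TRUE)
  loaded <- coerce_labels(data, label)
  feats <- loaded$features
  y <- loaded$labels
  if (length(unique(y)) < 2L) stop("both classes must be present", call. = FALSE)
  seed <- as.integer(seed)
  part <- resolve_split(split, y, seed)
  if (length(unique(y[part$train])) < 2L) {
    stop("a class is absent from the training rows; adjust the split",
         call. = FALSE)
  }
  sel_names <- NULL
  if (!is.null(selected)) {
    sel_names <- if (is.character(selected)) selected else names(feats)[selected]
    missing <- setdiff(sel_names, names(feats))
    if (length(missing)) {
      stop("selected features not in data: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    if (!length(sel_names)) stop("empty feature selection", call. = FALSE)
  }
  arms <- list(all = names(feats))
  if (!is.null(sel_names)) arms$selected <- sel_names
  rows <- list()
  for (arm in names(arms)) {
    cols <- arms[[arm]]
    for (code in classifiers) {
      res <- withr::with_seed(seed, {
        fit_predict(code,
                    feats[part$train, cols, drop = FALSE], y[part$train],
                    feats[part$test, cols, drop = FALSE], seed)
      })
      cc <- confusion_counts(y[part$test], res$class, positive = positive)
      m <- confusion_metrics(cc)
      m$auc <- auc_score(y[part$test], res$score, positive = positive)
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(classifier = code,
                       model = unname(classifier_labels[code]),
                       features = arm,
                       n_features = length(cols)),
        cc, m
      )
    }
  }
  structure(
    list(
      metrics = dplyr::bind_rows(rows),
      split = part,
      selected = sel_names,
      label_mapping = loaded$mapping,
      positive = positive,
      seed = seed
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d train / %d test rows, seed %d\n",
              length(x$split$train), length(x$split$test), x$seed))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Tidy an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return One row per classifier x arm with the five report metrics (all
#'   percentages).
#' @export
tidy.eval_report <- function(x, ...) {
  dplyr::select(x$metrics, "classifier", "model", "features", "n_features",
                "accuracy", "precision", "sensitivity", "f1", "auc")
}

#' Glance at an evaluation report
#'
#' @inheritParams tidy.eval_report
#' @return A one-row tibble summarising the best classifier per arm by
#'   accuracy.
#' @export
glance.eval_report <- function(x, ...) {
  best <- x$metrics |>
    dplyr::group_by(.data$features) |>
    dplyr::slice_max(.data$accuracy, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  tibble::tibble(
    n_train = length(x$split$train),
    n_test = length(x$split$test),
    best_all = best$classifier[best$features == "all"],
    best_all_accuracy = best$accuracy[best$features == "all"],
    best_selected = if ("selected" %in% best$features)
      best$classifier[best$features == "selected"] else NA_character_,
    best_selected_accuracy = if ("selected" %in% best$features)
      best$accuracy[best$features == "selected"] else NA_real_,
    seed = x$seed
  )
}

#' Bar-chart comparison of classifier metrics
#'
#' One panel per metric, classifiers on the x axis, one bar per arm when
#' a selected-feature arm is present.
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eval_report <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("accuracy", "precision", "sensitivity", "f1", "auc"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$classifier, y = .data$value,
                                   fill = .data$features)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = NULL, y = "percent", fill = "features",
                  title = "Classifier comparison") +
    ggplot2::theme_minimal()
}

#' ROC curves from test-set scores
#'
#' Draws empirical ROC curves (one step per test row) for a named list of
#' classifier score vectors on a common set of held-out labels.
#'
#' @param truth Binary labels of the test rows.
#' @param scores Named list of score vectors, one per classifier.
#' @param positive Positive label value.
#' @return A ggplot of ROC curves.
#' @export
plot_roc <- function(truth, scores, positive = 1) {
  stopifnot(is.list(scores), length(scores) >= 1)
  curves <- purrr::imap_dfr(scores, function(s, nm) {
    ord <- order(s, decreasing = TRUE)
    t_pos <- (truth == positive)[ord]
    tibble::tibble(
      model = nm,
      fpr = c(0, cumsum(!t_pos) / sum(!t_pos)),
      tpr = c(0, cumsum(t_pos) / sum(t_pos))
    )
  })
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                       colour = .data$model)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = "ROC curves") +
    ggplot2::theme_minimal()
}
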