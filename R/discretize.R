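#' Fit a binning model on continuous features
#'
#' Maps continuous feature columns to the integer codes the rough-set
#' calculus requires. `"quantile"` places cut points at empirical quantiles
#' of the training data (equal-frequency bins; duplicate edges collapsed),
#' `"width"` splits the observed \[min, max\] into equal-width bins.
#' Constant columns yield zero edges and a single bin. Edges are learned
#' from the rows passed here only, so fitting on training rows and
#' transforming test rows leaks nothing.
#'
#' @param data Data frame or matrix of finite numeric features.
#' @param strategy `"quantile"` (default) or `"width"`.
#' @param n_bins Number of bins per feature, >= 2. Default 3, a robust
#'   choice for heavy-tailed morphometry-style features.
#' @return A `bin_model`: per-feature strictly ascending cut points.
#' @examples
#' m <- fit_bins(data.frame(x = c(1, 2, 3, 4)), n_bins = 2)
#' bin_apply(m, data.frame(x = c(0, 2.5, 9)))
#' @export
fit_bins <- function(data, strategy = c("quantile", "width"), n_bins = 3L) {
  strategy <- match.arg(strategy)
  x <- as.matrix(data)
  if (!is.numeric(x)) stop("features must be numeric", call. = FALSE)
  if (anyNA(x) || any(!is.finite(x))) {
    stop("non-finite feature values cannot be binned", call. = FALSE)
  }
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be at least 2", call. = FALSE)
  edges <- lapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    if (min(v) == max(v)) return(numeric())
    e <- switch(strategy,
      quantile = stats::quantile(v, probs = seq_len(n_bins - 1L) / n_bins,
                                 names = FALSE, type = 7),
      width = min(v) + seq_len(n_bins - 1L) * (max(v) - min(v)) / n_bins
    )
    e <- unique(e)
    e[e > min(v) & e < max(v)]  # degenerate edges collapse bins
  })
  names(edges) <- colnames(x) %||% paste0("V", seq_len(ncol(x)))
  structure(list(strategy = strategy, n_bins = n_bins, edges = edges),
            class = "bin_model")
}

#' @export
print.bin_model <- function(x, ...) {
  cat(sprintf("<bin_model> %s, %d bins, %d features\n",
              x$strategy, x$n_bins, length(x$edges)))
  invisible(x)
}

#' Apply a fitted binning model
#'
#' Each value maps to the index of its half-open bin
#' `[edge_{k-1}, edge_k)`; a value exactly on an edge goes to the upper
#' bin, and values beyond the training range clamp to the outermost bins,
#' so codes always lie in `0 .. n_bins - 1` and are monotone in the raw
#' value.
#'
#' @param model A `bin_model` from [fit_bins()].
#' @param data Data frame or matrix with the same feature count (and order)
#'   used at fit time.
#' @return A tibble of integer codes with the model's feature names.
#' @export
bin_apply <- function(model, data) {
  stopifnot(inherits(model, "bin_model"))
  x <- as.matrix(data)
  if (ncol(x) != length(model$edges)) {
    stop(sprintf("model was fitted on %d features but data has %d columns",
                 length(model$edges), ncol(x)), call. = FALSE)
  }
  codes <- vapply(seq_along(model$edges), function(j) {
    findInterval(x[, j], model$edges[[j]], left.open = FALSE)
  }, integer(nrow(x)) + 0L)
  codes <- matrix(as.integer(codes), nrow = nrow(x))
  colnames(codes) <- names(model$edges)
  tibble::as_tibble(codes)
}

#' Discretize a labeled feature table into a decision table
#'
#' Convenience wrapper: fits bins on the feature columns of `data` (or uses
#' a pre-fitted model, e.g. one learned on training rows) and returns the
#' coded `decision_table`.
#'
#' @inheritParams decision_table
#' @inheritParams fit_bins
#' @param model Optional pre-fitted `bin_model`; when given, `strategy` and
#'   `n_bins` are ignored.
#' @return A `decision_table`.
#' @export
discretize_table <- function(data, label = "label",
                             strategy = c("quantile", "width"),
                             n_bins = 3L, model = NULL) {
  feats <- data[setdiff(names(data), label)]
  if (is.null(model)) model <- fit_bins(feats, strategy = strategy, n_bins = n_bins)
  coded <- bin_apply(model, feats)
  coded[[label]] <- data[[label]]
  decision_table(as.data.frame(coded), label = label)
}
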