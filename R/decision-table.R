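#' Build a decision table from a data frame
#'
#' A decision table (decision system) is the basic object of rough-set
#' analysis: a universe of objects described by discrete-valued conditional
#' attributes plus one decision (class) attribute. Attribute codes are
#' opaque integers -- indiscernibility only ever compares them for equality,
#' so no ordering or scale is assumed. Continuous features must be
#' discretized first (see [fit_bins()]).
#'
#' @param data A data frame with one row per object: integer-valued feature
#'   columns and one label column.
#' @param label Name of the decision column. Default `"label"`.
#' @return An object of class `decision_table` with components
#'   `values` (integer matrix, objects x attributes), `decision`
#'   (integer vector), `attribute_names`, and `object_ids`.
#' @examples
#' tab <- decision_table(data.frame(a = c(0, 1), b = c(1, 1), label = c(0, 1)))
#' dependency_degree(tab, c("a", "b"))
#' @export
decision_table <- function(data, label = "label") {
  stopifnot(is.data.frame(data))
  if (nrow(data) < 1L) stop("decision table needs at least one object", call. = FALSE)
  if (!label %in% names(data)) {
    stop(sprintf("label column '%s' not found; available: %s",
                 label, paste(names(data), collapse = ", ")), call. = FALSE)
  }
  feat <- data[setdiff(names(data), label)]
  vals <- as.matrix(feat)
  if (length(vals) && !is.numeric(vals)) {
    stop("all attribute columns must be numeric integer codes", call. = FALSE)
  }
  if (length(vals)) {
    if (anyNA(vals) || any(!is.finite(vals))) {
      stop("missing or non-finite attribute values are not allowed", call. = FALSE)
    }
    if (any(vals != round(vals))) {
      stop("non-integral attribute values; discretize continuous features first (see fit_bins())",
           call. = FALSE)
    }
  }
  dec <- data[[label]]
  if (anyNA(dec)) stop("missing decision values are not allowed", call. = FALSE)
  if (is.factor(dec) || is.character(dec)) dec <- as.integer(factor(dec))
  if (any(dec != round(dec))) stop("decision values must be integral", call. = FALSE)
  storage.mode(vals) <- "integer"
  structure(
    list(
      values = vals,
      decision = as.integer(dec),
      attribute_names = colnames(vals) %||% character(),
      object_ids = rownames(data) %||% as.character(seq_len(nrow(data)))
    ),
    class = "decision_table"
  )
}

#' @export
print.decision_table <- function(x, ...) {
  cat(sprintf("<decision_table> %d objects x %d attributes, %d decision class%s\n",
              n_objects(x), n_attributes(x),
              length(unique(x$decision)),
              if (length(unique(x$decision)) == 1L) "" else "es"))
  invisible(x)
}

#' @rdname decision_table
#' @param x A `decision_table`.
#' @export
n_objects <- function(x) length(x$decision)

#' @rdname decision_table
#' @export
n_attributes <- function(x) ncol(x$values)

#' Read / write decision tables as CSV
#'
#' The on-disk form is a plain CSV with a header, one column per attribute
#' and the decision in the column named by `label`. Cells must be integral;
#' non-integral cells are rejected with a pointer to the discretizer.
#'
#' @param path File path.
#' @param label Decision column name (default `"label"`).
#' @return `read_decision_table()` returns a `decision_table`;
#'   `write_decision_table()` returns `path` invisibly.
#' @export
read_decision_table <- function(path, label = "label") {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0L) stop("empty decision table file: ", path, call. = FALSE)
  decision_table(as.data.frame(df), label = label)
}

#' @rdname read_decision_table
#' @param table A `decision_table`.
#' @export
write_decision_table <- function(table, path, label = "label") {
  df <- tibble::as_tibble(as.data.frame(table$values))
  df[[label]] <- table$decision
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Convert an attribute specification to a logical inclusion mask
#'
#' Attribute subsets (the binary trial solutions of the Tabu search) can be
#' given as a logical mask, integer indices, or attribute names; every
#' rough-set operation accepts any of the three.
#'
#' @param table A `decision_table`.
#' @param attrs Logical mask of length `n_attributes(table)`, integer
#'   indices, or character names. `NULL` and `integer(0)` mean the empty
#'   subset; `TRUE` means all attributes.
#' @return A logical vector of length `n_attributes(table)`.
#' @export
attr_mask <- function(table, attrs) {
  p <- n_attributes(table)
  if (is.null(attrs)) return(rep(FALSE, p))
  if (is.logical(attrs)) {
    if (length(attrs) == 1L) return(rep(attrs, p))
    if (length(attrs) != p) {
      stop(sprintf("mask length %d does not match %d attributes", length(attrs), p),
           call. = FALSE)
    }
    return(as.logical(attrs))
  }
  if (is.character(attrs)) {
    idx <- match(attrs, table$attribute_names)
    if (anyNA(idx)) {
      stop("unknown attribute name(s): ", paste(attrs[is.na(idx)], collapse = ", "),
           call. = FALSE)
    }
  } else {
    idx <- as.integer(attrs)
    if (length(idx) && (min(idx) < 1L || max(idx) > p)) {
      stop("attribute index out of range", call. = FALSE)
    }
  }
  mask <- rep(FALSE, p)
  mask[idx] <- TRUE
  mask
}

`%||%` <- function(a, b) if (is.null(a)) b else a
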