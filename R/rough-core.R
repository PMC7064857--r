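# Exact rough-set calculus: indiscernibility partitions, Pawlak
# approximations, positive region, dependency degree, and a brute-force
# minimal-reduct oracle. Partitions are computed by grouping value tuples
# restricted to the subset; only set equality of blocks is contracted,
# never block order.

# Integer block id per object under the subset-restricted indiscernibility
# relation. The empty subset puts every object in one block.
block_ids <- function(table, mask) {
  n <- n_objects(table)
  if (!any(mask)) return(rep(1L, n))
  cols <- lapply(which(mask), function(j) table$values[, j])
  keys <- do.call(paste, c(cols, sep = "\r"))
  match(keys, unique(keys))
}

check_target <- function(table, target) {
  target <- as.integer(target)
  n <- n_objects(table)
  if (length(target) && (min(target) < 1L || max(target) > n)) {
    stop("target object index out of range", call. = FALSE)
  }
  target
}

#' Equivalence classes of the indiscernibility relation
#'
#' Two objects fall in the same block iff they agree on every attribute of
#' `attrs`. The empty subset yields the single block containing all of U.
#'
#' @inheritParams attr_mask
#' @return A list of disjoint integer vectors (object indices) covering all
#'   objects; block order is not meaningful.
#' @examples
#' tab <- t1_table()
#' equivalence_classes(tab, "b")
#' @export
equivalence_classes <- function(table, attrs) {
  ids <- block_ids(table, attr_mask(table, attrs))
  unname(split(seq_along(ids), ids))
}

#' Lower and upper approximations of a target set
#'
#' The lower approximation is the union of indiscernibility blocks wholly
#' contained in `target` (the objects certainly in the concept under
#' `attrs`); the upper approximation is the union of blocks intersecting
#' `target` (the objects possibly in it). `lower ⊆ target ⊆ upper` always.
#'
#' @inheritParams attr_mask
#' @param target Integer vector of object indices (a subset of U).
#' @return Sorted integer vector of object indices.
#' @export
lower_approximation <- function(table, attrs, target) {
  target <- check_target(table, target)
  ids <- block_ids(table, attr_mask(table, attrs))
  inside <- seq_along(ids) %in% target
  keep <- !(ids %in% ids[!inside])  # block touches no outside object
  sort(which(keep))
}

#' @rdname lower_approximation
#' @export
upper_approximation <- function(table, attrs, target) {
  target <- check_target(table, target)
  ids <- block_ids(table, attr_mask(table, attrs))
  sort(which(ids %in% ids[target]))
}

#' Positive region of the decision
#'
#' Objects whose indiscernibility block under `attrs` is pure with respect
#' to the decision: the union over decision classes X of the lower
#' approximation of X. These are the objects whose class is certainly
#' determined by the attributes in `attrs`.
#'
#' @inheritParams attr_mask
#' @return Sorted integer vector of object indices.
#' @export
positive_region <- function(table, attrs) {
  ids <- block_ids(table, attr_mask(table, attrs))
  pure <- vapply(split(table$decision, ids),
                 function(d) all(d == d[1L]), logical(1))
  as.integer(sort(which(unname(pure[as.character(ids)]))))
}

#' Dependency degree of the decision on an attribute subset
#'
#' gamma_P(D) = |POS_P(D)| / |U|: the fraction of objects whose decision
#' class is determined by the attributes in `attrs`. Monotone
#' nondecreasing in the subset; equals 1 on the full attribute set iff no
#' two objects share a condition row but differ in decision.
#'
#' @inheritParams attr_mask
#' @return A number in \[0, 1\].
#' @examples
#' dependency_degree(t1_table(), "b")        # 0.5
#' dependency_degree(t1_table(), c("b", "c")) # 1
#' @export
dependency_degree <- function(table, attrs) {
  length(positive_region(table, attrs)) / n_objects(table)
}

#' Test whether a subset is a relative reduct
#'
#' TRUE iff `attrs` preserves the dependency degree of the full attribute
#' set and no single attribute can be dropped without losing dependency
#' (inclusion-minimality one deletion deep, which by monotonicity is full
#' minimality for dependency-preserving subsets).
#'
#' @inheritParams attr_mask
#' @return Logical scalar.
#' @export
is_relative_reduct <- function(table, attrs) {
  mask <- attr_mask(table, attrs)
  g_full <- dependency_degree(table, rep(TRUE, n_attributes(table)))
  g <- dependency_degree(table, mask)
  if (abs(g - g_full) > 1e-12) return(FALSE)
  for (j in which(mask)) {
    m2 <- mask
    m2[j] <- FALSE
    if (dependency_degree(table, m2) >= g - 1e-12) return(FALSE)
  }
  TRUE
}

#' All minimal reducts by exhaustive enumeration
#'
#' Enumerates every attribute subset (guarded to small tables) and returns
#' the inclusion-minimal ones whose dependency degree equals that of the
#' full set, sorted by size then lexicographically. Intended as a testing
#' oracle for the Tabu search, not for production-size tables.
#'
#' @param table A `decision_table`.
#' @param max_attributes Refuse tables wider than this (default 15; the
#'   enumeration is 2^p).
#' @return A list of sorted integer index vectors.
#' @export
brute_force_min_reducts <- function(table, max_attributes = 15L) {
  p <- n_attributes(table)
  if (p > max_attributes) {
    stop(sprintf(
      "table has %d attributes; exhaustive reduct enumeration is limited to %d (2^p subsets)",
      p, max_attributes), call. = FALSE)
  }
  g_full <- dependency_degree(table, rep(TRUE, p))
  found <- list()
  for (k in 0:p) {
    combos <- utils::combn(p, k, simplify = FALSE)
    for (s in combos) {
      if (any(vapply(found, function(f) all(f %in% s), logical(1)))) next
      mask <- rep(FALSE, p)
      mask[s] <- TRUE
      if (dependency_degree(table, mask) >= g_full - 1e-12) {
        found[[length(found) + 1L]] <- as.integer(s)
      }
    }
  }
  ord <- order(lengths(found),
               vapply(found, function(s) paste(sprintf("%06d", s), collapse = ""),
                      character(1)))
  found[ord]
}

#' The six-object reference decision table
#'
#' A small fixture over attributes a, b, c whose unique minimal reduct is
#' \{b, c\} (full dependency degree 1); handy for examples and tests.
#'
#' @return A `decision_table` with 6 objects and 3 attributes.
#' @export
t1_table <- function() {
  decision_table(data.frame(
    a = c(0L, 0L, 0L, 1L, 1L, 1L),
    b = c(0L, 0L, 1L, 1L, 0L, 1L),
    c = c(0L, 1L, 0L, 0L, 1L, 1L),
    label = c(0L, 0L, 1L, 1L, 0L, 0L)
  ))
}
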