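# Independent reference implementations used as oracles. These follow the
# textbook definitions literally (object-by-object scans, pairwise loops)
# and deliberately share no code with the package internals.

# Objects indiscernible from i under the attribute index set `attrs`.
oracle_class_of <- function(tab, attrs, i) {
  n <- length(tab$decision)
  out <- integer()
  for (j in seq_len(n)) {
    same <- TRUE
    for (a in attrs) if (tab$values[i, a] != tab$values[j, a]) { same <- FALSE; break }
    if (same) out <- c(out, j)
  }
  out
}

oracle_lower <- function(tab, attrs, target) {
  n <- length(tab$decision)
  out <- integer()
  for (i in seq_len(n)) {
    if (all(oracle_class_of(tab, attrs, i) %in% target)) out <- c(out, i)
  }
  out
}

oracle_upper <- function(tab, attrs, target) {
  n <- length(tab$decision)
  out <- integer()
  for (i in seq_len(n)) {
    if (any(oracle_class_of(tab, attrs, i) %in% target)) out <- c(out, i)
  }
  out
}

# Positive region via the definition: union over decision classes of the
# lower approximation of each class.
oracle_positive_region <- function(tab, attrs) {
  out <- integer()
  for (v in unique(tab$decision)) {
    out <- union(out, oracle_lower(tab, attrs, which(tab$decision == v)))
  }
  sort(out)
}

oracle_gamma <- function(tab, attrs) {
  length(oracle_positive_region(tab, attrs)) / length(tab$decision)
}

# Exhaustive pairwise AUC: concordant pairs count 1, ties 1/2.
oracle_auc <- function(truth, score, positive = 1) {
  pos <- which(truth == positive)
  neg <- which(truth != positive)
  s <- 0
  for (i in pos) for (j in neg) {
    s <- s + if (score[i] > score[j]) 1 else if (score[i] == score[j]) 0.5 else 0
  }
  100 * s / (length(pos) * length(neg))
}

# Small random decision table (uniform codes, random binary decision).
random_table <- function(n_objects, n_attributes, n_values = 2L) {
  df <- as.data.frame(matrix(
    sample.int(n_values, n_objects * n_attributes, replace = TRUE) - 1L,
    nrow = n_objects
  ))
  names(df) <- paste0("x", seq_len(n_attributes))
  df$label <- sample(0:1, n_objects, replace = TRUE)
  decision_table(df)
}

random_mask <- function(p) {
  m <- runif(p) < 0.5
  if (!any(m)) m[sample.int(p, 1)] <- TRUE
  m
}
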