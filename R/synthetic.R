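# Seeded generators: (a) discrete decision tables with a planted minimal
# reduct plus redundant recodings and noise attributes, (b) continuous
# two-class feature data with informative / redundant / noise columns.
# Both are fully reproducible from their seed and return metadata rich
# enough to score any feature selection against the ground truth.

#' Simulate a decision table with a planted reduct
#'
#' Draws `reduct_size` planted attributes i.i.d. uniform over
#' `0 .. n_values - 1` and defines the decision as the parity of their code
#' sum, so the decision is a deterministic function of the planted set and
#' (before inconsistency flips) the planted attributes achieve full
#' dependency degree. Redundant attributes are injective recodings
#' (seeded code permutations) of randomly chosen planted columns -- they
#' induce the same indiscernibility partition, so alternative minimal
#' reducts may exist by substitution. Noise attributes are i.i.d. uniform
#' codes independent of the decision. `inconsistency_rate` flips the
#' decision of that fraction of objects, pushing the full-set dependency
#' degree below 1 whenever a flipped object shares its condition row with
#' an unflipped one.
#'
#' @param n_objects Number of objects (rows).
#' @param reduct_size Number of planted attributes, >= 1.
#' @param n_redundant Number of injective recodings of planted attributes.
#' @param n_noise Number of attributes independent of the decision.
#' @param n_values Number of distinct codes per attribute (default 3).
#' @param inconsistency_rate Fraction in \[0, 1) of objects whose decision
#'   is flipped after generation.
#' @param seed RNG seed; the same seed reproduces the table exactly.
#' @return A list with `table` (a `decision_table`) and `metadata`, a
#'   tibble with one row per attribute: `attribute`, `role`
#'   (planted/redundant/noise), and `source` (index of the planted
#'   attribute a redundant column recodes, NA otherwise).
#' @examples
#' sim <- simulate_decision_table(40, reduct_size = 2, n_noise = 3, seed = 1)
#' dependency_degree(sim$table, sim$metadata$attribute[sim$metadata$role == "planted"])
#' @export
simulate_decision_table <- function(n_objects, reduct_size,
                                    n_redundant = 0L, n_noise = 0L,
                                    n_values = 3L, inconsistency_rate = 0,
                                    seed = 1L) {
  stopifnot(n_objects >= 1, reduct_size >= 1, n_redundant >= 0, n_noise >= 0,
            n_values >= 2)
  if (inconsistency_rate < 0 || inconsistency_rate >= 1) {
    stop("inconsistency_rate must lie in [0, 1)", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    planted <- matrix(sample.int(n_values, n_objects * reduct_size, replace = TRUE) - 1L,
                      nrow = n_objects)
    decision <- as.integer(rowSums(planted) %% 2L)
    redundant <- NULL
    source <- rep(NA_integer_, reduct_size)
    if (n_redundant > 0L) {
      src <- sample.int(reduct_size, n_redundant, replace = TRUE)
      redundant <- vapply(src, function(j) {
        perm <- sample.int(n_values) - 1L  # injective recoding of the codes
        perm[planted[, j] + 1L]
      }, integer(n_objects))
      redundant <- matrix(as.integer(redundant), nrow = n_objects)
      source <- c(source, src)
    }
    noise <- NULL
    if (n_noise > 0L) {
      noise <- matrix(sample.int(n_values, n_objects * n_noise, replace = TRUE) - 1L,
                      nrow = n_objects)
      source <- c(source, rep(NA_integer_, n_noise))
    }
    if (inconsistency_rate > 0) {
      n_flip <- round(inconsistency_rate * n_objects)
      if (n_flip > 0L) {
        flip <- sample.int(n_objects, n_flip)
        decision[flip] <- 1L - decision[flip]
      }
    }
    vals <- cbind(planted, redundant, noise)
    roles <- c(rep("planted", reduct_size),
               rep("redundant", n_redundant),
               rep("noise", n_noise))
    colnames(vals) <- sprintf("%s%d", c(planted = "p", redundant = "r",
                                        noise = "z")[roles],
                              unlist(lapply(table(factor(roles, levels = unique(roles))),
                                            seq_len)))
    df <- as.data.frame(vals)
    df$label <- decision
    list(
      table = decision_table(df),
      metadata = tibble::tibble(
        attribute = colnames(vals),
        index = seq_along(roles),
        role = roles,
        source = source
      )
    )
  })
}

#' Simulate continuous two-class classification data
#'
#' Emulates a morphometry-style feature table: a few informative
#' dimensions among redundant and noisy ones. Informative features are
#' class-conditional normals N(0, 1) vs N(`effect_size`, 1) (a
#' standardized mean shift); redundant features are random linear
#' combinations of the informative ones plus N(0, 0.3) noise; noise
#' features are N(0, 1) regardless of class.
#'
#' @param n_samples Number of rows, >= 4.
#' @param n_informative,n_redundant,n_noise Feature counts per role.
#' @param class_balance Proportion of positive (label 1) samples.
#' @param effect_size Standardized between-class mean shift of the
#'   informative features, >= 0.
#' @param seed RNG seed.
#' @return A list with `data` (tibble of features plus a 0/1 `label`
#'   column) and `metadata` (tibble: `feature`, `role`).
#' @examples
#' sim <- simulate_classification(100, n_informative = 2, n_noise = 5,
#'                                effect_size = 3, seed = 7)
#' table(sim$data$label)
#' @export
simulate_classification <- function(n_samples, n_informative = 3L,
                                    n_redundant = 0L, n_noise = 0L,
                                    class_balance = 0.5, effect_size = 1,
                                    seed = 1L) {
  stopifnot(n_samples >= 4, n_informative >= 1, n_redundant >= 0, n_noise >= 0,
            effect_size >= 0, class_balance > 0, class_balance < 1)
  withr::with_seed(as.integer(seed), {
    n_pos <- max(2L, min(n_samples - 2L, round(class_balance * n_samples)))
    label <- sample(c(rep(1L, n_pos), rep(0L, n_samples - n_pos)))
    info <- matrix(stats::rnorm(n_samples * n_informative), nrow = n_samples)
    info <- info + effect_size * label  # recycled down columns: shift per class
    red <- NULL
    if (n_redundant > 0L) {
      w <- matrix(stats::rnorm(n_informative * n_redundant), nrow = n_informative)
      red <- info %*% w + 0.3 * matrix(stats::rnorm(n_samples * n_redundant),
                                       nrow = n_samples)
    }
    noise <- NULL
    if (n_noise > 0L) {
      noise <- matrix(stats::rnorm(n_samples * n_noise), nrow = n_samples)
    }
    x <- cbind(info, red, noise)
    roles <- c(rep("informative", n_informative),
               rep("redundant", n_redundant),
               rep("noise", n_noise))
    colnames(x) <- sprintf("%s%d", c(informative = "inf", redundant = "red",
                                     noise = "nse")[roles],
                           unlist(lapply(table(factor(roles, levels = unique(roles))),
                                         seq_len)))
    data <- tibble::as_tibble(x)
    data$label <- label
    list(
      data = data,
      metadata = tibble::tibble(feature = colnames(x), role = roles)
    )
  })
}
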