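# Tabu-search attribute reduction. The search walks over binary inclusion
# masks: at each iteration it mutates the current mask at 1..k_max random
# positions to build m trial solutions, discards any that sit on the Tabu
# list (no aspiration -- recently visited masks are avoided outright),
# moves to the best trial even when it does not improve, and remembers the
# incumbent best. After prolonged stagnation the current mask is replaced
# by a diversified one biased toward rarely used attributes. At
# termination the incumbent is shaken (greedy one-by-one deletions that
# never lower the dependency degree) several times under random visit
# orders, and the elite reduct is the intersection of the shaken sets.

#' Tabu search configuration
#'
#' @param n_neighbors Trial solutions generated per iteration (m).
#' @param tabu_tenure Number of recently visited masks remembered (FIFO).
#' @param max_iterations Search iterations.
#' @param max_flip Maximum positions mutated per trial solution (k is drawn
#'   uniformly from `1..max_flip`); clamped to the attribute count.
#' @param stagnation_limit Iterations without incumbent improvement before
#'   diversification replaces the current solution.
#' @param shake_rounds Independent shakes of the incumbent feeding the
#'   elite-reduct intersection.
#' @param seed RNG seed; recorded in every result.
#' @param cardinality_tiebreak At equal dependency degree, prefer the
#'   smaller subset (the search explicitly targets minimal reducts).
#' @return A `tabu_config` list.
#' @export
tabu_config <- function(n_neighbors = 10L, tabu_tenure = 20L,
                        max_iterations = 200L, max_flip = 3L,
                        stagnation_limit = 15L, shake_rounds = 5L,
                        seed = 1L, cardinality_tiebreak = TRUE) {
  cfg <- list(
    n_neighbors = as.integer(n_neighbors),
    tabu_tenure = as.integer(tabu_tenure),
    max_iterations = as.integer(max_iterations),
    max_flip = as.integer(max_flip),
    stagnation_limit = as.integer(stagnation_limit),
    shake_rounds = as.integer(shake_rounds),
    seed = as.integer(seed),
    cardinality_tiebreak = isTRUE(cardinality_tiebreak)
  )
  counts <- c("n_neighbors", "tabu_tenure", "max_iterations", "max_flip",
              "stagnation_limit", "shake_rounds")
  bad <- counts[vapply(cfg[counts], function(v) is.na(v) || v < 1L, logical(1))]
  if (length(bad)) stop("config values must be >= 1: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  structure(cfg, class = "tabu_config")
}

mask_key <- function(mask) paste(as.integer(mask), collapse = "")

# Lexicographic fitness: maximize gamma, then (optionally) minimize size.
objective_key <- function(gamma, size, tiebreak) {
  c(gamma, if (tiebreak) -size else 0)
}

objective_better <- function(a, b, tol = 1e-12) {
  if (a[1] > b[1] + tol) return(TRUE)
  if (a[1] < b[1] - tol) return(FALSE)
  a[2] > b[2] + tol
}

#' Compare two attribute subsets under the search objective
#'
#' The primary key is the dependency degree (higher wins); with the
#' cardinality tie-break enabled, the smaller subset wins at equal
#' dependency. Returns +1 if `attrs_a` is strictly better, -1 if strictly
#' worse, 0 if the two compare equal.
#'
#' @inheritParams attr_mask
#' @param attrs_a,attrs_b Attribute subsets in any form [attr_mask()]
#'   accepts.
#' @param config A [tabu_config()].
#' @return -1, 0 or +1.
#' @export
objective_compare <- function(table, attrs_a, attrs_b, config = tabu_config()) {
  ma <- attr_mask(table, attrs_a)
  mb <- attr_mask(table, attrs_b)
  ka <- objective_key(dependency_degree(table, ma), sum(ma), config$cardinality_tiebreak)
  kb <- objective_key(dependency_degree(table, mb), sum(mb), config$cardinality_tiebreak)
  if (objective_better(ka, kb)) 1L else if (objective_better(kb, ka)) -1L else 0L
}

# Draw up to m trial solutions by multipoint mutation of `current`,
# skipping masks on the tabu list and the all-zero mask (unless the
# decision is constant). Retries are bounded, so fewer than m may return.
generate_neighbors <- function(current, tabu_keys, config, n_attributes,
                               allow_empty = FALSE, max_retries = 25L) {
  out <- list()
  k_cap <- min(config$max_flip, n_attributes)
  for (i in seq_len(config$n_neighbors)) {
    for (try in seq_len(max_retries)) {
      k <- sample.int(k_cap, 1L)
      pos <- sample.int(n_attributes, k)
      cand <- current
      cand[pos] <- !cand[pos]
      if (!allow_empty && !any(cand)) next
      if (mask_key(cand) %in% tabu_keys) next
      out[[length(out) + 1L]] <- cand
      break
    }
  }
  out
}

# Frequency-based diversification: include attribute j with probability
# proportional to 1 / (1 + appearance_count[j]), scaled so the expected
# subset size is n/2 (clamped per attribute). Replaces the current
# solution only, never the incumbent.
diversify_mask <- function(appearance_counts, allow_empty = FALSE) {
  n <- length(appearance_counts)
  w <- 1 / (1 + appearance_counts)
  p <- pmin(1, w * (n / 2) / sum(w))
  mask <- stats::runif(n) < p
  if (!allow_empty && !any(mask)) {
    mask[which.max(w)] <- TRUE  # deterministic fallback: rarest attribute
  }
  mask
}

#' Shake an attribute subset
#'
#' Visits the included attributes one by one (ascending index by default)
#' and removes each whose removal keeps the dependency degree unchanged --
#' by monotonicity a removal can never increase it. The result is a subset
#' of `attrs` with the same dependency degree; when nothing is removable
#' the input comes back unchanged, and on a constant-decision table
#' everything is removable.
#'
#' @inheritParams attr_mask
#' @param order Optional integer permutation of the included attribute
#'   indices giving the visit order.
#' @return A logical mask.
#' @export
shake <- function(table, attrs, order = NULL) {
  mask <- attr_mask(table, attrs)
  g <- dependency_degree(table, mask)
  visit <- order %||% sort(which(mask))
  for (j in visit) {
    if (!mask[j]) next
    cand <- mask
    cand[j] <- FALSE
    if (dependency_degree(table, cand) >= g - 1e-12) mask <- cand
  }
  mask
}

#' Elite reduct of a list of shaken solutions
#'
#' The candidate is the set intersection of all shaken attribute sets; it
#' is returned when it preserves the full-set dependency degree, otherwise
#' the best shaken solution under the search objective is returned (the
#' intersection of distinct minimal reducts can lose dependency, in which
#' case the documented fallback applies).
#'
#' @inheritParams attr_mask
#' @param shaken Nonempty list of attribute subsets (any form
#'   [attr_mask()] accepts).
#' @param config A [tabu_config()].
#' @return Sorted integer vector of attribute indices.
#' @export
elite_reduct <- function(table, shaken, config = tabu_config()) {
  if (!length(shaken)) stop("elite_reduct() needs at least one shaken solution",
                            call. = FALSE)
  masks <- lapply(shaken, attr_mask, table = table)
  inter <- Reduce(`&`, masks)
  g_full <- dependency_degree(table, rep(TRUE, n_attributes(table)))
  if (dependency_degree(table, inter) >= g_full - 1e-12) return(sort(which(inter)))
  keys <- lapply(masks, function(m)
    objective_key(dependency_degree(table, m), sum(m), config$cardinality_tiebreak))
  best <- 1L
  for (i in seq_along(keys)[-1L]) if (objective_better(keys[[i]], keys[[best]])) best <- i
  sort(which(masks[[best]]))
}

#' Tabu-search attribute reduction
#'
#' Runs the full four-stage search (neighborhood mutation with a Tabu
#' list, stagnation-triggered diversification, terminal shaking of the
#' incumbent, elite-reduct intersection) and returns the selected
#' attribute subset with its dependency degree. The run is entirely
#' determined by `config$seed`: identical input and config reproduce the
#' result bit for bit.
#'
#' @param table A `decision_table`.
#' @param config A [tabu_config()].
#' @return A `tabu_reduct` object: `selected` (integer indices),
#'   `selected_names`, `gamma`, `gamma_full`, `elite`, `shaken`
#'   (list of shaken incumbent copies), `trace` (tibble: iteration,
#'   best gamma, best size, move accepted), and `config`.
#' @examples
#' res <- tabu_reduce(t1_table(), tabu_config(max_iterations = 60, seed = 4))
#' res$selected_names  # "b" "c"
#' @export
tabu_reduce <- function(table, config = tabu_config()) {
  stopifnot(inherits(table, "decision_table"), inherits(config, "tabu_config"))
  p <- n_attributes(table)
  g_full <- dependency_degree(table, rep(TRUE, p))
  constant_decision <- length(unique(table$decision)) == 1L
  if (p == 0L) {
    return(new_tabu_reduct(integer(), table, g_full, g_full, integer(), list(),
                           empty_trace(), config))
  }
  withr::with_seed(config$seed, {
    gamma_of <- local({
      cache <- new.env(hash = TRUE, parent = emptyenv())
      function(mask) {
        key <- mask_key(mask)
        got <- cache[[key]]
        if (!is.null(got)) return(got)
        g <- dependency_degree(table, mask)
        cache[[key]] <- g
        g
      }
    })
    key_of <- function(mask) objective_key(gamma_of(mask), sum(mask),
                                           config$cardinality_tiebreak)

    current <- stats::runif(p) < 0.5
    if (!any(current) && !constant_decision) current[sample.int(p, 1L)] <- TRUE
    best <- current
    best_key <- key_of(best)
    tabu <- list(current)
    appearance <- as.numeric(current)
    stagnation <- 0L
    trace <- vector("list", config$max_iterations)

    for (iter in seq_len(config$max_iterations)) {
      tabu_keys <- vapply(tabu, mask_key, character(1))
      nbrs <- generate_neighbors(current, tabu_keys, config, p,
                                 allow_empty = constant_decision)
      accepted <- FALSE
      if (length(nbrs)) {
        for (nb in nbrs) appearance <- appearance + nb
        keys <- lapply(nbrs, key_of)
        pick <- 1L
        for (i in seq_along(keys)[-1L]) {
          if (objective_better(keys[[i]], keys[[pick]])) pick <- i
        }
        current <- nbrs[[pick]]          # accepted even when not improving
        tabu <- c(tabu, list(current))
        if (length(tabu) > config$tabu_tenure) {
          tabu <- tabu[(length(tabu) - config$tabu_tenure + 1L):length(tabu)]
        }
        accepted <- TRUE
        if (objective_better(keys[[pick]], best_key)) {
          best <- current
          best_key <- keys[[pick]]
          stagnation <- 0L
        } else {
          stagnation <- stagnation + 1L
        }
      } else {
        stagnation <- stagnation + 1L
      }
      trace[[iter]] <- list(iteration = iter, best_gamma = best_key[1],
                            best_size = sum(best), accepted = accepted)
      if (stagnation >= config$stagnation_limit) {
        current <- diversify_mask(appearance, allow_empty = constant_decision)
        stagnation <- 0L                 # Tabu list retained across restarts
      }
    }

    shaken <- lapply(seq_len(config$shake_rounds), function(r) {
      idx <- which(best)
      ord <- if (length(idx) > 1L) sample(idx) else idx
      shake(table, best, order = ord)
    })
    elite <- if (length(shaken)) elite_reduct(table, shaken, config) else sort(which(best))
    trace <- dplyr::bind_rows(lapply(trace, tibble::as_tibble))
    new_tabu_reduct(elite, table, gamma_of(attr_mask(table, elite)), g_full,
                    elite, shaken, trace, config)
  })
}

empty_trace <- function() {
  tibble::tibble(iteration = integer(), best_gamma = numeric(),
                 best_size = integer(), accepted = logical())
}

new_tabu_reduct <- function(selected, table, gamma, gamma_full, elite, shaken,
                            trace, config) {
  nm <- table$attribute_names
  structure(
    list(
      selected = as.integer(selected),
      selected_names = if (length(nm)) nm[selected] else character(),
      gamma = gamma,
      gamma_full = gamma_full,
      elite = as.integer(elite),
      shaken = lapply(shaken, function(m) sort(which(attr_mask(table, m)))),
      trace = trace,
      config = config,
      n_attributes = n_attributes(table)
    ),
    class = "tabu_reduct"
  )
}

#' @export
print.tabu_reduct <- function(x, ...) {
  cat(sprintf("<tabu_reduct> %d / %d attributes, gamma = %.4f (full set %.4f), seed %d\n",
              length(x$selected), x$n_attributes, x$gamma, x$gamma_full,
              x$config$seed))
  if (length(x$selected_names)) {
    cat("selected:", paste(x$selected_names, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy a Tabu reduction result
#'
#' @param x A `tabu_reduct`.
#' @param ... Unused.
#' @return One row per selected attribute: `attribute`, `index`.
#' @export
tidy.tabu_reduct <- function(x, ...) {
  tibble::tibble(
    attribute = if (length(x$selected_names)) x$selected_names
                else as.character(x$selected),
    index = x$selected
  )
}

#' Glance at a Tabu reduction result
#'
#' @inheritParams tidy.tabu_reduct
#' @return A one-row tibble: selected count, attribute count, gamma of the
#'   selection and of the full set, iterations, seed.
#' @export
glance.tabu_reduct <- function(x, ...) {
  tibble::tibble(
    n_selected = length(x$selected),
    n_attributes = x$n_attributes,
    gamma = x$gamma,
    gamma_full = x$gamma_full,
    iterations = nrow(x$trace),
    seed = x$config$seed
  )
}

#' Plot the search trace of a Tabu reduction
#'
#' Incumbent dependency degree and subset size against iteration.
#'
#' @param object A `tabu_reduct`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tabu_reduct <- function(object, ...) {
  df <- tidyr::pivot_longer(object$trace,
                            c("best_gamma", "best_size"),
                            names_to = "quantity", values_to = "value")
  df$quantity <- c(best_gamma = "dependency degree (incumbent)",
                   best_size = "subset size (incumbent)")[df$quantity]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~quantity, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = NULL,
                  title = "Tabu search trace") +
    ggplot2::theme_minimal()
}
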