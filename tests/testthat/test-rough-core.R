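t1 <- t1_table()

test_that("equivalence classes match hand grouping on the reference table", {
  blocks <- equivalence_classes(t1, "b")
  expect_setequal(lapply(blocks, sort), list(c(1L, 2L, 5L), c(3L, 4L, 6L)))
  expect_equal(equivalence_classes(t1, NULL), list(1:6))
  distinct <- decision_table(data.frame(a = 0:3, b = c(1, 1, 0, 0), label = c(0, 1, 0, 1)))
  expect_length(equivalence_classes(distinct, c("a", "b")), 4L)
  expect_error(attr_mask(t1, c(TRUE, FALSE)), "mask length")
})

test_that("lower and upper approximations follow the Pawlak definitions", {
  expect_equal(lower_approximation(t1, "b", c(3, 4, 6)), c(3L, 4L, 6L))
  expect_equal(upper_approximation(t1, "b", 3), c(3L, 4L, 6L))
  expect_equal(lower_approximation(t1, "b", 1:6), 1:6)
  expect_equal(lower_approximation(t1, "b", integer()), integer())
  expect_equal(upper_approximation(t1, "b", integer()), integer())
  # singleton blocks: upper approximation is the target itself
  distinct <- decision_table(data.frame(a = 0:3, label = c(0, 1, 0, 1)))
  expect_equal(upper_approximation(distinct, "a", c(2, 4)), c(2L, 4L))
  expect_error(lower_approximation(t1, "b", 7), "out of range")
})

test_that("positive region and dependency degree match the T1 enumeration", {
  expect_equal(positive_region(t1, "b"), c(1L, 2L, 5L))
  expect_equal(dependency_degree(t1, "b"), 0.5)
  expect_equal(dependency_degree(t1, "c"), 0.5)
  expect_equal(dependency_degree(t1, c("b", "c")), 1)
  expect_equal(dependency_degree(t1, c("a", "b")), 2 / 3)
  expect_equal(dependency_degree(t1, NULL), 0)
  # constant decision: every block is pure
  const <- decision_table(data.frame(a = c(0, 1, 0), label = c(1, 1, 1)))
  expect_equal(positive_region(const, NULL), 1:3)
  expect_equal(dependency_degree(const, NULL), 1)
  # inconsistent pair drops out of the positive region under the full set
  incons <- decision_table(data.frame(a = c(0, 0, 1), label = c(0, 1, 1)))
  expect_equal(positive_region(incons, "a"), 3L)
})

test_that("relative-reduct test and brute-force oracle agree on T1", {
  expect_true(is_relative_reduct(t1, c("b", "c")))
  expect_false(is_relative_reduct(t1, c("a", "b", "c")))
  expect_false(is_relative_reduct(t1, "a"))
  expect_equal(brute_force_min_reducts(t1), list(c(2L, 3L)))
})

test_that("brute force enumerates all minimal reducts and guards width", {
  const <- decision_table(data.frame(a = c(0, 1), b = c(1, 0), label = c(1, 1)))
  expect_equal(brute_force_min_reducts(const), list(integer()))
  # two attributes, each separating the classes alone: both singletons minimal
  twin <- decision_table(data.frame(a = c(0, 1), b = c(1, 0), label = c(0, 1)))
  expect_equal(brute_force_min_reducts(twin), list(1L, 2L))
  expect_error(brute_force_min_reducts(
    decision_table({
      d <- as.data.frame(matrix(sample(0:1, 2 * 16, TRUE), 2))
      d$label <- c(0, 1); d
    })
  ), "limited to 15")
})

test_that("approximations sandwich the target and match oracles on random tables", {
  set.seed(101)
  for (rep in 1:60) {
    tab <- random_table(sample(2:8, 1), sample(1:5, 1), sample(2:3, 1))
    p <- n_attributes(tab)
    attrs <- sort(which(random_mask(p)))
    target <- which(runif(n_objects(tab)) < 0.5)
    lo <- lower_approximation(tab, attrs, target)
    hi <- upper_approximation(tab, attrs, target)
    expect_true(all(lo %in% target))
    expect_true(all(target %in% hi))
    expect_equal(lo, sort(oracle_lower(tab, attrs, target)))
    expect_equal(hi, sort(oracle_upper(tab, attrs, target)))
    expect_equal(positive_region(tab, attrs), oracle_positive_region(tab, attrs))
  }
})

test_that("full-set dependency is 1 exactly when condition rows determine decisions", {
  set.seed(77)
  for (rep in 1:40) {
    tab <- random_table(sample(2:8, 1), sample(1:4, 1))
    g <- dependency_degree(tab, rep(TRUE, n_attributes(tab)))
    keys <- apply(tab$values, 1, paste, collapse = ",")
    consistent <- !any(vapply(split(tab$decision, keys),
                              function(d) length(unique(d)) > 1, logical(1)))
    expect_equal(g == 1, consistent)
  }
})

test_that("decision table construction rejects bad input", {
  expect_error(decision_table(data.frame(a = 1:2, label = c(NA, 1))), "missing")
  expect_error(decision_table(data.frame(a = c(0.5, 1), label = 0:1)), "discretize")
  expect_error(decision_table(data.frame(a = 1:2, b = 3:4), label = "y"), "not found")
})

test_that("decision tables round-trip through CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_decision_table(t1, path)
  back <- read_decision_table(path)
  expect_equal(back$values, t1$values)
  expect_equal(back$decision, t1$decision)
})
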