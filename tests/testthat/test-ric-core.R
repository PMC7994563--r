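# The relational kernel: abstraction, containment, reduction, entropy.

test_that("abstraction is cell-wise disjunction with the expected algebra", {
  # hand-enumerated 2x2 case: marks are (arg, level) pairs, levels 0-based
  r_f <- relation(2, 2, marks = rbind(c(1, 0)))
  r_a <- relation(2, 2, marks = rbind(c(1, 1), c(2, 0)))
  q <- abstraction(r_f, r_a)
  expect_identical(q$cells, matrix(c(TRUE, TRUE, TRUE, FALSE), nrow = 2))

  set.seed(42)
  empty <- relation(4, 5)
  for (rep in 1:25) {
    a <- random_relation(4, 5)
    b <- random_relation(4, 5)
    c <- random_relation(4, 5)
    expect_identical(abstraction(a, empty)$cells, a$cells)   # identity element
    expect_identical(abstraction(a, a)$cells, a$cells)       # idempotent
    expect_identical(abstraction(a, b)$cells, abstraction(b, a)$cells)
    expect_identical(abstraction(abstraction(a, b), c)$cells,
                     abstraction(a, abstraction(b, c))$cells)
  }
  expect_error(abstraction(relation(2, 2), relation(3, 2)), "geometry")
})

test_that("containment counts failing argument columns and honors relax", {
  # 3-column instance failing in exactly one column
  r_f <- relation(3, 4, marks = rbind(c(1, 0), c(2, 1), c(3, 2)))
  cue <- discrete_fn(c(0, 3, 2), 4)   # column 2 holds an unregistered level
  expect_false(containment(cue, r_f, relax = 0)$accept)
  expect_identical(containment(cue, r_f, relax = 0)$failed_args, 1L)
  expect_true(containment(cue, r_f, relax = 1)$accept)

  # a fully marked relation accepts anything with no failures
  full <- eamem:::new_relation(matrix(TRUE, 4, 3))
  expect_identical(containment(cue, full)$failed_args, 0L)

  # unassigned cue arguments impose no constraint
  expect_true(containment(discrete_fn(rep(NA, 3), 4), relation(3, 4))$accept)

  set.seed(7)
  for (rep in 1:25) {
    f <- random_fn(5, 6)
    r <- random_relation(5, 6)
    u <- abstraction(r, f)
    expect_true(containment(f, u)$accept)        # union contains its parts
    # monotone: acceptance survives further abstraction
    x <- random_relation(5, 6)
    expect_true(containment(f, abstraction(u, x))$accept)
  }
})

test_that("reduction returns the cue under identity, rejects uncontained cues,
           and stays inside the relation's level sets", {
  r <- relation(3, 8, marks = rbind(c(1, 2), c(1, 3), c(2, 5), c(3, 0), c(3, 7)))
  f <- discrete_fn(c(3, 5, 0), 8)
  expect_identical(unclass(reduction(f, r))[1:3],
                   unclass(f)[1:3])              # identity on contained cue

  bad <- discrete_fn(c(4, 5, 0), 8)              # level 4 never marked in column 1
  expect_null(reduction(bad, r))                 # rejection value, not an error
  expect_s3_class(reduction(bad, r, relax = 1), "discrete_fn")

  # singleton column forces its level under either mode
  one <- relation(2, 8, marks = rbind(c(1, 5)))
  cue <- discrete_fn(c(NA, NA), 8)
  expect_identical(unclass(reduction(cue, one))[1], 5L)
  expect_identical(unclass(reduction(cue, one,
                                     reduction_policy("triangular", 3)))[1], 5L)

  # identity mode snaps an allowed-by-relax miss to the nearest marked level
  snapped <- reduction(bad, r, relax = 1)
  expect_identical(unclass(snapped)[1], 3L)

  set.seed(11)
  for (rep in 1:30) {
    rr <- random_relation(5, 8, p = 0.4)
    ff <- random_fn(5, 8)
    pol <- reduction_policy("triangular", seed = rep)
    out <- reduction(ff, rr, pol, relax = 5L)    # relax high: always defined
    lv <- unclass(out)
    for (i in 1:5) {
      s <- which(rr$cells[, i]) - 1L
      if (length(s) == 0L) expect_true(is.na(lv[i])) else expect_true(lv[i] %in% s)
    }
    # when defined, the output is contained at relax = 0
    expect_true(containment(out, rr)$accept)
  }
})

test_that("triangular reduction peaks at the cue and never leaves the support", {
  r <- relation(1, 8, marks = rbind(c(1, 2), c(1, 3), c(1, 4)))
  cue <- discrete_fn(3, 8)
  pol <- reduction_policy("triangular", seed = 99)
  draws <- vapply(1:2000, function(i) unclass(reduction(cue, r, pol))[1L],
                  integer(1))
  expect_true(all(draws %in% 2:4))
  counts <- table(draws)
  expect_identical(names(which.max(counts)), "3")
})

test_that("entropy is the mean log2 level count per column", {
  # any function, partial or total, has zero entropy
  expect_identical(ric_entropy(discrete_fn(c(1, NA, 0), 4)), 0)
  expect_identical(ric_entropy(function_to_relation(discrete_fn(c(2, 1), 4))), 0)

  r <- relation(2, 4, marks = rbind(c(1, 0), c(1, 1),
                                    c(2, 0), c(2, 1), c(2, 2), c(2, 3)))
  expect_equal(ric_entropy(r), 1.5)              # (log2 2 + log2 4) / 2

  expect_equal(ric_entropy(eamem:::new_relation(matrix(TRUE, 32, 64))), 5)

  set.seed(5)
  for (rep in 1:25) {
    a <- random_relation(6, 8)
    b <- random_relation(6, 8)
    ea <- ric_entropy(a)
    expect_gte(ea, 0)
    expect_lte(ea, log2(8))
    expect_gte(ric_entropy(abstraction(a, b)), ea)   # non-decreasing
  }

  # abstracting N full functions bounds entropy by log2(min(N, n_levels))
  set.seed(6)
  for (N in c(1, 3, 10)) {
    acc <- relation(6, 8)
    for (k in seq_len(N)) acc <- abstraction(acc, random_fn(6, 8, p_missing = 0))
    expect_lte(ric_entropy(acc), log2(min(N, 8)) + 1e-12)
  }
})

test_that("functions convert losslessly to single-mark relations and back", {
  expect_identical(sum(function_to_relation(discrete_fn(rep(NA, 3), 4))$cells), 0L)
  r <- function_to_relation(discrete_fn(c(1, 0), 2))
  expect_identical(r$cells, matrix(c(FALSE, TRUE, TRUE, FALSE), nrow = 2))

  set.seed(8)
  for (rep in 1:20) {
    f <- random_fn(6, 8, p_missing = 0)
    expect_identical(unclass(relation_to_function(function_to_relation(f))),
                     unclass(f))
  }
  expect_error(relation_to_function(relation(2, 2, rbind(c(1, 0), c(1, 1)))),
               "not a function")
})

test_that("discrete functions validate their levels", {
  expect_error(discrete_fn(c(0, 4), 4), "out of range")
  expect_error(discrete_fn(-1, 4), "out of range")
  expect_silent(discrete_fn(c(NA, 3), 4))
})
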