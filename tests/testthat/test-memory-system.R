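# Register bank protocols: register, recognize, retrieve, persistence.

toy_bank <- function(m_bits = 3, relax = 0) {
  # quantizer over [0, 8) per feature so levels equal floor(value) at m = 3
  q <- fit_quantizer(rbind(rep(0, 4), rep(8, 4)), m_bits = m_bits)
  register_bank(c("a", "b"), q, relax = relax)
}

test_that("registered instances are always recognized by their register", {
  bank <- toy_bank()
  v <- c(1.2, 3.4, 5.6, 7.1)
  bank <- memory_register(bank, v, "a")
  rep1 <- memory_recognize(bank, v)
  expect_true(rep1$accept[rep1$label == "a"])
  expect_true(attr(rep1, "system_accept"))

  # idempotent: registering the same instance leaves the table unchanged
  before <- bank$registers[["a"]]$table$cells
  bank2 <- memory_register(bank, v, "a")
  expect_identical(bank2$registers[["a"]]$table$cells, before)
  expect_identical(bank2$registers[["a"]]$registered_count, 2L)

  expect_error(memory_register(bank, v, "zz"), "unknown register label")
})

test_that("register entropy after two instances reflects differing columns", {
  bank <- toy_bank()
  # differ in exactly 2 of 4 features -> entropy = 2 * log2(2) / 4
  bank <- memory_register(bank, c(0.5, 1.5, 2.5, 3.5), "a")
  bank <- memory_register(bank, c(0.5, 1.5, 6.5, 7.5), "a")
  expect_equal(ric_entropy(bank$registers[["a"]]$table), 0.5)
})

test_that("recognition costs one containment evaluation per register and
           reports per-register status", {
  bank <- toy_bank()
  bank <- memory_register(bank, c(1, 2, 3, 4), "a")
  eamem:::op_count_reset()
  rep1 <- memory_recognize(bank, c(1, 2, 3, 4))
  expect_identical(eamem:::op_count("containment"), 2L)  # one per register
  expect_identical(rep1$label, c("a", "b"))
  expect_identical(rep1$failed_args[2L], 4L)             # empty register fails all
  expect_identical(attr(rep1, "accepting_labels"), "a")

  # a never-registered level fails everywhere at relax 0, passes at relax 1
  bank <- memory_register(bank, c(1, 2, 3, 7), "b")
  cue <- c(1, 2, 3, 5.5)
  expect_false(attr(memory_recognize(bank, cue), "system_accept"))
  bank$relax <- 1L
  relaxed <- memory_recognize(bank, cue)
  expect_identical(relaxed$accept, c(TRUE, TRUE))
})

test_that("registration never causes a previously accepted cue to be rejected", {
  set.seed(31)
  bank <- toy_bank()
  cues <- lapply(1:6, function(i) runif(4, 0, 8))
  bank <- memory_register(bank, cues[[1]], "a")
  accepted <- memory_recognize(bank, cues[[1]])$accept
  for (i in 2:6) {
    bank <- memory_register(bank, cues[[i]], sample(c("a", "b"), 1))
    now <- memory_recognize(bank, cues[[1]])$accept
    expect_true(all(now[accepted]))
    accepted <- now
  }
})

test_that("retrieval selects the minimal-entropy acceptor and is sound", {
  bank <- toy_bank()
  # register 'a' holds two instances (entropy > 0), 'b' holds one (entropy 0);
  # make the cue acceptable to both
  bank <- memory_register(bank, c(1, 2, 3, 4), "a")
  bank <- memory_register(bank, c(5, 6, 7, 4), "a")
  bank <- memory_register(bank, c(1, 2, 3, 4), "b")
  res <- memory_retrieve(bank, c(1, 2, 3, 4))
  expect_true(res$accepted)
  expect_identical(res$label, "b")               # 0 bits beats 0.75 bits
  # identity policy on a zero-entropy register reproduces the cue's bins
  expect_equal(res$features, dequantize(quantize(c(1, 2, 3, 4), bank$quantizer),
                                        bank$quantizer))
  # retrieved function is contained in the selected register's table
  expect_true(containment(res$fn, bank$registers[[res$label]]$table)$accept)

  # ties broken by bank order
  bank2 <- toy_bank()
  bank2 <- memory_register(bank2, c(1, 2, 3, 4), "a")
  bank2 <- memory_register(bank2, c(1, 2, 3, 4), "b")
  expect_identical(memory_retrieve(bank2, c(1, 2, 3, 4))$label, "a")

  # rejection is a value carrying the report
  miss <- memory_retrieve(bank, c(7, 7, 7, 7))
  expect_false(miss$accepted)
  expect_true(is.na(miss$label))
  expect_s3_class(miss$report, "recognition_report")
})

test_that("banks survive a JSON round trip bit-exactly", {
  set.seed(33)
  for (m in c(0, 2, 4)) {
    x <- matrix(rnorm(60), ncol = 3)
    q <- fit_quantizer(x, m)
    bank <- register_bank(c("a", "b", "c"), q, relax = 1)
    for (i in 1:15) {
      bank <- memory_register(bank, x[i, ], sample(c("a", "b", "c"), 1))
    }
    path <- withr::local_tempfile(fileext = ".json")
    save_bank(bank, path)
    back <- load_bank(path)
    expect_identical(back$quantizer$lo, bank$quantizer$lo)
    expect_identical(back$quantizer$hi, bank$quantizer$hi)
    expect_identical(back$relax, bank$relax)
    for (lb in bank_labels(bank)) {
      expect_identical(back$registers[[lb]]$table$cells,
                       bank$registers[[lb]]$table$cells)
      expect_identical(back$registers[[lb]]$registered_count,
                       bank$registers[[lb]]$registered_count)
      expect_identical(ric_entropy(back$registers[[lb]]$table),
                       ric_entropy(bank$registers[[lb]]$table))
    }
  }
})

test_that("malformed bank files are rejected with a pointed error", {
  bank <- toy_bank()
  bank <- memory_register(bank, c(1, 2, 3, 4), "a")
  path <- withr::local_tempfile(fileext = ".json")
  save_bank(bank, path)

  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  obj$registers[[2]]$rows <- obj$registers[[2]]$rows[1:3]   # wrong row count
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(obj, bad, auto_unbox = TRUE, digits = NA)
  expect_error(load_bank(bad), "register 'b' has 3 rows")

  obj2 <- jsonlite::read_json(path, simplifyVector = FALSE)
  obj2$quantizer <- NULL
  bad2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(obj2, bad2, auto_unbox = TRUE, digits = NA)
  expect_error(load_bank(bad2), "missing field 'quantizer'")
})
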