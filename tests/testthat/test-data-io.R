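test_that("CSV round trip preserves records exactly", {
  x <- generate_concentrations(n_replicates = 5, seed = 11)
  tf <- withr::local_tempfile(fileext = ".csv")
  write_concentrations(x, tf)
  y <- read_concentrations(tf)
  expect_equal(y$concentration, x$concentration)
  expect_identical(y[c("sector", "matrix", "element", "replicate_id")],
                   x[c("sector", "matrix", "element", "replicate_id")])
})

test_that("a single valid row reads back as one validated record", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sector,matrix,element,replicate_id,concentration",
               "lower,muscle,Pb,1,0.24"), tf)
  x <- read_concentrations(tf)
  expect_equal(nrow(x), 1L)
  expect_equal(x$concentration, 0.24)
  expect_equal(x$units, "mg/kg w/w")
})

test_that("schema mapping renames file columns to the canonical ones", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sector,matrix,element,replicate_id,value_mgkg",
               "lower,muscle,Pb,1,0.24"), tf)
  x <- read_concentrations(tf, schema = c(concentration = "value_mgkg"))
  expect_equal(x$concentration, 0.24)
  expect_error(read_concentrations(tf, schema = c(concentration = "nope")),
               "not present")
})

test_that("validation rejects bad rows with the row number", {
  good <- make_conc()
  expect_silent(validate_concentrations(good))

  neg <- good; neg$concentration[1] <- -0.1
  expect_error(validate_concentrations(neg), "negative.*row.*1")

  dup <- rbind(good, good[2, ])
  expect_error(validate_concentrations(dup), "duplicate")

  badsec <- good; badsec$sector[2] <- "estuary"
  expect_error(validate_concentrations(badsec), "unknown sector.*2")

  badel <- good; badel$element[3] <- "Hg"
  expect_error(validate_concentrations(badel), "unknown element.*3")

  nocol <- good[, -5]
  expect_error(validate_concentrations(nocol), "missing required column")

  na_conc <- good; na_conc$concentration[2] <- NA
  expect_error(validate_concentrations(na_conc), "missing or non-numeric")
})

test_that("the full study design yields 432 records", {
  x <- generate_concentrations(seed = 7)
  expect_equal(nrow(x), 3 * 3 * 4 * 12)
  expect_true(all(x$concentration > 0))
})

test_that("summaries report n, mean, sd and midpoint medians per cell", {
  x <- make_conc(values = c(1, 2, 3, 4))
  s <- summarize_concentrations(x)
  expect_equal(s$n, 4L)
  expect_equal(s$median, 2.5)
  expect_equal(s$mean, 2.5)

  x3 <- make_conc(values = c(0.2, 0.24, 0.28))
  expect_equal(summarize_concentrations(x3)$median, 0.24)

  x12 <- generate_concentrations(n_replicates = 12, seed = 3)
  s12 <- summarize_concentrations(x12)
  expect_true(all(s12$n == 12L))
  expect_equal(nrow(s12), 36L)

  # median invariant under record permutation
  perm <- x12[sample.int(nrow(x12)), ]
  expect_equal(summarize_concentrations(perm)$median, s12$median)

  expect_error(summarize_concentrations(x12[0, ]), "empty group")
})

test_that("guideline registry matches the published maximum limits", {
  g <- builtin_guidelines()
  expect_equal(nrow(g), 12L)
  expect_equal(anyDuplicated(paste(g$matrix, g$element)), 0L)
  expect_equal(guideline_limit("muscle", "Pb"), 0.3)
  expect_equal(guideline_limit("sediment", "Zn"), 123)
  expect_equal(guideline_limit("water", "As"), 0.01)
  expect_equal(guideline_limit(c("muscle", "water"), c("As", "Cu")),
               c(2, 1.3))
  expect_equal(g$value[g$matrix == "muscle"][order(g$element[g$matrix == "muscle"])],
               c(As = 2, Cu = 30, Pb = 0.3, Zn = 30), ignore_attr = TRUE)
  expect_equal(g$value[g$matrix == "sediment"][order(g$element[g$matrix == "sediment"])],
               c(5.9, 35.7, 35.0, 123))
  expect_error(guideline_limit("water", "Hg"), "no guideline limit")
})

test_that("element registry is extensible but rejects incomplete entries", {
  withr::defer(reset_elements())
  expect_error(element_params("Cd"), "unknown element")
  expect_error(register_element("Cd", rfd = -1), "positive")
  register_element("Cd", rfd = 1e-3, arm = 0.5, csf = 6.1)
  expect_equal(element_params("Cd")$csf, 6.1)
  expect_true(element_params("Cd")$carcinogen)
  expect_error(register_element("Cd", rfd = 1e-3), "already registered")
  reset_elements()
  expect_error(element_params("Cd"), "unknown element")
})
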