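test_that("intake equations reproduce hand arithmetic at defaults", {
  expect_equal(edi(0.24, "Pb"), 0.24 * 0.34 / 60 * 0.33)
  expect_equal(edi(0.11, "As"), 0.11 * 0.34 / 60 * 0.75)
  expect_equal(edi(0, "Zn"), 0)
  expect_equal(ewi(4.488e-4), 3.1416e-3)
  expect_equal(ewi(0), 0)
  expect_equal(ewi(1), 7)
  expect_equal(thq(2.51, "Zn"), 0.34 * 2.51 / (0.3 * 60))
  expect_equal(thq(0, "Pb"), 0)
  # linearity in the ingestion rate
  p2 <- exposure_params(FIR = 680)
  expect_equal(thq(1, "Pb", p2), 2 * thq(1, "Pb"))
  expect_error(ewi(-1), ">= 0")
})

test_that("parameter objects validate their domains", {
  expect_error(exposure_params(BW = 0), "positive")
  expect_error(exposure_params(AT = -1), "positive")
  expect_error(exposure_params(ARm = c(Pb = 1.2)), "\\(0, 1\\]")
  expect_error(toxicity_params(RfD = c(As = 0)), "positive")
  expect_error(toxicity_params(CSF = c(As = 1.5), carcinogens = c("As", "Pb")),
               "without a CSF")
  expect_error(edi(0.1, "Hg"), "ARm")
  expect_error(thq(0.1, "Hg"), "RfD.*Hg")
})

test_that("hazard index and total cancer risk are exact sums with flags", {
  hi <- hazard_index(c(0.0004, 0.1954, 0.0007, 0.0299))
  expect_equal(as.numeric(hi), 0.2264)
  expect_false(attr(hi, "exceeds"))
  expect_equal(as.numeric(hazard_index(0.73)), 0.73)
  expect_true(attr(hazard_index(c(0.6, 0.6)), "exceeds"))
  expect_error(hazard_index(numeric(0)), "at least one")

  tcr <- total_cancer_risk(c(7.0125e-7, 3.815e-9))
  expect_equal(as.numeric(tcr), 7.0125e-7 + 3.815e-9)
  expect_equal(attr(tcr, "classification"), "below 1e-6")
  expect_equal(attr(total_cancer_risk(1e-4), "classification"),
               "within band")
  expect_equal(attr(total_cancer_risk(1e-6), "classification"),
               "within band")
  expect_equal(attr(total_cancer_risk(0), "classification"), "below 1e-6")
  expect_equal(attr(total_cancer_risk(2e-4), "classification"),
               "above 1e-4")
  expect_error(total_cancer_risk(numeric(0)), "at least one")
})

test_that("cancer risk supports both scale modes and records the mode", {
  cr <- cancer_risk(4.675e-4, 1.5)
  expect_equal(as.numeric(cr), 1.5 * 4.675e-4 * 1e-3)
  expect_equal(attr(cr, "mode"), "as_printed")
  expect_equal(as.numeric(cancer_risk(4.488e-4, 0.0085)),
               0.0085 * 4.488e-4 * 1e-3)
  un <- cancer_risk(4.675e-4, 1.5, mode = "unscaled")
  expect_equal(as.numeric(un), 1.5 * 4.675e-4)
  expect_equal(as.numeric(cancer_risk(0, 1.5)), 0)
  expect_error(cancer_risk(1e-4, 1.5, mode = "bogus"))
})

test_that("the chain is homogeneous of degree 1 in concentration", {
  set.seed(42)
  for (i in 1:20) {
    conc <- runif(1, 0, 5)
    k <- runif(1, 0.1, 10)
    el <- sample(c("As", "Cu", "Pb", "Zn"), 1)
    expect_equal(edi(k * conc, el), k * edi(conc, el))
    expect_equal(thq(k * conc, el), k * thq(conc, el))
  }
})

test_that("EDI is independent of EF and ED when AT = EF * ED", {
  set.seed(42)
  for (i in 1:20) {
    ef <- runif(1, 100, 400)
    ed <- runif(1, 10, 90)
    p <- exposure_params(EF = ef, ED = ed)  # AT defaults to EF * ED
    expect_equal(edi(0.24, "Pb", p), edi(0.24, "Pb"))
    expect_equal(thq(0.24, "Pb", p), thq(0.24, "Pb"))
  }
  # but not when AT is overridden
  p2 <- exposure_params(AT = 1000)
  expect_false(isTRUE(all.equal(edi(0.24, "Pb", p2), edi(0.24, "Pb"))))
})

test_that("dietary_risk fits per-sector tables with consistent sums", {
  x <- generate_concentrations(seed = 5)
  fit <- dietary_risk(x)
  expect_s3_class(fit, "dietary_risk")
  expect_equal(fit$sectors, c("upper", "middle", "lower"))

  # HI is exactly the sum of the sector's THQs
  for (s in fit$sectors) {
    expect_identical(fit$hazard$HI[fit$hazard$sector == s],
                     sum(fit$intake$THQ[fit$intake$sector == s]))
    expect_identical(fit$tcr$TCR[fit$tcr$sector == s],
                     sum(fit$cancer$CR[fit$cancer$sector == s]))
  }

  s <- summary(fit)
  expect_named(s$hazard_table,
               c("sector", "THQ_As", "THQ_Cu", "THQ_Pb", "THQ_Zn", "HI"))
  expect_equal(rowSums(s$hazard_table[, 2:5]), s$hazard_table$HI,
               ignore_attr = TRUE)
  expect_equal(coef(fit), setNames(fit$hazard$HI, fit$hazard$sector))

  expect_error(dietary_risk(x[x$matrix == "water", ]), "muscle")
})

test_that("median-centered fits use the cell medians", {
  x <- generate_concentrations(seed = 5)
  fit_m <- dietary_risk(x, center = "median")
  cc <- fit_m$concentrations
  expect_equal(cc$center, cc$median)
  one <- cc[cc$sector == "lower" & cc$element == "Pb", ]
  expect_equal(fit_m$intake$THQ[fit_m$intake$sector == "lower" &
                                  fit_m$intake$element == "Pb"],
               thq(one$median, "Pb"))
})
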