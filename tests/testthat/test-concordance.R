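test_that("positive rates reproduce the reference detection table", {
  expect_equal(positiveRate(39, 50), 44)
  expect_equal(positiveRate(30, 59), 34)
  expect_equal(positiveRate(37, 52), 42)
  expect_equal(positiveRate(0, 10), 0)
  expect_equal(positiveRate(39, 50, exact = TRUE), 100 * 39 / 89)
  expect_error(positiveRate(0, 0), "zero")
  # pre-rounding rates of the two-way split sum to 100 exactly
  expect_equal(positiveRate(39, 50, exact = TRUE) +
                 positiveRate(50, 39, exact = TRUE), 100)
})

test_that("half-up rounding is used (not banker's rounding)", {
  expect_equal(positiveRate(1, 7), 13)   # 12.5 rounds up
  expect_equal(positiveRate(3, 5), 38)   # 37.5 rounds up
})

test_that("chi-square matches hand computation and a loop oracle", {
  r <- chiSquare(rbind(c(10, 0), c(0, 10)))
  expect_equal(r@statistic, 20)
  expect_equal(r@df, 1)
  ident <- chiSquare(rbind(c(12, 8), c(12, 8)))
  expect_equal(ident@statistic, 0)
  expect_equal(ident@pValue, 1)
  set.seed(55)
  for (rep in 1:10) {
    tab <- matrix(sample(5:60, 6), 2, 3)
    got <- chiSquare(tab)
    expect_equal(got@statistic, chisqOracle(tab), tolerance = 1e-9)
    expect_equal(got@df, 2)
    # invariant to row permutation
    expect_equal(chiSquare(tab[2:1, ])@statistic, got@statistic)
  }
  expect_error(chiSquare(rbind(c(0, 0), c(1, 2))), "margin")
})

test_that("2x2 Pearson chi-square equals the squared two-proportion z", {
  set.seed(56)
  for (rep in 1:5) {
    tab <- matrix(sample(10:80, 4), 2, 2)
    n1 <- sum(tab[1, ]); n2 <- sum(tab[2, ])
    p1 <- tab[1, 1] / n1; p2 <- tab[2, 1] / n2
    pPool <- (tab[1, 1] + tab[2, 1]) / (n1 + n2)
    z <- (p1 - p2) / sqrt(pPool * (1 - pPool) * (1 / n1 + 1 / n2))
    expect_equal(chiSquare(tab)@statistic, z^2, tolerance = 1e-9)
  }
})

test_that("the concordance report reproduces the reference comparison", {
  det <- referenceDetectionTable()
  strata <- referenceStrataTable()
  rep <- concordanceReport(det, strata)
  expect_equal(rep$positive_rate, c(44, 34, 42))
  expect_equal(rep$rate_diff, c(0, 10, 2))
  expect_equal(sum(strata[strata$method == "pathology",
                          c("low", "medium", "high")]), 39)
  expect_equal(rep$strata_abs_diff[rep$method == "pathology"], 0)
  expect_true(all(is.na(rep$chisq_stat[rep$method == "pathology"])))
  # a method identical to pathology: zero differences, p = 1
  det2 <- rbind(det, data.frame(method = "copy", n_cancer = 39,
                                n_hyperplasia = 50))
  r2 <- concordanceReport(det2)
  expect_equal(r2$rate_diff[r2$method == "copy"], 0)
  expect_equal(r2$chisq_p[r2$method == "copy"], 1)
  expect_error(concordanceReport(det[det$method != "pathology", ]),
               "pathology")
})

test_that("lesion-presence cancer calls respond to low-signal foci", {
  params <- PhantomParams(noiseSD = 0)
  ph <- generatePhantom(params, seed = 4)
  expect_false(callCancerFromSegmentation(ph$image, ph$mask))
  les <- insertLesion(ph$image, ph$mask, c(33, 33), 4, 70)
  expect_true(callCancerFromSegmentation(les$image, ph$mask))
})
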