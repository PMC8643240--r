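test_that("Dice hits its boundary behaviors and a worked example", {
  A <- rbind(c(1, 1), c(1, 2), c(2, 1))
  expect_equal(dice(A, A), 1)
  B <- rbind(c(5, 5), c(6, 6))
  expect_equal(dice(A, B), 0)
  # |M| = 3, |N| = 5, |M ∩ N| = 2 -> 0.5
  N <- rbind(c(1, 1), c(1, 2), c(3, 3), c(4, 4), c(5, 5))
  expect_equal(dice(A, N), 0.5)
  expect_equal(dice(N, A), 0.5)  # symmetry
  expect_error(dice(matrix(numeric(), 0, 2), matrix(numeric(), 0, 2)),
               "undefined")
})

test_that("directed Hausdorff is exact and asymmetric", {
  expect_equal(directedHausdorff(rbind(c(0, 0)), rbind(c(3, 4))), 5)
  A <- rbind(c(0, 0))
  B <- rbind(c(0, 0), c(10, 0))
  expect_equal(directedHausdorff(A, B), 0)
  expect_equal(directedHausdorff(B, A), 10)
  expect_equal(hausdorff(A, B), 10)
  expect_equal(hausdorff(B, B), 0)
  expect_error(directedHausdorff(A, matrix(numeric(), 0, 2)), "non-empty")
})

test_that("dice and hausdorff match brute-force oracles on random sets", {
  set.seed(77)
  for (rep in 1:40) {
    M <- randomPixelSet(sample(1:50, 1))
    N <- randomPixelSet(sample(1:50, 1))
    expect_equal(dice(M, N), diceOracle(M, N), tolerance = 1e-9)
    expect_equal(hausdorff(M, N), hausdorffOracle(M, N),
                 tolerance = 1e-9)
  }
})

test_that("hausdorff obeys the triangle inequality and nesting property", {
  set.seed(78)
  for (rep in 1:10) {
    A <- randomPixelSet(sample(5:30, 1))
    B <- randomPixelSet(sample(5:30, 1))
    C <- randomPixelSet(sample(5:30, 1))
    expect_lte(hausdorff(A, C), hausdorff(A, B) + hausdorff(B, C) + 1e-9)
    AB <- unique(rbind(A, B))
    expect_equal(directedHausdorff(A, AB), 0)  # A ⊆ A ∪ B
  }
})

test_that("segmentation evaluation works on identity, shift and checkerboard cases", {
  ph <- generatePhantom(PhantomParams(), seed = 2)
  sm <- evaluateSegmentation(ph$mask, ph$mask)
  expect_equal(sm@dsc, 1)
  expect_equal(sm@hd, 0)
  # shift the mask one pixel down: boundary HD is exactly 1
  shifted <- rbind(matrix(0L, 1, ncol(ph$mask)),
                   ph$mask[-nrow(ph$mask), ])
  sm2 <- evaluateSegmentation(shifted, ph$mask)
  expect_equal(sm2@hd, 1)
  expect_lt(sm2@dsc, 1)
  # checkerboard vs solid on 4x4: hand-counted overlap
  solid <- matrix(1L, 4, 4)
  cb <- matrix(as.integer((outer(1:4, 1:4, "+") %% 2) == 0), 4)
  sm3 <- evaluateSegmentation(cb, solid)
  expect_equal(sm3@dsc, 2 * 8 / (16 + 8))
  expect_error(evaluateSegmentation(matrix(0L, 3, 3), matrix(0L, 4, 4)),
               "differ")
  expect_error(evaluateSegmentation(solid, matrix(0L, 4, 4)),
               "reference foreground")
})

test_that("per-class mode reports one Dice per class plus macro average", {
  ph <- generatePhantom(PhantomParams(), seed = 2)
  sm <- evaluateSegmentation(ph$mask, ph$mask, mode = "per_class")
  expect_equal(unname(sm@perClass[c("class0", "class1", "class2")]),
               c(1, 1, 1))
  expect_equal(unname(sm@perClass[["macro"]]), 1)
  # mm conversion scales HD by the pixel spacing
  shifted <- rbind(matrix(0L, 1, ncol(ph$mask)), ph$mask[-64, ])
  mm <- evaluateSegmentation(shifted, ph$mask, pixelSpacing = 0.5)
  expect_equal(mm@hd, 0.5)
  expect_equal(mm@units, "mm")
})
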