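test_that("phantom generation is deterministic and leaves the global RNG alone", {
  params <- PhantomParams()
  set.seed(999)
  before <- .Random.seed
  a <- generatePhantom(params, seed = 7)
  expect_identical(.Random.seed, before)
  b <- generatePhantom(params, seed = 7)
  expect_identical(a, b)
  c2 <- generatePhantom(params, seed = 8)
  expect_false(identical(a$image, c2$image))
})

test_that("noiseless phantom intensities identify classes exactly", {
  params <- PhantomParams(noiseSD = 0)
  ph <- generatePhantom(params, seed = 1)
  m <- params@intensityMeans
  expect_setequal(unique(as.vector(ph$mask)), c(0L, 1L, 2L))
  expect_true(all(ph$image[ph$mask == 0L] == m[["surrounding"]]))
  expect_true(all(ph$image[ph$mask == 1L] == m[["central"]]))
  expect_true(all(ph$image[ph$mask == 2L] == m[["marginal"]]))
  # the gland's outer ring is all marginal zone, so the central zone sits
  # strictly inside the gland boundary
  expect_true(all(ph$mask[boundaryPixels(ph$mask > 0L)] == 2L))
  expect_true(sum(ph$mask == 1L) > 0 && sum(ph$mask == 2L) > 0)
})

test_that("rasterized gland area matches the analytic ellipse area and improves with resolution", {
  analytic <- pi * 20 * 10  # mm^2, 40 x 20 mm gland
  p64 <- PhantomParams()
  n64 <- sum(generatePhantom(p64, 1)$mask > 0L)
  expect_lt(abs(n64 - analytic) / analytic, 0.05)
  p128 <- PhantomParams(imageHeight = 128L, imageWidth = 128L)
  n128 <- sum(generatePhantom(p128, 1)$mask > 0L)
  expect_lt(abs(n128 - analytic) / analytic, 0.05)
  # halving the pixel spacing quarters the pixel area; the relative
  # rasterization error must not grow
  pFine <- PhantomParams(imageHeight = 128L, imageWidth = 128L,
                         pixelSpacing = 0.5)
  nFine <- sum(generatePhantom(pFine, 1)$mask > 0L) * 0.25
  expect_lte(abs(nFine - analytic) / analytic,
             abs(n64 - analytic) / analytic + 1e-9)
})

test_that("gland axes exceeding the image extent are rejected", {
  expect_error(PhantomParams(imageHeight = 16L, imageWidth = 16L),
               "exceed")
  expect_error(PhantomParams(centralFraction = 1), "centralFraction")
  expect_error(PhantomParams(noiseSD = -1), "noiseSD")
})

test_that("lesion insertion restricts to in-gland disc pixels, brute-force checked", {
  params <- PhantomParams(noiseSD = 0)
  ph <- generatePhantom(params, seed = 1)
  # single-pixel lesion
  ctr <- c(33L, 33L)
  one <- insertLesion(ph$image, ph$mask, ctr, radius = 0.5,
                      lesionIntensity = 70)
  expect_equal(sum(one$lesionMask), 1L)
  expect_equal(one$image[ctr[1], ctr[2]], 70)
  # disc partly outside the gland: exhaustive pixel scan
  ctr2 <- c(33L, 13L)  # near the left gland edge
  expect_gt(ph$mask[ctr2[1], ctr2[2]], 0L)
  les <- insertLesion(ph$image, ph$mask, ctr2, radius = 5,
                      lesionIntensity = 70)
  brute <- 0L
  for (r in seq_len(nrow(ph$mask))) for (cc in seq_len(ncol(ph$mask)))
    if ((r - ctr2[1])^2 + (cc - ctr2[2])^2 <= 25 && ph$mask[r, cc] > 0L)
      brute <- brute + 1L
  expect_identical(sum(les$lesionMask), brute)
  expect_lt(brute, sum((outer(seq_len(64) - ctr2[1], seq_len(64) - ctr2[2],
                              function(a, b) a^2 + b^2)) <= 25))
  # lesion darker than all gland classes => mean below rest of gland
  glandNotLesion <- ph$mask > 0L & !les$lesionMask
  expect_lt(mean(les$image[les$lesionMask]),
            mean(les$image[glandNotLesion]))
  # mask untouched, placement error outside gland
  expect_error(insertLesion(ph$image, ph$mask, c(1L, 1L), 3, 70),
               "inside the gland")
})

test_that("case record sampling is reproducible and respects invariants", {
  r1 <- sampleCaseRecord("cancer", seed = 5)
  r2 <- sampleCaseRecord("cancer", seed = 5)
  expect_identical(r1, r2)
  expect_equal(r1$gleason_score, r1$gleason_primary + r1$gleason_secondary)
  h <- sampleCaseRecord("hyperplasia", seed = 5)
  expect_true(is.na(h$risk_group))
  expect_equal(h$gleason_score, 2L)
})

test_that("empirical Gleason-score distribution matches the declared sampling table", {
  n <- 10000L
  scores <- vapply(seq_len(n),
                   function(i) sampleCaseRecord("cancer", seed = i)$gleason_score,
                   integer(1))
  model <- caseSamplingModel()
  emp <- tabulate(factor(scores, levels = model$gleasonScores), 5L) / n
  # each category within ~4 binomial standard errors of its probability
  se <- sqrt(model$gleasonProbs * (1 - model$gleasonProbs) / n)
  expect_true(all(abs(emp - model$gleasonProbs) < 4 * se + 1e-12))
})

test_that("cohorts have the requested composition and are seed-stable", {
  params <- PhantomParams()
  coh <- generateCohort(39, 50, params, seed = 3)
  expect_equal(nrow(coh$records), 89L)
  expect_equal(sum(coh$records$true_class == "cancer"), 39L)
  expect_equal(length(coh$images), 89L)
  coh2 <- generateCohort(39, 50, params, seed = 3)
  expect_identical(coh$images, coh2$images)
  expect_identical(coh$records, coh2$records)
  # lesions only on cancer cases
  lesionCases <- !vapply(coh$lesionMasks, is.null, logical(1))
  expect_true(all(coh$records$true_class[lesionCases] == "cancer"))
  expect_identical(coh$records$has_lesion, lesionCases)
  benign <- generateCohort(0, 5, params, seed = 3)
  expect_false(any(benign$records$has_lesion))
})
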