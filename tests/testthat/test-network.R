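# Tiny study conditions for fast network tests: coarse 16x16 phantoms
# (4 mm pixels, so the 40 x 20 mm gland still fits) and a narrow net.
tinyParams <- function(noiseSD = 0)
  PhantomParams(imageHeight = 16L, imageWidth = 16L, pixelSpacing = 4,
                noiseSD = noiseSD)

tinyConfig <- function(...)
  NetworkConfig(encoderChannels = c(8L, 16L), decoderChannels = c(8L),
                inputSize = c(16L, 16L), batchSize = 2L, seed = 3L, ...)

test_that("model building is seeded and outputs a valid probability map", {
  n1 <- buildPSSNet(NetworkConfig(seed = 9L))
  n2 <- buildPSSNet(NetworkConfig(seed = 9L))
  expect_identical(n1@params, n2@params)
  n3 <- buildPSSNet(NetworkConfig(seed = 10L))
  expect_false(identical(n1@params, n3@params))
  # untrained forward pass on a default 64x64 phantom
  ph <- generatePhantom(PhantomParams(), seed = 1)
  seg <- segmentImage(n1, ph$image)
  expect_equal(dim(seg$probs), c(64, 64, 3))
  expect_true(all(is.finite(seg$probs)))
  sums <- apply(seg$probs, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-6))
  expect_true(all(seg$mask %in% 0:2))
  # decoder must restore the input dims exactly
  expect_error(NetworkConfig(inputSize = c(30L, 30L)), "divisible")
  expect_error(NetworkConfig(decoderChannels = c(8L, 4L, 2L)),
               "decoder stage count")
})

test_that("training is bit-reproducible and reduces the loss", {
  b <- makePhantomBatch(6, tinyParams(noiseSD = 5), seedBase = 4)
  cfg <- tinyConfig(epochs = 10L)
  m1 <- trainPSSNet(b$images, b$masks, cfg)
  m2 <- trainPSSNet(b$images, b$masks, cfg)
  expect_identical(m1@params, m2@params)
  expect_identical(trainingLog(m1), trainingLog(m2))
  log <- trainingLog(m1)
  expect_lt(log$meanLoss[10], log$meanLoss[1])
  s1 <- segmentImage(m1, b$images[[1]])
  s2 <- segmentImage(m1, b$images[[1]])
  expect_identical(s1$mask, s2$mask)
  expect_error(trainPSSNet(list(), list(), cfg), "empty")
})

test_that("the network can overfit one phantom to near-zero loss", {
  b <- makePhantomBatch(1, tinyParams(), seedBase = 7)
  cfg <- tinyConfig(epochs = 400L)
  net <- trainPSSNet(rep(b$images, 2), rep(b$masks, 2), cfg)
  log <- trainingLog(net)
  expect_lt(log$meanLoss[400], 0.2)
  expect_lt(log$meanLoss[400], log$meanLoss[1] / 5)
  # the overfit model segments its training phantom accurately
  seg <- segmentImage(net, b$images[[1]])
  expect_gt(evaluateSegmentation(seg$mask, b$masks[[1]])@dsc, 0.95)
})

test_that("segmentation enforces the input contract and checkpoints round-trip", {
  net <- buildPSSNet(tinyConfig(epochs = 1L))
  expect_error(segmentImage(net, matrix(0, 64, 64)), "expects 16x16")
  b <- makePhantomBatch(2, tinyParams(noiseSD = 5), seedBase = 8)
  trained <- trainPSSNet(b$images, b$masks, tinyConfig(epochs = 2L))
  f <- tempfile(fileext = ".ckpt")
  saveModel(trained, f)
  back <- loadModel(f)
  expect_identical(back@params, trained@params)
  expect_identical(segmentImage(back, b$images[[1]])$mask,
                   segmentImage(trained, b$images[[1]])$mask)
  expect_error(batchNorm(array(1, c(2, 2, 1, 1)), training = TRUE))
})
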