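test_that("convolution matches hand examples and the identity/bias limits", {
  # 2x2 all-ones kernel on [[1,2],[3,4]], valid: single value 10
  x <- matrix(c(1, 3, 2, 4), 2)
  expect_equal(as.vector(convForward(x, matrix(1, 2, 2),
                                     padding = "valid")), 10)
  # 1x1 identity kernel preserves the input
  img <- matrix(rnorm(25), 5)
  expect_equal(convForward(img, matrix(1, 1, 1)), img)
  # zero kernels, bias 7: constant 7 output
  k <- array(0, c(3, 3, 1, 2))
  out <- convForward(array(rnorm(36), c(6, 6, 1, 1)), k, bias = c(7, -1))
  expect_true(all(out[, , 1, 1] == 7) && all(out[, , 2, 1] == -1))
  expect_error(convForward(array(0, c(4, 4, 2, 1)),
                           array(0, c(3, 3, 1, 1))), "channels")
})

test_that("convolution agrees with an exhaustive nested-loop oracle", {
  set.seed(101)
  for (rep in 1:5) {
    H <- sample(4:8, 1); W <- sample(4:8, 1)
    cin <- sample(1:3, 1); cout <- sample(1:3, 1)
    kh <- sample(1:3, 1)
    x <- array(rnorm(H * W * cin), c(H, W, cin))
    k <- array(rnorm(kh * kh * cin * cout), c(kh, kh, cin, cout))
    b <- rnorm(cout)
    got <- convForward(array(x, c(H, W, cin, 1L)), k, b,
                       padding = "valid")
    expect_equal(as.vector(got), as.vector(convOracle(x, k, b)),
                 tolerance = 1e-6)
  }
})

test_that("ReLU and its derivative follow max(0, x)", {
  expect_equal(relu(c(-3, 0, 5)), c(0, 0, 5))
  expect_equal(reluGrad(c(-1, 0, 2)), c(0, 0, 1))
  # finite-difference cross-check away from the kink
  xs <- c(-2.5, -0.3, 0.4, 3.1)
  h <- 1e-6
  fd <- (relu(xs + h) - relu(xs - h)) / (2 * h)
  expect_equal(reluGrad(xs), fd, tolerance = 1e-6)
})

test_that("batch normalization standardizes, recovers identity, and handles edge cases", {
  # hand computation: {1,2,3}, population variance 2/3
  b <- array(c(1, 2, 3), c(1, 1, 1, 3))
  out <- batchNorm(b, epsilon = 1e-12)$output
  expect_equal(as.vector(out), c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-4)
  # constant batch -> all zeros
  cst <- batchNorm(array(5, c(2, 2, 1, 3)), epsilon = 1e-3)$output
  expect_true(all(cst == 0))
  # identity recovery: scale = sqrt(var + eps), shift = mean
  set.seed(7)
  x <- array(rnorm(4 * 4 * 2 * 5, mean = 3, sd = 2), c(4, 4, 2, 5))
  eps <- 1e-5
  ref <- batchNorm(x, epsilon = eps)
  rec <- batchNorm(x, scale = sqrt(ref$batchVar + eps),
                   shift = ref$batchMean, epsilon = eps)
  expect_equal(rec$output, x, tolerance = 1e-6)
  # normalized maps have per-channel mean 0, variance 1
  for (ch in 1:2) {
    v <- ref$normalized[, , ch, ]
    expect_equal(mean(v), 0, tolerance = 1e-5)
    expect_equal(mean(v^2), 1, tolerance = 1e-3)
  }
  expect_error(batchNorm(array(1, c(2, 2, 1, 1)), training = TRUE),
               ">= 2 samples")
  # inference mode uses running statistics and is deterministic
  inf1 <- batchNorm(x, training = FALSE, runningMean = ref$runningMean,
                    runningVar = ref$runningVar)$output
  inf2 <- batchNorm(x, training = FALSE, runningMean = ref$runningMean,
                    runningVar = ref$runningVar)$output
  expect_identical(inf1, inf2)
})

test_that("average pooling matches the window-mean oracle", {
  expect_equal(avgPool(matrix(c(1, 3, 2, 4), 2), 2), matrix(2.5))
  m <- matrix(rnorm(64), 8)
  expect_equal(avgPool(m, 1), m)
  expect_equal(avgPool(m, 2), poolOracle(m, 2))
  expect_equal(avgPool(m, 4), poolOracle(m, 4))
  cst <- avgPool(matrix(3.3, 6, 6), 3)
  expect_true(all(cst == 3.3) && all(dim(cst) == c(2, 2)))
  expect_error(avgPool(matrix(0, 5, 5), 2), "divisible")
  # batched stacks pool each channel/sample independently
  set.seed(3)
  x <- array(rnorm(4 * 4 * 2 * 3), c(4, 4, 2, 3))
  got <- avgPool(x, 2)
  expect_equal(got[, , 2, 3], poolOracle(x[, , 2, 3], 2))
})

test_that("pixel softmax normalizes, is stable, and matches hand values", {
  p <- pixelSoftmax(array(c(1, 0, 0), c(1, 1, 3)))
  expect_equal(as.vector(p), c(exp(1), 1, 1) / (exp(1) + 2),
               tolerance = 1e-5)
  expect_equal(as.vector(pixelSoftmax(array(0, c(1, 1, 3)))), rep(1 / 3, 3))
  set.seed(11)
  s <- array(rnorm(6 * 5 * 4 * 2, sd = 300), c(6, 5, 4, 2))  # huge scores
  pr <- pixelSoftmax(s)
  expect_true(all(is.finite(pr)) && all(pr >= 0))
  sums <- apply(pr, c(1, 2, 4), sum)
  expect_true(all(abs(sums - 1) < 1e-6))
})

test_that("label prediction is argmax with lowest-index tie-break", {
  expect_equal(as.vector(predictLabels(array(c(0.1, 0.7, 0.2),
                                             c(1, 1, 3)))), 1L)
  expect_equal(as.vector(predictLabels(array(c(0.5, 0.5, 0),
                                             c(1, 1, 3)))), 0L)
  set.seed(21)
  pr <- pixelSoftmax(array(rnorm(7 * 6 * 3), c(7, 6, 3)))
  lab <- predictLabels(pr)
  for (r in 1:7) for (cc in 1:6)
    expect_identical(lab[r, cc], which.max(pr[r, cc, ]) - 1L)
})

test_that("cross-entropy loss matches its closed forms and a loop oracle", {
  # perfect prediction -> 0
  perfect <- array(0, c(2, 2, 3))
  perfect[, , 1] <- 1
  expect_equal(crossEntropyLoss(perfect, matrix(0L, 2, 2)), 0,
               tolerance = 1e-9)
  # uniform probabilities -> log 3
  expect_equal(crossEntropyLoss(array(1 / 3, c(2, 2, 3)),
                                matrix(2L, 2, 2)), log(3))
  # independent per-pixel loop oracle to 1e-8
  set.seed(31)
  pr <- pixelSoftmax(array(rnorm(5 * 4 * 3 * 2), c(5, 4, 3, 2)))
  lab <- array(sample(0:2, 40, TRUE), c(5, 4, 2))
  acc <- 0
  for (n in 1:2) for (r in 1:5) for (cc in 1:4)
    acc <- acc - log(pr[r, cc, lab[r, cc, n] + 1, n])
  expect_equal(crossEntropyLoss(pr, lab), acc / 40, tolerance = 1e-8)
  # lowering the true-class probability strictly increases the loss
  pr2 <- pr
  pr2[1, 1, lab[1, 1, 1] + 1, 1] <- pr2[1, 1, lab[1, 1, 1] + 1, 1] / 2
  expect_gt(crossEntropyLoss(pr2, lab), crossEntropyLoss(pr, lab))
  expect_error(crossEntropyLoss(pr, matrix(0L, 3, 3)), "grids differ")
})

test_that("transposed convolution upsamples and is the exact conv adjoint", {
  # 1x1 input, all-ones 2x2 kernel, stride 2: every output pixel = input
  up <- deconvUpsample(matrix(3), array(1, c(2, 2, 1, 1)), stride = 2)
  expect_equal(up, matrix(3, 2, 2))
  z <- deconvUpsample(array(0, c(3, 3, 2, 1)),
                      array(rnorm(2 * 2 * 4 * 2), c(2, 2, 4, 2)),
                      stride = 2)
  expect_true(all(z == 0) && all(dim(z) == c(6, 6, 4, 1)))
  # adjoint identity <conv(x), y> == <x, deconv(y)> on random tensors
  set.seed(41)
  for (rep in 1:5) {
    cin <- sample(1:3, 1); cout <- sample(1:3, 1)
    H <- 2L * sample(2:4, 1)
    x <- array(rnorm(H * H * cin), c(H, H, cin, 1))
    k <- array(rnorm(2 * 2 * cin * cout), c(2, 2, cin, cout))
    y <- array(rnorm((H / 2)^2 * cout), c(H / 2, H / 2, cout, 1))
    lhs <- sum(convForward(x, k, stride = 2, padding = "valid") * y)
    rhs <- sum(x * deconvUpsample(y, k, stride = 2))
    expect_equal(lhs, rhs, tolerance = 1e-6)
  }
  expect_error(deconvUpsample(matrix(1), array(1, c(3, 3, 1, 1)),
                              stride = 2), "stride x stride")
})
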