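test_that("1x1 projection is the per-pixel linear map", {
  F1 <- array(1, dim = c(4, 4, 2))
  W1 <- matrix(c(1, 2), nrow = 2, ncol = 1)
  expect_true(all(projectFeatures(F1, W1) == 3))
  expect_true(all(projectFeatures(F1, W1 * 0) == 0))

  set.seed(11)
  F2 <- array(rnorm(4 * 4 * 3), dim = c(4, 4, 3))
  W2 <- matrix(rnorm(3 * 5), 3, 5)
  expect_equal(projectFeatures(F2, W2), bruteProject(F2, W2),
               tolerance = 1e-12)
  expect_error(projectFeatures(F2, matrix(0, 4, 5)), "projection")
})

test_that("global pooling is the per-channel spatial mean", {
  A <- array(0, dim = c(2, 2, 2))
  A[, , 1] <- 7
  A[, , 2] <- matrix(c(1, 3, 2, 4), 2, 2)
  expect_equal(globalPool(A), c(7, 2.5))

  set.seed(12)
  A2 <- array(rnorm(6 * 6 * 240), dim = c(6, 6, 240))
  expect_equal(globalPool(A2), brutePool(A2), tolerance = 1e-12)
})

test_that("pooling commutes with the projection (CAM consistency)", {
  set.seed(13)
  F_ <- array(rnorm(5 * 7 * 8), dim = c(5, 7, 8))
  W <- matrix(rnorm(8 * 240), 8, 240)
  channelMeans <- colMeans(matrix(F_, nrow = 35, ncol = 8))
  expect_equal(globalPool(projectFeatures(F_, W)),
               as.numeric(channelMeans %*% W), tolerance = 1e-6)
})

test_that("softmax is normalized, shift-invariant and overflow-safe", {
  expect_equal(softmaxProbs(rep(0, 240)), rep(1 / 240, 240))
  expect_equal(softmaxProbs(c(0, log(3))), c(0.25, 0.75))
  set.seed(14)
  for (i in 1:20) {
    s <- rnorm(240, sd = 5)
    p <- softmaxProbs(s)
    expect_lt(abs(sum(p) - 1), 1e-9)
    expect_equal(p, softmaxProbs(s + 123.4), tolerance = 1e-12)
  }
  expect_equal(which.max(softmaxProbs(c(0, 1000, 999))), 2)  # no overflow
})

test_that("channel selection is argmax with low-index ties", {
  expect_equal(selectChannel(replace(numeric(240), 150, 1)), 150)
  expect_equal(selectChannel(rep(1 / 240, 240)), 1)
  set.seed(15)
  s <- rnorm(240)
  expect_equal(selectChannel(softmaxProbs(s)), which(s == max(s))[1])
})

test_that("mask thresholds the min-max normalized channel", {
  ch <- matrix(c(0, 0.5, 0.7, 1), 2, 2)  # already 0..1 after normalization
  m <- makeMask(ch, tau = 0.6)
  expect_equal(as.numeric(m), c(0, 0, 1, 1))
  expect_equal(attr(m, "tau"), 0.6)
  # tau -> 0+ keeps every pixel except the exact minimum (which normalizes
  # to 0 and a strictly positive threshold excludes it)
  m0 <- makeMask(ch, tau = 1e-9)
  expect_true(all(m0[ch > min(ch)] == 1))
  expect_equal(sum(m0), length(ch) - 1)
  # constant channel is degenerate: all-zero mask plus warning
  expect_warning(md <- makeMask(matrix(5, 3, 3), 0.6), "degenerate")
  expect_true(all(md == 0))
  expect_true(attr(md, "degenerate"))
  expect_error(makeMask(ch, tau = 1.2), "tau")
})

test_that("masks are nested in the threshold", {
  set.seed(16)
  for (i in 1:100) {
    ch <- matrix(rnorm(64), 8, 8)
    taus <- sort(runif(2, 0.05, 0.95))
    hi <- makeMask(ch, taus[2])
    lo <- makeMask(ch, taus[1])
    expect_true(all(lo[hi == 1] == 1))  # positives(tau2) subset positives(tau1)
  }
})

test_that("mask-to-box returns the largest 8-connected component", {
  m <- matrix(0, 8, 8)
  m[4, 6] <- 1  # single pixel at row 4, col 6 -> box [5,6) x [3,4)
  b <- maskToBox(m)
  expect_equal(unclass(b), c(x0 = 5, y0 = 3, x1 = 6, y1 = 4))

  # two components, sizes 6 and 2: the larger one wins
  m2 <- matrix(0, 8, 8)
  m2[2:3, 2:4] <- 1          # 6 pixels
  m2[7, 7:8] <- 1            # 2 pixels
  b2 <- maskToBox(m2)
  expect_equal(unclass(b2), c(x0 = 1, y0 = 1, x1 = 4, y1 = 3))

  # diagonal touching counts as connected (8-connectivity)
  m3 <- matrix(0, 4, 4)
  m3[1, 1] <- 1; m3[2, 2] <- 1; m3[3, 3] <- 1
  b3 <- maskToBox(m3)
  expect_equal(unclass(b3), c(x0 = 0, y0 = 0, x1 = 3, y1 = 3))

  expect_null(maskToBox(matrix(0, 4, 4)))
})

test_that("mask-to-box matches a flood-fill oracle on random blob masks", {
  set.seed(17)
  for (i in 1:25) {
    m <- matrix(rbinom(100, 1, 0.3), 10, 10)
    if (!any(m > 0)) next
    expect_equal(unclass(maskToBox(m)), bruteLargestComponentBox(m) * 1,
                 info = sprintf("case %d", i))
  }
})

test_that("a single activation bump is localized for every threshold", {
  set.seed(18)
  for (i in 1:10) {
    cy <- sample(4:9, 1); cx <- sample(4:9, 1)
    A <- bumpMap(12, 12, matrix(c(cy, cx), 1), heights = 1, sd = 2)
    for (tau in seq(0.3, 0.9, by = 0.1)) {
      b <- maskToBox(makeMask(A, tau))
      expect_true(b[["x0"]] <= cx - 1 && cx - 1 < b[["x1"]] &&
                    b[["y0"]] <= cy - 1 && cy - 1 < b[["y1"]])
    }
  }
})

test_that("crop-and-resize handles identity, constants and bilinear weights", {
  set.seed(19)
  img <- matrix(runif(64), 8, 8)
  full <- roiBox(0, 0, 8, 8)
  expect_equal(cropAndResize(img, full, outSize = c(8, 8)), img)
  cst <- cropAndResize(matrix(0.4, 8, 8), roiBox(1, 1, 7, 7),
                       outSize = c(16, 16))
  expect_true(all(abs(cst - 0.4) < 1e-12))
  # 2x2 checkerboard upsampled 2x: half-pixel-centre bilinear weights 3/4, 1/4
  cb <- matrix(c(1, 0, 0, 1), 2, 2)
  up <- cropAndResize(cb, roiBox(0, 0, 2, 2), outSize = c(4, 4))
  expect_equal(up[2, 2], 0.75 * 0.75 * 1 + 0.25 * 0.25 * 1)  # 0.625
  expect_equal(up[2, 3], 0.75 * 0.25 + 0.25 * 0.75)          # 0.375
  expect_equal(up[1, 1], 1)
  # clamping out-of-bounds boxes warns
  expect_warning(cropAndResize(img, roiBox(4, 4, 12, 12), c(4, 4)),
                 "clamped")
})

test_that("hand location falls back to the whole image on empty masks", {
  A <- array(0, dim = c(6, 6, 240))  # constant channels -> degenerate mask
  p <- rep(1 / 240, 240)
  loc <- locateHand(A, p, imageSize = c(96, 96))
  expect_true(loc$fallback)
  expect_equal(unclass(loc$box), c(x0 = 0, y0 = 0, x1 = 96, y1 = 96))
})
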