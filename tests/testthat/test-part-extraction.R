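test_that("min-max normalization maps to [0,1] with degenerate convention", {
  expect_equal(minmaxNormalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(minmaxNormalize(c(5, 5, 5)), c(0, 0, 0))
  set.seed(21)
  x <- matrix(rnorm(30), 5, 6)
  z <- minmaxNormalize(x)
  expect_equal(range(z), c(0, 1))
  expect_error(minmaxNormalize(numeric(0)), "empty")
})

test_that("stretching sharpens peaks without moving them", {
  set.seed(22)
  A <- bumpMap(10, 10, matrix(c(4, 7), 1), heights = 1, sd = 2) +
    matrix(rnorm(100, sd = 0.01), 10, 10)
  S <- stretchMap(A, eta = 4)
  expect_equal(which.max(S), which.max(A))
  expect_equal(attr(S, "eta"), 4)
  # hand-evaluated formula on a 3-value map
  S3 <- stretchMap(matrix(c(0, 0.5, 1), 1, 3), eta = 2)
  expect_equal(as.numeric(S3), c(0, (exp(1) - 1) / (exp(2) - 1), 1),
               tolerance = 1e-12)
  # mid values sink as eta grows (contrast monotonicity)
  mids <- vapply(c(1, 2, 4, 8), function(eta)
    stretchMap(matrix(c(0, 0.5, 1), 1, 3), eta)[1, 2], numeric(1))
  expect_true(all(diff(mids) < 0))
  expect_error(stretchMap(A, eta = 0), "eta")
})

test_that("anchors are centred boxes of the configured shapes", {
  cfg <- anchorConfig(ratios = 1, scales = 128, stride = 192)
  a <- generateAnchors(c(576, 576), cfg)
  centre <- a[a$cx == 288 & a$cy == 288, ]
  expect_equal(nrow(centre), 1)
  expect_equal(as.numeric(centre[1, c("x0", "y0", "x1", "y1")]),
               c(224, 224, 352, 352))

  # each interior lattice point carries 3 ratios x 5 scales = 15 anchors
  all15 <- generateAnchors(c(576, 576), anchorConfig(stride = 192),
                           filterBoundary = FALSE)
  expect_equal(sum(all15$cx == 288 & all15$cy == 288), 15)

  # boundary anchors are discarded, never clipped
  filt <- generateAnchors(c(576, 576), anchorConfig(stride = 192))
  expect_true(all(filt$x0 >= 0 & filt$y0 >= 0 &
                    filt$x1 <= 576 & filt$y1 <= 576))
  expect_lt(nrow(filt), nrow(all15))
})

test_that("summed-area scoring equals the brute-force mean", {
  # exact half/half and all-ones cases
  S <- matrix(0, 4, 8); S[, 1:4] <- 1
  b <- data.frame(x0 = 0, y0 = 0, x1 = 8, y1 = 4)
  expect_equal(scoreRegions(S, b)$score, 0.5)
  expect_equal(scoreRegions(matrix(1, 4, 4),
                            data.frame(x0 = 1, y0 = 1, x1 = 3, y1 = 3))$score, 1)

  set.seed(23)
  for (rep in 1:4) {
    S <- matrix(runif(30 * 40), 30, 40)
    x0 <- sample(0:35, 25, replace = TRUE)
    y0 <- sample(0:25, 25, replace = TRUE)
    boxes <- data.frame(x0 = x0, y0 = y0,
                        x1 = x0 + sample(1:5, 25, replace = TRUE),
                        y1 = y0 + sample(1:5, 25, replace = TRUE))
    got <- scoreRegions(S, boxes)$score
    expect_equal(got, bruteScore(S, boxes), tolerance = 1e-6)
  }
  expect_error(scoreRegions(S, data.frame(x0 = 0, y0 = 0, x1 = 0, y1 = 2)),
               "empty box")
  expect_error(scoreRegions(S, data.frame(x0 = 0, y0 = 0, x1 = 99, y1 = 2)),
               "within the map")
})

test_that("greedy NMS matches an exhaustive reference", {
  # identical boxes: only the best survives
  two <- data.frame(x0 = c(0, 0), y0 = c(0, 0), x1 = c(4, 4), y1 = c(4, 4),
                    score = c(0.9, 0.8))
  kept <- nmsRegions(two, 0.5)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$score, 0.9)
  # disjoint boxes all survive, sorted by score
  dis <- data.frame(x0 = c(0, 10, 20), y0 = 0, x1 = c(4, 14, 24), y1 = 4,
                    score = c(0.2, 0.9, 0.5))
  expect_equal(nmsRegions(dis, 0.25)$score, c(0.9, 0.5, 0.2))

  set.seed(24)
  for (rep in 1:20) {
    n <- sample(5:20, 1)
    x0 <- sample(0:30, n, replace = TRUE)
    y0 <- sample(0:30, n, replace = TRUE)
    r <- data.frame(x0 = x0, y0 = y0,
                    x1 = x0 + sample(2:10, n, replace = TRUE),
                    y1 = y0 + sample(2:10, n, replace = TRUE),
                    score = round(runif(n), 2))
    thr <- runif(1, 0.1, 0.6)
    got <- nmsRegions(r, thr)
    ref <- bruteNMS(r, thr)
    expect_equal(got[, c("x0", "y0", "x1", "y1", "score")],
                 ref[, c("x0", "y0", "x1", "y1", "score")],
                 ignore_attr = TRUE, info = sprintf("rep %d", rep))
    # antichain: no two kept boxes exceed the threshold pairwise
    if (nrow(got) > 1) {
      for (i in 1:(nrow(got) - 1)) for (j in (i + 1):nrow(got)) {
        iou <- boxIoU(roiBox(got$x0[i], got$y0[i], got$x1[i], got$y1[i]),
                      roiBox(got$x0[j], got$y0[j], got$x1[j], got$y1[j]))
        expect_lte(iou, thr)
      }
    }
  }
})

test_that("top-N keeps the highest survivors with non-increasing scores", {
  r <- data.frame(x0 = seq(0, 40, 10), y0 = 0, x1 = seq(4, 44, 10), y1 = 4,
                  score = c(0.5, 0.9, 0.7, 0.9, 0.1))
  kept <- topNParts(nmsRegions(r, 0.25), 3)
  expect_equal(nrow(kept), 3)
  expect_true(all(diff(kept$score) <= 0))
  # tie at 0.9: the earlier input row comes first
  expect_equal(kept$x0[1:2], c(10, 30))
  short <- topNParts(nmsRegions(r[1:2, ], 0.25), 4)
  expect_true(attr(short, "shortfall"))
  expect_equal(nrow(short), 2)
})

test_that("part crops have the requested size and count", {
  img <- matrix(0.3, 96, 96)
  r <- data.frame(x0 = c(0, 40), y0 = c(0, 40), x1 = c(32, 80),
                  y1 = c(32, 80), score = c(0.9, 0.8))
  parts <- extractParts(img, r, partSize = c(48, 48))
  expect_length(parts, 2)
  for (p in parts) {
    expect_equal(dim(p), c(48, 48))
    expect_true(all(abs(p - 0.3) < 1e-12))
  }
})

test_that("peak-centred boxes outscore offset boxes after stretching", {
  set.seed(26)
  for (rep in 1:10) {
    tallCy <- sample(20:40, 1); tallCx <- sample(20:40, 1)
    # second, smaller bump well away from the first
    smallCy <- ((tallCy + 30 - 1) %% 60) + 1
    smallCx <- ((tallCx + 30 - 1) %% 60) + 1
    A <- bumpMap(64, 64, rbind(c(tallCy, tallCx), c(smallCy, smallCx)),
                 heights = c(1, 0.6), sd = 4)
    for (eta in c(2, 4, 8)) {
      S <- stretchMap(A, eta)
      side <- 12
      mk <- function(cy, cx) data.frame(
        x0 = max(0, cx - side / 2), y0 = max(0, cy - side / 2),
        x1 = min(64, cx + side / 2), y1 = min(64, cy + side / 2))
      peakScore <- scoreRegions(S, mk(tallCy, tallCx))$score
      offsets <- expand.grid(dy = c(-side, 0, side), dx = c(-side, 0, side))
      offsets <- offsets[!(offsets$dy == 0 & offsets$dx == 0), ]
      for (k in seq_len(nrow(offsets))) {
        cy <- tallCy + offsets$dy[k]; cx <- tallCx + offsets$dx[k]
        if (cy - side / 2 < 0 || cx - side / 2 < 0 ||
            cy + side / 2 > 64 || cx + side / 2 > 64) next
        expect_gt(peakScore, scoreRegions(S, mk(cy, cx))$score)
      }
    }
  }
})

test_that("the proposal pipeline is deterministic", {
  set.seed(27)
  A <- matrix(runif(96 * 96), 96, 96)
  run <- function() {
    S <- stretchMap(A, 4)
    cfg <- anchorConfig(scales = c(24, 32, 48), stride = 16)
    topNParts(nmsRegions(scoreRegions(S, generateAnchors(dim(S), cfg)),
                         0.25), 4)
  }
  expect_identical(run(), run())
})
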