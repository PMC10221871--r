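randProbs <- function(n, C = 240) {
  m <- matrix(rexp(n * C), n, C)
  m / rowSums(m)
}

test_that("KL loss is zero at the target, log C against uniform, never negative", {
  Y <- labelProbs(makeDistribution(100, 3))
  expect_equal(klLoss(Y, Y), 0)
  onehot <- replace(numeric(240), 77, 1)
  expect_equal(klLoss(onehot, rep(1 / 240, 240)), log(240), tolerance = 1e-12)
  set.seed(31)
  for (i in 1:100) {
    p <- randProbs(1); q <- randProbs(1)
    expect_gte(klLoss(p, q), 0)
  }
  expect_error(klLoss(Y, Y[1:10]), "identical shapes")
})

test_that("L1 loss matches its definition", {
  Y <- randProbs(3)
  expect_equal(maeLoss(Y, Y), 0)
  a <- replace(numeric(240), 5, 1)
  b <- replace(numeric(240), 200, 1)
  expect_equal(maeLoss(a, b), 2)  # total-variation extreme
  set.seed(32)
  P <- randProbs(6); Q <- randProbs(6)
  naive <- mean(sapply(1:6, function(i) sum(abs(P[i, ] - Q[i, ]))))
  expect_equal(maeLoss(P, Q), naive, tolerance = 1e-12)
})

test_that("temporal loss shares the KL kernel and skips zero-init targets", {
  set.seed(33)
  Ybar <- randProbs(4); Yhat <- randProbs(4)
  expect_identical(as.numeric(temporalLoss(Ybar, Yhat)),
                   klLoss(Ybar, Yhat))
  expect_equal(as.numeric(temporalLoss(Yhat, Yhat)), 0)
  # rows still at the zero initialization are excluded and counted
  Ybar0 <- Ybar; Ybar0[2, ] <- 0
  tl <- temporalLoss(Ybar0, Yhat)
  expect_equal(attr(tl, "nExcluded"), 1)
  expect_equal(as.numeric(tl),
               klLoss(Ybar[-2, , drop = FALSE], Yhat[-2, , drop = FALSE]))
  allZero <- temporalLoss(Ybar * 0, Yhat)
  expect_equal(as.numeric(allZero), 0)
  expect_equal(attr(allZero, "nExcluded"), 4)
})

test_that("bias-corrected EMA reproduces a constant prediction stream exactly", {
  P <- matrix(labelProbs(makeDistribution(90, 3)), 1)
  st <- ensembleState(1, gamma = 0.6)
  for (t in 1:20) {
    up <- emaUpdate(st, P)
    st <- up$state
    expect_equal(st@epoch, t)
    expect_lt(max(abs(up$target - P)), 1e-12)
  }
})

test_that("EMA limits and normalization behave", {
  set.seed(34)
  # gamma -> 0: the target is the latest prediction
  st <- ensembleState(2, gamma = 1e-12)
  Yhat <- randProbs(2)
  expect_equal(emaUpdate(st, Yhat)$target, Yhat, tolerance = 1e-9)
  # targets stay probability vectors across random epochs
  st <- ensembleState(3, gamma = 0.6)
  for (t in 1:10) {
    up <- emaUpdate(st, randProbs(3))
    st <- up$state
    expect_equal(rowSums(up$target), rep(1, 3), tolerance = 1e-9)
  }
})

test_that("the ramp weight rises from Tmax exp(-5) to Tmax", {
  sch <- rampSchedule(tMax = 2, rampLength = 10)
  expect_equal(rampWeight(0, sch), 2 * exp(-5))
  expect_equal(rampWeight(10, sch), 2)
  expect_equal(rampWeight(25, sch), 2)  # saturates beyond the ramp
  w <- vapply(0:10, rampWeight, numeric(1), schedule = sch)
  expect_true(all(diff(w) > 0))
})

test_that("branch and total losses compose additively", {
  Y <- labelProbs(makeDistribution(120, 3))
  expect_equal(branchLoss(Y, Y, Ybar = Y, weight = 1), 0)
  set.seed(35)
  Yhat <- randProbs(1)[1, ]
  # no ensembling: independent of the assembled target
  expect_equal(branchLoss(Y, Yhat, Ybar = NULL, useEnsembling = FALSE),
               klLoss(Y, Yhat) + maeLoss(Y, Yhat))
  expect_equal(branchLoss(Y, Yhat, Ybar = Y, weight = 0),
               klLoss(Y, Yhat) + maeLoss(Y, Yhat))

  parts <- list(randProbs(1)[1, ], randProbs(1)[1, ])
  outputs <- list(raw = randProbs(1)[1, ], hand = randProbs(1)[1, ],
                  parts = parts)
  ybar <- randProbs(1)[1, ]
  tot <- totalLoss(outputs, Y, ybarRaw = ybar, ybarHand = ybar, weight = 0.5)
  manual <- branchLoss(Y, outputs$raw, ybar, 0.5) +
    branchLoss(Y, outputs$hand, ybar, 0.5) +
    mean(c(branchLoss(Y, parts[[1]], useEnsembling = FALSE),
           branchLoss(Y, parts[[2]], useEnsembling = FALSE)))
  expect_equal(as.numeric(tot), manual, tolerance = 1e-12)
  expect_gt(as.numeric(tot), 0)
  # perfect predictions everywhere vanish
  perfect <- list(raw = Y, hand = Y, parts = list(Y, Y))
  expect_equal(as.numeric(totalLoss(perfect, Y, Y, Y, weight = 1)), 0)
})

test_that("the KL gradient matches finite differences on a 5-bin toy", {
  y <- c(0.1, 0.2, 0.4, 0.2, 0.1)
  q <- c(0.3, 0.1, 0.2, 0.25, 0.15)
  analytic <- -y / q  # m = 1
  for (j in 1:5) {
    eps <- 1e-6
    qp <- q; qp[j] <- qp[j] + eps
    fd <- (klLoss(y, qp) - klLoss(y, q)) / eps
    expect_lt(abs(fd - analytic[j]), 1e-4)
  }
})
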