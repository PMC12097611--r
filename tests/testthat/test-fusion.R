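test_that("linear evidence projector separates, zeroes the boundary and is
           duplication invariant", {
  set.seed(10)
  x <- matrix(c(rnorm(20, -2), rnorm(20, 2)))
  y <- rep(c("a", "b"), each = 20)
  m <- fitEvidenceProjector(x, y, classOrder = c("b", "a"))
  s <- projectEvidence(m, x)
  expect_true(all(sign(s) == ifelse(y == "b", 1, -1)))
  # a point on the decision boundary scores 0
  b <- -m@bias / m@weights * m@scale + m@center
  expect_lt(abs(projectEvidence(m, matrix(b, 1))), 1e-9)
  # duplicating every training point leaves the projector unchanged
  md <- fitEvidenceProjector(rbind(x, x), c(y, y), classOrder = c("b", "a"))
  expect_equal(md@weights, m@weights, tolerance = 1e-4)
  expect_equal(md@bias, m@bias, tolerance = 1e-4)
  expect_error(fitEvidenceProjector(x, rep("a", 40)), "2 classes")
  # lda backend orients positive class positive too
  ml <- fitEvidenceProjector(cbind(x, rnorm(40)), y, backend = "lda",
                             classOrder = c("b", "a"))
  sl <- projectEvidence(ml, cbind(x, rnorm(40)))
  expect_gt(mean(sl[y == "b"]), mean(sl[y == "a"]))
})

test_that("Scott's rule bandwidth follows its closed form", {
  set.seed(11)
  s <- rnorm(32); s <- (s - mean(s)) / sd(s)  # unit sample sd
  expect_equal(scottBandwidth(s), 32^(-0.2))
  expect_equal(scottBandwidth(5 * s), 5 * 32^(-0.2))
  s4 <- rep(s, 4); s4 <- (s4 - mean(s4)) / sd(s4)  # same sigma-hat, 4n
  expect_equal(scottBandwidth(s4) / scottBandwidth(s), 4^(-0.2),
               tolerance = 1e-12)
  expect_error(scottBandwidth(rep(1, 10)), "zero spread")
  expect_error(scottBandwidth(1), ">= 2")
})

test_that("KDE evaluation matches the Gaussian mixture form", {
  d <- new("ClassConditionalDensity", supportPoints = c(2, 2),
           bandwidth = 0.7, classTag = "a")
  xs <- seq(-1, 5, by = 0.5)
  expect_equal(kdeDensity(d, xs), dnorm(xs, 2, 0.7))
  set.seed(12)
  d2 <- fitClassDensity(rnorm(40), "a")
  # integrates to 1
  grid <- seq(-10, 10, length.out = 4001)
  expect_equal(sum(kdeDensity(d2, grid)) * diff(grid[1:2]), 1,
               tolerance = 1e-3)
  # symmetric support -> symmetric density
  d3 <- fitClassDensity(c(-2, -1, 1, 2), "a")
  expect_equal(kdeDensity(d3, 1.3), kdeDensity(d3, -1.3))
  # far tail floored, never zero or -Inf in log space
  expect_gte(kdeDensity(d3, 1e6), 1e-300)
})

test_that("fused decision reduces to single modalities at alpha 0/1 and
           matches the analytic Gaussian Bayes rule", {
  set.seed(13)
  n <- 400
  y <- rep(c("a", "b"), each = n / 2)
  e <- c(rnorm(n / 2, 1), rnorm(n / 2, -1))
  f <- c(rnorm(n / 2, 1), rnorm(n / 2, -1))
  m <- fitFusionModel(e, f, y, alpha = 0.5)
  te <- seq(-3, 3, by = 0.1); tf <- rev(te)
  d1 <- fuseDecide(te, tf, m, alpha = 1)
  eOnly <- ifelse(bcifuse:::logKde(m@eegDensities$pos, te) >=
                  bcifuse:::logKde(m@eegDensities$neg, te), "a", "b")
  expect_identical(d1$class, eOnly)
  d0 <- fuseDecide(te, tf, m, alpha = 0)
  fOnly <- ifelse(bcifuse:::logKde(m@ftcdDensities$pos, tf) >=
                  bcifuse:::logKde(m@ftcdDensities$neg, tf), "a", "b")
  expect_identical(d0$class, fOnly)
  # closed-form check: standard Gaussians at +/-1 means, e = f = 0.6
  # Bayes log ratio = e + f > 0 -> positive class
  dd <- fuseDecide(0.6, 0.6, m, alpha = 0.5)
  expect_identical(dd$class, "a")
  expect_gt(dd$logRatio, 0)
})

test_that("alpha grid search has 101 candidates and tie-breaks to smallest", {
  set.seed(14)
  y <- rep(c("a", "b"), each = 30)
  e <- c(rnorm(30, 2), rnorm(30, -2))
  res <- alphaGridSearch(e, e, y, e, e, y)   # identical streams
  expect_equal(nrow(res$curve), 101)
  expect_equal(res$curve$alpha, seq(0, 1, 0.01))
  # identical modalities: flat curve, tie-break returns alpha = 0
  expect_true(all(res$curve$accuracy == res$curve$accuracy[1]))
  expect_equal(res$bestAlpha, 0)
  expect_error(alphaGridSearch(e, e, y, numeric(0), numeric(0), character(0)),
               "empty validation")
  # endpoints equal the single-modality accuracies; max >= both
  w <- pairedFeatureWorld(30, 30, 10, 10, 1.2, 0.8)
  r2 <- alphaSearchOnWorld(w)
  co <- r2$model@classOrder
  accEEG <- r2$curve$accuracy[r2$curve$alpha == 1]
  accFTCD <- r2$curve$accuracy[r2$curve$alpha == 0]
  expect_gte(r2$bestAccuracy, max(accEEG, accFTCD))
})

test_that("alpha recovery is directional: noise fTCD pushes alpha up", {
  set.seed(15)
  aNoiseF <- replicate(8, alphaSearchOnWorld(
    pairedFeatureWorld(30, 30, 20, 40, 2, 0))$bestAlpha)
  aNoiseE <- replicate(8, alphaSearchOnWorld(
    pairedFeatureWorld(30, 30, 40, 20, 0, 2))$bestAlpha)
  expect_gt(mean(aNoiseF), 0.5)
  expect_lt(mean(aNoiseE), 0.5)
  expect_gt(mean(aNoiseF), mean(aNoiseE) + 0.2)
})

test_that("signed-rank comparison is exact for small n and symmetric", {
  a <- 90 + (1:10) / 3; b <- a - runif(10, 0.5, 2)
  expect_equal(signedRankCompare(a, b, "greater"), 1 / 2^10)
  expect_equal(signedRankCompare(b, a, "less"),
               signedRankCompare(a, b, "greater"))
  expect_error(signedRankCompare(a[1:4], b[1:4]), ">= 5")
  expect_error(signedRankCompare(a, b[1:5]), "unequal")
  expect_warning(p <- signedRankCompare(a, a), "zero")
  expect_equal(p, 1)
})

test_that("alpha median test detects one-sided departures from 0.5", {
  expect_equal(alphaMedianTest(rep(0.9, 10), alternative = "greater"), 1 / 2^10)
  set.seed(16)
  sym <- 0.5 + c(-0.2, -0.1, -0.05, 0.05, 0.1, 0.2)
  expect_gte(alphaMedianTest(sym, alternative = "greater"), 0.5)
  expect_error(alphaMedianTest(c(0.4, 0.6, 0.7)), ">= 5")
  expect_warning(p <- alphaMedianTest(rep(0.5, 8)), "null median")
  expect_equal(p, 1)
  # rank-sum backend is available and directionally consistent
  p2 <- alphaMedianTest(rep(0.9, 10), alternative = "greater",
                        backend = "rank-sum")
  expect_lt(p2, 0.05)
})
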