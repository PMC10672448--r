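# Water band, MSC, centring, PCA, split, PLS-DA and figures of merit.

test_that("water-band selection retains 1300-1600 nm inclusive", {
  sm <- simulateSpectra(spectraSimConfig(nSamples = 20, seed = 1))
  wb <- selectWaterBand(sm)
  expect_identical(wavelengths(wb), 1300:1600)
  # idempotence on an already-restricted grid
  expect_identical(spectraValues(selectWaterBand(wb)), spectraValues(wb))
  # a grid not covering the band errors
  narrow <- SpectraMatrix(matrix(0.5, 2, 101), 1400:1500)
  expect_error(selectWaterBand(narrow), "does not cover")
})

test_that("MSC inverts the affine scatter model exactly", {
  ref <- 0.5 + 0.2 * sin(seq(0, 3, length.out = 50))
  X <- rbind(ref, 2 * ref + 3)
  rownames(X) <- c("s1", "s2")
  out <- mscFitTransform(X, reference = ref)
  expect_equal(out$corrected[1, ], ref, ignore_attr = TRUE)
  expect_equal(out$corrected[2, ], ref, ignore_attr = TRUE,
               tolerance = 1e-12)

  # constant spectrum has slope ~0 and is reported by id
  bad <- rbind(s1 = ref, flat = rep(1, 50))
  expect_error(mscApply(bad, out$state), "flat")

  # post-MSC, refitting the affine model against the reference gives
  # a = 0, b = 1 for generator spectra with real scatter
  sm <- simulateSpectra(spectraSimConfig(nSamples = 20, scatterSd = 0.2,
                                         offsetSd = 0.05, noiseSd = 0,
                                         seed = 3))
  V <- spectraValues(selectWaterBand(sm))
  msc <- mscFitTransform(V)
  refm <- msc$state@mscReference
  for (i in c(1, 7, 20)) {
    fit <- lm(msc$corrected[i, ] ~ refm)
    expect_equal(unname(coef(fit)), c(0, 1), tolerance = 1e-8)
  }
})

test_that("mean centring uses training means for test data", {
  set.seed(4)
  tr <- matrix(rnorm(30), 5)
  te <- matrix(rnorm(12), 2)
  ctr <- meanCenter(tr)
  expect_equal(unname(colMeans(ctr)), rep(0, 6), tolerance = 1e-10)
  m <- attr(ctr, "columnMeans")
  cte <- meanCenter(te, m)
  expect_equal(cte, sweep(te, 2, m), tolerance = 1e-14, ignore_attr = TRUE)
  # constant column centres to zero
  expect_equal(meanCenter(matrix(5, 3, 2)), matrix(0, 3, 2),
               ignore_attr = TRUE)
  expect_error(meanCenter(tr, 1:3), "length")
})

test_that("PCA matches the covariance eigendecomposition oracle", {
  set.seed(6)
  X <- scale(matrix(rnorm(80), 10, 8), scale = FALSE)
  k <- 5
  p <- pcaSpectra(X, k)
  # oracle: eigendecomposition of X'X
  ev <- eigen(crossprod(X), symmetric = TRUE)
  expect_equal(p$explainedVarianceFraction,
               (ev$values / sum(ev$values))[1:k], tolerance = 1e-8)
  for (j in 1:k)
    expect_equal(abs(sum(p$loadings[, j] * ev$vectors[, j])), 1,
                 tolerance = 1e-8)
  # orthonormal loadings, orthogonal scores
  expect_equal(crossprod(p$loadings), diag(k), tolerance = 1e-8)
  G <- crossprod(p$scores)
  expect_equal(G - diag(diag(G)), matrix(0, k, k), tolerance = 1e-8)

  # rank-1 matrix: first component carries all variance
  r1 <- outer(1:6, seq(0.1, 0.8, 0.1))
  r1 <- scale(r1, scale = FALSE)
  p1 <- pcaSpectra(r1, 2)
  expect_equal(p1$explainedVarianceFraction[1], 1, tolerance = 1e-10)
  expect_error(pcaSpectra(X, 9), "exceeds")
})

test_that("train/test splits are exact, disjoint and uniform", {
  s <- makeSplit(195, 58, seed = 5)
  expect_length(s$test, 58)
  expect_length(s$train, 137)
  expect_length(intersect(s$train, s$test), 0)
  expect_setequal(c(s$train, s$test), 1:195)
  expect_identical(makeSplit(195, 58, seed = 5), s)
  expect_error(makeSplit(10, 10), "nTest")

  # membership frequency over many seeds matches the hypergeometric rate
  counts <- integer(195)
  for (sd in 1:2000) counts[makeSplit(195, 58, seed = sd)$test] <-
    counts[makeSplit(195, 58, seed = sd)$test] + 1L
  phat <- counts / 2000
  se <- sqrt((58 / 195) * (1 - 58 / 195) / 2000)
  expect_true(all(abs(phat - 58 / 195) < 3.9 * se))

  # stratified split keeps every class in training
  y <- rep(c("a", "b"), c(4, 191))
  st <- makeSplit(195, 58, seed = 1, stratifyBy = y)
  expect_true(all(c("a", "b") %in% y[st$train]))
})

test_that("PLS-DA separates one-direction data with a single LV", {
  d <- separableSpectra()
  m <- plsdaFit(d$X, d$labels, 1L)
  pr <- plsdaPredict(m, d$X)
  expect_equal(as.character(pr$class), d$labels)
  # a class centroid is assigned to its class
  cen <- colMeans(d$X[d$labels == "beta", , drop = FALSE])
  expect_equal(as.character(plsdaPredict(m, rbind(cen))$class), "beta")
  cv <- chooseLV(d$X + matrix(rnorm(800, sd = 1e-3), 20), d$labels,
                 maxLV = 5, kFolds = 5, seed = 2)
  expect_equal(cv$nLatent, 1L)
})

test_that("PLS-DA algebra: orthogonal scores, coefficient equivalence,
           collinearity and the least-squares limit", {
  set.seed(8)
  X <- matrix(rnorm(30 * 6), 30)
  y <- rep(c("a", "b", "c"), each = 10)
  m <- plsdaFit(X, y, 4L)
  # X-scores of successive latent variables are orthogonal
  Tm <- sweep(X, 2, m@xMean) %*% m@xWeights %*%
    solve(crossprod(m@xLoadings, m@xWeights))
  G <- crossprod(Tm)
  expect_equal(G - diag(diag(G)), matrix(0, 4, 4), tolerance = 1e-8)

  # coefficient form equals the sequential score form
  Xc <- sweep(X, 2, m@xMean)
  E <- Xc; Tseq <- matrix(0, 30, 4)
  for (a in 1:4) {
    tt <- E %*% m@xWeights[, a]
    Tseq[, a] <- tt
    E <- E - tcrossprod(tt, m@xLoadings[, a])
  }
  fitSeq <- sweep(Tseq %*% t(m@yLoadings), 2, m@yMean, "+")
  expect_equal(unname(fitSeq), unname(m@fitted), tolerance = 1e-8)

  # duplicated X columns leave fitted class scores unchanged
  m2 <- plsdaFit(cbind(X, X), y, 4L)
  expect_equal(unname(m2@fitted), unname(m@fitted), tolerance = 1e-8)

  # with all min(n-1, p) components, fitted values equal least squares
  mFull <- plsdaFit(X, y, 6L)
  Y <- cbind(a = as.numeric(y == "a"), b = as.numeric(y == "b"),
             c = as.numeric(y == "c"))
  ols <- lm.fit(cbind(1, X), Y)
  expect_equal(unname(mFull@fitted), unname(ols$fitted.values),
               tolerance = 1e-8)

  expect_error(plsdaFit(X, rep("a", 30), 2L), "2 classes")
})

test_that("prediction ties resolve to the lexicographically first class", {
  sc <- rbind(c(0.5, 0.5), c(0.2, 0.7))
  cls <- epilichen:::.assignClass(sc, c("apothecia", "soredia"))
  expect_equal(as.character(cls), c("apothecia", "soredia"))
  expect_equal(epilichen:::.pickLV(c(0.3, 0.1, 0.1, 0.2)), 2L)
})

test_that("cross-validation selection guards folds and reports a curve", {
  d <- separableSpectra(n = 24)
  X <- d$X + matrix(rnorm(24 * 40, sd = 0.01), 24)
  cv <- chooseLV(X, d$labels, maxLV = 4, kFolds = 4, seed = 3)
  expect_equal(nrow(cv$curve), 4)
  expect_true(all(cv$curve$cv_error >= 0 & cv$curve$cv_error <= 1))
  # venetian blinds on an alternating class layout loses a class from a
  # fold's training half
  o <- order(rep(1:12, 2))  # a, b, a, b, ...
  expect_error(chooseLV(X[o, ], d$labels[o], maxLV = 2, kFolds = 2,
                        scheme = "venetian", seed = 1),
               "stratif")
})

test_that("class metrics reproduce confusion-count arithmetic", {
  perfect <- classMetrics(c("a", "a", "b"), c("a", "a", "b"), "a")
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$error, 0)

  true <- rep(c("a", "b"), c(10, 10))
  pred <- c(rep("a", 9), "b", rep("b", 8), "a", "a")
  m <- classMetrics(true, pred, "a")
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$error, 0.15)

  expect_error(classMetrics(c("a", "a"), c("a", "b"), "z"), "absent")
})

test_that("the full experiment is reproducible and Table-1 shaped", {
  sm <- simulateSpectra(spectraSimConfig(nSamples = 60, seed = 10))
  ex1 <- runPLSDAExperiment(sm, "growth_form", nTest = 18, kFolds = 5,
                            maxLV = 5, seed = 20)
  ex2 <- runPLSDAExperiment(sm, "growth_form", nTest = 18, kFolds = 5,
                            maxLV = 5, seed = 20)
  expect_identical(metricsTable(ex1), metricsTable(ex2))
  m <- ex1$metrics
  # one row per class per phase
  expect_equal(nrow(m), 4)
  expect_setequal(m$phase, c("cv", "prediction"))
  expect_setequal(m$class, c("foliose", "fruticose"))
  expect_error(runPLSDAExperiment(sm, "not_a_field"), "label field")
})

test_that("our PLS-DA agrees with an independent implementation", {
  set.seed(12)
  d <- separableSpectra(n = 30, p = 25)
  X <- d$X + matrix(rnorm(30 * 25, sd = 0.05), 30)
  colnames(X) <- sprintf("w%02d", 1:25)
  Xte <- d$X[c(3, 18), ] + rnorm(50, sd = 0.05)
  colnames(Xte) <- colnames(X)
  m <- plsdaFit(X, d$labels, 2L)
  ours <- as.character(plsdaPredict(m, Xte)$class)
  mo <- mixOmics::plsda(X, factor(d$labels), ncomp = 2, scale = FALSE)
  theirs <- as.character(predict(mo, Xte, dist = "max.dist")$class$max.dist[, 2])
  expect_equal(ours, theirs)
})
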