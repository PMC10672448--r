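# IAP, campaign comparisons, dissimilarity, ordination and trait models.

test_that("tree and station IAP follow the sum and mean definitions", {
  expect_equal(iapTree(c(3, 7, 10)), 20)
  expect_equal(iapTree(numeric(0)), 0)
  expect_equal(iapTree(10), 10)

  r <- iapStation(c(t1 = 10, t2 = 20))
  expect_equal(r$station_value, 15)
  expect_equal(r$n_trees, 2)
  r1 <- iapStation(7)
  expect_equal(r1$station_value, 7)
  expect_equal(r1$n_trees, 1)
  expect_error(iapStation(numeric(0)), "at least one tree")

  # mean idempotence: identical trees give the common tree value
  expect_equal(iapStation(rep(12, 5))$station_value, 12)
  # adding a frequency-0 species leaves the tree IAP unchanged
  expect_equal(iapTree(c(3, 7, 0)), iapTree(c(3, 7)))
})

test_that("station IAP recovers the binomial expectation of the generator", {
  pool <- makeSpeciesPool(8, seed = 4)
  pool$base_occupancy <- 0.4
  pool$year_effect <- 0
  s <- simulateSurvey(communitySimConfig(nStations = 1,
                                         treesPerStation = 50,
                                         speciesPool = pool,
                                         stationEffectSd = 0, seed = 12))
  r <- iapStation(s[s$year == 1997, ])
  # tree IAP ~ sum of 8 Binomial(10, .4): mean 32, var 8*10*.4*.6 = 19.2
  se <- sqrt(8 * 10 * 0.4 * 0.6 / 50)
  expect_lt(abs(r$station_value - 32), 3 * se)
})

test_that("pooled t test matches the closed form and its symmetries", {
  r <- compareYears(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t, -3.674235, tolerance = 1e-6)
  expect_equal(r$df, 4)
  expect_equal(r$p, 2 * pt(-abs(r$t), 4), tolerance = 1e-12)

  same <- compareYears(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  swapped <- compareYears(c(4, 5, 6), c(1, 2, 3))
  expect_equal(swapped$t, -r$t)
  expect_equal(swapped$p, r$p)

  expect_error(compareYears(1, c(1, 2)), "at least 2")

  # textbook-formula oracle on random inputs
  set.seed(77)
  for (i in 1:25) {
    x <- rnorm(sample(2:12, 1)); y <- rnorm(sample(2:12, 1), mean = runif(1))
    n1 <- length(x); n2 <- length(y)
    sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
    tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    r <- compareYears(x, y)
    expect_equal(r$t, tt, tolerance = 1e-10)
    expect_equal(r$p, 2 * pt(-abs(tt), n1 + n2 - 2), tolerance = 1e-10)
  }
})

test_that("frequency change is the difference of means over shared trees", {
  s <- tinySurvey()  # station A: tree A_t1 y1997, A_t2 y2022 only -> no pair
  # build a paired design: two trees sampled in both years at one station
  sp <- data.frame(
    station_id = "A",
    tree_id = rep(c("A_t1", "A_t2"), each = 4),
    year = rep(c(1997L, 2022L), 4),
    species = rep(rep(c("Sp one", "Sp two"), each = 2), 2),
    frequency = c(8L, 2L, 8L, 2L, 8L, 2L, 8L, 2L),
    stringsAsFactors = FALSE)
  fc <- frequencyChange(sp, 1997, 2022)
  expect_equal(fc["Sp one", "A"], -6)
  expect_equal(fc["Sp two", "A"], -6)
  expect_true(all(fc >= -10 & fc <= 10, na.rm = TRUE))
  # paired differencing agrees on this balanced design
  expect_equal(frequencyChange(sp, 1997, 2022, paired = TRUE), fc)
  expect_error(frequencyChange(sp, 1997, 2010), "2010")
})

test_that("species absent in both campaigns are not_observed (NA)", {
  sp <- data.frame(station_id = c("A", "A", "B", "B"),
                   tree_id = c("A_t1", "A_t1", "B_t1", "B_t1"),
                   year = c(1997L, 2022L, 1997L, 2022L),
                   species = c("Sp one", "Sp one", "Sp two", "Sp two"),
                   frequency = c(5L, 3L, 4L, 6L), stringsAsFactors = FALSE)
  fc <- frequencyChange(sp, 1997, 2022)
  expect_true(is.na(fc["Sp two", "A"]))
  expect_equal(fc["Sp one", "A"], -2)
  expect_equal(fc["Sp two", "B"], 2)
})

test_that("imposed frequency-change signs are recovered across species", {
  pool <- makeSpeciesPool(20, eutrophSlope = 0, seed = 8)
  pool$base_occupancy <- 0.4
  pool$year_effect <- rep(c(1.2, -1.2), 10)
  s <- simulateSurvey(communitySimConfig(nStations = 1,
                                         treesPerStation = 20,
                                         speciesPool = pool,
                                         stationEffectSd = 0, seed = 13))
  fc <- frequencyChange(s, 1997, 2022)
  signs <- sign(fc[pool$species, 1])
  agree <- mean(signs == sign(pool$year_effect), na.rm = TRUE)
  expect_gte(agree, 0.9)
})

test_that("Bray-Curtis dissimilarity satisfies its definition and bounds", {
  expect_equal(brayCurtis(c(2, 1, 0), c(1, 1, 1)), 1 / 3)
  expect_equal(brayCurtis(c(3, 1), c(3, 1)), 0)
  expect_equal(brayCurtis(c(2, 0), c(0, 5)), 1)
  expect_error(brayCurtis(c(0, 0), c(0, 0)), "all-zero")

  set.seed(5)
  for (i in 1:50) {
    a <- rpois(6, 3); b <- rpois(6, 3)
    if (sum(a) + sum(b) == 0) next
    d <- brayCurtis(a, b)
    expect_equal(d, brayCurtis(b, a))
    expect_gte(d, 0); expect_lte(d, 1)
  }
})

test_that("NMDS embeds exact configurations and is rank-invariant", {
  set.seed(3)
  pts <- matrix(rnorm(24), 12, 2)
  d <- as.matrix(dist(pts))
  ord <- suppressWarnings(nmdsOrdination(d, k = 2, nRestarts = 5, seed = 4))
  expect_lt(ord$stress, 0.01)
  expect_equal(dim(ord$coordinates), c(12L, 2L))

  ord2 <- suppressWarnings(nmdsOrdination(2 * d, k = 2, nRestarts = 5,
                                          seed = 4))
  expect_lt(abs(ord$stress - ord2$stress), 1e-6)

  two <- nmdsOrdination(matrix(c(0, 3, 3, 0), 2), seed = 1)
  expect_equal(two$stress, 0)

  asym <- matrix(c(0, 1, 2, 0), 2)
  expect_error(nmdsOrdination(asym), "symmetric")
})

test_that("trait regression and ANOVA match hand computations", {
  r <- traitEffect(c(2, 4, 6, 8), c(1, 2, 3, 4), "lin")
  expect_equal(r$pearson_r, 1)
  expect_equal(r$slope, 2)
  expect_lt(r$p_value, 1e-6)
  expect_gt(r$p_value, 0)
  expect_error(traitEffect(c(1, 2, 3), c(2, 2, 2)), "zero variance")

  a <- traitAnova(c(1, 2, 3, 4, 5, 6), rep(c("g1", "g2"), each = 3))
  expect_equal(a$F, 13.5)
  expect_equal(c(a$df1, a$df2), c(1, 4))

  flat <- traitAnova(rep(2, 6), rep(c("g1", "g2"), each = 3))
  expect_equal(flat$F, 0)
  expect_equal(flat$p, 1)

  expect_error(traitAnova(1:4, c("a", "a", "a", "b")), "fewer than 2")
})
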