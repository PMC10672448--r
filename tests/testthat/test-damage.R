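# Damage Index assignment, summaries, comparisons and the size check.

test_that("the max rule assigns the Damage Index", {
  expect_equal(assignDI(c(2, 5, 3)), 5L)
  expect_equal(assignDI(integer(0)), 1L)
  expect_equal(assignDI(3), 3L)
  expect_equal(assignDI(c(1, 1)), 1L)  # minimal-damage shares the floor
  expect_error(assignDI(c(2, 6)), "1..5")

  # monotone: adding a symptom never decreases the category
  set.seed(2)
  for (i in 1:30) {
    cats <- sample(1:5, sample(0:4, 1), replace = TRUE)
    extra <- sample(1:5, 1)
    expect_gte(assignDI(c(cats, extra)), assignDI(cats))
    # permutation invariance
    expect_equal(assignDI(sample(c(cats, extra))), assignDI(c(cats, extra)))
  }
})

test_that("affected-fraction breakpoints map to categories 1-5", {
  expect_equal(symptomCategory(c(0, 0.05, 0.1, 0.3, 0.6, 0.9, 1)),
               c(1L, 1L, 2L, 3L, 4L, 5L, 5L))
  expect_error(symptomCategory(1.2), "\\[0, 1\\]")
})

test_that("collapseThalli derives max_di from the symptom rows", {
  th <- collapseThalli(tinyThalliLong())
  expect_equal(nrow(th), 3)
  expect_equal(th$max_di[th$thallus_id == "th1"], 5L)
  expect_equal(th$max_di[th$thallus_id == "th2"], 1L)
  expect_equal(th$max_di[th$thallus_id == "th3"], 3L)
  expect_equal(th$n_symptoms, c(3L, 0L, 1L))
})

test_that("DI summaries report group n, mean and sd", {
  th <- data.frame(station_id = "A", tree_id = "t", year = 1997L,
                   species = "X y", thallus_id = as.character(1:3),
                   size_cm = 5, n_symptoms = 1L, max_di = c(1L, 1L, 5L))
  s <- diSummary(th)
  expect_equal(s$n, 3L)
  expect_equal(s$mean_di, 2.333)

  th$max_di <- 5L
  s5 <- diSummary(th)
  expect_equal(s5$mean_di, 5)
  expect_equal(s5$sd_di, 0)
})

test_that("per-locality DI comparison behaves like the shared t contract", {
  th <- collapseThalli(simulateThalli(damageSimConfig(treesPerStation = 2,
                                                      seed = 6)))
  same <- th[th$year == 1997, ]
  flip <- same; flip$year <- 2022L
  r <- diCompare(rbind(same, flip), 1997, 2022)
  expect_true(all(r$t == 0))
  expect_true(all(r$p == 1))

  # a +1 latent-stress shift is detected with high power at n = 200/group
  mk <- function(mu, yr, seed) damageSimConfig(
    stations = data.frame(station_id = "S", year = yr, mu = mu),
    species = "Parmelia serrana", treesPerStation = 20,
    thalliPerSpeciesPerTree = 10, symptomRate = 0, minSymptoms = 1,
    seed = seed)
  hits <- vapply(1:25, function(i) {
    a <- collapseThalli(simulateThalli(mk(0, 1997L, 100 + i)))
    b <- collapseThalli(simulateThalli(mk(1, 2022L, 200 + i)))
    diCompare(rbind(a, b), 1997, 2022)$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("DI change matrix differences means and orders by |change|", {
  mk <- function(stn, yr, di, n, sp = "Parmelia serrana")
    data.frame(station_id = stn, tree_id = "t", year = yr, species = sp,
               thallus_id = sprintf("%s_%s_%s_%d", stn, yr, sp, seq_len(n)),
               size_cm = 5, n_symptoms = 1L, max_di = as.integer(di))
  th <- rbind(mk("A", 1997L, 2, 10), mk("A", 2022L, 4, 10),
              mk("A", 1997L, 2, 10, "Ramalina farinacea"),
              mk("A", 2022L, 2, 10, "Ramalina farinacea"))
  dc <- diChange(th, 1997, 2022)
  expect_equal(dc["Parmelia serrana", "A"], 2)
  expect_equal(dc["Ramalina farinacea", "A"], 0)
  expect_true(all(dc >= -4 & dc <= 4, na.rm = TRUE))
  # identical campaigns give an all-zero matrix
  th0 <- rbind(mk("A", 1997L, 3, 5), mk("A", 2022L, 3, 5))
  expect_true(all(diChange(th0, 1997, 2022) == 0, na.rm = TRUE))
  # ordering from larger to smaller absolute change
  th3 <- rbind(mk("A", 1997L, 2, 5, "Parmelia serrana"),
               mk("A", 2022L, rep(c(2, 3), c(2, 3)), 5, "Parmelia serrana"),
               mk("A", 1997L, 3, 5, "Xanthoria parietina"),
               mk("A", 2022L, rep(c(1, 2), c(3, 2)), 5,
                  "Xanthoria parietina"),
               mk("A", 1997L, 1, 5, "Ramalina fraxinea"),
               mk("A", 2022L, rep(c(1, 2), c(1, 4)), 5, "Ramalina fraxinea"))
  dc3 <- diChange(th3, 1997, 2022)
  vals <- dc3[, "A"]
  vals <- vals[!is.na(vals)]
  # changes are (+0.6, -1.2, +0.8): sorted by decreasing |change|
  expect_true(!is.unsorted(rev(abs(vals))))
  expect_equal(unname(abs(vals)), unname(sort(abs(vals), decreasing = TRUE)))
  # unknown species warn and are excluded
  thu <- rbind(th0, mk("A", 1997L, 2, 5, "Unknown lichen"),
               mk("A", 2022L, 2, 5, "Unknown lichen"))
  expect_warning(dcu <- diChange(thu, 1997, 2022), "Unknown")
  expect_false("Unknown lichen" %in% rownames(dcu))
})

test_that("difference of means equals mean of per-tree differences on
           balanced fixtures", {
  set.seed(9)
  trees <- sprintf("t%d", 1:4)
  mk <- function(yr) data.frame(
    station_id = "A", tree_id = rep(trees, each = 5), year = yr,
    species = "Parmelia serrana",
    thallus_id = sprintf("%s_%d_%d", rep(trees, each = 5), yr, 1:20),
    size_cm = 5, n_symptoms = 1L,
    max_di = sample(1:5, 20, replace = TRUE))
  a <- mk(1997L); b <- mk(2022L)
  dc <- diChange(rbind(a, b), 1997, 2022)["Parmelia serrana", "A"]
  perTree <- mean(vapply(trees, function(tr)
    mean(b$max_di[b$tree_id == tr]) - mean(a$max_di[a$tree_id == tr]),
    numeric(1)))
  expect_equal(dc, perTree, tolerance = 1e-12)
})

test_that("size effect is flagged degenerate or recovered as imposed", {
  th <- data.frame(station_id = "A", tree_id = "t", year = 1997L,
                   species = "X y", thallus_id = as.character(1:10),
                   size_cm = 1:10, n_symptoms = 1L,
                   max_di = rep(1:5, each = 2))
  # size exactly proportional to DI -> r = 1
  th$size_cm <- th$max_di * 2
  r <- sizeEffect(th, perSpecies = FALSE)
  expect_equal(r$pearson_r, 1)

  # constant DI -> degenerate result, not an exception
  th$max_di <- 3L
  th$size_cm <- 1:10
  rd <- sizeEffect(th, perSpecies = FALSE)
  expect_true(rd$degenerate)
  expect_true(is.na(rd$pearson_r))

  # independence in the generator: |r| small at n = 500
  big <- damageSimConfig(
    stations = data.frame(station_id = "S", year = 1997L, mu = 0.8),
    species = targetSpecies()[1:5], treesPerStation = 10,
    thalliPerSpeciesPerTree = 10, symptomRate = 1, sizeEffect = 0,
    seed = 31)
  reps <- vapply(1:10, function(i) {
    big$seed <- 31 + i
    t5 <- collapseThalli(simulateThalli(big))
    abs(sizeEffect(t5, perSpecies = FALSE)$pearson_r)
  }, numeric(1))
  expect_gte(mean(reps < 0.1), 0.9)
})
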