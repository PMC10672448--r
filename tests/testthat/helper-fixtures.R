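# Small programmatic fixtures shared across test files.

tinySurvey <- function() {
  data.frame(
    station_id = rep(c("A", "A", "B"), each = 4),
    tree_id = rep(c("A_t1", "A_t2", "B_t1"), each = 4),
    year = rep(c(1997L, 1997L, 2022L, 2022L), 3),
    species = rep(c("Xanthoria parietina", "Physcia aipolia"), 6),
    frequency = c(3L, 7L, 2L, 5L, 8L, 1L, 6L, 2L, 4L, 4L, 4L, 4L),
    stringsAsFactors = FALSE)
}

tinyTraits <- function() {
  data.frame(
    species = c("Xanthoria parietina", "Physcia aipolia"),
    ph_indicator = c(7, 5),
    eutrophication_tolerance = c(8, 4),
    growth_form = c("foliose_broad", "foliose_narrow"),
    reproductive_structure = c("apothecia", "soredia"),
    stringsAsFactors = FALSE)
}

tinyThalliLong <- function() {
  # thallus th1: symptoms {2, 5, 3}; th2: none; th3: {3}
  data.frame(
    station_id = "A", tree_id = "A_t1", year = 1997L,
    species = "Xanthoria parietina",
    thallus_id = c("th1", "th1", "th1", "th2", "th3"),
    size_cm = c(5, 5, 5, 4, 6),
    symptom_type = c("necrosis", "stain", "twisting", NA, "colour_change"),
    affected_fraction = c(0.3, 0.95, 0.4, NA, 0.3),
    location = c("centre", "lobes", "lobes", NA, "centre"),
    category = c(2L, 5L, 3L, NA, 3L),
    stringsAsFactors = FALSE)
}

# Two-class spectra whose class signal lies along a single noiseless
# direction; separable with one latent variable.
separableSpectra <- function(n = 20, p = 40, gap = 1) {
  dir <- sin(seq_len(p) / 3)
  cls <- rep(c("alpha", "beta"), each = n / 2)
  X <- matrix(rnorm(n * p, sd = 0), n, p)
  X <- X + outer(ifelse(cls == "beta", gap, 0), dir)
  list(X = X, labels = cls)
}
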