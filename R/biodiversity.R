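# Community-level analysis: IAP, between-campaign comparisons,
# frequency-change matrices, ordination and trait models.

#' Index of Atmospheric Purity for one tree
#'
#' The IAP of a tree is the sum of the grid frequencies of all species
#' recorded on it. An empty observation set gives 0.
#'
#' @param frequencies integer grid frequencies (0-10), one per species, or a
#'   survey `data.frame` slice for a single tree and year.
#' @return the tree-level IAP (a number).
#' @examples
#' iapTree(c(3, 7, 10))  # 20
#' @export
iapTree <- function(frequencies) {
  if (is.data.frame(frequencies)) {
    if (nrow(frequencies) &&
        (length(unique(frequencies$tree_id)) > 1L ||
         length(unique(frequencies$year)) > 1L))
      .stopf("iapTree expects observations from a single tree and year")
    frequencies <- frequencies$frequency
  }
  if (!length(frequencies)) return(0)
  stopifnot(all(frequencies >= 0 & frequencies <= 10))
  sum(frequencies)
}

#' Index of Atmospheric Purity for one station
#'
#' The station IAP is the arithmetic mean of the tree-level IAP values over
#' the m trees sampled at the station in that campaign.
#'
#' @param x either a numeric vector of per-tree IAP values (optionally
#'   named by tree), or a survey `data.frame` restricted to one station and
#'   year (per-tree values are then computed with [iapTree()]).
#' @param station_id,year identifiers recorded in the result (taken from the
#'   data when a survey is supplied).
#' @return a list of class `IAPResult` with elements `station_id`, `year`,
#'   `per_tree` (named numeric), `station_value`, `n_trees`.
#' @examples
#' iapStation(c(t1 = 10, t2 = 20))$station_value  # 15
#' @export
iapStation <- function(x, station_id = NA_character_, year = NA_integer_) {
  if (is.data.frame(x)) {
    if (!nrow(x)) .stopf("at least one tree is required")
    if (length(unique(x$station_id)) > 1L || length(unique(x$year)) > 1L)
      .stopf("iapStation expects observations from one station and year")
    station_id <- x$station_id[1]
    year <- x$year[1]
    per_tree <- vapply(split(x$frequency, x$tree_id), sum, numeric(1))
  } else {
    per_tree <- x
    if (is.null(names(per_tree)))
      names(per_tree) <- sprintf("tree_%02d", seq_along(per_tree))
  }
  if (!length(per_tree)) .stopf("at least one tree is required")
  structure(list(station_id = station_id, year = as.integer(year),
                 per_tree = per_tree,
                 station_value = mean(per_tree),
                 n_trees = length(per_tree)),
            class = "IAPResult")
}

#' @export
print.IAPResult <- function(x, ...) {
  cat(sprintf("IAP %s (%s): %.3f over %d trees\n", x$station_id,
              ifelse(is.na(x$year), "?", x$year), x$station_value, x$n_trees))
  invisible(x)
}

#' Station-level IAP table for a whole survey
#'
#' @param survey a survey `data.frame`.
#' @return a `data.frame` with one row per station and year: `station_id`,
#'   `year`, `n_trees`, `iap`.
#' @export
iapStations <- function(survey) {
  sp <- split(survey, list(survey$station_id, survey$year), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    r <- iapStation(d)
    data.frame(station_id = r$station_id, year = r$year, n_trees = r$n_trees,
               iap = r$station_value, stringsAsFactors = FALSE)
  }))
  out <- out[order(out$station_id, out$year), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Student's t comparison between two campaigns
#'
#' Two-sided pooled-variance Student's t test (Welch's correction behind the
#' `welch` flag). Both samples need n >= 2. Degenerate inputs with zero
#' pooled variance return t = 0, p = 1 when the means are equal, and
#' t = +/-Inf, p = 0 otherwise.
#'
#' @param values_year1,values_year2 numeric samples (e.g. per-tree IAP or
#'   per-thallus DI values from each campaign).
#' @param welch use the Welch unequal-variance form.
#' @return a list with `t`, `df`, `p`.
#' @examples
#' compareYears(c(1, 2, 3), c(4, 5, 6))
#' @export
compareYears <- function(values_year1, values_year2, welch = FALSE) {
  x <- as.numeric(values_year1); y <- as.numeric(values_year2)
  if (length(x) < 2L || length(y) < 2L)
    .stopf("both samples need at least 2 observations")
  n1 <- length(x); n2 <- length(y)
  pooled <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
    (n1 + n2 - 2)
  if (pooled <= 0) {
    if (isTRUE(all.equal(mean(x), mean(y))))
      return(list(t = 0, df = n1 + n2 - 2L, p = 1))
    return(list(t = sign(mean(x) - mean(y)) * Inf, df = n1 + n2 - 2L, p = 0))
  }
  ht <- stats::t.test(x, y, var.equal = !welch)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Species frequency change between campaigns
#'
#' For each species and station, the mean grid frequency in the second
#' campaign minus the mean in the first, averaged over the trees sampled in
#' both campaigns (a species missing from a tree contributes frequency 0).
#' Species never observed at a station in either campaign get `NA`
#' (not observed). With `paired = TRUE` the cell is instead the mean of
#' per-tree paired differences; on trees shared between campaigns the two
#' definitions coincide.
#'
#' @param survey a survey `data.frame` holding both campaigns.
#' @param year1,year2 the two campaign years.
#' @param paired average per-tree differences instead of differencing means.
#' @return a species x station numeric matrix (heatmap-ready); cells are
#'   bounded in \[-10, 10\].
#' @export
frequencyChange <- function(survey, year1, year2, paired = FALSE) {
  if (!all(c(year1, year2) %in% survey$year))
    .stopf("year %s not present in the survey",
           paste(setdiff(c(year1, year2), survey$year), collapse = ", "))
  species <- sort(unique(survey$species))
  stations <- sort(unique(survey$station_id))
  out <- matrix(NA_real_, length(species), length(stations),
                dimnames = list(species, stations))
  for (stn in stations) {
    d <- survey[survey$station_id == stn, , drop = FALSE]
    shared <- intersect(unique(d$tree_id[d$year == year1]),
                        unique(d$tree_id[d$year == year2]))
    if (!length(shared)) next
    d <- d[d$tree_id %in% shared, , drop = FALSE]
    seen <- unique(d$species)
    f <- function(yr, sp) {
      v <- numeric(length(shared)); names(v) <- shared
      rows <- d[d$year == yr & d$species == sp, , drop = FALSE]
      v[rows$tree_id] <- rows$frequency
      v
    }
    for (sp in seen) {
      d1 <- f(year1, sp); d2 <- f(year2, sp)
      out[sp, stn] <- if (paired) mean(d2 - d1) else mean(d2) - mean(d1)
    }
  }
  out
}

#' Bray-Curtis dissimilarity between two frequency profiles
#'
#' `1 - 2 sum(min(a, b)) / (sum(a) + sum(b))`, in \[0, 1\].
#'
#' @param a,b non-negative frequency vectors on a shared species index.
#' @return the dissimilarity.
#' @examples
#' brayCurtis(c(2, 1, 0), c(1, 1, 1))  # 1/3
#' @export
brayCurtis <- function(a, b) {
  stopifnot(length(a) == length(b), all(a >= 0), all(b >= 0))
  tot <- sum(a) + sum(b)
  if (tot == 0) .stopf("both profiles are all-zero")
  1 - 2 * sum(pmin(a, b)) / tot
}

#' Per-tree frequency profiles from a survey
#'
#' @param survey a survey `data.frame`.
#' @return a trees x species matrix of grid frequencies (0 for absence);
#'   rownames are `tree_id|year`.
#' @export
frequencyProfiles <- function(survey) {
  key <- paste(survey$tree_id, survey$year, sep = "|")
  trees <- sort(unique(key))
  species <- sort(unique(survey$species))
  m <- matrix(0, length(trees), length(species),
              dimnames = list(trees, species))
  m[cbind(match(key, trees), match(survey$species, species))] <-
    survey$frequency
  m
}

#' Nonmetric multidimensional scaling of a dissimilarity matrix
#'
#' Kruskal stress-1 NMDS (global, monotone regression) with random restarts;
#' the best-stress solution is returned. The workhorse is
#' [vegan::metaMDS()] on the raw dissimilarities (no community
#' autotransformation).
#'
#' @param d a `dist` or symmetric zero-diagonal matrix.
#' @param k embedding dimension (default 2).
#' @param nRestarts random restarts (default 20).
#' @param seed integer seed.
#' @param maxit iteration cap per restart.
#' @return a list of class `OrdinationResult`: `coordinates` (n x k),
#'   `stress` (in \[0, 1\]), `converged`, `nRestarts`, `seed`.
#' @export
nmdsOrdination <- function(d, k = 2L, nRestarts = 20L, seed = 1L,
                           maxit = 500L) {
  if (is.matrix(d)) {
    if (!isSymmetric(unname(d)) || any(abs(diag(d)) > 1e-12))
      .stopf("dissimilarity matrix must be symmetric with a zero diagonal")
    d <- stats::as.dist(d)
  }
  n <- attr(d, "Size")
  stopifnot(k >= 1L)
  if (n == 2L) {
    coords <- matrix(0, 2L, k)
    coords[, 1] <- c(-d[1], d[1]) / 2
    rownames(coords) <- attr(d, "Labels")
    return(structure(list(coordinates = coords, stress = 0, converged = TRUE,
                          nRestarts = 0L, seed = seed),
                     class = "OrdinationResult"))
  }
  fit <- .withSeed(seed, function()
    vegan::metaMDS(d, k = k, try = nRestarts, trymax = nRestarts,
                   trace = 0, autotransform = FALSE, wascores = FALSE,
                   expand = FALSE, maxit = maxit))
  structure(list(coordinates = fit$points, stress = fit$stress,
                 converged = !is.null(fit$converged) &&
                   (isTRUE(fit$converged) ||
                      (is.numeric(fit$converged) && fit$converged > 0)),
                 nRestarts = as.integer(nRestarts), seed = seed),
            class = "OrdinationResult")
}

#' @export
print.OrdinationResult <- function(x, ...) {
  cat(sprintf("NMDS: %d points in %d dimensions, stress %.4f (%s)\n",
              nrow(x$coordinates), ncol(x$coordinates), x$stress,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Linear model of abundance change on a numeric trait
#'
#' Ordinary least squares of per-species change on an ordinal ecological
#' indicator (substratum pH or eutrophication tolerance), with the Pearson
#' correlation and its two-sided p value.
#'
#' @param change numeric per-species change values.
#' @param trait numeric per-species trait values.
#' @param trait_name label recorded in the result.
#' @return a list of class `TraitEffectResult`: `trait`, `slope`,
#'   `intercept`, `pearson_r`, `p_value`, `n_species`, `degenerate`.
#' @export
traitEffect <- function(change, trait, trait_name = deparse(substitute(trait))) {
  keep <- is.finite(change) & is.finite(trait)
  change <- change[keep]; trait <- trait[keep]
  if (length(change) < 3L)
    .stopf("at least 3 species with both change and trait values are needed")
  if (stats::var(trait) == 0) .stopf("trait has zero variance")
  if (stats::var(change) == 0)
    return(structure(list(trait = trait_name, slope = 0,
                          intercept = mean(change), pearson_r = NA_real_,
                          p_value = NA_real_, n_species = length(change),
                          degenerate = TRUE),
                     class = "TraitEffectResult"))
  fit <- stats::lm(change ~ trait)
  ct <- suppressWarnings(stats::cor.test(change, trait))
  structure(list(trait = trait_name,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 pearson_r = unname(ct$estimate),
                 p_value = max(ct$p.value, .Machine$double.xmin),
                 n_species = length(change), degenerate = FALSE),
            class = "TraitEffectResult")
}

#' @export
print.TraitEffectResult <- function(x, ...) {
  cat(sprintf("%s: slope %.3f, r = %.3f, p = %.3g (n = %d)%s\n", x$trait,
              x$slope, x$pearson_r, x$p_value, x$n_species,
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

#' One-way ANOVA of change on a categorical trait
#'
#' Fixed-effects one-way ANOVA of per-species change on growth form or
#' reproductive structure. Every group needs at least 2 members. When all
#' responses are identical the test is vacuous: F = 0, p = 1.
#'
#' @param change numeric per-species change values.
#' @param group categorical trait (factor or character).
#' @return a list with `F`, `df1`, `df2`, `p`.
#' @export
traitAnova <- function(change, group) {
  group <- factor(group)
  keep <- is.finite(change) & !is.na(group)
  change <- change[keep]; group <- droplevels(group[keep])
  tab <- table(group)
  if (length(tab) < 2L) .stopf("at least 2 groups are required")
  if (any(tab < 2L))
    .stopf("group(s) with fewer than 2 members: %s",
           paste(names(tab)[tab < 2L], collapse = ", "))
  if (stats::var(change) == 0)   # vacuous test: no variation at all
    return(list(F = 0, df1 = length(tab) - 1L,
                df2 = length(change) - length(tab), p = 1))
  a <- stats::anova(stats::lm(change ~ group))
  Fv <- a$`F value`[1]; p <- a$`Pr(>F)`[1]
  if (!is.finite(Fv)) { Fv <- 0; p <- 1 }   # zero variance everywhere
  list(F = Fv, df1 = a$Df[1], df2 = a$Df[2], p = p)
}

#' Per-species abundance change joined with traits
#'
#' Convenience wrapper: computes the frequency-change matrix, averages each
#' species over stations, and joins the trait table.
#'
#' @param survey a survey `data.frame` with both campaigns.
#' @param traits a trait `data.frame`.
#' @param year1,year2 campaign years.
#' @return a `data.frame` with `species`, `change` and the trait columns.
#' @export
speciesChangeTable <- function(survey, traits, year1, year2) {
  fc <- frequencyChange(survey, year1, year2)
  change <- rowMeans(fc, na.rm = TRUE)
  change[is.nan(change)] <- NA_real_
  df <- data.frame(species = rownames(fc), change = unname(change),
                   stringsAsFactors = FALSE)
  m <- match(normalizeSpecies(df$species), normalizeSpecies(traits$species))
  unmatched <- df$species[is.na(m)]
  if (length(unmatched))
    .warnf("no trait record for species: %s", paste(unmatched, collapse = ", "))
  cbind(df, traits[m, setdiff(names(traits), "species"), drop = FALSE],
        row.names = NULL)
}
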