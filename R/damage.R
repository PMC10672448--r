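# Damage Index: max-rule category assignment, summaries, between-campaign
# comparisons and the thallus-size check.

#' Damage Index of one thallus (max rule)
#'
#' A thallus presenting several symptoms takes the maximum of their 1-5
#' damage categories; a thallus with no visible symptoms scores 1 (category
#' 1 is the no-visible-damage floor, which recorded symptoms at category 1
#' also share).
#'
#' @param categories integer symptom categories (possibly empty), or a
#'   symptom `data.frame` with a `category` column.
#' @return the thallus DI, an integer in 1..5.
#' @examples
#' assignDI(c(2, 5, 3))  # 5
#' assignDI(integer(0))  # 1
#' @export
assignDI <- function(categories) {
  if (is.data.frame(categories)) categories <- categories$category
  categories <- categories[!is.na(categories)]
  if (!length(categories)) return(1L)
  if (any(categories != round(categories) | categories < 1 | categories > 5))
    .stopf("symptom categories must be integers in {1..5}")
  as.integer(max(categories))
}

#' Map affected surface fraction to a damage category
#'
#' Configurable breakpoint table standing in for per-species appendix range
#' tables: fractions in \[0, 0.1) score 1, \[0.1, 0.25) score 2,
#' \[0.25, 0.5) score 3, \[0.5, 0.9) score 4 and >= 0.9 score 5 (category 5
#' anchored at necrosis over 90% of the thallus). This default table is a
#' documented stand-in, not a published calibration.
#'
#' @param affected_fraction numeric in \[0, 1\].
#' @param breakpoints lower bounds of categories 1-5.
#' @return integer categories.
#' @export
symptomCategory <- function(affected_fraction,
                            breakpoints = c(0, 0.1, 0.25, 0.5, 0.9)) {
  stopifnot(length(breakpoints) == 5L, !is.unsorted(breakpoints))
  if (any(affected_fraction < 0 | affected_fraction > 1, na.rm = TRUE))
    .stopf("affected_fraction must be in [0, 1]")
  findInterval(affected_fraction, breakpoints)
}

#' Collapse long-format symptom rows to one row per thallus
#'
#' @param records a long thallus `data.frame` as from [readThalli()] or
#'   [simulateThalli()].
#' @return a per-thallus `data.frame` with `station_id`, `tree_id`, `year`,
#'   `species`, `thallus_id`, `size_cm`, `n_symptoms`, `max_di` (the
#'   max-rule DI).
#' @export
collapseThalli <- function(records) {
  idx <- !duplicated(records$thallus_id)
  out <- records[idx, c("station_id", "tree_id", "year", "species",
                        "thallus_id", "size_cm"), drop = FALSE]
  sp <- split(records$category, records$thallus_id)
  o <- match(out$thallus_id, names(sp))
  out$n_symptoms <- vapply(sp, function(k) sum(!is.na(k)), integer(1))[o]
  out$max_di <- vapply(sp, assignDI, integer(1))[o]
  rownames(out) <- NULL
  out
}

#' Damage Index summary by group
#'
#' Per-group count, mean and standard deviation of the per-thallus DI.
#' Groups with no records are omitted (with a warning when they were
#' explicitly requested through factor levels).
#'
#' @param thalli a per-thallus `data.frame` (see [collapseThalli()]).
#' @param by grouping columns, default station x year.
#' @return a `data.frame` with the grouping columns plus `n`, `mean_di`,
#'   `sd_di` (rounded to 3 decimals).
#' @export
diSummary <- function(thalli, by = c("station_id", "year")) {
  if (!nrow(thalli)) .stopf("no thallus records")
  sp <- split(thalli$max_di, thalli[by], drop = FALSE)
  empty <- vapply(sp, length, integer(1)) == 0L
  if (any(empty)) {
    .warnf("empty group(s) omitted: %s", paste(names(sp)[empty], collapse = ", "))
    sp <- sp[!empty]
  }
  keys <- do.call(rbind, strsplit(names(sp), ".", fixed = TRUE))
  out <- data.frame(keys, stringsAsFactors = FALSE)
  names(out) <- by
  if ("year" %in% by) out$year <- as.integer(out$year)
  out$n <- vapply(sp, length, integer(1))
  out$mean_di <- .roundReport(vapply(sp, mean, numeric(1)))
  out$sd_di <- .roundReport(vapply(sp, stats::sd, numeric(1)))
  rownames(out) <- NULL
  out[order(out[[1]]), , drop = FALSE]
}

#' Between-campaign DI comparison per locality
#'
#' Pooled-variance Student's t per station, pooling thalli across species and
#' trees within the locality (one comparison per locality); per-species tests
#' are additionally emitted with `perSpecies = TRUE`.
#'
#' @param thalli a per-thallus `data.frame`.
#' @param year1,year2 campaign years.
#' @param perSpecies also test each species within each station.
#' @param welch use Welch's correction.
#' @return a `data.frame` with `station_id` (and `species` when requested),
#'   `t`, `df`, `p`, `n1`, `n2`.
#' @export
diCompare <- function(thalli, year1, year2, perSpecies = FALSE,
                      welch = FALSE) {
  one <- function(d, stn, sp) {
    x <- d$max_di[d$year == year1]
    y <- d$max_di[d$year == year2]
    if (length(x) < 2L || length(y) < 2L) return(NULL)
    r <- compareYears(x, y, welch = welch)
    data.frame(station_id = stn, species = sp, t = r$t, df = r$df, p = r$p,
               n1 = length(x), n2 = length(y), stringsAsFactors = FALSE)
  }
  out <- list()
  for (stn in sort(unique(thalli$station_id))) {
    d <- thalli[thalli$station_id == stn, , drop = FALSE]
    out[[length(out) + 1L]] <- one(d, stn, NA_character_)
    if (perSpecies)
      for (sp in sort(unique(d$species)))
        out[[length(out) + 1L]] <-
          one(d[d$species == sp, , drop = FALSE], stn, sp)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) .stopf("no station has >= 2 thalli in both campaigns")
  if (!perSpecies) res$species <- NULL
  rownames(res) <- NULL
  res
}

#' DI change matrix between campaigns
#'
#' Per target species and station, the mean DI in the second campaign minus
#' the mean in the first. Species with no thalli at a station in either
#' campaign get `NA` (not observed); rows are ordered from larger to smaller
#' absolute change (species averaged over stations). Records of species
#' outside the configured target list raise a warning and are excluded.
#'
#' @param thalli a per-thallus `data.frame` with both campaigns.
#' @param year1,year2 campaign years.
#' @param species the target species list (defaults to the nine of
#'   [targetSpecies()]).
#' @return a species x station matrix; cells are bounded in \[-4, 4\].
#' @export
diChange <- function(thalli, year1, year2, species = targetSpecies()) {
  if (!all(c(year1, year2) %in% thalli$year))
    .stopf("both campaigns must be present")
  species <- normalizeSpecies(species)
  thalli$species <- normalizeSpecies(thalli$species)
  unknown <- setdiff(unique(thalli$species), species)
  if (length(unknown)) {
    .warnf("excluding species outside the target list: %s",
           paste(unknown, collapse = ", "))
    thalli <- thalli[thalli$species %in% species, , drop = FALSE]
  }
  stations <- sort(unique(thalli$station_id))
  out <- matrix(NA_real_, length(species), length(stations),
                dimnames = list(species, stations))
  for (stn in stations) for (sp in species) {
    d <- thalli[thalli$station_id == stn & thalli$species == sp, ,
                drop = FALSE]
    m1 <- d$max_di[d$year == year1]; m2 <- d$max_di[d$year == year2]
    if (length(m1) && length(m2)) out[sp, stn] <- mean(m2) - mean(m1)
  }
  ord <- order(-abs(rowMeans(out, na.rm = TRUE)))
  out[ord, , drop = FALSE]
}

#' Thallus size versus Damage Index
#'
#' OLS of DI on thallus size with Pearson correlation, pooled over all
#' records and (optionally) per species. A species with constant DI yields a
#' degenerate (NA-correlation) row rather than an error.
#'
#' @param thalli a per-thallus `data.frame`.
#' @param perSpecies also fit each species separately.
#' @return a `data.frame` with `species` ("(pooled)" for the pooled fit),
#'   `slope`, `pearson_r`, `p_value`, `n`, `degenerate`.
#' @export
sizeEffect <- function(thalli, perSpecies = TRUE) {
  fitOne <- function(d, label) {
    if (nrow(d) < 3L) return(NULL)
    if (stats::var(d$size_cm) == 0) .stopf("zero size variance (%s)", label)
    r <- traitEffect(d$max_di, d$size_cm, trait_name = label)
    data.frame(species = label, slope = r$slope, pearson_r = r$pearson_r,
               p_value = r$p_value, n = r$n_species,
               degenerate = r$degenerate, stringsAsFactors = FALSE)
  }
  out <- list(fitOne(thalli, "(pooled)"))
  if (perSpecies)
    for (sp in sort(unique(thalli$species)))
      out[[length(out) + 1L]] <-
        fitOne(thalli[thalli$species == sp, , drop = FALSE], sp)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
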