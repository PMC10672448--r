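# Ground-truth simulators for surveys, damage records, air quality and
# Vis-NIR spectra. Each generator takes a config built by its *SimConfig()
# helper and routes all randomness through the single config seed, so the
# same seed and config give bit-identical output.

.defaultStations <- c("Corachar", "VillarroyaPinares", "Bojar",
                      "ColladoGavilan", "ToroPinus", "Cinctorres",
                      "ToroQuercus")

#' The nine default target species for damage scoring
#'
#' Six foliose and three fruticose macrolichens routinely used as
#' damage-scoring targets in long-term epiphytic monitoring.
#' @return character vector of nine binomials.
#' @export
targetSpecies <- function() c(
  "Pleurosticta acetabulum", "Parmelina carporrhizans", "Parmelia serrana",
  "Xanthoria parietina", "Pseudevernia furfuracea", "Physcia aipolia",
  "Anaptychia ciliaris", "Ramalina fraxinea", "Ramalina farinacea")

#' Build a synthetic species pool with traits
#'
#' Each species gets ordinal pH and eutrophication indicator values (1-9),
#' a growth form, a reproductive structure, a baseline per-square occupancy
#' probability and a between-campaign effect on the logit of occupancy.
#' When `eutrophSlope` is nonzero the year effect is
#' `eutrophSlope * (eutrophication_tolerance - 5)`, imposing a trait-linked
#' abundance change whose sign and size are known ground truth for recovery
#' tests.
#'
#' @param nSpecies number of species.
#' @param eutrophSlope signed change in the occupancy logit per unit of
#'   (centred) eutrophication tolerance between the two campaigns.
#' @param baseOccupancyRange range the baseline occupancy probabilities are
#'   drawn from.
#' @param seed integer seed.
#' @return a `data.frame` usable as the `speciesPool` of
#'   [communitySimConfig()].
#' @export
makeSpeciesPool <- function(nSpecies = 30L, eutrophSlope = 0.2,
                            baseOccupancyRange = c(0.05, 0.6), seed = 1L) {
  .withSeed(seed, function() {
    eut <- sample(1:9, nSpecies, replace = TRUE)
    data.frame(
      species = sprintf("Lichenopsis simulata%02d", seq_len(nSpecies)),
      ph_indicator = sample(1:9, nSpecies, replace = TRUE),
      eutrophication_tolerance = eut,
      growth_form = sample(.growthForms, nSpecies, replace = TRUE),
      reproductive_structure = sample(.reproductiveStructures, nSpecies,
                                      replace = TRUE),
      base_occupancy = stats::runif(nSpecies, baseOccupancyRange[1],
                                    baseOccupancyRange[2]),
      year_effect = eutrophSlope * (eut - 5),
      stringsAsFactors = FALSE)
  })
}

#' Configuration for the community survey simulator
#'
#' @param nStations number of stations (default 7, the size of the
#'   biomonitoring network the simulator emulates).
#' @param treesPerStation trees sampled per station and campaign.
#' @param nSquares grid squares per quadrant (default 10).
#' @param speciesPool as from [makeSpeciesPool()]; columns `species`,
#'   `base_occupancy`, `year_effect` are required, trait columns are carried
#'   through.
#' @param years the two campaign years.
#' @param stationEffectSd SD of the per-station intercept on the occupancy
#'   logit.
#' @param seed integer seed.
#' @return a config list of class `communitySimConfig`.
#' @export
communitySimConfig <- function(nStations = 7L, treesPerStation = 10L,
                               nSquares = 10L, speciesPool = makeSpeciesPool(),
                               years = c(1997L, 2022L), stationEffectSd = 0.3,
                               seed = 1L) {
  stopifnot(nStations >= 1L, treesPerStation >= 1L, nSquares >= 1L,
            length(years) == 2L, stationEffectSd >= 0)
  if (any(speciesPool$base_occupancy < 0 | speciesPool$base_occupancy > 1))
    .stopf("base_occupancy must be a probability in [0, 1]")
  structure(list(nStations = as.integer(nStations),
                 treesPerStation = as.integer(treesPerStation),
                 nSquares = as.integer(nSquares), speciesPool = speciesPool,
                 years = as.integer(years), stationEffectSd = stationEffectSd,
                 seed = seed),
            class = "communitySimConfig")
}

#' Simulate a two-campaign community survey
#'
#' Per tree, species and campaign, square occupancy is drawn independently,
#' so the grid frequency is Binomial(`nSquares`, p). The occupancy
#' probability follows a logistic model
#' `p = plogis(qlogis(base_occupancy) + station_effect + is_year2 *
#' year_effect)`: the first campaign sits at the species baseline (plus a
#' station intercept) and the second is shifted by the species' year effect.
#' Frequency-0 outcomes produce no row (absence is the absence of the row).
#'
#' @param cfg a [communitySimConfig()].
#' @return a survey `data.frame` covering both campaigns.
#' @export
simulateSurvey <- function(cfg) {
  stopifnot(inherits(cfg, "communitySimConfig"))
  pool <- cfg$speciesPool
  .withSeed(cfg$seed, function() {
    stations <- if (cfg$nStations <= length(.defaultStations))
      .defaultStations[seq_len(cfg$nStations)]
    else sprintf("station_%02d", seq_len(cfg$nStations))
    stEff <- stats::rnorm(cfg$nStations, 0, cfg$stationEffectSd)
    grid <- expand.grid(tree = seq_len(cfg$treesPerStation),
                        st = seq_len(cfg$nStations),
                        sp = seq_len(nrow(pool)),
                        yi = c(0L, 1L), KEEP.OUT.ATTRS = FALSE)
    eta <- stats::qlogis(pool$base_occupancy[grid$sp]) + stEff[grid$st] +
      grid$yi * pool$year_effect[grid$sp]
    p <- stats::plogis(eta)
    f <- stats::rbinom(nrow(grid), cfg$nSquares, p)
    keep <- f >= 1L
    out <- data.frame(
      station_id = stations[grid$st[keep]],
      tree_id = sprintf("%s_t%02d", stations[grid$st[keep]],
                        grid$tree[keep]),
      year = cfg$years[grid$yi[keep] + 1L],
      species = pool$species[grid$sp[keep]],
      frequency = as.integer(f[keep]),
      stringsAsFactors = FALSE)
    out[order(out$station_id, out$tree_id, out$year, out$species), ,
        drop = FALSE] -> out
    rownames(out) <- NULL
    out
  })
}

#' Configuration for the thallus damage simulator
#'
#' Latent stress mu controls the location of the ordered five-class symptom
#' category distribution: each symptom's category is `cut(mu + logistic
#' noise)` at thresholds 0.5, 1.5, 2.5, 3.5 (so mu = 0 is an essentially
#' healthy population and each unit of mu shifts the distribution up about
#' one class). The number of symptoms per thallus is `minSymptoms +
#' Poisson(symptomRate)`. Thallus size is log-normal plus
#' `sizeEffect * max_di`, so size is independent of damage when `sizeEffect`
#' is 0.
#'
#' @param stations `data.frame` with columns `station_id`, `year`, `mu`
#'   (latent stress per station and campaign); defaults to a 7-station,
#'   1997/2022 design with higher stress in the later campaign.
#' @param species target species names.
#' @param treesPerStation trees per station.
#' @param thalliPerSpeciesPerTree at most 10.
#' @param symptomRate Poisson rate of symptoms per thallus.
#' @param minSymptoms minimum symptoms per thallus (0 allows fully healthy
#'   records; 1 forces at least one scored symptom).
#' @param categoryProbs optional explicit probabilities over categories 1-5,
#'   overriding the latent ordered model (useful for degenerate fixtures).
#' @param sizeMeanlog,sizeSdlog log-normal size parameters (cm).
#' @param sizeEffect additive size shift per damage category.
#' @param countsPerYear optional named vector (names = years) of total record
#'   counts; when given, thalli are distributed deterministically over
#'   stations, trees and species under the per-tree cap instead of the full
#'   factorial design.
#' @param seed integer seed.
#' @return a config list of class `damageSimConfig`.
#' @export
damageSimConfig <- function(stations = NULL, species = targetSpecies(),
                            treesPerStation = 4L,
                            thalliPerSpeciesPerTree = 10L,
                            symptomRate = 1.2, minSymptoms = 0L,
                            categoryProbs = NULL,
                            sizeMeanlog = 1.6, sizeSdlog = 0.35,
                            sizeEffect = 0, countsPerYear = NULL, seed = 1L) {
  if (is.null(stations))
    stations <- data.frame(
      station_id = rep(.defaultStations, 2L),
      year = rep(c(1997L, 2022L), each = 7L),
      mu = c(rep(0.2, 7L), c(-0.3, rep(0.9, 6L))))
  stopifnot(all(c("station_id", "year", "mu") %in% names(stations)),
            thalliPerSpeciesPerTree >= 1L, symptomRate >= 0, minSymptoms >= 0L)
  if (thalliPerSpeciesPerTree > 10L)
    .stopf("thalliPerSpeciesPerTree must be <= 10")
  if (!is.null(categoryProbs)) {
    if (length(categoryProbs) != 5L || any(categoryProbs < 0) ||
        sum(categoryProbs) <= 0)
      .stopf("categoryProbs must be 5 non-negative weights")
    categoryProbs <- categoryProbs / sum(categoryProbs)
  }
  structure(list(stations = stations, species = species,
                 treesPerStation = as.integer(treesPerStation),
                 thalliPerSpeciesPerTree = as.integer(thalliPerSpeciesPerTree),
                 symptomRate = symptomRate, minSymptoms = as.integer(minSymptoms),
                 categoryProbs = categoryProbs, sizeMeanlog = sizeMeanlog,
                 sizeSdlog = sizeSdlog, sizeEffect = sizeEffect,
                 countsPerYear = countsPerYear, seed = seed),
            class = "damageSimConfig")
}

# Expected mean symptom category under the ordered-logistic model, used by
# tests as a closed-form oracle for the simulator.
.expectedCategory <- function(mu, thresholds = c(0.5, 1.5, 2.5, 3.5)) {
  cdf <- c(stats::plogis(thresholds - mu), 1)
  sum(seq_len(5L) * diff(c(0, cdf)))
}

# Deterministic allocation of n thalli over stations x trees x species under
# the per-tree-species cap, cycling so the totals are exact.
.allocateThalli <- function(n, stations, trees, species, cap) {
  slots <- expand.grid(rep = seq_len(cap), sp = species, tree = trees,
                       st = stations, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
  # order so allocation spreads over stations first, then trees/species
  slots <- slots[order(slots$rep, match(slots$st, stations),
                       match(slots$tree, trees)), , drop = FALSE]
  if (n > nrow(slots))
    .stopf("cannot place %d thalli: only %d slots under the 10-per-tree cap",
           n, nrow(slots))
  slots[seq_len(n), , drop = FALSE]
}

#' Simulate thallus damage records
#'
#' @param cfg a [damageSimConfig()].
#' @return a long-format thallus `data.frame` (one row per symptom; a
#'   symptomless thallus keeps one row with NA symptom fields), as read by
#'   [readThalli()]. Use [collapseThalli()] for the per-thallus table with
#'   max-rule DI.
#' @export
simulateThalli <- function(cfg) {
  stopifnot(inherits(cfg, "damageSimConfig"))
  st <- cfg$stations
  .withSeed(cfg$seed, function() {
    pieces <- vector("list", nrow(st))
    for (i in seq_len(nrow(st))) {
      yr <- st$year[i]
      trees <- sprintf("%s_t%02d", st$station_id[i],
                       seq_len(cfg$treesPerStation))
      if (!is.null(cfg$countsPerYear)) {
        nTot <- cfg$countsPerYear[[as.character(yr)]]
        if (is.null(nTot)) .stopf("countsPerYear has no entry for year %d", yr)
        nHere <- .splitCount(nTot, sum(st$year == yr))[
          match(i, which(st$year == yr))]
        slots <- .allocateThalli(nHere, st$station_id[i], trees,
                                 cfg$species, cfg$thalliPerSpeciesPerTree)
      } else {
        slots <- expand.grid(rep = seq_len(cfg$thalliPerSpeciesPerTree),
                             sp = cfg$species, tree = trees,
                             st = st$station_id[i], KEEP.OUT.ATTRS = FALSE,
                             stringsAsFactors = FALSE)
      }
      if (!nrow(slots)) next
      nT <- nrow(slots)
      nSym <- cfg$minSymptoms + stats::rpois(nT, cfg$symptomRate)
      cats <- lapply(nSym, function(k) {
        if (k == 0L) return(integer(0))
        if (!is.null(cfg$categoryProbs))
          sample(1:5, k, replace = TRUE, prob = cfg$categoryProbs)
        else {
          z <- st$mu[i] + stats::rlogis(k)
          findInterval(z, c(0.5, 1.5, 2.5, 3.5)) + 1L
        }
      })
      maxdi <- vapply(cats, function(k) if (length(k)) max(k) else 1L,
                      integer(1))
      size <- stats::rlnorm(nT, cfg$sizeMeanlog, cfg$sizeSdlog) +
        cfg$sizeEffect * maxdi
      nRows <- pmax(nSym, 1L)
      idx <- rep(seq_len(nT), nRows)
      allCats <- unlist(lapply(cats, function(k) if (length(k)) k else NA_integer_))
      hasSym <- !is.na(allCats)
      nAll <- length(idx)
      af <- rep(NA_real_, nAll)
      lo <- c(0, 0.1, 0.25, 0.5, 0.9)[allCats[hasSym]]
      hi <- c(0.1, 0.25, 0.5, 0.9, 1)[allCats[hasSym]]
      af[hasSym] <- stats::runif(sum(hasSym), lo, hi)
      pieces[[i]] <- data.frame(
        station_id = st$station_id[i],
        tree_id = slots$tree[idx],
        year = yr,
        species = slots$sp[idx],
        thallus_id = sprintf("%s_%d_th%05d", st$station_id[i], yr, idx),
        size_cm = size[idx],
        symptom_type = ifelse(hasSym,
                              sample(.symptomTypes, nAll, replace = TRUE),
                              NA_character_),
        affected_fraction = af,
        location = ifelse(hasSym,
                          sample(c("centre", "lobes"), nAll, replace = TRUE),
                          NA_character_),
        category = allCats,
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, pieces)
    rownames(out) <- NULL
    out
  })
}

# Split n as evenly as possible into k integers (largest remainders first).
.splitCount <- function(n, k, i = NULL) {
  base <- n %/% k
  out <- rep(base, k)
  extra <- n - base * k
  if (extra > 0) out[seq_len(extra)] <- out[seq_len(extra)] + 1L
  if (is.null(i)) out else out[i]
}

#' Configuration for the NIR spectra simulator
#'
#' Spectra live on the full 350-2500 nm, 1 nm acquisition grid. Each spectrum
#' is a smooth reflectance baseline minus Gaussian absorption dips centred on
#' canonical first-overtone OH coordinates in the 1300-1600 nm water band,
#' then distorted by multiplicative scatter (`y = b x + a`, `b` log-normal
#' around 1, `a` normal around 0 -- exactly the affine model MSC inverts) and
#' white noise. Class membership in each of the five label fields shifts the
#' amplitudes of designated dips, giving a known, recoverable class signal.
#'
#' @param nSamples number of samples (default 195).
#' @param labelScheme named list of per-field class proportions.
#' @param peakCentres Gaussian dip centres in nm.
#' @param peakWidths dip SD in nm (recycled).
#' @param peakAmplitudes baseline dip depths (reflectance units, recycled).
#' @param classEffects named list: per label field, a list of
#'   `list(level, peaks, shift)` giving the additive amplitude shift applied
#'   to the indexed dips for samples of that level.
#' @param strategyByGrowthForm when `TRUE` (default) the reproduction
#'   strategy is sampled conditionally on growth form (fruticose thalli lean
#'   towards soredia), mimicking realistic trait confounding; `FALSE` samples
#'   the two fields independently.
#' @param scatterSd SD of `log(b)`.
#' @param offsetSd SD of the additive offset `a`.
#' @param noiseSd SD of the white noise.
#' @param grid wavelength grid (nm).
#' @param seed integer seed.
#' @return a config list of class `spectraSimConfig`.
#' @export
spectraSimConfig <- function(nSamples = 195L,
                             labelScheme = NULL,
                             peakCentres = c(1342, 1364, 1382, 1412, 1440,
                                             1462, 1476, 1494),
                             peakWidths = 18,
                             peakAmplitudes = 0.12,
                             classEffects = NULL,
                             strategyByGrowthForm = TRUE,
                             scatterSd = 0.1, offsetSd = 0.02,
                             noiseSd = 0.005, grid = 350:2500, seed = 1L) {
  stopifnot(nSamples >= 4L, scatterSd >= 0, offsetSd >= 0, noiseSd >= 0)
  if (is.null(labelScheme))
    labelScheme <- list(
      reproductive_structures = c(normal = 163, excessive = 32) / 195,
      growth_form = c(foliose = 2 / 3, fruticose = 1 / 3),
      reproduction_strategy = c(apothecia = 1 / 3, isidia = 1 / 3,
                                soredia = 1 / 3),
      phorophyte = c(Pinus = 0.45, Quercus = 0.55),
      bioclimatic_belt = c(`19c` = 0.5, `22a` = 0.5))
  if (is.null(classEffects))
    classEffects <- list(
      reproductive_structures = list(list(level = "excessive",
                                          peaks = c(1L, 2L), shift = 0.03)),
      growth_form = list(list(level = "fruticose", peaks = c(3L, 4L),
                              shift = 0.05)),
      reproduction_strategy = list(
        list(level = "isidia", peaks = 5L, shift = 0.04),
        list(level = "soredia", peaks = 6L, shift = 0.04)),
      phorophyte = list(list(level = "Quercus", peaks = 7L, shift = 0.04)),
      bioclimatic_belt = list(list(level = "22a", peaks = 8L, shift = 0.04)))
  nPk <- length(peakCentres)
  structure(list(nSamples = as.integer(nSamples), labelScheme = labelScheme,
                 peakCentres = peakCentres,
                 peakWidths = rep_len(peakWidths, nPk),
                 peakAmplitudes = rep_len(peakAmplitudes, nPk),
                 classEffects = classEffects,
                 strategyByGrowthForm = isTRUE(strategyByGrowthForm),
                 scatterSd = scatterSd, offsetSd = offsetSd, noiseSd = noiseSd,
                 grid = as.integer(grid), seed = seed),
            class = "spectraSimConfig")
}

#' Simulate labelled Vis-NIR spectra
#'
#' @param cfg a [spectraSimConfig()].
#' @return a [SpectraMatrix-class] with the five label fields attached.
#' @export
simulateSpectra <- function(cfg) {
  stopifnot(inherits(cfg, "spectraSimConfig"))
  .withSeed(cfg$seed, function() {
    n <- cfg$nSamples
    wl <- cfg$grid
    labs <- .sampleLabels(cfg)
    for (fld in names(labs)) {
      tab <- table(labs[[fld]])
      if (any(tab < 2L))
        .stopf("label field '%s': class '%s' has fewer than 2 samples",
               fld, names(tab)[which.min(tab)])
    }
    # smooth baseline: gentle slope plus two broad features outside the
    # water band, reflectance scale
    x01 <- (wl - 350) / 2150
    baseline <- 0.58 - 0.12 * x01 + 0.05 * exp(-((wl - 680) / 120)^2) -
      0.07 * exp(-((wl - 1930) / 90)^2)
    dipShapes <- vapply(seq_along(cfg$peakCentres), function(k)
      exp(-((wl - cfg$peakCentres[k]) / cfg$peakWidths[k])^2),
      numeric(length(wl)))
    amps <- matrix(rep(cfg$peakAmplitudes, each = n), n)
    for (fld in names(cfg$classEffects)) {
      for (ef in cfg$classEffects[[fld]]) {
        hit <- labs[[fld]] == ef$level
        amps[hit, ef$peaks] <- amps[hit, ef$peaks] + ef$shift
      }
    }
    clean <- matrix(rep(baseline, each = n), n) - amps %*% t(dipShapes)
    b <- stats::rlnorm(n, 0, cfg$scatterSd)
    a <- stats::rnorm(n, 0, cfg$offsetSd)
    noisy <- clean * b + a +
      matrix(stats::rnorm(n * length(wl), 0, cfg$noiseSd), n)
    ids <- sprintf("thallus_%03d", seq_len(n))
    rownames(noisy) <- ids
    SpectraMatrix(noisy, wl, ids, labs)
  })
}

.sampleLabels <- function(cfg) {
  n <- cfg$nSamples
  sch <- cfg$labelScheme
  # exact proportional class counts (largest remainders), randomly placed:
  # the configured proportions are honoured at any n
  draw <- function(p) {
    p <- p / sum(p)
    take <- floor(n * p)
    rem <- n - sum(take)
    if (rem > 0) {
      o <- order(n * p - take, decreasing = TRUE)
      take[o[seq_len(rem)]] <- take[o[seq_len(rem)]] + 1L
    }
    sample(rep(names(p), take))
  }
  labs <- list()
  for (fld in names(sch)) labs[[fld]] <- draw(sch[[fld]])
  if (cfg$strategyByGrowthForm &&
      all(c("growth_form", "reproduction_strategy") %in% names(sch))) {
    # mild confounding: fruticose thalli are soredia-leaning
    base <- sch$reproduction_strategy
    frut <- labs$growth_form == "fruticose"
    pf <- base * c(0.6, 0.6, 1.8)[match(names(base), c("apothecia", "isidia",
                                                       "soredia"))]
    pf <- pf / sum(pf)
    if (any(frut))
      labs$reproduction_strategy[frut] <- sample(names(base), sum(frut),
                                                 replace = TRUE, prob = pf)
  }
  as.data.frame(labs, stringsAsFactors = FALSE)
}

#' Configuration for the air-quality simulator
#'
#' Emulates multi-decade series at the monitoring stations: SO2 declining
#' exponentially towards a floor, O3 roughly flat at station-specific levels,
#' and temperature slowly warming.
#'
#' @param stations station ids.
#' @param years years covered.
#' @param nPerYear records per station, variable and year (monthly = 12).
#' @param so2Start,so2Decay,so2Floor SO2 decline: `floor + (start - floor) *
#'   exp(-decay * (year - years[1]))` micrograms/m3.
#' @param o3Range range of station-level O3 means.
#' @param tempBase,tempTrend temperature intercept (degrees C) and warming
#'   per year.
#' @param noiseSd named vector of within-year SDs per variable.
#' @param seed integer seed.
#' @return a config list of class `airSimConfig`.
#' @export
airSimConfig <- function(stations = .defaultStations, years = 1996:2023,
                         nPerYear = 12L, so2Start = 28, so2Decay = 0.12,
                         so2Floor = 3, o3Range = c(50, 90), tempBase = 12,
                         tempTrend = 0.03,
                         noiseSd = c(SO2 = 1.5, O3 = 6, temperature = 4),
                         seed = 1L) {
  stopifnot(nPerYear >= 1L, so2Start >= 0, so2Floor >= 0, all(noiseSd >= 0))
  structure(list(stations = stations, years = as.integer(years),
                 nPerYear = as.integer(nPerYear), so2Start = so2Start,
                 so2Decay = so2Decay, so2Floor = so2Floor, o3Range = o3Range,
                 tempBase = tempBase, tempTrend = tempTrend, noiseSd = noiseSd,
                 seed = seed),
            class = "airSimConfig")
}

#' Simulate air-quality records
#'
#' @param cfg an [airSimConfig()].
#' @return an air-quality `data.frame` (station, year, variable, value); gas
#'   values are truncated at 0.
#' @export
simulateAirQuality <- function(cfg) {
  stopifnot(inherits(cfg, "airSimConfig"))
  .withSeed(cfg$seed, function() {
    nS <- length(cfg$stations)
    o3Level <- stats::runif(nS, cfg$o3Range[1], cfg$o3Range[2])
    tempLevel <- cfg$tempBase + stats::rnorm(nS, 0, 1.5)
    g <- expand.grid(rep = seq_len(cfg$nPerYear), year = cfg$years,
                     st = seq_len(nS), KEEP.OUT.ATTRS = FALSE)
    dt <- g$year - cfg$years[1]
    mkvar <- function(variable, mean_) {
      v <- mean_ + stats::rnorm(nrow(g), 0, cfg$noiseSd[[variable]])
      if (variable != "temperature") v <- pmax(v, 0)
      data.frame(station_id = cfg$stations[g$st], year = g$year,
                 variable = variable, value = v, stringsAsFactors = FALSE)
    }
    out <- rbind(
      mkvar("SO2", cfg$so2Floor +
              (cfg$so2Start - cfg$so2Floor) * exp(-cfg$so2Decay * dt)),
      mkvar("O3", o3Level[g$st]),
      mkvar("temperature", tempLevel[g$st] + cfg$tempTrend * dt))
    rownames(out) <- NULL
    out
  })
}
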