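# Orchestration: air-quality aggregation and the end-to-end pipeline driven
# by one configuration list, writing CSV outputs and a JSON run manifest.

#' Annual means of air-quality variables
#'
#' Arithmetic mean per (station, year, variable); empty cells are simply
#' absent from the output.
#'
#' @param records an air-quality `data.frame` (see [readAirQuality()]).
#' @return a `data.frame` with `station_id`, `year`, `variable`, `mean_value`
#'   and `n`.
#' @export
annualMeans <- function(records) {
  sp <- split(records$value,
              records[c("station_id", "year", "variable")], drop = TRUE)
  keys <- do.call(rbind, strsplit(names(sp), ".", fixed = TRUE))
  out <- data.frame(station_id = keys[, 1], year = as.integer(keys[, 2]),
                    variable = keys[, 3],
                    mean_value = vapply(sp, mean, numeric(1)),
                    n = vapply(sp, length, integer(1)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$station_id, out$variable, out$year), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Default pipeline configuration
#'
#' The study conditions the simulators emulate: two campaigns (1997 and
#' 2022) over 7 stations, 10 trees per station, a 30-species pool with a
#' eutrophication-linked abundance change, 956 + 1432 damage records, a
#' 195-sample spectra matrix with a 58-sample random test set, and
#' multi-decade air-quality series.
#'
#' @param seed master seed; per-stage seeds are derived from it by fixed
#'   offsets so stages remain individually reproducible.
#' @return a nested configuration list.
#' @export
defaultConfig <- function(seed = 1L) {
  seed <- as.integer(seed)
  list(
    seed = seed,
    years = c(1997L, 2022L),
    community = list(n_stations = 7L, trees_per_station = 10L,
                     n_species = 30L, eutroph_slope = 0.2,
                     station_effect_sd = 0.3),
    damage = list(counts_per_year = list(`1997` = 956L, `2022` = 1432L),
                  trees_per_station = 4L, symptom_rate = 1.2),
    airquality = list(years = 1996:2023, n_per_year = 12L),
    spectra = list(n_samples = 195L, n_test = 58L, k_folds = 10L,
                   max_lv = 15L, label_fields = c("growth_form",
                                                  "bioclimatic_belt")),
    files = list())
}

.stageSeed <- function(seed, k) (as.integer(seed) + 1000L * k) %% .Machine$integer.max

.writeStage <- function(df, path) {
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "")
  list(file = basename(path), rows = nrow(df))
}

#' Run the full analysis pipeline
#'
#' Stages, in order: simulate (or load user-supplied tables), IAP and
#' between-campaign comparison, frequency-change / ordination / trait
#' models, Damage Index summaries and comparisons, air-quality annual means,
#' PLS-DA spectral classification, and a JSON run manifest. Any table can be
#' substituted with a real-data file through `config$files`
#' (`survey`, `traits`, `thalli`, `airquality`, `spectra`,
#' `spectra_labels`); every stage remains runnable standalone through the
#' exported functions. Warnings (unmatched species, empty groups) never
#' abort; stage errors do, naming the stage.
#'
#' @param config a configuration list from [defaultConfig()] /
#'   [readConfig()], or a path to a YAML file.
#' @param outdir output directory (created if needed).
#' @return the run manifest, invisibly (also written as `manifest.json`).
#' @export
runAll <- function(config = defaultConfig(), outdir) {
  if (is.character(config)) config <- readConfig(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  t00 <- proc.time()[["elapsed"]]
  manifest <- list(package_version = as.character(utils::packageVersion("epilichen")),
                   seed = config$seed, config = config, stages = list())
  addStage <- function(name, outputs, t0) {
    manifest$stages[[length(manifest$stages) + 1L]] <<-
      list(name = name, outputs = outputs,
           seconds = round(proc.time()[["elapsed"]] - t0, 2))
    .msgStage(name, t0)
  }
  run <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(fun(), error = function(e)
      .stopf("stage '%s' failed: %s", name, conditionMessage(e)))
    addStage(name, out, t0)
  }
  yrs <- config$years
  env <- new.env()

  run("simulate", function() {
    cc <- config$community
    pool <- makeSpeciesPool(cc$n_species, cc$eutroph_slope,
                            seed = .stageSeed(config$seed, 1L))
    env$traits <- if (!is.null(config$files$traits))
      readTraits(config$files$traits)
    else pool[c("species", "ph_indicator", "eutrophication_tolerance",
                "growth_form", "reproductive_structure")]
    env$survey <- if (!is.null(config$files$survey))
      readSurvey(config$files$survey)
    else simulateSurvey(communitySimConfig(
      nStations = cc$n_stations, treesPerStation = cc$trees_per_station,
      speciesPool = pool, years = yrs,
      stationEffectSd = cc$station_effect_sd,
      seed = .stageSeed(config$seed, 2L)))
    dc <- config$damage
    env$thalliLong <- if (!is.null(config$files$thalli))
      readThalli(config$files$thalli)
    else simulateThalli(damageSimConfig(
      treesPerStation = dc$trees_per_station, symptomRate = dc$symptom_rate,
      countsPerYear = dc$counts_per_year,
      seed = .stageSeed(config$seed, 3L)))
    env$air <- if (!is.null(config$files$airquality))
      readAirQuality(config$files$airquality)
    else simulateAirQuality(airSimConfig(
      years = config$airquality$years,
      nPerYear = config$airquality$n_per_year,
      seed = .stageSeed(config$seed, 4L)))
    sc <- config$spectra
    env$spectra <- if (!is.null(config$files$spectra))
      readSpectra(config$files$spectra,
                  labelsPath = config$files$spectra_labels)
    else simulateSpectra(spectraSimConfig(
      nSamples = sc$n_samples, seed = .stageSeed(config$seed, 5L)))
    writeSpectra(env$spectra, file.path(outdir, "spectra.csv"),
                 labelsPath = file.path(outdir, "spectra_labels.csv"))
    list(.writeStage(env$survey, file.path(outdir, "survey.csv")),
         .writeStage(env$traits, file.path(outdir, "traits.csv")),
         .writeStage(env$thalliLong, file.path(outdir, "thalli.csv")),
         .writeStage(env$air, file.path(outdir, "airquality.csv")),
         list(file = "spectra.csv", rows = length(sampleIds(env$spectra))),
         list(file = "spectra_labels.csv",
              rows = length(sampleIds(env$spectra))))
  })

  run("iap", function() {
    tab <- iapStations(env$survey)
    cmp <- do.call(rbind, lapply(sort(unique(env$survey$station_id)),
                                 function(stn) {
      d <- env$survey[env$survey$station_id == stn, , drop = FALSE]
      g <- function(yr) vapply(split(d$frequency[d$year == yr],
                                     d$tree_id[d$year == yr]), sum,
                               numeric(1))
      v1 <- g(yrs[1]); v2 <- g(yrs[2])
      if (length(v1) < 2L || length(v2) < 2L) return(NULL)
      r <- compareYears(v1, v2)
      data.frame(station_id = stn, t = r$t, df = r$df, p = r$p,
                 stringsAsFactors = FALSE)
    }))
    list(.writeStage(tab, file.path(outdir, "iap_station.csv")),
         .writeStage(cmp, file.path(outdir, "iap_comparison.csv")))
  })

  run("traits", function() {
    fc <- frequencyChange(env$survey, yrs[1], yrs[2])
    fcOut <- data.frame(species = rownames(fc), fc, check.names = FALSE)
    chg <- speciesChangeTable(env$survey, env$traits, yrs[1], yrs[2])
    eff <- do.call(rbind, lapply(
      c("ph_indicator", "eutrophication_tolerance"), function(tr) {
        r <- traitEffect(chg$change, chg[[tr]], trait_name = tr)
        data.frame(trait = tr, slope = r$slope, intercept = r$intercept,
                   pearson_r = r$pearson_r, p_value = r$p_value,
                   n_species = r$n_species, stringsAsFactors = FALSE)
      }))
    av <- do.call(rbind, lapply(
      c("growth_form", "reproductive_structure"), function(tr) {
        g <- chg[[tr]]
        ok <- !is.na(chg$change) & !is.na(g)
        # singleton categories carry no within-group information
        big <- names(which(table(g[ok]) >= 2L))
        ok <- ok & g %in% big
        if (length(big) < 2L) {
          .warnf("trait '%s': fewer than 2 usable groups, ANOVA skipped", tr)
          return(NULL)
        }
        r <- traitAnova(chg$change[ok], g[ok])
        data.frame(trait = tr, F = r$F, df1 = r$df1, df2 = r$df2, p = r$p,
                   stringsAsFactors = FALSE)
      }))
    prof <- frequencyProfiles(env$survey)
    dmat <- as.matrix(vegan::vegdist(prof, method = "bray"))
    ord <- nmdsOrdination(dmat, k = 2L, nRestarts = 20L,
                          seed = .stageSeed(config$seed, 6L))
    coords <- data.frame(tree = rownames(ord$coordinates),
                         ord$coordinates, stress = ord$stress)
    names(coords)[2:3] <- c("NMDS1", "NMDS2")
    list(.writeStage(fcOut, file.path(outdir, "frequency_change.csv")),
         .writeStage(eff, file.path(outdir, "trait_effects.csv")),
         .writeStage(av, file.path(outdir, "trait_anova.csv")),
         .writeStage(coords, file.path(outdir, "ordination.csv")))
  })

  run("damage", function() {
    th <- collapseThalli(env$thalliLong)
    sm <- diSummary(th)
    cmp <- diCompare(th, yrs[1], yrs[2])
    dc <- diChange(th, yrs[1], yrs[2])
    dcOut <- data.frame(species = rownames(dc), dc, check.names = FALSE)
    list(.writeStage(sm, file.path(outdir, "di_summary.csv")),
         .writeStage(cmp, file.path(outdir, "di_comparison.csv")),
         .writeStage(dcOut, file.path(outdir, "di_change.csv")))
  })

  run("airquality", function() {
    list(.writeStage(annualMeans(env$air),
                     file.path(outdir, "annual_means.csv")))
  })

  run("spectra", function() {
    sc <- config$spectra
    met <- do.call(rbind, lapply(seq_along(sc$label_fields), function(i) {
      ex <- runPLSDAExperiment(env$spectra, sc$label_fields[i],
                               nTest = sc$n_test, kFolds = sc$k_folds,
                               maxLV = sc$max_lv,
                               seed = .stageSeed(config$seed, 7L + i))
      cbind(model = sc$label_fields[i], metricsTable(ex))
    }))
    band <- selectWaterBand(env$spectra)
    pre <- meanCenter(mscFitTransform(spectraValues(band))$corrected)
    pca <- pcaSpectra(pre, k = 3L)
    sco <- data.frame(sample_id = sampleIds(env$spectra), pca$scores,
                      spectraLabels(env$spectra), check.names = FALSE)
    names(sco)[2:4] <- c("PC1", "PC2", "PC3")
    list(.writeStage(met, file.path(outdir, "plsda_metrics.csv")),
         .writeStage(sco, file.path(outdir, "pca_scores.csv")))
  })

  run("report", function() {
    files <- unlist(lapply(manifest$stages, function(s)
      vapply(s$outputs, `[[`, "", "file")))
    missing <- files[!file.exists(file.path(outdir, files))]
    if (length(missing))
      .stopf("manifest lists missing file(s): %s",
             paste(missing, collapse = ", "))
    list(list(file = "manifest.json", rows = length(files)))
  })

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  message(sprintf("[epilichen] total %.2fs", proc.time()[["elapsed"]] - t00))
  invisible(manifest)
}
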