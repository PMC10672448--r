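# Delimited-text readers and writers for the five table kinds.
#
# All tables are header-bearing delimited text (comma by default, tab
# accepted). Validation errors name the offending data row (1-based, header
# excluded) and field.

.symptomTypes <- c("colour_change", "necrosis", "twisting", "stain",
                   "parasite", "excessive_reproductive_structures",
                   "surface_loss")
.growthForms <- c("crustose", "foliose_broad", "foliose_narrow", "fruticose")
.reproductiveStructures <- c("apothecia", "isidia", "soredia")
.airVariables <- c("SO2", "O3", "temperature")

.readDelim <- function(path, sep = ",") {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "\"", comment.char = "")
}

.needCols <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    .stopf("%s: missing column(s): %s", basename(path),
           paste(miss, collapse = ", "))
}

.rowStop <- function(path, rows, field, msg) {
  .stopf("%s: row %s, field '%s': %s", basename(path),
         paste(rows, collapse = ", "), field, msg)
}

#' Read / write a community survey table
#'
#' A survey row is one species observed on one tree in one campaign, with its
#' grid frequency: the number (0-10) of the ten 10 x 10 cm squares of the
#' sampling quadrant in which the species occurs. Frequencies outside
#' \[0, 10\] are rejected with the offending row named; rows with frequency 0
#' are accepted on read and then dropped (absence is encoded by the row being
#' absent). Species names are normalized with [normalizeSpecies()];
#' (station, tree, year, species) must be unique.
#'
#' @param path file path.
#' @param sep field delimiter, `","` (default) or `"\t"`.
#' @return `readSurvey`: a `data.frame` with columns `station_id`, `tree_id`,
#'   `year`, `species`, `frequency`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeSurvey(data.frame(station_id = "A", tree_id = "t1", year = 1997,
#'                        species = "Xanthoria parietina", frequency = 7), f)
#' readSurvey(f)
#' @export
readSurvey <- function(path, sep = ",") {
  df <- .readDelim(path, sep)
  .needCols(df, c("station_id", "tree_id", "year", "species", "frequency"),
            path)
  f <- suppressWarnings(as.numeric(df$frequency))
  bad <- which(is.na(f) | f != round(f) | f < 0 | f > 10)
  if (length(bad))
    .rowStop(path, bad, "frequency", "must be an integer in [0, 10]")
  yr <- suppressWarnings(as.integer(df$year))
  if (anyNA(yr)) .rowStop(path, which(is.na(yr)), "year", "must be an integer")
  out <- data.frame(station_id = as.character(df$station_id),
                    tree_id = as.character(df$tree_id),
                    year = yr,
                    species = normalizeSpecies(df$species),
                    frequency = as.integer(f),
                    stringsAsFactors = FALSE)
  out <- out[out$frequency >= 1L, , drop = FALSE]
  key <- do.call(paste, c(out[c("station_id", "tree_id", "year", "species")],
                          sep = "\r"))
  if (anyDuplicated(key))
    .rowStop(path, which(duplicated(key)), "species",
             "duplicate (station, tree, year, species) record")
  rownames(out) <- NULL
  out
}

#' @rdname readSurvey
#' @param survey a survey `data.frame` as returned by [readSurvey()].
#' @return `writeSurvey`: the path, invisibly.
#' @export
writeSurvey <- function(survey, path, sep = ",") {
  utils::write.table(survey, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a species trait table
#'
#' One record per species: ordinal ecological indicator values for substratum
#' pH and eutrophication tolerance, plus growth form and reproductive
#' structure categories.
#'
#' @inheritParams readSurvey
#' @return `readTraits`: a `data.frame` with columns `species`,
#'   `ph_indicator`, `eutrophication_tolerance`, `growth_form`,
#'   `reproductive_structure`.
#' @export
readTraits <- function(path, sep = ",") {
  df <- .readDelim(path, sep)
  .needCols(df, c("species", "ph_indicator", "eutrophication_tolerance",
                  "growth_form", "reproductive_structure"), path)
  for (fld in c("ph_indicator", "eutrophication_tolerance")) {
    v <- suppressWarnings(as.numeric(df[[fld]]))
    if (anyNA(v) || any(!is.finite(v)))
      .rowStop(path, which(is.na(v) | !is.finite(v)), fld,
               "must be a finite number")
    df[[fld]] <- v
  }
  bad <- which(!df$growth_form %in% .growthForms)
  if (length(bad))
    .rowStop(path, bad, "growth_form",
             paste("must be one of:", paste(.growthForms, collapse = ", ")))
  bad <- which(!df$reproductive_structure %in% .reproductiveStructures)
  if (length(bad))
    .rowStop(path, bad, "reproductive_structure",
             paste("must be one of:",
                   paste(.reproductiveStructures, collapse = ", ")))
  df$species <- normalizeSpecies(df$species)
  if (anyDuplicated(df$species))
    .rowStop(path, which(duplicated(df$species)), "species",
             "one record per species is required")
  rownames(df) <- NULL
  df[c("species", "ph_indicator", "eutrophication_tolerance", "growth_form",
       "reproductive_structure")]
}

#' @rdname readTraits
#' @param traits a trait `data.frame`.
#' @export
writeTraits <- function(traits, path, sep = ",") {
  utils::write.table(traits, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write thallus damage records
#'
#' Long format: one row per recorded symptom, with a symptomless thallus
#' represented by a single row whose symptom fields are empty (NA). Symptom
#' categories are the 1-5 damage classes; `collapseThalli()` derives the
#' per-thallus maximum-rule Damage Index.
#'
#' @inheritParams readSurvey
#' @return `readThalli`: a `data.frame` with columns `station_id`, `tree_id`,
#'   `year`, `species`, `thallus_id`, `size_cm`, `symptom_type`,
#'   `affected_fraction`, `location`, `category`.
#' @seealso [collapseThalli()], [assignDI()]
#' @export
readThalli <- function(path, sep = ",") {
  df <- .readDelim(path, sep)
  .needCols(df, c("station_id", "tree_id", "year", "species", "thallus_id",
                  "size_cm", "symptom_type", "affected_fraction", "location",
                  "category"), path)
  df$symptom_type[df$symptom_type %in% c("", "NA")] <- NA
  df$location[df$location %in% c("", "NA")] <- NA
  has_sym <- !is.na(df$symptom_type)
  bad <- which(has_sym & !df$symptom_type %in% .symptomTypes)
  if (length(bad))
    .rowStop(path, bad, "symptom_type", "unknown symptom type")
  cat_ <- suppressWarnings(as.numeric(df$category))
  bad <- which(has_sym & (is.na(cat_) | !cat_ %in% 1:5))
  if (length(bad))
    .rowStop(path, bad, "category", "must be an integer in {1..5}")
  af <- suppressWarnings(as.numeric(df$affected_fraction))
  bad <- which(has_sym & (is.na(af) | af < 0 | af > 1))
  if (length(bad))
    .rowStop(path, bad, "affected_fraction", "must be in [0, 1]")
  bad <- which(has_sym & !df$location %in% c("centre", "lobes"))
  if (length(bad))
    .rowStop(path, bad, "location", "must be 'centre' or 'lobes'")
  sz <- suppressWarnings(as.numeric(df$size_cm))
  bad <- which(is.na(sz) | sz <= 0)
  if (length(bad)) .rowStop(path, bad, "size_cm", "must be a positive number")
  data.frame(station_id = as.character(df$station_id),
             tree_id = as.character(df$tree_id),
             year = as.integer(df$year),
             species = normalizeSpecies(df$species),
             thallus_id = as.character(df$thallus_id),
             size_cm = sz,
             symptom_type = as.character(df$symptom_type),
             affected_fraction = ifelse(has_sym, af, NA_real_),
             location = as.character(df$location),
             category = ifelse(has_sym, as.integer(cat_), NA_integer_),
             stringsAsFactors = FALSE)
}

#' @rdname readThalli
#' @param thalli a long-format thallus `data.frame`.
#' @export
writeThalli <- function(thalli, path, sep = ",") {
  utils::write.table(thalli, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' Read / write air-quality records
#'
#' @inheritParams readSurvey
#' @return `readAirQuality`: a `data.frame` with columns `station_id`, `year`,
#'   `variable` (one of SO2, O3, temperature), `value` (micrograms/m3 for the
#'   gases, degrees C for temperature). Gas concentrations must be
#'   non-negative.
#' @export
readAirQuality <- function(path, sep = ",") {
  df <- .readDelim(path, sep)
  .needCols(df, c("station_id", "year", "variable", "value"), path)
  bad <- which(!df$variable %in% .airVariables)
  if (length(bad))
    .rowStop(path, bad, "variable",
             paste("must be one of:", paste(.airVariables, collapse = ", ")))
  v <- suppressWarnings(as.numeric(df$value))
  if (anyNA(v)) .rowStop(path, which(is.na(v)), "value", "must be numeric")
  bad <- which(df$variable %in% c("SO2", "O3") & v < 0)
  if (length(bad))
    .rowStop(path, bad, "value", "gas concentrations must be >= 0")
  data.frame(station_id = as.character(df$station_id),
             year = as.integer(df$year),
             variable = as.character(df$variable),
             value = v, stringsAsFactors = FALSE)
}

#' @rdname readAirQuality
#' @param records an air-quality `data.frame`.
#' @export
writeAirQuality <- function(records, path, sep = ",") {
  utils::write.table(records, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read / write spectra
#'
#' Wide layout: first column `sample_id`, remaining column headers the
#' integer wavelengths in nm. Long layout: columns `sample_id`,
#' `wavelength_nm`, `value`. The wavelength grid must be uniform at 1 nm;
#' duplicate wavelengths and missing cells are errors. Per-sample labels can
#' be supplied as a companion table (columns `sample_id` plus any of the five
#' categorical fields).
#'
#' @param path spectra file path.
#' @param layout `"wide"` (default) or `"long"`.
#' @param labelsPath optional path of a per-sample label table.
#' @param sep field delimiter.
#' @return `readSpectra`: a [SpectraMatrix-class].
#' @export
readSpectra <- function(path, layout = c("wide", "long"), labelsPath = NULL,
                        sep = ",") {
  layout <- match.arg(layout)
  df <- .readDelim(path, sep)
  if (layout == "wide") {
    .needCols(df, "sample_id", path)
    wlcols <- names(df)[names(df) != "sample_id"]
    wl <- suppressWarnings(as.integer(wlcols))
    if (anyNA(wl))
      .stopf("%s: non-integer wavelength column header(s): %s", basename(path),
             paste(wlcols[is.na(wl)], collapse = ", "))
    if (anyDuplicated(wl))
      .stopf("%s: duplicate wavelength column(s): %s", basename(path),
             paste(unique(wl[duplicated(wl)]), collapse = ", "))
    o <- order(wl)
    values <- as.matrix(df[wlcols[o]])
    storage.mode(values) <- "double"
    wl <- wl[o]
    ids <- as.character(df$sample_id)
  } else {
    .needCols(df, c("sample_id", "wavelength_nm", "value"), path)
    wl <- sort(unique(as.integer(df$wavelength_nm)))
    ids <- unique(as.character(df$sample_id))
    key <- paste(df$sample_id, df$wavelength_nm)
    if (anyDuplicated(key))
      .stopf("%s: duplicated (sample, wavelength) cell(s)", basename(path))
    values <- matrix(NA_real_, length(ids), length(wl),
                     dimnames = list(ids, wl))
    values[cbind(match(as.character(df$sample_id), ids),
                 match(as.integer(df$wavelength_nm), wl))] <-
      as.numeric(df$value)
  }
  if (anyNA(values))
    .stopf("%s: missing cells in the spectra matrix", basename(path))
  if (length(wl) > 1L && any(diff(wl) != 1L))
    .stopf("%s: wavelength grid is not uniform at 1 nm", basename(path))
  labels <- NULL
  if (!is.null(labelsPath)) {
    lab <- .readDelim(labelsPath, sep)
    .needCols(lab, "sample_id", labelsPath)
    m <- match(ids, as.character(lab$sample_id))
    if (anyNA(m))
      .stopf("%s: labels missing for sample(s): %s", basename(labelsPath),
             paste(ids[is.na(m)], collapse = ", "))
    labels <- lab[m, setdiff(names(lab), "sample_id"), drop = FALSE]
  }
  rownames(values) <- ids
  SpectraMatrix(values, wl, ids, labels)
}

#' @rdname readSpectra
#' @param spectra a [SpectraMatrix-class].
#' @param labelsPath for `writeSpectra`, where to write the label table
#'   (skipped when `NULL` or when the object carries no labels).
#' @export
writeSpectra <- function(spectra, path, layout = c("wide", "long"),
                         labelsPath = NULL, sep = ",") {
  layout <- match.arg(layout)
  v <- spectraValues(spectra)
  wl <- wavelengths(spectra)
  ids <- sampleIds(spectra)
  if (layout == "wide") {
    out <- data.frame(sample_id = ids, v, check.names = FALSE)
    names(out) <- c("sample_id", as.character(wl))
  } else {
    out <- data.frame(sample_id = rep(ids, each = length(wl)),
                      wavelength_nm = rep(wl, times = length(ids)),
                      value = as.vector(t(v)))
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  lab <- spectraLabels(spectra)
  if (!is.null(labelsPath) && ncol(lab) > 0L)
    utils::write.table(cbind(sample_id = ids, lab), labelsPath, sep = sep,
                       row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Match survey species against a trait table
#'
#' Case-insensitive matching on the normalized trimmed binomial. Species
#' present in the survey but absent from the trait table are reported with a
#' warning, never silently dropped.
#'
#' @param survey a survey `data.frame`.
#' @param traits a trait `data.frame`.
#' @return the survey with trait columns joined; unmatched species keep NA
#'   traits.
#' @export
matchTraits <- function(survey, traits) {
  m <- match(normalizeSpecies(survey$species), normalizeSpecies(traits$species))
  unmatched <- sort(unique(survey$species[is.na(m)]))
  if (length(unmatched))
    .warnf("no trait record for species: %s", paste(unmatched, collapse = ", "))
  cbind(survey, traits[m, setdiff(names(traits), "species"), drop = FALSE],
        row.names = NULL)
}

#' Read a pipeline configuration file
#'
#' YAML with one section per stage; values omitted fall back to
#' [defaultConfig()].
#'
#' @param path YAML file path.
#' @return a nested configuration list.
#' @export
readConfig <- function(path) {
  if (!file.exists(path)) .stopf("config file not found: %s", path)
  .mergeConfig(defaultConfig(), yaml::read_yaml(path))
}

.mergeConfig <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(base[[nm]]) && is.list(over[[nm]]))
      base[[nm]] <- .mergeConfig(base[[nm]], over[[nm]])
    else base[[nm]] <- over[[nm]]
  }
  base
}
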