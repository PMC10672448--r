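# S4 classes for the spectral side of the pipeline.

# Allowed levels of the five per-sample categorical fields carried by a
# SpectraMatrix.
.spectraLabelLevels <- list(
  reproductive_structures = c("normal", "excessive"),
  growth_form             = c("foliose", "fruticose"),
  reproduction_strategy   = c("apothecia", "isidia", "soredia"),
  phorophyte              = c("Pinus", "Quercus"),
  bioclimatic_belt        = c("19c", "22a")
)

#' SpectraMatrix: Vis-NIR reflectance spectra with sample labels
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding thallus
#' reflectance spectra. Rows are wavelengths (an integer grid with a strict
#' 1 nm step), columns are samples; `colData` carries up to five categorical
#' fields describing each thallus (reproductive structures, growth form,
#' reproduction strategy, phorophyte, bioclimatic belt).
#'
#' @slot . inherits all slots from `SummarizedExperiment`; the single assay
#'   is named `"reflectance"`.
#' @seealso [SpectraMatrix()] for construction, [spectraValues()],
#'   [wavelengths()], [spectraLabels()] for access.
#' @export
setClass("SpectraMatrix", contains = "SummarizedExperiment")

setValidity("SpectraMatrix", function(object) {
  wl <- SummarizedExperiment::rowData(object)$wavelength_nm
  if (is.null(wl))
    return("rowData must contain 'wavelength_nm'")
  if (anyNA(wl) || any(wl != as.integer(wl)))
    return("wavelengths must be integers (nm)")
  if (length(wl) > 1L && any(diff(wl) != 1L))
    return("wavelength grid must be strictly increasing with a 1 nm step")
  if (!"reflectance" %in% SummarizedExperiment::assayNames(object))
    return("assay 'reflectance' is required")
  v <- SummarizedExperiment::assay(object, "reflectance")
  if (anyNA(v) || any(!is.finite(v)))
    return("reflectance values must be finite with no missing cells")
  cd <- SummarizedExperiment::colData(object)
  for (fld in intersect(names(.spectraLabelLevels), colnames(cd))) {
    bad <- setdiff(unique(as.character(cd[[fld]])), .spectraLabelLevels[[fld]])
    if (length(bad))
      return(sprintf("label field '%s' has unknown level(s): %s",
                     fld, paste(bad, collapse = ", ")))
  }
  TRUE
})

#' Construct a SpectraMatrix
#'
#' @param values numeric matrix, samples in rows and wavelengths in columns
#'   (the orientation spectra files use; it is transposed internally to the
#'   wavelength-by-sample assay).
#' @param wavelengths integer wavelength grid in nm, strictly increasing with
#'   step 1.
#' @param sampleIds character sample identifiers; defaults to the rownames of
#'   `values`.
#' @param labels `data.frame` (or DataFrame) of per-sample categorical fields,
#'   or `NULL`.
#' @return a [SpectraMatrix-class] object.
#' @examples
#' v <- matrix(runif(2 * 301), 2, dimnames = list(c("s1", "s2"), NULL))
#' sm <- SpectraMatrix(v, 1300:1600)
#' dim(sm)
#' @export
SpectraMatrix <- function(values, wavelengths,
                          sampleIds = rownames(values), labels = NULL) {
  values <- as.matrix(values)
  if (is.null(sampleIds))
    sampleIds <- sprintf("sample_%03d", seq_len(nrow(values)))
  if (length(wavelengths) != ncol(values))
    .stopf("values has %d columns but %d wavelengths were given",
           ncol(values), length(wavelengths))
  if (length(sampleIds) != nrow(values))
    .stopf("values has %d rows but %d sample ids were given",
           nrow(values), length(sampleIds))
  cd <- if (is.null(labels)) S4Vectors::DataFrame(row.names = sampleIds)
        else S4Vectors::DataFrame(labels, row.names = sampleIds)
  a <- t(values)
  dimnames(a) <- list(as.character(wavelengths), sampleIds)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays  = list(reflectance = a),
    rowData = S4Vectors::DataFrame(wavelength_nm = as.integer(wavelengths)),
    colData = cd)
  methods::new("SpectraMatrix", se)
}

#' PreprocessState: fitted spectral pretreatment parameters
#'
#' Captures everything fitted on the training spectra that must be re-applied,
#' unchanged, to test spectra: the MSC reference spectrum, the column means
#' used for centring, and the retained wavelength band.
#'
#' @slot mscReference numeric, reference spectrum over retained wavelengths.
#' @slot columnMeans numeric, training column means (length 0 until fitted).
#' @slot band numeric(2), wavelength band in nm.
#' @export
setClass("PreprocessState",
         representation(mscReference = "numeric",
                        columnMeans  = "numeric",
                        band         = "numeric"),
         prototype(mscReference = numeric(0), columnMeans = numeric(0),
                   band = c(1300, 1600)))

setValidity("PreprocessState", function(object) {
  if (length(object@columnMeans) &&
      length(object@columnMeans) != length(object@mscReference))
    return("columnMeans and mscReference must cover the same wavelengths")
  if (length(object@band) != 2L || object@band[1] >= object@band[2])
    return("band must be an increasing pair of wavelengths (nm)")
  TRUE
})

#' PLSDAModel: fitted PLS-DA latent-variable classifier
#'
#' Partial least squares discriminant analysis model with one-hot class
#' coding. Latent variables are extracted sequentially to maximize the
#' covariance between the (centred) spectra and class membership; successive
#' X-scores are mutually orthogonal.
#'
#' @slot nLatent integer, number of latent variables.
#' @slot classLabels character, class labels in lexicographic order (ties in
#'   prediction resolve to the first).
#' @slot xMean,yMean numeric, training column means of X and of the one-hot Y.
#' @slot xWeights,xLoadings matrix, wavelengths x nLatent.
#' @slot yLoadings matrix, classes x nLatent.
#' @slot coefficients matrix, wavelengths x classes regression coefficients.
#' @slot fitted matrix, training-sample class scores implied by the model.
#' @slot mscReference numeric, the MSC reference used upstream (may be empty
#'   when pretreatment is managed externally).
#' @export
setClass("PLSDAModel",
         representation(nLatent = "integer", classLabels = "character",
                        xMean = "numeric", yMean = "numeric",
                        xWeights = "matrix", xLoadings = "matrix",
                        yLoadings = "matrix", coefficients = "matrix",
                        fitted = "matrix", mscReference = "numeric"))

setValidity("PLSDAModel", function(object) {
  a <- object@nLatent
  p <- length(object@xMean)
  q <- length(object@classLabels)
  if (a < 1L) return("nLatent must be >= 1")
  if (!identical(dim(object@xWeights), c(p, as.integer(a))))
    return("xWeights must be wavelengths x nLatent")
  if (!identical(dim(object@yLoadings), c(q, as.integer(a))))
    return("yLoadings must be classes x nLatent")
  if (!identical(dim(object@coefficients), c(p, q)))
    return("coefficients must be wavelengths x classes")
  if (q < 2L) return("at least two classes are required")
  TRUE
})

#' @describeIn PLSDAModel-class compact display
#' @param object a `PLSDAModel`.
#' @export
setMethod("show", "PLSDAModel", function(object) {
  cat(sprintf("PLSDAModel: %d latent variable(s), %d wavelengths, %d classes\n",
              object@nLatent, length(object@xMean),
              length(object@classLabels)))
  cat("  classes:", paste(object@classLabels, collapse = ", "), "\n")
  cat(sprintf("  trained on %d samples\n", nrow(object@fitted)))
})
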