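# Generics and accessors for the S4 side.

#' Accessors for SpectraMatrix
#'
#' `wavelengths()` returns the integer nm grid; `spectraValues()` the
#' reflectance matrix in the samples-by-wavelengths orientation used by the
#' chemometric operations; `sampleIds()` the sample identifiers;
#' `spectraLabels()` the per-sample categorical fields as a `data.frame`.
#'
#' @param x a [SpectraMatrix-class].
#' @return see each accessor's description.
#' @name spectra-accessors
#' @examples
#' sm <- SpectraMatrix(matrix(0.5, 2, 301), 1300:1600)
#' length(wavelengths(sm))
NULL

#' @rdname spectra-accessors
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname spectra-accessors
#' @export
setMethod("wavelengths", "SpectraMatrix", function(x)
  SummarizedExperiment::rowData(x)$wavelength_nm)

#' @rdname spectra-accessors
#' @export
setGeneric("spectraValues", function(x) standardGeneric("spectraValues"))

#' @rdname spectra-accessors
#' @export
setMethod("spectraValues", "SpectraMatrix", function(x)
  t(SummarizedExperiment::assay(x, "reflectance")))

#' @rdname spectra-accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname spectra-accessors
#' @export
setMethod("sampleIds", "SpectraMatrix", function(x) colnames(x))

#' @rdname spectra-accessors
#' @export
setGeneric("spectraLabels", function(x) standardGeneric("spectraLabels"))

#' @rdname spectra-accessors
#' @export
setMethod("spectraLabels", "SpectraMatrix", function(x)
  as.data.frame(SummarizedExperiment::colData(x)))
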