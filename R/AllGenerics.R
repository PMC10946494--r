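#' @include utils.R
NULL

#' Spin-system identifiers of an object
#'
#' @param x a \linkS4class{ShiftTable}, \linkS4class{ShiftModelSet},
#'   \linkS4class{PredictionMap} or \linkS4class{SyntheticShiftSpec}.
#' @return character vector of spin-system ids.
#' @export
setGeneric("systemIds", function(x) standardGeneric("systemIds"))

#' Sample identifiers of an object
#' @param x a \linkS4class{ShiftTable} or \linkS4class{ShiftPredictions}.
#' @return character vector of sample ids.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' Chemical-shift matrix of an object
#'
#' @param x object holding per-sample chemical shifts.
#' @param samplesAsRows logical; if \code{TRUE} (default) the returned matrix
#'   is samples x spin systems, the orientation of the delimited-text format.
#' @param ... further arguments for methods.
#' @return numeric matrix of shifts in ppm, \code{NA} = not detected.
#' @export
setGeneric("shiftMatrix", function(x, ...) standardGeneric("shiftMatrix"))

#' Recording precision (decimals of ppm) of a shift table
#' @param x a \linkS4class{ShiftTable}.
#' @return integer number of decimals retained on ingest.
#' @export
setGeneric("shiftPrecision", function(x) standardGeneric("shiftPrecision"))

#' Number of present (detected) values per spin system
#' @param x a \linkS4class{ShiftTable}.
#' @return named integer vector.
#' @export
setGeneric("nPresent", function(x) standardGeneric("nPresent"))

#' Center each spin-system column on its mean
#'
#' @param x a \linkS4class{ShiftTable}.
#' @param scale logical; additionally divide by the per-system standard
#'   deviation. Defaults to \code{FALSE}: the display convention for shift
#'   distributions is mean-centering only.
#' @param ... further arguments for methods.
#' @return a \linkS4class{ShiftTable} whose present values have per-system
#'   mean zero; the missingness pattern is unchanged.
#' @export
setGeneric("centerColumns", function(x, ...) standardGeneric("centerColumns"))

#' Pairwise-complete observations for one (response, predictor) pair
#'
#' @param x a \linkS4class{ShiftTable}.
#' @param responseId,predictorId spin-system ids present in \code{x}.
#' @return list with elements \code{y}, \code{x} (ppm vectors over samples
#'   where both are present, in sample order), \code{n} and \code{samples}.
#' @export
setGeneric("pairedValues", function(x, responseId, predictorId)
  standardGeneric("pairedValues"))

#' Fit every ordered pairwise linear shift model
#' @param x a \linkS4class{ShiftTable}.
#' @param ... passed to methods; see \code{\link{fitAllPairs,ShiftTable-method}}.
#' @return a \linkS4class{ShiftModelSet}.
#' @export
setGeneric("fitAllPairs", function(x, ...) standardGeneric("fitAllPairs"))

#' Model records of a fitted model set
#' @param x a \linkS4class{ShiftModelSet}.
#' @return \code{DataFrame} with one row per ordered (response, predictor) pair.
#' @export
setGeneric("models", function(x) standardGeneric("models"))

#' Relative RMSE matrix (response x predictor, percent)
#' @param x a \linkS4class{ShiftModelSet}.
#' @param ... see method.
#' @return numeric matrix in percent with \code{NA} on the diagonal and in
#'   masked (unstable or unusable) cells.
#' @export
setGeneric("rrmseMatrix", function(x, ...) standardGeneric("rrmseMatrix"))

#' Best predictor of a response spin system
#' @param x a \linkS4class{ShiftModelSet}.
#' @param responseId response spin-system id.
#' @param ... see method.
#' @return predictor id (character scalar).
#' @export
setGeneric("bestPredictor", function(x, responseId, ...)
  standardGeneric("bestPredictor"))

#' Build a minimum-error prediction map from fitted models
#' @param x a \linkS4class{ShiftModelSet}.
#' @param rootId anchor spin-system id.
#' @param ... see method.
#' @return a bound \linkS4class{PredictionMap}.
#' @export
setGeneric("buildMap", function(x, rootId, ...) standardGeneric("buildMap"))

#' Bind fitted coefficients to a prediction-map topology
#' @param map a \linkS4class{PredictionMap}.
#' @param fit a \linkS4class{ShiftModelSet} containing a model for every edge.
#' @param ... see method.
#' @return the map with coefficients, metrics and chain error estimates.
#' @export
setGeneric("bindMap", function(map, fit, ...) standardGeneric("bindMap"))

#' @rdname PredictionMap-accessors
#' @export
setGeneric("mapRoot", function(x) standardGeneric("mapRoot"))

#' @rdname PredictionMap-accessors
#' @export
setGeneric("mapEdges", function(x) standardGeneric("mapEdges"))

#' @rdname PredictionMap-accessors
#' @export
setGeneric("mapAlternates", function(x) standardGeneric("mapAlternates"))

#' @rdname PredictionMap-accessors
#' @export
setGeneric("nodeDepths", function(x) standardGeneric("nodeDepths"))

#' @rdname PredictionMap-accessors
#' @export
setGeneric("chainErrors", function(x) standardGeneric("chainErrors"))

#' Single-hop ("semi-automated") shift prediction
#'
#' Each response is predicted from the \emph{observed} shift of its predictor.
#' @param map a bound \linkS4class{PredictionMap}.
#' @param newdata a \linkS4class{ShiftTable} holding the predictor columns.
#' @param ... see method.
#' @return a \linkS4class{ShiftPredictions}.
#' @export
setGeneric("predictSemi", function(map, newdata, ...)
  standardGeneric("predictSemi"))

#' Chained ("automated") shift prediction from a single anchor
#'
#' The whole map is predicted by composing models from the root: each node
#' uses its parent's \emph{predicted} value, the root its observed anchor
#' shift.
#' @param map a bound \linkS4class{PredictionMap}.
#' @param anchor named numeric vector of observed anchor shifts per sample,
#'   or a \linkS4class{ShiftTable} containing the root system.
#' @param ... see method.
#' @return a \linkS4class{ShiftPredictions}.
#' @export
setGeneric("predictAuto", function(map, anchor, ...)
  standardGeneric("predictAuto"))

#' Compare predicted with observed shifts
#' @param object a \linkS4class{ShiftPredictions}.
#' @param observed a \linkS4class{ShiftTable} of assigned shifts.
#' @param ... see method.
#' @return \code{DataFrame}: per system \code{n}, \code{maxAbsError} and
#'   \code{rmse} in ppm and in linewidth units, plus an overall row.
#' @export
setGeneric("validatePredictions", function(object, observed, ...)
  standardGeneric("validatePredictions"))

#' Simulate a correlated chemical-shift table
#' @param spec a \linkS4class{SyntheticShiftSpec}.
#' @param nSamples number of samples (spectra) to draw.
#' @param ... see method.
#' @return a \linkS4class{ShiftTable}.
#' @export
setGeneric("simulateShiftTable", function(spec, nSamples, ...)
  standardGeneric("simulateShiftTable"))

#' Parameter-recovery report for a fitted model set
#' @param spec the \linkS4class{SyntheticShiftSpec} the data came from.
#' @param fit a \linkS4class{ShiftModelSet} fitted on data from \code{spec}.
#' @param ... see method.
#' @return \code{DataFrame} of fitted vs population slopes with z-scores.
#' @export
setGeneric("recoveryReport", function(spec, fit, ...)
  standardGeneric("recoveryReport"))

#' Pick peaks in a 1D spectrum window
#' @param x a \linkS4class{Spectrum1D}.
#' @param ... see method.
#' @return \code{DataFrame} of peaks (ppm, intensity, prominence).
#' @export
setGeneric("pickPeaks", function(x, ...) standardGeneric("pickPeaks"))

#' Rigidly calibrate the ppm axis to a reference signal
#' @param x a \linkS4class{Spectrum1D}.
#' @param ... see method.
#' @return the calibrated \linkS4class{Spectrum1D}.
#' @export
setGeneric("calibrate", function(x, ...) standardGeneric("calibrate"))

#' @rdname Spectrum1D-class
#' @export
setGeneric("ppmAxis", function(x) standardGeneric("ppmAxis"))

#' @rdname Spectrum1D-class
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' Provenance of each predicted value
#' @param x a \linkS4class{ShiftPredictions}.
#' @return character matrix (systems x samples) with values
#'   \code{"observed_anchor"}, \code{"primary_edge"}, \code{"alternate_edge"}
#'   or \code{"unavailable"}.
#' @export
setGeneric("predictionSource", function(x) standardGeneric("predictionSource"))
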