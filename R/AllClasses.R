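#' @include AllGenerics.R
NULL

.MULTIPLICITIES <- c("singlet", "doublet", "triplet", "multiplet")
.CHEM_CLASSES <- c("amino_acid", "carboxylic_acid", "sugar", "alcohol",
                   "ketone", "other")
.SOURCES <- c("observed_anchor", "primary_edge", "alternate_edge",
              "unavailable")

#' ShiftTable: per-sample chemical shifts of named spin systems
#'
#' A \code{ShiftTable} stores the chemical shift (delta, ppm) of each
#' registered spin system in each sample. It extends
#' \linkS4class{SummarizedExperiment}: rows are spin systems (with the
#' registry columns in \code{rowData}), columns are samples, and the single
#' assay \code{"delta"} holds shifts in ppm (\code{NA} = signal not detected
#' in that spectrum). Shifts are quantized half-to-even at
#' \code{shiftPrecision(x)} decimals on ingest, the recording convention of
#' high-resolution 600 MHz profiling (4 decimals by default).
#'
#' The user-facing orientation (constructor input, delimited text files) is
#' samples x systems; use \code{shiftMatrix(x)} to recover it.
#'
#' @slot precision integer scalar, decimals of ppm retained on ingest.
#'
#' @param values numeric matrix, samples x spin systems, with sample ids as
#'   row names and spin-system ids as column names.
#' @param systems optional spin-system registry (\code{DataFrame} or
#'   \code{data.frame} with an \code{id} column, see
#'   \code{\link{readSpinSystems}}); matched to columns of \code{values} by id.
#' @param precision decimals of ppm retained (default 4).
#' @param quantize logical; round values half-to-even at \code{precision} on
#'   construction (default \code{TRUE}).
#'
#' @return \code{ShiftTable()} returns a validated \code{ShiftTable}. Spin
#'   systems with no present value are dropped with a message.
#' @seealso \code{\link{readShiftTable}}, \code{\link{centerColumns}},
#'   \code{\link{pairedValues}}, \code{\link{fitAllPairs}}
#' @examples
#' m <- cbind(valine_CH3 = c(0.9860, 0.9841), lactate_CH3 = c(1.3310, NA))
#' rownames(m) <- c("s1", "s2")
#' st <- ShiftTable(m)
#' shiftMatrix(st)
#' nPresent(st)
#' @aliases ShiftTable
#' @export ShiftTable
#' @exportClass ShiftTable
setClass("ShiftTable",
  contains = "SummarizedExperiment",
  representation(precision = "integer"))

setValidity("ShiftTable", function(object) {
  msg <- character(0)
  if (length(object@precision) != 1L || is.na(object@precision) ||
      object@precision < 0L)
    msg <- c(msg, "'precision' must be a single non-negative integer")
  if (!"delta" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'delta' is required")
  else {
    a <- SummarizedExperiment::assay(object, "delta")
    if (!is.numeric(a))
      msg <- c(msg, "assay 'delta' must be numeric")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
      msg <- c(msg, "spin-system ids must be set and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
      msg <- c(msg, "sample ids must be set and unique")
    if (nrow(a) > 0L && ncol(a) > 0L) {
      empty <- rownames(object)[rowSums(is.finite(a)) == 0L]
      if (length(empty))
        msg <- c(msg, paste0("spin system(s) with no present value: ",
                             .commas(empty)))
    }
  }
  if (length(msg)) msg else TRUE
})

ShiftTable <- function(values, systems = NULL, precision = 4L,
                       quantize = TRUE) {
  if (!is.matrix(values) || !is.numeric(values))
    .stopf("'values' must be a numeric samples x systems matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    .stopf("'values' needs sample ids as rownames and system ids as colnames")
  precision <- as.integer(precision)
  if (quantize) values[] <- .roundPpm(values, precision)
  keep <- colSums(is.finite(values)) > 0L
  if (!all(keep)) {
    message("dropping spin system(s) with no present value: ",
            .commas(colnames(values)[!keep]))
    values <- values[, keep, drop = FALSE]
  }
  rd <- S4Vectors::DataFrame(id = colnames(values),
                             row.names = colnames(values))
  if (!is.null(systems)) {
    systems <- S4Vectors::DataFrame(systems)
    if (!"id" %in% colnames(systems))
      .stopf("'systems' registry must have an 'id' column")
    hit <- match(colnames(values), systems$id)
    if (anyNA(hit))
      .stopf("system(s) absent from registry: %s",
             .commas(colnames(values)[is.na(hit)]))
    rd <- systems[hit, , drop = FALSE]
    rownames(rd) <- colnames(values)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(delta = t(values)),
    rowData = rd,
    colData = S4Vectors::DataFrame(row.names = rownames(values)))
  methods::new("ShiftTable", se, precision = precision)
}

#' Spectrum1D: a one-dimensional NMR spectrum
#'
#' Minimal container for a 1D spectrum: a strictly monotone ppm axis
#' (descending order, the plotting convention, is accepted), matched
#' intensities in arbitrary units, and free-form metadata (field strength,
#' pulse program, ...).
#'
#' @slot ppm numeric, strictly monotone ppm axis (length >= 2).
#' @slot intensity numeric, same length as \code{ppm}.
#' @slot meta named list of free-form metadata.
#'
#' @param ppm,intensity,meta see slots.
#' @return a validated \code{Spectrum1D}.
#' @seealso \code{\link{readSpectrum}}, \code{\link{pickPeaks}},
#'   \code{\link{calibrate}}
#' @aliases Spectrum1D ppmAxis,Spectrum1D-method intensities,Spectrum1D-method
#' @export Spectrum1D
#' @exportClass Spectrum1D
setClass("Spectrum1D",
  representation(ppm = "numeric", intensity = "numeric", meta = "list"))

setValidity("Spectrum1D", function(object) {
  msg <- character(0)
  if (length(object@ppm) < 2L)
    msg <- c(msg, "ppm axis needs at least 2 points")
  if (length(object@ppm) != length(object@intensity))
    msg <- c(msg, "ppm and intensity lengths differ")
  if (anyNA(object@ppm) || !all(is.finite(object@ppm)))
    msg <- c(msg, "ppm axis must be finite")
  d <- diff(object@ppm)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    msg <- c(msg, "ppm axis must be strictly monotone")
  if (length(msg)) msg else TRUE
})

Spectrum1D <- function(ppm, intensity, meta = list()) {
  methods::new("Spectrum1D", ppm = as.numeric(ppm),
               intensity = as.numeric(intensity), meta = meta)
}

#' ShiftModelSet: all ordered pairwise shift models
#'
#' Holds one fitted linear model \eqn{y = a x + b} per ordered
#' (response, predictor) spin-system pair, with quality metrics, as produced
#' by \code{\link{fitAllPairs}}.
#'
#' @slot models \code{DataFrame}, one row per ordered pair with columns
#'   \code{response}, \code{predictor}, \code{a}, \code{b}, \code{aSe},
#'   \code{n}, \code{r2}, \code{rmse}, \code{rrmse}, \code{maxAbsResid},
#'   \code{usable}, \code{stable}.
#' @slot systems \code{DataFrame} registry of the modelled spin systems.
#' @slot minN integer; pairs with fewer paired observations are flagged
#'   \code{stable = FALSE} (statistically unstable, low co-detection).
#'
#' @seealso \code{\link{fitAllPairs}}, \code{\link{bestPredictor}},
#'   \code{\link{rrmseMatrix}}, \code{\link{buildMap}}
#' @aliases ShiftModelSet
#' @exportClass ShiftModelSet
setClass("ShiftModelSet",
  representation(models = "DataFrame", systems = "DataFrame",
                 minN = "integer"))

.MODEL_COLS <- c("response", "predictor", "a", "b", "aSe", "n", "r2",
                 "rmse", "rrmse", "maxAbsResid", "usable", "stable")

setValidity("ShiftModelSet", function(object) {
  msg <- character(0)
  miss <- setdiff(.MODEL_COLS, colnames(object@models))
  if (length(miss))
    msg <- c(msg, paste0("missing model columns: ", .commas(miss)))
  else {
    m <- object@models
    if (any(m$response == m$predictor))
      msg <- c(msg, "self-pairs are not allowed")
    if (anyDuplicated(paste(m$response, m$predictor)))
      msg <- c(msg, "duplicate (response, predictor) pairs")
    ok <- !is.na(m$r2)
    if (any(m$r2[ok] < -1e-8 | m$r2[ok] > 1 + 1e-8))
      msg <- c(msg, "r2 outside [0, 1]")
    if (any(m$rmse < 0, na.rm = TRUE))
      msg <- c(msg, "negative rmse")
  }
  if (length(object@minN) != 1L || is.na(object@minN))
    msg <- c(msg, "'minN' must be a single integer")
  if (length(msg)) msg else TRUE
})

#' PredictionMap: a rooted directed tree of shift models
#'
#' A prediction map is a spanning arborescence over spin systems: every
#' non-root system has exactly one primary incoming edge (a linear model
#' predicting it from its parent), and every system is reachable from the
#' root anchor. Optional alternate edges provide a fallback predictor for
#' samples where a primary predictor signal is absent (e.g. predicting the
#' acetone singlet from pyruvate when ethanol is not detected).
#'
#' @slot root anchor spin-system id.
#' @slot edges \code{DataFrame} of primary edges (\code{predictor},
#'   \code{response}, coefficients and metrics; \code{NA} until bound).
#' @slot alternates \code{DataFrame} of alternate edges, same columns.
#' @slot bound logical; \code{TRUE} once coefficients are attached.
#' @slot chain \code{DataFrame} per node: \code{depth}, \code{parent},
#'   chained error estimates \code{chainRmse} (quadrature,
#'   \eqn{\sqrt{\sum \mathrm{rmse}^2}} along the path) and
#'   \code{chainEnvelope} (sum of max absolute training residuals).
#'
#' @seealso \code{\link{publishedMap}}, \code{\link{buildMap}},
#'   \code{\link{bindMap}}, \code{\link{predictSemi}}, \code{\link{predictAuto}}
#' @aliases PredictionMap
#' @exportClass PredictionMap
setClass("PredictionMap",
  representation(root = "character", edges = "DataFrame",
                 alternates = "DataFrame", bound = "logical",
                 chain = "DataFrame"))

.EDGE_COLS <- c("predictor", "response", "a", "b", "n", "r2", "rmse",
                "rrmse", "maxAbsResid")

# Structural arborescence check shared by validity and builders.
.checkArborescence <- function(root, edges) {
  if (length(root) != 1L || is.na(root))
    return("root must be a single spin-system id")
  if (nrow(edges) == 0L) return(TRUE)
  resp <- edges$response
  if (anyDuplicated(resp))
    return("a response has more than one primary incoming edge")
  if (root %in% resp)
    return("root must not have an incoming edge")
  nodes <- c(root, resp)
  if (!all(edges$predictor %in% nodes))
    return(paste0("predictor(s) outside the node set: ",
                  .commas(setdiff(edges$predictor, nodes))))
  # reachability from root; with unique parents this also implies acyclicity
  reach <- root
  repeat {
    nxt <- resp[edges$predictor %in% reach & !(resp %in% reach)]
    if (!length(nxt)) break
    reach <- c(reach, nxt)
  }
  orphan <- setdiff(resp, reach)
  if (length(orphan))
    return(paste0("system(s) unreachable from root: ", .commas(orphan)))
  TRUE
}

setValidity("PredictionMap", function(object) {
  miss <- setdiff(.EDGE_COLS, colnames(object@edges))
  if (length(miss))
    return(paste0("missing edge columns: ", .commas(miss)))
  ok <- .checkArborescence(object@root, object@edges)
  if (!isTRUE(ok)) return(ok)
  if (nrow(object@alternates)) {
    bad <- !object@alternates$response %in% object@edges$response
    if (any(bad))
      return("alternate edge for a system not in the map")
  }
  TRUE
})

#' ShiftPredictions: predicted shifts with provenance
#'
#' Result of \code{\link{predictSemi}} or \code{\link{predictAuto}}. Extends
#' \linkS4class{SummarizedExperiment} with assays \code{"delta"} (predicted
#' shifts, ppm, quantized at 4 decimals) and \code{"source"} (provenance of
#' each value: \code{observed_anchor}, \code{primary_edge},
#' \code{alternate_edge} or \code{unavailable}). \code{rowData} carries the
#' per-system chained error estimates; \code{metadata(x)$mode} is
#' \code{"semi"} or \code{"auto"}.
#'
#' @seealso \code{\link{validatePredictions}}, \code{\link{writePredictions}}
#' @aliases ShiftPredictions predictionSource,ShiftPredictions-method
#' @exportClass ShiftPredictions
setClass("ShiftPredictions", contains = "SummarizedExperiment")

setValidity("ShiftPredictions", function(object) {
  msg <- character(0)
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("delta", "source") %in% an))
    msg <- c(msg, "assays 'delta' and 'source' are required")
  else {
    src <- SummarizedExperiment::assay(object, "source")
    if (!all(src %in% .SOURCES))
      msg <- c(msg, paste0("sources must be in {", .commas(.SOURCES), "}"))
  }
  mode <- S4Vectors::metadata(object)$mode
  if (is.null(mode) || !mode %in% c("semi", "auto"))
    msg <- c(msg, "metadata 'mode' must be 'semi' or 'auto'")
  if (length(msg)) msg else TRUE
})

#' SyntheticShiftSpec: generative description of a correlated shift dataset
#'
#' Encodes the latent-factor model the shift-mapping method assumes: each
#' spin system's shift is its nominal position plus loadings on shared
#' standard-normal matrix-effect factors plus independent Gaussian residual
#' noise, observed with a per-system detection probability and quantized at
#' the recording precision.
#'
#' @slot systems \code{DataFrame}, one row per spin system: \code{id},
#'   \code{mu} (nominal ppm), \code{sigma} (residual sd, ppm),
#'   \code{detectProb} in (0, 1], plus any registry columns.
#' @slot loadings numeric matrix (systems x factors) of sensitivities in ppm
#'   per unit factor; every system must load on at least one factor.
#' @slot seed integer default seed (\code{NA} = use current RNG stream).
#'
#' @param systems,loadings,seed see slots.
#' @return a validated \code{SyntheticShiftSpec}.
#' @seealso \code{\link{serumPanelSpec}}, \code{\link{simulateShiftTable}},
#'   \code{\link{recoveryReport}}
#' @aliases SyntheticShiftSpec
#' @export SyntheticShiftSpec
#' @exportClass SyntheticShiftSpec
setClass("SyntheticShiftSpec",
  representation(systems = "DataFrame", loadings = "matrix",
                 seed = "integer"))

setValidity("SyntheticShiftSpec", function(object) {
  msg <- character(0)
  s <- object@systems
  need <- c("id", "mu", "sigma", "detectProb")
  miss <- setdiff(need, colnames(s))
  if (length(miss))
    return(paste0("missing system columns: ", .commas(miss)))
  if (anyDuplicated(s$id)) msg <- c(msg, "system ids must be unique")
  if (any(s$sigma < 0)) msg <- c(msg, "sigma must be >= 0")
  if (any(s$detectProb <= 0 | s$detectProb > 1))
    msg <- c(msg, "detectProb must be in (0, 1]")
  L <- object@loadings
  if (nrow(L) != nrow(s))
    msg <- c(msg, "loadings must have one row per system")
  else if (any(rowSums(L != 0) == 0L))
    msg <- c(msg, "every system must load on at least one factor")
  if (length(msg)) msg else TRUE
})

SyntheticShiftSpec <- function(systems, loadings, seed = NA_integer_) {
  systems <- S4Vectors::DataFrame(systems)
  loadings <- as.matrix(loadings)
  rownames(loadings) <- systems$id
  methods::new("SyntheticShiftSpec", systems = systems, loadings = loadings,
               seed = as.integer(seed))
}
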