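#' @include AllClasses.R
NULL

.newPredictions <- function(mode, predicted, source, map, sampleNames) {
  chain <- chainErrors(map)
  rd <- chain[match(rownames(predicted), chain$system), , drop = FALSE]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(delta = predicted, source = source),
    rowData = rd,
    colData = S4Vectors::DataFrame(row.names = sampleNames),
    metadata = list(mode = mode, root = mapRoot(map)))
  methods::new("ShiftPredictions", se)
}

#' @describeIn ShiftPredictions predicted shift matrix (samples x systems by
#'   default).
#' @param x a \code{ShiftPredictions}.
#' @param samplesAsRows see \code{\link{shiftMatrix}}.
#' @export
setMethod("shiftMatrix", "ShiftPredictions",
          function(x, samplesAsRows = TRUE) {
  a <- SummarizedExperiment::assay(x, "delta")
  if (samplesAsRows) t(a) else a
})

#' @describeIn ShiftPredictions provenance matrix (systems x samples).
#' @export
setMethod("predictionSource", "ShiftPredictions", function(x)
  SummarizedExperiment::assay(x, "source"))

#' @describeIn ShiftPredictions sample ids.
#' @export
setMethod("sampleIds", "ShiftPredictions", function(x) colnames(x))

#' @describeIn ShiftPredictions spin-system ids.
#' @export
setMethod("systemIds", "ShiftPredictions", function(x) rownames(x))

setMethod("show", "ShiftPredictions", function(object) {
  src <- SummarizedExperiment::assay(object, "source")
  cat(sprintf("ShiftPredictions (%s mode): %d systems x %d samples\n",
              S4Vectors::metadata(object)$mode, nrow(object), ncol(object)))
  print(table(factor(src, levels = .SOURCES)))
})

#' @describeIn predictSemi for every edge and sample, the response shift is
#'   \code{a * x + b} with \code{x} the \emph{observed} predictor shift.
#'   When the primary predictor signal is absent in a sample and the map has
#'   an alternate edge whose predictor is observed, the alternate is used
#'   (\code{useAlternates = FALSE} disables this fallback); otherwise the
#'   value is \code{unavailable}. Missingness is data, not an error, but
#'   every predictor system must exist as a column of \code{newdata}. The
#'   root carries its observed value when present.
#' @param useAlternates fall back to alternate edges on missing primary
#'   predictors (default \code{TRUE}).
#' @param digits decimals of ppm for reported predictions (default 4;
#'   \code{NULL} = no quantization).
#' @export
setMethod("predictSemi", c("PredictionMap", "ShiftTable"),
          function(map, newdata, useAlternates = TRUE, digits = 4L) {
  if (!map@bound) .stopf("map is not bound to fitted models; see bindMap()")
  edges <- map@edges
  alts <- if (useAlternates) map@alternates else .emptyEdges()
  needed <- unique(c(map@root, edges$predictor, alts$predictor))
  missSys <- setdiff(needed, systemIds(newdata))
  if (length(missSys))
    .stopf("predictor system(s) absent from the input table: %s",
           .commas(missSys))
  obs <- SummarizedExperiment::assay(newdata, "delta")
  samples <- colnames(newdata)
  nodes <- systemIds(map)
  pred <- matrix(NA_real_, length(nodes), length(samples),
                 dimnames = list(nodes, samples))
  src <- matrix("unavailable", length(nodes), length(samples),
                dimnames = list(nodes, samples))
  rootObs <- obs[map@root, ]
  pred[map@root, ] <- rootObs
  src[map@root, ][is.finite(rootObs)] <- "observed_anchor"
  for (k in seq_len(nrow(edges))) {
    xv <- obs[edges$predictor[k], ]
    ok <- is.finite(xv)
    pred[edges$response[k], ok] <- edges$a[k] * xv[ok] + edges$b[k]
    src[edges$response[k], ok] <- "primary_edge"
  }
  for (k in seq_len(nrow(alts))) {
    xv <- obs[alts$predictor[k], ]
    slot <- src[alts$response[k], ] == "unavailable" & is.finite(xv)
    pred[alts$response[k], slot] <- alts$a[k] * xv[slot] + alts$b[k]
    src[alts$response[k], slot] <- "alternate_edge"
  }
  if (!is.null(digits)) pred <- .roundPpm(pred, digits)
  .newPredictions("semi", pred, src, map, samples)
})

#' @describeIn predictAuto walks the map in topological order from the
#'   root: the root takes the observed anchor shift and every other system
#'   is predicted from its parent's \emph{predicted} value, so a node at
#'   depth d is the composition of d affine models applied to the anchor.
#'   Samples with a missing anchor value are reported entirely
#'   \code{unavailable} (with a message). Per-system chained error
#'   estimates from the map binding are available via
#'   \code{chainErrors(map)} and in \code{rowData} of the result.
#' @param digits decimals of ppm for reported predictions (default 4;
#'   \code{NULL} = no quantization, useful to inspect the exact affine
#'   composition).
#' @export
setMethod("predictAuto", c("PredictionMap", "numeric"),
          function(map, anchor, digits = 4L) {
  if (!map@bound) .stopf("map is not bound to fitted models; see bindMap()")
  if (is.null(names(anchor)))
    names(anchor) <- paste0("sample", seq_along(anchor))
  edges <- map@edges
  nodes <- systemIds(map)
  samples <- names(anchor)
  pred <- matrix(NA_real_, length(nodes), length(samples),
                 dimnames = list(nodes, samples))
  src <- matrix("unavailable", length(nodes), length(samples),
                dimnames = list(nodes, samples))
  ok <- is.finite(anchor)
  if (any(!ok))
    message("skipping ", sum(!ok), " sample(s) with no anchor value: ",
            .commas(samples[!ok]))
  pred[map@root, ok] <- anchor[ok]
  src[map@root, ok] <- "observed_anchor"
  # parents precede children when edges are walked in depth order
  o <- order(nodeDepths(map)[edges$response])
  for (k in o) {
    xv <- pred[edges$predictor[k], ]
    pred[edges$response[k], ok] <- edges$a[k] * xv[ok] + edges$b[k]
    src[edges$response[k], ok] <- "primary_edge"
  }
  if (!is.null(digits)) pred <- .roundPpm(pred, digits)
  .newPredictions("auto", pred, src, map, samples)
})

#' @describeIn predictAuto convenience: extract the anchor (root) column
#'   from a \linkS4class{ShiftTable} and chain from it.
#' @export
setMethod("predictAuto", c("PredictionMap", "ShiftTable"),
          function(map, anchor, digits = 4L) {
  if (!mapRoot(map) %in% systemIds(anchor))
    .stopf("anchor system '%s' absent from the input table", mapRoot(map))
  av <- SummarizedExperiment::assay(anchor, "delta")[mapRoot(map), ]
  predictAuto(map, setNames(as.numeric(av), colnames(anchor)),
              digits = digits)
})

#' @describeIn validatePredictions per spin system, compares predicted with
#'   observed (assigned) shifts over the samples where both exist and
#'   reports the sample count, maximum absolute error and RMSE, in ppm and
#'   in linewidth units (error / \code{linewidthPpm}). A system with no
#'   overlap is reported with \code{n = 0} and empty metrics. The anchor
#'   system (observed, zero error by construction) is excluded. The last
#'   row, \code{".overall"}, pools all evaluated values.
#' @param linewidthPpm full width at half maximum in ppm; 0.001 ppm
#'   corresponds to one linewidth at 600 MHz (a ~0.05 ppm shift range is
#'   ~50 linewidths). Adjust for other field strengths.
#' @export
setMethod("validatePredictions", c("ShiftPredictions", "ShiftTable"),
          function(object, observed, linewidthPpm = 0.001) {
  if (linewidthPpm <= 0) .stopf("'linewidthPpm' must be positive")
  sys <- intersect(systemIds(object), systemIds(observed))
  root <- S4Vectors::metadata(object)$root
  sys <- setdiff(sys, root)
  if (!length(sys))
    .stopf("no predicted system overlaps the observed table")
  pred <- SummarizedExperiment::assay(object, "delta")
  src <- SummarizedExperiment::assay(object, "source")
  obs <- SummarizedExperiment::assay(observed, "delta")
  common <- intersect(colnames(pred), colnames(obs))
  allErr <- numeric(0)
  rows <- lapply(sys, function(s) {
    e <- pred[s, common] - obs[s, common]
    e <- e[is.finite(e) & src[s, common] != "unavailable"]
    allErr <<- c(allErr, e)
    if (!length(e))
      return(data.frame(system = s, n = 0L, maxAbsError = NA_real_,
                        rmse = NA_real_, maxAbsErrorLw = NA_real_,
                        rmseLw = NA_real_))
    data.frame(system = s, n = length(e), maxAbsError = max(abs(e)),
               rmse = sqrt(mean(e^2)),
               maxAbsErrorLw = max(abs(e)) / linewidthPpm,
               rmseLw = sqrt(mean(e^2)) / linewidthPpm)
  })
  overall <- data.frame(system = ".overall", n = length(allErr),
                        maxAbsError = if (length(allErr)) max(abs(allErr))
                                      else NA_real_,
                        rmse = if (length(allErr)) sqrt(mean(allErr^2))
                               else NA_real_)
  overall$maxAbsErrorLw <- overall$maxAbsError / linewidthPpm
  overall$rmseLw <- overall$rmse / linewidthPpm
  out <- S4Vectors::DataFrame(do.call(rbind, c(rows, list(overall))))
  S4Vectors::metadata(out)$linewidthPpm <- linewidthPpm
  out
})

#' Export predictions (long format) to CSV
#'
#' One row per (sample, system): predicted shift, provenance and, when an
#' observed table is supplied, the observed shift and the error in ppm and
#' linewidth units.
#'
#' @param x a \linkS4class{ShiftPredictions}.
#' @param path output CSV file.
#' @param observed optional \linkS4class{ShiftTable} of assigned shifts.
#' @param linewidthPpm linewidth conversion (default 0.001 ppm).
#' @return \code{path}, invisibly.
#' @export
writePredictions <- function(x, path, observed = NULL,
                             linewidthPpm = 0.001) {
  pred <- SummarizedExperiment::assay(x, "delta")
  src <- SummarizedExperiment::assay(x, "source")
  df <- data.frame(
    sample = rep(colnames(pred), each = nrow(pred)),
    system = rep(rownames(pred), times = ncol(pred)),
    predicted = as.vector(pred),
    source = as.vector(src),
    stringsAsFactors = FALSE)
  if (!is.null(observed)) {
    obs <- SummarizedExperiment::assay(observed, "delta")
    hit <- cbind(match(df$system, rownames(obs)),
                 match(df$sample, colnames(obs)))
    df$observed <- obs[hit]
    df$error_ppm <- df$predicted - df$observed
    df$error_linewidths <- df$error_ppm / linewidthPpm
  }
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate the map on an external assigned-shift cohort
#'
#' Integration entry point for an independently assigned cohort (e.g. a
#' plasma validation set exported as CSV): reads the table, predicts with
#' the supplied bound map in the requested mode, and compares predicted
#' with assigned shifts.
#'
#' @param map a bound \linkS4class{PredictionMap}.
#' @param tablePath CSV/TSV of assigned shifts (see
#'   \code{\link{readShiftTable}}).
#' @param mode \code{"semi"} (single-hop from observed predictors) or
#'   \code{"auto"} (chained from the anchor).
#' @param linewidthPpm linewidth conversion (default 0.001 ppm).
#' @param ... passed to \code{\link{readShiftTable}}.
#' @return the \code{\link{validatePredictions}} report.
#' @export
validateOnCohort <- function(map, tablePath, mode = c("semi", "auto"),
                             linewidthPpm = 0.001, ...) {
  mode <- match.arg(mode)
  tab <- readShiftTable(tablePath, ...)
  p <- if (mode == "semi") predictSemi(map, tab) else predictAuto(map, tab)
  validatePredictions(p, tab, linewidthPpm = linewidthPpm)
}
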