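#' @include AllClasses.R
NULL

#' @describeIn ShiftTable spin-system ids (column order of the text format).
#' @param x a \code{ShiftTable}.
#' @export
setMethod("systemIds", "ShiftTable", function(x) rownames(x))

#' @describeIn ShiftTable sample ids, in input order.
#' @export
setMethod("sampleIds", "ShiftTable", function(x) colnames(x))

#' @describeIn ShiftTable shift matrix; samples x systems by default.
#' @param samplesAsRows see \code{\link{shiftMatrix}}.
#' @export
setMethod("shiftMatrix", "ShiftTable", function(x, samplesAsRows = TRUE) {
  a <- SummarizedExperiment::assay(x, "delta")
  if (samplesAsRows) t(a) else a
})

#' @describeIn ShiftTable decimals of ppm retained on ingest.
#' @export
setMethod("shiftPrecision", "ShiftTable", function(x) x@precision)

#' @describeIn ShiftTable per-system count of present (detected) values.
#' @export
setMethod("nPresent", "ShiftTable", function(x) {
  a <- SummarizedExperiment::assay(x, "delta")
  setNames(as.integer(rowSums(is.finite(a))), rownames(a))
})

#' @describeIn ShiftTable subtract (and optionally scale by) each
#'   spin system's mean over present values; missing entries untouched.
#'   Idempotent for \code{scale = FALSE}. Centered values are no longer
#'   quantized at the recording precision.
#' @param scale divide by the per-system standard deviation as well.
#' @export
setMethod("centerColumns", "ShiftTable", function(x, scale = FALSE) {
  a <- SummarizedExperiment::assay(x, "delta")
  mu <- rowMeans(a, na.rm = TRUE)
  bad <- !is.finite(mu)
  if (any(bad))
    .stopf("no present values to center for: %s", .commas(rownames(a)[bad]))
  a <- a - mu
  if (scale) {
    s <- apply(a, 1L, sd, na.rm = TRUE)
    s[!is.finite(s) | s == 0] <- 1
    a <- a / s
  }
  out <- x
  SummarizedExperiment::assays(out)[["delta"]] <- a
  S4Vectors::metadata(out)$centered <- TRUE
  out
})

#' @describeIn ShiftTable pairwise-complete (response, predictor)
#'   observations: only samples where both shifts are present, in sample
#'   order.
#' @param responseId,predictorId spin-system ids.
#' @export
setMethod("pairedValues", "ShiftTable",
          function(x, responseId, predictorId) {
  ids <- rownames(x)
  miss <- setdiff(c(responseId, predictorId), ids)
  if (length(miss))
    .stopf("unknown spin system(s): %s", .commas(miss))
  if (responseId == predictorId)
    .stopf("self-pair requested for '%s'", responseId)
  a <- SummarizedExperiment::assay(x, "delta")
  yv <- a[responseId, ]
  xv <- a[predictorId, ]
  keep <- is.finite(yv) & is.finite(xv)
  list(y = unname(yv[keep]), x = unname(xv[keep]),
       n = sum(keep), samples = colnames(x)[keep])
})

#' Read a chemical-shift table from delimited text
#'
#' The expected layout is the recording convention for assigned shifts: a
#' header row of spin-system ids, one row per spectrum with the sample id in
#' the first column, shifts in ppm, and empty cells or \code{"NA"} for
#' signals not detected. Values are quantized half-to-even at
#' \code{precision} decimals on ingest.
#'
#' @param path CSV or TSV file (separator inferred from the extension unless
#'   given).
#' @param systems optional registry (see \code{\link{readSpinSystems}}) used
#'   to annotate and check the columns.
#' @param precision decimals of ppm retained (default 4).
#' @param sep field separator; default \code{","}, or \code{"\t"} for
#'   \code{.tsv}/\code{.txt} files.
#' @return a \linkS4class{ShiftTable}; system columns with no present value
#'   are dropped with a message.
#' @seealso \code{\link{writeShiftTable}}
#' @export
readShiftTable <- function(path, systems = NULL, precision = 4L, sep = NULL) {
  if (!file.exists(path)) .stopf("shift table not found: %s", path)
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           comment.char = "", quote = "\"",
                           na.strings = character(0))
  if (ncol(raw) < 2L)
    .stopf("'%s': need a sample-id column plus at least one system", path)
  sampleIds <- raw[[1L]]
  if (anyDuplicated(sampleIds))
    .stopf("duplicate sample id(s): %s",
           .commas(unique(sampleIds[duplicated(sampleIds)])))
  sys <- colnames(raw)[-1L]
  if (anyDuplicated(sys))
    .stopf("duplicate system id(s) in header: %s",
           .commas(unique(sys[duplicated(sys)])))
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  vals[vals %in% c("", "NA", "na", "NaN")] <- NA_character_
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    b <- bad[1L, ]
    .stopf("non-numeric value \"%s\" at row %d (sample '%s'), column '%s'",
           vals[b[1L], b[2L]], b[1L], sampleIds[b[1L]], sys[b[2L]])
  }
  dimnames(num) <- list(sampleIds, sys)
  ShiftTable(num, systems = systems, precision = precision)
}

#' Write a chemical-shift table to delimited text
#'
#' Inverse of \code{\link{readShiftTable}}: values are printed with exactly
#' \code{shiftPrecision(x)} decimals, so a read/write/read round trip
#' reproduces the table bit-identically.
#'
#' @param x a \linkS4class{ShiftTable}.
#' @param path output file.
#' @param sep field separator (default \code{","}).
#' @return \code{path}, invisibly.
#' @export
writeShiftTable <- function(x, path, sep = ",") {
  m <- shiftMatrix(x)
  p <- shiftPrecision(x)
  txt <- formatC(m, format = "f", digits = p)
  txt[!is.finite(m)] <- "NA"
  df <- data.frame(sample = rownames(m), txt, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

setMethod("show", "ShiftTable", function(object) {
  cat("ShiftTable:", ncol(object), "samples x", nrow(object),
      "spin systems;", "precision", object@precision, "decimals\n")
  methods::callNextMethod()
})
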