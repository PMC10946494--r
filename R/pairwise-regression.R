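#' @include AllClasses.R
NULL

#' Fit one pairwise shift model y = a x + b
#'
#' Ordinary least squares with intercept of a response shift vector on a
#' predictor shift vector (both in ppm, pairwise-complete). Reported
#' metrics: \code{r2} = 1 - SSres/SStot; \code{rmse} = sqrt(SSres / n) (or
#' SSres / (n - 2) with \code{rmseDenom = "df"}); \code{rrmse} = 100 * rmse /
#' |mean(y)| in percent — relative to the response's typical position, so an
#' RMSE of 1e-4 ppm on a signal near 1 ppm reads as 0.01\%; and
#' \code{maxAbsResid}, the training error envelope in ppm. \code{aSe} is the
#' classical standard error of the slope.
#'
#' A constant predictor is a degenerate design and an error. A constant
#' response leaves \code{r2} undefined; the model is returned with
#' \code{usable = FALSE}.
#'
#' @param y,x numeric vectors of equal length (n >= 2), response and
#'   predictor shifts.
#' @param minN pairs with \code{n < minN} are flagged \code{stable = FALSE}
#'   (default 2 here; \code{\link{fitAllPairs}} applies its own threshold).
#' @param rmseDenom \code{"n"} (default) or \code{"df"} = n - 2.
#' @return named list with fields \code{a}, \code{b}, \code{aSe}, \code{n},
#'   \code{r2}, \code{rmse}, \code{rrmse}, \code{maxAbsResid},
#'   \code{usable}, \code{stable}.
#' @examples
#' fitPair(c(3, 5, 7), c(1, 2, 3))   # exact line: a = 2, b = 1, r2 = 1
#' @export
fitPair <- function(y, x, minN = 2L, rmseDenom = c("n", "df")) {
  rmseDenom <- match.arg(rmseDenom)
  if (length(y) != length(x)) .stopf("'y' and 'x' lengths differ")
  keep <- is.finite(y) & is.finite(x)
  y <- y[keep]; x <- x[keep]
  n <- length(y)
  if (n < 2L) .stopf("need at least 2 paired observations, got %d", n)
  if (diff(range(x)) == 0)
    .stopf("degenerate predictor: x is constant (%.4f)", x[1L])
  fit <- stats::.lm.fit(cbind(1, x), y)
  b <- fit$coefficients[1L]; a <- fit$coefficients[2L]
  res <- fit$residuals
  ssr <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  usable <- sst > 0
  r2 <- if (usable) min(max(1 - ssr / sst, 0), 1) else NA_real_
  denom <- if (rmseDenom == "n") n else max(n - 2L, 1L)
  rmse <- sqrt(ssr / denom)
  ybar <- mean(y)
  rrmse <- if (abs(ybar) > .Machine$double.eps) 100 * rmse / abs(ybar)
           else NA_real_
  sxx <- sum((x - mean(x))^2)
  aSe <- if (n > 2L) sqrt(ssr / (n - 2L) / sxx) else NA_real_
  list(a = unname(a), b = unname(b), aSe = unname(aSe), n = n, r2 = r2,
       rmse = rmse, rrmse = rrmse, maxAbsResid = max(abs(res)),
       usable = usable, stable = n >= minN)
}

#' @describeIn fitAllPairs fit every ordered (response, predictor) pair of
#'   spin systems on pairwise-complete observations. Pairs with fewer than 2
#'   paired samples are absent; pairs with \code{2 <= n < minN} are recorded
#'   but flagged \code{stable = FALSE} (statistically unstable through low
#'   co-detection, e.g. two rarely detected metabolites). k fully observed
#'   systems give exactly k(k-1) models. Degenerate pairs (constant
#'   predictor or response) are recorded with \code{usable = FALSE}.
#' @param minN stability threshold on the paired-sample count (default 50).
#' @param rmseDenom passed to \code{\link{fitPair}}.
#' @export
setMethod("fitAllPairs", "ShiftTable",
          function(x, minN = 50L, rmseDenom = c("n", "df")) {
  rmseDenom <- match.arg(rmseDenom)
  ids <- systemIds(x)
  if (length(ids) < 2L) .stopf("need at least 2 spin systems")
  a <- SummarizedExperiment::assay(x, "delta")
  fin <- is.finite(a)
  np <- length(ids) * (length(ids) - 1L)
  rec <- list(response = character(np), predictor = character(np),
              a = numeric(np), b = numeric(np), aSe = numeric(np),
              n = integer(np), r2 = numeric(np), rmse = numeric(np),
              rrmse = numeric(np), maxAbsResid = numeric(np),
              usable = logical(np), stable = logical(np))
  k <- 0L
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i == j) next
    keep <- fin[i, ] & fin[j, ]
    n <- sum(keep)
    if (n < 2L) next
    yv <- a[i, keep]; xv <- a[j, keep]
    one <- if (diff(range(xv)) == 0) {
      list(a = NA_real_, b = NA_real_, aSe = NA_real_, n = n,
           r2 = NA_real_, rmse = NA_real_, rrmse = NA_real_,
           maxAbsResid = NA_real_, usable = FALSE, stable = n >= minN)
    } else {
      fitPair(yv, xv, minN = minN, rmseDenom = rmseDenom)
    }
    k <- k + 1L
    rec$response[k] <- ids[i]; rec$predictor[k] <- ids[j]
    for (f in names(one)) rec[[f]][k] <- one[[f]]
  }
  m <- S4Vectors::DataFrame(lapply(rec, function(v) v[seq_len(k)]))
  m <- m[, .MODEL_COLS]
  reg <- rowData(x)
  methods::new("ShiftModelSet", models = m, systems = reg,
               minN = as.integer(minN))
})

#' @describeIn ShiftModelSet model records, one row per ordered pair.
#' @param x a \code{ShiftModelSet}.
#' @export
setMethod("models", "ShiftModelSet", function(x) x@models)

#' @describeIn ShiftModelSet ids of the modelled spin systems.
#' @export
setMethod("systemIds", "ShiftModelSet", function(x) x@systems$id)

#' @describeIn ShiftModelSet relative-RMSE table, responses as rows and
#'   predictors as columns, in percent. The diagonal is \code{NA};
#'   unusable models, and (with \code{maskUnstable}) models below the
#'   stability threshold, are masked as \code{NA}.
#' @param maskUnstable mask unstable cells (default \code{TRUE}).
#' @export
setMethod("rrmseMatrix", "ShiftModelSet", function(x, maskUnstable = TRUE) {
  ids <- systemIds(x)
  out <- matrix(NA_real_, length(ids), length(ids),
                dimnames = list(response = ids, predictor = ids))
  m <- x@models
  keep <- m$usable & (!maskUnstable | m$stable)
  out[cbind(m$response[keep], m$predictor[keep])] <- m$rrmse[keep]
  out
})

#' @describeIn ShiftModelSet the predictor whose model for
#'   \code{responseId} has the smallest |rRMSE| among stable, usable
#'   candidates; ties broken by higher r2, then lexicographic predictor id.
#'   Errors (listing any unstable candidates) when no stable model exists.
#' @param responseId response spin-system id.
#' @param candidates optional character vector restricting the candidate
#'   predictors (e.g. to one chemical class).
#' @export
setMethod("bestPredictor", "ShiftModelSet",
          function(x, responseId, candidates = NULL) {
  m <- x@models
  if (!responseId %in% m$response)
    .stopf("no models with response '%s'", responseId)
  m <- m[m$response == responseId, , drop = FALSE]
  if (!is.null(candidates))
    m <- m[m$predictor %in% candidates, , drop = FALSE]
  ok <- m$usable & m$stable & is.finite(m$rrmse)
  if (!any(ok)) {
    unstable <- m$predictor[m$usable & !m$stable]
    .stopf("no stable predictor for '%s'%s", responseId,
           if (length(unstable))
             paste0("; unstable candidate(s): ", .commas(unstable))
           else "")
  }
  m <- m[ok, , drop = FALSE]
  o <- order(abs(m$rrmse), -m$r2, m$predictor)
  m$predictor[o[1L]]
})

setMethod("show", "ShiftModelSet", function(object) {
  m <- object@models
  cat("ShiftModelSet:", nrow(m), "pairwise models over",
      length(systemIds(object)), "spin systems (minN =", object@minN, ")\n")
  cat(sprintf("  stable: %d | usable: %d | median rRMSE (stable): %.4g%%\n",
              sum(m$stable), sum(m$usable),
              stats::median(m$rrmse[m$stable & m$usable], na.rm = TRUE)))
})

#' Serialize / deserialize a model set as JSON
#'
#' One record per ordered pair with all model fields; round-trip safe.
#'
#' @param x a \linkS4class{ShiftModelSet}.
#' @param path JSON file.
#' @return \code{writeModelSet}: \code{path} invisibly;
#'   \code{readModelSet}: a \linkS4class{ShiftModelSet}.
#' @export
writeModelSet <- function(x, path) {
  payload <- list(minN = x@minN,
                  systems = as.data.frame(x@systems),
                  models = as.data.frame(x@models))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname writeModelSet
#' @export
readModelSet <- function(path) {
  if (!file.exists(path)) .stopf("model file not found: %s", path)
  p <- jsonlite::fromJSON(path)
  m <- S4Vectors::DataFrame(p$models)
  m$n <- as.integer(m$n)
  sys <- S4Vectors::DataFrame(p$systems)
  rownames(sys) <- sys$id
  methods::new("ShiftModelSet", models = m[.MODEL_COLS], systems = sys,
               minN = as.integer(p$minN))
}
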