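#' @include AllClasses.R
NULL

#' @rdname Spectrum1D-class
#' @param x a \code{Spectrum1D}.
#' @export
setMethod("ppmAxis", "Spectrum1D", function(x) x@ppm)

#' @rdname Spectrum1D-class
#' @export
setMethod("intensities", "Spectrum1D", function(x) x@intensity)

setMethod("show", "Spectrum1D", function(object) {
  r <- range(object@ppm)
  cat(sprintf("Spectrum1D: %d points, %.4f .. %.4f ppm\n",
              length(object@ppm), r[1L], r[2L]))
  if (length(object@meta))
    cat("meta:", .commas(paste(names(object@meta), unlist(object@meta),
                               sep = "=")), "\n")
})

#' Read a 1D spectrum
#'
#' Supports two plain-text forms: two-column \code{ppm<sep>intensity} (any
#' whitespace or comma separation, \code{#} comments), and JCAMP-DX with an
#' \code{##XYDATA=(X++(Y..Y))} block in AFFN or fixed form (the uncompressed
#' numeric representations; SQZ/DIF packed tables are not supported). A
#' descending ppm axis is kept as is.
#'
#' @param path input file.
#' @param format \code{"auto"} (default; JCAMP-DX is recognised by a leading
#'   \code{##} line), \code{"xy"} or \code{"jcamp"}.
#' @return a \linkS4class{Spectrum1D}; JCAMP header records (title, units,
#'   frequency) are kept in \code{meta}.
#' @export
readSpectrum <- function(path, format = c("auto", "xy", "jcamp")) {
  format <- match.arg(format)
  if (!file.exists(path)) .stopf("spectrum file not found: %s", path)
  if (format == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    format <- if (startsWith(trimws(first), "##")) "jcamp" else "xy"
  }
  if (format == "xy") .readXY(path) else .readJcamp(path)
}

.readXY <- function(path) {
  d <- utils::read.table(path, header = FALSE, comment.char = "#",
                         col.names = c("ppm", "intensity"),
                         colClasses = "numeric",
                         sep = "", fill = FALSE)
  Spectrum1D(d$ppm, d$intensity, meta = list(source = basename(path)))
}

# Minimal JCAMP-DX 1D reader: XYDATA=(X++(Y..Y)), AFFN / fixed numerics.
.readJcamp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\$\\$.*$", "", lines)            # strip comments
  ldr <- grepl("^\\s*##", lines)
  getLdr <- function(name) {
    key <- paste0("^\\s*##\\s*", name, "\\s*=")
    hit <- grep(key, lines[ldr], ignore.case = TRUE, value = TRUE)
    if (!length(hit)) return(NA_character_)
    trimws(sub(key, "", hit[1L], ignore.case = TRUE))
  }
  num <- function(name) suppressWarnings(as.numeric(getLdr(name)))
  xyIdx <- grep("^\\s*##\\s*XYDATA\\s*=", lines, ignore.case = TRUE)
  if (!length(xyIdx)) .stopf("no ##XYDATA block in %s", path)
  endIdx <- grep("^\\s*##\\s*END\\s*=?", lines, ignore.case = TRUE)
  endIdx <- endIdx[endIdx > xyIdx[1L]]
  endIdx <- if (length(endIdx)) endIdx[1L] else length(lines) + 1L
  body <- lines[seq(xyIdx[1L] + 1L, endIdx - 1L)]
  body <- body[!grepl("^\\s*##", body) & nzchar(trimws(body))]
  firstx <- num("FIRSTX"); lastx <- num("LASTX")
  npts <- num("NPOINTS")
  xf <- num("XFACTOR"); yf <- num("YFACTOR")
  if (is.na(xf)) xf <- 1
  if (is.na(yf)) yf <- 1
  if (is.na(firstx) || is.na(lastx) || is.na(npts))
    .stopf("JCAMP header must define FIRSTX, LASTX and NPOINTS")
  toks <- strsplit(trimws(body), "[,;[:space:]]+")
  y <- unlist(lapply(toks, function(tk) {
    v <- suppressWarnings(as.numeric(tk))
    if (anyNA(v)) .stopf("unsupported (non-AFFN?) data token in XYDATA")
    v[-1L]                                        # drop leading X value
  }), use.names = FALSE)
  if (length(y) != npts)
    .stopf("XYDATA holds %d points but NPOINTS=%d", length(y), npts)
  ppm <- seq(firstx, lastx, length.out = npts) * xf
  meta <- list(title = getLdr("TITLE"), xunits = getLdr("XUNITS"),
               frequencyMHz = num(".OBSERVE FREQUENCY"),
               source = basename(path))
  Spectrum1D(ppm, y * yf, meta = meta[!vapply(meta, function(z)
    is.null(z) || (length(z) == 1L && is.na(z)), logical(1L))])
}

# Topographic prominence of a local maximum at index i (within the window):
# drop to the lowest point that must be crossed before reaching higher
# terrain, on the more favourable side.
.prominence <- function(y, i) {
  h <- y[i]
  left <- if (i > 1L) {
    j <- i - 1L; lo <- y[j]
    while (j >= 1L && y[j] <= h) { lo <- min(lo, y[j]); j <- j - 1L }
    lo
  } else h
  right <- if (i < length(y)) {
    j <- i + 1L; lo <- y[j]
    while (j <= length(y) && y[j] <= h) { lo <- min(lo, y[j]); j <- j + 1L }
    lo
  } else h
  h - max(left, right)
}

#' @describeIn pickPeaks local maxima within a ppm window whose topographic
#'   prominence is at least \code{minProminence} times the window's maximum
#'   intensity. Peak positions are the axis value at the maximum sample,
#'   quantized at 4 decimals of ppm (instrument resolution of >65k points
#'   over ~20 ppm makes the sampled maximum accurate well below the third
#'   decimal); sorted by decreasing intensity. A flat window returns an
#'   empty peak list. Prominence is referenced to the window, not the whole
#'   spectrum, so crowded and sparse regions can share one threshold.
#' @param minProminence fraction of the window's maximum intensity in (0, 1].
#' @param window ppm interval \code{c(lo, hi)}; default the full axis.
#' @param refine logical; refine each position by a 3-point parabolic
#'   interpolation before quantizing (default \code{FALSE}).
#' @param digits decimals of ppm for reported positions (default 4).
#' @export
setMethod("pickPeaks", "Spectrum1D",
          function(x, minProminence = 0.05, window = NULL, refine = FALSE,
                   digits = 4L) {
  if (!is.numeric(minProminence) || minProminence <= 0 || minProminence > 1)
    .stopf("'minProminence' must be in (0, 1]")
  ppm <- x@ppm; y <- x@intensity
  if (is.null(window)) window <- range(ppm)
  window <- sort(window)
  if (window[1L] == window[2L]) .stopf("empty ppm window")
  keep <- which(ppm >= window[1L] & ppm <= window[2L])
  if (!length(keep)) .stopf("window [%g, %g] does not overlap the axis",
                            window[1L], window[2L])
  ppm <- ppm[keep]; y <- y[keep]
  emptyPeaks <- S4Vectors::DataFrame(ppm = numeric(0), intensity = numeric(0),
                                     prominence = numeric(0))
  if (length(y) < 3L || diff(range(y)) == 0) return(emptyPeaks)
  # local maxima via sign changes of the first difference; plateaus are
  # collapsed to their first sample
  s <- sign(diff(y))
  for (k in seq_along(s)) if (s[k] == 0 && k > 1L) s[k] <- s[k - 1L]
  idx <- which(diff(s) < 0 & s[-length(s)] > 0) + 1L
  if (!length(idx)) return(emptyPeaks)
  prom <- vapply(idx, function(i) .prominence(y, i), numeric(1L))
  thr <- minProminence * max(y)
  sel <- prom >= thr
  if (!any(sel)) return(emptyPeaks)
  idx <- idx[sel]; prom <- prom[sel]
  pos <- ppm[idx]
  if (refine) {
    pos <- vapply(seq_along(idx), function(k) {
      i <- idx[k]
      if (i <= 1L || i >= length(y)) return(ppm[i])
      y0 <- y[i - 1L]; y1 <- y[i]; y2 <- y[i + 1L]
      den <- y0 - 2 * y1 + y2
      if (den == 0) return(ppm[i])
      ppm[i] + 0.5 * (y0 - y2) / den * (ppm[i + 1L] - ppm[i])
    }, numeric(1L))
  }
  o <- order(y[idx], decreasing = TRUE)
  S4Vectors::DataFrame(ppm = .roundPpm(pos[o], digits),
                       intensity = y[idx][o], prominence = prom[o])
})

#' @describeIn calibrate rigidly shift the ppm axis so that a reference
#'   signal observed at \code{observedRefPpm} lands on \code{targetRefPpm}
#'   (e.g. the glucose anomeric doublet at 5.2410 ppm, or TMSP at 0).
#'   Intensities and all pairwise ppm differences are untouched. A shift
#'   larger than 0.5 ppm is suspicious and raises a warning but is applied.
#' @param observedRefPpm position at which the reference was found.
#' @param targetRefPpm position the reference should have.
#' @export
setMethod("calibrate", "Spectrum1D",
          function(x, observedRefPpm, targetRefPpm) {
  rng <- range(x@ppm)
  for (v in c(observedRefPpm, targetRefPpm))
    if (v < rng[1L] - 1 || v > rng[2L] + 1)
      .stopf("reference %.4f ppm is outside the axis range [%.4f, %.4f] +/- 1",
             v, rng[1L], rng[2L])
  shift <- targetRefPpm - observedRefPpm
  if (abs(shift) > 0.5)
    .warnf("calibration shift %.4f ppm exceeds 0.5 ppm; check the reference",
           shift)
  out <- x
  out@ppm <- x@ppm + shift
  out@meta$calibrationShiftPpm <- shift
  out
})

#' Recorded position of a multiplet
#'
#' The recorded shift of a split signal is the arithmetic mean of its
#' component positions (so a symmetric doublet or triplet is recorded at its
#' center, and a singlet at itself), quantized at \code{digits} decimals.
#' When a multiplet is partially overlapped the caller must supply the
#' visible components (after any J-coupling arithmetic); no overlap
#' resolution is attempted here.
#'
#' @param componentPpms ppm positions of the multiplet components (1 to 16).
#' @param digits decimals of ppm (default 4).
#' @return single ppm value.
#' @examples
#' multipletCenter(c(1.3280, 1.3390))   # doublet -> 1.3335
#' @export
multipletCenter <- function(componentPpms, digits = 4L) {
  if (!length(componentPpms)) .stopf("no multiplet components given")
  if (length(componentPpms) > 16L)
    .stopf("more than 16 components; not a single multiplet")
  if (!all(is.finite(componentPpms)))
    .stopf("multiplet components must be finite ppm values")
  .roundPpm(mean(componentPpms), digits)
}
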