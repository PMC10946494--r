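#' @include AllClasses.R arborescence.R
NULL

.emptyEdges <- function(predictor = character(0), response = character(0)) {
  n <- length(response)
  S4Vectors::DataFrame(predictor = predictor, response = response,
                       a = rep(NA_real_, n), b = rep(NA_real_, n),
                       n = rep(NA_integer_, n), r2 = rep(NA_real_, n),
                       rmse = rep(NA_real_, n), rrmse = rep(NA_real_, n),
                       maxAbsResid = rep(NA_real_, n))
}

# depth / chained error estimates per node, walking from the root
.chainStats <- function(root, edges) {
  nodes <- c(root, edges$response)
  depth <- setNames(rep(NA_real_, length(nodes)), nodes)
  qsum <- env <- depth
  parent <- setNames(rep(NA_character_, length(nodes)), nodes)
  depth[root] <- 0; qsum[root] <- 0; env[root] <- 0
  todo <- root
  while (length(todo)) {
    p <- todo[1L]; todo <- todo[-1L]
    kids <- which(edges$predictor == p)
    for (k in kids) {
      ch <- edges$response[k]
      depth[ch] <- depth[p] + 1
      parent[ch] <- p
      qsum[ch] <- qsum[p] + edges$rmse[k]^2
      env[ch] <- env[p] + edges$maxAbsResid[k]
      todo <- c(todo, ch)
    }
  }
  S4Vectors::DataFrame(system = nodes, depth = as.integer(depth),
                       parent = parent, chainRmse = sqrt(qsum),
                       chainEnvelope = env, row.names = nodes)
}

.newMap <- function(root, edges, alternates = .emptyEdges(), bound = FALSE) {
  methods::new("PredictionMap", root = root, edges = edges,
               alternates = alternates, bound = bound,
               chain = .chainStats(root, edges))
}

#' The published serum/plasma prediction map
#'
#' Returns the fixed 16-system map assembled from the best serum-trained
#' models, joined across chemical classes: the valine methyl doublet anchors
#' the amino-acid sub-map (alanine, leucine, isoleucine, tyrosine, glycine
#' directly; phenylalanine via tyrosine; histidine via glycine); leucine
#' bridges to lactate, which anchors the carboxylic-acid/sugar sub-map
#' (acetate, pyruvate, formate, 3-hydroxybutyrate, glucose anomeric); and
#' leucine also predicts ethanol, which predicts acetone. Pyruvate carries an
#' alternate edge to acetone for samples where the ethanol signal is absent.
#' Coefficients are placeholders (\code{NA}) until the map is bound to a
#' fitted \linkS4class{ShiftModelSet} with \code{\link{bindMap}}.
#'
#' @return an unbound \linkS4class{PredictionMap} with 15 primary edges.
#' @examples
#' m <- publishedMap()
#' length(mapEdges(m)$response)   # 15 predicted systems
#' @export
publishedMap <- function() {
  e <- rbind(
    c("valine_CH3",  "alanine_CH3"),
    c("valine_CH3",  "leucine_CH3"),
    c("valine_CH3",  "isoleucine_CH3"),
    c("valine_CH3",  "tyrosine_CH"),
    c("valine_CH3",  "glycine_CH2"),
    c("tyrosine_CH", "phenylalanine_CH"),
    c("glycine_CH2", "histidine_CH"),
    c("leucine_CH3", "lactate_CH3"),
    c("leucine_CH3", "ethanol_CH3"),
    c("lactate_CH3", "acetate_CH3"),
    c("lactate_CH3", "pyruvate_CH3"),
    c("lactate_CH3", "formate_CH"),
    c("lactate_CH3", "hydroxybutyrate_CH3"),
    c("lactate_CH3", "glucose_anomeric"),
    c("ethanol_CH3", "acetone_CH3"))
  .newMap("valine_CH3", .emptyEdges(e[, 1L], e[, 2L]),
          alternates = .emptyEdges("pyruvate_CH3", "acetone_CH3"))
}

#' @rdname PredictionMap-accessors
#' @title Accessors for PredictionMap objects
#' @description \code{mapRoot}: anchor id; \code{mapEdges} /
#'   \code{mapAlternates}: edge tables; \code{nodeDepths}: hops from the
#'   root per system; \code{chainErrors}: per-system chained error
#'   estimates (quadrature RMSE and summed max-residual envelope).
#' @param x a \linkS4class{PredictionMap}.
#' @export
setMethod("mapRoot", "PredictionMap", function(x) x@root)

#' @rdname PredictionMap-accessors
#' @export
setMethod("mapEdges", "PredictionMap", function(x) x@edges)

#' @rdname PredictionMap-accessors
#' @export
setMethod("mapAlternates", "PredictionMap", function(x) x@alternates)

#' @rdname PredictionMap-accessors
#' @export
setMethod("nodeDepths", "PredictionMap", function(x)
  setNames(x@chain$depth, x@chain$system))

#' @rdname PredictionMap-accessors
#' @export
setMethod("chainErrors", "PredictionMap", function(x) x@chain)

#' @rdname PredictionMap-accessors
#' @export
setMethod("systemIds", "PredictionMap", function(x) x@chain$system)

setMethod("show", "PredictionMap", function(object) {
  cat(sprintf("PredictionMap: root '%s', %d predicted systems, depth %d%s\n",
              object@root, nrow(object@edges),
              max(object@chain$depth),
              if (object@bound) " (bound)" else " (unbound)"))
  if (nrow(object@alternates))
    cat("  alternates:",
        paste(object@alternates$predictor, "->",
              object@alternates$response, collapse = "; "), "\n")
})

#' @describeIn buildMap construct the minimum-total-weight spanning
#'   arborescence rooted at \code{rootId} over the stable, usable models of
#'   \code{x} (Chu-Liu/Edmonds cycle contraction). The edge weight is the
#'   model's |rRMSE| (percent) or RMSE (ppm). Ties are broken by lower
#'   weight, then higher r2, then lexicographic (predictor, response), so
#'   the result is deterministic. With \code{classGuided = TRUE} candidate
#'   edges are restricted to pairs of the same chemical class plus edges
#'   whose predictor is a designated bridge system — the sub-map-then-join
#'   strategy. If some system cannot be reached the error names it and
#'   lists the unstable edges that would have connected it.
#' @param weight \code{"rrmse"} (default) or \code{"rmse"}.
#' @param classGuided restrict candidates by chemical class (default
#'   \code{FALSE}).
#' @param bridges predictor ids allowed to cross classes when
#'   \code{classGuided}; defaults to the anchors and joints of the published
#'   map.
#' @export
setMethod("buildMap", "ShiftModelSet",
          function(x, rootId, weight = c("rrmse", "rmse"),
                   classGuided = FALSE,
                   bridges = c("valine_CH3", "leucine_CH3", "lactate_CH3",
                               "ethanol_CH3", "pyruvate_CH3")) {
  weight <- match.arg(weight)
  ids <- systemIds(x)
  if (!rootId %in% ids) .stopf("root '%s' is not a modelled system", rootId)
  m <- x@models
  w <- if (weight == "rrmse") abs(m$rrmse) else m$rmse
  keep <- m$usable & m$stable & is.finite(w) & m$response != rootId
  if (classGuided) {
    cls <- setNames(x@systems$chemical_class, x@systems$id)
    if (is.null(x@systems$chemical_class))
      .stopf("class-guided construction needs 'chemical_class' in the registry")
    same <- cls[m$predictor] == cls[m$response]
    keep <- keep & (same | m$predictor %in% bridges)
  }
  m <- m[keep, , drop = FALSE]
  w <- w[keep]
  o <- order(w, -m$r2, m$predictor, m$response)
  m <- m[o, , drop = FALSE]; w <- w[o]
  nodeIdx <- setNames(seq_along(ids), ids)
  sel <- tryCatch(
    .minArborescence(length(ids), nodeIdx[m$predictor], nodeIdx[m$response],
                     w, nodeIdx[rootId]),
    error = function(e) {
      msg <- conditionMessage(e)
      if (grepl("^ARBOR_ORPHAN:", msg)) {
        orphan <- ids[as.integer(sub("^ARBOR_ORPHAN:", "", msg))]
        all <- x@models
        weak <- all[all$response == orphan & !(all$usable & all$stable), ,
                    drop = FALSE]
        .stopf(paste0("system '%s' is unreachable from '%s'; ",
                      "unstable/unusable incoming edges: %s"),
               orphan, rootId,
               if (nrow(weak)) .commas(weak$predictor) else "(none fitted)")
      }
      stop(e)
    })
  sel <- sort(sel)
  edges <- S4Vectors::DataFrame(
    predictor = m$predictor[sel], response = m$response[sel],
    a = m$a[sel], b = m$b[sel], n = m$n[sel], r2 = m$r2[sel],
    rmse = m$rmse[sel], rrmse = m$rrmse[sel],
    maxAbsResid = m$maxAbsResid[sel])
  .newMap(rootId, edges, bound = TRUE)
})

#' @describeIn bindMap attach the fitted coefficients and metrics of
#'   \code{fit} to every primary and alternate edge of \code{map} and
#'   recompute the per-node chained error estimates. Errors listing the
#'   absent pairs if any edge has no usable model.
#' @export
setMethod("bindMap", c("PredictionMap", "ShiftModelSet"),
          function(map, fit) {
  m <- fit@models
  key <- paste(m$response, m$predictor, sep = "|")
  lookup <- function(edges, label) {
    if (!nrow(edges)) return(edges)
    want <- paste(edges$response, edges$predictor, sep = "|")
    hit <- match(want, key)
    bad <- is.na(hit) | !m$usable[hit]
    if (any(bad))
      .stopf("no usable fitted model for %s edge(s): %s", label,
             .commas(paste(edges$predictor[bad], "->",
                           edges$response[bad])))
    edges$a <- m$a[hit]; edges$b <- m$b[hit]; edges$n <- m$n[hit]
    edges$r2 <- m$r2[hit]; edges$rmse <- m$rmse[hit]
    edges$rrmse <- m$rrmse[hit]; edges$maxAbsResid <- m$maxAbsResid[hit]
    edges
  }
  edges <- lookup(map@edges, "primary")
  alts <- lookup(map@alternates, "alternate")
  methods::new("PredictionMap", root = map@root, edges = edges,
               alternates = alts, bound = TRUE,
               chain = .chainStats(map@root, edges))
})

#' Total weight of a map under a model-set weighting
#'
#' Sum over primary edges of |rRMSE| (percent) or RMSE (ppm); useful to
#' compare an algorithmically built arborescence with a fixed topology
#' bound to the same models.
#'
#' @param map a bound \linkS4class{PredictionMap}.
#' @param weight \code{"rrmse"} or \code{"rmse"}.
#' @return numeric scalar.
#' @export
mapWeight <- function(map, weight = c("rrmse", "rmse")) {
  weight <- match.arg(weight)
  e <- map@edges
  sum(if (weight == "rrmse") abs(e$rrmse) else e$rmse)
}

#' Serialize / deserialize a prediction map as JSON
#'
#' Stores the root, primary edge list (predictor, response, coefficients,
#' metrics) and alternates; round-trip safe.
#'
#' @param map a \linkS4class{PredictionMap}.
#' @param path JSON file.
#' @return \code{writePredictionMap}: \code{path} invisibly;
#'   \code{readPredictionMap}: a \linkS4class{PredictionMap}.
#' @export
writePredictionMap <- function(map, path) {
  payload <- list(root = map@root, bound = map@bound,
                  edges = as.data.frame(map@edges),
                  alternates = as.data.frame(map@alternates))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname writePredictionMap
#' @export
readPredictionMap <- function(path) {
  if (!file.exists(path)) .stopf("map file not found: %s", path)
  p <- jsonlite::fromJSON(path)
  asEdges <- function(d) {
    if (is.null(d) || !length(d) || !NROW(d)) return(.emptyEdges())
    d <- S4Vectors::DataFrame(d)
    d$n <- as.integer(d$n)
    d[.EDGE_COLS]
  }
  .newMap(p$root, asEdges(p$edges), alternates = asEdges(p$alternates),
          bound = isTRUE(p$bound))
}
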