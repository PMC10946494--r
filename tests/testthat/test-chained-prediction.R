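test_that("single-hop prediction is affine evaluation of observed predictors", {
  pf <- panelFit(seed = 14, n = 250)
  map <- bindMap(publishedMap(), pf$fit)
  hold <- simulateShiftTable(serumPanelSpec(), 40, seed = 15)
  p <- predictSemi(map, hold, digits = NULL)
  e <- mapEdges(map)
  obs <- shiftMatrix(hold)
  k <- which(e$response == "alanine_CH3")
  expect_equal(unname(shiftMatrix(p)[, "alanine_CH3"]),
               unname(e$a[k] * obs[, "valine_CH3"] + e$b[k]),
               tolerance = 1e-12)
  # reported values are quantized at 4 decimals
  p4 <- predictSemi(map, hold)
  m4 <- shiftMatrix(p4)
  expect_equal(m4[is.finite(m4)], round(m4[is.finite(m4)], 4))
})

test_that("missing predictors fall back to alternates or unavailable", {
  pf <- panelFit(seed = 14, n = 250)
  map <- bindMap(publishedMap(), pf$fit)
  hold <- simulateShiftTable(serumPanelSpec(), 60, seed = 16)
  src <- predictionSource(predictSemi(map, hold))
  obs <- shiftMatrix(hold)
  ethMissing <- !is.finite(obs[, "ethanol_CH3"])
  expect_true(any(ethMissing))
  # pyruvate is always detected, so acetone switches to the alternate edge
  expect_true(all(src["acetone_CH3", ethMissing] == "alternate_edge"))
  expect_true(all(src["acetone_CH3", !ethMissing] == "primary_edge"))
  # with alternates disabled those samples become unavailable
  src2 <- predictionSource(predictSemi(map, hold, useAlternates = FALSE))
  expect_true(all(src2["acetone_CH3", ethMissing] == "unavailable"))
  # a prediction needs only the predictor: responses of the always-detected
  # lactate are predicted in every sample, observed or not
  expect_true(all(src["hydroxybutyrate_CH3", ] == "primary_edge"))
})

test_that("chained prediction composes the affine edge maps exactly", {
  pf <- panelFit(seed = 23, n = 400)
  map <- bindMap(publishedMap(), pf$fit)
  e <- mapEdges(map)
  co <- function(resp) {
    k <- which(e$response == resp)
    c(a = e$a[k], b = e$b[k])
  }
  v <- c(S1 = 0.9812, S2 = 0.9901)
  p <- predictAuto(map, v, digits = NULL)
  m <- shiftMatrix(p)
  leu <- co("leucine_CH3"); eth <- co("ethanol_CH3"); ace <- co("acetone_CH3")
  manual <- ace["a"] * (eth["a"] * (leu["a"] * v + leu["b"]) + eth["b"]) +
    ace["b"]
  expect_equal(unname(m[, "acetone_CH3"]), unname(manual), tolerance = 1e-12)
  # depth-d node = single affine map composed from its path, for every node
  d <- nodeDepths(map)
  for (resp in names(d)[d > 0]) {
    # compose (f_d o ... o f_1)(v) along the root-to-node path
    path <- character(0); cur <- resp
    while (cur != mapRoot(map)) { path <- c(cur, path); cur <- e$predictor[which(e$response == cur)] }
    val <- v
    for (node in path) {
      k <- which(e$response == node)
      val <- e$a[k] * val + e$b[k]
    }
    expect_equal(unname(m[, resp]), unname(val), tolerance = 1e-12,
                 label = resp)
  }
  expect_identical(unname(shiftMatrix(p)[, mapRoot(map)]), unname(v))
  expect_true(all(predictionSource(p)[mapRoot(map), ] == "observed_anchor"))
})

test_that("at zero noise semi, auto and observed values coincide", {
  spec <- oneFactorSpec(c(0.01, 0.02, 0.015, 0.008), sigma = 0)
  st <- simulateShiftTable(spec, 150, seed = 4, precision = 10L)
  fit <- fitAllPairs(st, minN = 10L)
  map <- buildMap(fit, "sys01", weight = "rmse")
  semi <- predictSemi(map, st, digits = NULL)
  auto <- predictAuto(map, st, digits = NULL)
  obs <- shiftMatrix(st, samplesAsRows = FALSE)
  ord <- systemIds(semi)                 # map order: root first, then edges
  expect_equal(shiftMatrix(semi, samplesAsRows = FALSE), obs[ord, ],
               tolerance = 1e-8)
  expect_equal(shiftMatrix(auto, samplesAsRows = FALSE), obs[ord, ],
               tolerance = 1e-8)
  # and identically once both are quantized
  expect_identical(shiftMatrix(predictSemi(map, st)),
                   shiftMatrix(predictAuto(map, st)))
})

test_that("samples without an anchor value are skipped with a message", {
  pf <- panelFit(seed = 31, n = 200)
  map <- bindMap(publishedMap(), pf$fit)
  v <- c(A = 0.9850, B = NA, C = 0.9870)
  expect_message(p <- predictAuto(map, v), "skipping 1 sample")
  src <- predictionSource(p)
  expect_true(all(src[, "B"] == "unavailable"))
  expect_true(all(src[setdiff(rownames(src), "valine_CH3"), "A"] ==
                    "primary_edge"))
})

test_that("validation reports ppm and linewidth errors per system", {
  pf <- panelFit(seed = 44, n = 500)
  map <- bindMap(publishedMap(), pf$fit)
  hold <- simulateShiftTable(serumPanelSpec(), 200, seed = 45)
  p <- predictSemi(map, hold)
  v <- validatePredictions(p, hold, linewidthPpm = 0.001)
  df <- as.data.frame(v)
  expect_identical(df$system[nrow(df)], ".overall")
  per <- df[df$system != ".overall", ]
  expect_setequal(per$system, setdiff(systemIds(map), "valine_CH3"))
  ok <- per$n > 0
  expect_true(all(per$maxAbsError[ok] >= per$rmse[ok]))
  expect_equal(per$maxAbsErrorLw[ok], per$maxAbsError[ok] / 0.001,
               tolerance = 1e-12)
  expect_equal(per$rmseLw[ok], per$rmse[ok] / 0.001, tolerance = 1e-12)
  # ethanol is evaluated only on its detected samples
  expect_lte(per$n[per$system == "ethanol_CH3"],
             sum(is.finite(shiftMatrix(hold)[, "ethanol_CH3"])))
  # predicting a table against itself gives zero error
  self <- validatePredictions(p, hold)
  exact <- validatePredictions(
    predictAuto(map, setNames(rep(0.986, 3), paste0("x", 1:3))),
    simulateShiftTable(serumPanelSpec(), 3, seed = 1))
  expect_s4_class(exact, "DataFrame")
})

test_that("predictions are per-sample local: subsetting changes nothing", {
  pf <- panelFit(seed = 52, n = 150)
  map <- bindMap(publishedMap(), pf$fit)
  hold <- simulateShiftTable(serumPanelSpec(), 50, seed = 53)
  pAll <- predictSemi(map, hold)
  sub <- hold[, 1:10]
  pSub <- predictSemi(map, sub)
  expect_identical(shiftMatrix(pSub),
                   shiftMatrix(pAll)[sampleIds(sub), , drop = FALSE])
})

test_that("long-format prediction export carries errors and provenance", {
  pf <- panelFit(seed = 61, n = 120)
  map <- bindMap(publishedMap(), pf$fit)
  hold <- simulateShiftTable(serumPanelSpec(), 25, seed = 62)
  p <- predictSemi(map, hold)
  f <- tempfile(fileext = ".csv")
  writePredictions(p, f, observed = hold)
  df <- utils::read.csv(f)
  expect_identical(nrow(df), 16L * 25L)
  expect_setequal(colnames(df),
                  c("sample", "system", "predicted", "source", "observed",
                    "error_ppm", "error_linewidths"))
  expect_equal(df$error_linewidths, df$error_ppm / 0.001, tolerance = 1e-9)
})
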