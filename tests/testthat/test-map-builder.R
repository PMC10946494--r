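test_that("the published map has the documented structure", {
  pm <- publishedMap()
  e <- mapEdges(pm)
  expect_identical(mapRoot(pm), "valine_CH3")
  expect_identical(nrow(e), 15L)                 # 15 predicted systems
  expect_identical(length(systemIds(pm)), 16L)
  reg <- serumSpinSystems()
  cls <- setNames(reg$chemical_class, reg$id)
  # amino-acid sub-map: 7 predicted amino acids
  expect_identical(sum(cls[e$response] == "amino_acid"), 7L)
  # lactate sub-map: 5 children (carboxylic acids + glucose)
  expect_identical(sum(e$predictor == "lactate_CH3"), 5L)
  d <- nodeDepths(pm)
  expect_identical(unname(d["valine_CH3"]), 0L)
  expect_identical(unname(d["acetone_CH3"]), 3L) # valine>leucine>ethanol>acetone
  alt <- mapAlternates(pm)
  expect_identical(paste(alt$predictor, alt$response),
                   "pyruvate_CH3 acetone_CH3")
  expect_false(pm@bound)
})

test_that("arborescence construction matches exhaustive enumeration", {
  set.seed(404)
  for (rep in 1:25) {
    k <- sample(4:6, 1L)
    full <- expand.grid(from = seq_len(k), to = seq_len(k))
    full <- full[full$from != full$to, ]
    keep <- runif(nrow(full)) < 0.8            # drop some edges
    E <- full[keep, ]
    w <- round(runif(nrow(E), 0.01, 1), 3)
    brute <- bruteArborescence(E$from, E$to, w, k, root = 1L)
    got <- tryCatch(
      shiftmap:::.minArborescence(k, E$from, E$to, w, root = 1L),
      error = function(e) NULL)
    if (is.null(brute) || !is.finite(brute)) {
      expect_null(got)
    } else {
      expect_false(is.null(got))
      expect_identical(length(got), k - 1L)
      expect_equal(sum(w[got]), brute, tolerance = 1e-12)
    }
  }
})

test_that("buildMap returns a valid, optimal, deterministic arborescence", {
  pf <- panelFit(seed = 42, n = 940)
  map <- buildMap(pf$fit, "valine_CH3")
  expect_true(validObject(map))
  expect_identical(nrow(mapEdges(map)), 15L)
  expect_true(map@bound)
  # no heavier than the fixed published topology bound to the same models
  pub <- bindMap(publishedMap(), pf$fit)
  expect_lte(mapWeight(map), mapWeight(pub) + 1e-12)
  # deterministic for identical inputs
  map2 <- buildMap(pf$fit, "valine_CH3")
  expect_identical(as.data.frame(mapEdges(map2)), as.data.frame(mapEdges(map)))
  # rmse weighting works too and yields a valid tree
  mapR <- buildMap(pf$fit, "lactate_CH3", weight = "rmse")
  expect_true(validObject(mapR))
  expect_identical(mapRoot(mapR), "lactate_CH3")
})

test_that("noiseless single-factor systems give a near-zero-weight tree", {
  spec <- oneFactorSpec(c(0.01, 0.02, 0.015, 0.005))
  st <- simulateShiftTable(spec, 200, seed = 8, precision = 8L)
  fit <- fitAllPairs(st, minN = 10L)
  map <- buildMap(fit, "sys01", weight = "rmse")
  expect_true(validObject(map))
  expect_lt(mapWeight(map, "rmse"), 1e-6)
})

test_that("class-guided construction respects classes and bridges", {
  pf <- panelFit(seed = 1, n = 940)
  map <- buildMap(pf$fit, "valine_CH3", classGuided = TRUE)
  reg <- serumSpinSystems()
  cls <- setNames(reg$chemical_class, reg$id)
  e <- mapEdges(map)
  bridges <- c("valine_CH3", "leucine_CH3", "lactate_CH3", "ethanol_CH3",
               "pyruvate_CH3")
  ok <- cls[e$predictor] == cls[e$response] | e$predictor %in% bridges
  expect_true(all(ok))
  expect_true(validObject(map))
})

test_that("binding attaches coefficients and reports absent pairs", {
  pf <- panelFit(seed = 12, n = 300)
  pub <- bindMap(publishedMap(), pf$fit)
  e <- mapEdges(pub)
  expect_true(all(is.finite(e$a)) && all(is.finite(e$b)))
  ch <- chainErrors(pub)
  expect_true(all(is.finite(ch$chainRmse)))
  # chain quadrature grows along the path
  expect_gte(ch["acetone_CH3", "chainRmse"], ch["ethanol_CH3", "chainRmse"])
  # a table without ethanol cannot bind the published topology
  m <- shiftMatrix(pf$table)
  m <- m[, setdiff(colnames(m), "ethanol_CH3")]
  fit2 <- fitAllPairs(ShiftTable(m), minN = 50L)
  expect_error(bindMap(publishedMap(), fit2),
               "ethanol_CH3 -> acetone_CH3")
})

test_that("unreachable systems are reported with their weak edges", {
  set.seed(2)
  n <- 80
  x <- 1 + 0.01 * rnorm(n)
  m <- cbind(a = round(x, 4), b = round(1.5 + x + 1e-4 * rnorm(n), 4),
             c = round(2 + x + 1e-4 * rnorm(n), 4))
  m[6:n, "c"] <- NA                          # c co-detected in 5 samples only
  rownames(m) <- paste0("s", seq_len(n))
  fit <- fitAllPairs(ShiftTable(m), minN = 50L)
  expect_error(buildMap(fit, "a"), "unreachable.*'c'|'c'.*unreachable")
})

test_that("prediction maps survive a JSON round trip", {
  pf <- panelFit(seed = 6, n = 120)
  map <- bindMap(publishedMap(), pf$fit)
  f <- tempfile(fileext = ".json")
  writePredictionMap(map, f)
  back <- readPredictionMap(f)
  expect_identical(mapRoot(back), mapRoot(map))
  expect_equal(as.data.frame(mapEdges(back)), as.data.frame(mapEdges(map)),
               tolerance = 1e-12)
  expect_equal(as.data.frame(mapAlternates(back)),
               as.data.frame(mapAlternates(map)), tolerance = 1e-12)
  expect_true(back@bound)
})
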