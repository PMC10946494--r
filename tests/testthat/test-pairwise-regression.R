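test_that("fitPair reproduces exact lines and the normal-equation oracle", {
  id <- fitPair(c(1, 2, 3), c(1, 2, 3))
  expect_equal(id[c("a", "b", "r2", "rmse", "maxAbsResid")],
               list(a = 1, b = 0, r2 = 1, rmse = 0, maxAbsResid = 0),
               tolerance = 1e-12)
  ln <- fitPair(c(3, 5, 7), c(1, 2, 3))
  expect_equal(ln[c("a", "b", "r2")], list(a = 2, b = 1, r2 = 1),
               tolerance = 1e-12)
  y <- c(1.33, 1.36, 1.34, 1.38); x <- c(0.98, 1.00, 0.99, 1.01)
  got <- fitPair(y, x)
  want <- oracleOLS(y, x)
  for (f in c("a", "b", "r2", "rmse", "rrmse", "maxAbsResid"))
    expect_equal(got[[f]], want[[f]], tolerance = 1e-12, label = f)
})

test_that("random fits match the oracle and satisfy the OLS identities", {
  set.seed(202)
  for (rep in 1:60) {
    n <- sample(3:40, 1L)
    x <- round(1 + 0.01 * rnorm(n), 4)
    if (diff(range(x)) == 0) next
    y <- round(1.3 + 0.8 * x + 0.002 * rnorm(n), 4)
    if (diff(range(y)) == 0) next
    got <- fitPair(y, x)
    want <- oracleOLS(y, x)
    expect_equal(got$a, want$a, tolerance = 1e-10)
    expect_equal(got$b, want$b, tolerance = 1e-10)
    expect_equal(got$r2, want$r2, tolerance = 1e-10)
    # r2 equals the squared Pearson correlation
    expect_equal(got$r2, cor(x, y)^2, tolerance = 1e-10)
    # reciprocity: a(y|x) * a(x|y) = r2
    rev <- fitPair(x, y)
    expect_equal(got$a * rev$a, got$r2, tolerance = 1e-10)
    # error envelope dominates the RMSE
    expect_gte(got$maxAbsResid, got$rmse - 1e-15)
    # shifting both variables moves only the intercept
    sh <- fitPair(y + 0.37, x + 0.37)
    expect_equal(sh$a, got$a, tolerance = 1e-9)
    expect_equal(sh$r2, got$r2, tolerance = 1e-9)
    expect_equal(sh$rmse, got$rmse, tolerance = 1e-12)
  }
})

test_that("degenerate designs are refused or flagged", {
  expect_error(fitPair(c(1, 2, 3), c(1, 1, 1)), "degenerate predictor")
  const <- fitPair(c(2, 2, 2), c(1, 2, 3))
  expect_false(const$usable)
  expect_true(is.na(const$r2))
  expect_error(fitPair(1, 1), "at least 2")
  # rmse denominator convention is configurable
  y <- c(1.1, 1.3, 1.2, 1.5); x <- c(1, 2, 3, 4)
  expect_equal(fitPair(y, x, rmseDenom = "df")$rmse,
               fitPair(y, x)$rmse * sqrt(4 / 2), tolerance = 1e-12)
})

test_that("fitAllPairs fits k(k-1) ordered models on complete columns", {
  set.seed(9)
  m <- matrix(round(rep(c(1, 2, 3), each = 20) + 0.01 * rnorm(60), 4),
              20, 3, dimnames = list(paste0("s", 1:20), c("a", "b", "c")))
  fit <- fitAllPairs(ShiftTable(m), minN = 5L)
  expect_identical(nrow(models(fit)), 6L)
  expect_setequal(paste(models(fit)$response, models(fit)$predictor),
                  c("a b", "a c", "b a", "b c", "c a", "c b"))
  full <- panelFit(seed = 21, n = 60, fullyDetected = TRUE)
  expect_identical(nrow(models(full$fit)), 240L)
  expect_true(all(models(full$fit)$stable))
})

test_that("low co-detection pairs are kept but flagged unstable", {
  set.seed(31)
  n <- 60
  x <- 1 + 0.01 * rnorm(n)
  m <- cbind(a = round(x, 4), b = round(2 * x + 0.3 + 1e-4 * rnorm(n), 4))
  m[9:n, "b"] <- NA                        # only 8 paired samples
  rownames(m) <- paste0("s", seq_len(n))
  fit <- fitAllPairs(ShiftTable(m), minN = 50L)
  rec <- models(fit)
  ba <- rec[rec$response == "b" & rec$predictor == "a", ]
  expect_identical(ba$n, 8L)
  expect_false(ba$stable)
  expect_true(ba$usable)
  rr <- rrmseMatrix(fit)
  expect_true(is.na(rr["b", "a"]))         # masked as unstable
  expect_false(is.na(rrmseMatrix(fit, maskUnstable = FALSE)["b", "a"]))
  expect_true(all(is.na(diag(rr))))
  expect_error(bestPredictor(fit, "b"), "unstable candidate")
})

test_that("bestPredictor minimises |rRMSE| and matches an exhaustive scan", {
  pf <- panelFit(seed = 77, n = 400)
  rec <- models(pf$fit)
  for (resp in c("alanine_CH3", "histidine_CH", "acetone_CH3")) {
    cand <- rec[rec$response == resp & rec$usable & rec$stable &
                  is.finite(rec$rrmse), ]
    o <- order(abs(cand$rrmse), -cand$r2, cand$predictor)
    expect_identical(bestPredictor(pf$fit, resp), cand$predictor[o[1L]])
  }
  # restricting candidates honours the subset
  aa <- serumSpinSystems()
  amino <- aa$id[aa$chemical_class == "amino_acid"]
  best <- bestPredictor(pf$fit, "histidine_CH", candidates = amino)
  expect_true(best %in% amino)
})

test_that("model sets serialize to JSON and back unchanged", {
  pf <- panelFit(seed = 5, n = 80)
  f <- tempfile(fileext = ".json")
  writeModelSet(pf$fit, f)
  back <- readModelSet(f)
  expect_equal(as.data.frame(models(back)), as.data.frame(models(pf$fit)),
               tolerance = 1e-12)
  expect_identical(back@minN, pf$fit@minN)
  expect_identical(systemIds(back), systemIds(pf$fit))
})
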