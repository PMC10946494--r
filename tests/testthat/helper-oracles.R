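# Independent oracles and fixture builders used across the suite.

# Normal-equation OLS, evaluated directly from the closed-form expressions
# (independent of the package's QR-based fitting path).
oracleOLS <- function(y, x) {
  xb <- mean(x); yb <- mean(y)
  a <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
  b <- yb - a * xb
  res <- y - (a * x + b)
  ssr <- sum(res^2)
  list(a = a, b = b, r2 = 1 - ssr / sum((y - yb)^2),
       rmse = sqrt(ssr / length(y)),
       rrmse = 100 * sqrt(ssr / length(y)) / abs(yb),
       maxAbsResid = max(abs(res)))
}

# Strict local maxima by exhaustive scan.
bruteLocalMaxima <- function(y) {
  which(vapply(seq_along(y), function(i)
    i > 1L && i < length(y) && y[i] > y[i - 1L] && y[i] > y[i + 1L],
    logical(1L)))
}

lorentzian <- function(ppm, center, hwhmPpm, amp = 1)
  amp * hwhmPpm^2 / ((ppm - center)^2 + hwhmPpm^2)

# Exhaustive minimum spanning arborescence: every non-root node picks one
# incoming edge; keep acyclic combinations; minimise total weight.
bruteArborescence <- function(from, to, w, nNodes, root) {
  nonroot <- setdiff(seq_len(nNodes), root)
  cand <- lapply(nonroot, function(v) which(to == v & from != v))
  if (any(lengths(cand) == 0L)) return(NULL)
  grid <- expand.grid(cand, KEEP.OUT.ATTRS = FALSE)
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    sel <- as.integer(grid[r, ])
    parent <- integer(nNodes)
    parent[nonroot] <- from[sel]
    ok <- TRUE
    for (v in nonroot) {
      seen <- logical(nNodes); cur <- v
      while (cur != root) {
        if (seen[cur]) { ok <- FALSE; break }
        seen[cur] <- TRUE
        cur <- parent[cur]
      }
      if (!ok) break
    }
    if (ok) best <- min(best, sum(w[sel]))
  }
  best
}

# Small latent-factor spec: k systems on one shared factor.
oneFactorSpec <- function(sens, sigma = 0, mu = NULL, detect = 1,
                          ids = sprintf("sys%02d", seq_along(sens))) {
  k <- length(sens)
  if (is.null(mu)) mu <- seq(1, by = 0.5, length.out = k)
  SyntheticShiftSpec(
    S4Vectors::DataFrame(id = ids, mu = mu,
                         sigma = rep_len(sigma, k),
                         detectProb = rep_len(detect, k)),
    loadings = matrix(sens, ncol = 1L,
                      dimnames = list(ids, "factor1")))
}

# A fully observed synthetic panel table plus its fitted model set.
panelFit <- function(seed = 42, n = 300, minN = 50L, fullyDetected = FALSE) {
  st <- simulateShiftTable(serumPanelSpec(fullyDetected = fullyDetected),
                           n, seed = seed)
  list(table = st, fit = fitAllPairs(st, minN = minN))
}

writeTempTable <- function(values, ...) {
  f <- tempfile(fileext = ".csv")
  writeShiftTable(ShiftTable(values, ...), f)
  f
}
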