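# Independent oracles, deliberately written as plain loops so they share
# no code path with the implementation they check.

bruteSizeFactors <- function(counts, geoMeans) {
  sf <- numeric(ncol(counts))
  for (s in seq_len(ncol(counts))) {
    ratios <- c()
    for (g in seq_len(nrow(counts))) {
      if (geoMeans[g] > 0 && counts[g, s] > 0)
        ratios <- c(ratios, counts[g, s] / geoMeans[g])
    }
    sf[s] <- median(ratios)
  }
  sf
}

bruteGeoMeans <- function(counts) {
  out <- numeric(nrow(counts))
  for (g in seq_len(nrow(counts))) {
    row <- counts[g, ]
    out[g] <- if (any(row == 0)) 0 else exp(sum(log(row)) / length(row))
  }
  out
}

# two-sided NB p by direct mass summation, truncated at mass 1 - 1e-12
bruteNbTwoSided <- function(obs, mu, disp) {
  dens <- function(k) {
    if (disp == 0) dpois(k, mu) else dnbinom(k, size = 1 / disp, mu = mu)
  }
  lower <- sum(dens(0:obs))
  upper <- 0
  k <- obs
  repeat {
    d <- dens(k)
    upper <- upper + d
    k <- k + 1
    if (upper >= 1 - 1e-12 || d < 1e-16 && k > mu * 10 + 100) break
  }
  min(1, 2 * min(lower, min(upper, 1)))
}

bruteBH <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

# diagonal-covariance Gaussian classifier with variances (s_j + s0)^2
gaussianOracleLabel <- function(st, x) {
  se2 <- (st$pooledSD + st$s0)^2
  disc <- vapply(seq_along(st$classes), function(k)
    sum((x - st$classCentroids[, k])^2 / se2) - 2 * log(st$priors[k]),
    numeric(1))
  st$classes[which.min(disc)]
}

fixedPointPF <- function(topology, deltaE, iter = 10000) {
  B <- sweep(topology@beta, 2L, pmax(topology@nDownstream, 1L), "/")
  PF <- deltaE
  for (i in seq_len(iter)) {
    nxt <- deltaE + as.numeric(B %*% PF)
    if (max(abs(nxt - PF)) < 1e-14) return(nxt)
    PF <- nxt
  }
  PF
}

# exact pPERT by enumerating every placement of the observed values
enumPPert <- function(topology, deltaE) {
  p <- length(topology@genes)
  vals <- deltaE[deltaE != 0]
  stopifnot(length(vals) == 1L)  # enumeration oracle for one DE gene
  B <- sweep(topology@beta, 2L, pmax(topology@nDownstream, 1L), "/")
  w <- colSums(solve(diag(p) - B)) - 1
  nullTA <- w * vals
  obsTA <- sum(solve(diag(p) - B, deltaE)) - sum(deltaE)
  med <- median(nullTA)
  mean(abs(nullTA - med) >= abs(obsTA - med))
}

bruteHyperUpper <- function(q, pathSize, nDE, universe) {
  tot <- 0
  for (k in q:min(pathSize, nDE))
    tot <- tot + choose(pathSize, k) * choose(universe - pathSize, nDE - k) /
      choose(universe, nDE)
  tot
}

# a tiny frozen reference shared across tests
tinyReference <- function() {
  counts <- rbind(gA = c(10, 20, 40, 10), gB = c(20, 40, 80, 20),
                  gC = c(5, 10, 20, 5), gD = c(0, 0, 0, 0),
                  gE = c(8, 16, 32, 8))
  colnames(counts) <- c("t1", "t2", "n1", "n2")
  buildFrozenReference(counts, c("tumor", "tumor", "normal", "normal"))
}
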