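# Shared fixtures and independent oracles for the test suite.
# All fixtures are generated in code; nothing is read from disk.

# A small, fast study configuration used where the full default scale is not
# needed. Three tissues, with the first and third sharing half their
# signatures (the confounded pair).
smallSimConfig <- function(...) {
  args <- list(nTissues = 3, genesTotal = 500, sigSizePerTissue = 40,
               coreSize = 20, confoundedPair = c(1L, 3L),
               cellsPerSample = 150, nOriginGenes = 20)
  args[names(list(...))] <- list(...)
  do.call(SimConfig, args)
}

# Analysis thresholds under study conditions: the HVG count is scaled to
# ~20% of the simulated genome (the default of 1000 presumes genome-scale
# input).
studyRunConfig <- function(...) {
  RunConfig(nHVGs = 300, ...)
}

# Run simulation + QC + clustering + grouping (+ KO-vs-control DE) for one
# tissue, returning everything recovery tests need.
runSingleTissue <- function(simConfig = SimConfig(), tissue = "liver",
                            runConfig = studyRunConfig()) {
  bulk <- simulateBulkProfiles(simConfig)
  pl <- S4Vectors::metadata(bulk)$planted
  sce <- simulateTissueExperiment(simConfig, tissue, bulk)
  qc <- suppressWarnings(qcNormalize(sce, pl$mito, pl$cycle, runConfig))
  an <- suppressWarnings(
    analyzeTissue(qc, pl$gainMarkers[[tissue]], pl$target, runConfig)
  )
  list(bulk = bulk, planted = pl, sce = sce, qc = qc, analysis = an,
       truth = S4Vectors::metadata(sce)$groundTruth)
}

# Memoised default-liver run shared by several test files.
.defaultLiverCache <- new.env(parent = emptyenv())
defaultLiverRun <- function() {
  if (is.null(.defaultLiverCache$run)) {
    .defaultLiverCache$run <- runSingleTissue()
  }
  .defaultLiverCache$run
}

# ---------------------------------------------------------------------------
# Independent oracles (deliberately coded differently from the package)
# ---------------------------------------------------------------------------

# Exact two-sided rank-sum p-value by enumeration of index subsets, with the
# U statistic computed by pairwise comparison counting (not via rank sums).
bruteRankSumP <- function(x, y) {
  pairwiseU <- function(a, b) {
    u <- 0
    for (ai in a) for (bj in b) {
      u <- u + (ai > bj) + 0.5 * (ai == bj)
    }
    u
  }
  pooled <- c(x, y)
  N <- length(pooled)
  n1 <- length(x)
  uObs <- pairwiseU(x, y)
  center <- n1 * (N - n1) / 2
  hits <- 0
  total <- 0
  idx <- utils::combn(N, n1)
  for (k in seq_len(ncol(idx))) {
    a <- pooled[idx[, k]]
    b <- pooled[-idx[, k]]
    u <- pairwiseU(a, b)
    total <- total + 1
    if (abs(u - center) >= abs(uObs - center) - 1e-9) hits <- hits + 1
  }
  list(U = uObs, p = hits / total)
}

# Permutation estimate of the two-sided rank-sum p-value.
permRankSumP <- function(x, y, nPerm = 10000) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  center <- n1 * (length(pooled) - n1) / 2
  off <- n1 * (n1 + 1) / 2
  uObs <- sum(r[seq_len(n1)]) - off
  stat <- replicate(nPerm, {
    s <- sample.int(length(pooled), n1)
    abs(sum(r[s]) - off - center)
  })
  mean(stat >= abs(uObs - center) - 1e-9)
}

# Benjamini-Hochberg step-up written from the definition.
bhStepUp <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in seq(m, 1)) {
    val <- min(1, p[o[i]] * m / i)
    prev <- min(prev, val)
    q[o[i]] <- prev
  }
  q
}

# Median/MAD keep-mask written from the definition (scaled MAD, lower tail
# for size and detected genes on log2 scale, upper tail for mito fraction).
madKeepOracle <- function(total, detected, mito, nMads = 3) {
  madOf <- function(v) {
    med <- sort(v)[ceiling(length(v) / 2)]
    if (length(v) %% 2 == 0) {
      s <- sort(v)
      med <- (s[length(v) / 2] + s[length(v) / 2 + 1]) / 2
    }
    dev <- abs(v - med)
    s <- sort(dev)
    m <- if (length(v) %% 2 == 0) {
      (s[length(v) / 2] + s[length(v) / 2 + 1]) / 2
    } else {
      s[ceiling(length(v) / 2)]
    }
    list(median = med, mad = 1.4826 * m)
  }
  keepLow <- function(v) {
    st <- madOf(v)
    if (st$mad == 0) rep(TRUE, length(v)) else v >= st$median - nMads * st$mad
  }
  keepHigh <- function(v) {
    st <- madOf(v)
    if (st$mad == 0) rep(TRUE, length(v)) else v <= st$median + nMads * st$mad
  }
  keepLow(log2(total + 1)) & keepLow(log2(detected + 1)) & keepHigh(mito)
}

# Adjusted Rand index between two partitions.
ariOf <- function(a, b) mclust::adjustedRandIndex(a, b)

precisionOf <- function(found, truth) {
  if (!length(found)) return(NA_real_)
  length(intersect(found, truth)) / length(found)
}
recallOf <- function(found, truth) {
  length(intersect(found, truth)) / length(truth)
}
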