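# Cell QC metrics, MAD outlier rule, gene filter, normalisation, flags.

test_that("QC metrics are direct arithmetic on counts", {
  m <- matrix(c(5, 0, 3,
                0, 0, 0), nrow = 3,
              dimnames = list(c("g1", "g2", "mt-1"), c("c1", "c2")))
  qc <- computeCellQC(m, "mt-1")
  expect_equal(qc$totalCounts, c(8, 0))
  expect_equal(qc$detectedGenes, c(2, 0))
  expect_equal(qc$mitoFraction, c(0.375, 0)) # zero-total cell: defined as 0
  expect_warning(computeCellQC(m, c("mt-1", "mt-99")), "mt-99")
})

test_that("the MAD filter flags exactly the planted extreme value", {
  # metric values 9,10,10,10,11,1 on the log2 scale for the library size
  totals <- 2^c(9, 10, 10, 10, 11, 1) - 1
  met <- S4Vectors::DataFrame(totalCounts = totals,
                              detectedGenes = rep(100, 6),
                              mitoFraction = rep(0.05, 6))
  keep <- madOutlierFilter(met, nMads = 3)
  expect_identical(unname(which(!keep)), 6L)
  # brute-force check of the same rule
  expect_identical(as.logical(keep),
                   madKeepOracle(totals, rep(100, 6), rep(0.05, 6)))
})

test_that("identical cells are all kept (zero MAD makes a metric inert)", {
  met <- S4Vectors::DataFrame(totalCounts = rep(1000, 5),
                              detectedGenes = rep(200, 5),
                              mitoFraction = rep(0.05, 5))
  expect_true(all(madOutlierFilter(met)))
  expect_error(madOutlierFilter(met[1, , drop = FALSE]), "at least 2")
})

test_that("the MAD filter matches independent implementations on random metrics", {
  set.seed(421)
  for (i in 1:100) {
    n <- sample(5:60, 1)
    total <- rpois(n, lambda = sample(c(50, 2000, 8000), 1))
    detected <- pmin(total, rpois(n, 300))
    mito <- rbeta(n, 2, 20)
    if (i %% 10 == 0) mito <- rep(0.05, n)       # MAD = 0 case
    if (i %% 17 == 0) total <- rep(total[1], n)  # MAD = 0 case
    met <- S4Vectors::DataFrame(totalCounts = total,
                                detectedGenes = detected,
                                mitoFraction = mito)
    expect_identical(as.logical(madOutlierFilter(met)),
                     madKeepOracle(total, detected, mito))
    # scater implements the same outlier rule; compare per metric
    fl <- attr(madOutlierFilter(met), "flags")
    expect_identical(
      unname(fl[, "lowTotal"]),
      as.logical(scater::isOutlier(log2(total + 1), nmads = 3,
                                   type = "lower"))
    )
    expect_identical(
      unname(fl[, "highMito"]),
      as.logical(scater::isOutlier(mito, nmads = 3, type = "higher"))
    )
  }
})

test_that("filtering is deterministic and independent of cell order", {
  set.seed(7)
  total <- rpois(40, 3000); detected <- rpois(40, 500)
  mito <- rbeta(40, 2, 20)
  met <- S4Vectors::DataFrame(totalCounts = total, detectedGenes = detected,
                              mitoFraction = mito)
  keep <- madOutlierFilter(met)
  perm <- sample(40)
  keepPerm <- madOutlierFilter(met[perm, , drop = FALSE])
  expect_identical(as.logical(keepPerm), as.logical(keep)[perm])
})

test_that("low-abundance gene filter applies an inclusive mean threshold", {
  m <- matrix(c(0, 0, 0, 0,   # all-zero: removed for any minMean > 0
                1, 0, 0, 0,   # mean 0.25: boundary, kept at minMean 0.25
                2, 1, 1, 1),  # mean 1.25
              nrow = 3, byrow = TRUE,
              dimnames = list(c("zero", "boundary", "high"), NULL))
  expect_identical(unname(filterLowAbundanceGenes(m, 0.25)),
                   c(FALSE, TRUE, TRUE))
  expect_false(filterLowAbundanceGenes(m, 1e-9)[["zero"]])
})

test_that("planted signature genes survive the default gene filter", {
  run <- defaultLiverRun()
  keep <- filterLowAbundanceGenes(
    SummarizedExperiment::assay(run$sce, "counts")
  )
  expect_true(all(keep[run$truth$signature]))
})

test_that("size factors are library-proportional with mean 1", {
  m <- cbind(c(60, 40), c(150, 50))
  colnames(m) <- c("a", "b"); rownames(m) <- c("g1", "g2")
  sf <- computeSizeFactors(m)
  expect_equal(unname(sf), c(2 / 3, 4 / 3))
  expect_equal(mean(sf), 1)
  # equal libraries: all factors 1
  expect_equal(unname(computeSizeFactors(cbind(c(5, 5), c(7, 3)))), c(1, 1))
  # scaling one cell by c scales its factor by c up to re-centering
  m2 <- m; m2[, 1] <- m2[, 1] * 3
  sf2 <- computeSizeFactors(m2)
  expect_equal(sf2[["a"]] / sf2[["b"]], 3 * sf[["a"]] / sf[["b"]])
  expect_error(computeSizeFactors(cbind(c(0, 0), c(1, 2))), "zero total")
})

test_that("log normalisation maps zero to zero and preserves within-cell ranks", {
  set.seed(11)
  m <- matrix(rpois(400, 3), 20)
  rownames(m) <- paste0("g", 1:20)
  norm <- normalizeLogCounts(m)
  expect_true(all(norm[m == 0] == 0))
  expect_true(all(norm >= 0))
  for (j in c(1, 7, 20)) {
    expect_identical(order(norm[, j]), order(m[, j]))
  }
  expect_equal(mean(attr(norm, "sizeFactors")), 1)
})

test_that("proliferating cells are recovered and the null flag rate matches the normal tail", {
  run <- defaultLiverRun()
  # recompute flags on the unfiltered normalised matrix to score recovery
  counts <- SummarizedExperiment::assay(run$sce, "counts")
  ok <- Matrix::colSums(counts) > 0
  norm <- normalizeLogCounts(counts[, ok])
  flags <- flagProliferating(norm, run$truth$cycle)
  truth <- run$sce$trueClass[ok] == "proliferating"
  expect_gte(mean(flags[truth]), 0.9)             # sensitivity
  expect_gte(mean(!flags[!truth]), 0.95)          # specificity
  # identical cells: no flags
  same <- matrix(1, 5, 10, dimnames = list(paste0("g", 1:5), NULL))
  expect_false(any(flagProliferating(same, "g1")))
  expect_error(flagProliferating(same, "absent"), "no cycle genes")
  # pure-control simulation: flag rate compatible with P(Z > 2)
  cfg <- smallSimConfig(koFraction = 0, hetFraction = 0,
                        outlierFraction = 0, doubletFraction = 0,
                        proliferatingFraction = 0, cellsPerSample = 500,
                        seed = 21)
  bulk <- simulateBulkProfiles(cfg)
  sce <- simulateTissueExperiment(cfg, "liver", bulk)
  pl <- S4Vectors::metadata(bulk)$planted
  norm0 <- normalizeLogCounts(SummarizedExperiment::assay(sce, "counts"))
  rate <- mean(flagProliferating(norm0, pl$cycle))
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.06)
})

test_that("contaminant flagging needs co-expression of both marker sets", {
  set.seed(31)
  nA <- 200; nB <- 200; nD <- 50
  gA <- paste0("a", 1:5); gB <- paste0("b", 1:5)
  mk <- function(hiA, hiB, n) {
    rbind(matrix(rnorm(5 * n, if (hiA) 4 else 0.2, 0.3), 5),
          matrix(rnorm(5 * n, if (hiB) 4 else 0.2, 0.3), 5))
  }
  norm <- cbind(mk(TRUE, FALSE, nA), mk(FALSE, TRUE, nB), mk(TRUE, TRUE, nD))
  norm <- pmax(norm, 0)
  rownames(norm) <- c(gA, gB)
  colnames(norm) <- sprintf("c%03d", seq_len(ncol(norm)))
  flags <- flagContaminants(norm, list(list(gA, gB)))
  truth <- rep(c(FALSE, FALSE, TRUE), c(nA, nB, nD))
  expect_gte(mean(flags[truth]), 0.8)    # doublet sensitivity
  expect_false(any(flags[seq_len(nA)]))  # one-set singlets never flagged
  expect_false(any(flagContaminants(norm, list())))
  expect_error(flagContaminants(norm, list(list(gA, c("a1", "b1")))),
               "disjoint")
})

test_that("planted outlier cells show the configured mitochondrial load", {
  run <- defaultLiverRun()
  qc <- computeCellQC(SummarizedExperiment::assay(run$sce, "counts"),
                      run$truth$mito)
  out <- run$sce$trueClass == "outlier"
  expect_lt(abs(mean(qc$mitoFraction[out]) - 0.20), 0.03)
  expect_lt(abs(mean(qc$mitoFraction[run$sce$trueClass == "control"]) -
                  0.05), 0.02)
})
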