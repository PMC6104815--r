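# Synthetic-data generator: planted structure, ground truth, determinism.

test_that("bulk profiles carry the planted fold structure", {
  cfg <- SimConfig()
  bulk <- simulateBulkProfiles(cfg)
  M <- SummarizedExperiment::assay(bulk, "meanExpr")
  pl <- S4Vectors::metadata(bulk)$planted

  expect_true(all(M > 0))
  # brute-force scan: every planted signature gene satisfies the fold
  # condition against every other tissue (confounded partner exempt for the
  # shared block, which is planted high in both)
  for (t in pl$tissues) {
    partner <- setdiff(pl$confoundedTissues, t)
    for (g in pl$signatures[[t]]) {
      others <- setdiff(pl$tissues, t)
      if (g %in% pl$sharedGenes) others <- setdiff(others, partner)
      expect_true(all(M[g, t] >= cfg@effectFold * M[g, others]),
                  label = sprintf("fold condition for %s in %s", g, t))
    }
  }
  # conserved-core genes are high in all tissues: above every non-planted
  # gene in every tissue
  filler <- grep("^Gene", rownames(M), value = TRUE)
  expect_true(min(M[pl$core, ]) > max(M[filler, ]))
})

test_that("the confounded pair shares at least half of its signatures", {
  bulk <- simulateBulkProfiles(SimConfig())
  pl <- S4Vectors::metadata(bulk)$planted
  expect_identical(pl$confoundedTissues, c("liver", "spleen"))
  shared <- intersect(pl$signatures$liver, pl$signatures$spleen)
  expect_gte(length(shared) / length(pl$signatures$liver), 0.5)
})

test_that("effectFold = 1 plants no tissue-specific signal", {
  cfg <- SimConfig(effectFold = 1, confoundedPair = integer())
  bulk <- simulateBulkProfiles(cfg)
  M <- SummarizedExperiment::assay(bulk, "meanExpr")
  # tissue-to-tissue jitter is bounded, so no gene reaches a 1.6-fold ratio
  ratios <- apply(M, 1L, function(v) max(v) / min(v))
  expect_lt(max(ratios), 1.6)
  for (t in colnames(M)) {
    expect_length(deriveTissueSignature(bulk, t, fcThreshold = 2), 0L)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(SimConfig(genesTotal = 100, sigSizePerTissue = 80),
               "configuration error")
  expect_error(SimConfig(koFraction = 0.7, hetFraction = 0.7),
               "koFraction")
  expect_error(SimConfig(confoundedPair = c(1, 9)), "confoundedPair")
  expect_error(simulateTissueExperiment(SimConfig(), "kidney",
                                        simulateBulkProfiles(SimConfig())),
               "unknown tissue")
})

test_that("identical configurations give identical output", {
  cfg <- smallSimConfig(seed = 42)
  b1 <- simulateBulkProfiles(cfg)
  b2 <- simulateBulkProfiles(cfg)
  expect_identical(SummarizedExperiment::assay(b1),
                   SummarizedExperiment::assay(b2))
  s1 <- simulateTissueExperiment(cfg, "liver", b1)
  s2 <- simulateTissueExperiment(cfg, "liver", b2)
  expect_identical(SummarizedExperiment::assay(s1, "counts"),
                   SummarizedExperiment::assay(s2, "counts"))
  expect_identical(s1$trueClass, s2$trueClass)
})

test_that("null perturbation makes CRE+ distributionally identical to CRE-", {
  cfg <- smallSimConfig(koFraction = 0, hetFraction = 0, seed = 3)
  bulk <- simulateBulkProfiles(cfg)
  sce <- simulateTissueExperiment(cfg, "liver", bulk)
  expect_false(any(sce$trueClass == "KO"))
  expect_false(any(sce$trueClass == "het"))
  # same expected profile on both samples: compare per-gene means of the
  # two samples' non-nuisance cells
  counts <- SummarizedExperiment::assay(sce, "counts")
  ok <- sce$trueClass == "control"
  mNeg <- Matrix::rowMeans(counts[, ok & sce$genotype == "CRE-"])
  mPos <- Matrix::rowMeans(counts[, ok & sce$genotype == "CRE+"])
  keep <- mNeg > 0.5
  expect_lt(median(abs(log2((mPos[keep] + 0.5) / (mNeg[keep] + 0.5)))), 0.2)
})

test_that("gain markers are elevated only in knockout cells", {
  run <- defaultLiverRun()
  counts <- SummarizedExperiment::assay(run$sce, "counts")
  gm <- run$truth$gainMarkers
  expect_identical(sort(gm), sort(c("Siglecf", "Ms4a1")))
  cls <- run$sce$trueClass
  mKO <- mean(as.matrix(counts[gm, cls == "KO"]))
  mCtrl <- mean(as.matrix(counts[gm, cls == "control"]))
  mHet <- mean(as.matrix(counts[gm, cls == "het"]))
  expect_gt(mKO, 3 * mCtrl)
  expect_gt(mKO, 3 * mHet)
  expect_lt(abs(log2(mHet / mCtrl)), 0.3)
})

test_that("realized library sizes track the configured mean", {
  cfg <- SimConfig(cellsPerSample = 500, seed = 11)
  bulk <- simulateBulkProfiles(cfg)
  sce <- simulateTissueExperiment(cfg, "lung", bulk)
  totals <- Matrix::colSums(SummarizedExperiment::assay(sce, "counts"))
  ok <- !sce$trueClass %in% c("outlier", "doublet")
  expect_gte(sum(ok), 900)
  expect_lt(abs(mean(totals[ok]) / cfg@meanLibrarySize - 1), 0.05)
})

test_that("control-cell count marginals follow the negative binomial model", {
  # fixed library size isolates the NB marginal: counts are iid
  # NB(p * L, dispersion) per gene
  cfg <- SimConfig(nTissues = 2, genesTotal = 200, sigSizePerTissue = 20,
                   coreSize = 10, confoundedPair = integer(),
                   cellsPerSample = 2500, koFraction = 0, hetFraction = 0,
                   outlierFraction = 0, doubletFraction = 0,
                   proliferatingFraction = 0, librarySdLog = 0,
                   meanLibrarySize = 2000, seed = 5)
  bulk <- simulateBulkProfiles(cfg)
  sce <- simulateTissueExperiment(cfg, "liver", bulk)
  counts <- as.matrix(SummarizedExperiment::assay(sce, "counts"))
  expect_identical(ncol(counts), 5000L)
  v <- SummarizedExperiment::assay(bulk, "meanExpr")[, "liver"]
  mu <- v / sum(v) * cfg@meanLibrarySize
  high <- names(mu)[mu >= 5]
  empMean <- rowMeans(counts[high, ])
  empVar <- apply(counts[high, ], 1L, var)
  thVar <- mu[high] + mu[high]^2 / cfg@nbDispersion
  # pooled relative accuracy: means within 1%, variances within 5%
  expect_lt(abs(sum(empMean) / sum(mu[high]) - 1), 0.01)
  expect_lt(abs(sum(empVar) / sum(thVar) - 1), 0.05)
  expect_lt(median(abs(empMean / mu[high] - 1)), 0.05)
})

test_that("knockout cells have lower expected eroded-gene expression than any control cell", {
  run <- defaultLiverRun()
  gt <- run$truth
  cd <- SummarizedExperiment::colData(run$sce)
  pKO <- sum(gt$classProportions$KO[gt$eroded])
  pCtrl <- sum(gt$classProportions$control[gt$eroded])
  expKO <- cd$expectedLibrarySize[cd$trueClass == "KO"] * pKO
  expCtrl <- cd$expectedLibrarySize[cd$trueClass == "control"] * pCtrl
  expect_lt(max(expKO), min(expCtrl))
})

test_that("ground-truth classes are mutually exclusive and eroded genes lie in the signature", {
  run <- defaultLiverRun()
  gt <- run$truth
  expect_true(all(gt$eroded %in% gt$signature))
  expect_false(any(is.na(run$sce$trueClass)))
  expect_identical(length(run$sce$trueClass), ncol(run$sce))
})
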