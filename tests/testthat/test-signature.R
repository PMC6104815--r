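# Signature derivation, confound handling, erosion scoring, set algebra.

# small constructed bulk table: 4 tissues, gene high in t1+t2 (confounded),
# gene specific to t1, ubiquitous gene, low gene
.toyBulk <- function() {
  M <- rbind(
    shared = c(40, 40, 2, 2),
    only1 = c(40, 2, 2, 2),
    ubiq = c(30, 30, 30, 30),
    low = c(1, 1, 1, 1),
    mid = c(6, 5, 5, 4)
  )
  colnames(M) <- paste0("t", 1:4)
  M
}

test_that("the fold rule excludes ubiquitous genes and honours exclusions", {
  M <- .toyBulk()
  # without exclusions the shared gene fails against its partner tissue
  s1 <- deriveTissueSignature(M, "t1", fcThreshold = 2, exprMin = 3)
  expect_identical(s1, "only1")
  # excluding the partner recovers it (the KC/SM case)
  s1x <- deriveTissueSignature(M, "t1", exclusions = "t2",
                               fcThreshold = 2, exprMin = 3)
  expect_identical(sort(s1x), c("only1", "shared"))
  # a gene equal in all tissues is never specific for fold > 1
  expect_false("ubiq" %in% s1x)
  expect_error(deriveTissueSignature(M, "t1", exclusions = "t1"), "itself")
  expect_error(deriveTissueSignature(M, "t1",
                                     exclusions = c("t2", "t3", "t4")),
               "all other")
  expect_error(deriveTissueSignature(M, "t9"), "unknown tissue")
})

test_that("confounded pairs are detected exactly and exclusion improves recall", {
  bulk <- simulateBulkProfiles(SimConfig())
  pl <- S4Vectors::metadata(bulk)$planted
  pairs <- detectConfoundedPairs(bulk)
  expect_identical(nrow(pairs), 1L)
  expect_identical(sort(as.vector(pairs[1, ])), c("liver", "spleen"))
  expect_false(any(pairs[, 1] == pairs[, 2])) # no self-pairs
  # orthogonal signatures: no pair flagged
  cfg0 <- SimConfig(confoundedPair = integer())
  expect_identical(nrow(detectConfoundedPairs(simulateBulkProfiles(cfg0))),
                   0L)
  # recall with exclusions >= recall without, on the confounded tissue
  recWith <- recallOf(
    deriveTissueSignature(bulk, "liver", exclusions = "spleen"),
    pl$signatures$liver
  )
  recWithout <- recallOf(deriveTissueSignature(bulk, "liver"),
                         pl$signatures$liver)
  expect_gte(recWith, recWithout)
  expect_gte(recWith, 0.95)
})

test_that("planted signatures are recovered with high precision and recall", {
  bulk <- simulateBulkProfiles(SimConfig())
  pl <- S4Vectors::metadata(bulk)$planted
  for (t in pl$tissues) {
    excl <- setdiff(pl$confoundedTissues, t)
    if (!t %in% pl$confoundedTissues) excl <- character()
    s <- deriveTissueSignature(bulk, t, exclusions = excl)
    expect_gte(precisionOf(s, pl$signatures[[t]]), 0.95)
    expect_gte(recallOf(s, pl$signatures[[t]]), 0.95)
  }
  # derivation is invariant to tissue column order
  M <- SummarizedExperiment::assay(bulk, "meanExpr")
  s1 <- deriveTissueSignature(M, "lung")
  s2 <- deriveTissueSignature(M[, rev(colnames(M))], "lung")
  expect_identical(s1, s2)
})

test_that("the prevalence filter applies the inclusive 20% rule", {
  expect_identical(formals(prevalenceFilter)$minFraction, 0.20)
  counts <- matrix(0, 3, 100,
                   dimnames = list(c("at20", "at19", "always"), NULL))
  counts["at20", 1:20] <- 1
  counts["at19", 1:19] <- 1
  counts["always", ] <- 2
  out <- prevalenceFilter(c("at20", "at19", "always"), counts)
  expect_identical(as.character(out), c("at20", "always"))
  expect_error(prevalenceFilter("at20", counts[, 0]), "empty control")
  # output is always a subset of the input
  set.seed(3)
  rnd <- matrix(rbinom(5 * 50, 1, 0.3), 5,
                dimnames = list(paste0("g", 1:5), NULL))
  sub <- prevalenceFilter(paste0("g", 1:5), rnd, 0.4)
  expect_true(all(sub %in% paste0("g", 1:5)))
})

test_that("the conserved core is recovered exactly on the default simulation", {
  bulk <- simulateBulkProfiles(SimConfig())
  pl <- S4Vectors::metadata(bulk)$planted
  core <- deriveConservedCore(bulk, excludeGenes = pl$mito)
  expect_setequal(core, pl$core)
  # a gene absent from one tissue is excluded
  M <- SummarizedExperiment::assay(bulk, "meanExpr")
  M[pl$core[1], 2] <- 0
  expect_false(pl$core[1] %in%
                 deriveConservedCore(M, excludeGenes = pl$mito))
  # unreachable threshold empties the core
  expect_length(deriveConservedCore(M, exprMin = max(M) + 1), 0L)
})

test_that("erosion is the fraction of signature genes flagged significant", {
  mkDE <- function(genes, sigFlag) {
    methods::new("DEResult",
      table = S4Vectors::DataFrame(
        gene = genes, logFC = ifelse(sigFlag, -2, 0), U = 0,
        p = ifelse(sigFlag, 1e-6, 0.9), q = ifelse(sigFlag, 1e-5, 0.95),
        significant = sigFlag,
        direction = ifelse(sigFlag, "down", "none")
      ),
      groupA = "KO", groupB = "control",
      params = list(fdrThreshold = 0.05, logfcThreshold = 0.25)
    )
  }
  sig <- sprintf("g%03d", 1:100)
  de <- mkDE(sig, rep(c(TRUE, FALSE), c(60, 40)))
  er <- identityErosion(sig, de, "liver")
  expect_equal(erosionFraction(er), 0.60)
  expect_identical(erodedGenes(er), sig[1:60])
  er0 <- identityErosion(sig, mkDE(sig, rep(FALSE, 100)))
  expect_equal(erosionFraction(er0), 0)
  expect_error(identityErosion(character(), de), "empty signature")
})

test_that("origin subtraction is an order-preserving set difference", {
  expect_identical(subtractOriginGenes(c("a", "b", "c"), character()),
                   c("a", "b", "c"))
  expect_identical(subtractOriginGenes(c("a", "b", "c"), "b"), c("a", "c"))
  set.seed(17)
  for (i in 1:20) {
    de <- sample(letters, sample(5:20, 1))
    origin <- sample(letters, sample(0:10, 1))
    out <- subtractOriginGenes(de, origin)
    expect_identical(length(out), length(de) - length(intersect(de, origin)))
    expect_identical(out, de[!de %in% origin]) # order preserved
  }
})

test_that("the Venn partition matches brute-force membership enumeration", {
  res <- crossTissueConservation(list(A = c("a", "b"), B = c("b", "c"),
                                      C = "b"))
  expect_identical(res$sharedAll, "b")
  expect_identical(res$unique, list(A = "a", B = "c", C = character()))
  expect_identical(sum(res$partition$count), 3L) # |union|
  # identical lists: everything in the all-tissues cell
  res2 <- crossTissueConservation(list(x = c("p", "q"), y = c("p", "q")))
  expect_identical(sort(res2$sharedAll), c("p", "q"))
  expect_identical(lengths(res2$unique), c(x = 0L, y = 0L))
  # randomized brute-force check
  set.seed(29)
  for (i in 1:15) {
    k <- sample(2:4, 1)
    lists <- lapply(seq_len(k), function(j) {
      sample(letters[1:12], sample(0:8, 1))
    })
    names(lists) <- LETTERS[seq_len(k)]
    res <- crossTissueConservation(lists)
    expect_identical(sum(res$partition$count),
                     length(unique(unlist(lists))))
    for (g in unique(unlist(lists))) {
      inSets <- names(lists)[vapply(lists, function(l) g %in% l,
                                    logical(1))]
      expect_identical(res$membership[[g]],
                       paste(inSets, collapse = "&"))
    }
    pw <- res$pairwise
    for (a in names(lists)) for (b in names(lists)) {
      expect_identical(pw[a, b],
                       length(intersect(lists[[a]], lists[[b]])))
    }
  }
  expect_error(crossTissueConservation(list(a = "x")), "at least 2")
})
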