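#' @importFrom stats rlnorm rnbinom runif qlnorm median quantile rnorm
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom S4Vectors metadata
NULL

# Baseline log-normal parameters of per-gene bulk expression (arbitrary
# units). Values are winsorised at the 97.5th percentile so that planted
# conserved-core genes sit strictly above every baseline gene in all tissues.
.BASE_MEANLOG <- log(5)
.BASE_SDLOG <- 0.5
.baselineCap <- function() qlnorm(0.975, .BASE_MEANLOG, .BASE_SDLOG)
# Tissue-to-tissue jitter of non-specific genes; max/min ratio 1.5625, well
# below the default fold threshold of 2.
.JITTER_LO <- 0.8
.JITTER_HI <- 1.25
# Expected baseline UMI count of a gain marker in a wild-type cell.
.GAIN_BASE_COUNT <- 0.2

.tissueNames <- function(n) {
  known <- c("liver", "lung", "spleen", "brain", "colon")
  if (n <= length(known)) known[seq_len(n)] else {
    c(known, sprintf("tissue%d", seq(length(known) + 1L, n)))
  }
}

.capitalize <- function(x) {
  paste0(toupper(substring(x, 1, 1)), substring(x, 2))
}

#' Lay out the simulated gene universe
#'
#' Assigns names to the reserved gene blocks (mitochondrial, cell cycle,
#' floxed target, conserved core, origin module, per-tissue gain markers,
#' per-tissue signatures with an optional shared block for the confounded
#' pair) and generic filler genes.
#' @noRd
.geneLayout <- function(config) {
  tissues <- .tissueNames(config@nTissues)
  mitoPool <- c("mt-Nd1", "mt-Nd2", "mt-Co1", "mt-Co2", "mt-Atp6",
                "mt-Cytb", "mt-Nd4", "mt-Nd5", "mt-Co3", "mt-Atp8",
                "mt-Nd3", "mt-Nd4l", "mt-Nd6")
  cyclePool <- c("Mki67", "Top2a", "Ccnb1", "Ccna2", "Cdk1", "Birc5",
                 "Ube2c", "Bub1", "Plk1", "Aurka", "Ccnb2", "Cenpa")
  corePool <- c("Fcgr1", "Mertk", "Cd14")
  originPool <- c("Cx3cr1", "Ccr2")
  gainPool <- list(liver = c("Siglecf", "Ms4a1"), lung = c("Epcam", "Cd101"))

  takeNames <- function(pool, n, fmt) {
    if (n <= length(pool)) pool[seq_len(n)] else {
      c(pool, sprintf(fmt, seq(length(pool) + 1L, n)))
    }
  }
  mito <- takeNames(mitoPool, config@nMitoGenes, "mt-X%02d")
  cycle <- takeNames(cyclePool, config@nCycleGenes, "Cycle%02d")
  target <- "Zeb2"
  coreBlock <- takeNames(corePool, max(config@coreSize - 1L, 0L), "Core%03d")
  origin <- takeNames(originPool, config@nOriginGenes, "Origin%02d")

  gain <- list()
  for (t in tissues) {
    pool <- if (!is.null(gainPool[[t]])) gainPool[[t]] else character()
    gain[[t]] <- takeNames(pool, config@gainMarkersPerTissue,
                           paste0("Gain", .capitalize(t), "%02d"))
  }

  sigs <- list()
  shared <- character()
  cp <- config@confoundedPair
  nSig <- config@sigSizePerTissue
  if (length(cp) == 2L) {
    nShared <- round(config@sharedFraction * nSig)
    shared <- sprintf("SigShared%03d", seq_len(nShared))
  }
  for (i in seq_along(tissues)) {
    t <- tissues[i]
    if (i %in% cp) {
      priv <- sprintf("Sig%s%03d", .capitalize(t),
                      seq_len(nSig - length(shared)))
      sigs[[t]] <- c(priv, shared)
    } else {
      sigs[[t]] <- sprintf("Sig%s%03d", .capitalize(t), seq_len(nSig))
    }
  }

  special <- c(mito, cycle, target, coreBlock, origin,
               unlist(gain, use.names = FALSE),
               unique(unlist(sigs, use.names = FALSE)))
  stopifnot(!anyDuplicated(special))
  nFill <- config@genesTotal - length(special)
  if (nFill < 0L) {
    stop("configuration error: planted gene blocks exceed genesTotal")
  }
  filler <- sprintf("Gene%04d", seq_len(nFill))
  list(
    tissues = tissues, genes = c(special, filler), mito = mito,
    cycle = cycle, target = target, core = c(coreBlock, target),
    origin = origin, gainMarkers = gain, signatures = sigs,
    sharedGenes = shared,
    confoundedTissues = if (length(cp)) tissues[cp] else character()
  )
}

#' Simulate bulk expression profiles for a panel of macrophage tissues
#'
#' Generates a genes x tissues table of positive mean expression values with
#' planted structure: each tissue's signature genes exceed `effectFold`
#' times their mean in every other (non-confounded) tissue; the confounded
#' pair, when set, shares a block of signature genes high in both tissues
#' (emulating overlapping transcriptional profiles such as liver and splenic
#' red-pulp macrophages); conserved-core genes are high in all tissues; gain
#' markers are near-absent everywhere; a mitochondrial block carries a fixed
#' share of expression. The planted ground truth is stored in
#' `metadata(.)$planted`.
#'
#' @param config a [SimConfig-class].
#' @return a [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#'   with assay `meanExpr` (genes x tissues) and planted truth in its
#'   metadata.
#' @examples
#' bulk <- simulateBulkProfiles(SimConfig(nTissues = 3, genesTotal = 600,
#'                                        cellsPerSample = 50))
#' dim(SummarizedExperiment::assay(bulk))
#' @export
simulateBulkProfiles <- function(config) {
  methods::validObject(config)
  layout <- .geneLayout(config)
  genes <- layout$genes
  tissues <- layout$tissues
  G <- length(genes)
  Tn <- length(tissues)

  M <- .withSeed(config@seed, {
    base <- rlnorm(G, .BASE_MEANLOG, .BASE_SDLOG)
    base <- pmin(base, .baselineCap())
    names(base) <- genes
    # origin markers (Cx3cr1, Ccr2, ...) are moderately expressed monocyte
    # genes; floor their baseline at the distribution median so the escaper
    # module is quantifiable at realistic sequencing depth
    base[layout$origin] <- pmax(base[layout$origin], exp(.BASE_MEANLOG))
    # signature genes are planted from moderate baselines: identity
    # programmes are many genes of individually modest abundance, so their
    # erosion removes only a few percent of a knockout cell's library and
    # the compositional shift of relative-abundance data stays second-order
    sigGenes <- unique(unlist(layout$signatures, use.names = FALSE))
    base[sigGenes] <- pmin(pmax(base[sigGenes], 1.2), 2.4)
    jitter <- matrix(runif(G * Tn, .JITTER_LO, .JITTER_HI), G, Tn,
                     dimnames = list(genes, tissues))
    M <- base * jitter

    # conserved core (incl. the floxed target): high in every tissue,
    # strictly above any winsorised baseline gene
    coreLevel <- 3 * .baselineCap()
    M[layout$core, ] <- coreLevel * jitter[layout$core, ]

    # tissue-specific signatures: guaranteed fold over the max of all other
    # tissues (shared genes of the confounded pair: high in both)
    if (config@effectFold > 1) {
      sigLevel <- function(b) b * .JITTER_HI * config@effectFold * 1.1
      for (t in tissues) {
        own <- setdiff(layout$signatures[[t]], layout$sharedGenes)
        M[own, t] <- sigLevel(base[own])
      }
      for (t in layout$confoundedTissues) {
        M[layout$sharedGenes, t] <- sigLevel(base[layout$sharedGenes]) *
          runif(length(layout$sharedGenes), 0.95, 1.05)
      }
    }

    # gain markers: near-absent in wild-type cells in every tissue
    gainGenes <- unlist(layout$gainMarkers, use.names = FALSE)
    for (t in tissues) {
      sRest <- sum(M[setdiff(genes, c(gainGenes, layout$mito)), t])
      v <- .GAIN_BASE_COUNT * sRest /
        (config@meanLibrarySize - .GAIN_BASE_COUNT * length(gainGenes))
      M[gainGenes, t] <- v
    }

    # mitochondrial block: fixed share of total expression
    for (t in tissues) {
      sRest <- sum(M[setdiff(genes, layout$mito), t])
      M[layout$mito, t] <- (config@mitoShare / (1 - config@mitoShare)) *
        sRest / length(layout$mito)
    }
    M
  })

  se <- SummarizedExperiment(assays = list(meanExpr = M))
  S4Vectors::metadata(se) <- list(planted = layout, config = config)
  se
}

#' Per-class expected expression proportions for one tissue
#'
#' Means are expressed relative to the control profile's total, so knockout
#' modifications literally scale per-gene means: eroded genes divided by
#' `effectFold`, gain markers multiplied by `effectFold`, the floxed target
#' multiplied by `truncBoost` (truncated 3' transcript accumulation);
#' heterozygous escapers carry the origin-gene module at `effectFold`.
#' @noRd
.classProportions <- function(config, layout, v, eroded, tissue) {
  total <- sum(v)
  pControl <- v / total
  ko <- v
  ko[eroded] <- ko[eroded] / config@effectFold
  ko[layout$gainMarkers[[tissue]]] <-
    ko[layout$gainMarkers[[tissue]]] * config@effectFold
  ko[layout$target] <- ko[layout$target] * config@truncBoost
  het <- v
  het[layout$origin] <- het[layout$origin] * config@effectFold
  list(control = pControl, het = het / total, KO = ko / total)
}

#' Rescale a proportion vector so the mitochondrial block carries `share`
#' of the total, then renormalise to sum 1.
#' @noRd
.setMitoShare <- function(p, mito, share) {
  s0 <- sum(p[mito])
  f <- share * (1 - s0) / (s0 * (1 - share))
  p[mito] <- p[mito] * f
  p / sum(p)
}

#' Simulate a mosaic conditional-knockout single-cell experiment
#'
#' Draws UMI counts for one CRE- and one CRE+ sample of a given tissue from
#' a negative binomial model (variance `mu + mu^2 / nbDispersion`) whose
#' per-cell means are the bulk profile scaled to a log-normal library size.
#' CRE+ cells are a mixture of homozygous knockouts (eroded signature genes
#' down `effectFold`-fold, gain markers up, floxed target boosted) and
#' heterozygous escapers (origin-gene module up, emulating recent niche
#' refilling by escaper cells). Planted nuisance cells: QC outliers (library
#' scaled to 10%, mitochondrial share raised), intra-sample doublets (sums
#' of two cell profiles) and proliferating cells (cycle genes up). Cell
#' classes are mutually exclusive and sampled without replacement, seeded;
#' identical configurations give byte-identical output.
#'
#' @param config a [SimConfig-class].
#' @param tissue tissue name or index present in `bulk`.
#' @param bulk result of [simulateBulkProfiles()].
#' @return a
#'   [SingleCellExperiment][SingleCellExperiment::SingleCellExperiment-class]
#'   with a sparse `counts` assay (genes x cells), per-cell `colData`
#'   (sample, genotype, trueClass, expectedLibrarySize) and the full ground
#'   truth in `metadata(.)$groundTruth`.
#' @examples
#' cfg <- SimConfig(nTissues = 2, genesTotal = 400, cellsPerSample = 60,
#'                  sigSizePerTissue = 30, coreSize = 10)
#' bulk <- simulateBulkProfiles(cfg)
#' sce <- simulateTissueExperiment(cfg, "liver", bulk)
#' table(sce$trueClass, sce$genotype)
#' @export
simulateTissueExperiment <- function(config, tissue, bulk) {
  methods::validObject(config)
  layout <- S4Vectors::metadata(bulk)$planted
  if (is.null(layout)) {
    stop("'bulk' must be the output of simulateBulkProfiles()")
  }
  if (is.numeric(tissue)) tissue <- layout$tissues[tissue]
  if (is.na(tissue) || !tissue %in% layout$tissues) {
    stop(sprintf("unknown tissue id '%s'", tissue))
  }
  tIdx <- match(tissue, layout$tissues)
  v <- assay(bulk, "meanExpr")[, tissue]
  genes <- layout$genes
  G <- length(genes)
  n <- config@cellsPerSample

  res <- .withSeed(config@seed + 101L * tIdx, {
    sig <- layout$signatures[[tissue]]
    eroded <- sort(sample(sig, round(config@erosionFraction * length(sig))))
    props <- .classProportions(config, layout, v, eroded, tissue)

    sampleCells <- function(sampleName, genotype) {
      baseClass <- rep("control", n)
      if (genotype == "CRE+") {
        nKO <- round(config@koFraction * n)
        nHet <- round(config@hetFraction * n)
        if (nKO + nHet > n) nHet <- n - nKO
        perm <- sample.int(n)
        baseClass[perm[seq_len(nKO)]] <- "KO"
        if (nHet > 0) baseClass[perm[nKO + seq_len(nHet)]] <- "het"
      }
      nOut <- round(config@outlierFraction * n)
      nDbl <- round(config@doubletFraction * n)
      nPro <- round(config@proliferatingFraction * n)
      special <- sample.int(n, nOut + nDbl + nPro)
      trueClass <- baseClass
      outIdx <- special[seq_len(nOut)]
      dblIdx <- special[nOut + seq_len(nDbl)]
      proIdx <- special[nOut + nDbl + seq_len(nPro)]
      trueClass[outIdx] <- "outlier"
      trueClass[dblIdx] <- "doublet"
      trueClass[proIdx] <- "proliferating"

      lib <- rlnorm(n, log(config@meanLibrarySize) -
                      config@librarySdLog^2 / 2, config@librarySdLog)
      mu <- matrix(0, G, n, dimnames = list(genes, NULL))
      for (cls in c("control", "het", "KO")) {
        idx <- which(baseClass == cls)
        if (length(idx)) {
          mu[, idx] <- outer(props[[cls]], lib[idx])
        }
      }
      # proliferating: cycle genes elevated on top of the base profile
      for (i in proIdx) {
        p <- props[[baseClass[i]]]
        p[layout$cycle] <- p[layout$cycle] * config@effectFold
        mu[, i] <- p * lib[i]
      }
      # outliers: 10% library, elevated mitochondrial share
      for (i in outIdx) {
        p <- .setMitoShare(props[[baseClass[i]]], layout$mito,
                           config@outlierMitoShare)
        mu[, i] <- p * (0.1 * lib[i])
      }
      # doublets: sum of the cell's own profile and a sampled partner
      partnerOf <- rep(NA_integer_, n)
      if (length(dblIdx)) {
        candidates <- setdiff(seq_len(n), special)
        partners <- sample(candidates, length(dblIdx), replace = TRUE)
        partnerLib <- rlnorm(length(dblIdx),
                             log(config@meanLibrarySize) -
                               config@librarySdLog^2 / 2,
                             config@librarySdLog)
        for (k in seq_along(dblIdx)) {
          i <- dblIdx[k]; j <- partners[k]
          mu[, i] <- props[[baseClass[i]]] * lib[i] +
            props[[baseClass[j]]] * partnerLib[k]
          lib[i] <- lib[i] + partnerLib[k]
        }
        partnerOf[dblIdx] <- partners
      }
      counts <- matrix(
        rnbinom(G * n, mu = as.vector(mu), size = config@nbDispersion),
        G, n, dimnames = list(genes, NULL)
      )
      list(counts = counts, trueClass = trueClass, baseClass = baseClass,
           lib = lib, partnerOf = partnerOf, sampleName = sampleName,
           genotype = genotype)
    }

    neg <- sampleCells(paste0(tissue, "_CREneg"), "CRE-")
    pos <- sampleCells(paste0(tissue, "_CREpos"), "CRE+")
    list(neg = neg, pos = pos, eroded = eroded, props = props)
  })

  counts <- cbind(res$neg$counts, res$pos$counts)
  barcodes <- c(
    sprintf("%s_CREneg_%04d", tissue, seq_len(n)),
    sprintf("%s_CREpos_%04d", tissue, seq_len(n))
  )
  colnames(counts) <- barcodes
  cd <- S4Vectors::DataFrame(
    barcode = barcodes,
    sample = rep(c(res$neg$sampleName, res$pos$sampleName), each = n),
    genotype = factor(rep(c("CRE-", "CRE+"), each = n),
                      levels = c("CRE-", "CRE+")),
    trueClass = factor(c(res$neg$trueClass, res$pos$trueClass),
                       levels = c("control", "het", "KO", "outlier",
                                  "doublet", "proliferating")),
    baseClass = c(res$neg$baseClass, res$pos$baseClass),
    expectedLibrarySize = c(res$neg$lib, res$pos$lib),
    row.names = barcodes
  )
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = methods::as(counts, "CsparseMatrix")),
    colData = cd
  )
  S4Vectors::metadata(sce) <- list(
    groundTruth = list(
      tissue = tissue, signature = layout$signatures[[tissue]],
      eroded = res$eroded, gainMarkers = layout$gainMarkers[[tissue]],
      core = layout$core, origin = layout$origin, target = layout$target,
      mito = layout$mito, cycle = layout$cycle,
      classProportions = res$props
    ),
    config = config
  )
  sce
}
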