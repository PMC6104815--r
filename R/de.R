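#' @importFrom stats pnorm p.adjust
#' @importFrom utils combn
NULL

#' Wilcoxon rank-sum test with exact small-sample branch
#'
#' Ties receive mid-ranks. When the combined sample size is at most 12 the
#' two-sided p-value is computed by exact enumeration of all group
#' assignments of the observed values (a conditional permutation test, valid
#' under ties); otherwise the normal approximation with tie-corrected
#' variance and continuity correction is used.
#'
#' @param x,y numeric vectors, each nonempty.
#' @return list with elements `U` (Mann-Whitney statistic for `x`) and `p`
#'   (two-sided p-value).
#' @examples
#' rankSumTest(c(1, 2), c(3, 4)) # U = 0, exact p = 1/3
#' @export
rankSumTest <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop("both groups must be nonempty")
  N <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (N <= 12L) {
    # exact enumeration over all assignments; doubled ranks keep the
    # arithmetic in integers so tie comparisons are exact
    r2 <- as.integer(round(2 * r))
    center2 <- n1 * n2 # 2 * n1 * n2 / 2
    off2 <- n1 * (n1 + 1L)
    obs <- abs(as.integer(round(2 * U)) - center2)
    subsets <- utils::combn(N, n1)
    u2 <- colSums(matrix(r2[subsets], nrow = n1)) - off2
    p <- mean(abs(u2 - center2) >= obs)
  } else {
    mu <- n1 * n2 / 2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 *
      ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- U - mu
      z <- (z - sign(z) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  list(U = unname(U), p = unname(p))
}

#' Log2 fold change of group means
#'
#' `log2((mean(a) + pseudo) / (mean(b) + pseudo))`, intended for de-logged
#' normalised expression values; the pseudocount stabilises low expressors.
#'
#' @param a,b numeric vectors of (de-logged) expression values.
#' @param pseudo pseudocount (default 1).
#' @return scalar log2 fold change of `a` over `b`.
#' @export
logFoldChange <- function(a, b, pseudo = 1) {
  log2((mean(a) + pseudo) / (mean(b) + pseudo))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity,
#' capped at 1 (delegates to [stats::p.adjust()]).
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of q-values, same order as the input.
#' @export
bhFdr <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Differential expression between two cell groups
#'
#' Genes expressed in at least `minPrevalence` of cells in either group are
#' tested with the Wilcoxon rank-sum test on normalised log expression; log
#' fold changes are computed on de-logged normalised means; q-values are BH
#' across tested genes only. A gene is significant iff
#' `q <= fdrThreshold` and `|logFC| >= logfcThreshold`.
#'
#' @param norm normalised log-expression matrix (genes x cells).
#' @param cellsA,cellsB disjoint nonempty cell index or name vectors; logFC
#'   is A over B.
#' @param fdrThreshold,logfcThreshold significance thresholds.
#' @param minPrevalence minimum expressed fraction for testing (default 0.1).
#' @param groupA,groupB labels recorded in the result.
#' @return a [DEResult-class].
#' @export
findDEGenes <- function(norm, cellsA, cellsB, fdrThreshold = 0.05,
                        logfcThreshold = 0.25, minPrevalence = 0.1,
                        groupA = "A", groupB = "B") {
  if (is.character(cellsA)) cellsA <- match(cellsA, colnames(norm))
  if (is.character(cellsB)) cellsB <- match(cellsB, colnames(norm))
  if (!length(cellsA) || !length(cellsB)) {
    stop("both cell sets must be nonempty")
  }
  if (length(intersect(cellsA, cellsB))) {
    stop("cell sets must be disjoint")
  }
  A <- as.matrix(norm[, cellsA, drop = FALSE])
  B <- as.matrix(norm[, cellsB, drop = FALSE])
  prevA <- rowMeans(A > 0)
  prevB <- rowMeans(B > 0)
  tested <- which(prevA >= minPrevalence | prevB >= minPrevalence)
  genes <- rownames(norm)[tested]
  U <- p <- lfc <- numeric(length(tested))
  for (k in seq_along(tested)) {
    g <- tested[k]
    rs <- rankSumTest(A[g, ], B[g, ])
    U[k] <- rs$U
    p[k] <- rs$p
    lfc[k] <- logFoldChange(2^A[g, ] - 1, 2^B[g, ] - 1)
  }
  q <- bhFdr(p)
  sig <- q <= fdrThreshold & abs(lfc) >= logfcThreshold
  tab <- S4Vectors::DataFrame(
    gene = genes, logFC = lfc, U = U, p = p, q = q, significant = sig,
    direction = ifelse(lfc > 0, "up", ifelse(lfc < 0, "down", "none"))
  )
  methods::new("DEResult", table = tab, groupA = groupA, groupB = groupB,
               params = list(fdrThreshold = fdrThreshold,
                             logfcThreshold = logfcThreshold,
                             minPrevalence = minPrevalence,
                             nA = length(cellsA), nB = length(cellsB)))
}

#' Top markers per group
#'
#' One-vs-rest differential expression for every group; significant genes
#' are ranked by descending log fold change (ties broken by smaller q, then
#' gene symbol) and the top `n` reported per group. Groups with fewer than
#' 3 cells are skipped with a warning.
#'
#' @param norm normalised log-expression matrix (genes x cells).
#' @param groups factor (or vector) of per-group labels, one per cell, or a
#'   [GroupAssignment-class].
#' @param n markers reported per group (default 15).
#' @param ... passed to [findDEGenes()].
#' @return named list of per-group marker data.frames (gene, logFC, q).
#' @export
topMarkersPerGroup <- function(norm, groups, n = 15, ...) {
  if (methods::is(groups, "GroupAssignment")) groups <- cellGroups(groups)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2L) stop("need at least 2 groups")
  out <- list()
  for (g in levels(droplevels(groups))) {
    inG <- which(groups == g)
    if (length(inG) < 3L) {
      warning(sprintf("group '%s' has fewer than 3 cells; skipped", g))
      next
    }
    de <- findDEGenes(norm, inG, which(groups != g), groupA = g,
                      groupB = "rest", ...)
    tab <- as.data.frame(deTable(de))
    tab <- tab[tab$significant, , drop = FALSE]
    tab <- tab[order(-tab$logFC, tab$q, tab$gene), , drop = FALSE]
    out[[g]] <- utils::head(tab[, c("gene", "logFC", "q")], n)
  }
  out
}
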