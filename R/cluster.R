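#' @importFrom stats prcomp dist
NULL

#' Select highly variable genes
#'
#' Per-gene variances of the log-normalised matrix are compared with a
#' running-median variance-versus-mean trend computed in 20 equal-occupancy
#' mean bins; genes are ranked by their residual above the trend and the top
#' `nHVGs` are returned. Constant genes have non-positive residuals and are
#' never selected while any positive-residual gene remains.
#'
#' @param norm normalised log-expression matrix (genes x cells).
#' @param nHVGs number of genes to return (at most the gene count).
#' @return character vector of selected gene identifiers, ranked.
#' @export
selectHVGs <- function(norm, nHVGs = 1000) {
  if (ncol(norm) < 2L) stop("need at least 2 cells")
  if (nHVGs > nrow(norm)) {
    stop("nHVGs exceeds the number of genes")
  }
  m <- Matrix::rowMeans(norm)
  v <- .rowVars(norm)
  nbins <- min(20L, nrow(norm))
  # equal-occupancy bins on the mean, ties resolved by gene order
  bin <- ceiling(rank(m, ties.method = "first") * nbins / length(m))
  trend <- tapply(v, bin, median)
  resid <- v - trend[as.character(bin)]
  ord <- order(-resid, rownames(norm))
  rownames(norm)[ord][seq_len(nHVGs)]
}

#' Reduce cells to a PCA embedding
#'
#' Genes are centred and cells are projected onto the top principal
#' components. The sign of each component is fixed by making its
#' largest-magnitude gene loading positive, so the embedding is fully
#' deterministic.
#'
#' @param norm normalised log-expression matrix (genes x cells), typically
#'   restricted to highly variable genes.
#' @param nComponents embedding dimension; must be smaller than both matrix
#'   dimensions.
#' @return cells x `nComponents` numeric matrix, with the proportion of
#'   variance explained attached as attribute `"varExplained"`.
#' @export
reduceCellDims <- function(norm, nComponents = 20) {
  if (nComponents >= min(dim(norm))) {
    stop("nComponents must be smaller than both the cell and gene count")
  }
  if (all(norm == 0)) stop("degenerate all-zero matrix")
  pc <- stats::prcomp(t(as.matrix(norm)), center = TRUE, scale. = FALSE,
                      rank. = nComponents)
  k <- ncol(pc$x)
  for (j in seq_len(k)) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  emb <- pc$x
  rownames(emb) <- colnames(norm)
  attr(emb, "varExplained") <- pc$sdev[seq_len(k)]^2 / sum(pc$sdev^2)
  emb
}

#' Agglomerate over-partitioned communities
#'
#' Repeatedly merges the cluster pair whose between-cluster edge count most
#' exceeds the configuration-model expectation `vol(A) vol(B) / 2m` (vol =
#' sum of member degrees, m = edge count), while some pair reaches at least
#' `threshold` times that expectation. Fragments of one dense kNN region
#' are connected close to expectation (ratios near 1) and merge; separated
#' populations joined by a thin interface or a few doublet bridges sit far
#' below it. Deterministic: ties broken by smallest cluster ids.
#' @noRd
.mergeConnectedClusters <- function(labels, edges, threshold = 0.5) {
  deg <- tabulate(c(edges[, 1L], edges[, 2L]), nbins = length(labels))
  twoM <- 2 * nrow(edges)
  repeat {
    ids <- sort(unique(labels))
    if (length(ids) < 2L) break
    vol <- vapply(split(deg, labels), sum, numeric(1))
    a <- labels[edges[, 1L]]
    b <- labels[edges[, 2L]]
    cross <- a != b
    if (!any(cross)) break
    key <- paste(pmin(a[cross], b[cross]), pmax(a[cross], b[cross]))
    cnt <- table(key)
    pairIds <- do.call(rbind, strsplit(names(cnt), " "))
    lo <- as.integer(pairIds[, 1L])
    hi <- as.integer(pairIds[, 2L])
    expected <- pmax(vol[as.character(lo)] * vol[as.character(hi)] / twoM,
                     1e-12)
    score <- as.integer(cnt) / as.numeric(expected)
    if (max(score) < threshold) break
    best <- which(score == max(score))
    best <- best[order(lo[best], hi[best])][1L]
    labels[labels == hi[best]] <- lo[best]
  }
  labels
}

#' @noRd
.knnIndices <- function(d, k) {
  n <- nrow(d)
  idx <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    ord <- order(d[i, ], seq_len(n))
    ord <- ord[ord != i]
    idx[i, ] <- ord[seq_len(k)]
  }
  idx
}

#' Cluster cells on a mutual kNN graph
#'
#' Builds the mutual k-nearest-neighbour graph (Euclidean distances in the
#' embedding) and partitions it by seeded Louvain modularity optimisation;
#' modularity resists the sparse bridges that doublet-like cells create
#' between populations. Because modularity optimisation over-partitions
#' large uniform regions (the resolution limit), strongly connected
#' communities are then agglomerated: two clusters merge while their edge
#' count reaches at least half the configuration-model expectation, a
#' connectivity no pair of genuinely separated populations attains. Singleton
#' clusters are merged into the cluster with the nearest centroid. Labels
#' are contiguous integers from 0 in order of decreasing cluster size, and
#' are deterministic given the seed.
#'
#' @param embedding cells x dimensions matrix from [reduceCellDims()].
#' @param kNeighbors neighbourhood size (default 15); at least
#'   `kNeighbors + 1` cells required.
#' @param seed integer seed for the community search.
#' @return a [ClusterResult-class].
#' @export
clusterCells <- function(embedding, kNeighbors = 15, seed = 0) {
  n <- nrow(embedding)
  if (n < kNeighbors + 1L) {
    stop("need at least kNeighbors + 1 cells")
  }
  # canonical cell order (lexicographic on coordinates): community search
  # depends on vertex order, so this makes the partition invariant to the
  # order in which cells arrive
  canon <- do.call(order, as.data.frame(embedding))
  original <- embedding
  embedding <- embedding[canon, , drop = FALSE]
  d <- as.matrix(stats::dist(embedding))
  knn <- .knnIndices(d, kNeighbors)
  # mutual kNN edge list
  edges <- NULL
  nb <- vector("list", n)
  for (i in seq_len(n)) {
    cand <- knn[i, ]
    mutual <- cand[vapply(cand, function(j) i %in% knn[j, ], logical(1))]
    nb[[i]] <- mutual
    keep <- mutual[mutual > i]
    if (length(keep)) edges <- rbind(edges, cbind(i, keep))
  }
  if (is.null(edges)) {
    labels <- rep(1L, n) # no mutual neighbours at all: one cluster
  } else {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
    labels <- .withSeed(seed, {
      igraph::membership(igraph::cluster_louvain(g))
    })
    # isolated vertices form singletons; handled by the merge step below
    labels <- as.integer(labels)
    labels <- .mergeConnectedClusters(labels, edges)
  }
  # merge clusters too small to be resolved on a k-NN graph (fringe cells
  # and disconnected micro-components, singletons included) into the
  # cluster with the nearest centroid; smallest first, deterministically
  minSize <- 2L * kNeighbors
  repeat {
    sizes <- table(labels)
    if (length(sizes) == 1L) break
    small <- as.integer(names(sizes)[sizes < minSize])
    if (!length(small)) break
    sm <- small[order(sizes[as.character(small)], small)][1L]
    idx <- which(labels == sm)
    others <- setdiff(unique(labels), sm)
    cent <- vapply(others, function(l) {
      colMeans(embedding[labels == l, , drop = FALSE])
    }, numeric(ncol(embedding)))
    own <- colMeans(embedding[idx, , drop = FALSE])
    dd <- sqrt(colSums((cent - own)^2))
    labels[idx] <- others[which.min(dd)]
  }
  # contiguous labels from 0, decreasing size, ties by first appearance
  sizes <- table(labels)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  relabel <- seq_along(ord) - 1L
  names(relabel) <- names(sizes)[ord]
  out <- integer(n)
  out[canon] <- relabel[as.character(labels)]
  names(out) <- rownames(original)
  methods::new("ClusterResult", labels = as.integer(out),
               params = list(kNeighbors = as.integer(kNeighbors),
                             seed = as.integer(seed),
                             nComponents = ncol(embedding)))
}
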