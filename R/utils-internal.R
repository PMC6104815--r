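# Internal helpers shared across modules. Not exported.

#' Evaluate an expression under a temporary RNG state
#'
#' Saves and restores `.Random.seed` so that seeded internals never perturb
#' the caller's RNG stream.
#' @noRd
.withSeed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

#' Per-row variance of a dense matrix without copying per row
#' @noRd
.rowVars <- function(x) {
  n <- ncol(x)
  if (n < 2L) stop("need at least 2 columns to compute a variance")
  m <- Matrix::rowMeans(x)
  (Matrix::rowSums(x^2) - n * m^2) / (n - 1)
}

#' Between-class-variance (Otsu) threshold for a numeric vector
#'
#' Exhaustive scan over midpoints between consecutive sorted unique values;
#' the threshold maximising between-class variance is returned, with ties
#' broken toward the smallest threshold so results are deterministic.
#' @noRd
.otsuThreshold <- function(x) {
  u <- sort(unique(x))
  if (length(u) < 2L) stop("cannot threshold a constant vector")
  xs <- sort(x)
  n <- length(xs)
  cand <- (u[-length(u)] + u[-1L]) / 2
  # cumulative counts/sums at each candidate (all values <= candidate go low)
  nlo <- findInterval(cand, xs)
  cs <- cumsum(xs)
  slo <- cs[nlo]
  nhi <- n - nlo
  mlo <- slo / nlo
  mhi <- (cs[n] - slo) / nhi
  bcv <- (nlo / n) * (nhi / n) * (mlo - mhi)^2
  cand[which.max(bcv)]
}

#' Coerce a counts input (SingleCellExperiment or matrix-like) to a matrix
#' of counts with gene and cell names, genes as rows.
#' @noRd
.countsMatrix <- function(x) {
  if (methods::is(x, "SummarizedExperiment")) {
    x <- SummarizedExperiment::assay(x, "counts")
  }
  if (is.null(rownames(x))) rownames(x) <- sprintf("gene%d", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- sprintf("cell%d", seq_len(ncol(x)))
  x
}

#' @noRd
.assertProportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single proportion in [0, 1]", name))
  }
  invisible(TRUE)
}
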