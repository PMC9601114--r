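#' Count adjacent in-frame codon pairs
#'
#' Walks each CDS in frame and counts every adjacent codon pair (codon t,
#' codon t+1), the start codon participating as the first 5' member and the
#' terminal stop as the last 3' member, pooled over genes into a 64 x 64
#' table (rows = 5' codon, columns = 3' codon, alphabetical order).  Because
#' validated CDS have no internal stops, stop codons never appear as 5'
#' members.
#'
#' @param x A [CdsSet-class].
#' @return A [ContextMatrix-class] with the observed counts filled.
#' @export
pairCounts <- function(x) {
  stopifnot(methods::is(x, "CdsSet"), length(x) >= 1L)
  obs <- matrix(0L, 64L, 64L, dimnames = list(ALL_CODONS, ALL_CODONS))
  for (s in as.character(cdsSequences(x))) {
    codons <- .codonsOf(s)
    k <- length(codons)
    if (k < 2L) next
    i5 <- match(codons[-k], ALL_CODONS)
    i3 <- match(codons[-1L], ALL_CODONS)
    obs <- obs + matrix(tabulate((i3 - 1L) * 64L + i5, nbins = 64L * 64L),
                        64L, 64L)
  }
  methods::new("ContextMatrix", observed = obs,
               expected = matrix(numeric(0), 0, 0),
               residuals = matrix(numeric(0), 0, 0),
               nPairs = sum(obs))
}

#' Independence-model expectations and adjusted residuals
#'
#' Fills the expected counts \eqn{E_{ij} = n_{i\cdot} n_{\cdot j} / N} of the
#' row-column independence model and the adjusted Pearson residuals
#' \deqn{d_{ij} = \frac{O_{ij} - E_{ij}}
#'   {\sqrt{E_{ij}\,(1 - n_{i\cdot}/N)\,(1 - n_{\cdot j}/N)}},}
#' which have unit asymptotic variance under independence.  Cells with
#' \eqn{E_{ij} = 0} get residual 0.  The sum of squared *unadjusted* Pearson
#' residuals over supported cells equals the table's chi-square statistic.
#'
#' @param x A [ContextMatrix-class] from [pairCounts()].
#' @return The [ContextMatrix-class] with `expected` and `residuals` filled.
#' @export
contextResiduals <- function(x) {
  stopifnot(methods::is(x, "ContextMatrix"), x@nPairs > 0L)
  O <- x@observed
  N <- sum(O)
  rs <- rowSums(O)
  cs <- colSums(O)
  E <- outer(rs, cs) / N
  denom <- sqrt(E * outer(1 - rs / N, 1 - cs / N))
  R <- matrix(0, 64L, 64L, dimnames = dimnames(O))
  ok <- E > 0 & denom > 0
  R[ok] <- (O[ok] - E[ok]) / denom[ok]
  methods::new("ContextMatrix", observed = O, expected = E,
               residuals = R, nPairs = x@nPairs)
}

#' Mean of per-gene codon-context residual matrices
#'
#' Computes the adjusted-residual matrix of each gene's own codon-pair table
#' and averages them cell-wise, the per-gene alternative to the pooled
#' dataset-level matrix of [pairCounts()] + [contextResiduals()].
#'
#' @param x A [CdsSet-class].
#' @return A 64 x 64 numeric matrix, the element-wise mean of the per-gene
#'   adjusted residual matrices.
#' @export
meanContextResiduals <- function(x) {
  stopifnot(methods::is(x, "CdsSet"), length(x) >= 1L)
  acc <- matrix(0, 64L, 64L, dimnames = list(ALL_CODONS, ALL_CODONS))
  for (i in seq_len(length(x))) {
    cm <- contextResiduals(pairCounts(x[i]))
    acc <- acc + pairResiduals(cm)
  }
  acc / length(x)
}

#' Hierarchical-clustering leaf order for the residual heatmap
#'
#' Clusters the rows and the columns of the adjusted-residual matrix by
#' average-linkage hierarchical agglomeration on Euclidean distances and
#' returns the leaf orders, the standard ordering for a clustered codon-pair
#' heatmap.
#'
#' @param x A [ContextMatrix-class] with residuals filled, or a plain numeric
#'   matrix of residuals.
#' @return A list with `rows` and `cols`, each a permutation of the row /
#'   column indices.
#' @export
clusterOrder <- function(x) {
  R <- if (methods::is(x, "ContextMatrix")) pairResiduals(x) else as.matrix(x)
  if (!length(R)) stop("residuals not filled; run contextResiduals() first")
  list(rows = stats::hclust(stats::dist(R), method = "average")$order,
       cols = stats::hclust(stats::dist(t(R)), method = "average")$order)
}

#' @describeIn ContextMatrix-class Observed pair counts.
#' @export
setMethod("observedPairs", "ContextMatrix", function(x) x@observed)

#' @describeIn ContextMatrix-class Expected counts under independence.
#' @export
setMethod("expectedPairs", "ContextMatrix", function(x) x@expected)

#' @describeIn ContextMatrix-class Adjusted Pearson residuals.
#' @export
setMethod("pairResiduals", "ContextMatrix", function(x) x@residuals)

setMethod("show", "ContextMatrix", function(object) {
  cat("ContextMatrix: 64 x 64 codon pairs,", object@nPairs, "pairs counted\n")
  cat("  residuals:", if (length(object@residuals)) "filled" else "not computed", "\n")
})
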