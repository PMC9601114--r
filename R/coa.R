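#' Correspondence analysis of the gene-by-codon RSCU matrix
#'
#' Classical correspondence analysis: the matrix is normalised to proportions
#' \eqn{P} with grand total 1, row and column masses \eqn{r, c} are its
#' margins, the standardised residual matrix
#' \eqn{S = D_r^{-1/2}(P - r c^\top) D_c^{-1/2}} is decomposed by SVD, and
#' principal coordinates are the mass-rescaled singular vectors scaled by the
#' singular values.  Each axis carries a fraction of the total inertia (the
#' table's chi-square statistic divided by the grand total) equal to its
#' squared singular value over the sum.
#'
#' Genes are points in the 59-dimensional codon space; codons project into
#' the same space, so the first two axes give the usual gene/codon biplot of
#' codon-usage trends.
#'
#' @param rscuMatrix Non-negative numeric matrix, genes x codons (typically
#'   the genes x 59 RSCU matrix from [rscu()]).  `NA` entries (amino acids
#'   absent from a gene) are imputed as 0 with a warning.  At least 3 rows
#'   and one positive entry per row are required.
#' @return A [CoaResult-class].
#' @examples
#' set.seed(1)
#' m <- matrix(rpois(5 * 8, 4), 5, dimnames = list(paste0("g", 1:5), NULL))
#' coaFit(m)
#' @export
coaFit <- function(rscuMatrix) {
  X <- as.matrix(rscuMatrix)
  if (nrow(X) < 3L) stop("correspondence analysis needs at least 3 genes")
  if (anyNA(X)) {
    warning("imputed ", sum(is.na(X)), " NA entries as 0 for correspondence analysis")
    X[is.na(X)] <- 0
  }
  if (any(X < 0)) stop("matrix must be non-negative")
  if (sum(X) == 0) stop("matrix is all zero")
  if (any(rowSums(X) == 0)) stop("every gene needs at least one positive entry")

  keepCols <- colSums(X) > 0
  Xk <- X[, keepCols, drop = FALSE]

  P <- Xk / sum(Xk)
  r <- rowSums(P)
  c <- colSums(P)
  S <- (P - outer(r, c)) / sqrt(outer(r, c))
  sv <- svd(S)

  kmax <- min(nrow(Xk) - 1L, ncol(Xk) - 1L)
  d <- sv$d[seq_len(kmax)]
  tol <- max(dim(S)) * max(sv$d, 0) * .Machine$double.eps * 100
  keep <- which(d > tol)
  total <- sum(sv$d^2)

  if (!length(keep)) {
    ng <- nrow(X)
    gc <- matrix(0, ng, 1L, dimnames = list(rownames(X), "axis1"))
    cc <- matrix(0, ncol(X), 1L, dimnames = list(colnames(X), "axis1"))
    return(methods::new("CoaResult", geneCoords = gc, codonCoords = cc,
                        inertia = 0, totalInertia = 0))
  }

  d <- d[keep]
  F <- sweep(sv$u[, keep, drop = FALSE], 1L, sqrt(r), "/")
  F <- sweep(F, 2L, d, "*")
  G <- sweep(sv$v[, keep, drop = FALSE], 1L, sqrt(c), "/")
  G <- sweep(G, 2L, d, "*")

  ax <- paste0("axis", seq_along(d))
  dimnames(F) <- list(rownames(X), ax)
  Gfull <- matrix(NA_real_, ncol(X), length(d),
                  dimnames = list(colnames(X), ax))
  Gfull[keepCols, ] <- G

  methods::new("CoaResult", geneCoords = F, codonCoords = Gfull,
               inertia = d^2, totalInertia = total)
}

#' @describeIn CoaResult-class Gene (row) principal coordinates.
#' @export
setMethod("geneCoords", "CoaResult", function(x) x@geneCoords)

#' @describeIn CoaResult-class Codon (column) principal coordinates; rows for
#'   codons absent from every gene are `NA`.
#' @export
setMethod("codonCoords", "CoaResult", function(x) x@codonCoords)

#' @describeIn CoaResult-class Fraction of total inertia per retained axis
#'   (sums to 1 when the table has any variation).
#' @export
setMethod("inertiaFractions", "CoaResult", function(x) {
  if (x@totalInertia <= 0) return(rep(0, length(x@inertia)))
  x@inertia / x@totalInertia
})

setMethod("show", "CoaResult", function(object) {
  fr <- inertiaFractions(object)
  cat("CoaResult:", nrow(object@geneCoords), "genes x",
      nrow(object@codonCoords), "codons,", length(fr), "axes\n")
  k <- min(2L, length(fr))
  cat("  inertia:", paste0(sprintf("axis%d=%.2f%%", seq_len(k),
                                   100 * fr[seq_len(k)]), collapse = ", "), "\n")
})
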