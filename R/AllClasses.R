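#' @import methods
NULL

#' A set of validated coding sequences with their QC report
#'
#' `CdsSet` holds the coding sequences that passed CDS validation (as a
#' [Biostrings::DNAStringSet]) together with the per-record quality-control
#' report covering every input record, passed or rejected.
#'
#' A valid CDS is an uppercase A/C/G/T string whose length is a multiple of 3,
#' that starts with an initiation codon (ATG by default), ends with one of the
#' three stop codons, and contains no internal stop codon.
#'
#' @slot seqs A `DNAStringSet` of the sequences that passed validation.
#' @slot qc A `data.frame` with columns `id`, `status` (`"pass"`/`"fail"`) and
#'   `reason` (`NA` for passes; one of the rejection codes otherwise).
#'
#' @seealso [validateCds()], [qcReport()], [cdsSequences()]
#' @export
setClass("CdsSet", representation(seqs = "DNAStringSet", qc = "data.frame"))

setValidity("CdsSet", function(object) {
  msg <- character()
  qc <- object@qc
  need <- c("id", "status", "reason")
  if (!all(need %in% names(qc)))
    msg <- c(msg, "qc must have columns id, status, reason")
  else {
    if (sum(qc$status == "pass") != length(object@seqs))
      msg <- c(msg, "number of passing qc rows must equal number of sequences")
    if (anyDuplicated(names(object@seqs)))
      msg <- c(msg, "sequence ids must be unique")
    bad <- setdiff(qc$status, c("pass", "fail"))
    if (length(bad)) msg <- c(msg, "qc status must be 'pass' or 'fail'")
  }
  if (length(msg)) msg else TRUE
})

#' Correspondence analysis of a gene-by-codon RSCU matrix
#'
#' Classical correspondence analysis result: principal coordinates for genes
#' (rows) and codons (columns) and the fraction of total inertia carried by
#' each retained axis.
#'
#' @slot geneCoords Numeric matrix, genes x axes, row principal coordinates.
#' @slot codonCoords Numeric matrix, codons x axes, column principal
#'   coordinates.
#' @slot inertia Numeric vector of per-axis principal inertias (squared
#'   singular values), decreasing.
#' @slot totalInertia Total inertia of the table (chi-square / grand total).
#'
#' @seealso [coaFit()], [inertiaFractions()]
#' @export
setClass("CoaResult", representation(
  geneCoords = "matrix", codonCoords = "matrix",
  inertia = "numeric", totalInertia = "numeric"
))

setValidity("CoaResult", function(object) {
  msg <- character()
  if (ncol(object@geneCoords) != ncol(object@codonCoords))
    msg <- c(msg, "gene and codon coordinate matrices must have equal axis counts")
  if (length(object@inertia) != ncol(object@geneCoords))
    msg <- c(msg, "one inertia value per retained axis required")
  if (is.unsorted(rev(object@inertia)))
    msg <- c(msg, "axes must be ordered by decreasing inertia")
  if (object@totalInertia > 1e-12 &&
      abs(sum(object@inertia) / object@totalInertia - 1) > 1e-9)
    msg <- c(msg, "retained inertias must sum to the total inertia")
  if (length(msg)) msg else TRUE
})

#' Codon-pair context matrices
#'
#' The 64 x 64 table of adjacent in-frame codon pairs (rows are the 5' codon,
#' columns the 3' codon) with, once filled by [contextResiduals()], the
#' independence-model expectation and the adjusted Pearson residuals.
#'
#' @slot observed 64 x 64 matrix of observed pair counts, codons in
#'   alphabetical order.
#' @slot expected 64 x 64 matrix of expected counts under independence
#'   (empty until [contextResiduals()] is applied).
#' @slot residuals 64 x 64 matrix of adjusted Pearson residuals (empty until
#'   [contextResiduals()] is applied).
#' @slot nPairs Total number of codon pairs counted.
#'
#' @seealso [pairCounts()], [contextResiduals()], [clusterOrder()]
#' @export
setClass("ContextMatrix", representation(
  observed = "matrix", expected = "matrix",
  residuals = "matrix", nPairs = "integer"
))

setValidity("ContextMatrix", function(object) {
  msg <- character()
  if (!identical(dim(object@observed), c(64L, 64L)))
    msg <- c(msg, "observed must be 64 x 64")
  if (sum(object@observed) != object@nPairs)
    msg <- c(msg, "observed counts must sum to nPairs")
  if (any(object@observed < 0))
    msg <- c(msg, "observed counts must be non-negative")
  if (length(object@expected) &&
      object@nPairs > 0L &&
      max(abs(rowSums(object@expected) - rowSums(object@observed))) > 1e-6)
    msg <- c(msg, "expected row sums must match observed row sums")
  if (length(msg)) msg else TRUE
})
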