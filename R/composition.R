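#' Per-gene nucleotide composition by codon position
#'
#' Computes, for every validated CDS, the overall base percentages (A, T, G,
#' C), the base percentages at the third codon position (A3, T3, G3, C3), the
#' GC content overall and at each codon position (GC, GC1, GC2, GC3), the AT
#' content, and GC12 (the arithmetic mean of GC1 and GC2, the y-coordinate of
#' the neutrality plot).
#'
#' The terminal stop codon is part of the CDS and is included by default;
#' `exclude_stop = TRUE` drops it for sensitivity checks.
#'
#' @param x A [CdsSet-class].
#' @param exclude_stop Drop the terminal stop codon before counting.
#' @return A `data.frame` with one row per gene and columns `id`, `A`, `T`,
#'   `G`, `C`, `A3`, `T3`, `G3`, `C3`, `GC`, `AT`, `GC1`, `GC2`, `GC3`,
#'   `GC12`, `n_codons`.  All percentages are on the 0-100 scale.
#' @examples
#' cds <- validateCds(c(g1 = "ATGGGGTAA"))
#' compositionProfile(cds)
#' @export
compositionProfile <- function(x, exclude_stop = FALSE) {
  stopifnot(methods::is(x, "CdsSet"))
  seqs <- as.character(cdsSequences(x))
  rows <- lapply(seq_along(seqs), function(i) {
    codons <- .codonsOf(seqs[[i]])
    if (exclude_stop) codons <- codons[-length(codons)]
    .compositionRow(names(seqs)[i], codons)
  })
  do.call(rbind, rows)
}

.compositionRow <- function(id, codons) {
  bases <- c("A", "T", "G", "C")
  pos <- lapply(1:3, function(p) {
    b <- substr(codons, p, p)
    vapply(bases, function(x) sum(b == x), 0L)
  })
  tot <- pos[[1]] + pos[[2]] + pos[[3]]
  n <- length(codons) * 3L
  pct <- function(cnt, denom) 100 * cnt / denom
  gcPos <- vapply(pos, function(p) pct(p[["G"]] + p[["C"]], sum(p)), 0)
  out <- data.frame(
    id = id,
    A = pct(tot[["A"]], n), T = pct(tot[["T"]], n),
    G = pct(tot[["G"]], n), C = pct(tot[["C"]], n),
    A3 = pct(pos[[3]][["A"]], length(codons)),
    T3 = pct(pos[[3]][["T"]], length(codons)),
    G3 = pct(pos[[3]][["G"]], length(codons)),
    C3 = pct(pos[[3]][["C"]], length(codons)),
    GC = pct(tot[["G"]] + tot[["C"]], n),
    AT = pct(tot[["A"]] + tot[["T"]], n),
    GC1 = gcPos[1], GC2 = gcPos[2], GC3 = gcPos[3],
    GC12 = (gcPos[1] + gcPos[2]) / 2,
    n_codons = length(codons),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Dataset-mean nucleotide composition
#'
#' Unweighted arithmetic mean of every composition field across genes; each
#' gene contributes equally regardless of its length, matching per-gene
#' averaging of composition statistics.
#'
#' @param profiles A `data.frame` from [compositionProfile()].
#' @return A one-row `data.frame` with `id = "MEAN"`.
#' @export
datasetComposition <- function(profiles) {
  if (!nrow(profiles)) stop("empty composition table")
  num <- profiles[setdiff(names(profiles), "id")]
  out <- as.data.frame(as.list(colMeans(num)))
  cbind(data.frame(id = "MEAN", stringsAsFactors = FALSE), out)
}
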