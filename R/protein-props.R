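#' Translate validated coding sequences
#'
#' Standard-genetic-code translation with the terminal stop dropped, so the
#' protein length is always one less than the codon count.
#'
#' @param x A [CdsSet-class].
#' @return Named character vector of amino-acid strings.
#' @examples
#' translateCds(validateCds(c(g1 = "ATGAAATAA")))
#' @export
translateCds <- function(x) {
  stopifnot(methods::is(x, "CdsSet"))
  seqs <- cdsSequences(x)
  noStop <- Biostrings::subseq(seqs, 1L, Biostrings::width(seqs) - 3L)
  aa <- Biostrings::translate(noStop)
  setNames(as.character(aa), names(seqs))
}

#' Grand average of hydropathicity (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over a protein's residues: positive values
#' indicate hydrophobic proteins, negative hydrophilic.  The per-residue
#' scale spans -4.5 (Arg) to +4.5 (Ile).
#'
#' @param protein Amino-acid string over the 20 standard letters.
#' @return The mean hydropathy, a single numeric.
#' @examples
#' gravy("IR")  # mean of +4.5 and -4.5
#' @export
gravy <- function(protein) {
  aa <- strsplit(toupper(protein), "")[[1L]]
  if (!length(aa)) stop("empty protein")
  h <- .KD_HYDROPATHY[aa]
  if (anyNA(h)) stop("unknown amino-acid letter(s): ",
                     paste(unique(aa[is.na(h)]), collapse = ", "))
  mean(h)
}

#' Aromaticity
#'
#' Fraction of residues that are phenylalanine, tryptophan or tyrosine.
#'
#' @param protein Amino-acid string.
#' @return A value in \[0, 1\].
#' @export
aromaticity <- function(protein) {
  aa <- strsplit(toupper(protein), "")[[1L]]
  if (!length(aa)) stop("empty protein")
  mean(aa %in% .AROMATIC_AA)
}

## Henderson-Hasselbalch net charge at a given pH (EMBOSS pKa set)
.netCharge <- function(counts, pH) {
  pos <- c("Nterm", "K", "R", "H")
  neg <- c("Cterm", "D", "E", "C", "Y")
  sum(counts[pos] / (1 + 10^(pH - .PKA[pos]))) -
    sum(counts[neg] / (1 + 10^(.PKA[neg] - pH)))
}

#' Isoelectric point
#'
#' The pH at which the protein's net charge is zero, found by bisection on
#' \[0, 14\] to a tolerance of 0.001 under the Henderson-Hasselbalch
#' net-charge model over the termini and the ionisable side chains (D, E, C,
#' Y, H, K, R) with the EMBOSS pKa set (N-terminus 8.6, C-terminus 3.6,
#' K 10.8, R 12.5, H 6.5, D 3.9, E 4.1, C 8.5, Y 10.1).
#'
#' @param protein Amino-acid string.
#' @return The pI, a single numeric in (0, 14).
#' @export
isoelectricPoint <- function(protein) {
  aa <- strsplit(toupper(protein), "")[[1L]]
  if (!length(aa)) stop("empty protein")
  counts <- c(Nterm = 1, Cterm = 1,
              vapply(c("K", "R", "H", "D", "E", "C", "Y"),
                     function(a) sum(aa == a), 0))
  lo <- 0; hi <- 14
  while (hi - lo > 0.001) {
    mid <- (lo + hi) / 2
    if (.netCharge(counts, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Protein physicochemical property table
#'
#' Translates each CDS and computes protein length, GRAVY, aromaticity and
#' isoelectric point — the properties whose regressions on ENC probe the
#' influence of protein-level selection on codon usage.
#'
#' @param x A [CdsSet-class].
#' @return A `data.frame` with columns `id`, `length_aa`, `gravy`, `aromo`,
#'   `pI`.
#' @export
proteinProps <- function(x) {
  prots <- translateCds(x)
  data.frame(
    id = names(prots),
    length_aa = nchar(prots),
    gravy = vapply(prots, gravy, 0, USE.NAMES = FALSE),
    aromo = vapply(prots, aromaticity, 0, USE.NAMES = FALSE),
    pI = vapply(prots, isoelectricPoint, 0, USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
}
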