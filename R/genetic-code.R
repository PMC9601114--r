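## Standard genetic code tables and the fixed codon orderings used throughout.
## All codon vectors are alphabetical so that matrix outputs have a stable,
## documented column order.

#' @importFrom Biostrings GENETIC_CODE
.GC_TABLE <- Biostrings::GENETIC_CODE

#' The 64 codons in alphabetical order
#' @keywords internal
ALL_CODONS <- sort(names(.GC_TABLE))

#' The three stop codons of the standard genetic code
#' @keywords internal
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' The 61 sense codons in alphabetical order
#' @keywords internal
SENSE_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)

#' The 59 degenerate sense codons (sense minus ATG and TGG)
#'
#' Methionine (ATG) and tryptophan (TGG) are encoded by a single codon each and
#' carry no synonymous-choice information, so RSCU and the correspondence
#' analysis operate on the remaining 59 codons.
#' @keywords internal
DEGENERATE_CODONS <- setdiff(SENSE_CODONS, c("ATG", "TGG"))

## amino acid -> synonymous codon family, degenerate amino acids only
.SYN_FAMILIES <- local({
  aa <- .GC_TABLE[SENSE_CODONS]
  fam <- split(SENSE_CODONS, aa)
  fam <- lapply(fam, sort)
  fam[vapply(fam, length, 1L) > 1L]
})

## Wright's degeneracy classes.  Ile is the single 3-fold amino acid; Leu, Ser
## and Arg are 6-fold (two codon boxes pooled per amino acid).
.DEGENERACY_CLASS <- vapply(.SYN_FAMILIES, length, 1L)

.KD_HYDROPATHY <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

## EMBOSS pKa set used by the isoelectric-point solver
.PKA <- c(
  Nterm = 8.6, Cterm = 3.6,
  K = 10.8, R = 12.5, H = 6.5,
  D = 3.9, E = 4.1, C = 8.5, Y = 10.1
)

.AROMATIC_AA <- c("F", "W", "Y")

## does a codon end in G or C?
.gcEnding <- function(codons) substr(codons, 3L, 3L) %in% c("G", "C")
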