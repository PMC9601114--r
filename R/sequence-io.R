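#' Read coding sequences from a FASTA file
#'
#' Reads a (possibly gzipped) multi-FASTA file of nucleotide sequences and
#' returns the raw records for validation with [validateCds()].  Sequences are
#' uppercased and RNA `U` is mapped to `T`; no other normalisation or
#' filtering happens at this stage.  The record id is the first
#' whitespace-delimited token of the header; duplicate ids receive a numeric
#' suffix with a warning.
#'
#' @param path Path to a FASTA file (plain or gzip).
#' @return A named character vector of raw sequences in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">g1 some description", "atgaaatAA"), fa)
#' readCdsFasta(fa)
#' @export
readCdsFasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    warning("FASTA file contains no records: ", path)
    return(setNames(character(0), character(0)))
  }
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[`, "", 1L)
  ids[is.na(ids) | ids == ""] <- "unnamed"
  if (anyDuplicated(ids)) {
    warning("duplicate FASTA ids; numeric suffixes appended")
    ids <- make.unique(ids, sep = "_")
  }
  seqs <- toupper(as.character(set))
  seqs <- chartr("U", "T", seqs)
  setNames(unname(seqs), ids)
}

## rejection reason for one raw sequence, or NA if it passes.
## Checks run in a fixed order; the first failure is reported.
.cdsReason <- function(seq, starts) {
  if (grepl("[^ACGT]", seq)) return("AMBIGUOUS_BASE")
  n <- nchar(seq)
  if (n %% 3L != 0L) return("NOT_MULTIPLE_OF_3")
  if (n < 6L) return("TOO_SHORT")
  codons <- substring(seq, seq(1L, n - 2L, 3L), seq(3L, n, 3L))
  if (!(codons[1L] %in% starts)) return("BAD_START")
  k <- length(codons)
  if (k > 2L && any(codons[2:(k - 1L)] %in% STOP_CODONS)) return("INTERNAL_STOP")
  if (!(codons[k] %in% STOP_CODONS)) return("BAD_STOP")
  NA_character_
}

#' Validate raw sequences as coding sequences
#'
#' Applies the standard CDS quality filters: only unambiguous A/C/G/T
#' sequences whose length is an exact multiple of three, with a proper
#' initiation codon, a terminal stop codon and no internal stop codon are
#' retained.  Rejections are reported as data, one reason per record (the
#' first failing check in the fixed order `AMBIGUOUS_BASE`,
#' `NOT_MULTIPLE_OF_3`, `TOO_SHORT`, `BAD_START`, `INTERNAL_STOP`,
#' `BAD_STOP`).
#'
#' @param records Named character vector of raw sequences, as returned by
#'   [readCdsFasta()], or a `DNAStringSet`.
#' @param allow_alt_starts If `TRUE`, CTG/GTG/TTG are accepted as initiation
#'   codons in addition to ATG.  Default `FALSE`.
#' @return A [CdsSet-class] containing the passing sequences and the full QC
#'   report.
#' @examples
#' validateCds(c(g1 = "ATGAAATAA", g2 = "ATGAAATA"))
#' @export
validateCds <- function(records, allow_alt_starts = FALSE) {
  if (methods::is(records, "XStringSet")) {
    recs <- setNames(as.character(records), names(records))
  } else {
    recs <- records
  }
  if (is.null(names(recs)) && length(recs))
    names(recs) <- paste0("seq", seq_along(recs))
  starts <- if (allow_alt_starts) c("ATG", "CTG", "GTG", "TTG") else "ATG"
  reason <- vapply(recs, .cdsReason, "", starts = starts, USE.NAMES = FALSE)
  qc <- data.frame(
    id = names(recs) %||% character(0),
    status = ifelse(is.na(reason), "pass", "fail"),
    reason = reason,
    stringsAsFactors = FALSE
  )
  passed <- Biostrings::DNAStringSet(recs[is.na(reason)])
  methods::new("CdsSet", seqs = passed, qc = qc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @describeIn CdsSet-class The passing sequences as a `DNAStringSet`.
#' @export
setMethod("cdsSequences", "CdsSet", function(x) x@seqs)

#' @describeIn CdsSet-class The full QC report (`id`, `status`, `reason`).
#' @export
setMethod("qcReport", "CdsSet", function(x) x@qc)

#' @describeIn CdsSet-class Number of sequences that passed validation.
#' @param x A `CdsSet`.
#' @export
setMethod("length", "CdsSet", function(x) length(x@seqs))

#' @describeIn CdsSet-class Ids of the passing sequences.
#' @export
setMethod("names", "CdsSet", function(x) names(x@seqs))

#' @describeIn CdsSet-class Subset a `CdsSet` by index or id; the QC report
#'   keeps all original records.
#' @param i index, logical or character vector of ids.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "CdsSet", function(x, i, j, ..., drop = TRUE) {
  methods::new("CdsSet", seqs = x@seqs[i],
               qc = x@qc[x@qc$id %in% names(x@seqs[i]) | x@qc$status == "fail", ,
                         drop = FALSE])
})

setMethod("show", "CdsSet", function(object) {
  n_fail <- sum(object@qc$status == "fail")
  cat("CdsSet with", length(object@seqs), "validated CDS (",
      n_fail, "rejected of", nrow(object@qc), "input records )\n")
  if (length(object@seqs)) {
    w <- Biostrings::width(object@seqs)
    cat("  length range:", min(w), "-", max(w), "nt\n")
  }
  if (n_fail) {
    tab <- table(object@qc$reason[object@qc$status == "fail"])
    cat("  rejections:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
})

#' Write validated coding sequences to FASTA
#'
#' @param x A [CdsSet-class] or `DNAStringSet`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(x, path) {
  seqs <- if (methods::is(x, "CdsSet")) cdsSequences(x) else x
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write the QC report as TSV
#'
#' @param x A [CdsSet-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeQcReport <- function(x, path) {
  utils::write.table(qcReport(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

## split one CDS into its in-frame codons
.codonsOf <- function(seq) {
  s <- as.character(seq)
  n <- nchar(s)
  substring(s, seq(1L, n - 2L, 3L), seq(3L, n, 3L))
}
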