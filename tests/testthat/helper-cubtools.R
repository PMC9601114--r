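# Shared fixtures built in code.

# assemble a CdsSet from one or more codon vectors (start/stop added)
makeCds <- function(..., stop_codon = "TAA") {
  bodies <- list(...)
  seqs <- vapply(bodies, function(b)
    paste0("ATG", paste(b, collapse = ""), stop_codon), "")
  names(seqs) <- if (is.null(names(bodies)) || any(names(bodies) == ""))
    paste0("g", seq_along(bodies)) else names(bodies)
  validateCds(seqs)
}

# a random valid CDS body of n sense codons (uniform over the 59 degenerate)
randomBody <- function(n) {
  sample(setdiff(cubtools:::SENSE_CODONS, c("ATG", "TGG")), n, replace = TRUE)
}

# write a named character vector to a temporary FASTA file
tmpFasta <- function(seqs) {
  fa <- tempfile(fileext = ".fa")
  writeLines(paste0(">", names(seqs), "\n", seqs), fa)
  fa
}
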