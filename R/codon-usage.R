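#' Count in-frame codons
#'
#' Tallies every in-frame codon of each gene, terminal stop included.
#'
#' @param x A [CdsSet-class].
#' @return An integer matrix, genes x 64, codons in alphabetical order.  Row
#'   sums equal the codon counts of the genes.
#' @examples
#' cds <- validateCds(c(g1 = "ATGAAATAA"))
#' counts <- codonCounts(cds)
#' counts[, c("ATG", "AAA", "TAA")]
#' @export
codonCounts <- function(x) {
  stopifnot(methods::is(x, "CdsSet"))
  seqs <- as.character(cdsSequences(x))
  m <- t(vapply(seqs, function(s) {
    codons <- factor(.codonsOf(s), levels = ALL_CODONS)
    tabulate(codons, nbins = 64L)
  }, integer(64L)))
  colnames(m) <- ALL_CODONS
  if (length(seqs) == 1L) rownames(m) <- names(seqs)
  m
}

#' Relative synonymous codon usage (RSCU)
#'
#' For each amino acid with more than one codon, RSCU of a codon is its
#' observed count divided by the count expected if all synonymous codons were
#' used equally: \eqn{RSCU_j = x_j / (\frac{1}{n_i}\sum_j x_j)} where
#' \eqn{n_i} is the degeneracy of the amino acid.  A zero count for a codon of
#' an amino acid that is present in the gene is replaced by 0.5 before the
#' ratio is formed; this replacement applies only inside the RSCU
#' computation.  Codons of an amino acid entirely absent from a gene get
#' `NA`.
#'
#' @param counts A codon-count matrix from [codonCounts()] (or a single named
#'   64-codon count vector).
#' @return A numeric matrix, genes x 59 degenerate sense codons (alphabetical
#'   order).  For an amino acid with no zero counts the values over its
#'   synonymous codons sum to the degeneracy.
#' @examples
#' cds <- validateCds(c(g1 = "ATGTTTTTTTTCTAA"))
#' rscu(codonCounts(cds))[, c("TTT", "TTC")]
#' @export
rscu <- function(counts) {
  counts <- .asCountMatrix(counts)
  out <- matrix(NA_real_, nrow(counts), length(DEGENERATE_CODONS),
                dimnames = list(rownames(counts), DEGENERATE_CODONS))
  for (fam in .SYN_FAMILIES) {
    sub <- counts[, fam, drop = FALSE]
    tot <- rowSums(sub)
    adj <- sub
    adj[adj == 0] <- 0.5
    vals <- adj / (rowSums(adj) / length(fam))
    vals[tot == 0, ] <- NA_real_
    out[, fam] <- vals
  }
  out
}

.asCountMatrix <- function(counts) {
  if (is.null(dim(counts))) counts <- matrix(counts, 1L, dimnames = list(NULL, names(counts)))
  if (!all(ALL_CODONS %in% colnames(counts)))
    stop("counts must have all 64 codons as columns")
  counts[, ALL_CODONS, drop = FALSE]
}

#' Classify RSCU values into the four standard usage categories
#'
#' Codons are over-represented at RSCU > 1.6, under-represented below 0.6,
#' more frequently used between 1 and 1.6 (inclusive), and less frequently
#' used between 0.6 (inclusive) and 1.
#'
#' @param values Numeric vector of RSCU values.
#' @return Character vector over `{"over", "more_frequent", "less_frequent",
#'   "under"}`, `NA` preserved.
#' @export
rscuCategories <- function(values) {
  out <- rep(NA_character_, length(values))
  out[!is.na(values) & values > 1.6] <- "over"
  out[!is.na(values) & values >= 1 & values <= 1.6] <- "more_frequent"
  out[!is.na(values) & values >= 0.6 & values < 1] <- "less_frequent"
  out[!is.na(values) & values < 0.6] <- "under"
  names(out) <- names(values)
  out
}

#' Mean RSCU across genes with usage categories
#'
#' Per-codon unweighted mean of the per-gene RSCU values (`NA` from absent
#' amino acids ignored), with categories recomputed on the means.  A
#' pooled-count mode sums codon counts over all genes first and computes one
#' RSCU profile from the pooled counts.
#'
#' @param rscuMatrix Genes x 59 RSCU matrix from [rscu()], or with
#'   `pooled = TRUE` a genes x 64 count matrix from [codonCounts()].
#' @param pooled If `TRUE`, pool counts across genes instead of averaging
#'   per-gene RSCU.
#' @return A `data.frame` with columns `codon`, `aa`, `mean_rscu`,
#'   `category`.
#' @export
meanRscu <- function(rscuMatrix, pooled = FALSE) {
  if (!nrow(rscuMatrix)) stop("no RSCU profiles supplied")
  if (pooled) {
    m <- rscu(matrix(colSums(.asCountMatrix(rscuMatrix)), 1L,
                     dimnames = list(NULL, ALL_CODONS)))
    vals <- m[1L, ]
  } else {
    stopifnot(identical(colnames(rscuMatrix), DEGENERATE_CODONS))
    vals <- colMeans(rscuMatrix, na.rm = TRUE)
    vals[is.nan(vals)] <- NA_real_
  }
  data.frame(
    codon = DEGENERATE_CODONS,
    aa = unname(.GC_TABLE[DEGENERATE_CODONS]),
    mean_rscu = unname(vals),
    category = unname(rscuCategories(vals)),
    stringsAsFactors = FALSE
  )
}

#' Effective number of codons (ENC)
#'
#' Wright's ENC estimated from codon homozygosity.  For each amino acid with
#' total count \eqn{n \ge 2}, \eqn{\hat F = (n \sum p_i^2 - 1)/(n - 1)} with
#' \eqn{p_i} the within-amino-acid codon frequencies; \eqn{\hat F} measures
#' the probability that two random codons of that amino acid are identical.
#' Class means \eqn{\bar F_k} average \eqn{\hat F} over amino acids of
#' degeneracy \eqn{k} (amino acids with \eqn{n < 2} or \eqn{\hat F \le 0} are
#' excluded), and
#' \deqn{ENC = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6,}
#' capped into \eqn{[20, 61]}: 20 is one codon per amino acid (extreme bias),
#' 61 is uniform synonymous usage (no bias).  If isoleucine (the only 3-fold
#' amino acid) is absent, \eqn{\bar F_3} is imputed as
#' \eqn{(\bar F_2 + \bar F_4)/2}; if any other class mean is undefined the
#' ENC is `NA` with a reason.
#'
#' @param counts A codon-count matrix from [codonCounts()] (or a single named
#'   64-codon count vector).
#' @return A `data.frame` with columns `id`, `enc`, `f2`, `f3`, `f4`, `f6`,
#'   `note` (`NA` or the reason ENC is undefined; `"F3 imputed"` when the
#'   fallback was used).
#' @examples
#' cds <- validateCds(c(g1 = paste0("ATG", strrep("AAA", 30), "TAA")))
#' enc(codonCounts(cds))
#' @export
enc <- function(counts) {
  counts <- .asCountMatrix(counts)
  ids <- rownames(counts) %||% paste0("gene", seq_len(nrow(counts)))
  out <- lapply(seq_len(nrow(counts)), function(i) .encOne(ids[i], counts[i, ]))
  do.call(rbind, out)
}

.encOne <- function(id, cnt) {
  fhat <- vapply(.SYN_FAMILIES, function(fam) {
    x <- cnt[fam]
    n <- sum(x)
    if (n < 2) return(NA_real_)
    p <- x / n
    (n * sum(p^2) - 1) / (n - 1)
  }, 0)
  classMean <- function(k) {
    f <- fhat[.DEGENERACY_CLASS == k]
    f <- f[!is.na(f) & f > 0]
    if (!length(f)) NA_real_ else mean(f)
  }
  f2 <- classMean(2L); f3 <- classMean(3L)
  f4 <- classMean(4L); f6 <- classMean(6L)
  note <- NA_character_
  if (is.na(f3) && !is.na(f2) && !is.na(f4)) {
    f3 <- (f2 + f4) / 2
    note <- "F3 imputed"
  }
  if (anyNA(c(f2, f3, f4, f6))) {
    miss <- c("F2", "F3", "F4", "F6")[is.na(c(f2, f3, f4, f6))]
    return(data.frame(id = id, enc = NA_real_, f2 = f2, f3 = f3, f4 = f4,
                      f6 = f6, note = paste("undefined:", paste(miss, collapse = ",")),
                      stringsAsFactors = FALSE))
  }
  val <- 2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6
  val <- min(max(val, 20), 61)
  data.frame(id = id, enc = val, f2 = f2, f3 = f3, f4 = f4, f6 = f6,
             note = note, stringsAsFactors = FALSE)
}
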