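#' Parity-rule-2 coordinates
#'
#' Under pure mutation pressure, complementary bases are used equally at the
#' third codon position (A3 = T3 and G3 = C3), so the AT bias
#' \eqn{A_3/(A_3+T_3)} and the GC bias \eqn{G_3/(G_3+C_3)} both sit at the
#' 0.5 centre of the parity plot; deviations implicate natural selection.
#' Coordinates are computed from third-position base counts; the terminal
#' stop codon is excluded by default (its third base is not a synonymous
#' choice), switchable with `include_stop`.
#'
#' @param x A [CdsSet-class].
#' @param include_stop Include the terminal stop codon's third base.
#' @return A `data.frame` with columns `id`, `gc_bias` (x-axis), `at_bias`
#'   (y-axis).  A coordinate whose denominator is zero is `NA` with a
#'   warning.
#' @export
parityPoints <- function(x, include_stop = FALSE) {
  stopifnot(methods::is(x, "CdsSet"))
  seqs <- as.character(cdsSequences(x))
  rows <- lapply(seq_along(seqs), function(i) {
    codons <- .codonsOf(seqs[[i]])
    if (!include_stop) codons <- codons[-length(codons)]
    b3 <- substr(codons, 3L, 3L)
    a3 <- sum(b3 == "A"); t3 <- sum(b3 == "T")
    g3 <- sum(b3 == "G"); c3 <- sum(b3 == "C")
    data.frame(
      id = names(seqs)[i],
      gc_bias = if (g3 + c3 > 0) g3 / (g3 + c3) else NA_real_,
      at_bias = if (a3 + t3 > 0) a3 / (a3 + t3) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (anyNA(out$gc_bias) || anyNA(out$at_bias))
    warning("zero third-position denominator for some genes; coordinate set to NA")
  out
}

#' Pearson product-moment correlation with two-sided p-value
#'
#' NA pairs are dropped pairwise; the p-value comes from the t transform
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} with \eqn{n-2} degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Named list with `r`, `p`, `n`.  `r` and `p` are `NA` when fewer
#'   than 3 complete pairs remain or either variable has zero variance.
#' @export
pearsonCorr <- function(x, y) {
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n))
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Ordinary least-squares fit with correlation report
#'
#' @param x,y Numeric vectors (x the predictor).
#' @return List with `slope`, `intercept`, `r`, `p`, `n`, `residuals`,
#'   `fitted`.
#' @keywords internal
.olsFit <- function(x, y) {
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs for a regression")
  if (stats::sd(x) == 0) stop("predictor is constant; slope undefined")
  fit <- stats::lm(y ~ x)
  pc <- pearsonCorr(x, y)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r = pc$r, p = pc$p, n = length(x),
       residuals = unname(stats::residuals(fit)),
       fitted = unname(stats::fitted(fit)))
}

#' Neutrality-plot regression of GC12 on GC3
#'
#' Regresses the mean GC content at the first and second codon positions
#' (GC12) on GC3.  A slope near 1 indicates mutation pressure acting equally
#' on all codon positions; a slope near 0 indicates natural selection
#' constraining the first two positions.  Residuals support the usual
#' residual-vs-GC3 linearity check.
#'
#' @param profiles Composition table from [compositionProfile()] (needs
#'   columns `GC12`, `GC3`; at least 3 genes with non-constant GC3).
#' @return List with `slope`, `intercept`, `r`, `p`, `n`, `residuals`,
#'   `fitted`, plus `gc3` and `gc12` (the points actually fitted).
#' @export
neutralityFit <- function(profiles) {
  stopifnot(all(c("GC12", "GC3") %in% names(profiles)))
  fit <- .olsFit(profiles$GC3, profiles$GC12)
  fit$gc3 <- profiles$GC3
  fit$gc12 <- profiles$GC12
  fit
}

#' ENC versus nucleotide-composition regression suite
#'
#' Fits the twelve standard regressions of ENC on compositional properties:
#' the overall base contents A, T, G, C, the third-position contents A3, T3,
#' G3, C3, and the GC contents GC, GC1, GC2, GC3, each with the OLS slope and
#' the Pearson correlation.
#'
#' @param profiles Composition table from [compositionProfile()].
#' @param encScores ENC table from [enc()].
#' @return A `data.frame` in long format with columns `x`, `y`, `slope`,
#'   `intercept`, `r`, `p`, `n` — one row per compositional property (y =
#'   `"ENC"` throughout; the regression is ENC on the property).
#' @export
encCompositionSuite <- function(profiles, encScores) {
  merged <- merge(profiles, encScores[, c("id", "enc")], by = "id")
  merged <- merged[!is.na(merged$enc), , drop = FALSE]
  if (nrow(merged) < 3L) stop("fewer than 3 genes shared between tables")
  vars <- c("A", "T", "G", "C", "A3", "T3", "G3", "C3",
            "GC", "GC1", "GC2", "GC3")
  rows <- lapply(vars, function(v) {
    f <- .olsFit(merged[[v]], merged$enc)
    data.frame(x = v, y = "ENC", slope = f$slope, intercept = f$intercept,
               r = f$r, p = f$p, n = f$n, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-codon correlation of RSCU with GC3
#'
#' Correlates each degenerate codon's per-gene RSCU with per-gene GC3, and
#' labels each codon by its third base (GC-ending vs AT-ending).  Under
#' GC-biased mutation pressure, GC-ending codons correlate positively with
#' GC3 and AT-ending codons negatively.
#'
#' @param rscuMatrix Genes x 59 RSCU matrix from [rscu()] with gene row
#'   names matching `profiles$id`.
#' @param profiles Composition table from [compositionProfile()].
#' @return A `data.frame` with columns `codon`, `ending` (`"GC"`/`"AT"`),
#'   `r`, `p`, `n`; codons with RSCU defined in fewer than 3 genes are
#'   dropped with a warning.
#' @export
codonVsGc3 <- function(rscuMatrix, profiles) {
  ids <- rownames(rscuMatrix)
  if (is.null(ids)) stop("rscuMatrix must carry gene ids as row names")
  m <- match(ids, profiles$id)
  if (anyNA(m)) stop("RSCU genes missing from composition table")
  gc3 <- profiles$GC3[m]
  rows <- lapply(DEGENERATE_CODONS, function(cod) {
    pc <- pearsonCorr(rscuMatrix[, cod], gc3)
    data.frame(codon = cod,
               ending = if (.gcEnding(cod)) "GC" else "AT",
               r = pc$r, p = pc$p, n = pc$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  dropped <- out$n < 3L
  if (any(dropped)) {
    warning("dropped ", sum(dropped), " codons defined in fewer than 3 genes")
    out <- out[!dropped, , drop = FALSE]
  }
  out
}

#' Overall-base versus third-position-base correlation grid
#'
#' The 4 x 4 grid of Pearson correlations between overall base contents
#' (A, T, G, C) and third-position contents (A3, T3, G3, C3).  Positive
#' correlation between homogeneous pairs (A-A3, G-G3, ...) and negative
#' between heterogeneous ones is the classic signature of directional
#' mutation pressure combined with selection.
#'
#' @param profiles Composition table from [compositionProfile()].
#' @return A `data.frame` with 16 rows and columns `x`, `y`, `r`, `p`, `n`.
#' @export
baseVsBase3 <- function(profiles) {
  if (nrow(profiles) < 3L) stop("need at least 3 genes")
  rows <- list()
  for (b in c("A", "T", "G", "C")) {
    for (b3 in c("A3", "T3", "G3", "C3")) {
      pc <- pearsonCorr(profiles[[b]], profiles[[b3]])
      rows[[length(rows) + 1L]] <- data.frame(
        x = b, y = b3, r = pc$r, p = pc$p, n = pc$n, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Read a minimum-free-energy table
#'
#' Reads a two-column TSV of gene id and mRNA folding minimum free energy in
#' kcal/mol (non-positive, as produced by an external RNA-folding tool); a
#' header line is detected and skipped.  Rows with a positive mFE are
#' rejected with a warning.  All downstream statistics use the absolute
#' value.
#'
#' @param path Path to the TSV.
#' @return A `data.frame` with columns `id`, `mfe`, `abs_mfe`.
#' @export
loadMfeTable <- function(path) {
  if (!file.exists(path)) stop("mFE table not found: ", path)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("id", "mfe"),
                           colClasses = c("character", "character"))
  if (nrow(raw) && is.na(suppressWarnings(as.numeric(raw$mfe[1L]))))
    raw <- raw[-1L, , drop = FALSE]
  raw$mfe <- as.numeric(raw$mfe)
  bad <- is.na(raw$mfe) | raw$mfe > 0
  if (any(bad)) {
    warning("rejected ", sum(bad), " mFE rows (missing or positive values)")
    raw <- raw[!bad, , drop = FALSE]
  }
  data.frame(id = raw$id, mfe = raw$mfe, abs_mfe = -raw$mfe,
             stringsAsFactors = FALSE)
}

#' Correlate |mFE| with ENC and GC contents
#'
#' Pearson correlations of the absolute minimum free energy against ENC and
#' against GC, GC1, GC2, GC3.  Genes without an mFE value are skipped.
#'
#' @param mfe Table from [loadMfeTable()] (or [generateMfe()]).
#' @param encScores ENC table from [enc()].
#' @param profiles Composition table from [compositionProfile()].
#' @return A `data.frame` with columns `x` (`"abs_mfe"`), `y`, `r`, `p`, `n`.
#' @export
correlateMfe <- function(mfe, encScores, profiles) {
  merged <- merge(mfe, encScores[, c("id", "enc")], by = "id")
  merged <- merge(merged, profiles[, c("id", "GC", "GC1", "GC2", "GC3")],
                  by = "id")
  if (nrow(merged) < 3L) stop("fewer than 3 genes shared with the mFE table")
  rows <- lapply(c(ENC = "enc", GC = "GC", GC1 = "GC1", GC2 = "GC2",
                   GC3 = "GC3"), function(v) {
    pc <- pearsonCorr(merged$abs_mfe, merged[[v]])
    data.frame(x = "abs_mfe", y = v, r = pc$r, p = pc$p, n = pc$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$y <- c("ENC", "GC", "GC1", "GC2", "GC3")
  rownames(out) <- NULL
  out
}
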