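#' Specification for the synthetic CDS generator
#'
#' Collects and validates the parameters of [generateGenes()].  The defaults
#' describe a gene set with the dataset-level statistical structure of a
#' typical GC-rich mammalian coding-gene collection: a broad spread of GC3
#' across genes, GC12 coupled to GC3 through a shallow linear relation (the
#' neutrality-plot signature of selection constraining the first two codon
#' positions), and moderate synonymous-codon bias.
#'
#' @param n_genes Number of genes.
#' @param length_codons Integer pair `(min, max)`: total codons per gene
#'   including the start and stop codons, drawn uniformly; minimum 2.
#' @param gc3_target Either a single value in (0, 1) used for every gene or a
#'   pair `(lo, hi)` from which each gene's target third-position GC fraction
#'   is drawn uniformly.
#' @param bias_strength Non-negative codon-bias concentration.  Per gene and
#'   per amino acid the synonymous-codon probabilities are drawn from a
#'   Dirichlet distribution whose mean favours G/C-ending codons in
#'   proportion to the gene's GC3 target and whose spread grows with
#'   `bias_strength`: 0 gives exactly the mean (uniform synonymous usage at
#'   `gc3_target = 0.5`), large values concentrate each gene on one preferred
#'   codon per amino acid.
#' @param gc12_slope,gc12_intercept,gc12_noise_sd Linear coupling of the
#'   per-gene GC12 target (percent) to the GC3 target (percent):
#'   `GC12 = slope * GC3 + intercept + N(0, noise_sd)`.
#' @param mw_prob Relative weight of methionine and tryptophan in the
#'   amino-acid pool next to a weight of 1 for each degenerate amino acid.
#' @param seed Integer seed; every stochastic draw flows from it.
#' @return A validated list of class `"GeneratorSpec"`.
#' @export
generatorSpec <- function(n_genes = 224L,
                          length_codons = c(200L, 1000L),
                          gc3_target = c(0.35, 0.85),
                          bias_strength = 0.65,
                          gc12_slope = 0.213,
                          gc12_intercept = 36,
                          gc12_noise_sd = 4,
                          mw_prob = 0.15,
                          seed = 1L) {
  stopifnot(n_genes >= 1L, length(length_codons) == 2L,
            length_codons[1L] <= length_codons[2L],
            all(gc3_target > 0 & gc3_target < 1),
            length(gc3_target) %in% c(1L, 2L),
            bias_strength >= 0, gc12_noise_sd >= 0, mw_prob >= 0)
  if (length_codons[1L] < 2L)
    stop("minimum gene length is 2 codons (start + stop)")
  spec <- list(n_genes = as.integer(n_genes),
               length_codons = as.integer(length_codons),
               gc3_target = gc3_target, bias_strength = bias_strength,
               gc12_slope = gc12_slope, gc12_intercept = gc12_intercept,
               gc12_noise_sd = gc12_noise_sd, mw_prob = mw_prob,
               seed = as.integer(seed))
  class(spec) <- "GeneratorSpec"
  spec
}

## GC fraction of the first two bases of each codon
.gc12OfCodon <- function(codons) {
  (as.integer(substr(codons, 1L, 1L) %in% c("G", "C")) +
     as.integer(substr(codons, 2L, 2L) %in% c("G", "C"))) / 2
}

## synonymous-codon mean probabilities favouring G/C endings at rate t
.codonMeans <- function(t) {
  lapply(.SYN_FAMILIES, function(fam) {
    w <- ifelse(.gcEnding(fam), t, 1 - t)
    w / sum(w)
  })
}

## one Dirichlet draw with mean m and spread parameter b (b = 0: return m)
.dirichletDraw <- function(m, b) {
  if (b == 0) return(m)
  g <- stats::rgamma(length(m), shape = m * length(m) / b)
  if (sum(g) <= 0) {
    p <- numeric(length(m))
    p[sample.int(length(m), 1L, prob = m)] <- 1
    return(p)
  }
  g / sum(g)
}

## exponential tilt of amino-acid weights so that the expected GC12 of the
## sampled amino acids hits `target` (a fraction); base weights `base`,
## per-amino-acid GC12 fractions `g`.
.tiltWeights <- function(base, g, target) {
  f <- function(lam) {
    w <- base * exp(lam * (g - mean(g)))
    sum(w * g) / sum(w) - target
  }
  lo <- -40; hi <- 40
  flo <- f(lo); fhi <- f(hi)
  if (flo >= 0) lam <- lo
  else if (fhi <= 0) lam <- hi
  else lam <- stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
  w <- base * exp(lam * (g - mean(g)))
  w / sum(w)
}

#' Generate synthetic coding sequences
#'
#' Builds `n_genes` CDS, each `ATG` + sampled sense codons + one stop codon.
#' Per gene, a GC3 target is drawn, synonymous-codon probabilities are drawn
#' per amino acid from a Dirichlet whose mean allocates probability
#' `gc3_target` to G/C-ending codons and whose spread is `bias_strength`,
#' and amino acids are sampled with exponentially tilted weights so that the
#' gene's expected GC12 follows `gc12_slope * GC3 + gc12_intercept` plus
#' noise.  Every output passes [validateCds()]; generation is fully
#' reproducible from `spec$seed`.
#'
#' @param spec A [generatorSpec()].
#' @return A [CdsSet-class] of `n_genes` validated CDS named
#'   `synth001, ...`.
#' @examples
#' cds <- generateGenes(generatorSpec(n_genes = 5, length_codons = c(50, 80)))
#' cds
#' @export
generateGenes <- function(spec) {
  stopifnot(inherits(spec, "GeneratorSpec"))
  set.seed(spec$seed)
  aaNames <- c(names(.SYN_FAMILIES), "M", "W")
  base <- c(rep(1, length(.SYN_FAMILIES)), spec$mw_prob, spec$mw_prob)
  seqs <- character(spec$n_genes)
  for (gi in seq_len(spec$n_genes)) {
    L <- if (spec$length_codons[1L] == spec$length_codons[2L])
      spec$length_codons[1L]
    else sample(spec$length_codons[1L]:spec$length_codons[2L], 1L)
    body <- L - 2L
    t3 <- if (length(spec$gc3_target) == 1L) spec$gc3_target
    else stats::runif(1L, spec$gc3_target[1L], spec$gc3_target[2L])

    m <- .codonMeans(t3)
    p <- lapply(m, .dirichletDraw, b = spec$bias_strength)
    gAA <- c(vapply(seq_along(p), function(i)
      sum(p[[i]] * .gc12OfCodon(.SYN_FAMILIES[[i]])), 0),
      0, 0.5)  # M = ATG, W = TGG

    t12 <- (spec$gc12_slope * (t3 * 100) + spec$gc12_intercept +
              stats::rnorm(1L, 0, spec$gc12_noise_sd)) / 100
    t12 <- min(max(t12, min(gAA) + 0.01), max(gAA) - 0.01)
    w <- .tiltWeights(base, gAA, t12)

    codons <- character(body)
    if (body > 0L) {
      aaSeq <- sample(aaNames, body, replace = TRUE, prob = w)
      for (a in unique(aaSeq)) {
        at <- which(aaSeq == a)
        codons[at] <- if (a == "M") "ATG"
        else if (a == "W") "TGG"
        else sample(.SYN_FAMILIES[[a]], length(at), replace = TRUE,
                    prob = p[[a]])
      }
    }
    stop_codon <- sample(STOP_CODONS, 1L)
    seqs[gi] <- paste0("ATG", paste(codons, collapse = ""), stop_codon)
  }
  names(seqs) <- sprintf("synth%03d", seq_len(spec$n_genes))
  cds <- validateCds(seqs)
  stopifnot(length(cds) == spec$n_genes)
  cds
}

#' Generate synthetic mRNA minimum free energies
#'
#' Emulates the association of folding free energy with transcript length
#' and GC content: `abs_mfe = length_coef * length_nt * (1 + gc_coef *
#' GC/100) + N(0, noise_sd)`, clamped at 0, with `mfe = -abs_mfe`.  The
#' default length coefficient approximates the ~0.35 kcal/mol per nucleotide
#' folding energy typical of long GC-rich mRNAs.
#'
#' @param genes A [CdsSet-class].
#' @param coupling Named numeric vector with `length_coef`, `gc_coef`,
#'   `noise_sd` (all non-negative).
#' @param seed Integer seed.
#' @return A `data.frame` with columns `id`, `mfe` (kcal/mol, non-positive)
#'   and `abs_mfe`.
#' @export
generateMfe <- function(genes,
                        coupling = c(length_coef = 0.35, gc_coef = 0.6,
                                     noise_sd = 30),
                        seed = 1L) {
  stopifnot(methods::is(genes, "CdsSet"), all(coupling >= 0))
  set.seed(seed)
  comp <- compositionProfile(genes)
  len <- comp$n_codons * 3
  absMfe <- coupling[["length_coef"]] * len *
    (1 + coupling[["gc_coef"]] * comp$GC / 100) +
    stats::rnorm(nrow(comp), 0, coupling[["noise_sd"]])
  absMfe <- pmax(absMfe, 0)
  data.frame(id = comp$id, mfe = -absMfe, abs_mfe = absMfe,
             stringsAsFactors = FALSE)
}
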