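---
title: "Methods: codon usage bias analysis with cubtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon usage bias analysis with cubtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cubtools)
```

# The scientific problem

Synonymous codons are not used uniformly: within a gene some codons of an
amino acid are preferred over their synonyms.  This codon usage bias (CUB)
carries information about the two evolutionary forces that shape silent
sites — directional mutation pressure (which moves all codon positions
together, most visibly the nearly neutral third position) and natural
selection (which constrains first and second positions through the protein,
and can prefer particular synonymous codons for translational reasons).
`cubtools` implements the standard descriptive and inferential toolkit used
to dissect CUB in a set of coding sequences (CDS), for example the
protein-coding genes of a pathway such as human autophagy: composition
profiles, RSCU, Wright's effective number of codons, parity-rule-2 and
neutrality diagnostics, correspondence analysis, codon-pair context, protein
physicochemical properties and mRNA folding-energy correlations.

# Input validation

Every analysis assumes clean CDS.  `validateCds()` enforces: unambiguous
A/C/G/T after U→T mapping, length an exact multiple of 3 (and at least 6
nt), an ATG initiation codon (CTG/GTG/TTG optionally accepted), a terminal
stop in {TAA, TAG, TGA}, and no internal stop.  Rejections are data, not
errors: each record receives exactly one reason code, the first failing
check in a fixed order (`AMBIGUOUS_BASE`, `NOT_MULTIPLE_OF_3`, `TOO_SHORT`,
`BAD_START`, `INTERNAL_STOP`, `BAD_STOP`), so QC reports are deterministic
and auditable.  Ambiguous bases are rejected rather than masked because all
downstream formulas assume unambiguous counts.

# The statistics

## RSCU

For amino acid $i$ with degeneracy $n_i$ and codon counts $x_{ij}$,

$$\mathrm{RSCU}_{ij} = \frac{x_{ij}}{\frac{1}{n_i}\sum_j x_{ij}},$$

the observed count relative to the expectation under uniform synonymous
usage; 1 means no bias.  A zero $x_{ij}$ for an amino acid that is present
is replaced by 0.5 before forming the ratio, a conventional continuity
adjustment that keeps log-scale summaries finite; the replacement is local
to RSCU and never leaks into ENC or composition.  Codons of an absent amino
acid are `NA` and are ignored (not zero-filled) when averaging across
genes.  The codon space has exactly 59 dimensions: 64 codons minus 3 stops
minus ATG (Met) and TGG (Trp), which offer no synonymous choice.  Mean RSCU
is the unweighted average of per-gene profiles, so long genes do not
dominate; a pooled-count mode (`meanRscu(..., pooled = TRUE)`) is available
when a single dataset-level profile is wanted.  Categories follow the usual
thresholds: over-represented above 1.6, under-represented below 0.6, more
frequently used in [1, 1.6], less frequently used in [0.6, 1).

## Wright's ENC

For each amino acid with total count $n \ge 2$, the codon homozygosity is
estimated as $\hat F = (n\sum_i p_i^2 - 1)/(n-1)$.  Class means $\bar F_k$
average $\hat F$ over the amino acids of degeneracy $k$ (2-fold: F, Y, H,
Q, N, K, D, E, C; 3-fold: I; 4-fold: V, P, T, A, G; 6-fold: L, S, R), and

$$\mathrm{ENC} = 2 + \frac{9}{\bar F_2} + \frac{1}{\bar F_3} +
\frac{5}{\bar F_4} + \frac{3}{\bar F_6}.$$

Numerical choices: amino acids with $n < 2$ or $\hat F \le 0$ are excluded
from their class mean ($\hat F$ is undefined at $n \le 1$ and can be
non-positive by sampling at small $n$); a missing $\bar F_3$ (no
isoleucine) is imputed as $(\bar F_2 + \bar F_4)/2$, the standard fallback
for the single 3-fold class; any other missing class makes the ENC `NA`
with a recorded reason.  The value is capped into $[20, 61]$ — the analytic
endpoints of the scale (one codon per amino acid gives exactly 20; exactly
equal synonymous usage gives a raw value above 61 because $\hat F$
undershoots $1/k$ at finite $n$, and is reported as the no-bias endpoint
61).  These two endpoints are the package's primary correctness anchors and
are asserted exactly in the test suite.

## Parity rule 2 and the neutrality plot

Parity coordinates are $G_3/(G_3+C_3)$ (x) and $A_3/(A_3+T_3)$ (y) from
third-position base counts; 0.5/0.5 is the no-bias centre expected under
symmetric mutation pressure.  The counts exclude the terminal stop codon by
default (its third base is not a synonymous choice and would distort
single-gene toys); `include_stop = TRUE` restores it, and the composition
module's `A3`-style percentages remain stop-inclusive by default — the two
uses are deliberately independent switches, since the literature is silent
on the stop's treatment and the effect is one codon per gene.

The neutrality plot regresses GC12 (the mean of GC1 and GC2) on GC3 by
ordinary least squares; the slope estimates the relative strength of
mutation pressure (slope near 1) versus selection (near 0).  The fit
returns residuals for the standard residual-linearity plot.  All
correlations are Pearson product-moment with two-sided p-values from the
$t$ transform on $n-2$ degrees of freedom; no multiple-testing correction
is applied (the suites are descriptive, reported pair by pair), and
significance is conventionally annotated at $p < 0.01$.

## Correspondence analysis

`coaFit()` is classical CA: normalise the genes × 59 RSCU matrix to
proportions $P$, form row/column masses $r, c$, decompose the standardised
residuals $S = D_r^{-1/2}(P - rc^\top)D_c^{-1/2}$ by SVD, and report
mass-rescaled principal coordinates and per-axis inertia fractions
(squared singular values over total inertia).  RSCU is treated as the
abundance matrix directly, the common practice in codon-usage work since it
removes amino-acid composition before ordination.  `NA` RSCU entries are
zero-imputed with a warning (CA requires a complete non-negative table);
all-zero columns are dropped from the decomposition and returned as `NA`
coordinates.  Degenerate tables with identical rows have zero inertia and
all points at the origin.  Two axes are what one normally plots; the full
decomposition is retained.  The implementation is cross-checked in the test
suite against an independent eigendecomposition route and against the
chi-square inertia identity.

## Codon-pair context

Adjacent in-frame codon pairs are pooled into a 64 × 64 table (rows 5′,
columns 3′, alphabetical order); the start codon opens the first pair and
the terminal stop closes the last.  Against the independence expectation
$E_{ij} = n_{i\cdot}n_{\cdot j}/N$ the package reports adjusted Pearson
residuals

$$d_{ij} = \frac{O_{ij}-E_{ij}}
{\sqrt{E_{ij}(1-n_{i\cdot}/N)(1-n_{\cdot j}/N)}},$$

chosen because they have unit asymptotic variance under independence and
are therefore comparable across cells; cells with $E_{ij}=0$ are reported
as 0.  The sum of squared unadjusted residuals reproduces the table's
chi-square statistic, which the tests verify against a brute-force
contingency computation.  Because published codon-context heatmaps are
ambiguous about pooling, both the pooled matrix (primary) and the mean of
per-gene residual matrices (`meanContextResiduals()`) are provided.
Heatmap ordering uses average-linkage hierarchical clustering of Euclidean
distances on residual rows and columns.

## Protein properties

Proteins are the standard-code translations with the stop dropped.  GRAVY
is the mean Kyte–Doolittle hydropathy; aromaticity is the F/W/Y fraction;
the isoelectric point solves net charge = 0 by bisection on pH ∈ [0, 14]
to 0.001, under the Henderson–Hasselbalch model with the EMBOSS pKa set
(N-terminus 8.6, C-terminus 3.6, K 10.8, R 12.5, H 6.5, D 3.9, E 4.1,
C 8.5, Y 10.1).  Published pI values from learned models cannot be
reproduced from a classical pKa table; what the downstream analysis uses is
the ordering and correlation of pI with ENC, which any fixed classical set
preserves, so value-level agreement with such tools is explicitly not a
goal.

## mRNA minimum free energy

Folding energies are consumed, never computed: `loadMfeTable()` reads a
two-column id/mFE TSV from an external RNA-folding tool, rejects positive
values, and all statistics use the absolute value $|mFE|$ (larger =
more stable fold).  Genes without an mFE entry are skipped.

# The synthetic-data generator

`generateGenes()` exists so that every pipeline stage is testable without
downloads.  Each gene is ATG + sampled sense codons + a stop.  Three
statistical controls matter:

- **GC3**: per gene a target $t$ is drawn (default uniform on
  0.35–0.85, a broad spread like that of GC-rich mammalian gene sets);
  within each amino acid, codon probabilities allocate weight $t$ to
  G/C-ending codons.
- **Bias strength** $b$: per gene and amino acid the synonymous
  probabilities are drawn from a Dirichlet with mean as above and shape
  $\alpha_j = m_j k/b$, so $b = 0$ gives exactly the mean (uniform usage at
  $t = 0.5$) and large $b$ concentrates each gene on one preferred codon.
  Under this scheme the expected codon homozygosity is
  $E[\sum p_j^2] = (k\sum m_j^2 + b)/(k + b)$, which makes expected ENC an
  analytic, monotonically decreasing function of $b$; the default
  $b = 0.65$ puts expected ENC in the mid-40s, the "low bias" regime
  typical of human gene sets.
- **GC12–GC3 coupling**: a per-gene GC12 target is set as
  $\mathrm{slope}\times\mathrm{GC3} + \mathrm{intercept} + N(0, sd)$ and
  achieved by exponentially tilting the amino-acid sampling weights toward
  amino acids whose codons are G/C-rich at positions 1–2 (the tilt
  parameter is solved by root-finding so the expected GC12 hits the
  target).  Defaults (slope 0.213, intercept 36, sd 4) emulate a shallow
  neutrality slope with moderate scatter, the signature of selection
  dominating mutation pressure in mammalian data; the noise sd was chosen
  so that, with the default GC3 spread, the implied GC12–GC3 correlation
  `slope·sd(GC3)/sqrt(slope²·var(GC3)+sd²)` is about 0.6.

`generateMfe()` emulates the empirical association of folding energy with
length and GC: $|mFE| = c_L \cdot \mathrm{length} \cdot
(1 + c_{GC}\cdot GC/100) + N(0, sd)$, clamped at zero; the default
$c_L = 0.35$ kcal/mol per nucleotide approximates typical mRNA folding
energies.

What the generator does **not** emulate: real amino-acid composition,
codon autocorrelation along genes, isochore structure, splice-form
redundancy, or any evolutionary dynamics.  Passing tests on synthetic data
therefore demonstrate that the estimators recover the statistical structure
they target (GC3 spreads, neutrality slopes, bias gradients), not that any
biological conclusion about a particular gene set is reproduced.

# Problem sizes and determinism

The test suite runs the property checks at sizes chosen to make sampling
bounds sharp but cheap: RSCU sum-to-degeneracy over 1000 random short
genes; CA oracle equivalence on 5 × 5 tables; neutrality-slope recovery
(tolerance 0.05) on 200 genes of 300–600 codons at noise sd 1; ENC
monotonicity in bias strength over 50 single-gene replicates per level.
All stochastic fixtures are seeded; the generator guarantees byte-identical
FASTA for identical specs, and `runPipeline()` is fully deterministic given
its input, which the tests verify by byte-comparing rerun bundles.

# Known limitations

- ENC follows Wright's estimator; web tools in circulation differ in
  unpublished details (treatment of rare amino acids, capping), so
  dataset-level ENC values can differ slightly between tools.
- The four-category RSCU classification uses hard thresholds; values on a
  boundary (exactly 1.6 or 0.6) are classified into the inner bands.
- pI is a classical fixed-pKa model (see above).
- CA inertia fractions depend on the 0-imputation of `NA` RSCU when amino
  acids are absent; for short genes with many absent amino acids the
  first-axis fraction can be inflated by the imputation.
- The codon-context analysis is descriptive; no codon-pair score against a
  genomic reference is computed.
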