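#' Run the full codon-usage-bias pipeline
#'
#' Executes every analysis stage on a CDS FASTA file — QC, composition,
#' RSCU/ENC, parity and neutrality diagnostics, the correlation suite,
#' correspondence analysis, codon-pair context, protein properties and
#' (when a table is supplied) mFE correlations — and writes the full TSV
#' report bundle plus `summary.json` with the dataset-level headline
#' quantities.
#'
#' All numeric TSVs use tab separators, `.` decimals and values rounded to 4
#' decimals; `run_config.json` echoes the configuration for reproducibility.
#'
#' @param input_fasta Path to a CDS FASTA file (plain or gzip).
#' @param out_dir Output directory, created if needed.
#' @param mfe_table Optional path to a two-column id/mFE TSV; if `NULL` the
#'   mFE stage is skipped with a notice.
#' @param exclude_stop_composition Drop the terminal stop from composition.
#' @param parity_include_stop Include the stop codon's third base in parity
#'   coordinates.
#' @param pooled_rscu Report pooled-count mean RSCU instead of the per-gene
#'   average.
#' @param pooled_context If `FALSE`, export the mean of per-gene residual
#'   matrices instead of the pooled 64 x 64 residuals.
#' @param allow_alt_starts Accept CTG/GTG/TTG initiation codons.
#' @param seed Seed recorded in the config (no pipeline stage is stochastic;
#'   kept for config completeness).
#' @return Invisibly, a list with the main in-memory results (`cds`,
#'   `composition`, `rscu`, `mean_rscu`, `enc`, `parity`, `neutrality`,
#'   `correlations`, `coa`, `context`, `protein`, `mfe`, `summary`).
#' @export
runPipeline <- function(input_fasta, out_dir, mfe_table = NULL,
                        exclude_stop_composition = FALSE,
                        parity_include_stop = FALSE,
                        pooled_rscu = FALSE,
                        pooled_context = TRUE,
                        allow_alt_starts = FALSE,
                        seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, file) {
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], round, digits = 4L)
    utils::write.table(df, file.path(out_dir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  mat_tsv <- function(m, file) {
    df <- data.frame(id = rownames(m), round(m, 4L), check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, file.path(out_dir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  cds <- validateCds(readCdsFasta(input_fasta),
                     allow_alt_starts = allow_alt_starts)
  if (length(cds) == 0L) stop("no sequences passed CDS validation")
  writeQcReport(cds, file.path(out_dir, "qc_report.tsv"))

  comp <- compositionProfile(cds, exclude_stop = exclude_stop_composition)
  tsv(rbind(comp, datasetComposition(comp)), "composition.tsv")

  counts <- codonCounts(cds)
  rscuMat <- rscu(counts)
  mat_tsv(rscuMat, "rscu.tsv")
  mRscu <- if (pooled_rscu) meanRscu(counts, pooled = TRUE) else meanRscu(rscuMat)
  tsv(mRscu, "rscu_mean.tsv")
  encTab <- enc(counts)
  tsv(encTab, "enc.tsv")

  parity <- parityPoints(cds, include_stop = parity_include_stop)
  tsv(parity, "parity.tsv")

  neut <- neutralityFit(comp)
  tsv(data.frame(id = comp$id, GC3 = neut$gc3, GC12 = neut$gc12,
                 fitted = neut$fitted, residual = neut$residuals),
      "neutrality.tsv")

  corrs <- encCompositionSuite(comp, encTab)
  b3 <- baseVsBase3(comp)
  b3$slope <- NA_real_; b3$intercept <- NA_real_
  cg <- codonVsGc3(rscuMat, comp)
  cg <- data.frame(x = paste0("RSCU_", cg$codon, "_", cg$ending),
                   y = "GC3", slope = NA_real_, intercept = NA_real_,
                   r = cg$r, p = cg$p, n = cg$n, stringsAsFactors = FALSE)
  neutRow <- data.frame(x = "GC3", y = "GC12", slope = neut$slope,
                        intercept = neut$intercept, r = neut$r, p = neut$p,
                        n = neut$n, stringsAsFactors = FALSE)
  tsv(rbind(corrs, neutRow, b3[, names(corrs)], cg[, names(corrs)]),
      "correlations.tsv")

  coa <- coaFit(rscuMat)
  mat_tsv(geneCoords(coa), "coa_genes.tsv")
  mat_tsv(codonCoords(coa), "coa_codons.tsv")
  tsv(data.frame(axis = seq_along(inertiaFractions(coa)),
                 inertia_fraction = inertiaFractions(coa)),
      "coa_inertia.tsv")

  ctx <- contextResiduals(pairCounts(cds))
  mat_tsv(observedPairs(ctx), "context_observed.tsv")
  resid <- if (pooled_context) pairResiduals(ctx) else meanContextResiduals(cds)
  mat_tsv(resid, "context_residuals.tsv")
  ord <- clusterOrder(resid)
  tsv(data.frame(position = seq_len(64L),
                 row_codon = ALL_CODONS[ord$rows],
                 col_codon = ALL_CODONS[ord$cols]),
      "context_order.tsv")

  prot <- proteinProps(cds)
  tsv(prot, "protein_props.tsv")
  protCorr <- do.call(rbind, lapply(
    c("length_aa", "pI", "gravy", "aromo"), function(v) {
      f <- .olsFit(prot[[v]][match(encTab$id, prot$id)], encTab$enc)
      data.frame(x = v, y = "ENC", slope = f$slope, intercept = f$intercept,
                 r = f$r, p = f$p, n = f$n, stringsAsFactors = FALSE)
    }))
  tsv(protCorr, "protein_correlations.tsv")

  mfe <- NULL
  if (!is.null(mfe_table)) {
    mfe <- loadMfeTable(mfe_table)
    tsv(correlateMfe(mfe, encTab, comp), "mfe_correlations.tsv")
  } else {
    message("no mFE table supplied; mFE stage skipped")
  }

  fr <- inertiaFractions(coa)
  summary <- list(
    n_input = nrow(qcReport(cds)),
    n_passed = length(cds),
    mean_enc = mean(encTab$enc, na.rm = TRUE),
    mean_gc = mean(comp$GC),
    mean_gc3 = mean(comp$GC3),
    over_represented = mRscu$codon[!is.na(mRscu$category) &
                                     mRscu$category == "over"],
    under_represented = mRscu$codon[!is.na(mRscu$category) &
                                      mRscu$category == "under"],
    neutrality_slope = neut$slope,
    neutrality_r = neut$r,
    coa_axis1_inertia_pct = 100 * fr[1L],
    coa_axis2_inertia_pct = if (length(fr) >= 2L) 100 * fr[2L] else NA,
    mean_abs_mfe = if (!is.null(mfe)) mean(mfe$abs_mfe) else NULL
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  config <- list(input_fasta = input_fasta, mfe_table = mfe_table,
                 out_dir = out_dir,
                 flags = list(exclude_stop_composition = exclude_stop_composition,
                              parity_include_stop = parity_include_stop,
                              pooled_rscu = pooled_rscu,
                              pooled_context = pooled_context,
                              allow_alt_starts = allow_alt_starts),
                 seed = seed,
                 version = as.character(utils::packageVersion("cubtools")))
  jsonlite::write_json(config, file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE)

  invisible(list(cds = cds, composition = comp, rscu = rscuMat,
                 mean_rscu = mRscu, enc = encTab, parity = parity,
                 neutrality = neut, correlations = corrs, coa = coa,
                 context = ctx, protein = prot, mfe = mfe,
                 summary = summary))
}
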