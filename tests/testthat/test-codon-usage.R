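test_that("codon counts walk the frame and conserve totals", {
  cds <- validateCds(c(g1 = "ATGAAATAA", g2 = "ATGTTTTTTTTCTAA"))
  counts <- codonCounts(cds)
  expect_equal(unname(counts["g1", c("ATG", "AAA", "TAA")]), c(1, 1, 1))
  expect_equal(sum(counts["g1", ]), 3)
  expect_equal(unname(counts["g2", c("TTT", "TTC", "ATG", "TAA")]),
               c(2, 1, 1, 1))
  w <- Biostrings::width(cdsSequences(cds))
  expect_equal(unname(rowSums(counts)), w / 3)
})

test_that("RSCU matches direct substitution into its definition", {
  counts <- codonCounts(validateCds(c(g = "ATGTTTTTTTTCTAA")))
  r <- rscu(counts)
  expect_equal(r[1, "TTT"], 2 / (3 / 2))
  expect_equal(r[1, "TTC"], 1 / (3 / 2))
  # equal use of all synonymous codons -> RSCU 1 everywhere present
  cds <- makeCds(cubtools:::.SYN_FAMILIES[["L"]])
  rl <- rscu(codonCounts(cds))
  expect_equal(unname(rl[1, cubtools:::.SYN_FAMILIES[["L"]]]), rep(1, 6))
})

test_that("the 0.5 replacement applies to zero counts of present amino acids", {
  counts <- codonCounts(makeCds(rep("TTT", 4)))
  r <- rscu(counts)
  expect_equal(r[1, "TTT"], 4 / (4.5 / 2))
  expect_equal(r[1, "TTC"], 0.5 / (4.5 / 2))
  # absent amino acids give NA, not 0.5-imputed values
  expect_true(is.na(r[1, "GGG"]))
})

test_that("RSCU space has exactly 59 codons and sums to degeneracy", {
  set.seed(31)
  for (i in 1:20) {
    r <- rscu(codonCounts(makeCds(randomBody(200))))
    expect_identical(colnames(r), cubtools:::DEGENERATE_CODONS)
    expect_equal(ncol(r), 59)
    for (fam in cubtools:::.SYN_FAMILIES) {
      vals <- r[1, fam]
      if (!anyNA(vals)) expect_equal(sum(vals), length(fam))
    }
  }
})

test_that("RSCU agrees with an independent implementation on a zero-free gene", {
  skip_if_not_installed("seqinr")
  set.seed(32)
  body <- c(rep(cubtools:::DEGENERATE_CODONS, 3), randomBody(300))
  cds <- makeCds(body)
  ours <- rscu(codonCounts(cds))
  s <- tolower(strsplit(as.character(cdsSequences(cds))[[1]], "")[[1]])
  theirs <- seqinr::uco(s, index = "rscu")
  names(theirs) <- toupper(names(theirs))
  expect_equal(unname(ours[1, cubtools:::DEGENERATE_CODONS]),
               unname(theirs[cubtools:::DEGENERATE_CODONS]),
               tolerance = 1e-10)
})

test_that("usage categories follow the 0.6 / 1 / 1.6 boundaries", {
  vals <- c(a = 1.61, b = 1.6, c = 1.0, d = 0.99, e = 0.6, f = 0.59, g = NA)
  expect_identical(unname(rscuCategories(vals)),
                   c("over", "more_frequent", "more_frequent",
                     "less_frequent", "less_frequent", "under", NA))
})

test_that("mean RSCU averages per-gene profiles and recomputes categories", {
  r1 <- rscu(codonCounts(makeCds(c("CTG", "CTG", "CTG", "CTT", "AAA"))))
  r2 <- rscu(codonCounts(makeCds(c("CTG", "CTG", "CTT", "GGG"))))
  m <- meanRscu(rbind(r1, r2))
  row <- m[m$codon == "CTG", ]
  expect_equal(row$mean_rscu, mean(c(r1[1, "CTG"], r2[1, "CTG"])))
  # NA-ignoring mean: GGG defined only in gene 2
  expect_equal(m$mean_rscu[m$codon == "GGG"], unname(r2[1, "GGG"]))
  expect_identical(m$category[m$codon == "CTG"], "over")
  expect_error(meanRscu(r1[0, , drop = FALSE]), "no RSCU")
})

test_that("pooled mean RSCU equals RSCU of summed counts", {
  set.seed(33)
  cds <- makeCds(randomBody(80), randomBody(120))
  counts <- codonCounts(cds)
  pooled <- meanRscu(counts, pooled = TRUE)
  direct <- rscu(matrix(colSums(counts), 1,
                        dimnames = list(NULL, cubtools:::ALL_CODONS)))
  expect_equal(pooled$mean_rscu, unname(direct[1, ]))
})

test_that("ENC hits its analytic endpoints", {
  # one codon per degenerate amino acid, twice each: every F-hat = 1 -> 20
  biased <- makeCds(rep(vapply(cubtools:::.SYN_FAMILIES, `[`, "", 1L), 2))
  expect_equal(enc(codonCounts(biased))$enc, 20)
  # every synonymous codon exactly twice: raw 2+27+5+35+33 = 102 -> cap 61
  equal2 <- makeCds(rep(cubtools:::DEGENERATE_CODONS, 2))
  e <- enc(codonCounts(equal2))
  expect_equal(e$enc, 61)
  expect_equal(e$f2, 1 / 3)
  expect_equal(e$f3, 1 / 5)
  expect_equal(e$f4, 1 / 7)
  expect_equal(e$f6, 1 / 11)
})

test_that("ENC handles missing degeneracy classes as documented", {
  # only Phe codons: F4/F6 undefined -> NA with reason
  e <- enc(codonCounts(makeCds(c("TTT", "TTT", "TTC"))))
  expect_true(is.na(e$enc))
  expect_match(e$note, "undefined")
  # all classes but Ile present: F3 imputed as (F2+F4)/2
  body <- rep(c("TTT", "TAT", "CAT", "CAA", "AAT", "AAA", "GAT", "GAA",
                "TGT", "GTT", "CCT", "ACT", "GCT", "GGT",
                "CTT", "TCT", "CGT"), 2)
  e2 <- enc(codonCounts(makeCds(body)))
  expect_identical(e2$note, "F3 imputed")
  expect_equal(e2$f3, (e2$f2 + e2$f4) / 2)
})

test_that("ENC is invariant to which synonymous codon is preferred", {
  set.seed(34)
  aa <- names(cubtools:::.SYN_FAMILIES)
  pick <- function(which_codon) {
    body <- unlist(lapply(cubtools:::.SYN_FAMILIES, function(fam)
      rep(fam[min(which_codon, length(fam))], 5)))
    enc(codonCounts(makeCds(body)))$enc
  }
  expect_equal(pick(1), pick(2))
})

test_that("long uniform-usage genes approach the 61 cap", {
  set.seed(35)
  spec <- generatorSpec(n_genes = 3, length_codons = c(3000, 3000),
                        gc3_target = 0.5, bias_strength = 0, seed = 35)
  e <- enc(codonCounts(generateGenes(spec)))
  expect_true(all(e$enc > 60.5))
})
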