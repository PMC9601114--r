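test_that("parity coordinates are the third-position bias ratios", {
  # third bases incl. the start ATG: A3 = 3, T3 = 1, G3 = 1, C3 = 1
  p <- parityPoints(makeCds(c("AAA", "AAA", "AAA", "AAT", "GGC")))
  expect_equal(p$at_bias, 0.75)
  expect_equal(p$gc_bias, 0.5)
  # equal A3 and T3 -> exactly the 0.5 centre
  q <- parityPoints(makeCds(c("AAA", "AAT", "GGC")))
  expect_equal(q$at_bias, 0.5)
  expect_equal(q$gc_bias, 0.5)
  # boundary: A3 = 0, T3 > 0
  b <- parityPoints(makeCds(c("TTT", "TTT", "GGC")))
  expect_equal(b$at_bias, 0)
})

test_that("zero third-position denominators yield NA with a warning", {
  # only G/C third bases (ATG start + GGC): A3 + T3 = 0
  expect_warning(p <- parityPoints(makeCds(c("GGC", "GGC"))), "denominator")
  expect_true(is.na(p$at_bias))
  expect_equal(p$gc_bias, 1 / 3)  # G3 = 1 (start ATG), C3 = 2
})

test_that("parity coordinates are invariant when all counts double", {
  set.seed(41)
  body <- randomBody(60)
  p1 <- parityPoints(makeCds(body))
  # an internal ATG codes Met, so body+body+ATG doubles every third-position
  # count relative to start+body
  pd <- parityPoints(makeCds(c(body, body, "ATG")))
  expect_equal(pd$at_bias, p1$at_bias)
  expect_equal(pd$gc_bias, p1$gc_bias)
})

test_that("stop-codon inclusion in parity is switchable", {
  cds <- makeCds(c("GGG", "GGC"), stop_codon = "TAA")
  expect_warning(excl <- parityPoints(cds), "denominator")
  expect_true(is.na(excl$at_bias))        # no A3/T3 without the stop
  incl <- parityPoints(cds, include_stop = TRUE)
  expect_equal(incl$at_bias, 1)           # the stop's A is the only A3/T3 base
  expect_equal(incl$gc_bias, 2 / 3)       # G3 from ATG + GGG, C3 from GGC
})

test_that("pearsonCorr matches a brute-force product-moment computation", {
  brute <- function(x, y) {
    n <- length(x)
    r <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    t <- r * sqrt((n - 2) / (1 - r^2))
    list(r = r, p = 2 * stats::pt(-abs(t), n - 2))
  }
  set.seed(42)
  for (i in 1:25) {
    x <- rnorm(sample(5:40, 1))
    y <- rnorm(length(x)) + 0.5 * x
    got <- pearsonCorr(x, y)
    want <- brute(x, y)
    expect_equal(got$r, want$r, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
})

test_that("pearsonCorr handles exact linearity, NA pairs and zero variance", {
  x <- 1:10
  expect_equal(pearsonCorr(x, 2 * x + 1)$r, 1)
  expect_equal(pearsonCorr(x, -x)$r, -1)
  expect_equal(pearsonCorr(c(1, 2, 3, 4), c(1, 3, 2, 4))$r, 0.8)
  withNA <- pearsonCorr(c(x, NA), c(2 * x, 5))
  expect_equal(withNA$n, 10)
  expect_true(is.na(pearsonCorr(rep(1, 5), rnorm(5))$r))
  expect_true(is.na(pearsonCorr(1:2, 2:1)$r))  # n < 3
})

test_that("neutrality regression satisfies OLS identities and known fits", {
  ident <- neutralityFit(data.frame(GC12 = c(40, 50, 60), GC3 = c(40, 50, 60)))
  expect_equal(ident$slope, 1)
  expect_equal(ident$r, 1)
  flat <- neutralityFit(data.frame(GC12 = c(50, 50, 50), GC3 = c(40, 50, 60)))
  expect_equal(flat$slope, 0)
  expect_error(neutralityFit(data.frame(GC12 = c(40, 50, 60), GC3 = rep(50, 3))),
               "constant")
  set.seed(43)
  d <- data.frame(GC3 = runif(100, 30, 90))
  d$GC12 <- 0.4 * d$GC3 + 20 + rnorm(100, 0, 2)
  fit <- neutralityFit(d)
  expect_equal(fit$slope, fit$r * sd(d$GC12) / sd(d$GC3), tolerance = 1e-9)
  expect_equal(mean(fit$residuals), 0, tolerance = 1e-9)
  # residuals are orthogonal to the predictor
  expect_equal(unname(coef(lm(fit$residuals ~ d$GC3))[2]), 0, tolerance = 1e-9)
})

test_that("neutrality fit recovers the generator's GC12-GC3 slope", {
  spec <- generatorSpec(n_genes = 200, length_codons = c(300, 600),
                        gc12_slope = 0.3, gc12_intercept = 35,
                        gc12_noise_sd = 1, seed = 44)
  comp <- compositionProfile(generateGenes(spec))
  fit <- neutralityFit(comp)
  expect_lt(abs(fit$slope - 0.3), 0.05)
})

test_that("the ENC-composition suite reports exactly the 12 standard pairs", {
  set.seed(45)
  cds <- generateGenes(generatorSpec(n_genes = 60, length_codons = c(150, 300),
                                     seed = 45))
  comp <- compositionProfile(cds)
  e <- enc(codonCounts(cds))
  suite <- encCompositionSuite(comp, e)
  expect_equal(nrow(suite), 12)
  expect_setequal(suite$x, c("A", "T", "G", "C", "A3", "T3", "G3", "C3",
                             "GC", "GC1", "GC2", "GC3"))
  # engine self-check: regressing ENC on itself gives slope 1, r 1
  fake <- comp
  fake$GC3 <- e$enc[match(comp$id, e$id)]
  row <- encCompositionSuite(fake, e)
  expect_equal(row$slope[row$x == "GC3"], 1)
  expect_equal(row$r[row$x == "GC3"], 1)
  expect_error(encCompositionSuite(comp[1:2, ], e[1:2, ]), "fewer than 3")
})

test_that("GC-ending codon usage rises with GC3 under a GC3 gradient", {
  spec <- generatorSpec(n_genes = 120, length_codons = c(300, 500),
                        gc3_target = c(0.3, 0.85), bias_strength = 0,
                        seed = 46)
  cds <- generateGenes(spec)
  comp <- compositionProfile(cds)
  cg <- codonVsGc3(rscu(codonCounts(cds)), comp)
  expect_lte(nrow(cg), 59)
  expect_setequal(unique(cg$ending), c("GC", "AT"))
  expect_gt(cg$r[cg$codon == "GCC"], 0)
  expect_lt(cg$r[cg$codon == "GCA"], 0)
  # with GC3 constant every correlation is undefined
  const <- generateGenes(generatorSpec(n_genes = 10, gc3_target = 0.5,
                                       length_codons = c(200, 200),
                                       bias_strength = 0,
                                       gc12_noise_sd = 0, seed = 47))
  compc <- compositionProfile(const)
  compc$GC3 <- 50
  cgc <- codonVsGc3(rscu(codonCounts(const)), compc)
  expect_true(all(is.na(cgc$r)))
})

test_that("base vs third-position-base grid has 16 pairs with homogeneous r > 0", {
  spec <- generatorSpec(n_genes = 150, length_codons = c(200, 400), seed = 48)
  comp <- compositionProfile(generateGenes(spec))
  grid <- baseVsBase3(comp)
  expect_equal(nrow(grid), 16)
  homo <- grid[paste0(grid$x, "3") == grid$y, ]
  expect_true(all(homo$r > 0))
})

test_that("mFE tables are parsed, sign-checked and correlated on |mFE|", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("id\tmfe", "g1\t-212.2", "g2\t-500", "g3\t5", "g4\t-100"), tf)
  expect_warning(m <- loadMfeTable(tf), "positive")
  expect_equal(nrow(m), 3)
  expect_equal(m$abs_mfe[m$id == "g1"], 212.2)
  expect_equal(m$mfe, -m$abs_mfe)

  spec <- generatorSpec(n_genes = 200, length_codons = c(200, 500), seed = 49)
  cds <- generateGenes(spec)
  comp <- compositionProfile(cds)
  e <- enc(codonCounts(cds))
  mfe <- generateMfe(cds, coupling = c(length_coef = 0.3, gc_coef = 1,
                                       noise_sd = 5), seed = 49)
  rep <- correlateMfe(mfe, e, comp)
  expect_setequal(rep$y, c("ENC", "GC", "GC1", "GC2", "GC3"))
  expect_gt(rep$r[rep$y == "GC"], 0)
  # genes missing from the mFE table are skipped
  rep2 <- correlateMfe(mfe[1:150, ], e, comp)
  expect_true(all(rep2$n == 150))
  expect_error(correlateMfe(mfe[0, ], e, comp), "fewer than 3")
})
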