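test_that("error-free panels equal the template composition", {
  m <- smallModel()
  p <- simulatePanel(m, c("f/f" = 1, "M/f" = 1, "H1/H2" = 1), seed = 3)
  g <- assay(p, "genotype")
  expect_true(all(g[, 1] == 0))
  expect_true(all(g[, 2] == 1))
  # site-wise composition oracle for every accession
  for (j in 1:3) {
    pair <- c(colData(p)$hap1[j], colData(p)$hap2[j])
    tpl <- haplotypeTemplates(m)
    expect_equal(unname(g[, j]), unname(tpl[, pair[1]] + tpl[, pair[2]]))
  }
})

test_that("panels are byte-identical under a fixed seed", {
  m <- smallModel()
  p1 <- simulatePanel(m, c("M/f" = 3, "H1/f" = 2), errorRate = 0.05,
                      missingRate = 0.1, seed = 42)
  p2 <- simulatePanel(m, c("M/f" = 3, "H1/f" = 2), errorRate = 0.05,
                      missingRate = 0.1, seed = 42)
  expect_identical(assay(p1, "genotype"), assay(p2, "genotype"))
  p3 <- simulatePanel(m, c("M/f" = 3, "H1/f" = 2), errorRate = 0.05,
                      missingRate = 0.1, seed = 43)
  expect_false(identical(assay(p1, "genotype"), assay(p3, "genotype")))
})

test_that("empirical flip and missing rates match their parameters", {
  m <- defaultModel()
  errorRate <- 0.02; missingRate <- 0.05
  p <- simulatePanel(m, c("M/f" = 20), errorRate = errorRate,
                     missingRate = missingRate, seed = 9)
  nCalls <- length(assay(p, "truth"))           # > 2e4 site-calls
  flips <- sum(assay(p, "errorMask"))
  sdFlip <- sqrt(nCalls * errorRate * (1 - errorRate))
  expect_lt(abs(flips - nCalls * errorRate), 3 * sdFlip)
  miss <- sum(is.na(assay(p, "genotype")))
  sdMiss <- sqrt(nCalls * missingRate * (1 - missingRate))
  expect_lt(abs(miss - nCalls * missingRate), 3 * sdMiss)
})

test_that("simulatePanel validates its inputs", {
  m <- smallModel()
  expect_error(simulatePanel(m, integer()), "at least one accession")
  expect_error(simulatePanel(m, c("X/Y" = 1)), "unknown class")
  expect_error(simulatePanel(m, c("f/f" = 1), errorRate = 1), "lie in")
})

test_that("allele depths follow the binomial depth model", {
  m <- smallModel(nSites = 200, nDiagnosticB = 10)
  # genotype 0 with zero error: all reads are ref
  p0 <- simulatePanel(m, c("f/f" = 5), seed = 1)
  d0 <- simulateAlleleDepths(p0, m, meanDepth = 10, baseError = 1e-9,
                             seed = 2)
  expect_true(all(assay(d0, "alt") == 0))
  # genotype 1: alt fraction averages 0.5
  p1 <- simulatePanel(m, c("M/f" = 10), seed = 1)
  d1 <- simulateAlleleDepths(p1, m, meanDepth = 10, baseError = 0.01,
                             seed = 2)
  frac <- sum(assay(d1, "alt")) / sum(assay(d1, "alt") + assay(d1, "ref"))
  expect_lt(abs(frac - 0.5), 0.01)
  # genotype 2 with base error 0.01 at depth 100: alt mean ~ 99
  p2 <- simulatePanel(m, c("M/M" = 10), seed = 1)
  d2 <- simulateAlleleDepths(p2, m, meanDepth = 100, baseError = 0.01,
                             seed = 2)
  expect_lt(abs(mean(assay(d2, "alt")) - 99), 1)
  # total depth has the stated mean
  expect_lt(abs(mean(assay(d2, "alt") + assay(d2, "ref")) - 100), 2)
})

test_that("RNA depths are restricted to genes and honour silencing", {
  m <- defaultModel()
  p <- simulatePanel(m, c("H1/f" = 2, "M/f" = 2, "f/f" = 2), seed = 5)
  d <- simulateAlleleDepths(p, m, meanDepth = 30, baseError = 1e-9,
                            seed = 6, source = "RNA")
  tot <- assay(d, "ref") + assay(d, "alt")
  inGene <- overlapsAny(rowRanges(d), sdrGenes(m))
  expect_true(all(tot[!inGene, ] == 0))
  # YABBY3 M-allele silenced in hermaphrodites: H1/f samples show no alt
  # reads there, while M/f (female-sterile) samples do
  yab <- overlapsAny(rowRanges(d),
                     sdrGenes(m)[mcols(sdrGenes(m))$name == "VviYABBY3"])
  expect_true(all(assay(d, "alt")[yab, 1:2] == 0))
  expect_gt(sum(assay(d, "alt")[yab, 3:4]), 0)
  # f/f carries no M allele anywhere: alt identically zero
  expect_true(all(assay(d, "alt")[, 5:6] == 0))
})

test_that("ASE counts follow the effect specification", {
  m <- defaultModel()
  samples <- data.frame(id = c("s1", "s2", "s3"),
                        class = c("H1/f", "f/f", "M/f"))
  a <- simulateAseCounts(m, samples, meanExpr = 50, seed = 4)
  yab <- mcols(rowRanges(a))$gene == "VviYABBY3"
  # hermaphrodite: M copy of YABBY3 silenced -> alt ~ 0, ref > 0
  expect_true(all(assay(a, "alt")[yab, 1] == 0))
  expect_gt(sum(assay(a, "ref")[yab, 1]), 0)
  # f/f: no M allele at any site
  expect_true(all(assay(a, "alt")[, 2] == 0))
  # male at YABBY3 with multiplier 1: balanced expression
  fracM <- sum(assay(a, "alt")[yab, 3]) /
    sum(assay(a, "alt")[yab, 3] + assay(a, "ref")[yab, 3])
  expect_lt(abs(fracM - 0.5), 0.05)
  expect_equal(unname(colData(a)$femaleSterile), c(FALSE, FALSE, TRUE))
})

test_that("bulk depth tracks show the expected fold pattern", {
  m <- defaultModel()
  tr <- simulateBulkDepths(m, unitCoverage = 50, seed = 8)
  expect_named(tr, c("female.f", "female.M", "male.f", "male.M"))
  u <- 50
  sdrMean <- function(nm) mean(tr[[nm]]$raw[!tr[[nm]]$flank]) / u
  flankMean <- function(nm) mean(tr[[nm]]$raw[tr[[nm]]$flank]) / u
  expect_lt(abs(sdrMean("female.f") - 2), 0.1)   # 2 units on f-hap
  expect_lt(sdrMean("female.M"), 0.05)           # ~0 on M-hap
  expect_lt(abs(sdrMean("male.f") - 1), 0.1)     # 1 unit on each hap
  expect_lt(abs(sdrMean("male.M") - 1), 0.1)
  for (nm in names(tr)) expect_lt(abs(flankMean(nm) - 2), 0.1)
  expect_error(simulateBulkDepths(m, windowWidth = 0), "positive")
})
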