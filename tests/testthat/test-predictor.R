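test_that("site log-likelihoods follow the binomial error model", {
  ll <- siteLogLikelihoods(10, 0, 0.01)
  expect_equal(unname(ll["homF"] - ll["het"]), 10 * log(0.99 / 0.5),
               tolerance = 1e-12)
  expect_equal(unname(ll["homF"] - ll["het"]), 6.831, tolerance = 1e-3)
  # balanced reads favour the heterozygous model
  ll55 <- siteLogLikelihoods(5, 5, 0.01)
  expect_equal(names(which.max(ll55)), "het")
  # no reads: uninformative
  expect_equal(unname(siteLogLikelihoods(0, 0, 0.01)), c(0, 0, 0))
  expect_error(siteLogLikelihoods(1, 1, 0.6), "0.5")
})

test_that("region Bayes factor sums site evidence and applies the threshold", {
  res <- regionBayesFactor(rep(10, 10), rep(0, 10), baseError = 0.01)
  expect_equal(res$call, 0L)
  expect_equal(unname(res$logBF["het"]), 100 * log(1.98), tolerance = 1e-9)
  expect_equal(unname(res$logBF["het"]), 68.31, tolerance = 1e-2)
  # balanced reads at depth >= 10 call heterozygous
  res1 <- regionBayesFactor(rep(5, 10), rep(5, 10))
  expect_equal(res1$call, 1L)
  # all sites below the depth filter: no-call
  res0 <- regionBayesFactor(rep(1, 5), rep(1, 5), minDepth = 3)
  expect_true(is.na(res0$call))
  expect_equal(res0$nSites, 0L)
  # weak evidence below the BF threshold: no-call
  resw <- regionBayesFactor(3, 0, baseError = 0.01, minDepth = 1)
  expect_true(is.na(resw$call))
})

test_that("log Bayes factors are additive over sites", {
  set.seed(2)
  ref <- rpois(20, 12); alt <- rpois(20, 12)
  whole <- regionBayesFactor(ref, alt, minDepth = 1)
  perSite <- lapply(seq_along(ref), function(i)
    siteLogLikelihoods(ref[i], alt[i], 0.01))
  summed <- Reduce(`+`, perSite)
  expect_equal(whole$logLik, summed, tolerance = 1e-12)
})

test_that("swapping ref/alt labels maps call 0 to 2 and fixes 1", {
  set.seed(3)
  for (g in 0:2) {
    p <- c(0.01, 0.5, 0.99)[g + 1]
    tot <- rpois(15, 20)
    alt <- rbinom(15, tot, p)
    fwd <- regionBayesFactor(tot - alt, alt)
    swp <- regionBayesFactor(alt, tot - alt)
    expect_equal(swp$call, c(2L, 1L, 0L)[fwd$call + 1L])
    expect_equal(unname(swp$logLik["homF"]), unname(fwd$logLik["homM"]))
  }
})

test_that("calls converge to the true model as depth grows", {
  m <- smallModel()
  accByDepth <- vapply(c(5, 20, 100), function(d) {
    p <- simulatePanel(m, setNames(rep(2L, 10), sdrClasses()), seed = 7)
    dep <- simulateAlleleDepths(p, m, meanDepth = d, baseError = 0.01,
                                seed = 70 + d)
    pred <- predictPanel(dep, m)
    mean(pred$class == colData(p)$class)
  }, numeric(1))
  expect_true(all(diff(accByDepth) >= 0))
  expect_equal(accByDepth[3], 1)
})

test_that("phenotype prediction applies the two-factor rule", {
  h <- predictPhenotype(c(0, 0, 1, 1))
  expect_equal(h$phenotype, "hermaphrodite")
  expect_equal(h$class, "H1/f")
  expect_false(h$femaleSterile); expect_false(h$maleSterile)
  mm <- predictPhenotype(c(1, 1, 1, 1))
  expect_equal(mm$phenotype, "male")
  expect_equal(mm$class, "M/f")
  ff <- predictPhenotype(c(0, 0, 0, 0))
  expect_equal(ff$phenotype, "female")
  expect_equal(ff$class, "f/f")
  # A female-sterile with C male-sterile: no template pair produces it
  bad <- predictPhenotype(c(2, 0, 0, 2))
  expect_equal(bad$phenotype, "inconsistent")
  # A or C no-call: unknown
  expect_equal(predictPhenotype(c(NA, 0, 1, 1))$phenotype, "unknown")
})

test_that("INP1 indel genotyping from allele sequences", {
  m <- defaultModel()
  call <- inp1IndelGenotype(alleleSequences = m@inp1Alleles, model = m)
  expect_setequal(call$alleles, c("deleted", "intact"))
  expect_false(call$maleSterile)
  intact <- m@inp1Alleles[["intact"]]
  both <- inp1IndelGenotype(alleleSequences = c(intact, intact), model = m)
  expect_equal(both$alleles, c("intact", "intact"))
  expect_false(both$maleSterile)
  del <- m@inp1Alleles[["deleted"]]
  ff <- inp1IndelGenotype(alleleSequences = c(del, del), model = m)
  expect_true(ff$maleSterile)
})

test_that("INP1 indel genotyping from spanning-read lengths", {
  m <- defaultModel()
  L <- nchar(m@inp1Alleles[["intact"]])
  hom <- inp1IndelGenotype(readLengths = rep(L - 8L, 30), model = m)
  expect_equal(hom$alleles, c("deleted", "deleted"))
  expect_true(hom$maleSterile)
  het <- inp1IndelGenotype(readLengths = c(rep(L, 14), rep(L - 8L, 16)),
                           model = m)
  expect_setequal(het$alleles, c("deleted", "intact"))
  # modes differing by neither 0 nor 8 are ambiguous
  expect_error(inp1IndelGenotype(readLengths = c(rep(L, 10), rep(L - 4L, 10)),
                                 model = m), "ambiguous")
  expect_error(inp1IndelGenotype(model = m), "provide")
})

test_that("simulated INP1 reads genotype every class correctly", {
  m <- defaultModel()
  p <- simulatePanel(m, c("f/f" = 3, "M/f" = 3, "H1/f" = 3, "H1/H1" = 3),
                     seed = 2)
  reads <- simulateInp1Reads(p, m, depth = 30, baseError = 0.005, seed = 3)
  sterile <- vapply(reads, function(r)
    inp1IndelGenotype(readLengths = r, model = m)$maleSterile, logical(1))
  expect_equal(sterile, unname(colData(p)$phenotype == "female"))
})
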