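test_that("minor allele frequency counts alleles over non-missing calls", {
  expect_equal(siteMAF(c(rep(0, 13), rep(1, 13))), 13 / 52)
  expect_equal(siteMAF(rep(0, 10)), 0)
  # minor allele is the reference one here: 5 ref alleles out of 20
  expect_equal(siteMAF(c(rep(1, 5), rep(2, 5))), 0.25)
  expect_equal(siteMAF(c(0, 1, NA, NA)), 0.25)
  expect_error(siteMAF(c(NA, NA)), "missing")
})

test_that("a fully sex-linked site has maf = nMale / (2 n)", {
  for (nf in c(5, 13, 40)) for (nm in c(5, 13, 40)) {
    g <- c(rep(0, nf), rep(1, nm))
    expect_equal(siteMAF(g), nm / (2 * (nf + nm)))
  }
})

test_that("exact HWE test matches the enumeration oracle exhaustively", {
  for (n in c(1, 2, 5, 10, 20, 30)) {
    for (nHomRef in 0:n) for (nHet in 0:(n - nHomRef)) {
      nHomAlt <- n - nHomRef - nHet
      expect_equal(hweExact(nHomRef, nHet, nHomAlt),
                   hweOracle(nHomRef, nHet, nHomAlt),
                   tolerance = 1e-10,
                   info = paste(nHomRef, nHet, nHomAlt))
    }
  }
})

test_that("HWE test flags the sex-linked pattern and extreme deficits", {
  # 13 females hom-ref + 13 males het: oracle value, heterozygote excess
  expect_equal(hweExact(13, 13, 0), hweOracle(13, 13, 0), tolerance = 1e-12)
  # all-het extreme: far from equilibrium
  expect_lt(hweExact(0, 26, 0), 0.01)
  # extreme het deficit sits at the minimum of the support
  p <- hweExact(25, 0, 25)
  support <- seq(0, 50, by = 2)
  probs <- vapply(support, function(h)
    exp(vitiSDR:::hweLogProb(h, 50, 50)), numeric(1))
  expect_equal(p, min(probs) / sum(probs), tolerance = 1e-9)
  # monomorphic site
  expect_equal(hweExact(0, 0, 10), 1)
  expect_equal(hweExact(10, 0, 0), 1)
  expect_error(hweExact(-1, 0, 1), ">= 0")
})

test_that("r2 behaves as composite LD", {
  a <- c(0, 0, 1, 1, 2, 2)
  expect_equal(ldR2(a, a), 1)
  expect_equal(ldR2(a, 2 - a), 1)      # ref/alt swap at one site
  expect_true(is.na(ldR2(a, rep(1, 6))))
  set.seed(1)
  x <- sample(0:2, 4000, replace = TRUE)
  y <- sample(0:2, 4000, replace = TRUE)
  expect_lt(ldR2(x, y), 0.01)          # independent dosages
})

test_that("r2 is invariant to ref/alt recoding at either site", {
  set.seed(7)
  for (rep in 1:20) {
    a <- sample(0:2, 30, replace = TRUE)
    b <- sample(0:2, 30, replace = TRUE)
    if (var(a) == 0 || var(b) == 0) next
    expect_equal(ldR2(a, b), ldR2(2 - a, b))
    expect_equal(ldR2(a, b), ldR2(a, 2 - b))
  }
})

test_that("LD within the SDR of a wild panel is complete", {
  m <- smallModel()
  p <- simulatePanel(m, c("f/f" = 10, "M/f" = 10), seed = 2)
  r2 <- ldMatrix(p, maxSites = 20)
  sl <- mcols(sdrSites(m))$class[
    match(as.integer(rownames(r2)), start(sdrSites(m)))] == "sexlinked"
  expect_true(all(abs(r2[sl, sl] - 1) < 1e-9))
  expect_true(all(diag(r2)[sl] == 1))
})

test_that("cosegregation scan recovers the sex-linked set exactly", {
  m <- smallModel()
  # wild-panel scale: 60 females, 69 males
  p <- simulatePanel(m, c("f/f" = 60, "M/f" = 69), seed = 4)
  st <- cosegregationScan(p)
  truthSL <- mcols(rowRanges(p))$class == "sexlinked"
  # error-free panel: perfect recall and precision on sex-linked sites;
  # H-diagnostic sites follow ancestry so they cosegregate too
  expect_true(all(st$sexLinked[truthSL]))
  expect_true(all(st$mismatches[truthSL] == 0))
  # sex-linked sites violate HWE (every male het) and have elevated maf
  expect_true(all(st$hweP[truthSL] < 1e-4))
  expect_equal(unique(st$maf[truthSL]), 69 / 258)
})

test_that("sites independent of sex are not flagged", {
  m <- smallModel()
  p <- simulatePanel(m, c("f/f" = 60, "M/f" = 69), seed = 5)
  g <- assay(p, "genotype")
  set.seed(6)
  g[1, ] <- sample(0:1, ncol(g), replace = TRUE)   # maf ~ 0.5, sex-blind
  assay(p, "genotype") <- g
  st <- cosegregationScan(p, maxMismatchFrac = 0.02)
  expect_false(st$sexLinked[1])
  expect_gt(st$mismatches[1] / ncol(g), 0.2)
})

test_that("scan rejects hermaphrodite labels and tiny panels", {
  m <- smallModel()
  p <- simulatePanel(m, c("f/f" = 3, "M/f" = 3, "H1/f" = 1), seed = 1)
  expect_error(cosegregationScan(p), "exclude hermaphrodites")
  p2 <- simulatePanel(m, c("f/f" = 1, "M/f" = 5), seed = 1)
  expect_error(cosegregationScan(p2), "at least 2")
})

test_that("sdrBoundaries picks the largest gap-limited run", {
  expect_equal(sdrBoundaries(c(100, 200, 300)), IRanges(100, 300))
  # two clusters: the larger one wins
  pos <- c(1e4, 1.1e4, 1.2e4, 5e4, 5.1e4, 5.2e4, 5.3e4)
  expect_equal(sdrBoundaries(pos, maxGapBp = 5000), IRanges(5e4, 5.3e4))
  expect_equal(length(sdrBoundaries(numeric())), 0L)
})

test_that("scan boundaries recover the simulated SDR span", {
  m <- defaultModel()
  p <- simulatePanel(m, c("f/f" = 12, "M/f" = 12), seed = 3)
  st <- cosegregationScan(p)
  bound <- sdrBoundaries(st$position[st$sexLinked])
  sl <- start(sdrSites(m))[mcols(sdrSites(m))$class == "sexlinked"]
  expect_equal(start(bound), min(sl))
  expect_equal(end(bound), max(sl))
  # within one inter-site spacing of the true SDR span
  spacing <- max(diff(sl))
  expect_lt(start(bound) - m@sdrStart, spacing)
  expect_lt(m@sdrEnd - end(bound), spacing)
})
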