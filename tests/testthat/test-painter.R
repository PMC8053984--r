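test_that("painting codes genotypes relative to the f allele", {
  m <- smallModel()
  pos <- start(sdrSites(m))
  pf <- paintSites(composeGenotype(m, "f", "f"), m)
  expect_true(all(pf$state == 0))
  pm <- paintSites(composeGenotype(m, "M", "f"), m)
  expect_true(all(pm$state == 1))
  ph <- paintSites(composeGenotype(m, "H1", "H2"), m)
  byRegion <- split(ph$state[ph$class == "sexlinked"],
                    ph$region[ph$class == "sexlinked"])
  expect_true(all(byRegion$A == 0))
  expect_true(all(byRegion$C == 2))
  expect_true(all(byRegion$D == 1))
  expect_true(all(ph$state[ph$region == "B"] == 1))
  # missing preserved
  g <- composeGenotype(m, "H1", "f"); g[5] <- NA
  expect_true(is.na(paintSites(g, m)$state[5]))
  expect_error(paintSites(c(0, 1), m, positions = c(1, 2)), "no overlap")
})

test_that("region numeric calls follow the composition table", {
  m <- smallModel()
  for (lab in c("H1/f", "H2/f")) {
    pair <- strsplit(lab, "/")[[1]]
    painted <- paintSites(composeGenotype(m, pair[1], pair[2]), m)
    num <- regionNumeric(painted, m)
    expected <- classSignatures()[lab, ]
    expect_equal(num$state, unname(expected), info = lab)
    expect_true(all(num$concordance == 1))
  }
})

test_that("discordant or sparse regions become no-calls", {
  m <- smallModel()
  painted <- paintSites(composeGenotype(m, "f", "f"), m)
  # 50/50 split in region A -> no-call at concordance 0.9
  aIdx <- which(painted$region == "A")
  painted$state[aIdx] <- rep(c(0L, 1L), length.out = length(aIdx))
  num <- regionNumeric(painted, m, minConcordance = 0.9)
  expect_true(is.na(num$state[num$region == "A"]))
  # too few supporting sites
  num2 <- regionNumeric(paintSites(composeGenotype(m, "f", "f"), m), m,
                        minSites = 1000L)
  expect_true(all(is.na(num2$state)))
  expect_error(regionNumeric(painted, m, minConcordance = 0.4), "0.5")
})

test_that("classification is the inverse of composition for all ten classes", {
  m <- smallModel()
  for (lab in sdrClasses()) {
    pair <- strsplit(lab, "/")[[1]]
    painted <- paintSites(composeGenotype(m, pair[1], pair[2]), m)
    cls <- classifyGenotype(regionNumeric(painted, m))
    expect_equal(as.character(cls), lab)
  }
})

test_that("classification handles no-calls and contradictions", {
  expect_equal(classifyGenotype(c(0, 1, 2, 1)), "H1/H2")
  expect_equal(classifyGenotype(c(0, 0, 0, 0)), "f/f")
  expect_equal(as.character(classifyGenotype(c(0, NA, 1, 1))), "H1/f")
  # contradictory signature
  out <- classifyGenotype(c(2, 0, 0, 2))
  expect_equal(as.character(out), "unknown")
  expect_equal(attr(out, "diagnostics"), c(2, 0, 0, 2))
  # fewer than 3 called regions
  expect_equal(classifyGenotype(c(0, NA, NA, 1)), "unknown")
  expect_error(classifyGenotype(c(0, 1)), "four regions")
})

test_that("breakpoints land at template crossovers", {
  m <- defaultModel()
  pos <- start(sdrSites(m))
  bp <- sdrBreakpointPositions(m)
  spacing <- max(diff(pos))
  bH1 <- detectBreakpoints(haplotypeAncestry(m, "H1"), pos)
  expect_length(bH1, 1)
  expect_lt(abs(bH1 - bp["bBC"]), spacing)
  bH2 <- detectBreakpoints(haplotypeAncestry(m, "H2"), pos)
  expect_length(bH2, 2)
  expect_lt(abs(bH2[1] - bp["bAB"]), spacing)
  expect_lt(abs(bH2[2] - bp["bCD"]), spacing)
  expect_length(detectBreakpoints(haplotypeAncestry(m, "f"), pos), 0)
  # three distinct recombination sites across H1 + H2
  expect_length(unique(c(bH1, bH2)), 3)
  expect_error(detectBreakpoints(rep(NA, 5), 1:5), "missing")
})

test_that("midpoint placement floors ties toward the lower coordinate", {
  expect_equal(detectBreakpoints(c("f", "M"), c(10, 21)), 15)
  expect_equal(detectBreakpoints(c(0, 0, 1, 1, 0), c(1, 3, 8, 12, 20)),
               c(5, 16))
})

test_that("panel classification is near-perfect at 1% genotyping error", {
  m <- defaultModel()
  nPerClass <- setNames(rep(3L, 10), sdrClasses())
  acc <- 0L; tot <- 0L
  for (r in 1:10) {
    p <- simulatePanel(m, nPerClass, errorRate = 0.01, seed = 300 + r)
    calls <- classifyPanel(p, m)
    acc <- acc + sum(calls$class == colData(p)$class)
    tot <- tot + nrow(calls)
  }
  expect_gte(acc / tot, 0.99)
})
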