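suppressPackageStartupMessages({
  library(SummarizedExperiment)
  library(GenomicRanges)
  library(S4Vectors)
  library(IRanges)
})

# compact model for fast unit tests; same geometry as the default
smallModel <- function(nSites = 120L, nDiagnosticB = 12L, seed = 11L) {
  buildSDRModel(nSites = nSites, nDiagnosticB = nDiagnosticB, seed = seed)
}

# default full-scale model, built once per test run
defaultModel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- buildSDRModel()
    cache
  }
})

# independent enumeration oracle for the exact HWE test: enumerates every
# heterozygote count compatible with the allele counts and computes each
# table probability directly from binomial coefficients
hweOracle <- function(nHomRef, nHet, nHomAlt) {
  n <- nHomRef + nHet + nHomAlt
  nA <- 2 * nHomRef + nHet
  nB <- 2 * n - nA
  if (nA == 0 || nB == 0) return(1)
  hets <- seq(min(nA, nB) %% 2, min(nA, nB), by = 2)
  prob <- vapply(hets, function(h) {
    naa <- (nA - h) / 2
    nbb <- n - naa - h
    exp(lchoose(n, naa) + lchoose(n - naa, h) + h * log(2) -
          lchoose(2 * n, nA))
  }, numeric(1))
  prob <- prob / sum(prob)
  pObs <- prob[match(nHet, hets)]
  min(1, sum(prob[prob <= pObs * (1 + 1e-9)]))
}
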