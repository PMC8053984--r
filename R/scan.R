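#' Minor allele frequency of a genotype vector
#'
#' @param genotypes integer vector of M-allele dosages (0/1/2, NA missing).
#' @return minor allele frequency over non-missing calls, in [0, 0.5].
#' @examples
#' siteMAF(c(rep(0, 13), rep(1, 13)))  # 0.25
#' @export
siteMAF <- function(genotypes) {
  g <- genotypes[!is.na(genotypes)]
  if (!length(g)) stop("all genotypes missing at this site")
  p <- sum(g) / (2 * length(g))
  min(p, 1 - p)
}

# log conditional probability of nAB heterozygotes given allele counts,
# under Hardy-Weinberg (Levene/Haldane distribution)
hweLogProb <- function(nAB, n, nA) {
  nAA <- (nA - nAB) / 2
  nBB <- n - nAA - nAB
  lgamma(n + 1) - lgamma(nAA + 1) - lgamma(nAB + 1) - lgamma(nBB + 1) +
    nAB * log(2) + lgamma(nA + 1) + lgamma(2 * n - nA + 1) - lgamma(2 * n + 1)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact conditional test: given the observed allele counts, the
#' probabilities of all heterozygote counts of matching parity are
#' enumerated under the Hardy-Weinberg sampling distribution, and the
#' p-value is the sum of probabilities no larger than that of the observed
#' configuration (no mid-p adjustment). Fully sex-linked sites, at which
#' every male is heterozygous and every female homozygous, show the strong
#' heterozygote excess this test flags.
#'
#' @param nHomRef,nHet,nHomAlt genotype counts (>= 0, summing to >= 1).
#' @return p-value in (0, 1]; a monomorphic site returns 1.
#' @examples
#' hweExact(13, 13, 0)
#' hweExact(25, 0, 25)  # extreme heterozygote deficit
#' @export
hweExact <- function(nHomRef, nHet, nHomAlt) {
  if (min(nHomRef, nHet, nHomAlt) < 0) stop("genotype counts must be >= 0")
  n <- nHomRef + nHet + nHomAlt
  if (n < 1) stop("need at least one genotype")
  nA <- 2 * nHomRef + nHet          # ref allele count
  if (nA == 0 || nA == 2 * n) return(1)
  nMinor <- min(nA, 2 * n - nA)
  hets <- seq(nMinor %% 2, nMinor, by = 2)
  lp <- hweLogProb(hets, n, nA)
  lp <- lp - max(lp)
  pr <- exp(lp) / sum(exp(lp))
  pObs <- pr[match(nHet, hets)]
  min(1, sum(pr[pr <= pObs * (1 + 1e-9)]))
}

#' Composite linkage disequilibrium r-squared between two sites
#'
#' Squared Pearson correlation of unphased genotype dosages across samples
#' non-missing at both sites (the Burrows composite measure). Invariant to
#' swapping the ref/alt coding at either site.
#'
#' @param dosageA,dosageB integer dosage vectors (0/1/2, NA missing).
#' @return r-squared in [0, 1]; \code{NA} if either site is monomorphic
#'   among the shared non-missing samples.
#' @examples
#' ldR2(c(0, 1, 1, 0), c(0, 1, 1, 0))  # 1
#' @export
ldR2 <- function(dosageA, dosageB) {
  ok <- !is.na(dosageA) & !is.na(dosageB)
  a <- dosageA[ok]; b <- dosageB[ok]
  if (length(a) < 2 || stats::var(a) == 0 || stats::var(b) == 0)
    return(NA_real_)
  stats::cor(a, b)^2
}

#' Pairwise LD matrix for a panel
#'
#' @param panel a [GenotypePanel].
#' @param maxSites cap on the number of sites (evenly subsampled) to keep
#'   the matrix tractable.
#' @return symmetric matrix of r-squared values with site positions as
#'   dimnames.
#' @export
ldMatrix <- function(panel, maxSites = 200L) {
  g <- assay(panel, "genotype")
  idx <- if (nrow(g) > maxSites)
    unique(round(seq(1, nrow(g), length.out = maxSites))) else seq_len(nrow(g))
  g <- g[idx, , drop = FALSE]
  pos <- as.character(start(rowRanges(panel)))[idx]
  n <- nrow(g)
  r2 <- matrix(NA_real_, n, n, dimnames = list(pos, pos))
  for (i in seq_len(n)) {
    gi <- g[i, ]
    # diagonal is exactly 1 for polymorphic sites
    ok <- !is.na(gi)
    r2[i, i] <- if (sum(ok) >= 2 && stats::var(gi[ok]) > 0) 1 else NA_real_
    for (j in seq_len(n)[-seq_len(i)])
      r2[i, j] <- r2[j, i] <- ldR2(gi, g[j, ])
  }
  r2
}

#' Cosegregation scan for sex-linked sites
#'
#' In a dioecious panel females are f/f and males M/f, so a fully
#' sex-linked site has every female homozygous for the reference (f) allele
#' and every male heterozygous. For each site the scan counts accessions
#' violating that expectation (missing calls are not counted) and flags the
#' site as sex-linked when the mismatch fraction is at most
#' \code{maxMismatchFrac}. Hermaphroditic (cultivated) accessions must be
#' excluded beforehand; their recombinant haplotypes are interpreted
#' downstream by the painter.
#'
#' @param panel a [GenotypePanel].
#' @param sexLabels character vector (\code{"female"}/\code{"male"}) per
#'   accession; defaults to the panel's truth phenotype.
#' @param maxMismatchFrac tolerated mismatch fraction (default 0.02).
#' @return \code{DataFrame} per site: position, region, maf, hweP,
#'   mismatches, sexLinked flag.
#' @export
cosegregationScan <- function(panel, sexLabels = colData(panel)$phenotype,
                              maxMismatchFrac = 0.02) {
  if (!all(sexLabels %in% c("female", "male")))
    stop("sexLabels must be 'female' or 'male'; exclude hermaphrodites")
  if (sum(sexLabels == "female") < 2 || sum(sexLabels == "male") < 2)
    stop("need at least 2 accessions of each sex")
  g <- assay(panel, "genotype")
  isF <- sexLabels == "female"
  n <- length(sexLabels)

  mism <- apply(g, 1, function(row) {
    sum(row[isF] != 0, na.rm = TRUE) + sum(row[!isF] != 1, na.rm = TRUE)
  })
  maf <- apply(g, 1, function(row) {
    if (all(is.na(row))) NA_real_ else siteMAF(row)
  })
  hweP <- apply(g, 1, function(row) {
    row <- row[!is.na(row)]
    if (!length(row)) return(NA_real_)
    hweExact(sum(row == 0), sum(row == 1), sum(row == 2))
  })
  DataFrame(position = start(rowRanges(panel)),
            region = mcols(rowRanges(panel))$region,
            maf = maf, hweP = hweP,
            mismatches = mism,
            sexLinked = mism / n <= maxMismatchFrac)
}

#' SDR boundaries from flagged sites
#'
#' Returns the smallest interval covering the largest run (most sites) of
#' flagged positions in which consecutive sites are separated by at most
#' \code{maxGapBp}.
#'
#' @param positions sorted positions of flagged sites.
#' @param maxGapBp largest tolerated inter-site gap (default 10,000).
#' @return \code{IRanges} of length 1, or length 0 if no site is flagged.
#' @export
sdrBoundaries <- function(positions, maxGapBp = 10000) {
  if (!length(positions)) return(IRanges())
  positions <- sort(positions)
  grp <- cumsum(c(1, diff(positions) > maxGapBp))
  sizes <- table(grp)
  best <- as.integer(names(sizes)[which.max(sizes)])
  run <- positions[grp == best]
  IRanges(run[1], run[length(run)])
}
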