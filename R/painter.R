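#' Paint an accession's genotypes across the SDR
#'
#' Chromosome painting expresses each marker genotype relative to the
#' f-allele: 0 = homozygous f-allele, 1 = heterozygous, 2 = homozygous
#' M-allele, missing preserved. The result is annotated with the model's
#' region and site-class labels, ready for region-level calling and
#' breakpoint detection.
#'
#' @param genotypes integer vector of M-allele dosages at \code{positions}.
#' @param model an [SDRModel].
#' @param positions positions of \code{genotypes}; defaults to the model's
#'   site positions (lengths must then match).
#' @return \code{DataFrame}: position, region, class, state.
#' @examples
#' m <- buildSDRModel(nSites = 30, nDiagnosticB = 5)
#' paintSites(composeGenotype(m, "H1", "H2"), m)
#' @export
paintSites <- function(genotypes, model, positions = start(sdrSites(model))) {
  if (length(genotypes) != length(positions))
    stop("genotypes and positions differ in length")
  sitePos <- start(sdrSites(model))
  idx <- match(positions, sitePos)
  if (all(is.na(idx)))
    stop("no overlap between genotyped positions and model sites")
  keep <- !is.na(idx)
  DataFrame(position = positions[keep],
            region = mcols(sdrSites(model))$region[idx[keep]],
            class = mcols(sdrSites(model))$class[idx[keep]],
            state = as.integer(genotypes[keep]))
}

#' Per-region numeric genotype from painted sites
#'
#' For each region A--D, the modal non-missing painted state is called if it
#' is supported by at least \code{minSites} sites and reaches a within-region
#' concordance of at least \code{minConcordance}; otherwise the region is a
#' no-call (\code{NA}). Regions A, C and D are called from sex-linked sites;
#' region B, which carries no sex-linked SNPs, is called from the
#' H-diagnostic markers that track haplotype ancestry there.
#'
#' @param painted output of [paintSites()].
#' @param model an [SDRModel].
#' @param minSites minimum supporting sites per region (default 5).
#' @param minConcordance minimal modal-state frequency in (0.5, 1]
#'   (default 0.8).
#' @return \code{DataFrame} with one row per region: region, state (0/1/2 or
#'   NA), nSites, concordance.
#' @export
regionNumeric <- function(painted, model, minSites = 5L,
                          minConcordance = 0.8) {
  if (minSites < 1) stop("minSites must be >= 1")
  if (minConcordance <= 0.5 || minConcordance > 1)
    stop("minConcordance must lie in (0.5, 1]")
  res <- lapply(c("A", "B", "C", "D"), function(reg) {
    wantClass <- if (reg == "B") "diagnostic" else "sexlinked"
    st <- painted$state[painted$region == reg & painted$class == wantClass]
    st <- st[!is.na(st)]
    if (length(st) < minSites)
      return(DataFrame(region = reg, state = NA_integer_,
                       nSites = length(st), concordance = NA_real_))
    tab <- tabulate(st + 1L, 3L)
    conc <- max(tab) / length(st)
    state <- if (conc >= minConcordance) which.max(tab) - 1L else NA_integer_
    DataFrame(region = reg, state = state, nSites = length(st),
              concordance = conc)
  })
  do.call(rbind, res)
}

#' Classify a numeric genotype into one of the ten haplotype combinations
#'
#' Matches the per-region numeric genotype (A, B, C, D) against the ten
#' diploid class signatures (see [classSignatures()]). With all four regions
#' called the match must be exact; with no-call regions the unique signature
#' consistent with the called regions is returned, or \code{"unknown"} if
#' none or several are consistent. A fully called vector matching no
#' signature is contradictory and returns \code{"unknown"} with the
#' offending vector attached as attribute \code{"diagnostics"}.
#'
#' @param numeric integer vector of length 4 (regions A--D; NA = no-call),
#'   or the \code{DataFrame} returned by [regionNumeric()].
#' @return a class label from [sdrClasses()], or \code{"unknown"}.
#' @examples
#' classifyGenotype(c(0, 1, 2, 1))        # H1/H2
#' classifyGenotype(c(0, NA, 1, 1))       # unique completion: H1/f
#' @export
classifyGenotype <- function(numeric) {
  if (is(numeric, "DataFrame") || is.data.frame(numeric))
    numeric <- numeric$state
  if (length(numeric) != 4)
    stop("numeric genotype must cover the four regions A-D")
  called <- !is.na(numeric)
  if (sum(called) < 3) return("unknown")
  sig <- classSignatures()
  hit <- apply(sig, 1, function(s) all(s[called] == numeric[called]))
  if (sum(hit) == 1) return(rownames(sig)[hit])
  out <- "unknown"
  attr(out, "diagnostics") <- numeric
  out
}

#' Detect recombination breakpoints along a site-state vector
#'
#' Scans a per-site state vector (haplotype ancestry coded f/M, or painted
#' diploid states 0/1/2) ordered by position and reports a breakpoint at
#' every transition between maximal runs of equal state, placed at the
#' midpoint between the two flanking informative sites (ties broken toward
#' the lower coordinate by flooring). Missing states are skipped. Applied to
#' the H1 template this yields the single B/C crossover; applied to H2, the
#' two crossovers at the A/B and C/D boundaries.
#'
#' @param states per-site states (character or integer; NA skipped).
#' @param positions site positions, same length, increasing.
#' @return numeric vector of breakpoint positions (possibly empty).
#' @examples
#' m <- buildSDRModel(nSites = 60, nDiagnosticB = 10)
#' detectBreakpoints(haplotypeAncestry(m, "H2"), start(sdrSites(m)))
#' @export
detectBreakpoints <- function(states, positions) {
  if (length(states) != length(positions))
    stop("states and positions differ in length")
  ok <- !is.na(states)
  if (!any(ok)) stop("all states are missing")
  s <- states[ok]; p <- positions[ok]
  change <- which(s[-1] != s[-length(s)])
  if (!length(change)) return(numeric())
  floor((p[change] + p[change + 1]) / 2)
}

#' Paint, call and classify every accession of a panel
#'
#' Convenience wrapper running [paintSites()], [regionNumeric()] and
#' [classifyGenotype()] across a panel's accessions.
#'
#' @param panel a [GenotypePanel].
#' @param model an [SDRModel].
#' @param minSites,minConcordance forwarded to [regionNumeric()].
#' @return \code{DataFrame} with one row per accession: id, regions A--D
#'   numeric states, class call and implied phenotype (from the A/C factor
#'   rule; \code{"unknown"} when either factor region is a no-call).
#' @export
classifyPanel <- function(panel, model, minSites = 5L, minConcordance = 0.8) {
  g <- assay(panel, "genotype")
  pos <- start(rowRanges(panel))
  rows <- lapply(seq_len(ncol(g)), function(j) {
    painted <- paintSites(g[, j], model, pos)
    num <- regionNumeric(painted, model, minSites, minConcordance)
    cls <- classifyGenotype(num)
    phen <- if (is.na(num$state[1]) || is.na(num$state[3])) "unknown"
            else phenotypeFromFactors(num$state[1], num$state[3])$phenotype
    DataFrame(id = colnames(g)[j],
              A = num$state[1], B = num$state[2], C = num$state[3],
              D = num$state[4], class = as.character(cls), phenotype = phen)
  })
  do.call(rbind, rows)
}
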