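#' Site log-likelihoods under the three genotype models
#'
#' For a site with \code{ref} f-allele reads and \code{alt} M-allele reads,
#' the log-likelihood of the data under the three competing genotype models
#' -- homozygous f, heterozygous, homozygous M -- with per-read error
#' \code{baseError}: the alt-read probability is \code{baseError}, 0.5 and
#' \code{1 - baseError} respectively. The binomial coefficient is omitted;
#' it cancels in every Bayes factor.
#'
#' @param ref,alt read counts (>= 0).
#' @param baseError per-read miscall probability in (0, 0.5).
#' @return named numeric: \code{homF}, \code{het}, \code{homM}.
#' @examples
#' ll <- siteLogLikelihoods(10, 0, 0.01)
#' ll["homF"] - ll["het"]  # 10 * log(0.99 / 0.5)
#' @export
siteLogLikelihoods <- function(ref, alt, baseError = 0.01) {
  if (baseError <= 0 || baseError >= 0.5)
    stop("baseError must lie in (0, 0.5)")
  if (min(ref, alt) < 0) stop("read counts must be >= 0")
  p <- c(homF = baseError, het = 0.5, homM = 1 - baseError)
  ref * log(1 - p) + alt * log(p)
}

#' Bayes-factor genotype call for one SDR region
#'
#' Sums site log-likelihoods over a region's informative sites (sites with
#' total depth >= \code{minDepth}), treating sites as independent, under
#' three models: all sites homozygous for the reference (f) sequence, all
#' heterozygous, and all homozygous for the alternative (M) sequence. The
#' region is called as the maximizing model when its smallest pairwise log
#' Bayes factor reaches \code{bfThreshold}; otherwise it is a no-call.
#'
#' @param ref,alt per-site read counts for the region's sites.
#' @param baseError per-read miscall probability (default 0.01).
#' @param minDepth minimum total depth for a site to be used (default 3).
#' @param bfThreshold minimal log Bayes factor separating the called model
#'   from its best rival (default \code{log(100)}).
#' @return list: \code{call} (0/1/2 or NA), \code{logLik} (3 models),
#'   \code{logBF} (log BF of the best model against each rival),
#'   \code{nSites} used.
#' @examples
#' regionBayesFactor(rep(10, 10), rep(0, 10))  # call 0, ln BF ~ 68.3
#' @export
regionBayesFactor <- function(ref, alt, baseError = 0.01, minDepth = 3L,
                              bfThreshold = log(100)) {
  if (length(ref) != length(alt)) stop("ref and alt differ in length")
  use <- which(ref + alt >= minDepth)
  if (!length(use))
    return(list(call = NA_integer_,
                logLik = c(homF = NA, het = NA, homM = NA),
                logBF = NA_real_, nSites = 0L))
  ll <- c(homF = 0, het = 0, homM = 0)
  for (i in use) ll <- ll + siteLogLikelihoods(ref[i], alt[i], baseError)
  best <- which.max(ll)
  bf <- ll[best] - ll[-best]
  call <- if (min(bf) >= bfThreshold) c(homF = 0L, het = 1L, homM = 2L)[best]
          else NA_integer_
  list(call = unname(call), logLik = ll, logBF = bf, nSites = length(use))
}

#' Predict flower-sex phenotype from region calls
#'
#' Decomposes flower sex into its two factors: the accession is
#' female-sterile iff region A (housing VviYABBY3) carries at least one
#' M-derived haplotype (numeric state 1 or 2), and male-sterile iff region
#' C (housing VviINP1) carries none (state 0). Male = female-sterile and
#' male-fertile; female = male-sterile and female-fertile; hermaphrodite =
#' neither. The full four-region vector is additionally classified into one
#' of the ten haplotype combinations.
#'
#' @param regionCalls integer vector of length 4 (regions A--D, NA =
#'   no-call) or the \code{DataFrame} from [regionNumeric()].
#' @return list: \code{phenotype} (\code{"female"}, \code{"male"},
#'   \code{"hermaphrodite"}, \code{"inconsistent"} when A says
#'   female-sterile while C says male-sterile, or \code{"unknown"} when A
#'   or C is a no-call), \code{femaleSterile}, \code{maleSterile},
#'   \code{class} (label or \code{"unknown"}).
#' @examples
#' predictPhenotype(c(0, 0, 1, 1))  # hermaphrodite, H1/f
#' @export
predictPhenotype <- function(regionCalls) {
  if (is(regionCalls, "DataFrame") || is.data.frame(regionCalls))
    regionCalls <- regionCalls$state
  if (length(regionCalls) != 4)
    stop("regionCalls must cover the four regions A-D")
  a <- regionCalls[1]; cc <- regionCalls[3]
  if (is.na(a) || is.na(cc))
    return(list(phenotype = "unknown", femaleSterile = NA, maleSterile = NA,
                class = "unknown"))
  fac <- phenotypeFromFactors(a, cc)
  cls <- classifyGenotype(regionCalls)
  list(phenotype = fac$phenotype, femaleSterile = fac$femaleSterile,
       maleSterile = fac$maleSterile, class = as.character(cls))
}

#' Bayes-factor prediction across a depth table
#'
#' Runs [regionBayesFactor()] on each sample and region of an
#' [AlleleDepthTable] and derives the phenotype and haplotype-combination
#' call. Region B uses the H-diagnostic markers. For RNA-derived tables,
#' sites in genes subject to allele-specific silencing (those listed in
#' \code{effectSpec}) are excluded before summation: their monoallelic
#' expression would otherwise bias the region call.
#'
#' @param depths an [AlleleDepthTable].
#' @param model an [SDRModel].
#' @param baseError,minDepth,bfThreshold forwarded to
#'   [regionBayesFactor()].
#' @param effectSpec allele-silencing spec used for the RNA exclusion rule
#'   (default [aseEffectSpec()]); ignored for DNA tables.
#' @return \code{DataFrame}: one row per sample with region states A--D,
#'   minimal log BF per region, class and phenotype.
#' @export
predictPanel <- function(depths, model, baseError = 0.01, minDepth = 3L,
                         bfThreshold = log(100),
                         effectSpec = aseEffectSpec()) {
  sites <- rowRanges(depths)
  pos <- start(sites)
  sitePos <- start(sdrSites(model))
  idx <- match(pos, sitePos)
  if (all(is.na(idx))) stop("depth table sites do not match the model")
  region <- mcols(sdrSites(model))$region[idx]
  siteClass <- mcols(sdrSites(model))$class[idx]

  exclude <- rep(FALSE, length(pos))
  if (identical(metadata(depths)$source, "RNA") && nrow(effectSpec)) {
    silenced <- sdrGenes(model)[mcols(sdrGenes(model))$name %in%
                                  effectSpec$gene]
    if (length(silenced)) {
      hits <- findOverlaps(sites, silenced)
      exclude[S4Vectors::queryHits(hits)] <- TRUE
    }
  }

  regIdx <- lapply(c(A = "A", B = "B", C = "C", D = "D"), function(reg) {
    wantClass <- if (reg == "B") "diagnostic" else "sexlinked"
    which(!is.na(region) & region == reg & siteClass == wantClass & !exclude)
  })

  refM <- assay(depths, "ref"); altM <- assay(depths, "alt")
  rows <- lapply(seq_len(ncol(refM)), function(j) {
    states <- integer(4); minBF <- numeric(4)
    for (r in 1:4) {
      k <- regIdx[[r]]
      res <- regionBayesFactor(refM[k, j], altM[k, j], baseError, minDepth,
                               bfThreshold)
      states[r] <- ifelse(is.null(res$call), NA_integer_, res$call)
      minBF[r] <- if (all(is.na(res$logBF))) NA_real_ else min(res$logBF)
    }
    pred <- predictPhenotype(states)
    DataFrame(id = colnames(refM)[j],
              A = states[1], B = states[2], C = states[3], D = states[4],
              minLogBF.A = minBF[1], minLogBF.B = minBF[2],
              minLogBF.C = minBF[3], minLogBF.D = minBF[4],
              class = pred$class, phenotype = pred$phenotype)
  })
  do.call(rbind, rows)
}

#' Genotype the VviINP1 8 bp indel marker
#'
#' The f haplotype of VviINP1 lacks an 8 bp segment whose deletion causes a
#' frameshift and premature stop; M and H haplotypes are intact. Two input
#' forms are supported. With two resolved allele sequences, each allele is
#' labelled \code{deleted} if it lacks the 8 bp motif (their lengths must
#' then differ by 8 when heterozygous). With a histogram of read lengths
#' spanning the indel, the modal lengths are compared with the intact
#' amplicon length: modes may differ by 0 (homozygous) or 8 (heterozygous);
#' anything else is ambiguous. Male sterility is implied iff both alleles
#' are deleted.
#'
#' @param alleleSequences character vector of the two resolved allele
#'   sequences (either order), or \code{NULL}.
#' @param readLengths integer vector of spanning-read lengths, used when
#'   \code{alleleSequences} is \code{NULL}.
#' @param model an [SDRModel] supplying the motif and intact length.
#' @param minModeFrac a length is a mode when its count is at least this
#'   fraction of the top count (default 0.25).
#' @return list: \code{alleles} (two of \code{"deleted"}/\code{"intact"}),
#'   \code{maleSterile} (logical).
#' @examples
#' m <- buildSDRModel()
#' inp1IndelGenotype(alleleSequences = m@inp1Alleles, model = m)
#' @export
inp1IndelGenotype <- function(alleleSequences = NULL, readLengths = NULL,
                              model, minModeFrac = 0.25) {
  intactLen <- nchar(model@inp1Alleles["intact"])
  if (!is.null(alleleSequences)) {
    if (length(alleleSequences) != 2)
      stop("need exactly two resolved allele sequences")
    hasMotif <- vapply(alleleSequences, function(s)
      Biostrings::countPattern(model@inp1Motif,
                               Biostrings::DNAString(s)) > 0, logical(1))
    alleles <- ifelse(hasMotif, "intact", "deleted")
    if (sum(hasMotif) == 1) {
      dlen <- abs(diff(nchar(alleleSequences)))
      if (dlen != 8)
        stop("heterozygous alleles must differ in length by 8 bp, got ", dlen)
    }
  } else {
    if (is.null(readLengths) || !length(readLengths))
      stop("provide allele sequences or spanning-read lengths")
    tab <- table(readLengths)
    modes <- as.integer(names(tab)[tab >= minModeFrac * max(tab)])
    # collapse +-1 bp neighbours onto the stronger mode
    modes <- modes[order(-tab[as.character(modes)])]
    keep <- modes[1]
    for (mm in modes[-1]) if (min(abs(mm - keep)) > 1) keep <- c(keep, mm)
    modes <- sort(keep)
    offs <- intactLen - modes
    if (length(modes) == 1) {
      if (offs == 0) alleles <- c("intact", "intact")
      else if (offs == 8) alleles <- c("deleted", "deleted")
      else stop("ambiguous read-length mode at offset ", offs)
    } else if (length(modes) == 2 && diff(modes) == 8 && all(offs %in% c(0, 8))) {
      alleles <- c("deleted", "intact")
    } else {
      stop("ambiguous read-length histogram: modes differ by ",
           paste(diff(modes), collapse = ","), " (need 0 or 8)")
    }
  }
  list(alleles = unname(alleles), maleSterile = all(alleles == "deleted"))
}

#' Simulate VviINP1-spanning read lengths for a panel
#'
#' For each accession, reads spanning the indel are drawn uniformly from
#' its two alleles; a deleted allele yields reads 8 bp shorter than the
#' intact amplicon. With probability \code{baseError} a read's apparent
#' length is perturbed by one base (sequencing indel error).
#'
#' @param panel a [GenotypePanel] (class labels are read from colData).
#' @param model an [SDRModel].
#' @param depth spanning reads per accession.
#' @param baseError per-read length-error probability.
#' @param seed integer seed.
#' @return list of integer read-length vectors, one per accession.
#' @export
simulateInp1Reads <- function(panel, model, depth = 30L, baseError = 0.005,
                              seed = 1L) {
  intactLen <- nchar(model@inp1Alleles["intact"])
  inp1 <- attr(haplotypeTemplates(model), "inp1")
  set.seed(seed)
  lapply(seq_len(ncol(panel)), function(j) {
    haps <- c(colData(panel)$hap1[j], colData(panel)$hap2[j])
    allele <- sample(haps, depth, replace = TRUE)
    len <- ifelse(inp1[allele] == "deleted", intactLen - 8L, intactLen)
    err <- stats::runif(depth) < baseError
    len[err] <- len[err] + sample(c(-1L, 1L), sum(err), replace = TRUE)
    as.integer(len)
  })
}
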