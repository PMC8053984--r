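#' Simulate a diploid genotype panel
#'
#' Composes accession genotypes site-wise from the haplotype templates of an
#' [SDRModel], then applies a symmetric genotyping-error model (each call is
#' flipped to one of the two other states, chosen uniformly, with probability
#' \code{errorRate}) and random missingness. The error-free composition is
#' kept in the \code{"truth"} assay so downstream accuracy can be scored
#' against simulation truth.
#'
#' @param model an [SDRModel].
#' @param nPerClass named integer vector mapping diploid class labels (see
#'   [sdrClasses()]) to accession counts; any subset of the ten classes.
#' @param errorRate per-call probability of a genotype flip, in [0, 1).
#' @param missingRate per-call probability of a missing call, in [0, 1).
#' @param seed integer seed; the panel is reproducible byte-for-byte.
#' @return a [GenotypePanel] (sites x accessions). \code{colData} columns:
#'   \code{hap1}, \code{hap2}, \code{class}, \code{phenotype} (truth);
#'   \code{metadata()} records seed and rates.
#' @examples
#' m <- buildSDRModel(nSites = 50, nDiagnosticB = 5)
#' p <- simulatePanel(m, c("f/f" = 3, "M/f" = 3), seed = 1)
#' table(assay(p, "genotype")[, 1])
#' @export
simulatePanel <- function(model, nPerClass, errorRate = 0, missingRate = 0,
                          seed = 1L) {
  if (length(nPerClass) == 0 || sum(nPerClass) == 0)
    stop("nPerClass must request at least one accession")
  bad <- setdiff(names(nPerClass), sdrClasses())
  if (length(bad))
    stop("unknown class label(s): ", paste(bad, collapse = ", "))
  if (errorRate < 0 || errorRate >= 1 || missingRate < 0 || missingRate >= 1)
    stop("errorRate and missingRate must lie in [0, 1)")

  sites <- sdrSites(model)
  nSite <- length(sites)
  classes <- rep(names(nPerClass), nPerClass)
  n <- length(classes)

  set.seed(seed)
  truth <- matrix(0L, nrow = nSite, ncol = n)
  hap1 <- hap2 <- character(n)
  for (j in seq_len(n)) {
    pair <- classPair(classes[j])
    hap1[j] <- pair[1]; hap2[j] <- pair[2]
    truth[, j] <- composeGenotype(model, pair[1], pair[2])
  }

  geno <- truth
  if (errorRate > 0) {
    flip <- matrix(stats::runif(nSite * n) < errorRate, nSite, n)
    if (any(flip)) {
      idx <- which(flip)
      # uniformly one of the two other states
      shift <- sample(1:2, length(idx), replace = TRUE)
      geno[idx] <- (geno[idx] + shift[seq_along(idx)]) %% 3L
    }
  }
  errorMask <- geno != truth
  missingMask <- matrix(FALSE, nSite, n)
  if (missingRate > 0) {
    missingMask <- matrix(stats::runif(nSite * n) < missingRate, nSite, n)
    geno[missingMask] <- NA_integer_
  }

  ids <- sprintf("acc%03d", seq_len(n))
  colnames(geno) <- colnames(truth) <- ids
  cd <- DataFrame(id = ids, hap1 = hap1, hap2 = hap2, class = classes,
                  phenotype = unname(mapply(phenotypeOf, hap1, hap2)),
                  row.names = ids)
  se <- SummarizedExperiment(
    assays = list(genotype = geno, truth = truth,
                  errorMask = errorMask, missingMask = missingMask),
    rowRanges = sites, colData = cd)
  metadata(se) <- list(seed = seed, errorRate = errorRate,
                       missingRate = missingRate)
  new("GenotypePanel", se)
}

# effective alt-read probability given allele doses and a base error
altReadProb <- function(doseF, doseM, baseError) {
  tot <- doseF + doseM
  p <- ifelse(tot > 0, doseM / tot, 0)
  p * (1 - baseError) + (1 - p) * baseError
}

#' Simulate per-site allele read depths for a panel
#'
#' Draws a total depth per accession and site from Poisson(\code{meanDepth})
#' and splits it into f-allele (ref) and M-allele (alt) reads binomially,
#' with alt-read probability \code{baseError}, 0.5 or \code{1 - baseError}
#' for genotypes 0, 1 and 2. Sites with a missing genotype get zero depth
#' (assay dropout). For \code{source = "RNA"}, only sites inside annotated
#' genes are expressed; the expected depth scales with the expressed allele
#' dose, and genes listed in \code{effectSpec} have their M-allele
#' expression multiplied per phenotype group (the default silences the
#' VviYABBY3 M-allele except in female-sterile samples), producing
#' monoallelic expression in hermaphrodites.
#'
#' @param panel a [GenotypePanel].
#' @param model the [SDRModel] that generated the panel.
#' @param meanDepth mean total depth per site (> 0).
#' @param baseError per-read miscall probability in [0, 0.5).
#' @param seed integer seed.
#' @param source \code{"DNA"} or \code{"RNA"}.
#' @param effectSpec for RNA, a data.frame as from [aseEffectSpec()].
#' @return an [AlleleDepthTable].
#' @examples
#' m <- buildSDRModel(nSites = 50, nDiagnosticB = 5)
#' p <- simulatePanel(m, c("M/f" = 2), seed = 1)
#' d <- simulateAlleleDepths(p, m, meanDepth = 20, seed = 2)
#' summary(as.vector(assay(d, "alt") / pmax(1, assay(d, "ref") + assay(d, "alt"))))
#' @export
simulateAlleleDepths <- function(panel, model, meanDepth = 20,
                                 baseError = 0.01, seed = 1L,
                                 source = c("DNA", "RNA"),
                                 effectSpec = aseEffectSpec()) {
  source <- match.arg(source)
  if (meanDepth <= 0) stop("meanDepth must be positive")
  if (baseError < 0 || baseError >= 0.5) stop("baseError must lie in [0, 0.5)")
  if (!"truth" %in% assayNames(panel))
    stop("panel carries no truth genotypes")
  geno <- assay(panel, "genotype")
  nSite <- nrow(geno); n <- ncol(geno)
  sites <- rowRanges(panel)

  geneOf <- rep(NA_character_, nSite)
  if (source == "RNA") {
    hits <- findOverlaps(sites, sdrGenes(model))
    geneOf[S4Vectors::queryHits(hits)] <-
      mcols(sdrGenes(model))$name[S4Vectors::subjectHits(hits)]
  }
  fs <- colData(panel)$phenotype == "male"   # female-sterile samples

  set.seed(seed)
  ref <- alt <- matrix(0L, nSite, n, dimnames = dimnames(geno))
  for (j in seq_len(n)) {
    g <- geno[, j]
    doseF <- 2 - g
    doseM <- as.numeric(g)
    if (source == "RNA") {
      mult <- rep(1, nSite)
      expressed <- !is.na(geneOf)
      for (k in seq_len(nrow(effectSpec))) {
        inGene <- !is.na(geneOf) & geneOf == effectSpec$gene[k]
        mult[inGene] <- if (fs[j]) effectSpec$femaleSterileMult[k]
                        else effectSpec$defaultMult[k]
      }
      doseM <- doseM * mult
      doseF[!expressed] <- 0
      doseM[!expressed] <- 0
    }
    lambda <- meanDepth * (doseF + doseM) / 2
    lambda[is.na(lambda)] <- 0           # missing genotype -> dropout
    tot <- stats::rpois(nSite, lambda)
    pAlt <- altReadProb(doseF, doseM, baseError)
    pAlt[is.na(pAlt)] <- 0
    a <- stats::rbinom(nSite, tot, pAlt)
    alt[, j] <- a
    ref[, j] <- tot - a
  }

  se <- SummarizedExperiment(assays = list(ref = ref, alt = alt),
                             rowRanges = sites, colData = colData(panel))
  metadata(se) <- c(metadata(panel),
                    list(source = source, meanDepth = meanDepth,
                         baseError = baseError, depthSeed = seed))
  new("AlleleDepthTable", se)
}

#' Default allele-specific expression effect specification
#'
#' One row per gene subject to allele-specific regulation: the M-allele
#' expression multiplier in female-sterile samples
#' (\code{femaleSterileMult}) and in all other samples (\code{defaultMult}).
#' The default encodes the VviYABBY3 pattern: the M-allele is expressed only
#' when the flower is female-sterile (male), and silenced in hermaphrodites
#' and (vacuously) females.
#'
#' @return data.frame with columns gene, femaleSterileMult, defaultMult.
#' @examples
#' aseEffectSpec()
#' @export
aseEffectSpec <- function() {
  data.frame(gene = "VviYABBY3", femaleSterileMult = 1, defaultMult = 0)
}

#' Simulate allele-specific expression counts
#'
#' Generates an [AseCountTable] for the transcribed (in-gene) marker sites
#' of an [SDRModel]: per sample and site, a Poisson total depth proportional
#' to the expressed allele dose split binomially into f- and M-allele reads,
#' honouring the per-gene, per-phenotype-group M-allele multipliers of
#' \code{effectSpec}. A sample with no M allele at a site yields exactly
#' zero M-allele reads when \code{baseError = 0}.
#'
#' @param model an [SDRModel].
#' @param samples data.frame with columns \code{id} and \code{class}
#'   (diploid class labels).
#' @param effectSpec as from [aseEffectSpec()].
#' @param meanExpr mean total read count at a fully expressed site.
#' @param baseError per-read allele miscall probability.
#' @param seed integer seed.
#' @return an [AseCountTable] over in-gene sites.
#' @export
simulateAseCounts <- function(model, samples, effectSpec = aseEffectSpec(),
                              meanExpr = 30, baseError = 0, seed = 1L) {
  if (is.null(samples$class))
    stop("samples must carry a 'class' column of diploid class labels")
  sites <- sdrSites(model)
  hits <- findOverlaps(sites, sdrGenes(model))
  keep <- unique(S4Vectors::queryHits(hits))
  sites <- sites[keep]
  geneOf <- mcols(sdrGenes(model))$name[
    S4Vectors::subjectHits(hits)[match(keep, S4Vectors::queryHits(hits))]]
  nSite <- length(sites)
  n <- nrow(samples)

  phen <- unname(vapply(samples$class, function(cl) {
    pair <- classPair(cl); phenotypeOf(pair[1], pair[2])
  }, character(1)))
  fs <- phen == "male"
  ms <- phen == "female"

  set.seed(seed)
  ref <- alt <- matrix(0L, nSite, n,
                       dimnames = list(NULL, samples$id))
  for (j in seq_len(n)) {
    pair <- classPair(samples$class[j])
    g <- composeGenotype(model, pair[1], pair[2])[keep]
    doseF <- 2 - g
    doseM <- as.numeric(g)
    mult <- rep(1, nSite)
    for (k in seq_len(nrow(effectSpec))) {
      inGene <- geneOf == effectSpec$gene[k]
      mult[inGene] <- if (fs[j]) effectSpec$femaleSterileMult[k]
                      else effectSpec$defaultMult[k]
    }
    doseM <- doseM * mult
    lambda <- meanExpr * (doseF + doseM) / 2
    tot <- stats::rpois(nSite, lambda)
    a <- stats::rbinom(nSite, tot, altReadProb(doseF, doseM, baseError))
    alt[, j] <- a
    ref[, j] <- tot - a
  }

  mcols(sites)$gene <- geneOf
  cd <- DataFrame(id = samples$id, class = samples$class, phenotype = phen,
                  femaleSterile = fs, maleSterile = ms,
                  row.names = samples$id)
  se <- SummarizedExperiment(assays = list(ref = ref, alt = alt),
                             rowRanges = sites, colData = cd)
  metadata(se) <- list(seed = seed, meanExpr = meanExpr,
                       baseError = baseError)
  new("AseCountTable", se)
}
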