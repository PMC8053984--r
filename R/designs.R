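#' Reference panel designs for validation studies
#'
#' Class compositions of the three validation panels the package uses to
#' benchmark its predictors, mirroring the published validation cohorts:
#' \describe{
#'   \item{dnaPanel}{193 accessions genotyped from shotgun DNA depths: 137
#'     wild (69 f/f females, 68 M/f males) plus 56 cultivars and hybrids
#'     carrying H haplotypes.}
#'   \item{inp1Panel}{167 accessions scored with the VviINP1 8 bp indel
#'     marker across wild-species-like backgrounds.}
#'   \item{rnaPanel}{48 transcriptome samples: 29 wild-class plus 19
#'     cultivated-class.}
#' }
#' Within the cultivated groups the H-class mixture follows the observed
#' predominance of H1 (H1/f commonest, H2 only heterozygous, H2/H2 absent
#' from nature).
#'
#' @return named list of three named integer vectors suitable for
#'   [simulatePanel()]'s \code{nPerClass}.
#' @examples
#' sapply(referencePanelDesigns(), sum)
#' @export
referencePanelDesigns <- function() {
  list(
    dnaPanel = c("f/f" = 69L, "M/f" = 68L, "H1/f" = 25L, "H2/f" = 8L,
                 "H1/H1" = 8L, "H1/H2" = 15L),
    inp1Panel = c("f/f" = 60L, "M/f" = 70L, "H1/f" = 15L, "H2/f" = 8L,
                  "H1/H1" = 7L, "H1/H2" = 7L),
    rnaPanel = c("f/f" = 15L, "M/f" = 14L, "H1/f" = 8L, "H2/f" = 4L,
                 "H1/H1" = 2L, "H1/H2" = 5L)
  )
}

#' Run the three flower-sex validation studies
#'
#' End-to-end drivers for the package's validation panels; each builds the
#' default [SDRModel], simulates the relevant data type under the study
#' conditions, runs the predictor and returns the achieved accuracy.
#'
#' \code{validateDnaPrediction()}: 193 accessions with 0.5% genotyping
#' error and 2% missingness, Poisson depth ~20x, base error 1%, scored as
#' the fraction of accessions whose Bayes-factor phenotype call matches
#' simulation truth.
#'
#' \code{validateInp1Marker()}: 167 accessions; VviINP1 spanning reads
#' (depth 30, length-error 0.5%) give the indel genotype, and the linked
#' C-region Bayes-factor call confirms it; scored on implied male-sterility
#' versus truth.
#'
#' \code{validateRnaPrediction()}: 48 samples (29 wild-class, 19
#' cultivated-class); RNA allele depths with VviYABBY3 monoallelic-
#' expression masking, predictor run with the RNA site-exclusion rule.
#'
#' @param seed integer seed driving every stochastic step.
#' @return list: \code{accuracy} (fraction correct), \code{n}, and the
#'   per-sample prediction table.
#' @examples
#' \donttest{validateDnaPrediction(seed = 1)$accuracy}
#' @export
validateDnaPrediction <- function(seed = 1L) {
  model <- buildSDRModel()
  design <- referencePanelDesigns()$dnaPanel
  panel <- simulatePanel(model, design, errorRate = 0.005,
                         missingRate = 0.02, seed = seed)
  depths <- simulateAlleleDepths(panel, model, meanDepth = 20,
                                 baseError = 0.01, seed = seed + 1L)
  pred <- predictPanel(depths, model)
  acc <- mean(pred$phenotype == colData(panel)$phenotype)
  list(accuracy = acc, n = sum(design), predictions = pred,
       truth = colData(panel)$phenotype)
}

#' @rdname validateDnaPrediction
#' @export
validateInp1Marker <- function(seed = 1L) {
  model <- buildSDRModel()
  design <- referencePanelDesigns()$inp1Panel
  panel <- simulatePanel(model, design, seed = seed)
  reads <- simulateInp1Reads(panel, model, depth = 30, baseError = 0.005,
                             seed = seed + 1L)
  depths <- simulateAlleleDepths(panel, model, meanDepth = 20,
                                 baseError = 0.01, seed = seed + 2L)
  pred <- predictPanel(depths, model)
  sterile <- vapply(seq_along(reads), function(j) {
    indel <- inp1IndelGenotype(readLengths = reads[[j]], model = model)
    cState <- pred$C[j]
    # the indel marker leads; the linked C-region state backs it up
    if (!is.na(cState) && (cState == 0) != indel$maleSterile)
      return(NA)                      # marker conflict: no confident call
    indel$maleSterile
  }, logical(1))
  truth <- colData(panel)$phenotype == "female"
  acc <- mean(!is.na(sterile) & sterile == truth)  # conflicts score as wrong
  list(accuracy = acc, n = sum(design), maleSterile = sterile,
       truth = truth)
}

#' @rdname validateDnaPrediction
#' @export
validateRnaPrediction <- function(seed = 1L) {
  model <- buildSDRModel()
  design <- referencePanelDesigns()$rnaPanel
  panel <- simulatePanel(model, design, errorRate = 0.005,
                         missingRate = 0.02, seed = seed)
  depths <- simulateAlleleDepths(panel, model, meanDepth = 20,
                                 baseError = 0.01, seed = seed + 1L,
                                 source = "RNA")
  pred <- predictPanel(depths, model)
  acc <- mean(pred$phenotype == colData(panel)$phenotype)
  list(accuracy = acc, n = sum(design), predictions = pred,
       truth = colData(panel)$phenotype)
}
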