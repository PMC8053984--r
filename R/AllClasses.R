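#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start end width strand findOverlaps
#' @importFrom SummarizedExperiment SummarizedExperiment rowRanges colData assay
#'   assays assayNames
NULL

#' SDRModel: the canonical model of the grapevine sex-determining region
#'
#' An \code{SDRModel} holds everything downstream analyses need to know about
#' the sex-determining region (SDR): its span on the f-haplotype reference,
#' the three recombination breakpoints that partition it into gene regions
#' A--D, the flanking (pseudo-autosomal) intervals, the ordered set of
#' sex-linked and H-diagnostic marker sites with their f- and M-alleles, the
#' gene map, and the VviINP1 8 bp indel marker (motif, amplicon alleles).
#'
#' Region semantics follow the biology of the locus: region A carries the
#' female-sterility candidate (VviYABBY3), region B the recombination hotspot
#' genes (beta-fructofuranosidase, transaldolase) and no sex-linked SNPs,
#' region C the male-sterility candidate (VviINP1) among eleven genes, and
#' region D the single gene VviAPT3.
#'
#' @slot chrom chromosome name of the f-reference.
#' @slot sdrStart,sdrEnd 1-based closed span of the SDR.
#' @slot breakpoints named numeric of length 3 (\code{bAB}, \code{bBC},
#'   \code{bCD}); each is the first base of the region to its right.
#' @slot flankLeft,flankRight \code{IRanges} of the flanking intervals.
#' @slot sites \code{GRanges} of marker sites with metadata columns
#'   \code{region} (A/B/C/D), \code{class} (\code{"sexlinked"} or
#'   \code{"diagnostic"}), \code{ref} (f-allele base) and \code{alt}
#'   (M-allele base).
#' @slot geneMap \code{GRanges} of genes with \code{name} and \code{region}.
#' @slot inp1Motif the 8 bp segment deleted from the f allele of VviINP1.
#' @slot inp1Alleles named character of the two synthetic amplicon alleles
#'   (\code{intact}, \code{deleted}).
#' @slot seed integer seed that fixed the randomly placed site positions.
#'
#' @seealso [buildSDRModel()], [haplotypeTemplates()], [classSignatures()]
#' @export
setClass("SDRModel",
  representation(
    chrom = "character",
    sdrStart = "numeric",
    sdrEnd = "numeric",
    breakpoints = "numeric",
    flankLeft = "IRanges",
    flankRight = "IRanges",
    sites = "GRanges",
    geneMap = "GRanges",
    inp1Motif = "character",
    inp1Alleles = "character",
    seed = "integer"
  )
)

setValidity("SDRModel", function(object) {
  msg <- character()
  bp <- object@breakpoints
  if (!identical(names(bp), c("bAB", "bBC", "bCD")))
    msg <- c(msg, "breakpoints must be named bAB, bBC, bCD")
  else {
    if (!(object@sdrStart < bp["bAB"] && bp["bAB"] < bp["bBC"] &&
          bp["bBC"] < bp["bCD"] && bp["bCD"] < object@sdrEnd))
      msg <- c(msg, "breakpoints must satisfy sdrStart < bAB < bBC < bCD < sdrEnd")
  }
  s <- object@sites
  if (length(s)) {
    pos <- start(s)
    if (any(pos < object@sdrStart | pos > object@sdrEnd))
      msg <- c(msg, "all sites must lie within the SDR")
    if (is.unsorted(pos, strictly = TRUE))
      msg <- c(msg, "site positions must be strictly increasing")
    expreg <- regionOfPosition(object, pos)
    if (!all(expreg == mcols(s)$region))
      msg <- c(msg, "site region labels disagree with breakpoint intervals")
    if (any(mcols(s)$region == "B" & mcols(s)$class == "sexlinked"))
      msg <- c(msg, "region B must contain no sex-linked sites")
  }
  g <- object@geneMap
  if (length(g)) {
    greg <- regionOfPosition(object, start(g))
    gend <- regionOfPosition(object, end(g))
    if (any(greg != gend))
      msg <- c(msg, "genes must not straddle region boundaries")
  }
  if (nchar(object@inp1Motif) != 8L)
    msg <- c(msg, "inp1Motif must be exactly 8 bp")
  if (length(msg)) msg else TRUE
})

#' GenotypePanel: diploid genotypes for a set of accessions at SDR sites
#'
#' Extends \code{RangedSummarizedExperiment}. Rows are marker sites (the
#' \code{rowRanges} carry the site annotation of the generating
#' [SDRModel]), columns are accessions. The \code{"genotype"} assay codes
#' each call as the count of M-alleles (0/1/2, \code{NA} = missing); the
#' \code{"truth"} assay (present for simulated panels) holds the error-free
#' template composition. \code{colData} records each accession's haplotype
#' pair, diploid class label and true phenotype.
#'
#' @seealso [simulatePanel()], [paintSites()], [cosegregationScan()]
#' @export
setClass("GenotypePanel", contains = "RangedSummarizedExperiment")

setValidity("GenotypePanel", function(object) {
  msg <- character()
  if (!"genotype" %in% assayNames(object))
    msg <- c(msg, "a 'genotype' assay is required")
  else {
    g <- assay(object, "genotype")
    if (!all(g %in% c(0L, 1L, 2L, NA)))
      msg <- c(msg, "genotypes must be 0, 1, 2 or NA")
  }
  if (length(msg)) msg else TRUE
})

#' AlleleDepthTable: per-site reference/alternative read counts
#'
#' Extends \code{RangedSummarizedExperiment} with assays \code{"ref"}
#' (reads supporting the f-allele) and \code{"alt"} (reads supporting the
#' M-allele); rows are sites, columns are samples. \code{metadata()$source}
#' is \code{"DNA"} or \code{"RNA"}.
#'
#' @seealso [simulateAlleleDepths()], [predictPanel()]
#' @export
setClass("AlleleDepthTable", contains = "RangedSummarizedExperiment")

setValidity("AlleleDepthTable", function(object) {
  msg <- character()
  if (!all(c("ref", "alt") %in% assayNames(object)))
    msg <- c(msg, "'ref' and 'alt' assays are required")
  else if (min(assay(object, "ref"), 0) < 0 || min(assay(object, "alt"), 0) < 0)
    msg <- c(msg, "read counts must be non-negative")
  src <- metadata(object)$source
  if (is.null(src) || !src %in% c("DNA", "RNA"))
    msg <- c(msg, "metadata()$source must be 'DNA' or 'RNA'")
  if (length(msg)) msg else TRUE
})

#' AseCountTable: allele-specific expression counts at transcribed sites
#'
#' Extends \code{RangedSummarizedExperiment} with assays \code{"ref"} and
#' \code{"alt"} restricted to sites inside annotated genes; \code{colData}
#' carries the two flower-sex factors \code{femaleSterile} and
#' \code{maleSterile} (logical).
#'
#' @seealso [simulateAseCounts()], [aseScan()]
#' @export
setClass("AseCountTable", contains = "RangedSummarizedExperiment")

setValidity("AseCountTable", function(object) {
  msg <- character()
  if (!all(c("ref", "alt") %in% assayNames(object)))
    msg <- c(msg, "'ref' and 'alt' assays are required")
  need <- c("femaleSterile", "maleSterile")
  if (!all(need %in% colnames(colData(object))))
    msg <- c(msg, "colData must contain femaleSterile and maleSterile")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SDRModel", function(object) {
  bp <- object@breakpoints
  cat("SDRModel on", object@chrom, "\n")
  cat(sprintf("  SDR span: %d-%d (%s kb)\n", object@sdrStart, object@sdrEnd,
              format((object@sdrEnd - object@sdrStart + 1) / 1000)))
  cat(sprintf("  breakpoints: bAB=%d bBC=%d bCD=%d\n", bp[1], bp[2], bp[3]))
  tab <- table(factor(mcols(object@sites)$region, levels = c("A", "B", "C", "D")),
               mcols(object@sites)$class)
  cat("  sites per region:\n")
  print(tab)
  cat(sprintf("  genes: %d; INP1 motif: %s\n", length(object@geneMap),
              object@inp1Motif))
})
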