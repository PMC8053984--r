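#' Canonical haplotype names and diploid classes
#'
#' The four SDR haplotypes are \code{f} (female), \code{M} (male) and the two
#' hermaphroditic recombinants \code{H1} (single crossover at the B/C
#' boundary) and \code{H2} (double crossover at the A/B and C/D boundaries).
#' Unordered diploid combinations of the four haplotypes give exactly ten
#' classes.
#'
#' @return \code{sdrHaplotypes()}: the four haplotype names;
#'   \code{sdrClasses()}: the ten diploid class labels.
#' @examples
#' sdrClasses()
#' @export
sdrHaplotypes <- function() c("f", "M", "H1", "H2")

#' @rdname sdrHaplotypes
#' @export
sdrClasses <- function() {
  haps <- sdrHaplotypes()
  out <- character()
  for (i in seq_along(haps))
    for (j in i:length(haps))
      out <- c(out, classLabel(haps[i], haps[j]))
  out
}

# canonical label for an unordered pair: H1 < H2 < M < f
classLabel <- function(h1, h2) {
  ord <- c(H1 = 1L, H2 = 2L, M = 3L, f = 4L)
  pair <- c(h1, h2)[order(ord[c(h1, h2)])]
  paste(pair, collapse = "/")
}

# split "H1/f" back into its haplotype pair
classPair <- function(label) {
  pair <- strsplit(label, "/", fixed = TRUE)[[1]]
  if (length(pair) != 2L || !all(pair %in% sdrHaplotypes()))
    stop("not a diploid SDR class label: ", label)
  pair
}

#' Default gene map of the SDR
#'
#' Synthetic coordinates for the 16 annotated SDR genes, laid out to respect
#' the locus architecture: two genes in region A (VviYABBY3, VviSKU5), two in
#' region B (beta-fructofuranosidase and transaldolase, the latter on the
#' minus strand so that its 5' end abuts the B/C boundary where the H1
#' crossover occurred and its 3' end faces the A/B boundary of the H2
#' crossover), eleven in region C (TPP through WRKY, including VviINP1), and
#' VviAPT3 alone in region D, 47 kb downstream of the C/D breakpoint.
#'
#' @param sdrStart first base of the SDR (genes are placed relative to it).
#' @return a data.frame with columns name, start, end, strand, region.
#' @keywords internal
defaultGeneTable <- function(sdrStart = 1000001L) {
  g <- rbind(
    data.frame(name = "VviYABBY3",  start =   2000L, end =   5999L, strand = "+", region = "A"),
    data.frame(name = "VviSKU5",    start =  10000L, end =  14999L, strand = "+", region = "A"),
    data.frame(name = "bFFase",     start =  25000L, end =  27999L, strand = "+", region = "B"),
    data.frame(name = "transaldolase", start = 30000L, end = 43899L, strand = "-", region = "B"),
    data.frame(name = "TPP",        start =  45000L, end =  47999L, strand = "+", region = "C"),
    data.frame(name = "VviINP1",    start =  50000L, end =  52499L, strand = "+", region = "C"),
    data.frame(name = "VviPPR1",    start =  54000L, end =  56499L, strand = "+", region = "C"),
    data.frame(name = "VviLRR1",    start =  58000L, end =  60499L, strand = "+", region = "C"),
    data.frame(name = "VviFMO1",    start =  62000L, end =  64499L, strand = "+", region = "C"),
    data.frame(name = "VviEXO70",   start =  66000L, end =  68999L, strand = "+", region = "C"),
    data.frame(name = "VviCYP1",    start =  71000L, end =  73499L, strand = "+", region = "C"),
    data.frame(name = "VviGH1",     start =  75000L, end =  77499L, strand = "+", region = "C"),
    data.frame(name = "KASIII",     start =  79000L, end =  81499L, strand = "+", region = "C"),
    data.frame(name = "PLATZ",      start =  83000L, end =  84999L, strand = "+", region = "C"),
    data.frame(name = "WRKY",       start =  86000L, end =  87999L, strand = "+", region = "C"),
    data.frame(name = "VviAPT3",    start = 137000L, end = 139999L, strand = "+", region = "D")
  )
  g$start <- g$start + sdrStart
  g$end <- g$end + sdrStart
  g
}

#' Build the canonical SDR model
#'
#' Constructs an [SDRModel] describing the f-reference geometry of the
#' grapevine sex-determining region: a 145,500 bp span partitioned into gene
#' regions A--D by the three recombination breakpoints observed in the H1
#' (one crossover) and H2 (two crossovers) hermaphroditic haplotypes. The
#' C/D breakpoint sits exactly 47 kb upstream of VviAPT3. Marker sites are
#' placed uniformly at random within regions (none in region B, which
#' harbours no sex-linked SNPs; region B instead receives H-diagnostic
#' markers that track haplotype ancestry) and then fixed by \code{seed}, so
#' the default model is fully deterministic.
#'
#' @param chrom chromosome name (default \code{"chr2"}).
#' @param sdrStart first base of the SDR on the f-reference.
#' @param sdrWidth SDR width in bp (default 145,500).
#' @param breakpoints named numeric \code{c(bAB=, bBC=, bCD=)}; defaults give
#'   regions of 25, 20, 45 and 55.5 kb.
#' @param nSites number of sex-linked sites, split across regions A/C/D in
#'   proportion to their widths (default 1,066).
#' @param nDiagnosticB number of H1-vs-H2 diagnostic markers placed in
#'   region B (default 30).
#' @param flankWidth width of each flanking interval (default 50 kb).
#' @param geneTable gene map as returned by [defaultGeneTable()].
#' @param seed integer seed fixing the random site placement and allele
#'   bases.
#' @return a validated [SDRModel].
#' @examples
#' model <- buildSDRModel()
#' model
#' @export
buildSDRModel <- function(chrom = "chr2",
                          sdrStart = 1000001L,
                          sdrWidth = 145500L,
                          breakpoints = c(bAB = sdrStart + 25000L,
                                          bBC = sdrStart + 45000L,
                                          bCD = sdrStart + 90000L),
                          nSites = 1066L,
                          nDiagnosticB = 30L,
                          flankWidth = 50000L,
                          geneTable = defaultGeneTable(sdrStart),
                          seed = 101L) {
  sdrEnd <- sdrStart + sdrWidth - 1L
  bp <- breakpoints[c("bAB", "bBC", "bCD")]
  if (anyNA(bp)) stop("breakpoints must be named bAB, bBC, bCD")
  if (!(sdrStart < bp["bAB"] && bp["bAB"] < bp["bBC"] &&
        bp["bBC"] < bp["bCD"] && bp["bCD"] < sdrEnd))
    stop("breakpoints out of order: need sdrStart < bAB < bBC < bCD < sdrEnd")

  regionBounds <- c(A = sdrStart, B = unname(bp["bAB"]), C = unname(bp["bBC"]),
                    D = unname(bp["bCD"]), end = sdrEnd + 1)
  widths <- diff(regionBounds)
  names(widths) <- c("A", "B", "C", "D")

  # site counts proportional to A/C/D widths, remainder to D
  acd <- widths[c("A", "C", "D")]
  nACD <- floor(nSites * acd / sum(acd))
  nACD["D"] <- nSites - nACD["A"] - nACD["C"]

  placeSites <- function(region, n) {
    lo <- regionBounds[region]
    hi <- regionBounds[match(region, names(widths)) + 1L] - 1
    sort(sample(seq(lo, hi), n))
  }
  set.seed(seed)
  posA <- placeSites("A", nACD["A"])
  posB <- if (nDiagnosticB > 0) placeSites("B", nDiagnosticB) else integer()
  posC <- placeSites("C", nACD["C"])
  posD <- placeSites("D", nACD["D"])
  pos <- c(posA, posB, posC, posD)
  cls <- c(rep("sexlinked", length(posA)), rep("diagnostic", length(posB)),
           rep("sexlinked", length(posC)), rep("sexlinked", length(posD)))
  o <- order(pos)
  pos <- pos[o]; cls <- cls[o]
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, length(pos), replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))

  sites <- GRanges(chrom, IRanges(pos, width = 1L))
  mcols(sites)$region <- regionOfBounds(pos, regionBounds)
  mcols(sites)$class <- cls
  mcols(sites)$ref <- ref
  mcols(sites)$alt <- unname(alt)

  genes <- GRanges(chrom, IRanges(geneTable$start, geneTable$end),
                   strand = geneTable$strand)
  mcols(genes)$name <- geneTable$name
  mcols(genes)$region <- regionOfBounds(geneTable$start, regionBounds)

  # synthetic VviINP1 amplicon: 220 bp intact allele containing the 8 bp
  # motif; the f allele lacks the motif (212 bp)
  motif <- paste(sample(bases, 8L, replace = TRUE), collapse = "")
  ampL <- paste(sample(bases, 100L, replace = TRUE), collapse = "")
  ampR <- paste(sample(bases, 112L, replace = TRUE), collapse = "")
  intact <- paste0(ampL, motif, ampR)
  deleted <- paste0(ampL, ampR)

  new("SDRModel",
      chrom = chrom, sdrStart = as.numeric(sdrStart), sdrEnd = as.numeric(sdrEnd),
      breakpoints = as.numeric(bp) |> stats::setNames(c("bAB", "bBC", "bCD")),
      flankLeft = IRanges(sdrStart - flankWidth, sdrStart - 1L),
      flankRight = IRanges(sdrEnd + 1L, sdrEnd + flankWidth),
      sites = sites, geneMap = genes,
      inp1Motif = motif,
      inp1Alleles = c(intact = intact, deleted = deleted),
      seed = as.integer(seed))
}

regionOfBounds <- function(pos, regionBounds) {
  c("A", "B", "C", "D")[findInterval(pos, regionBounds[1:4])]
}

#' Map positions to SDR regions
#'
#' @param model an [SDRModel].
#' @param pos positions on the f-reference.
#' @return character vector of region labels (A/B/C/D), \code{NA} outside
#'   the SDR.
#' @export
regionOfPosition <- function(model, pos) {
  out <- rep(NA_character_, length(pos))
  inside <- pos >= model@sdrStart & pos <= model@sdrEnd
  bounds <- c(model@sdrStart, model@breakpoints, model@sdrEnd + 1)
  out[inside] <- regionOfBounds(pos[inside], bounds)
  out
}

#' Accessors for SDRModel components
#'
#' @param model an [SDRModel].
#' @return \code{sdrSites}: site \code{GRanges}; \code{sdrGenes}: gene
#'   \code{GRanges}; \code{sdrBreakpointPositions}: named breakpoint
#'   positions; \code{sdrRegions}: \code{GRanges} of the four region
#'   intervals; \code{sdrSpan}: \code{GRanges} of the SDR itself;
#'   \code{sdrFlanks}: \code{GRanges} of the two flanking intervals.
#' @examples
#' sdrRegions(buildSDRModel())
#' @export
sdrSites <- function(model) model@sites

#' @rdname sdrSites
#' @export
sdrGenes <- function(model) model@geneMap

#' @rdname sdrSites
#' @export
sdrBreakpointPositions <- function(model) model@breakpoints

#' @rdname sdrSites
#' @export
sdrSpan <- function(model)
  GRanges(model@chrom, IRanges(model@sdrStart, model@sdrEnd))

#' @rdname sdrSites
#' @export
sdrRegions <- function(model) {
  b <- model@breakpoints
  gr <- GRanges(model@chrom,
                IRanges(c(model@sdrStart, b),
                        end = c(b - 1, model@sdrEnd)))
  mcols(gr)$region <- c("A", "B", "C", "D")
  gr
}

#' @rdname sdrSites
#' @export
sdrFlanks <- function(model) {
  gr <- GRanges(model@chrom, c(model@flankLeft, model@flankRight))
  mcols(gr)$side <- c("left", "right")
  gr
}

#' Haplotype ancestry along the SDR
#'
#' Each SDR haplotype is a mosaic of f- and M-derived segments: \code{f} and
#' \code{M} are unrecombined; \code{H1} switches from f to M ancestry at the
#' B/C breakpoint; \code{H2} is M-derived between the A/B and C/D breakpoints
#' and f-derived outside them.
#'
#' @param model an [SDRModel].
#' @param haplotype one of \code{"f"}, \code{"M"}, \code{"H1"}, \code{"H2"}.
#' @param pos positions to evaluate (default: the model's site positions).
#' @return character vector of \code{"f"}/\code{"M"} ancestry at \code{pos}.
#' @examples
#' m <- buildSDRModel()
#' table(haplotypeAncestry(m, "H2"))
#' @export
haplotypeAncestry <- function(model, haplotype, pos = start(sdrSites(model))) {
  haplotype <- match.arg(haplotype, sdrHaplotypes())
  b <- model@breakpoints
  switch(haplotype,
    f = rep("f", length(pos)),
    M = rep("M", length(pos)),
    H1 = ifelse(pos < b["bBC"], "f", "M"),
    H2 = ifelse(pos >= b["bAB"] & pos < b["bCD"], "M", "f"))
}

#' Haplotype allele templates over the model sites
#'
#' Returns the allele carried by each haplotype at every marker site, coded
#' 0 = f-allele, 1 = M-allele. Alleles follow ancestry: a site on an
#' M-derived segment carries the M-allele. The attribute \code{"inp1"}
#' records each haplotype's VviINP1 state (\code{"deleted"} for f,
#' \code{"intact"} for M/H1/H2).
#'
#' @param model an [SDRModel].
#' @return integer matrix sites x haplotypes with attribute \code{inp1}.
#' @export
haplotypeTemplates <- function(model) {
  pos <- start(sdrSites(model))
  haps <- sdrHaplotypes()
  tpl <- vapply(haps, function(h)
    as.integer(haplotypeAncestry(model, h, pos) == "M"),
    integer(length(pos)))
  rownames(tpl) <- as.character(pos)
  attr(tpl, "inp1") <- c(f = "deleted", M = "intact", H1 = "intact",
                         H2 = "intact")
  tpl
}

#' Compose a diploid genotype from two haplotype templates
#'
#' @param model an [SDRModel].
#' @param h1,h2 haplotype names.
#' @return integer vector over model sites: count of M-alleles (0/1/2).
#' @examples
#' table(composeGenotype(buildSDRModel(), "H1", "H2"))
#' @export
composeGenotype <- function(model, h1, h2) {
  tpl <- haplotypeTemplates(model)
  unname(tpl[, h1] + tpl[, h2])
}

#' Flower-sex phenotype of a haplotype pair
#'
#' Applies the dominance rule M > H > f: any M haplotype gives a male
#' flower, otherwise any H haplotype gives a hermaphroditic flower,
#' otherwise the flower is female. This is equivalent to the two-factor
#' decomposition used throughout the package: an accession is
#' female-sterile iff at least one haplotype has M ancestry in region A,
#' and male-sterile iff no haplotype has M ancestry in region C.
#'
#' @param h1,h2 haplotype names in \code{f, M, H1, H2}.
#' @return one of \code{"female"}, \code{"male"}, \code{"hermaphrodite"}.
#' @examples
#' phenotypeOf("M", "f")
#' phenotypeOf("H1", "H2")
#' @export
phenotypeOf <- function(h1, h2) {
  haps <- c(h1, h2)
  if (!all(haps %in% sdrHaplotypes()))
    stop("haplotypes must be among f, M, H1, H2")
  if ("M" %in% haps) "male"
  else if (any(c("H1", "H2") %in% haps)) "hermaphrodite"
  else "female"
}

#' Per-region ancestry signature of a haplotype
#'
#' @param haplotype haplotype name.
#' @return integer vector over regions A--D: 1 where the haplotype is
#'   M-derived.
#' @keywords internal
regionAncestrySignature <- function(haplotype) {
  switch(match.arg(haplotype, sdrHaplotypes()),
    f = c(A = 0L, B = 0L, C = 0L, D = 0L),
    M = c(A = 1L, B = 1L, C = 1L, D = 1L),
    H1 = c(A = 0L, B = 0L, C = 1L, D = 1L),
    H2 = c(A = 0L, B = 1L, C = 1L, D = 0L))
}

#' Numeric-genotype signatures of the ten diploid classes
#'
#' For each unordered pair of SDR haplotypes, the per-region numeric
#' genotype (0 = homozygous f-allele, 1 = heterozygous, 2 = homozygous
#' M-allele) obtained by summing the two per-region ancestry signatures.
#' The ten signatures are pairwise distinct, which is what makes region
#' genotyping invertible into a haplotype-combination call.
#'
#' @return integer matrix, 10 classes x regions A--D.
#' @examples
#' classSignatures()
#' @export
classSignatures <- function() {
  cls <- sdrClasses()
  sig <- t(vapply(cls, function(lab) {
    pair <- classPair(lab)
    regionAncestrySignature(pair[1]) + regionAncestrySignature(pair[2])
  }, integer(4)))
  colnames(sig) <- c("A", "B", "C", "D")
  sig
}

#' Phenotype from the two-factor region rule
#'
#' @param aState,cState numeric genotype of regions A and C (0/1/2).
#' @return list with logical \code{femaleSterile}, \code{maleSterile} and
#'   the implied \code{phenotype}.
#' @keywords internal
phenotypeFromFactors <- function(aState, cState) {
  fs <- aState >= 1
  ms <- cState == 0
  phen <- if (fs && ms) "inconsistent"
          else if (fs) "male"
          else if (ms) "female"
          else "hermaphrodite"
  list(femaleSterile = fs, maleSterile = ms, phenotype = phen)
}
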