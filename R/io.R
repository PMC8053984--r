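#' Write a genotype panel as VCF v4.2
#'
#' Emits a minimal single-chromosome VCF with GT fields: genotype 0 ->
#' \code{0/0}, 1 -> \code{0/1}, 2 -> \code{1/1}, missing -> \code{./.}.
#' REF/ALT are the model's f- and M-allele bases carried on the panel's
#' \code{rowRanges}.
#'
#' @param panel a [GenotypePanel].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writePanelVcf <- function(panel, path) {
  rr <- rowRanges(panel)
  g <- assay(panel, "genotype")
  gt <- matrix(c("0/0", "0/1", "1/1")[g + 1L], nrow(g), ncol(g))
  gt[is.na(g)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", as.character(seqnames(rr))[1], ">"),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(g)), collapse = "\t"))
  body <- paste(as.character(seqnames(rr)), start(rr),
                paste0("site", seq_along(rr)),
                mcols(rr)$ref, mcols(rr)$alt, ".", "PASS",
                paste0("REGION=", mcols(rr)$region), "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genotypes back from a GT-only VCF
#'
#' Thin wrapper over \code{vcfR} returning the dosage matrix and positions;
#' used for round-tripping panels written by [writePanelVcf()].
#'
#' @param path VCF file path.
#' @return list: \code{genotype} (sites x samples integer matrix),
#'   \code{position}, \code{chrom}, \code{ref}, \code{alt}.
#' @export
readPanelVcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gtChar <- vcfR::extract.gt(v, element = "GT")
  geno <- matrix(NA_integer_, nrow(gtChar), ncol(gtChar),
                 dimnames = dimnames(gtChar))
  geno[gtChar == "0/0"] <- 0L
  geno[gtChar == "0/1" | gtChar == "1/0"] <- 1L
  geno[gtChar == "1/1"] <- 2L
  list(genotype = geno,
       position = as.integer(v@fix[, "POS"]),
       chrom = v@fix[, "CHROM"],
       ref = v@fix[, "REF"], alt = v@fix[, "ALT"])
}

#' Write an allele depth table as TSV
#'
#' Long format with columns sample, chrom, pos, ref_count, alt_count.
#'
#' @param depths an [AlleleDepthTable].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeDepthTsv <- function(depths, path) {
  rr <- rowRanges(depths)
  refM <- assay(depths, "ref"); altM <- assay(depths, "alt")
  df <- data.frame(
    sample = rep(colnames(refM), each = nrow(refM)),
    chrom = rep(as.character(seqnames(rr)), ncol(refM)),
    pos = rep(start(rr), ncol(refM)),
    ref_count = as.vector(refM), alt_count = as.vector(altM))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an allele depth TSV into an AlleleDepthTable
#'
#' @param path TSV with columns sample, chrom, pos, ref_count, alt_count.
#' @param source \code{"DNA"} or \code{"RNA"}.
#' @return an [AlleleDepthTable].
#' @export
readDepthTsv <- function(path, source = c("DNA", "RNA")) {
  source <- match.arg(source)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("sample", "chrom", "pos", "ref_count", "alt_count")
  if (!all(need %in% names(df)))
    stop("TSV must have columns ", paste(need, collapse = ", "))
  pos <- sort(unique(df$pos))
  samples <- unique(df$sample)
  refM <- altM <- matrix(0L, length(pos), length(samples),
                         dimnames = list(NULL, samples))
  i <- match(df$pos, pos); j <- match(df$sample, samples)
  refM[cbind(i, j)] <- as.integer(df$ref_count)
  altM[cbind(i, j)] <- as.integer(df$alt_count)
  rr <- GRanges(df$chrom[match(pos, df$pos)], IRanges(pos, width = 1))
  se <- SummarizedExperiment(assays = list(ref = refM, alt = altM),
                             rowRanges = rr)
  metadata(se) <- list(source = source)
  new("AlleleDepthTable", se)
}

#' Export model regions and genes as BED6
#'
#' @param model an [SDRModel].
#' @param path output BED path.
#' @param what \code{"regions"} or \code{"genes"}.
#' @return \code{path}, invisibly.
#' @export
exportModelBed <- function(model, path, what = c("regions", "genes")) {
  what <- match.arg(what)
  gr <- if (what == "regions") sdrRegions(model) else sdrGenes(model)
  mcols(gr)$name <- if (what == "regions") mcols(gr)$region
                    else mcols(gr)$name
  mcols(gr)$score <- 0
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Export a window depth track as bedGraph
#'
#' @param track a track \code{GRanges} (normalized if available, else raw).
#' @param path output bedGraph path.
#' @return \code{path}, invisibly.
#' @export
exportTrackBedGraph <- function(track, path) {
  gr <- GenomicRanges::granges(track)
  mcols(gr)$score <- if (!is.null(mcols(track)$depth)) mcols(track)$depth
                     else mcols(track)$raw
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Write per-site scan statistics as TSV
#'
#' Includes \code{-log10} transformed Hardy-Weinberg p-values alongside the
#' minor allele frequency and cosegregation mismatch counts.
#'
#' @param stats \code{DataFrame} from [cosegregationScan()].
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeSiteStatsTsv <- function(stats, path) {
  df <- as.data.frame(stats)
  df$negLog10HweP <- -log10(df$hweP)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
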