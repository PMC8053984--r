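#' Simulate bulked-pool window depth tracks
#'
#' Emulates the bulk-segregant design used to delineate the SDR: shotgun
#' reads from a pool of female (f/f) and a pool of male (M/f) accessions are
#' mapped uniquely to a two-haplotype assembly (f-hap and M-hap), and unique
#' mapping depth is summarised per fixed-width window. Expected normalized
#' depth, in units where the collapsed flanking sequence is 2: inside the
#' SDR the female bulk maps 2 on the f-hap and 0 on the M-hap, while the
#' male bulk maps 1 on each; the flanks are 2 everywhere. Raw depths are
#' Poisson with mean \code{unitCoverage} per 1-unit of expected depth, plus
#' a small mismapping background.
#'
#' @param model an [SDRModel].
#' @param nFemale,nMale pool sizes (>= 1); they set the pool labels only,
#'   coverage is controlled by \code{unitCoverage}.
#' @param unitCoverage expected raw reads per window per normalized unit.
#' @param windowWidth window width in bp (> 0; default 500).
#' @param mismapRate background depth (fraction of \code{unitCoverage})
#'   added to every window, emulating rare mismapped reads.
#' @param noise \code{"poisson"} for sampled depths, \code{"none"} for the
#'   expectation itself.
#' @param seed integer seed.
#' @return named list of four \code{GRanges} tracks (\code{female.f},
#'   \code{female.M}, \code{male.f}, \code{male.M}) with metadata columns
#'   \code{raw} (raw depth) and \code{flank} (logical), and track-level
#'   \code{metadata()} giving pool, haplotype assembly and coverage.
#' @examples
#' tr <- simulateBulkDepths(buildSDRModel(), unitCoverage = 30, seed = 1)
#' sapply(tr, function(x) mean(x$raw[!x$flank]))
#' @export
simulateBulkDepths <- function(model, nFemale = 13L, nMale = 13L,
                               unitCoverage = 30, windowWidth = 500L,
                               mismapRate = 0.01,
                               noise = c("poisson", "none"), seed = 1L) {
  noise <- match.arg(noise)
  if (windowWidth <= 0) stop("windowWidth must be positive")
  if (nFemale < 1 || nMale < 1) stop("pool sizes must be >= 1")

  lo <- start(model@flankLeft)
  hi <- end(model@flankRight)
  starts <- seq(lo, hi, by = windowWidth)
  wins <- GRanges(model@chrom,
                  IRanges(starts, width = pmin(windowWidth, hi - starts + 1)))
  mid <- (start(wins) + end(wins)) / 2
  inSDR <- mid >= model@sdrStart & mid <= model@sdrEnd

  expectedFold <- list(
    female.f = ifelse(inSDR, 2, 2),
    female.M = ifelse(inSDR, 0, 2),
    male.f   = ifelse(inSDR, 1, 2),
    male.M   = ifelse(inSDR, 1, 2))

  set.seed(seed)
  out <- lapply(names(expectedFold), function(nm) {
    lambda <- unitCoverage * (expectedFold[[nm]] + mismapRate)
    raw <- if (noise == "poisson") stats::rpois(length(lambda), lambda)
           else lambda
    gr <- wins
    mcols(gr)$raw <- raw
    mcols(gr)$flank <- !inSDR
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    metadata(gr) <- list(pool = paste0(parts[1], "-bulk"),
                         haplotype = paste0(parts[2], "-hap"),
                         unitCoverage = unitCoverage,
                         poolSize = if (parts[1] == "female") nFemale else nMale)
    gr
  })
  names(out) <- names(expectedFold)
  out
}

#' Normalize a window depth track by its flanking median
#'
#' Divides raw window depths by half the median raw depth of the flanking
#' windows, so that the collapsed (shared-sequence) flanks sit at 2.0
#' normalized units and a single haplotype dose corresponds to 1.0.
#'
#' @param track a \code{GRanges} with metadata columns \code{raw} and
#'   \code{flank}, as produced by [simulateBulkDepths()].
#' @return the track with an added \code{depth} column of normalized units.
#' @export
normalizeTrack <- function(track) {
  flank <- mcols(track)$flank
  if (sum(flank) < 20) stop("need at least 20 flank windows to normalize")
  med <- stats::median(mcols(track)$raw[flank])
  if (med <= 0) stop("flank median depth is zero; cannot normalize")
  mcols(track)$depth <- mcols(track)$raw / (med / 2)
  track
}

#' Classify normalized depth into fold classes
#'
#' @param depth normalized depth (>= 0).
#' @return character vector in \code{"0x"}, \code{"1x"}, \code{"2x"}:
#'   \code{2x} for depth >= 1.5, \code{1x} for [0.5, 1.5), \code{0x} below.
#' @examples
#' classifyFold(c(0.05, 1.02, 1.98))
#' @export
classifyFold <- function(depth) {
  if (any(depth < 0)) stop("normalized depth must be non-negative")
  ifelse(depth >= 1.5, "2x", ifelse(depth >= 0.5, "1x", "0x"))
}

# majority vote over a centered k-window kernel
majoritySmooth <- function(x, k = 5L) {
  n <- length(x)
  half <- k %/% 2
  out <- logical(n)
  cs <- cumsum(c(0L, as.integer(x)))
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    out[i] <- (cs[hi + 1L] - cs[lo]) * 2L > (hi - lo + 1L)
  }
  out
}

#' Delineate the SDR from classified bulk depth tracks
#'
#' Finds, on each haplotype assembly, the longest run of windows whose fold
#' pattern matches the SDR expectation -- female bulk 2x with male bulk 1x
#' on the f-hap; female 0x with male 1x on the M-hap -- after smoothing
#' isolated discordant windows by majority vote in a 5-window kernel. A
#' diagnostic checks that both pools are 2x across the flanks.
#'
#' @param tracks named list of four tracks as from [simulateBulkDepths()]
#'   (\code{female.f}, \code{female.M}, \code{male.f}, \code{male.M}); raw
#'   tracks are normalized on the fly.
#' @param minRunWindows minimum qualifying run length (default 20).
#' @return a \code{GRanges} with one interval per assembly (metadata column
#'   \code{haplotype}; empty if no qualifying run) and metadata
#'   \code{flankDiagnostic}, the fraction of flank windows at 2x in all four
#'   tracks.
#' @examples
#' tr <- simulateBulkDepths(buildSDRModel(), unitCoverage = 30, seed = 1)
#' delineateSDR(tr)
#' @export
delineateSDR <- function(tracks, minRunWindows = 20L) {
  need <- c("female.f", "female.M", "male.f", "male.M")
  if (!all(need %in% names(tracks)))
    stop("tracks must be named ", paste(need, collapse = ", "))
  tracks <- lapply(tracks[need], function(tr) {
    if (is.null(mcols(tr)$depth)) tr <- normalizeTrack(tr)
    tr
  })
  fold <- lapply(tracks, function(tr) classifyFold(mcols(tr)$depth))
  flank <- mcols(tracks[[1]])$flank
  flankOK <- Reduce(`&`, lapply(fold, function(f) f[flank] == "2x"))
  diag <- mean(flankOK)

  findRun <- function(ok) {
    ok <- majoritySmooth(ok, 5L)
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cand <- which(r$values & r$lengths >= minRunWindows)
    if (!length(cand)) return(NULL)
    best <- cand[which.max(r$lengths[cand])]
    c(starts[best], ends[best])
  }

  wins <- GenomicRanges::granges(tracks[[1]])
  res <- list(
    `f-hap` = findRun(fold$female.f == "2x" & fold$male.f == "1x"),
    `M-hap` = findRun(fold$female.M == "0x" & fold$male.M == "1x"))
  keep <- !vapply(res, is.null, logical(1))
  if (!any(keep)) {
    out <- GRanges()
  } else {
    i1 <- vapply(res[keep], function(x) x[1], integer(1))
    i2 <- vapply(res[keep], function(x) x[2], integer(1))
    out <- GRanges(unique(as.character(seqnames(wins)))[1],
                   IRanges(start(wins)[i1], end(wins)[i2]))
    mcols(out)$haplotype <- names(res)[keep]
  }
  metadata(out) <- list(flankDiagnostic = diag)
  out
}
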