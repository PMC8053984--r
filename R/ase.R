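#' Permutation test for allele-specific expression association
#'
#' Tests, at one transcribed polymorphic site, whether the M-allele read
#' fraction differs between the two levels of a flower-sex factor
#' (typically female-sterile yes/no). Samples with total depth below
#' \code{minDepth} are dropped; the statistic is the difference in mean
#' M-allele fraction between groups, and its two-sided p-value comes from
#' random label permutations with the add-one rule
#' \eqn{p = (1 + \#\{|T^*| \ge |T|\}) / (1 + n_{perm})}.
#'
#' @param ref,alt per-sample read counts for the f- and M-allele.
#' @param group logical (or two-level) factor per sample.
#' @param minDepth minimum total depth to retain a sample (default 10).
#' @param nPerm number of permutations (default 10,000).
#' @param seed integer seed.
#' @return list: \code{statistic}, \code{p}, group means, per-group sample
#'   sizes after filtering, and \code{valid} (both groups have >= 2
#'   samples).
#' @examples
#' aseSiteTest(rep(25, 8), c(25, 25, 25, 25, 0, 0, 0, 0),
#'             rep(c(TRUE, FALSE), each = 4), nPerm = 200, seed = 1)
#' @export
aseSiteTest <- function(ref, alt, group, minDepth = 10L, nPerm = 10000L,
                        seed = 1L) {
  group <- as.logical(group)
  if (anyNA(group)) stop("group must be a binary factor without NAs")
  keep <- (ref + alt) >= minDepth
  ref <- ref[keep]; alt <- alt[keep]; g <- group[keep]
  n1 <- sum(g); n0 <- sum(!g)
  if (n1 == 0 || n0 == 0)
    stop("a phenotype group is empty after depth filtering")
  frac <- alt / (ref + alt)
  stat <- mean(frac[g]) - mean(frac[!g])
  set.seed(seed)
  eps <- 1e-12
  nExtreme <- 0L
  for (b in seq_len(nPerm)) {
    gp <- sample(g)
    if (abs(mean(frac[gp]) - mean(frac[!gp])) >= abs(stat) - eps)
      nExtreme <- nExtreme + 1L
  }
  list(statistic = stat, p = (1 + nExtreme) / (1 + nPerm),
       meanGroup1 = mean(frac[g]), meanGroup0 = mean(frac[!g]),
       n1 = n1, n0 = n0, valid = n1 >= 2 && n0 >= 2)
}

#' ASE association scan over a count table
#'
#' Applies [aseSiteTest()] to every site of an [AseCountTable] against one
#' of its flower-sex factors, and attaches Benjamini-Hochberg adjusted
#' p-values for flagging (raw permutation p-values are reported).
#'
#' @param ase an [AseCountTable].
#' @param factorName \code{"femaleSterile"} (default) or
#'   \code{"maleSterile"}.
#' @param minDepth,nPerm forwarded to [aseSiteTest()].
#' @param seed integer seed (one sub-seed per site is derived from it).
#' @return \code{DataFrame}: position, gene, statistic, p, negLog10P,
#'   padj, group means and sizes, valid flag. Sites where a group is empty
#'   after filtering are skipped.
#' @export
aseScan <- function(ase, factorName = c("femaleSterile", "maleSterile"),
                    minDepth = 10L, nPerm = 10000L, seed = 1L) {
  factorName <- match.arg(factorName)
  grp <- colData(ase)[[factorName]]
  refM <- assay(ase, "ref"); altM <- assay(ase, "alt")
  pos <- start(rowRanges(ase))
  gene <- mcols(rowRanges(ase))$gene
  rows <- list()
  for (i in seq_len(nrow(refM))) {
    res <- tryCatch(
      aseSiteTest(refM[i, ], altM[i, ], grp, minDepth, nPerm,
                  seed = seed + i),
      error = function(e) NULL)
    if (is.null(res)) next
    rows[[length(rows) + 1L]] <- DataFrame(
      position = pos[i], gene = gene[i], statistic = res$statistic,
      p = res$p, negLog10P = -log10(res$p),
      meanGroup1 = res$meanGroup1, meanGroup0 = res$meanGroup0,
      n1 = res$n1, n0 = res$n0, valid = res$valid)
  }
  if (!length(rows)) return(DataFrame())
  out <- do.call(rbind, rows)
  out$padj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Rank ASE association results
#'
#' @param results \code{DataFrame} from [aseScan()] (>= 1 row).
#' @return the table ordered by decreasing \code{-log10(p)}, ties broken by
#'   position.
#' @export
rankSites <- function(results) {
  if (!nrow(results)) stop("no results to rank")
  results[order(-results$negLog10P, results$position), , drop = FALSE]
}
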