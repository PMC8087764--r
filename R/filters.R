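#' SNP filter cascade: missingness and minor-allele frequency
#'
#' Applies, in this order: (1) remove sites with more than
#' \code{maxSiteMissing} missing genotypes, (2) remove samples with more
#' than \code{maxSampleMissing} missing genotypes (over the surviving
#' sites), (3) remove sites whose minor-allele frequency, recomputed after
#' the removals, is below \code{mafMin}.  The order is fixed and reported
#' because the upstream tools leave it unspecified.
#'
#' @param gd a \linkS4class{GenotypeData}.
#' @param mafMin minimum minor-allele frequency (default 1\%).
#' @param maxSiteMissing maximum missing fraction per site (default 50\%).
#' @param maxSampleMissing maximum missing fraction per sample.
#' @return list(geno = filtered GenotypeData, report = data.frame with the
#'   count removed at each step).
#' @export
filterSites <- function(gd, mafMin = 0.01, maxSiteMissing = 0.5,
                        maxSampleMissing = 0.5) {
  d <- dosages(gd)
  siteMiss <- rowMeans(is.na(d))
  keepSite <- siteMiss <= maxSiteMissing
  nSiteRm <- sum(!keepSite)
  d1 <- d[keepSite, , drop = FALSE]
  sampMiss <- colMeans(is.na(d1))
  keepSamp <- sampMiss <= maxSampleMissing
  nSampRm <- sum(!keepSamp)
  d2 <- d1[, keepSamp, drop = FALSE]
  p <- rowMeans(d2, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0
  keepMAF <- maf >= mafMin & !is.nan(p)
  nMafRm <- sum(!keepMAF)
  out <- gd[which(keepSite)[keepMAF], keepSamp]
  if (nrow(out) == 0) warning("no sites survive the filter cascade")
  report <- data.frame(
    step = c("input", "site_missingness", "sample_missingness", "maf"),
    removed = c(0L, nSiteRm, nSampRm, nMafRm),
    sitesLeft = c(nrow(d), nrow(d1), nrow(d1), nrow(out)),
    samplesLeft = c(ncol(d), ncol(d), ncol(d2), ncol(out)))
  list(geno = out, report = report)
}

#' Hardy-Weinberg exact test
#'
#' Two-sided exact p-value for a biallelic genotype table: with the allele
#' counts fixed, the probabilities of all heterozygote counts of the same
#' parity are enumerated, and those no larger than the observed table's
#' probability are summed.  Monomorphic tables give p = 1.
#'
#' @param nAA,nAa,naa genotype counts.
#' @return p-value in (0, 1].
#' @examples
#' hweExactP(1, 3, 1)
#' @export
hweExactP <- function(nAA, nAa, naa) {
  stopifnot(nAA >= 0, nAa >= 0, naa >= 0)
  n <- nAA + nAa + naa
  if (n < 1) stop("need at least one genotype")
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  if (nA == 0 || na == 0) return(1)
  hets <- seq(nAa %% 2, min(nA, na), by = 2)
  # log P(nAa = h | nA, na, n) up to a common constant
  lp <- lgamma(n + 1) - lgamma((nA - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma((na - hets) / 2 + 1) + hets * log(2)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[match(nAa, hets)]
  min(1, sum(pr[pr <= obs + 1e-12 * obs]))
}

#' Hardy-Weinberg exact test across the sites of a GenotypeData
#'
#' @param gd a \linkS4class{GenotypeData}.
#' @param perPopulation if TRUE, test within each population and return the
#'   minimum p per site (a deviation anywhere flags the site); the default
#'   tests all samples jointly.
#' @return p-value per site.
#' @export
hweTest <- function(gd, perPopulation = FALSE) {
  d <- dosages(gd)
  testMat <- function(m) {
    apply(m, 1, function(x) {
      x <- x[!is.na(x)]
      if (!length(x)) return(NA_real_)
      hweExactP(sum(x == 0), sum(x == 1), sum(x == 2))
    })
  }
  if (!perPopulation) return(testMat(d))
  pops <- populationsOf(gd)
  ps <- vapply(unique(pops), function(pp)
    testMat(d[, pops == pp, drop = FALSE]), numeric(nrow(d)))
  apply(as.matrix(ps), 1, function(x)
    if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE))
}

# squared dosage correlation with pairwise-complete observations
.r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
  cor(x[ok], y[ok])^2
}

#' Windowed linkage-disequilibrium pruning
#'
#' Greedy left-to-right scan: within each window (sites closer than
#' \code{windowBp}), any pair with squared dosage correlation above
#' \code{r2Max} loses its later-positioned member.  The surviving set
#' contains no intra-window pair exceeding the threshold.  The step size is
#' recorded for provenance; a greedy scan with per-site anchoring is
#' equivalent to sliding the window by any step no larger than the minimum
#' inter-site spacing.
#'
#' @param gd a \linkS4class{GenotypeData}.
#' @param r2Max prune threshold on r-squared (default 0.25).
#' @param windowBp window span in bp (default 100 kbp).
#' @param stepBp nominal window step in bp (default 100).
#' @return integer indices of the retained sites.
#' @export
ldPrune <- function(gd, r2Max = 0.25, windowBp = 1e5, stepBp = 100) {
  if (windowBp <= 0) stop("windowBp must be positive")
  rr <- SummarizedExperiment::rowRanges(gd)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  d <- dosages(gd)
  keep <- rep(TRUE, nrow(d))
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    for (ii in seq_along(idx)) {
      i <- idx[ii]
      if (!keep[i]) next
      jj <- ii + 1
      while (jj <= length(idx) && pos[idx[jj]] - pos[i] < windowBp) {
        j <- idx[jj]
        if (keep[j]) {
          r2 <- .r2(d[i, ], d[j, ])
          if (!is.na(r2) && r2 > r2Max) keep[j] <- FALSE
        }
        jj <- jj + 1
      }
    }
  }
  which(keep)
}

#' Linkage-disequilibrium decay table
#'
#' Pairwise r-squared against inter-site distance, binned, per population.
#' Pairs below \code{r2Min} are excluded (matching the upstream reporting
#' convention); pairs farther apart than \code{maxBp} are skipped.
#'
#' @param gd a \linkS4class{GenotypeData}.
#' @param r2Min minimum reported r-squared (default 0.001).
#' @param binBp distance bin width.
#' @param maxBp maximum pair distance considered.
#' @param byPopulation compute within each population separately.
#' @return data.frame(population, bin, distance, meanR2, nPairs).
#' @export
ldDecay <- function(gd, r2Min = 0.001, binBp = 1000, maxBp = 1e5,
                    byPopulation = TRUE) {
  rr <- SummarizedExperiment::rowRanges(gd)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  pops <- populationsOf(gd)
  groups <- if (byPopulation) unique(pops) else "all"
  out <- list()
  for (gname in groups) {
    d <- if (identical(gname, "all")) dosages(gd) else
      dosages(gd)[, pops == gname, drop = FALSE]
    dist <- numeric(0); r2v <- numeric(0)
    for (cc in unique(chrom)) {
      idx <- which(chrom == cc)
      if (length(idx) < 2) next
      for (a in seq_len(length(idx) - 1)) {
        for (b in (a + 1):length(idx)) {
          dd <- pos[idx[b]] - pos[idx[a]]
          if (dd > maxBp) break
          r2 <- .r2(d[idx[a], ], d[idx[b], ])
          if (!is.na(r2) && r2 >= r2Min) {
            dist <- c(dist, dd); r2v <- c(r2v, r2)
          }
        }
      }
    }
    if (!length(dist)) next
    bin <- floor(dist / binBp)
    agg <- tapply(r2v, bin, mean)
    cnt <- tapply(r2v, bin, length)
    out[[gname]] <- data.frame(
      population = gname, bin = as.integer(names(agg)),
      distance = (as.integer(names(agg)) + 0.5) * binBp,
      meanR2 = as.numeric(agg), nPairs = as.integer(cnt))
  }
  if (!length(out))
    return(data.frame(population = character(), bin = integer(),
                      distance = numeric(), meanR2 = numeric(),
                      nPairs = integer()))
  do.call(rbind, out)
}
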