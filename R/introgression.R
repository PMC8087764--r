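#' ABBA-BABA D statistic from derived-allele frequencies
#'
#' Frequency-weighted Patterson's D over the quartet (((P1, P2), P3), O):
#' per site the ABBA weight is (1-p1) p2 p3 (1-p4) and the BABA weight is
#' p1 (1-p2) p3 (1-p4); D is the normalized difference of their sums.
#' Population samples and single genomes mix naturally, the latter
#' entering as frequencies in \{0, 0.5, 1\}.
#'
#' @param freq matrix or data.frame with columns p1, p2, p3, p4 of
#'   derived-allele frequencies; rows with any missing value are dropped
#'   and counted.
#' @return a \code{DStatResult} list: \code{D}, per-site \code{abba} and
#'   \code{baba} weights, \code{nUsed}, \code{nDropped}.
#' @export
dStatistic <- function(freq) {
  freq <- as.matrix(freq[, c("p1", "p2", "p3", "p4")])
  if (any(freq < 0 | freq > 1, na.rm = TRUE))
    stop("frequencies must lie in [0, 1]")
  ok <- stats::complete.cases(freq)
  f <- freq[ok, , drop = FALSE]
  abba <- (1 - f[, 1]) * f[, 2] * f[, 3] * (1 - f[, 4])
  baba <- f[, 1] * (1 - f[, 2]) * f[, 3] * (1 - f[, 4])
  den <- sum(abba) + sum(baba)
  D <- if (den == 0) {
    warning("zero ABBA+BABA denominator; D undefined")
    NaN
  } else (sum(abba) - sum(baba)) / den
  structure(list(D = D, abba = abba, baba = baba, nUsed = sum(ok),
                 nDropped = sum(!ok)), class = "DStatResult")
}

#' @export
print.DStatResult <- function(x, ...) {
  cat(sprintf("D = %.4f (ABBA sum %.2f, BABA sum %.2f, %d sites)\n",
              x$D, sum(x$abba), sum(x$baba), x$nUsed))
  invisible(x)
}

#' Block-jackknife significance for the D statistic
#'
#' Delete-one-block jackknife over contiguous site blocks: the standard
#' error comes from the jackknife variance of the delete-block estimates,
#' Z = D / SE and the p-value is two-sided normal.  Identical blocks give
#' SE = 0, reported as p = 0 with a degenerate-variance warning.
#'
#' @param abba,baba per-site weights (from \code{\link{dStatistic}}).
#' @param blocks block assignment per site, or a single integer number of
#'   contiguous equal-size blocks (default 20).
#' @return list(D, SE, Z, p, nBlocks, pseudovalues).
#' @export
blockJackknife <- function(abba, baba, blocks = 20) {
  stopifnot(length(abba) == length(baba))
  S <- length(abba)
  if (length(blocks) == 1)
    blocks <- ceiling(seq_len(S) / (S / blocks))
  ub <- unique(blocks)
  B <- length(ub)
  if (B < 5) stop("need at least 5 non-empty blocks")
  num <- sum(abba) - sum(baba)
  den <- sum(abba) + sum(baba)
  D <- num / den
  Dminus <- vapply(ub, function(b) {
    i <- blocks != b
    (sum(abba[i]) - sum(baba[i])) / (sum(abba[i]) + sum(baba[i]))
  }, numeric(1))
  SE <- sqrt((B - 1) / B * sum((Dminus - mean(Dminus))^2))
  if (SE == 0) {
    warning("degenerate jackknife variance (all blocks identical)")
    return(list(D = D, SE = 0, Z = Inf * sign(D), p = 0, nBlocks = B,
                pseudovalues = Dminus))
  }
  Z <- D / SE
  list(D = D, SE = SE, Z = Z, p = 2 * pnorm(-abs(Z)), nBlocks = B,
       pseudovalues = Dminus)
}

#' Admixture fraction f_G
#'
#' Ratio of the observed ABBA-BABA excess to the excess expected under
#' complete introgression from the P3 lineage, with P3's sampled alleles
#' split at random (seeded) into donor and reference halves per site:
#' f_G = S(p1, p2, p3a, p4) / S(p1, p3b, p3a, p4), S being the
#' ABBA-minus-BABA numerator sum.
#'
#' @param freq matrix with columns p1, p2, p4 (derived frequencies).
#' @param p3Derived,p3Total derived and total allele counts in P3 per
#'   site (total >= 2 so the sample can be halved).
#' @param seed seed for the random halving.
#' @return list(fG, numerator, denominator).
#' @export
fAdmixture <- function(freq, p3Derived, p3Total, seed = NULL) {
  stopifnot(all(p3Total >= 2), length(p3Derived) == nrow(freq))
  if (!is.null(seed)) set.seed(seed)
  nA <- floor(p3Total / 2)
  nB <- p3Total - nA
  kA <- rhyper(length(p3Derived), p3Derived, p3Total - p3Derived, nA)
  p3a <- kA / nA
  p3b <- (p3Derived - kA) / nB
  f <- as.matrix(freq)
  Snum <- function(p1, p2, p3, p4)
    sum((1 - p1) * p2 * p3 * (1 - p4) - p1 * (1 - p2) * p3 * (1 - p4))
  num <- Snum(f[, "p1"], f[, "p2"], p3a, f[, "p4"])
  den <- Snum(f[, "p1"], p3b, p3a, f[, "p4"])
  if (den == 0) {
    warning("zero denominator in f_G")
    return(list(fG = NaN, numerator = num, denominator = den))
  }
  list(fG = num / den, numerator = num, denominator = den)
}

#' Windowed local D statistics
#'
#' Sliding SNP-count windows (default 500 SNPs, step 250); a trailing
#' partial window is reported with its size.
#'
#' @param abba,baba per-site weights, in position order.
#' @param window,step window size and step in SNPs.
#' @return data.frame(start, end, n, D) in site indices.
#' @export
windowedD <- function(abba, baba, window = 500, step = 250) {
  S <- length(abba)
  starts <- seq(1, max(1, S - window + 1), by = step)
  last <- starts[length(starts)]
  if (last + window - 1 < S) starts <- c(starts, last + step)
  res <- lapply(starts, function(s) {
    e <- min(s + window - 1, S)
    a <- sum(abba[s:e]); b <- sum(baba[s:e])
    data.frame(start = s, end = e, n = e - s + 1,
               D = if (a + b == 0) NA_real_ else (a - b) / (a + b))
  })
  do.call(rbind, res)
}

#' Classify candidate SNPs by selection direction and ABBA/BABA pattern
#'
#' Candidates are polarized with the outgroup (when two outgroup calls
#' are supplied they must agree, else the site is unknown).  With derived
#' frequencies d_s (wild sororia), d_a (domesticated argyrosperma) and
#' d_m (moschata): an ABBA site has the derived allele shared by the
#' domesticate and moschata but not the wild lineage; BABA is the mirror
#' pattern; otherwise a derived allele (nearly) fixed in only one
#' subspecies marks the direction of selection.  ABBA/BABA take
#' precedence over the selection labels; anything else is unknown.
#'
#' @param freq data.frame with columns snpId, ds, da, dm and optionally
#'   \code{outgroupOk} (FALSE when the outgroups disagree or are
#'   missing).
#' @param hi,lo frequency thresholds (defaults 0.8 / 0.2); these are
#'   analysis conventions, not study-fixed values.
#' @return data.frame(snpId, label) with label in sel_domesticated,
#'   sel_wild, ABBA, BABA, unknown.
#' @export
classifyCandidates <- function(freq, hi = 0.8, lo = 0.2) {
  stopifnot(lo >= 0, hi <= 1, lo < hi)
  ok <- if (is.null(freq$outgroupOk)) rep(TRUE, nrow(freq)) else
    freq$outgroupOk & !is.na(freq$outgroupOk)
  ds <- freq$ds; da <- freq$da; dm <- freq$dm
  lab <- rep("unknown", nrow(freq))
  miss <- is.na(ds) | is.na(da) | is.na(dm) | !ok
  selDom <- !miss & da >= hi & ds <= lo
  selWild <- !miss & ds >= hi & da <= lo
  abba <- selDom & dm >= hi
  baba <- selWild & dm >= hi
  lab[selDom] <- "sel_domesticated"
  lab[selWild] <- "sel_wild"
  lab[abba] <- "ABBA"
  lab[baba] <- "BABA"
  data.frame(snpId = freq$snpId, label = lab)
}

#' Derived-frequency table for a taxon quartet from genotypes
#'
#' @param gd a \linkS4class{GenotypeData} polarized so that REF is
#'   ancestral, or supply \code{aa} calls.
#' @param taxa named list(p1, p2, p3, p4) of population labels.
#' @param aa optional per-site ancestral calls ("REF"/"ALT"/NA).
#' @return data.frame(snpId, p1, p2, p3, p4, p3Derived, p3Total).
#' @export
derivedFreqTable <- function(gd, taxa, aa = NULL) {
  stopifnot(all(c("p1", "p2", "p3", "p4") %in% names(taxa)))
  d <- dosages(gd)
  grp <- populationsOf(gd)
  if (is.null(aa)) aa <- rep("REF", nrow(d))
  out <- data.frame(snpId = rownames(d))
  for (tx in c("p1", "p2", "p3", "p4")) {
    m <- d[, grp %in% taxa[[tx]], drop = FALSE]
    tot <- 2 * rowSums(!is.na(m))
    derived <- rowSums(m, na.rm = TRUE)
    derived <- ifelse(aa == "ALT", tot - derived, derived)
    out[[tx]] <- ifelse(tot > 0 & !is.na(aa), derived / tot, NA_real_)
    if (tx == "p3") {
      out$p3Derived <- as.integer(derived)
      out$p3Total <- as.integer(tot)
    }
  }
  out
}
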