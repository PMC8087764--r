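#' Per-site and per-population nucleotide diversity
#'
#' Unbiased per-site expected heterozygosity n/(n-1) 2 p (1 - p), with n
#' the number of non-missing alleles at the site in the population.  The
#' population mean averages over the variant sites of the data set
#' (per-SNP pi, the reduced-representation convention), not per bp.
#'
#' @param gd a \linkS4class{GenotypeData}.
#' @param by group samples by "population" or "status".
#' @return data.frame(population, pi, nSites), with the per-site values in
#'   attribute \code{"perSite"} (sites x groups matrix).
#' @export
nucleotideDiversity <- function(gd, by = c("population", "status")) {
  by <- match.arg(by)
  cd <- SummarizedExperiment::colData(gd)
  grp <- if (by == "population") cd$population else cd$status
  d <- dosages(gd)
  groups <- unique(grp)
  perSite <- sapply(groups, function(g) {
    m <- d[, grp == g, drop = FALSE]
    n <- 2 * rowSums(!is.na(m))
    p <- rowSums(m, na.rm = TRUE) / n
    pi <- ifelse(n >= 2, n / (n - 1) * 2 * p * (1 - p), NA_real_)
    pi
  })
  perSite <- matrix(perSite, nrow = nrow(d),
                    dimnames = list(rownames(d), groups))
  res <- data.frame(
    population = groups,
    pi = apply(perSite, 2, mean, na.rm = TRUE),
    nSites = apply(perSite, 2, function(x) sum(!is.na(x))),
    row.names = NULL)
  attr(res, "perSite") <- perSite
  res
}

# Weir & Cockerham (1984) per-locus variance components from genotype
# dosages; returns a, b, c per locus.  Uses observed heterozygosity, so it
# is missing-aware: per-locus sample sizes count non-missing diploids.
.wcComponents <- function(d, grp, pops) {
  r <- length(pops)
  S <- nrow(d)
  a <- b <- cc <- rep(NA_real_, S)
  subIdx <- lapply(pops, function(pp) which(grp == pp))
  for (s in seq_len(S)) {
    x <- d[s, ]
    ni <- pi <- hi <- numeric(r)
    for (k in seq_len(r)) {
      xx <- x[subIdx[[k]]]
      xx <- xx[!is.na(xx)]
      ni[k] <- length(xx)
      if (ni[k] > 0) {
        pi[k] <- mean(xx) / 2
        hi[k] <- mean(xx == 1)
      }
    }
    ok <- ni > 0
    if (sum(ok) < 2) next
    ni <- ni[ok]; pi <- pi[ok]; hi <- hi[ok]
    ri <- length(ni)
    nbar <- mean(ni)
    nc <- (ri * nbar - sum(ni^2) / (ri * nbar)) / (ri - 1)
    pbar <- sum(ni * pi) / (ri * nbar)
    s2 <- sum(ni * (pi - pbar)^2) / ((ri - 1) * nbar)
    hbar <- sum(ni * hi) / (ri * nbar)
    if (nbar <= 1 || nc == 0) next
    a[s] <- nbar / nc *
      (s2 - 1 / (nbar - 1) *
         (pbar * (1 - pbar) - (ri - 1) / ri * s2 - hbar / 4))
    b[s] <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (ri - 1) / ri * s2 -
         (2 * nbar - 1) / (4 * nbar) * hbar)
    cc[s] <- hbar / 2
  }
  data.frame(a = a, b = b, c = cc)
}

#' Weir-Cockerham F_ST
#'
#' Multilocus Weir & Cockerham (1984) theta as the ratio of summed
#' variance components, sum(a) / sum(a + b + c); loci with zero total
#' variance are skipped.  Slightly negative estimates are possible (and
#' expected) under no differentiation.
#'
#' @param gd a \linkS4class{GenotypeData}.
#' @param pops populations to include (default: all).
#' @param by group samples by "population" or "status".
#' @return an \code{FstResult} list: \code{theta} (multilocus estimate),
#'   \code{perLocus} (a, b, c and per-locus theta), \code{pops}.
#' @export
wcFst <- function(gd, pops = NULL, by = c("population", "status")) {
  by <- match.arg(by)
  cd <- SummarizedExperiment::colData(gd)
  grp <- if (by == "population") cd$population else cd$status
  if (is.null(pops)) pops <- unique(grp)
  if (length(pops) < 2) stop("need at least 2 populations")
  d <- dosages(gd)[, grp %in% pops, drop = FALSE]
  comp <- .wcComponents(d, grp[grp %in% pops], pops)
  tot <- comp$a + comp$b + comp$c
  use <- !is.na(tot) & tot != 0
  theta <- sum(comp$a[use]) / sum(tot[use])
  perLocus <- comp
  perLocus$theta <- ifelse(use, comp$a / tot, NA_real_)
  structure(list(theta = theta, perLocus = perLocus, pops = pops,
                 nLociUsed = sum(use)),
            class = "FstResult")
}

#' @export
print.FstResult <- function(x, ...) {
  cat(sprintf("Weir-Cockerham F_ST = %.4f over %d loci (%s)\n", x$theta,
              x$nLociUsed, paste(x$pops, collapse = " vs ")))
  if (!is.null(x$ci))
    cat(sprintf("  %d%% CI: %.4f - %.4f (%d bootstraps)\n",
                round(100 * x$level), x$ci[1], x$ci[2], x$nBoot))
  invisible(x)
}

#' Bootstrap confidence interval for multilocus F_ST
#'
#' Loci are resampled with replacement and the ratio-of-sums theta is
#' recomputed from the cached per-locus variance components; the CI is the
#' percentile interval.
#'
#' @inheritParams wcFst
#' @param nBoot bootstrap replicates (default 100).
#' @param level confidence level (default 0.95).
#' @param seed optional seed.
#' @return the \code{FstResult} of \code{\link{wcFst}} with elements
#'   \code{ci}, \code{level}, \code{nBoot} added.
#' @export
bootstrapFstCI <- function(gd, pops = NULL, nBoot = 100, level = 0.95,
                           seed = NULL, by = c("population", "status")) {
  if (nBoot < 2) stop("nBoot must be at least 2")
  fst <- wcFst(gd, pops, by = match.arg(by))
  comp <- fst$perLocus
  use <- which(!is.na(comp$a + comp$b + comp$c) &
                 (comp$a + comp$b + comp$c) != 0)
  if (length(use) < 2) stop("need at least 2 informative loci")
  if (!is.null(seed)) set.seed(seed)
  boots <- vapply(seq_len(nBoot), function(i) {
    idx <- sample(use, length(use), replace = TRUE)
    sum(comp$a[idx]) / sum(comp$a[idx] + comp$b[idx] + comp$c[idx])
  }, numeric(1))
  alpha <- (1 - level) / 2
  fst$ci <- unname(quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE))
  fst$level <- level
  fst$nBoot <- nBoot
  fst$bootDist <- boots
  fst
}

#' Pairwise F_ST matrix with bootstrap confidence intervals
#'
#' @inheritParams bootstrapFstCI
#' @return data.frame(pop1, pop2, fst, lower, upper).
#' @export
pairwiseFst <- function(gd, nBoot = 100, level = 0.95, seed = NULL,
                        by = c("population", "status")) {
  by <- match.arg(by)
  cd <- SummarizedExperiment::colData(gd)
  grp <- if (by == "population") cd$population else cd$status
  pops <- unique(grp)
  cmb <- utils::combn(pops, 2)
  res <- lapply(seq_len(ncol(cmb)), function(i) {
    f <- bootstrapFstCI(gd, cmb[, i], nBoot = nBoot, level = level,
                        seed = if (is.null(seed)) NULL else seed + i,
                        by = by)
    data.frame(pop1 = cmb[1, i], pop2 = cmb[2, i], fst = f$theta,
               lower = f$ci[1], upper = f$ci[2])
  })
  do.call(rbind, res)
}

#' Genotype principal component analysis
#'
#' Missing dosages are mean-imputed per site; sites are centred by 2 p-hat
#' and scaled by sqrt(2 p-hat (1 - p-hat)); the decomposition is a thin
#' SVD.  Explained-variance fractions are non-increasing and sum to at
#' most 1.
#'
#' @param gd a \linkS4class{GenotypeData}.
#' @param nComponents number of components to return (default 10).
#' @return list(scores samples x K, loadings sites x K, explained
#'   variance fractions, sdev).
#' @export
genotypePCA <- function(gd, nComponents = 10) {
  d <- dosages(gd)
  if (ncol(d) < 2) stop("need at least 2 samples")
  p <- rowMeans(d, na.rm = TRUE) / 2
  keep <- !is.na(p) & p > 0 & p < 1
  d <- d[keep, , drop = FALSE]
  p <- p[keep]
  for (s in seq_len(nrow(d))) {
    miss <- is.na(d[s, ])
    if (any(miss)) d[s, miss] <- 2 * p[s]
  }
  X <- (d - 2 * p) / sqrt(2 * p * (1 - p))
  sv <- svd(t(X))   # samples x sites
  k <- min(nComponents, length(sv$d))
  ev <- sv$d^2 / sum(sv$d^2)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)],
                                                      k, k)
  rownames(scores) <- colnames(d)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  rownames(loadings) <- rownames(d)
  list(scores = scores, loadings = loadings,
       explained = ev[seq_len(k)], sdev = sv$d[seq_len(k)])
}
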