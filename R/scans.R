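#' Benjamini-Hochberg q-values and Bonferroni adjustment
#'
#' Thin wrappers over \code{stats::p.adjust} kept as named operations so
#' every scan applies exactly the correction the study design prescribes.
#'
#' @param p p-values in [0, 1].
#' @return adjusted values, same length.
#' @export
bhQvalues <- function(p) {
  if (!length(p)) return(numeric(0))
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  p.adjust(p, method = "BH")
}

#' @rdname bhQvalues
#' @export
bonferroni <- function(p) {
  if (!length(p)) return(numeric(0))
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  p.adjust(p, method = "bonferroni")
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic PSRF from between- and within-chain variances:
#' R-hat = sqrt(((n-1)/n W + B/n) / W).  Zero within-chain variance in
#' every chain gives NaN.
#'
#' @param chains list of equally sized matrices (iterations x parameters)
#'   or vectors, one per chain.
#' @return R-hat per parameter.
#' @export
gelmanRubin <- function(chains) {
  stopifnot(length(chains) >= 2)
  chains <- lapply(chains, function(x) if (is.matrix(x)) x else
    matrix(x, ncol = 1))
  n <- unique(vapply(chains, nrow, integer(1)))
  if (length(n) != 1) stop("chains must have equal lengths")
  if (n < 10) stop("chains too short")
  means <- sapply(chains, colMeans)
  vars <- sapply(chains, function(x) apply(x, 2, var))
  means <- matrix(means, ncol = length(chains))
  vars <- matrix(vars, ncol = length(chains))
  W <- rowMeans(vars)
  B_over_n <- apply(means, 1, var)
  rhat <- sqrt(((n - 1) / n * W + B_over_n) / W)
  rhat[W == 0] <- NaN
  rhat
}

# derived-allele counts and totals per population
.alleleCountsByPop <- function(gd, by = "population") {
  cd <- SummarizedExperiment::colData(gd)
  grp <- if (by == "population") cd$population else cd$status
  d <- dosages(gd)
  pops <- unique(grp)
  A <- sapply(pops, function(pp)
    rowSums(d[, grp == pp, drop = FALSE], na.rm = TRUE))
  N <- sapply(pops, function(pp)
    2 * rowSums(!is.na(d[, grp == pp, drop = FALSE])))
  list(A = matrix(as.integer(A), nrow(d), dimnames = list(rownames(d),
                                                          pops)),
       N = matrix(as.integer(N), nrow(d), dimnames = list(rownames(d),
                                                          pops)),
       pops = pops)
}

.scanResult <- function(gd, statistic, p, adjusted, flag) {
  rr <- SummarizedExperiment::rowRanges(gd)
  data.frame(snpId = names(rr),
             chrom = as.character(GenomicRanges::seqnames(rr)),
             pos = GenomicRanges::start(rr),
             statistic = statistic, p = p, adjusted = adjusted,
             flag = flag, row.names = NULL)
}

#' Hierarchical F-model scan with an environmental covariate
#'
#' Bayesian genome scan for loci whose differentiation tracks a binary
#' wild (0) / domesticated (1) population covariate.  Population allele
#' frequencies follow a beta distribution around an ancestral frequency
#' with a locus-by-population precision parameterized on the logit scale
#' by a population effect plus, per locus, nothing (neutral), a locus
#' effect (selection unrelated to the covariate), or an environmental
#' sensitivity times the covariate.  Per-locus model indicators move by
#' product-space MCMC; two independent chains are run and convergence of
#' the population effects is checked with the Gelman-Rubin statistic.
#' q-values are cumulative means of the sorted posterior error
#' probabilities of the environmental model.
#'
#' @param gd a \linkS4class{GenotypeData} (outgroup samples are ignored).
#' @param env named 0/1 covariate per population (see
#'   \code{\link{makeEnvVector}}); default derived from the status column.
#' @param pilotRuns,pilotLen pilot batches used to tune proposal widths
#'   toward 25-45\% acceptance.
#' @param burnIn,sampleIters,thin main-run MCMC controls.
#' @param seeds two integers, one per chain.
#' @param qCut candidate cutoff on the q-value (default 0.05).
#' @param priorNeutral prior probability of the neutral model per locus.
#' @param sdAlpha,sdG prior standard deviations of the locus effect and
#'   the environmental sensitivity (logit scale; a binary covariate needs
#'   effects of ~4-6 to represent near-fixation, hence the wide default).
#' @param rhatMax convergence threshold on R-hat.
#' @return a ScanResult data.frame (statistic = posterior probability of
#'   the environmental model, p = posterior error probability, adjusted =
#'   q-value), with attributes \code{rhat} and \code{converged}.
#' @export
bayescenvScan <- function(gd, env = NULL, pilotRuns = 20, pilotLen = 10000,
                          burnIn = 1e5, sampleIters = 1e5, thin = 20,
                          seeds = c(1, 2), qCut = 0.05,
                          priorNeutral = 0.8, sdAlpha = 1, sdG = 4,
                          rhatMax = 1.1) {
  keep <- SummarizedExperiment::colData(gd)$status != "outgroup"
  gd2 <- gd[, keep]
  ac <- .alleleCountsByPop(gd2)
  if (length(ac$pops) < 2) stop("need at least 2 populations")
  if (is.null(env)) env <- makeEnvVector(popMap(gd2))
  env <- env[ac$pops]
  if (anyNA(env)) stop("environment covariate missing for some population")
  runs <- lapply(seeds, function(s) {
    set.seed(s)
    fmodel_mcmc_cpp(ac$A, ac$N, as.numeric(env),
                    as.integer(pilotRuns), as.integer(pilotLen),
                    as.integer(burnIn), as.integer(sampleIters),
                    as.integer(thin), priorNeutral, sdAlpha, sdG,
                    -1.0, 1.8)
  })
  rhat <- gelmanRubin(lapply(runs, `[[`, "beta_chain"))
  converged <- all(is.nan(rhat) | rhat < rhatMax)
  if (!converged)
    warning("chains not converged (max R-hat = ",
            round(max(rhat, na.rm = TRUE), 3), "); results flagged")
  postEnv <- rowMeans(sapply(runs, function(r) r$post_prob[, 3]))
  pep <- 1 - postEnv
  o <- order(pep)
  q <- numeric(length(pep))
  q[o] <- cumsum(pep[o]) / seq_along(pep)   # mean PEP among the called set
  res <- .scanResult(gd2, statistic = postEnv, p = pep, adjusted = q,
                     flag = q < qCut)
  attr(res, "rhat") <- rhat
  attr(res, "converged") <- converged
  attr(res, "meanG") <- rowMeans(sapply(runs, `[[`, "mean_g"))
  res
}

#' PCA-based Mahalanobis outlier scan
#'
#' Each SNP's scaled dosages are regressed on the first K principal
#' component scores; the K z-scores are combined into a Mahalanobis
#' distance, rescaled by the genomic inflation factor
#' lambda = median(D2) / median(chi-squared K), and referred to a
#' chi-squared K distribution.  Bonferroni correction determines the
#' candidates.  Constant SNPs are excluded and reported as NA.
#'
#' @param gd a \linkS4class{GenotypeData} (outgroup samples are ignored).
#' @param K number of principal components (default 2).
#' @param robust use a trimmed robust mean/covariance of the z-scores
#'   (classical moments otherwise).
#' @param minMaf sites rarer than this are excluded from the test (their
#'   z-scores are too unstable for the chi-squared reference; the
#'   genome-scan default).
#' @param alpha candidate cutoff on the Bonferroni-adjusted p (default
#'   0.05).
#' @return ScanResult data.frame (statistic = Mahalanobis D2) with
#'   attribute \code{lambda}.
#' @export
pcadaptScan <- function(gd, K = 2, robust = TRUE, minMaf = 0.05,
                        alpha = 0.05) {
  keep <- SummarizedExperiment::colData(gd)$status != "outgroup"
  gd2 <- gd[, keep]
  d <- dosages(gd2)
  n <- ncol(d)
  if (n <= K) stop("need more samples than components")
  p <- rowMeans(d, na.rm = TRUE) / 2
  ok <- !is.na(p) & pmin(p, 1 - p) >= minMaf
  X <- d[ok, , drop = FALSE]
  pok <- p[ok]
  for (s in seq_len(nrow(X))) {
    miss <- is.na(X[s, ])
    if (any(miss)) X[s, miss] <- 2 * pok[s]
  }
  X <- (X - 2 * pok) / sqrt(2 * pok * (1 - pok))
  sv <- svd(t(X), nu = K, nv = 0)
  U <- sv$u[, seq_len(K), drop = FALSE]     # orthonormal sample scores
  B <- t(U) %*% t(X)                        # K x sites coefficients
  ss <- colSums(t(X)^2)
  resid <- pmax(ss - colSums(B^2), 0)
  sigma2 <- resid / (n - K)
  z <- t(B) / sqrt(pmax(sigma2, 1e-12))     # sites x K
  if (robust) {
    mu0 <- colMeans(z); S0 <- stats::cov(z)
    d0 <- stats::mahalanobis(z, mu0, S0)
    core <- d0 <= quantile(d0, 0.95)
    mu <- colMeans(z[core, , drop = FALSE])
    S <- stats::cov(z[core, , drop = FALSE])
  } else {
    mu <- colMeans(z); S <- stats::cov(z)
  }
  D2 <- stats::mahalanobis(z, mu, S)
  lambda <- median(D2) / qchisq(0.5, K)
  pv <- pchisq(D2 / lambda, K, lower.tail = FALSE)
  stat <- p2 <- adj <- rep(NA_real_, nrow(d))
  stat[ok] <- D2
  p2[ok] <- pv
  adj[ok] <- bonferroni(pv)
  res <- .scanResult(gd2, statistic = stat, p = p2, adjusted = adj,
                     flag = !is.na(adj) & adj < alpha)
  attr(res, "lambda") <- lambda
  attr(res, "nExcluded") <- sum(!ok)
  res
}

#' Latent-factor ridge association scan
#'
#' Latent factors of the genotype matrix are estimated from the SVD of
#' the genotypes projected off the covariate (ridge-regularized
#' projection); effect sizes come from regressing the residualized
#' genotypes on the covariate.  z-scores are calibrated by the genomic
#' inflation factor (median chi-squared rescaling) and converted to
#' Benjamini-Hochberg q-values.  With K = 0 and a vanishing ridge
#' penalty the z-scores reduce to per-SNP ordinary least squares.
#'
#' @param gd a \linkS4class{GenotypeData} (outgroup samples are ignored).
#' @param env per-sample 0/1 covariate; by default samples inherit their
#'   population's wild/domesticated status.
#' @param K number of latent factors (default 6).
#' @param ridgeLambda ridge penalty (default 1e-5).
#' @param qCut candidate cutoff on the q-value.
#' @return ScanResult data.frame (statistic = calibrated z-score) with
#'   attribute \code{lambda}.
#' @export
lfmmScan <- function(gd, env = NULL, K = 6, ridgeLambda = 1e-5,
                     qCut = 0.05) {
  keep <- SummarizedExperiment::colData(gd)$status != "outgroup"
  gd2 <- gd[, keep]
  d <- dosages(gd2)
  n <- ncol(d)
  if (is.null(env)) {
    st <- SummarizedExperiment::colData(gd2)$status
    env <- as.numeric(st == "domesticated")
  }
  if (length(unique(env)) < 2) stop("covariate is constant across samples")
  if (n <= K + 1) stop("need more samples than K + 1")
  p <- rowMeans(d, na.rm = TRUE) / 2
  ok <- !is.na(p) & p > 0 & p < 1
  Y <- d[ok, , drop = FALSE]
  pok <- p[ok]
  for (s in seq_len(nrow(Y))) {
    miss <- is.na(Y[s, ])
    if (any(miss)) Y[s, miss] <- 2 * pok[s]
  }
  Y <- t(Y)                       # samples x sites
  Y <- scale(Y, center = TRUE, scale = FALSE)
  X <- cbind(1, env)
  P <- X %*% solve(crossprod(X) + ridgeLambda * diag(ncol(X)), t(X))
  R <- Y - P %*% Y
  W <- 0
  if (K > 0) {
    sv <- svd(R, nu = K, nv = K)
    W <- sv$u[, seq_len(K), drop = FALSE] %*%
      (sv$d[seq_len(K)] * t(sv$v[, seq_len(K), drop = FALSE]))
  }
  Yr <- Y - W
  XtXi <- solve(crossprod(X))
  Bhat <- XtXi %*% t(X) %*% Yr          # 2 x sites
  fit <- X %*% Bhat
  dfres <- n - ncol(X) - K
  s2 <- colSums((Yr - fit)^2) / dfres
  seB <- sqrt(pmax(s2, 1e-300) * XtXi[2, 2])
  zz <- Bhat[2, ] / seB
  lambda <- median(zz^2) / qchisq(0.5, 1)
  zcal <- zz / sqrt(lambda)
  pv <- pchisq(zcal^2, 1, lower.tail = FALSE)
  stat <- p2 <- adj <- rep(NA_real_, sum(ok) + sum(!ok))
  stat[ok] <- zcal
  p2[ok] <- pv
  adj[ok] <- bhQvalues(pv)
  res <- .scanResult(gd2, statistic = stat, p = p2, adjusted = adj,
                     flag = !is.na(adj) & adj < qCut)
  attr(res, "lambda") <- lambda
  res
}

#' Consensus candidates across scans
#'
#' A SNP is a consensus candidate when it is significant, at each test's
#' own cutoff, in at least \code{minTests} of the supplied scans.
#'
#' @param results list of ScanResult data.frames sharing the SNP index.
#' @param minTests minimum number of flagging tests (default 2).
#' @return data.frame(snpId, chrom, pos, nTests, candidate).
#' @export
consensusCandidates <- function(results, minTests = 2) {
  stopifnot(length(results) >= 1)
  ids <- lapply(results, `[[`, "snpId")
  if (!all(vapply(ids, identical, logical(1), ids[[1]])))
    stop("scan results do not share the same SNP index")
  flags <- sapply(results, function(r) r$flag & !is.na(r$flag))
  nTests <- rowSums(matrix(flags, ncol = length(results)))
  data.frame(snpId = results[[1]]$snpId, chrom = results[[1]]$chrom,
             pos = results[[1]]$pos, nTests = nTests,
             candidate = nTests >= minTests)
}
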