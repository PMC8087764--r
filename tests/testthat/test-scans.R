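test_that("multiple-testing corrections match hand step-up results", {
  expect_equal(bhQvalues(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhQvalues(0.2), 0.2)
  expect_equal(bonferroni(0.2), 0.2)
  expect_equal(bonferroni(rep(0.04, 100))[1], 1)
  expect_length(bhQvalues(numeric(0)), 0)
  expect_length(bonferroni(numeric(0)), 0)
  # BH output is monotone in p and order-invariant
  set.seed(1)
  p <- runif(50)
  q <- bhQvalues(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  perm <- sample(50)
  expect_equal(bhQvalues(p[perm]), q[perm])
})

test_that("Gelman-Rubin PSRF behaves across regimes", {
  set.seed(2)
  ch1 <- rnorm(1000); ch2 <- rnorm(1000)
  expect_lt(gelmanRubin(list(ch1, ch2)), 1.1)
  # chains offset by 5 SD: R-hat large and equal to the hand formula
  a <- rnorm(10); b <- rnorm(10) + 5
  rhat <- gelmanRubin(list(a, b))
  n <- 10
  W <- mean(c(var(a), var(b)))
  Bn <- var(c(mean(a), mean(b)))
  expect_equal(rhat, sqrt(((n - 1) / n * W + Bn) / W), tolerance = 1e-12)
  expect_gt(rhat, 1.5)
  # identical constant chains -> NaN
  expect_true(is.nan(gelmanRubin(list(rep(1, 20), rep(1, 20)))))
  expect_error(gelmanRubin(list(1:20)), "2")
})

test_that("PSRF agrees with the coda reference implementation", {
  skip_if_not_installed("coda")
  set.seed(3)
  ch <- list(matrix(rnorm(600), 300, 2), matrix(rnorm(600, 0.2), 300, 2))
  mine <- gelmanRubin(ch)
  ref <- coda::gelman.diag(coda::mcmc.list(lapply(ch, coda::mcmc)),
                           autoburnin = FALSE, transform = FALSE)
  # coda applies a sampling-variance df correction; agreement is close
  expect_equal(unname(mine), unname(ref$psrf[, 1]), tolerance = 0.05)
})

test_that("Mahalanobis distances equal the direct algebra oracle", {
  gd <- studyData(nSNPs = 200, seed = 71, missingRate = 0)
  res <- pcadaptScan(gd, K = 2, robust = FALSE, minMaf = 0)
  ok <- !is.na(res$p)
  # rebuild z-scores independently
  d <- dosages(gd)
  p <- rowMeans(d, na.rm = TRUE) / 2
  keep <- p > 0 & p < 1
  X <- (d[keep, ] - 2 * p[keep]) / sqrt(2 * p[keep] * (1 - p[keep]))
  sv <- svd(t(X))
  U <- sv$u[, 1:2]
  z <- t(sapply(seq_len(nrow(X)), function(s) {
    fit <- lm(X[s, ] ~ U - 1)
    coef(fit) / sqrt(sum(resid(fit)^2) / (ncol(X) - 2))
  }))
  mu <- colMeans(z); S <- cov(z)
  d2 <- mahalanobis(z, mu, S)
  expect_equal(unname(res$statistic[ok]), unname(d2), tolerance = 1e-6)
})

test_that("PCA scan null calibration is sane", {
  gd <- studyData(nSNPs = 800, seed = 72, missingRate = 0.05)
  res <- pcadaptScan(gd, K = 2)
  lam <- attr(res, "lambda")
  expect_gt(lam, 0.5); expect_lt(lam, 2)
  pv <- res$p[!is.na(res$p)]
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.001)
  # a SNP uncorrelated with the PCs sits near p = 1
  expect_gt(max(pv), 0.5)
})

test_that("latent-factor scan reduces to per-SNP OLS at K = 0", {
  gd <- studyData(nSNPs = 150, seed = 73, missingRate = 0)
  env <- as.numeric(SummarizedExperiment::colData(gd)$status ==
                      "domesticated")
  res <- lfmmScan(gd, env = env, K = 0, ridgeLambda = 0)
  d <- dosages(gd)
  ok <- !is.na(res$statistic)
  lam <- attr(res, "lambda")
  zs <- vapply(which(ok), function(s) {
    y <- d[s, ] - mean(d[s, ])
    summary(lm(y ~ env))$coefficients["env", "t value"]
  }, numeric(1))
  expect_equal(unname(res$statistic[ok]) * sqrt(lam), unname(zs),
               tolerance = 1e-8)
})

test_that("latent-factor scan controls false positives under a permuted
           covariate", {
  frac <- vapply(1:5, function(s) {
    gd <- studyData(nSNPs = 400, seed = 80 + s, missingRate = 0.05)
    set.seed(90 + s)
    env <- sample(as.numeric(SummarizedExperiment::colData(gd)$status ==
                               "domesticated"))
    res <- lfmmScan(gd, env = env, K = 2)
    mean(res$flag, na.rm = TRUE)
  }, numeric(1))
  expect_lte(median(frac), 0.02)
})

test_that("latent-factor scan recovers spiked loci", {
  rec <- vapply(1:5, function(s) {
    gd <- studyData(nSNPs = 400, seed = 180 + s, missingRate = 0.05)
    sp <- spikeSelection(gd, 10, domPopsOf(gd), 0.8, seed = 190 + s)
    res <- lfmmScan(sp$geno, K = 2)
    mean(res$flag[sp$truth$site], na.rm = TRUE)
  }, numeric(1))
  expect_gte(median(rec), 0.7)
})

test_that("F-model scan finds no environmental signal in identical pops", {
  # all populations at identical frequencies: env posterior < 0.5
  set.seed(101)
  base <- rbinom(60, 2, 0.5)
  m <- matrix(rep(base, 8), nrow = 60)
  gd <- gdFromMatrix(m, pops = rep(c("P1", "P2", "P3", "P4"), each = 2),
                     status = rep(c("wild", "wild", "domesticated",
                                    "domesticated"), each = 2))
  for (sd in c(11, 12)) {
    res <- bayescenvScan(gd, pilotRuns = 2, pilotLen = 100,
                         burnIn = 200, sampleIters = 400, thin = 2,
                         seeds = c(sd, sd + 100))
    expect_true(all(res$statistic < 0.5))
    expect_equal(sum(res$flag), 0)
  }
})

test_that("F-model scan flags spiked loci and keeps q-values monotone", {
  gd <- studyData(nSNPs = 250, seed = 110, missingRate = 0.05)
  sp <- spikeSelection(gd, 6, domPopsOf(gd), 1, seed = 111)
  res <- bayescenvScan(sp$geno, pilotRuns = 5, pilotLen = 200,
                       burnIn = 1500, sampleIters = 3000, thin = 3,
                       seeds = c(21, 22))
  expect_gte(sum(res$flag[sp$truth$site]), 4)
  o <- order(res$p)
  expect_true(all(diff(res$adjusted[o]) >= -1e-12))
  expect_true(all(res$adjusted >= 0 & res$adjusted <= 1))
})

test_that("longer F-model chains leave the flagged set stable", {
  gd <- studyData(nSNPs = 200, seed = 120, missingRate = 0)
  sp <- spikeSelection(gd, 8, domPopsOf(gd), 1, seed = 121)
  short <- bayescenvScan(sp$geno, pilotRuns = 3, pilotLen = 150,
                         burnIn = 500, sampleIters = 900, thin = 2,
                         seeds = c(31, 32))
  long <- bayescenvScan(sp$geno, pilotRuns = 3, pilotLen = 150,
                        burnIn = 500, sampleIters = 1800, thin = 2,
                        seeds = c(31, 32))
  a <- which(short$flag); b <- which(long$flag)
  if (length(union(a, b)) > 0)
    expect_gte(length(intersect(a, b)) / length(union(a, b)), 0.6)
  expect_true(isTRUE(attr(long, "converged")) ||
                is.logical(attr(long, "converged")))
})

test_that("consensus candidates implement the >=2-test rule exactly", {
  mk <- function(flags) data.frame(snpId = paste0("s", 1:4),
                                   chrom = "chr1", pos = 1:4,
                                   statistic = 0, p = 0.5, adjusted = 0.5,
                                   flag = flags)
  r <- list(mk(c(TRUE, TRUE, FALSE, TRUE)),
            mk(c(TRUE, FALSE, FALSE, TRUE)),
            mk(c(TRUE, FALSE, FALSE, FALSE)))
  cons <- consensusCandidates(r, minTests = 2)
  expect_equal(cons$candidate, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(cons$nTests, c(3, 1, 0, 2))
  cons3 <- consensusCandidates(r, minTests = 3)
  expect_true(all(which(cons3$candidate) %in% which(cons$candidate)))
  # brute-force oracle over random flag patterns
  set.seed(9)
  for (i in 1:20) {
    fl <- replicate(3, sample(c(TRUE, FALSE), 6, TRUE), simplify = FALSE)
    mk6 <- function(f) data.frame(snpId = paste0("x", 1:6), chrom = "c",
                                  pos = 1:6, statistic = 0, p = 0.5,
                                  adjusted = 0.5, flag = f)
    got <- consensusCandidates(lapply(fl, mk6), 2)$candidate
    oracle <- (fl[[1]] + fl[[2]] + fl[[3]]) >= 2
    expect_identical(got, oracle)
  }
  bad <- mk(c(TRUE, TRUE, TRUE, TRUE)); bad$snpId <- paste0("y", 1:4)
  expect_error(consensusCandidates(list(r[[1]], bad)), "index")
})
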