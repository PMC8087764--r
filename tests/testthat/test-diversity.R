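test_that("per-site pi follows the unbiased heterozygosity formula", {
  # monomorphic -> 0
  gd0 <- gdFromMatrix(matrix(0, 1, 4), pops = rep("P1", 4),
                      status = rep("wild", 4))
  expect_equal(nucleotideDiversity(gd0)$pi, 0)
  # n = 2 diploids (4 alleles), allele counts 2/2:
  # pi = 4/3 * 2 * 0.5 * 0.5 = 2/3
  gd <- gdFromMatrix(matrix(c(1, 1), 1, 2), pops = rep("P1", 2),
                     status = rep("wild", 2))
  expect_equal(nucleotideDiversity(gd)$pi, 4 / 3 * 2 * 0.25,
               tolerance = 1e-12)
})

test_that("pi equals the mean pairwise-difference oracle", {
  set.seed(8)
  m <- matrix(rbinom(50 * 10, 2, runif(50 * 10, 0.1, 0.9)), 50, 10)
  gd <- gdFromMatrix(m, pops = rep("P1", 10), status = rep("wild", 10))
  res <- nucleotideDiversity(gd)
  perSite <- attr(res, "perSite")[, "P1"]
  for (s in seq_len(50)) {
    alleles <- unlist(lapply(m[s, ], function(d) c(rep(1, d),
                                                   rep(0, 2 - d))))
    n <- length(alleles)
    diffs <- outer(alleles, alleles, "!=")
    oracle <- sum(diffs[upper.tri(diffs)]) / choose(n, 2)
    expect_equal(perSite[s], oracle, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("Weir-Cockerham theta hits its textbook anchor points", {
  # two populations fixed for alternative alleles -> theta = 1
  m <- matrix(c(rep(0, 20), rep(2, 20)), 1, 40)
  gd <- gdFromMatrix(m, pops = rep(c("P1", "P2"), each = 20))
  expect_equal(wcFst(gd)$theta, 1)
  # identical genotype counts -> sum(a) = 0, theta <= 0 and small
  onePop <- rep(c(0, 1, 2), times = c(4, 4, 2))
  m2 <- rbind(c(onePop, onePop), c(rev(onePop), rev(onePop)))
  gd2 <- gdFromMatrix(m2, pops = rep(c("P1", "P2"), each = 10))
  th <- wcFst(gd2)$theta
  expect_lte(th, 0)
  expect_lt(abs(th), 0.2)
})

test_that("variance components match an independent WC84 transcription", {
  # pop1: 10 AA, 10 Aa, 0 aa; pop2: 0 AA, 10 Aa, 10 aa
  spec <- dosageFromCounts(list(P1 = c(10, 10, 0), P2 = c(0, 10, 10)))
  gd <- gdFromMatrix(spec$dosage, pops = spec$pops)
  fst <- wcFst(gd)
  oracle <- wcOracle(rbind(c(10, 10, 0), c(0, 10, 10)))
  expect_equal(fst$perLocus$a[1], oracle[["a"]], tolerance = 1e-12)
  expect_equal(fst$perLocus$b[1], oracle[["b"]], tolerance = 1e-12)
  expect_equal(fst$perLocus$c[1], oracle[["c"]], tolerance = 1e-12)
  expect_equal(fst$theta, oracle[["theta"]], tolerance = 1e-12)
})

test_that("theta is invariant to pop order and allele relabeling", {
  gd <- studyData(nSNPs = 150, seed = 13, missingRate = 0.1)
  t1 <- wcFst(gd, by = "status")$theta
  t2 <- wcFst(gd[, rev(seq_len(ncol(gd)))], by = "status")$theta
  expect_equal(t1, t2, tolerance = 1e-12)
  flip <- gd
  d <- dosages(gd)
  d[3, ] <- 2 - d[3, ]    # swap REF/ALT at one site
  SummarizedExperiment::assay(flip, "dosage") <- d
  expect_equal(wcFst(flip, by = "status")$theta, t1, tolerance = 1e-12)
})

test_that("theta decreases with migration in an island model", {
  thetaAt <- function(m, seeds) {
    vapply(seeds, function(s) {
      sizes <- c(A = 5000, B = 5000)
      mig <- matrix(c(0, m, m, 0), 2, dimnames = list(names(sizes),
                                                      names(sizes)))
      mod <- DemographicModel(sizes, data.frame(time = 1e6,
        derived = "B", ancestral = "A", size = NA), mig, "continuous")
      h <- sim_twoDemeGeno(mod, 150, s)
      wcFst(h)$theta
    }, numeric(1))
  }
  sim_twoDemeGeno <- function(mod, nSNPs, seed) {
    haps <- simulateCoalescent(mod, simParams(c(A = 10, B = 10),
                                              nSNPs = nSNPs, seed = seed))
    emitGenotypes(haps, pairingSeed = seed + 1)
  }
  set.seed(33)
  th <- vapply(c(1e-5, 1e-4, 1e-3),
               function(m) mean(thetaAt(m, 1:10)), numeric(1))
  expect_true(all(diff(th) < 0))
})

test_that("bootstrap CI is reproducible, ordered and degenerate-safe", {
  gd <- studyData(nSNPs = 200, seed = 17, missingRate = 0)
  f1 <- bootstrapFstCI(gd, nBoot = 50, seed = 5, by = "status")
  f2 <- bootstrapFstCI(gd, nBoot = 50, seed = 5, by = "status")
  expect_identical(f1$ci, f2$ci)
  expect_lte(f1$ci[1], f1$ci[2])
  expect_error(bootstrapFstCI(gd, nBoot = 1), "nBoot")
  # all loci identical -> zero-width CI at the point estimate
  spec <- dosageFromCounts(list(P1 = c(8, 2, 0), P2 = c(2, 2, 6)))
  m <- spec$dosage[rep(1, 10), ]
  gdI <- gdFromMatrix(m, pops = spec$pops)
  fI <- bootstrapFstCI(gdI, nBoot = 30, seed = 1)
  expect_equal(fI$ci[1], fI$theta, tolerance = 1e-12)
  expect_equal(fI$ci[2], fI$theta, tolerance = 1e-12)
})

test_that("bootstrap CI covers the long-run F_ST at its nominal rate", {
  # long-run value from one large reference simulation
  bigRef <- function() {
    gd <- studyData(nSNPs = 6000, seed = 999, missingRate = 0,
                    samples = c(jalisco = 10, southern = 10,
                                domesticated = 20))
    wcFst(gd, by = "status")$theta
  }
  target <- bigRef()
  covered <- vapply(1:35, function(s) {
    gd <- studyData(nSNPs = 250, seed = 2000 + s, missingRate = 0)
    f <- bootstrapFstCI(gd, nBoot = 100, seed = 3000 + s, by = "status")
    f$ci[1] <= target && target <= f$ci[2]
  }, logical(1))
  # percentile intervals over a ratio-of-sums undercover mildly at
  # B = 100; observed long-run coverage sits near 0.85-0.9
  expect_gte(mean(covered), 0.8)
  expect_lte(mean(covered), 1.0)
})

test_that("genotype PCA matches an eigendecomposition oracle", {
  set.seed(12)
  m <- matrix(rbinom(50 * 20, 2, 0.5), 50, 20)
  gd <- gdFromMatrix(m, pops = rep(c("P1", "P2"), each = 10))
  pca <- genotypePCA(gd, nComponents = 5)
  # oracle: eigen of the sample covariance of the scaled matrix
  p <- rowMeans(m) / 2
  keep <- p > 0 & p < 1
  X <- (m[keep, ] - 2 * p[keep]) / sqrt(2 * p[keep] * (1 - p[keep]))
  ev <- eigen(tcrossprod(t(X)))
  for (k in 1:5) {
    sc <- pca$scores[, k]
    or <- ev$vectors[, k] * sqrt(ev$values[k])
    expect_lt(min(max(abs(sc - or)), max(abs(sc + or))), 1e-8)
  }
  expect_true(all(diff(pca$explained) <= 1e-12))
  expect_lte(sum(pca$explained), 1 + 1e-12)
})

test_that("PC1 separates two internally identical clusters", {
  m <- cbind(matrix(rep(c(0, 2), 10), 10, 6),
             matrix(rep(c(2, 0), 10), 10, 6))
  gd <- gdFromMatrix(m, pops = rep(c("P1", "P2"), each = 6))
  pca <- genotypePCA(gd, nComponents = 2)
  s1 <- pca$scores[1:6, 1]; s2 <- pca$scores[7:12, 1]
  expect_lt(max(abs(s1 - mean(s1))), 1e-8)
  expect_lt(max(abs(s2 - mean(s2))), 1e-8)
  expect_gt(abs(mean(s1) - mean(s2)), 1)
})

test_that("PCA scores are sample-order invariant up to sign", {
  gd <- studyData(nSNPs = 120, seed = 23, missingRate = 0.1)
  pca <- genotypePCA(gd, 3)
  perm <- sample(ncol(gd))
  pcaP <- genotypePCA(gd[, perm], 3)
  for (k in 1:3) {
    a <- pca$scores[perm, k]; b <- pcaP$scores[, k]
    expect_lt(min(max(abs(a - b)), max(abs(a + b))), 1e-6)
  }
})
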