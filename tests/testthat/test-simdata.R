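test_that("no mutation rate means no segregating sites", {
  m <- DemographicModel(c(A = 500))
  h <- simulateCoalescent(m, simParams(c(A = 1), mu = 0, L = 1e6,
                                       nLoci = 1, seed = 1))
  expect_equal(nrow(h$haplotypes), 0)
})

test_that("pairwise TMRCA matches the closed form 2N within 3 SE", {
  m <- DemographicModel(c(A = 1000))
  tm <- simTMRCA(m, c(A = 1), 4000, seed = 42)
  se <- sd(tm) / sqrt(length(tm))
  expect_lt(abs(mean(tm) - 2000), 3 * se)
})

test_that("mean segregating sites matches Watterson's expectation", {
  # n = 10 haploids, theta = 4 N mu L = 10 -> E[S] = 10 * sum(1/1:9)
  N <- 1000; L <- 1e5
  mu <- 10 / (4 * N * L)
  m <- DemographicModel(c(A = N))
  set.seed(7)
  S <- replicate(250, nrow(simulateCoalescent(
    m, simParams(c(A = 5), mu = mu, L = L, nLoci = 1))$haplotypes))
  expected <- 10 * sum(1 / 1:9)
  se <- sd(S) / sqrt(length(S))
  expect_lt(abs(mean(S) - expected), 3 * se)
})

test_that("identical seeds give identical output", {
  m <- studyModel(withOutgroup = TRUE)
  p <- simParams(c(jalisco = 3, southern = 3, domesticated = 3,
                   moschata = 2), nSNPs = 100, seed = 11)
  h1 <- simulateCoalescent(m, p)
  h2 <- simulateCoalescent(m, p)
  expect_identical(h1, h2)
  g1 <- emitGenotypes(h1, pairingSeed = 5, missingRate = 0.1)
  g2 <- emitGenotypes(h2, pairingSeed = 5, missingRate = 0.1)
  expect_identical(dosages(g1), dosages(g2))
})

test_that("relabeling demes consistently leaves statistics unchanged", {
  base <- c(jalisco = 30000, southern = 30000, domesticated = 10000)
  mk <- function(perm) {
    sizes <- base[perm]
    splits <- data.frame(time = c(8000, 30000),
                         derived = c("domesticated", "southern"),
                         ancestral = c("jalisco", "jalisco"), size = NA)
    DemographicModel(sizes, splits)
  }
  p1 <- mk(c("jalisco", "southern", "domesticated"))
  p2 <- mk(c("domesticated", "jalisco", "southern"))
  set.seed(3); c1 <- cushaw:::.simSNPCounts(p1, c(jalisco = 10,
    southern = 10, domesticated = 10), 6000)
  set.seed(4); c2 <- cushaw:::.simSNPCounts(p2, c(jalisco = 10,
    southern = 10, domesticated = 10), 6000)
  # demes are addressed by name, so per-deme summaries agree up to
  # Monte-Carlo error whatever the storage order
  for (dm in c("jalisco", "southern", "domesticated")) {
    se <- sqrt(var(c1[, dm]) / nrow(c1) + var(c2[, dm]) / nrow(c2))
    expect_lt(abs(mean(c1[, dm]) - mean(c2[, dm])), 4 * se)
  }
})

test_that("divergence between demes grows with split time", {
  fstAt <- function(tSplit) {
    sizes <- c(A = 10000, B = 10000)
    m <- DemographicModel(sizes, data.frame(time = tSplit, derived = "B",
                                            ancestral = "A", size = NA))
    mean(replicate(20, {
      cnt <- cushaw:::.simSNPCounts(m, c(A = 20, B = 20), 200)
      f <- cnt / 20
      mean((f[, 1] - f[, 2])^2)   # squared frequency divergence
    }))
  }
  set.seed(21)
  d <- vapply(c(2000, 10000, 40000), fstAt, numeric(1))
  expect_true(all(diff(d) > 0))
})

test_that("genotype pairing and dosage emission obey the contract", {
  # 2 haplotypes [0] and [1] at one site -> single diploid with dosage 1
  h <- structure(list(haplotypes = matrix(c(0, 1), 1, 2), chrom = "chr1",
                      pos = 100L, demes = c("A", "A"), tmrca = 1,
                      missingRate = 0), class = "HaplotypeSet")
  g <- emitGenotypes(h, pairingSeed = 1)
  expect_equal(unname(dosages(g)[1, 1]), 1)
  # odd haplotype count errors
  h$haplotypes <- matrix(c(0, 1, 1), 1, 3)
  h$demes <- c("A", "A", "A")
  expect_error(emitGenotypes(h), "odd")
})

test_that("missingness injection matches its binomial rate", {
  gd0 <- studyData(nSNPs = 1000, seed = 31, missingRate = 0)
  expect_equal(sum(is.na(dosages(gd0))), 0)
  gd <- studyData(nSNPs = 1000, seed = 31, missingRate = 0.2)
  n <- length(dosages(gd))
  obs <- mean(is.na(dosages(gd)))
  se <- sqrt(0.2 * 0.8 / n)
  expect_lt(abs(obs - 0.2), 3 * se)
})

test_that("environment vector codes wild 0 and domesticated 1", {
  pm <- data.frame(sample = c("a", "b", "c"),
                   population = c("P1", "P2", "P3"),
                   status = c("wild", "domesticated", "wild"))
  expect_equal(makeEnvVector(pm), c(P1 = 0, P2 = 1, P3 = 0))
  expect_equal(unname(makeEnvVector(pm[c(2, 1, 3), ])), c(1, 0, 0))
  allWild <- within(pm, status <- "wild")
  expect_true(all(makeEnvVector(allWild) == 0))
  expect_error(makeEnvVector(pm, domesticatedPops = "nope"), "unknown")
})

test_that("selection spiking fixes loci and leaves controls untouched", {
  gd <- studyData(nSNPs = 300, seed = 41, missingRate = 0)
  dom <- domPopsOf(gd)
  sp0 <- spikeSelection(gd, 0, dom, 1, seed = 5)
  expect_identical(dosages(sp0$geno), dosages(gd))
  sp <- spikeSelection(gd, 8, dom, 1, seed = 6)
  tgt <- populationsOf(gd) %in% dom
  for (s in sp$truth$site)
    expect_true(all(dosages(sp$geno)[s, tgt] == 2, na.rm = TRUE))
  expect_error(spikeSelection(gd, 1e5, dom, 1), "exceeds")
})

test_that("spiked loci gain differentiation over the genome median", {
  hits <- vapply(1:8, function(s) {
    gd <- studyData(nSNPs = 250, seed = 500 + s, missingRate = 0)
    sp <- spikeSelection(gd, 5, domPopsOf(gd), 1, seed = 600 + s)
    fst <- wcFst(sp$geno, by = "status")
    per <- fst$perLocus$theta
    median(per[sp$truth$site], na.rm = TRUE) >
      median(per, na.rm = TRUE)
  }, logical(1))
  expect_gte(sum(hits), 7)
})

test_that("SV call-set generator respects jitter and sharing", {
  cs0 <- makeSVCallsets(10, 3, 4, jitterSd = 0, seed = 1)
  shared0 <- cs0$A[S4Vectors::mcols(cs0$A)$id %in% cs0$truth$id]
  sharedB <- cs0$B[S4Vectors::mcols(cs0$B)$id %in% cs0$truth$id]
  expect_identical(GenomicRanges::start(shared0),
                   GenomicRanges::start(sharedB))
  expect_identical(GenomicRanges::end(shared0),
                   GenomicRanges::end(sharedB))
  # no shared records -> empty consensus
  cs <- makeSVCallsets(0, 5, 5, jitterSd = 0, seed = 2)
  expect_length(consensusSVs(cs$A, cs$B)$consensus, 0)
  expect_error(makeSVCallsets(-1, 0, 0), "nShared")
})

test_that("jittered endpoint offsets follow the rounded-normal law", {
  sd <- 50; tol <- 100; n <- 200
  cs <- makeSVCallsets(n, 0, 0, jitterSd = sd, seed = 3)
  within <- with(cs$truth, startOffset <= tol & endOffset <= tol)
  pSingle <- 2 * pnorm((tol + 0.5) / sd) - 1
  pBoth <- pSingle^2
  se <- sqrt(pBoth * (1 - pBoth) / n)
  expect_lt(abs(mean(within) - pBoth), 3 * se + 1e-6)
})

test_that("four-taxon simulation is symmetric without gene flow", {
  sim <- simFourTaxon(3000, f = 0, seed = 9)
  d <- dStatistic(data.frame(sim$freq))
  expect_lt(abs(d$D), 0.15)
  expect_true(all(sim$freq >= 0 & sim$freq <= 1))
})
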