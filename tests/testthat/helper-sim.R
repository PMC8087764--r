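# shared fixture builders; everything is generated in code, seeded

# small GenotypeData with hand-set dosages (sites x samples)
gdFromMatrix <- function(m, pops = NULL, status = NULL, pos = NULL,
                         chrom = "chr1") {
  n <- ncol(m)
  if (is.null(pops)) pops <- rep(c("P1", "P2"), length.out = n)
  if (is.null(status))
    status <- ifelse(pops == unique(pops)[1], "wild", "domesticated")
  if (is.null(pos)) pos <- seq_len(nrow(m)) * 1000
  GenotypeData(m, chrom = chrom, pos = pos,
               popMap = data.frame(sample = paste0("s", seq_len(n)),
                                   population = pops, status = status))
}

# study-condition synthetic data: three in-group demes (+ outgroup),
# secondary-contact gene flow, two populations per deme
studyData <- function(nSNPs = 1000, seed = 1, missingRate = 0.05,
                      withOutgroup = FALSE, popsPerDeme = 2,
                      geneFlowMode = "secondary_contact",
                      samples = NULL) {
  model <- studyModel(geneFlowMode = geneFlowMode,
                      withOutgroup = withOutgroup)
  if (is.null(samples)) {
    samples <- c(jalisco = 10, southern = 10, domesticated = 20)
    if (withOutgroup) samples <- c(samples, moschata = 5)
  }
  haps <- simulateCoalescent(model, simParams(samples, nSNPs = nSNPs,
                                              seed = seed))
  emitGenotypes(haps, pairingSeed = seed + 1000, missingRate = missingRate,
                popsPerDeme = popsPerDeme)
}

domPopsOf <- function(gd) {
  pm <- popMap(gd)
  unique(pm$population[pm$status == "domesticated"])
}

# independent enumeration oracle for the Hardy-Weinberg exact test:
# hypergeometric-type probabilities computed from factorials
hweOracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  if (nA == 0 || na == 0) return(1)
  hets <- seq(nAa %% 2, min(nA, na), by = 2)
  pr <- vapply(hets, function(h) {
    nAA_h <- (nA - h) / 2
    naa_h <- (na - h) / 2
    factorial(n) / (factorial(nAA_h) * factorial(h) * factorial(naa_h)) *
      2^h
  }, numeric(1))
  pr <- pr / sum(pr)
  obs <- pr[hets == nAa]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

# brute-force per-site ABBA/BABA sums
dStatOracle <- function(f) {
  num <- den <- 0
  for (i in seq_len(nrow(f))) {
    abba <- (1 - f[i, 1]) * f[i, 2] * f[i, 3] * (1 - f[i, 4])
    baba <- f[i, 1] * (1 - f[i, 2]) * f[i, 3] * (1 - f[i, 4])
    num <- num + abba - baba
    den <- den + abba + baba
  }
  unname(num / den)
}

# independent Weir-Cockerham (1984) transcription for two-allele data,
# written directly from the published component formulas
wcOracle <- function(counts) {
  # counts: r x 3 matrix of genotype counts (AA, Aa, aa) per population
  r <- nrow(counts)
  ni <- rowSums(counts)
  pi <- (2 * counts[, 1] + counts[, 2]) / (2 * ni)
  hi <- counts[, 2] / ni
  nbar <- mean(ni)
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  pbar <- sum(ni * pi) / (r * nbar)
  s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(ni * hi) / (r * nbar)
  a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                            hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc, theta = a / (a + b + cc))
}

# dosage matrix from per-population genotype count spec
dosageFromCounts <- function(countsList) {
  # countsList: named list pop -> c(AA, Aa, aa)
  cols <- unlist(lapply(countsList, function(x)
    rep(c(0, 1, 2), times = x)))
  pops <- rep(names(countsList),
              times = vapply(countsList, sum, numeric(1)))
  list(dosage = matrix(cols, nrow = 1), pops = pops)
}
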