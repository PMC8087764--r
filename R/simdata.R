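#' Simulation parameters for the coalescent generator
#'
#' Either a fixed number of segregating sites (\code{nSNPs}; one
#' independent genealogy per site, a single mutation dropped on a branch
#' chosen proportionally to its length) or infinite-sites mutation
#' (\code{mu} per site per generation over \code{L} sites split into
#' \code{nLoci} independent non-recombining loci).
#'
#' @param samplesPerDeme named vector of diploid sample counts.
#' @param nSNPs fixed segregating-site count (SNP mode), or NULL.
#' @param mu per-site per-generation mutation rate (sequence mode).
#' @param L genome length in bp (positions are drawn on 1..L).
#' @param nLoci number of independent genealogies in sequence mode.
#' @param seed integer seed; identical seeds give identical output.
#' @param missingRate fraction of genotype entries set missing downstream.
#' @export
simParams <- function(samplesPerDeme, nSNPs = NULL, mu = 1e-8, L = 2.3e8,
                      nLoci = 100, seed = NULL, missingRate = 0) {
  stopifnot(all(samplesPerDeme >= 1), missingRate >= 0, missingRate < 1)
  if (is.null(nSNPs) && !is.finite(mu * L))
    stop("mu * L must be finite")
  structure(list(samplesPerDeme = samplesPerDeme, nSNPs = nSNPs, mu = mu,
                 L = L, nLoci = nLoci, seed = seed,
                 missingRate = missingRate), class = "SimParams")
}

#' Simulate haplotypes under a structured coalescent model
#'
#' @param model a \linkS4class{DemographicModel}.
#' @param params a \code{\link{simParams}} object.
#' @return a \code{HaplotypeSet}: list with \code{haplotypes} (sites x
#'   haploid samples 0/1 matrix of derived alleles), \code{chrom},
#'   \code{pos}, \code{demes} (deme label per haplotype column) and
#'   \code{tmrca} (per simulated genealogy, in generations).
#' @export
simulateCoalescent <- function(model, params) {
  stopifnot(is(model, "DemographicModel"), inherits(params, "SimParams"))
  validObject(model)
  labs <- model@popLabels
  spd <- params$samplesPerDeme
  if (is.null(names(spd))) names(spd) <- labs
  if (!all(names(spd) %in% labs))
    stop("samplesPerDeme names must match model demes")
  hap <- integer(length(labs))
  names(hap) <- labs
  hap[names(spd)] <- 2L * as.integer(spd)
  if (sum(hap) < 2) stop("need at least 2 haploid lineages")
  if (!is.null(params$seed)) set.seed(params$seed)
  mc <- .modelToC(model)
  if (!is.null(params$nSNPs)) {
    res <- sim_snp_haplotypes_cpp(mc, unname(hap), as.integer(params$nSNPs))
    G <- res$genotypes
    pos <- sort(sample.int(params$L, nrow(G)))
    tmrca <- res$tmrca
  } else {
    res <- sim_seq_haplotypes_cpp(mc, unname(hap), as.integer(params$nLoci),
                                  params$mu, params$L / params$nLoci)
    G <- res$genotypes
    pos <- floor(res$relpos / params$nLoci * params$L) + 1
    if (nrow(G) > params$L)
      stop("more segregating sites than available positions")
    while (anyDuplicated(pos)) {      # infinite sites: reject collisions
      dup <- duplicated(pos)
      pos[dup] <- (pos[dup] + sample.int(37, sum(dup), replace = TRUE) -
                     1) %% params$L + 1
    }
    o <- order(pos)
    G <- G[o, , drop = FALSE]
    pos <- pos[o]
    tmrca <- res$tmrca
  }
  structure(list(haplotypes = G, chrom = rep("chr1", nrow(G)),
                 pos = as.integer(pos),
                 demes = rep(labs, hap), tmrca = tmrca,
                 missingRate = params$missingRate),
            class = "HaplotypeSet")
}

#' Mean time to most recent common ancestor, by simulation
#'
#' @inheritParams simulateCoalescent
#' @param nReps number of independent genealogies.
#' @param seed optional seed.
#' @return TMRCA per replicate, in generations.
#' @export
simTMRCA <- function(model, samplesPerDeme, nReps, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labs <- model@popLabels
  hap <- integer(length(labs)); names(hap) <- labs
  hap[names(samplesPerDeme)] <- 2L * as.integer(samplesPerDeme)
  sim_tmrca_cpp(.modelToC(model), unname(hap), as.integer(nReps))
}

# derived-allele counts per deme for independent SNPs (fast path used by
# expectedSFS and the introgression simulations)
.simSNPCounts <- function(model, haploidPerDeme, nSNPs) {
  labs <- model@popLabels
  hap <- integer(length(labs)); names(hap) <- labs
  hap[names(haploidPerDeme)] <- as.integer(haploidPerDeme)
  cnt <- sim_snp_counts_cpp(.modelToC(model), unname(hap),
                            as.integer(nSNPs))
  colnames(cnt) <- labs
  cnt
}

#' @export
print.HaplotypeSet <- function(x, ...) {
  cat("HaplotypeSet:", nrow(x$haplotypes), "segregating sites x",
      ncol(x$haplotypes), "haplotypes\n")
  cat("  demes:", paste(unique(x$demes), collapse = ", "), "\n")
  invisible(x)
}

#' Pair haplotypes into diploid genotypes
#'
#' Haplotypes are paired at random (without replacement) within each deme;
#' the dosage is the count of derived alleles.  Missing entries are
#' injected uniformly at \code{missingRate}.
#'
#' @param haps a \code{HaplotypeSet} from \code{\link{simulateCoalescent}}.
#' @param pairingSeed seed for the pairing and missingness draws.
#' @param missingRate overrides the rate recorded in \code{haps}.
#' @param status named vector mapping deme to sample status; by default the
#'   deme called "domesticated" is domesticated, demes named "moschata",
#'   "martinezii" or "outgroup" are outgroups, everything else is wild.
#' @param popsPerDeme split each deme into this many equally sized
#'   populations (labelled deme_1, deme_2, ...), emulating multi-population
#'   sampling within taxa.
#' @return a \linkS4class{GenotypeData} (REF is the ancestral allele).
#' @export
emitGenotypes <- function(haps, pairingSeed = NULL, missingRate = NULL,
                          status = NULL, popsPerDeme = 1L) {
  if (is.null(missingRate)) missingRate <- haps$missingRate
  if (!is.null(pairingSeed)) set.seed(pairingSeed)
  demes <- haps$demes
  H <- ncol(haps$haplotypes)
  tab <- table(demes)[unique(demes)]
  if (any(tab %% 2 != 0)) stop("odd haplotype count in deme(s): ",
                               paste(names(tab)[tab %% 2 != 0],
                                     collapse = ", "))
  cols1 <- integer(0); cols2 <- integer(0); pops <- character(0)
  for (d in names(tab)) {
    idx <- which(demes == d)
    idx <- idx[sample.int(length(idx))]
    n <- length(idx) / 2
    cols1 <- c(cols1, idx[seq_len(n)])
    cols2 <- c(cols2, idx[n + seq_len(n)])
    sub <- sort(rep(seq_len(popsPerDeme), length.out = n))
    pops <- c(pops, if (popsPerDeme > 1) paste0(d, "_", sub) else rep(d, n))
  }
  dos <- haps$haplotypes[, cols1, drop = FALSE] +
    haps$haplotypes[, cols2, drop = FALSE]
  if (missingRate > 0) {
    miss <- runif(length(dos)) < missingRate
    dos[miss] <- NA
  }
  if (is.null(status)) {
    status <- setNames(rep("wild", length(tab)), names(tab))
    status[names(tab) == "domesticated"] <- "domesticated"
    status[names(tab) %in% c("moschata", "martinezii", "outgroup")] <-
      "outgroup"
  }
  demeOf <- sub("_[0-9]+$", "", pops)
  pm <- data.frame(sample = sprintf("s%03d", seq_along(pops)),
                   population = pops, status = unname(status[demeOf]))
  GenotypeData(dos, chrom = haps$chrom, pos = haps$pos, popMap = pm)
}

#' Environmental covariate from a population map
#'
#' Codes each population as wild (0) or domesticated (1).
#'
#' @param popMap data.frame(sample, population, status) or a named status
#'   vector (one entry per population).
#' @param domesticatedPops optionally name the domesticated populations
#'   explicitly instead of using the status column.
#' @return named 0/1 vector, one entry per population, in order of first
#'   appearance.
#' @export
makeEnvVector <- function(popMap, domesticatedPops = NULL) {
  if (is.data.frame(popMap)) {
    pops <- unique(popMap$population)
    st <- popMap$status[match(pops, popMap$population)]
  } else {
    pops <- names(popMap)
    st <- unname(popMap)
  }
  if (is.null(domesticatedPops)) {
    if (any(is.na(st)) || any(!nzchar(st))) stop("unlabelled population")
    env <- as.numeric(st == "domesticated")
  } else {
    if (!all(domesticatedPops %in% pops))
      stop("unknown population(s): ",
           paste(setdiff(domesticatedPops, pops), collapse = ", "))
    env <- as.numeric(pops %in% domesticatedPops)
  }
  setNames(env, pops)
}

#' Spike divergently selected loci into a genotype matrix
#'
#' Raises the derived-allele frequency of \code{nLoci} randomly chosen
#' polymorphic sites in the target samples toward fixation:
#' p' = p + shift (1 - p), and resamples the target genotypes binomially at
#' p'.  This is a post-hoc frequency manipulation emulating the elevated
#' differentiation of selected loci, not a forward selection model.
#'
#' @param gd a \linkS4class{GenotypeData}.
#' @param nLoci number of loci to spike.
#' @param targetPops populations whose samples are resampled.
#' @param shift in (0, 1]; 1 fixes the derived allele in the target.
#' @param seed optional seed.
#' @return list(geno = modified GenotypeData, truth = data.frame of spiked
#'   site ids).
#' @export
spikeSelection <- function(gd, nLoci, targetPops, shift, seed = NULL) {
  stopifnot(shift > 0, shift <= 1, nLoci >= 0)
  if (!is.null(seed)) set.seed(seed)
  d <- dosages(gd)
  p <- rowMeans(d, na.rm = TRUE) / 2
  poly <- which(p > 0 & p < 1)
  if (nLoci > length(poly)) stop("nLoci exceeds the polymorphic site count")
  if (nLoci == 0)
    return(list(geno = gd, truth = data.frame(snpId = character(),
                                              site = integer())))
  sel <- sort(sample(poly, nLoci))
  tgt <- which(populationsOf(gd) %in% targetPops)
  if (!length(tgt)) stop("no samples in the target populations")
  for (s in sel) {
    obs <- d[s, tgt]
    ok <- !is.na(obs)
    pt <- if (any(ok)) mean(obs[ok]) / 2 else 0
    pp <- pt + shift * (1 - pt)
    d[s, tgt[ok]] <- rbinom(sum(ok), 2, pp)
  }
  out <- gd
  SummarizedExperiment::assay(out, "dosage") <- d
  list(geno = out,
       truth = data.frame(snpId = rownames(d)[sel], site = sel,
                          targetPops = paste(targetPops, collapse = ","),
                          shift = shift))
}

#' Toy structural-variant call sets with a shared, jittered core
#'
#' Shared records appear in both call sets with endpoints perturbed by
#' rounded Gaussian jitter in set B; private records appear in one set
#' only.  Used to exercise the +/- 100 bp dual-caller consensus rule.
#'
#' @param nShared,nOnlyA,nOnlyB record counts.
#' @param jitterSd standard deviation (bp) of the endpoint jitter.
#' @param seed optional seed.
#' @param chromLengths named chromosome lengths.
#' @return list(A, B, truth) where A and B are \linkS4class{GRanges}
#'   call sets and truth lists the shared record ids.
#' @export
makeSVCallsets <- function(nShared, nOnlyA, nOnlyB, jitterSd = 0,
                           seed = NULL,
                           chromLengths = c(chr1 = 3e7, chr2 = 2e7)) {
  stopifnot(nShared >= 0, nOnlyA >= 0, nOnlyB >= 0, jitterSd >= 0)
  if (!is.null(seed)) set.seed(seed)
  rndSV <- function(n, prefix) {
    if (n == 0)
      return(data.frame(chrom = character(), start = integer(),
                        end = integer(), type = character(),
                        id = character(), chrom2 = character(),
                        start2 = integer(), end2 = integer(),
                        support = integer()))
    chrom <- sample(names(chromLengths), n, replace = TRUE)
    len <- pmax(50L, as.integer(round(exp(runif(n, log(500), log(5e4))))))
    start <- vapply(chrom, function(cc)
      sample.int(chromLengths[[cc]] - 1e5, 1), integer(1)) |> unname()
    type <- sample(c("CNV_gain", "CNV_loss", "inversion", "translocation"),
                   n, replace = TRUE)
    tr <- type == "translocation"
    df <- data.frame(chrom = chrom, start = start, end = start + len,
                     type = type, id = paste0(prefix, seq_len(n)),
                     chrom2 = NA_character_, start2 = NA_integer_,
                     end2 = NA_integer_, support = 10L)
    if (any(tr)) {
      df$chrom2[tr] <- sample(names(chromLengths), sum(tr), replace = TRUE)
      df$start2[tr] <- vapply(df$chrom2[tr], function(cc)
        sample.int(chromLengths[[cc]] - 1e5, 1), integer(1)) |> unname()
      df$end2[tr] <- df$start2[tr] + pmax(50L, as.integer(round(
        exp(runif(sum(tr), log(500), log(5e4))))))
    }
    df
  }
  shared <- rndSV(nShared, "sv_shared_")
  onlyA <- rndSV(nOnlyA, "sv_a_")
  onlyB <- rndSV(nOnlyB, "sv_b_")
  jit <- function(x, n) x + as.integer(round(rnorm(n, 0, jitterSd)))
  sharedB <- shared
  if (nShared > 0 && jitterSd > 0) {
    sharedB$start <- jit(sharedB$start, nShared)
    sharedB$end <- pmax(sharedB$start, jit(sharedB$end, nShared))
    tr <- sharedB$type == "translocation"
    if (any(tr)) {
      sharedB$start2[tr] <- jit(sharedB$start2[tr], sum(tr))
      sharedB$end2[tr] <- pmax(sharedB$start2[tr],
                               jit(sharedB$end2[tr], sum(tr)))
    }
  }
  A <- svCallset(rbind(shared, onlyA), "callerA")
  B <- svCallset(rbind(sharedB, onlyB), "callerB")
  list(A = A, B = B,
       truth = data.frame(id = shared$id,
                          startOffset = abs(sharedB$start - shared$start),
                          endOffset = abs(sharedB$end - shared$end)))
}

#' Toy gene intervals and gene-to-term annotation map
#'
#' @param nGenes number of gene intervals.
#' @param chromLengths named chromosome lengths.
#' @param seed optional seed.
#' @return \code{makeGeneIntervals}: a GRanges with a \code{gene_id}
#'   column; \code{makeTermMap}: data.frame(gene, term).
#' @export
makeGeneIntervals <- function(nGenes, chromLengths = c(chr1 = 3e7,
                                                       chr2 = 2e7),
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chrom <- sample(names(chromLengths), nGenes, replace = TRUE)
  start <- vapply(chrom, function(cc)
    sample.int(chromLengths[[cc]] - 1e4, 1), integer(1)) |> unname()
  len <- sample(500:5000, nGenes, replace = TRUE)
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, start + len))
  S4Vectors::mcols(gr)$gene_id <- sprintf("g%04d", seq_len(nGenes))
  sort(gr)
}

#' @rdname makeGeneIntervals
#' @param geneIds gene identifiers to annotate.
#' @param nTerms number of distinct terms.
#' @param meanTermsPerGene average annotation count per gene.
#' @export
makeTermMap <- function(geneIds, nTerms = 20, meanTermsPerGene = 2,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  terms <- sprintf("T%03d", seq_len(nTerms))
  k <- pmax(1L, rpois(length(geneIds), meanTermsPerGene))
  data.frame(gene = rep(geneIds, k),
             term = unlist(lapply(k, function(m) sample(terms, m))))
}

#' The synthetic study system: wild lineages, a domesticate and outgroups
#'
#' Builds the demographic model the synthetic data are generated under: a
#' wild taxon with two sub-lineages ("jalisco" and "southern"), a
#' domesticated deme derived from one of them, optional secondary-contact
#' gene flow between the domesticate and both wild demes, and an outgroup
#' ("moschata") for polarization.  Defaults follow the study system's
#' scale: domestication ~8,000 generations ago, wild lineages separated
#' ~30,000 generations ago, an annual life cycle (1 generation = 1 year).
#'
#' @param origin which wild deme the domesticate derives from.
#' @param geneFlowMode gene flow between the domesticate and the wild demes.
#' @param Ne named sizes for jalisco, southern, domesticated, ancestor
#'   (and moschata when \code{withOutgroup}).
#' @param tDom,tWild,tOut split times in generations.
#' @param mJD,mDJ,mSD,mDS,mJS,mSJ backward migration rates (first letter
#'   = deme the lineages are in, second = destination; J/S/D =
#'   jalisco/southern/domesticated).  The wild-wild rates only apply to
#'   continuous gene flow, which runs until the common ancestor; under
#'   secondary contact migration involves the domesticate only.
#' @param secondaryContactEnd end of the contact window, generations ago.
#' @param withOutgroup include the moschata outgroup deme.
#' @export
studyModel <- function(origin = c("jalisco", "southern"),
                       geneFlowMode = c("secondary_contact", "continuous",
                                        "none"),
                       Ne = c(jalisco = 30000, southern = 30000,
                              domesticated = 10000, ancestor = 30000,
                              moschata = 30000),
                       tDom = 8000, tWild = 30000, tOut = 6e5,
                       mJD = 5e-4, mDJ = 5e-4, mSD = 1e-4, mDS = 1e-4,
                       mJS = 0, mSJ = 0,
                       secondaryContactEnd = 4000, withOutgroup = FALSE) {
  origin <- match.arg(origin)
  geneFlowMode <- match.arg(geneFlowMode)
  demes <- c("jalisco", "southern", "domesticated")
  if (withOutgroup) demes <- c(demes, "moschata")
  sizes <- Ne[demes]
  splits <- data.frame(
    time = c(tDom, tWild),
    derived = c("domesticated", "southern"),
    ancestral = c(origin, "jalisco"),
    size = c(NA, Ne[["ancestor"]]))
  if (withOutgroup)
    splits <- rbind(splits, data.frame(time = tOut, derived = "moschata",
                                       ancestral = "jalisco", size = NA))
  mig <- matrix(0, length(demes), length(demes),
                dimnames = list(demes, demes))
  if (geneFlowMode != "none") {
    mig["jalisco", "domesticated"] <- mJD
    mig["domesticated", "jalisco"] <- mDJ
    mig["southern", "domesticated"] <- mSD
    mig["domesticated", "southern"] <- mDS
    if (geneFlowMode == "continuous") {
      mig["jalisco", "southern"] <- mJS
      mig["southern", "jalisco"] <- mSJ
    }
  }
  DemographicModel(sizes, splits, mig, geneFlowMode,
                   secondaryContactEnd = secondaryContactEnd,
                   domesticatedDeme = "domesticated")
}

#' Four-taxon frequency simulation for ABBA-BABA analyses
#'
#' Simulates derived-allele counts for the quartet (((P1, P2), P3), P4)
#' with an optional admixture pulse from P3 into P2 (the moschata-into-
#' argyrosperma direction).  Each SNP is an independent genealogy.  The
#' default split times put the P3 divergence one coalescent unit beyond
#' the P1/P2 split: incomplete lineage sorting still generates the
#' ABBA/BABA site classes the statistics rest on (as in closely related
#' congeners) while leaving the D statistic usable power at moderate
#' admixture fractions.
#'
#' @param nSNPs segregating sites.
#' @param f admixture pulse probability (P2 ancestry replaced by P3).
#' @param samples named diploid counts for p1, p2, p3, p4.
#' @param Ne diploid size for all demes.
#' @param t12,t123,tOut split times (generations).
#' @param tPulse pulse time (generations ago), must predate no split.
#' @param seed optional seed.
#' @return list(freq = site x 4 derived-frequency matrix, counts, haploids).
#' @export
simFourTaxon <- function(nSNPs, f = 0,
                         samples = c(p1 = 20, p2 = 20, p3 = 20, p4 = 2),
                         Ne = 20000, t12 = 40000, t123 = 80000,
                         tOut = 2e5, tPulse = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  demes <- c("p1", "p2", "p3", "p4")
  sizes <- setNames(rep(Ne, 4), demes)
  splits <- data.frame(time = c(t12, t123, tOut),
                       derived = c("p2", "p3", "p4"),
                       ancestral = c("p1", "p1", "p1"), size = NA)
  pulses <- if (f > 0)
    data.frame(time = tPulse, deme = "p2", source = "p3", prob = f)
  else NULL
  model <- DemographicModel(sizes, splits, pulses = pulses)
  hap <- 2L * samples[demes]
  cnt <- .simSNPCounts(model, hap, nSNPs)
  freq <- sweep(cnt, 2, as.numeric(hap), "/")
  colnames(freq) <- colnames(cnt) <- demes
  list(freq = freq, counts = cnt, haploids = hap)
}
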