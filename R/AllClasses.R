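#' GenotypeData: diploid dosages with positions and a population map
#'
#' A thin extension of \linkS4class{RangedSummarizedExperiment} holding a
#' sites-by-samples matrix of derived/alternate allele dosages in
#' \{0, 1, 2, NA\} (assay \code{"dosage"}), site positions as the row ranges
#' (width-1 \linkS4class{GRanges} with \code{ref}, \code{alt} and the
#' ancestral allele \code{aa} in \code{mcols}), and per-sample
#' \code{population} and \code{status} (\code{"wild"},
#' \code{"domesticated"}, \code{"feral"} or \code{"outgroup"}) in
#' \code{colData}.
#'
#' @export
setClass("GenotypeData", contains = "RangedSummarizedExperiment")

setValidity("GenotypeData", function(object) {
  msg <- character()
  if (!"dosage" %in% names(SummarizedExperiment::assays(object)))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- SummarizedExperiment::assay(object, "dosage")
    bad <- d[!is.na(d)]
    if (length(bad) && !all(bad %in% 0:2))
      msg <- c(msg, "dosages must be 0, 1, 2 or NA")
  }
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("population", "status") %in% colnames(cd)))
    msg <- c(msg, "colData needs 'population' and 'status' columns")
  rr <- SummarizedExperiment::rowRanges(object)
  if (length(rr)) {
    sp <- split(GenomicRanges::start(rr),
                as.character(GenomicRanges::seqnames(rr)))
    if (!all(vapply(sp, function(p) !is.unsorted(p, strictly = TRUE),
                    logical(1))))
      msg <- c(msg, "positions must be strictly increasing within chromosome")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeData object
#'
#' @param dosage numeric matrix, sites x samples, values in \{0,1,2,NA\}
#'   (dosage of the derived/alternate allele).
#' @param chrom,pos chromosome and 1-based position per site.
#' @param popMap data.frame with columns \code{sample}, \code{population},
#'   \code{status}; one row per column of \code{dosage}.
#' @param ref,alt,aa reference, alternate and ancestral allele per site.
#' @return a \linkS4class{GenotypeData}.
#' @examples
#' gd <- GenotypeData(matrix(c(0, 1, 2, 1), 2, 2), chrom = "chr1",
#'   pos = c(10, 20),
#'   popMap = data.frame(sample = c("s1", "s2"),
#'     population = c("P1", "P2"), status = c("wild", "domesticated")))
#' @export
GenotypeData <- function(dosage, chrom, pos, popMap,
                         ref = NULL, alt = NULL, aa = NULL) {
  dosage <- as.matrix(dosage)
  n <- nrow(dosage)
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  if (is.null(ref)) ref <- rep("A", n)
  if (is.null(alt)) alt <- rep("C", n)
  if (is.null(aa)) aa <- ref
  o <- order(chrom, pos)
  rr <- GenomicRanges::GRanges(chrom[o], IRanges::IRanges(pos[o], width = 1),
                               ref = ref[o], alt = alt[o], aa = aa[o])
  names(rr) <- paste0(chrom[o], ":", pos[o])
  dosage <- dosage[o, , drop = FALSE]
  rownames(dosage) <- names(rr)
  colnames(dosage) <- popMap$sample
  cd <- S4Vectors::DataFrame(population = as.character(popMap$population),
                             status = as.character(popMap$status),
                             row.names = popMap$sample)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = dosage), rowRanges = rr, colData = cd)
  new("GenotypeData", se)
}

#' @describeIn GenotypeData sites-by-samples dosage matrix
#' @param x a GenotypeData
#' @export
dosages <- function(x) SummarizedExperiment::assay(x, "dosage")

#' @describeIn GenotypeData population map (sample, population, status)
#' @export
popMap <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  data.frame(sample = rownames(cd), population = cd$population,
             status = cd$status, stringsAsFactors = FALSE)
}

#' @describeIn GenotypeData population label per sample
#' @export
populationsOf <- function(x) {
  setNames(SummarizedExperiment::colData(x)$population, colnames(x))
}

setMethod("show", "GenotypeData", function(object) {
  cat("GenotypeData:", nrow(object), "sites x", ncol(object), "samples\n")
  cat("  populations:",
      paste(unique(SummarizedExperiment::colData(object)$population),
            collapse = ", "), "\n")
  d <- SummarizedExperiment::assay(object, "dosage")
  cat(sprintf("  missing: %.2f%%\n", 100 * mean(is.na(d))))
})

#' Demographic model for the structured coalescent
#'
#' Demes with diploid effective sizes, backward-in-time split events
#' (the derived deme's lineages merge into the ancestral deme), a
#' per-generation backward migration matrix gated by the gene-flow mode,
#' and optional instantaneous admixture pulses.  Time is in generations
#' (one generation = one calendar year for an annual plant).
#'
#' @slot popLabels deme names (present-day demes).
#' @slot demeSizes named diploid effective sizes.
#' @slot splitEvents data.frame(time, derived, ancestral, size); \code{size}
#'   is the ancestral deme's size after the (backward) merge, NA = unchanged.
#' @slot migration named square matrix of backward migration rates
#'   m[i, j] per lineage per generation.
#' @slot geneFlowMode one of \code{"none"}, \code{"continuous"},
#'   \code{"secondary_contact"}.
#' @slot secondaryContactEnd time (generations before present) at which
#'   migration stops when mode is secondary contact.
#' @slot pulses data.frame(time, deme, source, prob): at \code{time}, each
#'   lineage in \code{deme} traces its ancestry to \code{source} with
#'   probability \code{prob} (a forward-time admixture pulse).
#' @slot domesticatedDeme optional name of the domesticated deme; when set,
#'   its split time must not exceed any other split time (the domesticate
#'   diverged after the wild lineages did).
#' @export
setClass("DemographicModel", representation(
  popLabels = "character", demeSizes = "numeric", splitEvents = "data.frame",
  migration = "matrix", geneFlowMode = "character",
  secondaryContactEnd = "numeric", pulses = "data.frame",
  domesticatedDeme = "character"))

setValidity("DemographicModel", function(object) {
  msg <- character()
  if (any(object@demeSizes < 1)) msg <- c(msg, "all deme sizes must be >= 1")
  se <- object@splitEvents
  if (nrow(se)) {
    if (any(se$time <= 0)) msg <- c(msg, "split times must be positive")
    if (!all(c(se$derived, se$ancestral) %in% object@popLabels))
      msg <- c(msg, "split events reference unknown demes")
    ok <- !is.na(se$size)
    if (any(ok) && any(se$size[ok] < 1))
      msg <- c(msg, "ancestral sizes must be >= 1")
  }
  m <- object@migration
  if (any(m < 0) || any(m >= 1))
    msg <- c(msg, "migration rates must satisfy 0 <= m < 1")
  if (!object@geneFlowMode %in% c("none", "continuous", "secondary_contact"))
    msg <- c(msg, "unknown gene flow mode")
  if (object@geneFlowMode == "secondary_contact" && nrow(se) &&
      object@secondaryContactEnd >= min(se$time))
    msg <- c(msg, "secondary contact must end before the earliest split")
  if (length(object@domesticatedDeme) && nrow(se)) {
    td <- se$time[se$derived == object@domesticatedDeme]
    if (length(td) && any(se$time < max(td)))
      msg <- c(msg, "the domesticated deme must diverge after the wild ones")
  }
  p <- object@pulses
  if (nrow(p) && (any(p$prob < 0) || any(p$prob > 1)))
    msg <- c(msg, "pulse probabilities must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a DemographicModel
#'
#' @param demeSizes named vector of diploid effective sizes (names are the
#'   present-day deme labels).
#' @param splitEvents data.frame(time, derived, ancestral) with optional
#'   \code{size} column (ancestral size after the merge).
#' @param migration square matrix of backward per-generation migration
#'   rates, dimnames matching the demes; default no migration.
#' @param geneFlowMode "none", "continuous" or "secondary_contact".
#' @param secondaryContactEnd generations before present at which migration
#'   switches off under secondary contact.
#' @param pulses data.frame(time, deme, source, prob); default none.
#' @param domesticatedDeme optional deme name, enforces the constraint that
#'   the domesticate split most recently.
#' @export
DemographicModel <- function(demeSizes, splitEvents = NULL, migration = NULL,
                             geneFlowMode = c("none", "continuous",
                                              "secondary_contact"),
                             secondaryContactEnd = 0,
                             pulses = NULL, domesticatedDeme = character()) {
  geneFlowMode <- match.arg(geneFlowMode)
  labs <- names(demeSizes)
  if (is.null(labs)) stop("demeSizes must be named")
  if (is.null(splitEvents))
    splitEvents <- data.frame(time = numeric(), derived = character(),
                              ancestral = character(), size = numeric())
  if (is.null(splitEvents$size)) splitEvents$size <- NA_real_
  if (is.null(migration)) {
    migration <- matrix(0, length(labs), length(labs),
                        dimnames = list(labs, labs))
  }
  if (is.null(pulses))
    pulses <- data.frame(time = numeric(), deme = character(),
                         source = character(), prob = numeric())
  new("DemographicModel", popLabels = labs, demeSizes = demeSizes,
      splitEvents = splitEvents, migration = migration,
      geneFlowMode = geneFlowMode,
      secondaryContactEnd = as.numeric(secondaryContactEnd),
      pulses = pulses, domesticatedDeme = domesticatedDeme)
}

setMethod("show", "DemographicModel", function(object) {
  cat("DemographicModel with", length(object@popLabels), "demes:",
      paste(object@popLabels, collapse = ", "), "\n")
  cat("  gene flow:", object@geneFlowMode)
  if (object@geneFlowMode == "secondary_contact")
    cat(" (until", object@secondaryContactEnd, "generations ago)")
  cat("\n  splits:", nrow(object@splitEvents),
      " pulses:", nrow(object@pulses), "\n")
})

# flatten a model for the C++ simulator (0-based deme indices)
.modelToC <- function(model) {
  labs <- model@popLabels
  idx <- function(x) match(x, labs) - 1L
  se <- model@splitEvents
  mig <- model@migration[labs, labs, drop = FALSE]
  migEnd <- switch(model@geneFlowMode,
                   none = 0,
                   continuous = Inf,
                   secondary_contact = model@secondaryContactEnd)
  p <- model@pulses
  list(N = unname(model@demeSizes[labs]),
       split_time = as.numeric(se$time),
       split_derived = idx(se$derived), split_ancestral = idx(se$ancestral),
       split_newsize = as.numeric(se$size),
       mig = unname(mig), mig_end = migEnd,
       pulse_time = as.numeric(p$time), pulse_deme = idx(p$deme),
       pulse_source = idx(p$source), pulse_prob = as.numeric(p$prob))
}

#' Unfolded multidimensional site-frequency spectrum
#'
#' Joint counts of derived-allele occurrences across demes, polarized with
#' an outgroup.  The two monomorphic corner cells (all-ancestral and
#' all-derived) are masked and carry no mass.
#'
#' @slot counts integer array, one dimension per deme, dimension d has
#'   2n_d + 1 entries (derived counts 0..2n_d).
#' @slot demes deme names in axis order.
#' @slot sampleSizes haploid sample sizes per deme.
#' @slot dropped named counts of sites excluded during polarization.
#' @export
setClass("MultiSFS", representation(
  counts = "array", demes = "character", sampleSizes = "integer",
  dropped = "integer"))

setValidity("MultiSFS", function(object) {
  msg <- character()
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  if (!identical(dim(object@counts), object@sampleSizes + 1L))
    msg <- c(msg, "array dimensions must be sampleSizes + 1")
  corner <- object@counts[matrix(c(rep(1L, length(dim(object@counts))),
                                   dim(object@counts)), 2, byrow = TRUE)]
  if (any(corner != 0)) msg <- c(msg, "monomorphic corner cells must be 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn MultiSFS total polymorphic (polarized) site count
#' @param x a MultiSFS
#' @export
msfsTotal <- function(x) sum(x@counts)

setMethod("show", "MultiSFS", function(object) {
  cat("MultiSFS over", paste(object@demes, collapse = " x "),
      sprintf("(haploid sizes %s)\n",
              paste(object@sampleSizes, collapse = ", ")))
  cat("  polarized SNPs:", sum(object@counts),
      " dropped:", sum(object@dropped), "\n")
})

#' Result of fitting one demographic scenario to an observed MultiSFS
#'
#' @slot modelId scenario identifier.
#' @slot par maximum composite-likelihood parameter estimates.
#' @slot lnL maximized composite log-likelihood (natural log).
#' @slot k number of free parameters.
#' @slot AIC 2k - 2 lnL.
#' @slot obsSignature fingerprint of the observed spectrum used, so fits on
#'   different data cannot be ranked together by mistake.
#' @export
setClass("FitResult", representation(
  modelId = "character", par = "numeric", lnL = "numeric", k = "integer",
  AIC = "numeric", obsSignature = "numeric"))

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult [%s]: lnL = %.2f, k = %d, AIC = %.2f\n",
              object@modelId, object@lnL, object@k, object@AIC))
  print(round(object@par, 4))
})
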