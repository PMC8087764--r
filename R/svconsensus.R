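#' Dual-caller structural-variant consensus
#'
#' A record from call set A is retained when call set B holds a record of
#' the same chromosome and type whose start and end both lie within
#' \code{tol} bp.  Matching is one-to-one and greedy by smallest total
#' endpoint offset (ties broken by leftmost A record).  Translocations
#' must satisfy the rule at both loci.  Records of type "unaligned"
#' bypass matching (they come from the whole-genome aligner only) and are
#' returned in a separate channel.  Exact duplicate records within one
#' caller are deduplicated with a warning.
#'
#' @param a,b \linkS4class{GRanges} call sets (see
#'   \code{\link{svCallset}}).
#' @param tol endpoint tolerance in bp (default 100).
#' @return list(consensus = matched A records, matches = data.frame of
#'   matched pairs with offsets, unaligned = unaligned-region records).
#' @export
consensusSVs <- function(a, b, tol = 100) {
  dedup <- function(x, lab) {
    key <- paste(GenomicRanges::seqnames(x), GenomicRanges::start(x),
                 GenomicRanges::end(x), S4Vectors::mcols(x)$type)
    if (anyDuplicated(key)) {
      warning("duplicate records in ", lab, " deduplicated")
      x <- x[!duplicated(key)]
    }
    x
  }
  a <- dedup(a, "call set A")
  b <- dedup(b, "call set B")
  una <- a[S4Vectors::mcols(a)$type == "unaligned"]
  aM <- a[S4Vectors::mcols(a)$type != "unaligned"]
  bM <- b[S4Vectors::mcols(b)$type != "unaligned"]
  am <- data.frame(chrom = as.character(GenomicRanges::seqnames(aM)),
                   start = GenomicRanges::start(aM),
                   end = GenomicRanges::end(aM),
                   type = S4Vectors::mcols(aM)$type,
                   id = S4Vectors::mcols(aM)$id,
                   chrom2 = S4Vectors::mcols(aM)$chrom2,
                   start2 = S4Vectors::mcols(aM)$start2,
                   end2 = S4Vectors::mcols(aM)$end2,
                   idx = seq_along(aM))
  bm <- data.frame(chrom = as.character(GenomicRanges::seqnames(bM)),
                   start = GenomicRanges::start(bM),
                   end = GenomicRanges::end(bM),
                   type = S4Vectors::mcols(bM)$type,
                   id = S4Vectors::mcols(bM)$id,
                   chrom2 = S4Vectors::mcols(bM)$chrom2,
                   start2 = S4Vectors::mcols(bM)$start2,
                   end2 = S4Vectors::mcols(bM)$end2,
                   idx = seq_along(bM))
  pairs <- list()
  for (key in unique(paste(am$chrom, am$type))) {
    ai <- am[paste(am$chrom, am$type) == key, , drop = FALSE]
    bi <- bm[paste(bm$chrom, bm$type) == key, , drop = FALSE]
    if (!nrow(ai) || !nrow(bi)) next
    for (i in seq_len(nrow(ai))) {
      ds <- abs(bi$start - ai$start[i])
      de <- abs(bi$end - ai$end[i])
      okp <- ds <= tol & de <= tol
      if (ai$type[i] == "translocation") {
        okp <- okp & !is.na(bi$chrom2) & !is.na(ai$chrom2[i]) &
          bi$chrom2 == ai$chrom2[i] &
          abs(bi$start2 - ai$start2[i]) <= tol &
          abs(bi$end2 - ai$end2[i]) <= tol
      }
      if (any(okp, na.rm = TRUE)) {
        w <- which(okp)
        pairs[[length(pairs) + 1]] <- data.frame(
          aIdx = ai$idx[i], bIdx = bi$idx[w], aId = ai$id[i],
          bId = bi$id[w], totalOffset = ds[w] + de[w],
          dStart = ds[w], dEnd = de[w])
      }
    }
  }
  if (length(pairs)) {
    cand <- do.call(rbind, pairs)
    cand <- cand[order(cand$totalOffset, cand$aIdx), ]
    usedA <- logical(length(aM)); usedB <- logical(length(bM))
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      if (!usedA[cand$aIdx[i]] && !usedB[cand$bIdx[i]]) {
        keep[i] <- TRUE
        usedA[cand$aIdx[i]] <- TRUE
        usedB[cand$bIdx[i]] <- TRUE
      }
    }
    matches <- cand[keep, c("aId", "bId", "dStart", "dEnd",
                            "totalOffset")]
    rownames(matches) <- NULL
    consensus <- aM[sort(unique(cand$aIdx[keep]))]
  } else {
    matches <- data.frame(aId = character(), bId = character(),
                          dStart = integer(), dEnd = integer(),
                          totalOffset = integer())
    consensus <- aM[integer(0)]
  }
  list(consensus = consensus, matches = matches, unaligned = una)
}

#' Assign genes to structural variants
#'
#' Inversions and translocations take any gene overlapping by at least
#' 1 bp; copy-number variants and unaligned regions take only genes
#' contained entirely within the variant.
#'
#' @param svs \linkS4class{GRanges} of SVs with a \code{type} column.
#' @param genes \linkS4class{GRanges} of gene intervals with a
#'   \code{gene_id} column (1-based inclusive).
#' @return data.frame(svId, type, gene).
#' @export
assignGenes <- function(svs, genes) {
  types <- S4Vectors::mcols(svs)$type
  vocab <- c("CNV_gain", "CNV_loss", "inversion", "translocation",
             "unaligned")
  if (any(!types %in% vocab))
    stop("unknown SV type(s): ",
         paste(setdiff(unique(types), vocab), collapse = ", "))
  overlapTypes <- types %in% c("inversion", "translocation")
  res <- list()
  if (any(overlapTypes)) {
    hits <- GenomicRanges::findOverlaps(svs[overlapTypes], genes)
    if (length(hits))
      res$any <- data.frame(
        svId = S4Vectors::mcols(svs[overlapTypes])$id[
          S4Vectors::queryHits(hits)],
        type = types[overlapTypes][S4Vectors::queryHits(hits)],
        gene = S4Vectors::mcols(genes)$gene_id[S4Vectors::subjectHits(hits)])
  }
  if (any(!overlapTypes)) {
    hits <- GenomicRanges::findOverlaps(genes, svs[!overlapTypes],
                                        type = "within")
    if (length(hits))
      res$within <- data.frame(
        svId = S4Vectors::mcols(svs[!overlapTypes])$id[
          S4Vectors::subjectHits(hits)],
        type = types[!overlapTypes][S4Vectors::subjectHits(hits)],
        gene = S4Vectors::mcols(genes)$gene_id[S4Vectors::queryHits(hits)])
  }
  if (!length(res))
    return(data.frame(svId = character(), type = character(),
                      gene = character()))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$svId, out$gene), ]
}

#' Fisher-exact term enrichment
#'
#' One-sided Fisher's exact test per annotation term on the 2x2 table of
#' foreground/background membership against term annotation.
#'
#' @param foreground gene ids of interest (must be a subset of the
#'   universe).
#' @param universe all gene ids.
#' @param termMap data.frame(gene, term).
#' @param alpha significance cutoff (default 0.05).
#' @return data.frame(term, fgWith, fgWithout, bgWith, bgWithout, p,
#'   enriched), sorted by p.
#' @export
fisherEnrichment <- function(foreground, universe, termMap, alpha = 0.05) {
  foreground <- unique(foreground)
  universe <- unique(universe)
  if (!all(foreground %in% universe))
    stop("foreground must be a subset of the universe")
  if (!length(foreground))
    return(data.frame(term = character(), fgWith = integer(),
                      fgWithout = integer(), bgWith = integer(),
                      bgWithout = integer(), p = numeric(),
                      enriched = logical()))
  termMap <- termMap[termMap$gene %in% universe, , drop = FALSE]
  terms <- unique(termMap$term)
  bg <- setdiff(universe, foreground)
  res <- lapply(terms, function(tt) {
    withTerm <- unique(termMap$gene[termMap$term == tt])
    a <- sum(foreground %in% withTerm)
    b <- length(foreground) - a
    cc <- sum(bg %in% withTerm)
    dd <- length(bg) - cc
    p <- fisher.test(matrix(c(a, b, cc, dd), 2, byrow = TRUE),
                     alternative = "greater")$p.value
    data.frame(term = tt, fgWith = a, fgWithout = b, bgWith = cc,
               bgWithout = dd, p = p, enriched = p < alpha)
  })
  out <- do.call(rbind, res)
  out[order(out$p), ]
}
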