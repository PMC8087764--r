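svdf <- function(...) {
  df <- data.frame(...)
  if (is.null(df$id)) df$id <- paste0("r", seq_len(nrow(df)))
  df
}

test_that("the +/-100 bp rule keeps exact matches and drops boundary
           violations", {
  a <- svCallset(svdf(chrom = "chr1", start = 1000, end = 2000,
                      type = "inversion"), "A")
  bSame <- svCallset(svdf(chrom = "chr1", start = 1000, end = 2000,
                          type = "inversion"), "B")
  expect_length(consensusSVs(a, bSame)$consensus, 1)
  # start offset 101 -> rejected even with a perfect end
  bOff <- svCallset(svdf(chrom = "chr1", start = 1101, end = 2000,
                         type = "inversion"), "B")
  expect_length(consensusSVs(a, bOff)$consensus, 0)
  bEdge <- svCallset(svdf(chrom = "chr1", start = 1100, end = 2100,
                          type = "inversion"), "B")
  expect_length(consensusSVs(a, bEdge)$consensus, 1)
  # same coordinates but different type never match
  bType <- svCallset(svdf(chrom = "chr1", start = 1000, end = 2000,
                          type = "CNV_loss"), "B")
  expect_length(consensusSVs(a, bType)$consensus, 0)
})

test_that("consensus equals a quadratic all-pairs oracle on jittered
           call sets", {
  consensusOracle <- function(a, b, tol = 100) {
    am <- as.data.frame(a); bm <- as.data.frame(b)
    am$type <- S4Vectors::mcols(a)$type; bm$type <- S4Vectors::mcols(b)$type
    cand <- list()
    for (i in seq_len(nrow(am))) for (j in seq_len(nrow(bm))) {
      if (am$seqnames[i] != bm$seqnames[j]) next
      if (am$type[i] != bm$type[j]) next
      if (am$type[i] == "unaligned") next
      ds <- abs(am$start[i] - bm$start[j])
      de <- abs(am$end[i] - bm$end[j])
      okTr <- TRUE
      if (am$type[i] == "translocation") {
        a2 <- S4Vectors::mcols(a)[i, ]; b2 <- S4Vectors::mcols(b)[j, ]
        okTr <- !is.na(a2$chrom2) && !is.na(b2$chrom2) &&
          a2$chrom2 == b2$chrom2 &&
          abs(a2$start2 - b2$start2) <= tol &&
          abs(a2$end2 - b2$end2) <= tol
      }
      if (ds <= tol && de <= tol && okTr)
        cand[[length(cand) + 1]] <- c(i, j, ds + de)
    }
    if (!length(cand)) return(integer(0))
    cand <- do.call(rbind, cand)
    cand <- cand[order(cand[, 3], cand[, 1]), , drop = FALSE]
    usedA <- usedB <- integer(0); keep <- integer(0)
    for (r in seq_len(nrow(cand))) {
      if (cand[r, 1] %in% usedA || cand[r, 2] %in% usedB) next
      keep <- c(keep, cand[r, 1])
      usedA <- c(usedA, cand[r, 1]); usedB <- c(usedB, cand[r, 2])
    }
    sort(keep)
  }
  for (s in 1:8) {
    cs <- makeSVCallsets(30, 10, 10, jitterSd = 40, seed = 400 + s)
    got <- consensusSVs(cs$A, cs$B)
    oracleIdx <- consensusOracle(cs$A, cs$B)
    expect_identical(S4Vectors::mcols(got$consensus)$id,
                     S4Vectors::mcols(cs$A)$id[oracleIdx])
    # consensus records come from call set A, no invented coordinates
    expect_true(all(S4Vectors::mcols(got$consensus)$id %in%
                      S4Vectors::mcols(cs$A)$id))
    # matched pair set is direction-symmetric
    swapped <- consensusSVs(cs$B, cs$A)
    expect_setequal(paste(got$matches$aId, got$matches$bId),
                    paste(swapped$matches$bId, swapped$matches$aId))
  }
})

test_that("unaligned records bypass matching; duplicates warn", {
  a <- svCallset(svdf(chrom = c("chr1", "chr1"),
                      start = c(100, 5000), end = c(900, 9000),
                      type = c("unaligned", "inversion")), "A")
  b <- svCallset(svdf(chrom = "chr1", start = 5000, end = 9000,
                      type = "inversion"), "B")
  res <- consensusSVs(a, b)
  expect_length(res$unaligned, 1)
  expect_length(res$consensus, 1)
  dupA <- svCallset(svdf(chrom = c("chr1", "chr1"),
                         start = c(100, 100), end = c(200, 200),
                         type = c("CNV_gain", "CNV_gain"),
                         id = c("d1", "d2")), "A")
  expect_warning(consensusSVs(dupA, b), "duplicate")
})

test_that("read-support filtering and type vocabulary are enforced", {
  df <- svdf(chrom = "chr1", start = c(1, 100), end = c(50, 200),
             type = "inversion", support = c(3L, 10L))
  expect_message(x <- svCallset(df, "sniffles", minSupport = 6),
                 "support")
  expect_length(x, 1)
  expect_error(svCallset(svdf(chrom = "chr1", start = 1, end = 2,
                              type = "weird"), "A"), "unknown SV type")
  expect_error(svCallset(svdf(chrom = "chr1", start = 10, end = 2,
                              type = "inversion"), "A"), "start")
})

test_that("gene assignment distinguishes overlap from containment", {
  svs <- svCallset(svdf(chrom = c("chr1", "chr1"),
                        start = c(1000, 1000), end = c(2000, 2000),
                        type = c("inversion", "CNV_gain"),
                        id = c("inv1", "cnv1")), "A")
  genes <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(c(1500, 1100),
                                                   c(2500, 1200)))
  S4Vectors::mcols(genes)$gene_id <- c("half", "inside")
  res <- assignGenes(svs, genes)
  expect_setequal(res$gene[res$svId == "inv1"], c("half", "inside"))
  expect_equal(res$gene[res$svId == "cnv1"], "inside")
})

test_that("gene assignment equals a brute-force interval oracle", {
  set.seed(11)
  genes <- makeGeneIntervals(100, seed = 12)
  cs <- makeSVCallsets(20, 0, 0, jitterSd = 0, seed = 13)
  svs <- cs$A
  res <- assignGenes(svs, genes)
  gdf <- as.data.frame(genes); sdf <- as.data.frame(svs)
  sdf$type <- S4Vectors::mcols(svs)$type
  sdf$id <- S4Vectors::mcols(svs)$id
  pairs <- character(0)
  for (i in seq_len(nrow(sdf))) for (j in seq_len(nrow(gdf))) {
    if (sdf$seqnames[i] != gdf$seqnames[j]) next
    ov <- min(sdf$end[i], gdf$end[j]) - max(sdf$start[i], gdf$start[j])
    contained <- gdf$start[j] >= sdf$start[i] && gdf$end[j] <= sdf$end[i]
    hit <- if (sdf$type[i] %in% c("inversion", "translocation"))
      ov >= 0 else contained
    if (hit) pairs <- c(pairs,
                        paste(sdf$id[i], S4Vectors::mcols(genes)$gene_id[j]))
  }
  expect_setequal(paste(res$svId, res$gene), pairs)
  # containment implies overlap
  cnv <- res[res$type %in% c("CNV_gain", "CNV_loss"), ]
  for (r in seq_len(nrow(cnv))) {
    g <- genes[S4Vectors::mcols(genes)$gene_id == cnv$gene[r]]
    sv <- svs[S4Vectors::mcols(svs)$id == cnv$svId[r]]
    expect_gte(length(GenomicRanges::findOverlaps(g, sv)), 1)
  }
})

test_that("Fisher enrichment equals the hypergeometric tail oracle", {
  # a=5 fg-with, b=5 fg-without, c=5 bg-with, d=85 bg-without
  fg <- paste0("f", 1:10)
  bg <- paste0("b", 1:90)
  term <- data.frame(gene = c(fg[1:5], bg[1:5]), term = "T1")
  res <- fisherEnrichment(fg, c(fg, bg), term)
  oracle <- sum(vapply(5:10, function(k)
    choose(10, k) * choose(90, 10 - k) / choose(100, 10), numeric(1)))
  expect_equal(res$p, oracle, tolerance = 1e-12)
  expect_equal(res[, c("fgWith", "fgWithout", "bgWith", "bgWithout")],
               data.frame(fgWith = 5L, fgWithout = 5L, bgWith = 5L,
                          bgWithout = 85L), ignore_attr = TRUE)
  # foreground = universe -> all p = 1
  resAll <- fisherEnrichment(c(fg, bg), c(fg, bg), term)
  expect_true(all(resAll$p == 1))
  # empty foreground -> empty result
  expect_equal(nrow(fisherEnrichment(character(0), fg, term)), 0)
  # term with no foreground genes never enriched
  t2 <- data.frame(gene = bg[6:20], term = "T2")
  r2 <- fisherEnrichment(fg, c(fg, bg), t2)
  expect_false(any(r2$enriched))
  expect_error(fisherEnrichment("zzz", fg, term), "subset")
})
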