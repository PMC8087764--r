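#' Write a GenotypeData object as VCFv4.2
#'
#' Emits GT genotypes (unphased) with the ancestral allele in the \code{AA}
#' INFO tag.  The ancestral allele is the REF allele for simulator output.
#'
#' @param x a \linkS4class{GenotypeData}.
#' @param file output path.
#' @return invisibly, the file path.
#' @export
writeVCF <- function(x, file) {
  rr <- SummarizedExperiment::rowRanges(x)
  d <- dosages(x)
  gt <- matrix("./.", nrow(d), ncol(d))
  gt[!is.na(d) & d == 0] <- "0/0"
  gt[!is.na(d) & d == 1] <- "0/1"
  gt[!is.na(d) & d == 2] <- "1/1"
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(x)), collapse = "\t"))
  body <- cbind(as.character(GenomicRanges::seqnames(rr)),
                GenomicRanges::start(rr), names(rr),
                S4Vectors::mcols(rr)$ref, S4Vectors::mcols(rr)$alt, ".",
                "PASS", paste0("AA=", S4Vectors::mcols(rr)$aa), "GT", gt)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(file)
}

#' Read a VCF (plus population map) into a GenotypeData object
#'
#' Keeps biallelic SNPs only.  Genotypes are converted to alternate-allele
#' dosages; the ancestral allele is taken from the \code{AA} INFO tag when
#' present, otherwise REF is assumed ancestral.
#'
#' @param file VCF path (may be gzipped).
#' @param popMap data.frame(sample, population, status) or path to a
#'   tab-separated file with those columns.
#' @return a \linkS4class{GenotypeData}.
#' @export
readVCF <- function(file, popMap) {
  if (is.character(popMap)) popMap <- readPopMap(popMap)
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  bi <- vcfR::is.biallelic(v)
  snp <- !vcfR::is.indel(v)
  v <- v[bi & snp, ]
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  a1 <- substr(gt, 1, 1); a2 <- substr(gt, 3, 3)
  dos <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  ok <- a1 %in% c("0", "1") & a2 %in% c("0", "1")
  dos[ok] <- as.numeric(a1[ok]) + as.numeric(a2[ok])
  info <- vcfR::extract.info(v, "AA")
  aa <- ifelse(is.na(info), fix[, "REF"], info)
  keep <- match(colnames(dos), popMap$sample)
  if (anyNA(keep)) stop("samples missing from the population map: ",
                        paste(colnames(dos)[is.na(keep)], collapse = ", "))
  GenotypeData(dos, chrom = fix[, "CHROM"], pos = as.numeric(fix[, "POS"]),
               popMap = popMap[keep, ], ref = fix[, "REF"],
               alt = fix[, "ALT"], aa = aa)
}

#' @rdname readVCF
#' @export
readPopMap <- function(file) {
  pm <- utils::read.table(file, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  colnames(pm)[1:3] <- c("sample", "population", "status")
  pm
}

#' @rdname readVCF
#' @param x data.frame(sample, population, status)
#' @param file output path
#' @export
writePopMap <- function(x, file) {
  utils::write.table(x[, c("sample", "population", "status")], file,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(file)
}

#' Serialize a MultiSFS as flattened text
#'
#' dadi-style layout: a header line with the axis sizes and deme names, a
#' line of flattened counts (last axis fastest), and a mask line.
#'
#' @param x a \linkS4class{MultiSFS}.
#' @param file output path.
#' @export
writeMSFS <- function(x, file) {
  dims <- dim(x@counts)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste(c(dims, x@demes), collapse = " "), con)
  flat <- aperm(x@counts)  # last axis fastest
  writeLines(paste(as.vector(flat), collapse = " "), con)
  m <- array(0L, dims)
  m[matrix(rep(1L, length(dims)), 1)] <- 1L
  m[matrix(dims, 1)] <- 1L
  writeLines(paste(as.vector(aperm(m)), collapse = " "), con)
  invisible(file)
}

#' @rdname writeMSFS
#' @export
readMSFS <- function(file) {
  ln <- readLines(file)
  hd <- strsplit(trimws(ln[1]), "\\s+")[[1]]
  nd <- length(hd) / 2
  dims <- as.integer(hd[seq_len(nd)])
  demes <- hd[nd + seq_len(nd)]
  cnt <- as.numeric(strsplit(trimws(ln[2]), "\\s+")[[1]])
  a <- aperm(array(cnt, rev(dims)))
  new("MultiSFS", counts = a, demes = demes,
      sampleSizes = dims - 1L, dropped = c(unpolarizable = 0L))
}

#' Read/write structural-variant call sets
#'
#' Tab-separated records with 1-based inclusive coordinates:
#' \code{chrom start end type id [chrom2 start2 end2] [support]}.  BED-like
#' 0-based half-open input can be converted with \code{bedToOneBased}.
#'
#' @param file path to a TSV with columns chrom, start, end, type, id and
#'   optionally chrom2, start2, end2, support.
#' @param caller caller label stored on each record.
#' @param minSupport drop records with read support below this (used for
#'   read-based callers; NA keeps everything).
#' @return a \linkS4class{GRanges} with metadata columns caller, type, id,
#'   and partner-locus columns for translocations.
#' @export
readSVCallset <- function(file, caller, minSupport = NA) {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  svCallset(df, caller, minSupport = minSupport)
}

#' @rdname readSVCallset
#' @param df data.frame of records (same columns as the file format).
#' @export
svCallset <- function(df, caller, minSupport = NA) {
  vocab <- c("CNV_gain", "CNV_loss", "inversion", "translocation",
             "unaligned")
  if (!all(df$type %in% vocab))
    stop("unknown SV type(s): ",
         paste(setdiff(unique(df$type), vocab), collapse = ", "))
  if (any(df$start > df$end)) stop("SV records need start <= end")
  if (!is.na(minSupport) && "support" %in% names(df)) {
    drop <- !is.na(df$support) & df$support < minSupport
    if (any(drop)) {
      message(sum(drop), " record(s) below the read-support threshold removed")
      df <- df[!drop, , drop = FALSE]
    }
  }
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start, df$end))
  S4Vectors::mcols(gr)$caller <- caller
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$id <- if (!is.null(df$id)) df$id else
    paste0(caller, "_", seq_len(nrow(df)))
  for (cc in c("chrom2", "start2", "end2", "support"))
    S4Vectors::mcols(gr)[[cc]] <- if (!is.null(df[[cc]])) df[[cc]] else NA
  gr
}

#' @rdname readSVCallset
#' @param bed data.frame with 0-based half-open start/end
#' @export
bedToOneBased <- function(bed) {
  bed$start <- bed$start + 1L
  bed
}

#' @rdname readSVCallset
#' @param x GRanges callset to write
#' @export
writeSVCallset <- function(x, file) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(x)),
                   start = GenomicRanges::start(x),
                   end = GenomicRanges::end(x),
                   type = S4Vectors::mcols(x)$type,
                   id = S4Vectors::mcols(x)$id,
                   chrom2 = S4Vectors::mcols(x)$chrom2,
                   start2 = S4Vectors::mcols(x)$start2,
                   end2 = S4Vectors::mcols(x)$end2,
                   support = S4Vectors::mcols(x)$support)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
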