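#' Default pipeline configuration
#'
#' Every stage threshold lives in the configuration, never hard-coded in
#' the stages, so sensitivity re-runs (e.g. repeating the demographic
#' fits without the Hardy-Weinberg filter) only touch the config.  The
#' numeric defaults are the study-standard values: MAF 1\%, 50\%
#' missingness, HWE p 0.01, LD r2 0.25 in 100 kbp windows with 100 bp
#' step, 100 bootstraps, 10 principal components, K = 2 (PCA scan) and
#' K = 6 (latent factors), alpha 0.05, 2-test consensus, 500/250 SNP
#' D-statistic windows, 100 bp SV tolerance, 40 fit cycles.
#'
#' @return nested named list.
#' @export
defaultConfig <- function() {
  list(
    seed = 1,
    outDir = "cushaw_run",
    input = list(vcf = NULL, popmap = NULL),
    simdata = list(enabled = TRUE, nSNPs = 2000,
                   samplesPerDeme = list(jalisco = 10, southern = 10,
                                         domesticated = 10, moschata = 5),
                   missingRate = 0.05, popsPerDeme = 2,
                   origin = "jalisco",
                   geneFlowMode = "secondary_contact",
                   nSpiked = 0, spikeShift = 1),
    filters = list(mafMin = 0.01, maxSiteMissing = 0.5,
                   maxSampleMissing = 0.5, hweP = 0.01, ldR2 = 0.25,
                   ldWindowBp = 100000, ldStepBp = 100),
    diversity = list(nBoot = 100, level = 0.95, nComponents = 10),
    demography = list(enabled = TRUE, nCycles = 40, simsPerEval = 200000,
                      nInit = 10, minCount = 1),
    scans = list(kPcadapt = 2, kLfmm = 6, alpha = 0.05, minTests = 2,
                 ridgeLambda = 1e-5,
                 bayescenv = list(pilotRuns = 20, pilotLen = 10000,
                                  burnIn = 100000, sampleIters = 100000,
                                  thin = 20)),
    introgression = list(enabled = TRUE, windowSnps = 500,
                         stepSnps = 250, nBlocks = 20, hi = 0.8,
                         lo = 0.2,
                         simdata = list(nSNPs = 5000, f = 0.1)),
    sv = list(enabled = TRUE, tol = 100, alpha = 0.05,
              callsetA = NULL, callsetB = NULL, genes = NULL,
              terms = NULL,
              simdata = list(nShared = 50, nOnlyA = 20, nOnlyB = 20,
                             jitterSd = 20)))
}

#' Read and write pipeline configurations
#'
#' YAML configurations are merged over the defaults, so a config file
#' only needs the fields it changes.  parse -> serialize -> parse is the
#' identity.
#'
#' @param path YAML file.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  mergeLists(defaultConfig(), user)
}

#' @rdname readPipelineConfig
#' @param config nested configuration list.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

mergeLists <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(base[[nm]])))
      base[nm] <- list(mergeLists(base[[nm]], override[[nm]]))
    else base[nm] <- list(override[[nm]])   # keeps explicit NULLs
  }
  base
}

#' Validate a pipeline configuration
#'
#' @param config nested list (or YAML path).
#' @return character vector of violations, empty when the config is valid.
#' @export
validateConfig <- function(config) {
  if (is.character(config)) config <- readPipelineConfig(config)
  v <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  inRange <- function(x, lo, hi) is.numeric(x) && length(x) == 1 &&
    !is.na(x) && x >= lo && x <= hi
  f <- config$filters
  chk(inRange(f$mafMin, 0, 0.5), "filters.mafMin must be in [0, 0.5]")
  chk(inRange(f$maxSiteMissing, 0, 1),
      "filters.maxSiteMissing must be in [0, 1]")
  chk(inRange(f$maxSampleMissing, 0, 1),
      "filters.maxSampleMissing must be in [0, 1]")
  chk(inRange(f$hweP, 0, 1), "filters.hweP must be in [0, 1]")
  chk(inRange(f$ldR2, 0, 1), "filters.ldR2 must be in [0, 1]")
  chk(inRange(f$ldWindowBp, 1, Inf), "filters.ldWindowBp must be positive")
  chk(inRange(config$diversity$nBoot, 2, Inf),
      "diversity.nBoot must be at least 2")
  chk(inRange(config$scans$alpha, 0, 1), "scans.alpha must be in [0, 1]")
  chk(inRange(config$scans$minTests, 1, 3),
      "scans.minTests must be between 1 and 3")
  chk(inRange(config$introgression$windowSnps, 2, Inf),
      "introgression.windowSnps must be at least 2")
  chk(inRange(config$sv$tol, 0, Inf), "sv.tol must be non-negative")
  chk(inRange(config$demography$nCycles, 0, Inf),
      "demography.nCycles must be non-negative")
  if (!isTRUE(config$simdata$enabled)) {
    chk(is.character(config$input$vcf) && file.exists(config$input$vcf),
        "input.vcf missing or not found")
    chk(is.character(config$input$popmap) &&
          file.exists(config$input$popmap),
        "input.popmap missing or not found")
  }
  v
}

.writeStage <- function(outDir, stage, table, metrics) {
  utils::write.table(table, file.path(outDir, paste0(stage, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(metrics,
                       file.path(outDir, paste0(stage, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages in the study's order — input (simulated or
#' VCF), filter cascade, diversity/structure, demographic model
#' comparison, selection scans, introgression, structural variants —
#' writing one TSV plus a JSON metrics sidecar per stage, a log of seeds
#' and parameters, and a \code{summary.md}.  A stage failure halts the
#' run with a stage-named error; outputs of completed stages are kept.
#'
#' @param config nested list (see \code{\link{defaultConfig}}) or YAML
#'   path.
#' @param outDir overrides \code{config$outDir}.
#' @return invisibly, a list of stage summaries.
#' @export
runPipeline <- function(config = defaultConfig(), outDir = NULL) {
  if (is.character(config)) config <- readPipelineConfig(config)
  viol <- validateConfig(config)
  if (length(viol))
    stop("invalid configuration:\n  ", paste(viol, collapse = "\n  "))
  if (is.null(outDir)) outDir <- config$outDir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  log <- c(paste("cushaw pipeline run,", format(Sys.time())),
           paste("seed:", seed))
  summaryLines <- c("# Pipeline summary", "")
  out <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # ---- input -------------------------------------------------------
  gd <- stage("input", {
    if (isTRUE(config$simdata$enabled)) {
      sc <- config$simdata
      model <- studyModel(origin = sc$origin,
                          geneFlowMode = sc$geneFlowMode,
                          withOutgroup = TRUE)
      spd <- unlist(sc$samplesPerDeme)
      haps <- simulateCoalescent(model, simParams(
        samplesPerDeme = spd, nSNPs = sc$nSNPs,
        seed = stageSeed(seed, 1)))
      g <- emitGenotypes(haps, pairingSeed = stageSeed(seed, 2),
                         missingRate = sc$missingRate,
                         popsPerDeme = sc$popsPerDeme)
      if (sc$nSpiked > 0) {
        domPops <- unique(popMap(g)$population[
          popMap(g)$status == "domesticated"])
        g <- spikeSelection(g, sc$nSpiked, domPops, sc$spikeShift,
                            seed = stageSeed(seed, 3))$geno
      }
      writeVCF(g, file.path(outDir, "genotypes.vcf"))
      writePopMap(popMap(g), file.path(outDir, "popmap.tsv"))
      g
    } else readVCF(config$input$vcf, config$input$popmap)
  })
  log <- c(log, paste("input:", nrow(gd), "sites,", ncol(gd), "samples"))

  # ---- filters -----------------------------------------------------
  filt <- stage("filters", {
    f <- config$filters
    r1 <- filterSites(gd, f$mafMin, f$maxSiteMissing, f$maxSampleMissing)
    hwe <- hweTest(r1$geno)
    keepHWE <- is.na(hwe) | hwe >= f$hweP
    g2 <- r1$geno[keepHWE, ]
    kept <- ldPrune(g2, f$ldR2, f$ldWindowBp, f$ldStepBp)
    g3 <- g2[kept, ]
    report <- rbind(r1$report,
                    data.frame(step = c("hwe", "ld_prune"),
                               removed = c(sum(!keepHWE),
                                           nrow(g2) - length(kept)),
                               sitesLeft = c(nrow(g2), nrow(g3)),
                               samplesLeft = ncol(g3)))
    .writeStage(outDir, "filters", report,
                list(sites_in = nrow(gd), sites_out = nrow(g3),
                     samples_out = ncol(g3)))
    list(geno = g3, report = report)
  })
  gf <- filt$geno
  summaryLines <- c(summaryLines, "## SNP filtering", "",
                    paste0("| ", paste(colnames(filt$report),
                                       collapse = " | "), " |"),
                    paste0("|", paste(rep("---",
                                          ncol(filt$report)),
                                      collapse = "|"), "|"),
                    apply(filt$report, 1, function(r)
                      paste0("| ", paste(r, collapse = " | "), " |")), "")

  # ---- diversity ---------------------------------------------------
  divr <- stage("diversity", {
    pi <- nucleotideDiversity(gf, by = "status")
    ing <- gf[, SummarizedExperiment::colData(gf)$status != "outgroup"]
    fst <- bootstrapFstCI(ing, nBoot = config$diversity$nBoot,
                          level = config$diversity$level,
                          seed = stageSeed(seed, 4), by = "status")
    pca <- genotypePCA(ing, config$diversity$nComponents)
    utils::write.table(
      data.frame(sample = rownames(pca$scores), pca$scores),
      file.path(outDir, "pca_scores.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    .writeStage(outDir, "diversity", pi,
                list(fst = fst$theta, fst_lower = fst$ci[1],
                     fst_upper = fst$ci[2],
                     pi = setNames(as.list(pi$pi), pi$population)))
    list(pi = pi, fst = fst, pca = pca)
  })
  summaryLines <- c(summaryLines, "## Diversity and structure", "",
                    sprintf("- wild vs domesticated F_ST = %.4f (%.0f%% CI %.4f-%.4f)",
                            divr$fst$theta, 100 * config$diversity$level,
                            divr$fst$ci[1], divr$fst$ci[2]),
                    sprintf("- pi (%s) = %.4f", divr$pi$population,
                            divr$pi$pi), "")

  # ---- demography --------------------------------------------------
  if (isTRUE(config$demography$enabled)) {
    demo <- stage("demography", {
      pm <- popMap(gf)
      demePops <- function(d)
        unique(pm$population[grepl(paste0("^", d), pm$population)])
      pops <- list(jalisco = demePops("jalisco"),
                   southern = demePops("southern"),
                   domesticated = demePops("domesticated"))
      og <- outgroupAlleles(gf)
      obs <- polarizeAndBuildMSFS(gf, pops, og)
      writeMSFS(obs, file.path(outDir, "observed.msfs"))
      dg <- config$demography
      scens <- domesticationScenarios()
      fits <- lapply(seq_along(scens), function(i)
        fitModel(obs, scens[[i]], nCycles = dg$nCycles,
                 simsPerEval = dg$simsPerEval, nInit = dg$nInit,
                 minCount = dg$minCount,
                 seed = stageSeed(seed, 10 + i)))
      cmp <- compareModels(fits)
      .writeStage(outDir, "demography", cmp,
                  list(best_model = attr(cmp, "best"),
                       n_polarized = msfsTotal(obs)))
      cmp
    })
    summaryLines <- c(summaryLines, "## Demographic model comparison", "",
                      paste0("- best model: ", attr(demo, "best")),
                      sprintf("- %s: AIC = %.1f (delta %.1f)", demo$model,
                              demo$AIC, demo$deltaAIC), "")
    out$demography <- demo
  }

  # ---- scans -------------------------------------------------------
  scan <- stage("scans", {
    sc <- config$scans
    ing <- gf[, SummarizedExperiment::colData(gf)$status %in%
                c("wild", "domesticated")]
    ing <- filterSites(ing, config$filters$mafMin, 1, 1)$geno
    bs <- sc$bayescenv
    r1 <- bayescenvScan(ing, pilotRuns = bs$pilotRuns,
                        pilotLen = bs$pilotLen, burnIn = bs$burnIn,
                        sampleIters = bs$sampleIters, thin = bs$thin,
                        seeds = c(stageSeed(seed, 20),
                                  stageSeed(seed, 21)),
                        qCut = sc$alpha)
    r2 <- pcadaptScan(ing, K = sc$kPcadapt, alpha = sc$alpha)
    r3 <- lfmmScan(ing, K = sc$kLfmm, ridgeLambda = sc$ridgeLambda,
                   qCut = sc$alpha)
    cons <- consensusCandidates(list(bayescenv = r1, pcadapt = r2,
                                     lfmm = r3), sc$minTests)
    for (nm in c("bayescenv", "pcadapt", "lfmm"))
      utils::write.table(get(c(bayescenv = "r1", pcadapt = "r2",
                               lfmm = "r3")[[nm]]),
                         file.path(outDir, paste0("scan_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    .writeStage(outDir, "scans", cons,
                list(n_candidates = sum(cons$candidate),
                     flagged = list(bayescenv = sum(r1$flag),
                                    pcadapt = sum(r2$flag, na.rm = TRUE),
                                    lfmm = sum(r3$flag, na.rm = TRUE)),
                     bayescenv_converged = attr(r1, "converged")))
    list(results = list(bayescenv = r1, pcadapt = r2, lfmm = r3),
         consensus = cons, geno = ing)
  })
  summaryLines <- c(summaryLines, "## Selection scans", "",
                    sprintf("- consensus candidates (>= %d tests): %d",
                            config$scans$minTests,
                            sum(scan$consensus$candidate)), "")

  # ---- introgression ----------------------------------------------
  if (isTRUE(config$introgression$enabled)) {
    intro <- stage("introgression", {
      ic <- config$introgression
      sim <- simFourTaxon(ic$simdata$nSNPs, f = ic$simdata$f,
                          seed = stageSeed(seed, 30))
      freq <- data.frame(sim$freq)
      ds <- dStatistic(freq)
      jk <- blockJackknife(ds$abba, ds$baba, ic$nBlocks)
      fg <- fAdmixture(freq, sim$counts[, "p3"],
                       rep(sim$haploids[["p3"]], nrow(freq)),
                       seed = stageSeed(seed, 31))
      wd <- windowedD(ds$abba, ds$baba, ic$windowSnps, ic$stepSnps)
      utils::write.table(wd, file.path(outDir, "windowed_d.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      .writeStage(outDir, "introgression", wd,
                  list(D = ds$D, Z = jk$Z, p = jk$p, fG = fg$fG))
      list(d = ds, jk = jk, fG = fg$fG, windows = wd)
    })
    summaryLines <- c(summaryLines, "## Introgression", "",
                      sprintf("- genome-wide D = %.4f (Z = %.2f, p = %.3g), f_G = %.3f",
                              intro$d$D, intro$jk$Z, intro$jk$p,
                              intro$fG), "")
    out$introgression <- intro
  }

  # ---- structural variants ----------------------------------------
  if (isTRUE(config$sv$enabled)) {
    sv <- stage("sv", {
      svc <- config$sv
      if (!is.null(svc$callsetA)) {
        A <- readSVCallset(svc$callsetA, "callerA")
        B <- readSVCallset(svc$callsetB, "callerB", minSupport = 6)
      } else {
        cs <- makeSVCallsets(svc$simdata$nShared, svc$simdata$nOnlyA,
                             svc$simdata$nOnlyB, svc$simdata$jitterSd,
                             seed = stageSeed(seed, 40))
        A <- cs$A; B <- cs$B
      }
      cons <- consensusSVs(A, B, tol = svc$tol)
      genes <- if (!is.null(svc$genes))
        readGFF3Genes(svc$genes) else
          makeGeneIntervals(200, seed = stageSeed(seed, 41))
      hits <- assignGenes(c(cons$consensus, cons$unaligned), genes)
      terms <- if (!is.null(svc$terms))
        utils::read.table(svc$terms, header = TRUE, sep = "\t") else
          makeTermMap(S4Vectors::mcols(genes)$gene_id,
                      seed = stageSeed(seed, 42))
      enr <- fisherEnrichment(unique(hits$gene),
                              S4Vectors::mcols(genes)$gene_id, terms,
                              alpha = svc$alpha)
      .writeStage(outDir, "sv", cons$matches,
                  list(n_consensus = length(cons$consensus),
                       n_unaligned = length(cons$unaligned),
                       n_genes_hit = length(unique(hits$gene)),
                       n_enriched = sum(enr$enriched)))
      list(consensus = cons, hits = hits, enrichment = enr)
    })
    summaryLines <- c(summaryLines, "## Structural variants", "",
                      sprintf("- high-confidence consensus SVs: %d",
                              length(sv$consensus$consensus)),
                      sprintf("- enriched terms (p < %.2f): %d",
                              config$sv$alpha, sum(sv$enrichment$enriched)),
                      "")
    out$sv <- sv
  }

  writeLines(summaryLines, file.path(outDir, "summary.md"))
  writeLines(c(log, paste("R version:", R.version.string),
               paste("cushaw version:",
                     as.character(utils::packageVersion("cushaw")))),
             file.path(outDir, "run.log"))
  out$filters <- filt$report
  out$diversity <- divr
  out$scans <- scan$consensus
  invisible(out)
}

#' Read gene features from a GFF3 file
#'
#' @param path GFF3 path; only rows with type "gene" are kept, with the
#'   ID attribute as \code{gene_id}.
#' @return GRanges with a gene_id column.
#' @export
readGFF3Genes <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    g <- rtracklayer::import(path)
    g <- g[g$type == "gene"]
    S4Vectors::mcols(g) <- S4Vectors::DataFrame(gene_id = g$ID)
    return(g)
  }
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  df <- df[df[[3]] == "gene", ]
  ids <- sub(".*ID=([^;]+).*", "\\1", df[[9]])
  gr <- GenomicRanges::GRanges(df[[1]], IRanges::IRanges(df[[4]], df[[5]]))
  S4Vectors::mcols(gr)$gene_id <- ids
  gr
}
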