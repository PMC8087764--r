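#' Outgroup allele calls from the outgroup samples of a GenotypeData
#'
#' A site is polarizable when the outgroup is monomorphic and non-missing:
#' the ancestral allele is the one the outgroup carries.
#'
#' @param gd a \linkS4class{GenotypeData}.
#' @param outgroupPops population labels of the outgroup samples (default:
#'   samples with status "outgroup").
#' @return character vector per site: "REF", "ALT", or NA when the
#'   outgroup is polymorphic or entirely missing.
#' @export
outgroupAlleles <- function(gd, outgroupPops = NULL) {
  cd <- SummarizedExperiment::colData(gd)
  sel <- if (is.null(outgroupPops)) cd$status == "outgroup" else
    cd$population %in% outgroupPops
  if (!any(sel)) stop("no outgroup samples found")
  m <- dosages(gd)[, sel, drop = FALSE]
  apply(m, 1, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_character_)
    if (all(x == 0)) return("REF")
    if (all(x == 2)) return("ALT")
    NA_character_
  })
}

#' Polarize sites and build the unfolded multidimensional SFS
#'
#' The ancestral allele at each site is the allele carried by a
#' monomorphic outgroup; sites with a polymorphic or missing outgroup are
#' dropped and counted, as are sites with missing in-group genotypes
#' (complete-case polarization, no down-projection) and sites monomorphic
#' across the in-group demes (the masked corner cells).
#'
#' @param gd a \linkS4class{GenotypeData}.
#' @param pops named list: axis name -> population label(s) forming that
#'   deme, in axis order.
#' @param outgroup per-site ancestral calls from
#'   \code{\link{outgroupAlleles}}, or population label(s) to derive them
#'   from.
#' @return a \linkS4class{MultiSFS}.
#' @export
polarizeAndBuildMSFS <- function(gd, pops, outgroup) {
  if (is.character(outgroup) && length(outgroup) < nrow(gd))
    outgroup <- outgroupAlleles(gd, outgroup)
  stopifnot(length(outgroup) == nrow(gd))
  d <- dosages(gd)
  grp <- populationsOf(gd)
  demes <- names(pops)
  idx <- lapply(pops, function(pp) which(grp %in% pp))
  nInd <- vapply(idx, length, integer(1))
  sizes <- 2L * nInd
  counts <- array(0L, dim = unname(sizes) + 1L, dimnames = NULL)
  dropped <- c(outgroup_unusable = 0L, ingroup_missing = 0L,
               monomorphic = 0L)
  for (s in seq_len(nrow(d))) {
    aa <- outgroup[s]
    if (is.na(aa)) {
      dropped["outgroup_unusable"] <- dropped["outgroup_unusable"] + 1L
      next
    }
    der <- integer(length(demes))
    bad <- FALSE
    for (k in seq_along(demes)) {
      x <- d[s, idx[[k]]]
      if (anyNA(x)) { bad <- TRUE; break }
      der[k] <- if (aa == "REF") sum(x) else sizes[k] - sum(x)
    }
    if (bad) {
      dropped["ingroup_missing"] <- dropped["ingroup_missing"] + 1L
      next
    }
    if (all(der == 0) || all(der == sizes)) {
      dropped["monomorphic"] <- dropped["monomorphic"] + 1L
      next
    }
    cell <- matrix(der + 1L, 1)
    counts[cell] <- counts[cell] + 1L
  }
  if (sum(counts) == 0) stop("no polarizable polymorphic sites")
  new("MultiSFS", counts = counts, demes = demes,
      sampleSizes = as.integer(unname(sizes)), dropped = dropped)
}

#' Expected SFS entry proportions by coalescent simulation
#'
#' Simulates independent genealogies under the model and accumulates
#' every branch's length into the spectrum cell indexed by its subtree's
#' joint derived-allele counts.  This is the Rao-Blackwellized estimator
#' of the site-sampled spectrum (a segregating site falls on a branch
#' with probability proportional to its length), with no
#' mutation-placement noise.  Zero cells are floored at a
#' pseudo-frequency (default 0.1 / nSimSNPs) so that unexplained
#' observed cells are penalized rather than driving the composite
#' likelihood to -Inf; proportions are renormalized to sum to 1.
#'
#' @param model a \linkS4class{DemographicModel} over the in-group demes.
#' @param haploidSizes named haploid sample sizes, in axis order.
#' @param nSimSNPs number of simulated genealogies (>= 1000).
#' @param seed optional seed.
#' @param zeroFloor pseudo-frequency for empty cells.
#' @return array of expected proportions, same shape as the observed SFS.
#' @export
expectedSFS <- function(model, haploidSizes, nSimSNPs, seed = NULL,
                        zeroFloor = 0.1 / nSimSNPs) {
  stopifnot(nSimSNPs >= 1000)
  if (!is.null(seed)) set.seed(seed)
  labs <- model@popLabels
  if (!setequal(names(haploidSizes), labs) ||
      !identical(names(haploidSizes), labs))
    stop("haploidSizes must name the model demes in model order")
  sizes <- as.integer(haploidSizes)
  dims <- sizes + 1L
  flat <- sim_expected_sfs_cpp(.modelToC(model),
                               as.integer(haploidSizes),
                               as.integer(nSimSNPs))
  a <- array(flat, dim = dims)
  # mask the monomorphic corners before normalizing
  a[matrix(rep(1L, length(dims)), 1)] <- 0
  a[matrix(dims, 1)] <- 0
  if (sum(a) == 0) stop("simulation yielded no polymorphic sites")
  prop <- a / sum(a)
  # masked corners stay at zero mass; interior zero cells are floored
  mask <- array(FALSE, dim = dim(prop))
  mask[matrix(rep(1L, length(sizes)), 1)] <- TRUE
  mask[matrix(sizes + 1L, 1)] <- TRUE
  prop[!mask & prop == 0] <- zeroFloor
  prop / sum(prop)
}

#' Composite log-likelihood of an observed SFS
#'
#' Multinomial composite log-likelihood over SFS entries, natural log:
#' lnL = sum over cells with at least \code{minCount} observations of
#' m_i log e_i.  Cells with zero expectation are floored.
#'
#' @param obs a \linkS4class{MultiSFS}.
#' @param expProp expected proportions (same shape).
#' @param minCount minimum observed count for a cell to enter (default 1).
#' @param zeroFloor floor for zero expected proportions.
#' @return the composite log-likelihood (natural log).
#' @export
compositeLogLik <- function(obs, expProp, minCount = 1,
                            zeroFloor = 0.1 / sum(obs@counts)) {
  m <- obs@counts
  stopifnot(identical(dim(m), dim(expProp)))
  use <- m >= minCount
  if (!any(use)) stop("no observed cells reach the minimum count")
  e <- expProp[use]
  e[e <= 0] <- zeroFloor
  sum(m[use] * log(e))
}

#' The six domestication scenarios
#'
#' Model bank crossing the domestication origin (from the Jalisco wild
#' lineage or the Southern wild lineage) with the gene-flow regime.
#' Continuous gene flow carries independent directional rates for every
#' deme pair, from the present back to the common ancestral population;
#' secondary contact carries the four domesticate-wild rates, active
#' only in the recent contact epoch (the most recent half of the
#' domestication branch, a design constant).  Priors are log-uniform:
#' divergence times 1,000-200,000 generations, diploid sizes
#' 100-60,000, migration rates 0.0001-0.5.  The domesticate is
#' constrained to diverge after the wild lineages split.
#'
#' The composite likelihood over polymorphic-site proportions carries no
#' information about the absolute coalescent scale (all sizes and times
#' can be rescaled jointly), so the Jalisco wild deme size is fixed at
#' \code{anchorNe} in every scenario as the scale anchor, the way
#' SFS-based fits anchor one size through external diversity
#' information.
#'
#' @param origins,flows subsets of scenarios to build.
#' @param anchorNe fixed diploid size of the Jalisco wild deme.
#' @return named list of scenario objects, each with \code{id},
#'   \code{paramNames}, \code{priors} (lo/hi per parameter), \code{build}
#'   (parameter vector to \linkS4class{DemographicModel}) and
#'   \code{feasible} (constraint check).
#' @export
domesticationScenarios <- function(origins = c("jalisco", "southern"),
                                   flows = c("none", "continuous",
                                             "secondary_contact"),
                                   anchorNe = 30000) {
  mk <- function(origin, flow) {
    pn <- c("N_SOU", "N_DOM", "N_ANC", "T_DOM", "T_WILD")
    priors <- list(N_SOU = c(100, 60000),
                   N_DOM = c(100, 60000), N_ANC = c(100, 60000),
                   T_DOM = c(1000, 200000), T_WILD = c(1000, 200000))
    if (flow != "none") {
      pn <- c(pn, "M_JD", "M_DJ", "M_SD", "M_DS")
      for (m in c("M_JD", "M_DJ", "M_SD", "M_DS"))
        priors[[m]] <- c(1e-4, 0.5)
    }
    if (flow == "continuous") {
      # continuous flow runs among every lineage pair until the common
      # ancestor, so the wild-wild directions are free as well
      pn <- c(pn, "M_JS", "M_SJ")
      for (m in c("M_JS", "M_SJ")) priors[[m]] <- c(1e-4, 0.5)
    }
    build <- function(par) {
      par <- c(par, N_JAL = anchorNe)
      studyModel(origin = origin, geneFlowMode = flow,
                 Ne = c(jalisco = par[["N_JAL"]], southern = par[["N_SOU"]],
                        domesticated = par[["N_DOM"]],
                        ancestor = par[["N_ANC"]], moschata = 30000),
                 tDom = par[["T_DOM"]], tWild = par[["T_WILD"]],
                 mJD = if (flow == "none") 0 else par[["M_JD"]],
                 mDJ = if (flow == "none") 0 else par[["M_DJ"]],
                 mSD = if (flow == "none") 0 else par[["M_SD"]],
                 mDS = if (flow == "none") 0 else par[["M_DS"]],
                 mJS = if (flow == "continuous") par[["M_JS"]] else 0,
                 mSJ = if (flow == "continuous") par[["M_SJ"]] else 0,
                 # the contact epoch is the recent half of the
                 # domestication branch (a design constant, not fitted)
                 secondaryContactEnd = if (flow == "secondary_contact")
                   0.5 * par[["T_DOM"]] else 0)
    }
    feasible <- function(par) par[["T_DOM"]] <= par[["T_WILD"]]
    structure(list(id = paste0(origin, "_", sub("_contact", "", flow)),
                   origin = origin, flow = flow, paramNames = pn,
                   priors = priors, build = build, feasible = feasible,
                   anchorNe = anchorNe),
              class = "DemogScenario")
  }
  out <- list()
  for (o in origins) for (f in flows) {
    sc <- mk(o, f)
    out[[sc$id]] <- sc
  }
  out
}

.momentStart <- function(obs, scenario) {
  cnt <- obs@counts
  sz <- obs@sampleSizes
  idx <- which(cnt > 0, arr.ind = TRUE)
  if (is.null(dim(idx))) idx <- matrix(idx, ncol = 1)
  w <- cnt[cnt > 0]
  freq <- sweep(idx - 1, 2, sz, "/")
  het <- function(d) sum(w * 2 * freq[, d] * (1 - freq[, d])) / sum(w)
  pis <- vapply(seq_along(sz), het, numeric(1))
  hudson <- function(a, b) {
    p1 <- freq[, a]; p2 <- freq[, b]
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (sz[a] - 1) -
      p2 * (1 - p2) / (sz[b] - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    max(sum(w * num) / sum(w * den), 1e-3)
  }
  anchor <- scenario$anchorNe
  NS <- anchor * pis[2] / pis[1]
  ND <- anchor * pis[3] / pis[1]
  fJS <- hudson(1, 2)
  fD <- min(hudson(1, 3), hudson(2, 3))
  TW <- (anchor + NS) * fJS       # 2 * mean(N) * F_ST, drift approximation
  TD <- (anchor + ND) * fD
  par <- c(N_SOU = unname(NS), N_DOM = unname(ND), N_ANC = anchor,
           T_DOM = unname(min(TD, 0.9 * TW)), T_WILD = unname(TW),
           M_JD = 1e-3, M_DJ = 1e-3, M_SD = 1e-3, M_DS = 1e-3,
           M_JS = 2e-4, M_SJ = 2e-4)
  par <- par[scenario$paramNames]
  lo <- vapply(scenario$priors, `[`, numeric(1), 1)
  hi <- vapply(scenario$priors, `[`, numeric(1), 2)
  pmin(pmax(par, lo), hi)
}

.drawLogUniform <- function(priors) {
  vapply(priors, function(b) exp(runif(1, log(b[1]), log(b[2]))),
         numeric(1))
}

.obsSignature <- function(obs) {
  c(sum(obs@counts), dim(obs@counts))
}

#' Fit a domestication scenario to an observed MultiSFS
#'
#' Simulation-based composite-likelihood search: initial log-uniform draws
#' from the priors, then coordinate refinement cycles that perturb each
#' parameter multiplicatively (shrinking steps), re-simulating the
#' expected SFS for every evaluation.  Within a cycle all evaluations
#' share one simulation seed (common random numbers), so comparisons are
#' not dominated by Monte-Carlo noise; the seed is refreshed each cycle.
#' Search stops early once a cycle improves the composite log-likelihood
#' by less than \code{tol}.  With \code{nCycles = 0} the best initial draw
#' is returned (degenerate mode, documented contract).
#'
#' @param obs observed \linkS4class{MultiSFS}.
#' @param scenario one scenario from \code{\link{domesticationScenarios}}.
#' @param nCycles refinement cycles (default 40).
#' @param simsPerEval simulated SNPs per expected-SFS evaluation
#'   (default 200,000).
#' @param nInit initial prior draws.
#' @param tol stopping criterion on the lnL improvement (default 0.001).
#' @param seed optional seed.
#' @param minCount minimum observed SFS count per cell (default 1).
#' @param initSims simulated SNPs per initial-draw evaluation (scouting
#'   draws are screened at a smaller simulation size than refinement).
#' @param warmStart named parameter vector from a nested scenario's fit;
#'   one of the initial draws inherits its shared parameters.
#' @param searchSims simulated genealogies per refinement-cycle
#'   evaluation (the likelihood entering the reported fit and any AIC
#'   comparison is recomputed at \code{simsPerEval}).
#' @param firstCycle index of the first cycle in the step-size schedule
#'   (used when a fit is resumed or polished).
#' @return a \linkS4class{FitResult}.
#' @export
fitModel <- function(obs, scenario, nCycles = 40, simsPerEval = 200000,
                     nInit = 10, tol = 0.001, seed = NULL, minCount = 1,
                     initSims = min(simsPerEval, 5000), warmStart = NULL,
                     searchSims = max(initSims, round(simsPerEval / 2)),
                     firstCycle = 1) {
  stopifnot(inherits(scenario, "DemogScenario"))
  if (is.null(seed)) seed <- sample.int(1e6, 1)
  sizes <- setNames(obs@sampleSizes, obs@demes)
  lo <- vapply(scenario$priors, `[`, numeric(1), 1)
  hi <- vapply(scenario$priors, `[`, numeric(1), 2)
  if (any(lo > hi)) stop("infeasible prior box")
  evalPar <- function(par, simSeed, nSims = searchSims) {
    if (!scenario$feasible(par)) return(-Inf)
    e <- expectedSFS(scenario$build(par), sizes, nSims, seed = simSeed)
    compositeLogLik(obs, e, minCount = minCount)
  }
  set.seed(stageSeed(seed, 0))
  draws <- replicate(nInit, .drawLogUniform(scenario$priors),
                     simplify = FALSE)
  # method-of-moments starting point from the observed spectrum, plus
  # coalescent-rescaled variants (gene flow deflates the F_ST-based
  # time estimates, so the truth tends to sit at a larger scale)
  ms <- .momentStart(obs, scenario)
  msScaled <- lapply(c(1, 2, 4), function(f) {
    par <- ms
    isTN <- grepl("^[TN]_", names(par))
    isM <- grepl("^M_", names(par))
    par[isTN] <- par[isTN] * f
    par[isM] <- par[isM] / f
    pmin(pmax(par, lo[names(par)]), hi[names(par)])
  })
  draws <- c(msScaled, draws)
  if (!is.null(warmStart)) {
    # also seed a start with the parameters shared with an already
    # fitted (nested) scenario
    shared <- intersect(names(warmStart), scenario$paramNames)
    ws <- draws[[2]]
    ws[shared] <- pmin(pmax(warmStart[shared], lo[shared]), hi[shared])
    draws <- c(draws, list(ws))
  }
  draws <- lapply(draws, function(p) {   # enforce the divergence order
    if (p[["T_DOM"]] > p[["T_WILD"]]) {
      tmp <- p[["T_DOM"]]; p[["T_DOM"]] <- p[["T_WILD"]]
      p[["T_WILD"]] <- tmp
    }
    p
  })
  s0 <- stageSeed(seed, 1)
  lnLs <- vapply(draws, evalPar, numeric(1), simSeed = s0, nSims = initSims)
  best <- draws[[which.max(lnLs)]]
  bestLnL <- max(lnLs)
  if (nCycles > 0) {
    # within a cycle every evaluation shares one simulation seed
    # (common random numbers); the seed is refreshed between cycles so
    # the search cannot lock onto one Monte-Carlo realization's wiggles
    dir <- setNames(rep(1, length(scenario$paramNames)),
                    scenario$paramNames)
    for (cyc in seq_len(nCycles)) {
      sCRN <- stageSeed(seed, firstCycle + cyc)
      step <- exp(log(3) * 0.65^(firstCycle + cyc - 2))
      bestLnL <- evalPar(best, sCRN)
      startLnL <- bestLnL
      base <- best
      for (pn in scenario$paramNames) {
        for (dd in c(dir[[pn]], -dir[[pn]])) {
          cand <- best
          cand[[pn]] <- min(max(cand[[pn]] * step^dd, lo[[pn]]),
                            hi[[pn]])
          ll <- if (scenario$feasible(cand)) evalPar(cand, sCRN) else -Inf
          if (ll > bestLnL) {
            best <- cand; bestLnL <- ll; dir[[pn]] <- dd
            break
          }
        }
      }
      # joint scale move along the coalescent-rescaling direction
      # (N, T up; migration rates down) -- the near-flat ridge of the
      # unanchored model that single-coordinate moves cannot follow
      isT <- grepl("^T_", scenario$paramNames)
      isN <- grepl("^N_", scenario$paramNames)
      isM <- grepl("^M_", scenario$paramNames)
      for (dd in c(1, -1)) {
        f <- step^dd
        cand <- best
        cand[isT | isN] <- cand[isT | isN] * f
        cand[isM] <- cand[isM] / f
        cand <- pmin(pmax(cand, lo[scenario$paramNames]),
                     hi[scenario$paramNames])
        ll <- if (scenario$feasible(cand)) evalPar(cand, sCRN) else -Inf
        if (ll > bestLnL) { best <- cand; bestLnL <- ll; break }
      }
      # paired domestication-branch move: T_DOM and N_DOM trade off
      # along the drift ridge T/2N, so move them together
      for (dd in c(1, -1)) {
        cand <- best
        cand[["T_DOM"]] <- min(max(cand[["T_DOM"]] * step^dd,
                                   lo[["T_DOM"]]), hi[["T_DOM"]])
        cand[["N_DOM"]] <- min(max(cand[["N_DOM"]] * step^-dd,
                                   lo[["N_DOM"]]), hi[["N_DOM"]])
        ll <- if (scenario$feasible(cand)) evalPar(cand, sCRN) else -Inf
        if (ll > bestLnL) { best <- cand; bestLnL <- ll; break }
      }
      # domestication-time leap: T_DOM collapses toward the prior floor
      # on a migration-compensated ridge separated from the deeper basin
      # by a shallow saddle that greedy steps cannot cross; leap over it
      # by scanning T_DOM as a fraction of the current wild split, with
      # and without drift-preserving N_DOM compensation (early cycles,
      # while the steps are still large)
      for (frac in if (firstCycle + cyc - 1 <= 2)
        c(0.1, 0.25, 0.5, 0.9) else numeric(0)) {
        Tg <- frac * best[["T_WILD"]]
        if (Tg < lo[["T_DOM"]] || Tg > hi[["T_DOM"]]) next
        for (keepDrift in c(FALSE, TRUE)) {
          cand <- best
          if (keepDrift)
            cand[["N_DOM"]] <- min(max(cand[["N_DOM"]] * Tg /
                                         cand[["T_DOM"]],
                                       lo[["N_DOM"]]), hi[["N_DOM"]])
          cand[["T_DOM"]] <- Tg
          if (max(abs(log(cand / best))) < 1e-9) next
          ll <- if (scenario$feasible(cand)) evalPar(cand, sCRN) else -Inf
          if (ll > bestLnL) { best <- cand; bestLnL <- ll }
        }
      }
      # symmetric migration-rate line scan between the domesticate and
      # its progenitor-side deme (the dominant gene-flow direction);
      # single-coordinate moves stall at the prior floor because the
      # two directional rates need to move together
      if ("M_JD" %in% scenario$paramNames && firstCycle + cyc - 1 <= 3) {
        for (g in c(1e-4, 3e-4, 1e-3, 3e-3)) {
          cand <- best
          cand[["M_JD"]] <- g
          cand[["M_DJ"]] <- g
          if (abs(log(g / best[["M_JD"]])) < 1e-9 &&
              abs(log(g / best[["M_DJ"]])) < 1e-9) next
          ll <- if (scenario$feasible(cand)) evalPar(cand, sCRN) else -Inf
          if (ll > bestLnL) { best <- cand; bestLnL <- ll }
        }
      }
      # pattern move: the surface is a long correlated valley, so the
      # cycle's net displacement is extrapolated while it keeps paying
      # (Hooke-Jeeves style)
      delta <- log(best) - log(base)
      if (any(abs(delta) > 1e-9)) {
        for (rep in 1:4) {
          cand <- exp(log(best) + delta)
          cand <- pmin(pmax(cand, lo[scenario$paramNames]),
                       hi[scenario$paramNames])
          if (!scenario$feasible(cand)) break
          ll <- evalPar(cand, sCRN)
          if (ll <= bestLnL) break
          best <- cand; bestLnL <- ll
        }
      }
      if (bestLnL - startLnL < tol && cyc > 1) break
    }
  }
  if (searchSims != simsPerEval)
    bestLnL <- evalPar(best, stageSeed(seed, 998), nSims = simsPerEval)
  new("FitResult", modelId = scenario$id, par = best, lnL = bestLnL,
      k = length(scenario$paramNames), AIC = 2 * length(scenario$paramNames)
      - 2 * bestLnL, obsSignature = .obsSignature(obs))
}

#' Replicated fits with likelihood-based retention
#'
#' Runs independent fits from different seeds, checks that replicates
#' converge to similar likelihoods, retains the outputs above the 95th
#' percentile of the replicate likelihood distribution, and reports the
#' best.
#'
#' @inheritParams fitModel
#' @param nReplicates independent fits.
#' @param ... passed to \code{\link{fitModel}}.
#' @return list(best = FitResult, replicates = data.frame(seed, lnL,
#'   retained)).
#' @export
fitModelReplicates <- function(obs, scenario, nReplicates = 3, seed = 1,
                               ...) {
  fits <- lapply(seq_len(nReplicates), function(i)
    fitModel(obs, scenario, seed = stageSeed(seed, 100 + i), ...))
  lnLs <- vapply(fits, function(f) f@lnL, numeric(1))
  thr <- quantile(lnLs, 0.95, names = FALSE)
  retained <- lnLs >= thr
  list(best = fits[[which.max(lnLs)]],
       replicates = data.frame(replicate = seq_len(nReplicates),
                               lnL = lnLs, retained = retained))
}

#' Fit the whole scenario bank with warm starts
#'
#' Fits the no-flow scenario of each origin first and warm-starts the
#' gene-flow scenarios from its estimates (the scenarios are nested in
#' their demographic parameters).  All fits of one call share the same
#' per-cycle simulation seeds (common random numbers), so the AIC
#' comparison is not dominated by Monte-Carlo noise.
#'
#' @inheritParams fitModel
#' @param scenarios list from \code{\link{domesticationScenarios}}.
#' @param ... further arguments to \code{\link{fitModel}}.
#' @return named list of \linkS4class{FitResult}.
#' @export
fitAllModels <- function(obs, scenarios = domesticationScenarios(),
                         nCycles = 40, simsPerEval = 200000, nInit = 10,
                         seed = NULL, ...) {
  if (is.null(seed)) seed <- sample.int(1e6, 1)
  fits <- list()
  nIndiv <- max(nCycles - 1, 1)
  for (origin in unique(vapply(scenarios, `[[`, character(1), "origin"))) {
    ids <- names(scenarios)[vapply(scenarios, `[[`, character(1),
                                   "origin") == origin]
    baseId <- ids[vapply(scenarios[ids], `[[`, character(1),
                         "flow") == "none"]
    warm <- NULL
    for (id in c(baseId, setdiff(ids, baseId))) {
      fits[[id]] <- fitModel(obs, scenarios[[id]], nCycles = nIndiv,
                             simsPerEval = simsPerEval, nInit = nInit,
                             seed = seed, warmStart = warm, ...)
      if (id %in% baseId) warm <- fits[[id]]@par
    }
  }
  # one final cross-pollinated cycle (the last of the cycle budget):
  # every scenario is polished from the best of its own optimum and the
  # other scenarios' optima mapped into its parameter space (with the
  # progenitor-side migration mirror for cross-origin transfers)
  if (nCycles > nIndiv) {
    pool0 <- lapply(fits, function(f) f@par)
    for (id in names(fits)) {
      sc <- scenarios[[id]]
      lo <- vapply(sc$priors, `[`, numeric(1), 1)
      hi <- vapply(sc$priors, `[`, numeric(1), 2)
      own <- fits[[id]]@par
      starts <- list(own)
      for (cand in pool0) {
        par <- own
        shared <- intersect(names(cand), names(par))
        par[shared] <- cand[shared]
        starts[[length(starts) + 1]] <- pmin(pmax(par, lo[names(par)]),
                                             hi[names(par)])
        if (all(c("M_JD", "M_SD") %in% names(par))) {
          sw <- par
          sw[c("M_JD", "M_DJ", "M_SD", "M_DS")] <-
            par[c("M_SD", "M_DS", "M_JD", "M_DJ")]
          starts[[length(starts) + 1]] <- sw
        }
      }
      sScreen <- stageSeed(seed, 900)
      sizes0 <- setNames(obs@sampleSizes, obs@demes)
      lls <- vapply(starts, function(par) {
        if (!sc$feasible(par)) return(-Inf)
        compositeLogLik(obs, expectedSFS(sc$build(par), sizes0,
                                         simsPerEval, seed = sScreen))
      }, numeric(1))
      bestStart <- starts[[which.max(lls)]]
      fits[[id]] <- fitModel(obs, sc, nCycles = 1,
                             simsPerEval = simsPerEval, nInit = 1,
                             seed = seed, warmStart = bestStart,
                             firstCycle = nIndiv + 1, ...)
    }
  }
  # Final ranking stage.  A single simulated-SFS evaluation of lnL has
  # a Monte-Carlo standard deviation comparable to the between-model
  # differences, so the final comparison (i) pools candidate parameter
  # vectors across scenarios (they share their parameters; continuous
  # candidates also map to the F_SC -> 1 boundary of the nested
  # secondary-contact scenarios), screening them under one shared seed,
  # and (ii) re-evaluates each scenario's chosen vector as the mean
  # composite log-likelihood over six shared simulation seeds.
  sizes <- setNames(obs@sampleSizes, obs@demes)
  sFinal <- stageSeed(seed, 999)
  finalReps <- 6
  pool <- lapply(fits, function(f) f@par)
  for (id in names(fits)) {
    sc <- scenarios[[id]]
    bestLnL <- -Inf
    bestPar <- fits[[id]]@par
    lo <- vapply(sc$priors, `[`, numeric(1), 1)
    hi <- vapply(sc$priors, `[`, numeric(1), 2)
    cands <- list()
    for (cand in pool) {
      par <- fits[[id]]@par
      shared <- intersect(names(cand), names(par))
      par[shared] <- cand[shared]
      cands[[length(cands) + 1]] <- par
      # cross-origin transfer: the progenitor-side migration pair swaps
      # roles between the Jalisco- and southern-origin topologies
      if (all(c("M_JD", "M_SD") %in% names(par))) {
        sw <- par
        sw[c("M_JD", "M_DJ", "M_SD", "M_DS")] <-
          par[c("M_SD", "M_DS", "M_JD", "M_DJ")]
        cands[[length(cands) + 1]] <- sw
      }
    }
    for (par in cands) {
      par <- pmin(pmax(par, lo[names(par)]), hi[names(par)])
      if (!sc$feasible(par)) next
      e <- expectedSFS(sc$build(par), sizes, simsPerEval, seed = sFinal)
      lnL <- compositeLogLik(obs, e)
      if (lnL > bestLnL) { bestLnL <- lnL; bestPar <- par }
    }
    lnLreps <- vapply(seq_len(finalReps), function(r)
      compositeLogLik(obs, expectedSFS(sc$build(bestPar), sizes,
                                       simsPerEval,
                                       seed = stageSeed(seed, 2000 + r))),
      numeric(1))
    fits[[id]]@par <- bestPar
    fits[[id]]@lnL <- mean(lnLreps)
    fits[[id]]@AIC <- 2 * fits[[id]]@k - 2 * mean(lnLreps)
  }
  fits[names(scenarios)]
}

#' Rank fitted scenarios by AIC
#'
#' AIC = 2k - 2 lnL with k the number of optimized parameters; the table
#' is sorted ascending and reports the AIC difference to the best model.
#' Fits must share the same observed spectrum.
#'
#' @param fits list of \linkS4class{FitResult}.
#' @return data.frame(model, k, lnL, AIC, deltaAIC) with attribute
#'   \code{"best"}.
#' @export
compareModels <- function(fits) {
  if (length(fits) < 2) stop("need at least 2 fits")
  sig <- lapply(fits, function(f) f@obsSignature)
  if (!all(vapply(sig, identical, logical(1), sig[[1]])))
    stop("fits were computed on different observed spectra")
  df <- data.frame(
    model = vapply(fits, function(f) f@modelId, character(1)),
    k = vapply(fits, function(f) f@k, integer(1)),
    lnL = vapply(fits, function(f) f@lnL, numeric(1)),
    AIC = vapply(fits, function(f) f@AIC, numeric(1)))
  df <- df[order(df$AIC), ]
  df$deltaAIC <- df$AIC - df$AIC[1]
  rownames(df) <- NULL
  attr(df, "best") <- df$model[1]
  df
}
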