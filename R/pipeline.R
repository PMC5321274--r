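#' Run the full WGD detection and dating pipeline on a cohort
#'
#' Orchestrates every stage on a synthetic cohort (or any object with
#' the same layout): sequence pairing and rate estimation on the
#' sequence tier, per-species clock calibration from ortholog Ks peaks,
#' per-species mixture detection inside the dating window, pooled
#' multi-species age analysis, Ka/Ks profiling, gene-count WGD
#' placement, and the gene-tree duplication screen.  A run manifest
#' records parameters, seeds and per-stage record counts; when
#' \code{outdir} is given every stage table is written as TSV and its
#' md5 checksum enters the manifest, so identical config and seed give
#' identical manifests.
#'
#' @param cohort a [simulateCohort()] result.
#' @param kRange mixture component counts searched (default 2:5).
#' @param tMax dating window in myr (default 200).
#' @param nRandomStarts,nKmeansStarts EM starts per fit (defaults 20
#'   and 20 here; see [fitGmm()] for the full-budget defaults).
#' @param doPlacement,doScreen,doSequenceTier stage switches.
#' @param placementFamilies cap on gene families scored (NULL = all).
#' @param outdir optional output directory for stage TSVs.
#' @param seed integer seed for the stochastic stages.
#' @return list with per-stage results and \code{manifest}.
#' @export
runWgdPipeline <- function(cohort, kRange = 2:5, tMax = 200,
                           nRandomStarts = 20, nKmeansStarts = 20,
                           doPlacement = TRUE, doScreen = TRUE,
                           doSequenceTier = TRUE,
                           placementFamilies = NULL,
                           outdir = NULL, seed = 1L) {
  stopifnot(inherits(cohort, "paleodupCohort"))
  config <- cohort$config
  manifest <- list(seed = as.integer(seed),
                   configSeed = config$seed,
                   kRange = kRange, tMax = tMax,
                   stages = list())
  out <- list()
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
  }

  # --- stage: pair + rates (sequence tier) ---------------------------
  if (doSequenceTier && length(cohort$transcripts)) {
    hits <- allVsAllAlign(cohort$transcripts)
    pairs <- bestMatchPairs(hits, "within", cohort$speciesMap)
    kept <- filterPairs(pairs)
    rates <- batchRates(kept, cohort$transcripts)
    out$hits <- hits; out$pairs <- kept; out$rates <- rates
    note("rates", nHits = nrow(hits), nBestPairs = nrow(pairs),
         nFiltered = nrow(kept), nEstimated = sum(rates$status == "ok"))
  }

  # --- stage: calibrate ----------------------------------------------
  tA <- config$divergenceTimes[[1]]; tD <- config$divergenceTimes[[2]]
  ogA <- names(config$divergenceTimes)[1]
  ogD <- names(config$divergenceTimes)[2]
  clocks <- list()
  calRows <- list()
  for (sp in names(cohort$orthologKs)) {
    ksA <- kdePeak(cohort$orthologKs[[sp]][[ogA]])
    ksD <- kdePeak(cohort$orthologKs[[sp]][[ogD]])
    cal <- calibrateClock(ksA, ksD, tA, tD, species = sp)
    clocks[[sp]] <- cal
    calRows[[sp]] <- data.frame(species = sp, ksA = ksA, ksD = ksD,
                                tA = tA, tD = tD, cKs = clockRate(cal),
                                maxKs = maxKsForWindow(cal, tMax))
  }
  out$calibration <- do.call(rbind, calRows)
  rownames(out$calibration) <- NULL
  out$clocks <- clocks
  note("calibrate", nSpecies = length(clocks))

  # --- stage: detect (per-species mixtures) + ages -------------------
  detect <- list(); ages <- list(); omegaAll <- list()
  for (sp in names(cohort$paralogKs)) {
    cal <- clocks[[sp]]
    ksCeil <- maxKsForWindow(cal, tMax)
    pk <- cohort$paralogKs[[sp]]
    keep <- pk$ks <= ksCeil
    ksVals <- pk$ks[keep]
    fit <- selectModel(ksVals, kRange = kRange, seed = seed, scale = "ks",
                       nRandomStarts = nRandomStarts,
                       nKmeansStarts = nKmeansStarts)
    retained <- retainComponents(fit)
    dated <- if (nrow(retained)) dateComponents(retained, cal)
             else dateComponents(components(fit), cal)[0, ]
    detect[[sp]] <- list(fit = fit, retained = retained, dated = dated,
                         nInWindow = sum(keep), nTotal = nrow(pk))
    ages[[sp]] <- ksToTime(ksVals, cal)
    if (!is.null(pk$omega)) omegaAll[[sp]] <- pk$omega[keep]
  }
  out$detect <- detect
  note("detect", nSpecies = length(detect),
       nInWindow = sum(vapply(detect, `[[`, numeric(1), "nInWindow")))

  # --- stage: pooled analysis ----------------------------------------
  pooled <- pooledAnalysis(ages, kRange = kRange, seed = seed,
                           nRandomStarts = nRandomStarts,
                           nKmeansStarts = nKmeansStarts)
  pooledRetained <- retainComponents(pooled)
  out$pooled <- pooled
  out$pooledRetained <- pooledRetained
  note("pooled", n = sum(lengths(ages)), kSelected = pooled@k)

  # --- stage: profile -------------------------------------------------
  if (length(omegaAll)) {
    allAges <- unlist(ages, use.names = FALSE)
    allOmega <- unlist(omegaAll, use.names = FALSE)
    bins <- binOmega(allAges, allOmega, window = c(0, tMax))
    wgdCand <- pooledRetained[pooledRetained$mean >= 40 &
                                pooledRetained$mean <= 120, , drop = FALSE]
    wgdAge <- if (nrow(wgdCand)) wgdCand$mean[which.max(wgdCand$proportion)]
              else NA_real_
    shift <- if (is.finite(wgdAge)) omegaShiftReport(bins, wgdAge) else NULL
    out$omegaBins <- bins
    out$omegaShift <- shift
    out$wgdAgePooled <- wgdAge
    note("profile", nBinned = sum(bins$bins$nPairs),
         nExcluded = bins$nExcludedOmega + bins$nExcludedAge)
  }

  # --- stage: placement -----------------------------------------------
  if (doPlacement && !is.null(cohort$geneCounts)) {
    filt <- filterGeneCounts(cohort$geneCounts)
    counts <- filt$counts
    if (!is.null(placementFamilies) && nrow(counts) > placementFamilies)
      counts <- counts[seq_len(placementFamilies), , drop = FALSE]
    placement <- testHypotheses(counts)
    out$placement <- placement
    note("place", nFamilies = nrow(counts), nRemoved = filt$nRemoved,
         best = bestHypothesis(placement))
  }

  # --- stage: gene-tree screen ----------------------------------------
  if (doScreen && !is.null(cohort$geneTrees)) {
    calls <- do.call(rbind, lapply(cohort$geneTrees, function(tr)
      screenTree(outgroupBranchFilter(tr))))
    dates <- collectAndFitDates(calls, seed = seed)
    out$screenCalls <- calls
    out$screenDates <- dates
    note("screen", nTrees = length(cohort$geneTrees),
         nPassing = sum(calls$passes),
         dominantMean = dates$dominantMean)
  }

  # --- manifest + optional TSV outputs --------------------------------
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    writeStage <- function(df, name) {
      p <- file.path(outdir, paste0(name, ".tsv"))
      write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
      unname(tools::md5sum(p))
    }
    hashes <- list()
    hashes$calibration <- writeStage(out$calibration, "calibration")
    if (!is.null(out$rates)) hashes$rates <- writeStage(out$rates, "rates")
    pooledComp <- components(pooled)
    hashes$pooled <- writeStage(pooledComp, "pooled_components")
    if (!is.null(out$omegaBins))
      hashes$omegaBins <- writeStage(out$omegaBins$bins, "omega_bins")
    if (!is.null(out$placement))
      hashes$placement <- writeStage(placementTable(out$placement),
                                     "placement")
    if (!is.null(out$screenCalls))
      hashes$screen <- writeStage(out$screenCalls, "screen_calls")
    manifest$hashes <- hashes
  }
  out$manifest <- manifest
  out
}
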