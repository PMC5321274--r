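# Synthetic cohort generator: every input the pipeline consumes, with
# the statistical structure the analysis assumes.
#
# Paralog Ks values are a mixture of an exponential small-scale
# duplication (SSD) background -- the simplest generator with the
# L-shape the background is known to have -- and truncated-normal WGD
# components centred at 2 * C_Ks * age.  Ortholog Ks values scatter
# normally around 2 * C_Ks * T_div.  Codon pairs are produced by
# substitution counting on a uniform sense-codon background.  Gene
# counts evolve by an exact event-level (Gillespie) linear birth-death
# simulation, deliberately independent of the closed-form transition
# probabilities used for inference.  Gene trees contain two ingroup
# paralog subclades joined at the duplication age, with uniform
# per-leaf dropout emulating unexpressed copies.

.defaultClocks <- function() {
  tab <- cornusCalibrationTable()
  setNames((tab$ksA / (2 * tab$tA) + tab$ksD / (2 * tab$tD)) / 2, tab$species)
}

#' Configuration of the synthetic cohort
#'
#' Bundles and validates every generator parameter.  Defaults are the
#' study conditions: per-species clocks recomputed from the published
#' ortholog-Ks peaks; WGD components planted at 74, 22 and 7 myr; the
#' ingroup+outgroup divergence ages 80.21 and 95.75 myr; a gene-count
#' WGD on the ingroup stem with retention rate 0.1; 98 gene trees with
#' duplication dates around 76.1 myr (sd 2.7).
#'
#' @param speciesClocks named numeric vector of clocks C_Ks
#'   (substitutions/site/myr), all > 0.
#' @param wgdEvents data.frame with columns age (myr), proportion,
#'   sd (myr); proportions in (0,1) summing to at most 1.
#' @param ssdRate decay constant of the SSD age background (1/myr).
#' @param nPairs paralog pairs per species.
#' @param divergenceTimes named numeric vector: age of the node shared
#'   with each outgroup (names are outgroup codes).
#' @param orthoN ortholog pairs per species/outgroup combination.
#' @param orthoSd Ks-scale scatter of ortholog Ks.
#' @param omegaBase,omegaShift mean Ka/Ks of paralog pairs and its
#'   increase for pairs younger than the oldest planted WGD.
#' @param nFamilies,birth,death,wgdBranch,q gene-count simulation:
#'   family count, per-copy rates (1/myr), WGD branch id and retention.
#' @param nTrees,dupAge,dupSd,dropout gene-tree simulation: tree count,
#'   duplication age distribution (myr) and per-leaf dropout rate.
#' @param nSeqPairs,nCodons sequence-tier size: codon-pair count per
#'   species and codons per sequence.
#' @param seed integer seed.
#' @return validated list of class \code{"paleodupConfig"}.
#' @export
simulationConfig <- function(speciesClocks = .defaultClocks(),
                             wgdEvents = data.frame(
                               age = c(74, 22, 7),
                               proportion = c(0.25, 0.20, 0.15),
                               sd = c(5, 3, 2)),
                             ssdRate = 0.05,
                             nPairs = 2000,
                             divergenceTimes = c(ACH = 80.21, DFE = 95.75),
                             orthoN = 500, orthoSd = 0.08,
                             omegaBase = 0.2, omegaShift = 0.2,
                             nFamilies = 3000, birth = 0.002, death = 0.002,
                             wgdBranch = "cornus_stem", q = 0.1,
                             nTrees = 98, dupAge = 76.1, dupSd = 2.7,
                             dropout = 0.15,
                             nSeqPairs = 15, nCodons = 200,
                             seed = 1L) {
  if (any(speciesClocks <= 0)) stop("all clocks must be positive")
  if (nrow(wgdEvents)) {
    if (any(wgdEvents$proportion <= 0 | wgdEvents$proportion >= 1))
      stop("WGD proportions must lie in (0,1)")
    if (sum(wgdEvents$proportion) > 1)
      stop("WGD proportions must sum to at most 1")
    if (any(wgdEvents$age < 0)) stop("WGD ages must be >= 0")
  }
  if (ssdRate <= 0) stop("ssdRate must be positive")
  if (q < 0 || q > 1) stop("q must lie in [0,1]")
  structure(list(
    speciesClocks = speciesClocks, wgdEvents = wgdEvents,
    ssdRate = ssdRate, nPairs = nPairs,
    divergenceTimes = divergenceTimes, orthoN = orthoN, orthoSd = orthoSd,
    omegaBase = omegaBase, omegaShift = omegaShift,
    nFamilies = nFamilies, birth = birth, death = death,
    wgdBranch = wgdBranch, q = q,
    nTrees = nTrees, dupAge = dupAge, dupSd = dupSd, dropout = dropout,
    nSeqPairs = nSeqPairs, nCodons = nCodons,
    seed = as.integer(seed)), class = "paleodupConfig")
}

.rtnorm <- function(n, mean, sd) {
  # normal truncated at 0 by resampling
  out <- rnorm(n, mean, sd)
  bad <- which(out < 0)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < 0]
  }
  out
}

#' Simulate a paralog Ks sample with planted WGD components
#'
#' Draws \code{nPairs} Ks values from the mixture: with probability
#' \code{proportion[i]} from the i-th WGD component,
#' Normal(2 C_Ks age_i, 2 C_Ks sd_i) truncated at 0; with the remaining
#' probability from the exponential SSD background with age decay
#' \code{ssdRate} (converted to the Ks scale by the same clock).  The
#' generating component of every draw is recorded.
#'
#' @param nPairs number of pairs.
#' @param clock C_Ks (substitutions/site/myr), > 0.
#' @param wgdEvents data.frame(age, proportion, sd) as in
#'   [simulationConfig()].
#' @param ssdRate SSD age decay constant (1/myr).
#' @param seed integer seed.
#' @return data.frame: ks, label ("SSD" or "WGD_i"), trueAge (the
#'   component age for WGD draws, NA for SSD).
#' @export
simulateParalogKs <- function(nPairs, clock,
                              wgdEvents = simulationConfig()$wgdEvents,
                              ssdRate = 0.05, seed = 1L) {
  if (clock <= 0) stop("clock must be positive")
  if (nPairs == 0)
    return(data.frame(ks = numeric(0), label = character(0),
                      trueAge = numeric(0)))
  set.seed(as.integer(seed))
  nW <- nrow(wgdEvents)
  probs <- c(if (nW) wgdEvents$proportion, 1 - sum(wgdEvents$proportion))
  comp <- sample.int(nW + 1L, nPairs, replace = TRUE, prob = probs)
  ks <- numeric(nPairs)
  label <- character(nPairs)
  trueAge <- rep(NA_real_, nPairs)
  for (i in seq_len(nW)) {
    idx <- which(comp == i)
    if (!length(idx)) next
    ks[idx] <- .rtnorm(length(idx), 2 * clock * wgdEvents$age[i],
                       2 * clock * wgdEvents$sd[i])
    label[idx] <- paste0("WGD_", i)
    trueAge[idx] <- wgdEvents$age[i]
  }
  idx <- which(comp == nW + 1L)
  if (length(idx)) {
    ks[idx] <- 2 * clock * rexp(length(idx), rate = ssdRate)
    label[idx] <- "SSD"
  }
  data.frame(ks = ks, label = label, trueAge = trueAge)
}

#' Simulate an ortholog Ks sample against a dated outgroup
#'
#' Values are Normal(2 C_Ks T_div, sigma) truncated at 0, so the sample
#' KDE peak converges to 2 C_Ks T_div as n grows.
#'
#' @param n sample size.
#' @param clock C_Ks of the focal species.
#' @param tDiv divergence time to the outgroup (myr).
#' @param sigma Ks-scale scatter (the dispersion of per-pair rate
#'   variation; a free parameter of the generator).
#' @param seed integer seed.
#' @return numeric vector of Ks values.
#' @export
simulateOrthologKs <- function(n, clock, tDiv, sigma = 0.08, seed = 1L) {
  if (clock <= 0) stop("clock must be positive")
  if (is.na(tDiv)) stop("divergence time missing for this species pair")
  set.seed(as.integer(seed))
  if (tDiv == 0) return(rep(0, n))
  .rtnorm(n, 2 * clock * tDiv, sigma)
}

#' Simulate a codon-sequence pair with controlled divergence
#'
#' Builds a random sense-codon sequence and derives its partner by
#' placing Poisson-distributed synonymous and nonsynonymous
#' single-nucleotide substitutions (never creating a stop codon).
#' Event counts are Poisson with means \code{targetKs * S} and
#' \code{targetKa * N}, where S and N are the sequence's NG86 site
#' counts, so the realized per-site divergences scatter around the
#' targets.
#'
#' @param targetKs,targetKa target per-site divergences, >= 0.
#' @param nCodons codons per sequence, >= 50.
#' @param seed integer seed.
#' @return list: seqA, seqB (nucleotide strings), nSyn, nNon (event
#'   counts), S, N (site counts of seqA), realizedKs, realizedKa
#'   (events per site), saturationRisk (TRUE when a target is so large
#'   that the corrected distance is likely undefined).
#' @export
simulateCodonPair <- function(targetKs, targetKa = targetKs / 5,
                              nCodons = 200, seed = 1L) {
  if (targetKs < 0 || targetKa < 0) stop("targets must be >= 0")
  if (nCodons < 50) stop("need at least 50 codons")
  .codonTable()
  set.seed(as.integer(seed))
  sense <- .ng86$codons[.ng86$aa != "*"]
  codA <- sample(sense, nCodons, replace = TRUE)
  S <- sum(.ng86$synSites[codA])
  N <- 3 * nCodons - S
  nSyn <- rpois(1, targetKs * S)
  nNon <- rpois(1, targetKa * N)
  codB <- codA
  bases <- c("A", "C", "G", "T")
  mutate <- function(codons, synonymous, nEvents) {
    for (ev in seq_len(nEvents)) {
      repeat {
        i <- sample.int(length(codons), 1L)
        sp <- strsplit(codons[i], "")[[1]]
        pos <- sample.int(3L, 1L)
        alt <- sample(setdiff(bases, sp[pos]), 1L)
        cand <- sp; cand[pos] <- alt
        candC <- paste(cand, collapse = "")
        if (.ng86$aa[[candC]] == "*") next
        isSyn <- .ng86$aa[[candC]] == .ng86$aa[[codons[i]]]
        if (isSyn == synonymous) {
          codons[i] <- candC
          break
        }
      }
    }
    codons
  }
  codB <- mutate(codB, TRUE, nSyn)
  codB <- mutate(codB, FALSE, nNon)
  satur <- function(target) 0.75 * (1 - exp(-4 / 3 * target)) >= 0.70
  list(seqA = paste(codA, collapse = ""), seqB = paste(codB, collapse = ""),
       nSyn = nSyn, nNon = nNon, S = S, N = N,
       realizedKs = nSyn / S, realizedKa = nNon / N,
       saturationRisk = satur(targetKs) || satur(targetKa))
}

# exact event-level linear birth-death simulation of one lineage set
.gillespie <- function(n0, t, lambda, mu, cap = 1000L) {
  n <- n0
  time <- 0
  if (lambda == 0 && mu == 0) return(n)
  repeat {
    if (n == 0L || n >= cap) return(n)
    rate <- n * (lambda + mu)
    time <- time + rexp(1, rate)
    if (time > t) return(n)
    n <- if (runif(1) < lambda / (lambda + mu)) n + 1L else n - 1L
  }
}

#' Simulate gene-count matrices under a birth-death process with a WGD
#'
#' Each family starts with one copy at the root and evolves copy number
#' by an exact event-level linear birth-death simulation along every
#' branch.  On the WGD branch, at its midpoint, every extant copy
#' duplicates and each new copy survives with probability \code{q}.
#'
#' @param nFamilies number of families.
#' @param tree dated `phylo`; default [cornusSpeciesTree()].
#' @param birth,death per-copy rates (1/myr), >= 0.
#' @param wgdBranch branch id (see [placementBranches()]) or NULL.
#' @param q retention rate in [0,1].
#' @param seed integer seed.
#' @return integer matrix families x species.
#' @export
simulateGeneCounts <- function(nFamilies, tree = cornusSpeciesTree(),
                               birth = 0.002, death = 0.002,
                               wgdBranch = "cornus_stem", q = 0.1,
                               seed = 1L) {
  if (birth < 0 || death < 0) stop("rates must be >= 0")
  if (q < 0 || q > 1) stop("q must lie in [0,1]")
  set.seed(as.integer(seed))
  info <- .treeInfo(tree)
  wgdEdge <- if (is.null(wgdBranch)) NA_integer_
             else unname(placementBranches(info$tree)[wgdBranch])
  nNode <- max(info$edge)
  # preorder edge order: parent states known before children
  preorder <- rev(seq_len(nrow(info$edge)))
  out <- matrix(0L, nFamilies, info$nTip, dimnames = list(NULL, info$tips))
  for (f in seq_len(nFamilies)) {
    state <- integer(nNode)
    state[info$root] <- 1L
    for (e in preorder) {
      p <- info$edge[e, 1L]; ch <- info$edge[e, 2L]
      t <- info$len[e]
      n <- state[p]
      if (!is.na(wgdEdge) && e == wgdEdge) {
        n <- .gillespie(n, t / 2, birth, death)
        if (n > 0L) n <- n + rbinom(1L, n, q)
        n <- .gillespie(n, t / 2, birth, death)
      } else {
        n <- .gillespie(n, t, birth, death)
      }
      state[ch] <- n
    }
    out[f, ] <- state[seq_len(info$nTip)]
  }
  out
}

#' Simulate dated gene trees with a planted ingroup duplication
#'
#' Each tree joins two copies of the ingroup subtree at a duplication
#' node whose age is drawn from Normal(\code{dupAge}, \code{dupSd}),
#' attaches the outgroup (ACH) at its species-tree age and optionally
#' the far outgroup (DFE) at the root age.  Leaf labels are
#' \code{"<species>_<copy>"}.  Every leaf except the outgroups is then
#' dropped independently with probability \code{dropout}, emulating
#' unexpressed gene copies.  When a drawn age is younger than the
#' ingroup crown, the copy subtrees are compressed so the duplication
#' still predates both crowns.
#'
#' @param nTrees number of trees.
#' @param dupAge,dupSd duplication age distribution (myr); must centre
#'   above the ingroup crown age.
#' @param dropout per-leaf dropout probability in [0,1).
#' @param tree dated species tree; default [cornusSpeciesTree()].
#' @param includeFarOutgroup attach DFE at the root age.
#' @param seed integer seed.
#' @return list: trees (`ape::multiPhylo`), trueAges (numeric).
#' @export
simulateGeneTrees <- function(nTrees, dupAge = 76.1, dupSd = 2.7,
                              dropout = 0.15, tree = cornusSpeciesTree(),
                              includeFarOutgroup = FALSE, seed = 1L) {
  set.seed(as.integer(seed))
  g <- speciesGroups()
  ingroup <- ape::keep.tip(tree, g$cornus)
  crown <- max(ape::node.depth.edgelength(ingroup))
  tA <- 80.21; tD <- 95.75
  if (dupAge <= crown) stop("'dupAge' must exceed the ingroup crown age")
  trees <- vector("list", nTrees)
  trueAges <- numeric(nTrees)
  for (i in seq_len(nTrees)) {
    a <- rnorm(1, dupAge, dupSd)
    a <- min(max(a, 1), tA - 0.5)
    sub <- ingroup
    scl <- min(1, 0.98 * a / crown)
    sub$edge.length <- sub$edge.length * scl
    height <- crown * scl
    mk <- function(copy) {
      s <- sub
      s$tip.label <- paste0(s$tip.label, "_", copy)
      s$root.edge <- a - height
      ape::write.tree(s)
    }
    n1 <- sub(";$", "", mk(1)); n2 <- sub(";$", "", mk(2))
    dupClade <- sprintf("(%s,%s):%0.6f", sub(";", "", n1), sub(";", "", n2),
                        tA - a)
    core <- sprintf("(ACH_0:%0.6f,%s)", tA, dupClade)
    nwk <- if (includeFarOutgroup)
      sprintf("(DFE_0:%0.6f,%s:%0.6f);", tD, core, tD - tA)
    else paste0(core, ";")
    gt <- ape::read.tree(text = nwk)
    if (dropout > 0) {
      cand <- grep("^(ACH|DFE)_", gt$tip.label, invert = TRUE, value = TRUE)
      drop <- cand[runif(length(cand)) < dropout]
      if (length(drop) >= length(cand)) drop <- drop[-1]
      if (length(drop)) gt <- ape::drop.tip(gt, drop)
    }
    trees[[i]] <- gt
    trueAges[i] <- a
  }
  class(trees) <- "multiPhylo"
  list(trees = trees, trueAges = trueAges)
}

#' Generate a complete synthetic cohort
#'
#' Runs every generator of the synthetic-data module under one
#' configuration and seed: per-species paralog Ks samples with truth
#' labels and per-pair omega values, ortholog Ks samples against both
#' outgroups, a sequence tier of codon pairs (for the pairing and rate
#' stages), a gene-count matrix with a planted WGD, and dated gene
#' trees.  All sub-seeds derive deterministically from \code{seed}.
#'
#' @param config a [simulationConfig()].
#' @return list of class \code{"paleodupCohort"}.
#' @export
simulateCohort <- function(config = simulationConfig()) {
  stopifnot(inherits(config, "paleodupConfig"))
  seed <- config$seed
  subSeed <- function(offset) (seed * 1000L + offset) %% .Machine$integer.max
  species <- names(config$speciesClocks)
  oldestWgd <- if (nrow(config$wgdEvents)) max(config$wgdEvents$age) else NA
  paralog <- list(); ortholog <- list()
  for (si in seq_along(species)) {
    sp <- species[si]
    clock <- config$speciesClocks[[sp]]
    pk <- simulateParalogKs(config$nPairs, clock, config$wgdEvents,
                            config$ssdRate, seed = subSeed(si))
    # per-pair omega: purifying baseline, shifted upward for pairs
    # younger than the oldest planted WGD
    set.seed(subSeed(100L + si))
    age <- pk$ks / (2 * clock)
    base <- config$omegaBase +
      ifelse(!is.na(oldestWgd) & age < oldestWgd, config$omegaShift, 0)
    pk$omega <- pmax(rnorm(nrow(pk), base, 0.08), 0.01)
    paralog[[sp]] <- pk
    ortholog[[sp]] <- lapply(seq_along(config$divergenceTimes), function(oi)
      simulateOrthologKs(config$orthoN, clock,
                         config$divergenceTimes[[oi]], config$orthoSd,
                         seed = subSeed(200L + si * 10L + oi)))
    names(ortholog[[sp]]) <- names(config$divergenceTimes)
  }
  # sequence tier: two ingroup species suffice to exercise pairing+rates
  seqSpecies <- species[seq_len(min(2L, length(species)))]
  transcripts <- character(0); truePairs <- list()
  for (si in seq_along(seqSpecies)) {
    sp <- seqSpecies[si]
    clock <- config$speciesClocks[[sp]]
    for (j in seq_len(config$nSeqPairs)) {
      ksT <- simulateParalogKs(1, clock, config$wgdEvents, config$ssdRate,
                               seed = subSeed(300L + si * 100L + j))$ks
      ksT <- min(ksT, 0.9)
      cp <- simulateCodonPair(ksT, ksT / 5, nCodons = config$nCodons,
                              seed = subSeed(400L + si * 100L + j))
      ida <- sprintf("%s_p%03d_a", sp, j)
      idb <- sprintf("%s_p%03d_b", sp, j)
      transcripts[[ida]] <- cp$seqA
      transcripts[[idb]] <- cp$seqB
      truePairs[[length(truePairs) + 1L]] <-
        data.frame(geneA = ida, geneB = idb, species = sp, targetKs = ksT)
    }
  }
  speciesMap <- setNames(sub("_.*$", "", names(transcripts)),
                         names(transcripts))
  counts <- simulateGeneCounts(config$nFamilies, birth = config$birth,
                               death = config$death,
                               wgdBranch = config$wgdBranch, q = config$q,
                               seed = subSeed(500L))
  gt <- simulateGeneTrees(config$nTrees, config$dupAge, config$dupSd,
                          config$dropout, seed = subSeed(600L))
  structure(list(
    config = config,
    paralogKs = paralog,
    orthologKs = ortholog,
    transcripts = transcripts,
    speciesMap = speciesMap,
    truePairs = do.call(rbind, truePairs),
    geneCounts = counts,
    geneTrees = gt$trees,
    geneTreeAges = gt$trueAges), class = "paleodupCohort")
}

#' Write a synthetic cohort to plain-text files
#'
#' FASTA for the sequence tier, TSVs for Ks samples (with truth labels)
#' and gene counts, newick for the gene trees.
#'
#' @param cohort a [simulateCohort()] result.
#' @param outdir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
writeCohort <- function(cohort, outdir) {
  stopifnot(inherits(cohort, "paleodupCohort"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  fa <- file.path(outdir, "transcripts.fasta")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(cohort$transcripts), fa)
  files <- c(files, fa)
  wtsv <- function(df, name) {
    p <- file.path(outdir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  pk <- do.call(rbind, lapply(names(cohort$paralogKs), function(sp)
    cbind(species = sp, cohort$paralogKs[[sp]])))
  files <- c(files, wtsv(pk, "paralog_ks.tsv"))
  ok <- do.call(rbind, lapply(names(cohort$orthologKs), function(sp)
    do.call(rbind, lapply(names(cohort$orthologKs[[sp]]), function(og)
      data.frame(species = sp, outgroup = og,
                 ks = cohort$orthologKs[[sp]][[og]])))))
  files <- c(files, wtsv(ok, "ortholog_ks.tsv"))
  files <- c(files, wtsv(
    data.frame(gene = names(cohort$speciesMap),
               species = unname(cohort$speciesMap)), "species_map.tsv"))
  cm <- data.frame(family = paste0("fam", seq_len(nrow(cohort$geneCounts))),
                   cohort$geneCounts)
  files <- c(files, wtsv(cm, "gene_counts.tsv"))
  nw <- file.path(outdir, "gene_trees.nwk")
  ape::write.tree(cohort$geneTrees, nw)
  files <- c(files, nw)
  invisible(files)
}
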