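# Topology screen for WGD duplication nodes in dated gene trees.

# age of every node = max path length from the node down to its tips
.nodeAges <- function(tree) {
  info <- .treeInfo(tree)
  nNode <- max(info$edge)
  age <- numeric(nNode)
  for (e in seq_len(nrow(info$edge))) {
    p <- info$edge[e, 1L]; ch <- info$edge[e, 2L]
    age[p] <- max(age[p], age[ch] + info$len[e])
  }
  list(age = age, tree = info$tree)
}

#' Species of each leaf of a gene tree
#'
#' Default convention of the synthetic gene trees: the species code is
#' the leaf label up to the first underscore.
#'
#' @param labels character leaf labels.
#' @return named character vector leaf -> species code.
#' @export
leafSpecies <- function(labels) {
  setNames(sub("_.*$", "", labels), labels)
}

#' Screen a dated gene tree for duplication at the ingroup ancestor
#'
#' A tree passes when it contains a node whose two daughter clades both
#' consist exclusively of ingroup (\emph{Cornus}) leaves, each daughter
#' containing at least one BW-group species and at least one non-BW
#' ingroup species, with the outgroup (\emph{Alangium}) present in the
#' tree but outside both daughters.  Such a node is interpreted as a
#' gene duplication in the ingroup common ancestor; its age is the
#' duplication date.  When several nodes qualify the oldest is reported
#' (a WGD predates within-clade duplications).  Trees whose duplication
#' age violates the 68-myr fossil minimum are flagged, not corrected.
#'
#' @param tree a rooted, dated `phylo` gene tree.
#' @param leafMap named character vector leaf label -> species code;
#'   default derives codes with [leafSpecies()].
#' @param groups species groups ([speciesGroups()]); \code{bw} defines
#'   the BW side of the deepest ingroup split.
#' @param outgroup species code that must be present and external
#'   (default \code{"ACH"}).
#' @param minAge fossil minimum for the duplication node (myr).
#' @return one-row data.frame: passes, age, nQualifying, belowMinAge,
#'   subcladeA, subcladeB (comma-separated species).
#' @export
screenTree <- function(tree, leafMap = leafSpecies(tree$tip.label),
                       groups = speciesGroups(), outgroup = "ACH",
                       minAge = 68) {
  if (!ape::is.rooted(tree))
    stop("gene tree is unrooted; root it on the outgroup first")
  sp <- unname(leafMap[tree$tip.label])
  if (anyNA(sp)) stop("leaf(s) missing from the leaf map")
  if (!outgroup %in% sp)
    stop("outgroup ", outgroup, " absent from the tree")
  cornus <- groups$cornus
  bw <- groups$bw
  nonbw <- setdiff(cornus, bw)
  ag <- .nodeAges(tree)
  tr <- ag$tree
  nTip <- length(tr$tip.label)
  spOf <- unname(leafMap[tr$tip.label])
  # tip sets per node via postorder accumulation
  tipsBelow <- vector("list", max(tr$edge))
  for (tip in seq_len(nTip)) tipsBelow[[tip]] <- spOf[tip]
  children <- vector("list", max(tr$edge))
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
    tipsBelow[[p]] <- c(tipsBelow[[p]], tipsBelow[[ch]])
    children[[p]] <- c(children[[p]], ch)
  }
  qualAge <- numeric(0)
  qualA <- character(0); qualB <- character(0)
  for (node in (nTip + 1L):max(tr$edge)) {
    kids <- children[[node]]
    if (length(kids) != 2L) next
    sA <- tipsBelow[[kids[1L]]]; sB <- tipsBelow[[kids[2L]]]
    okClade <- function(s)
      all(s %in% cornus) && any(s %in% bw) && any(s %in% nonbw)
    if (okClade(sA) && okClade(sB)) {
      qualAge <- c(qualAge, ag$age[node])
      qualA <- c(qualA, paste(sort(unique(sA)), collapse = ","))
      qualB <- c(qualB, paste(sort(unique(sB)), collapse = ","))
    }
  }
  if (!length(qualAge))
    return(data.frame(passes = FALSE, age = NA_real_, nQualifying = 0L,
                      belowMinAge = NA, subcladeA = NA_character_,
                      subcladeB = NA_character_))
  best <- which.max(qualAge)
  data.frame(passes = TRUE, age = qualAge[best],
             nQualifying = length(qualAge),
             belowMinAge = qualAge[best] < minAge,
             subcladeA = qualA[best], subcladeB = qualB[best])
}

#' Prune a disproportionately long far outgroup from a gene tree
#'
#' Removes the far-outgroup tip(s) when their tip-to-root path length
#' strictly exceeds \code{factor} times the median tip-to-root path of
#' the remaining taxa (long branches distort downstream dating).  At
#' exactly \code{factor} times the tip is kept.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param farOutgroup species code of the far outgroup (default
#'   \code{"DFE"}).
#' @param leafMap named character vector leaf -> species code.
#' @param factor path-length multiple triggering removal (default 2).
#' @return the (possibly pruned) tree.
#' @export
outgroupBranchFilter <- function(tree, farOutgroup = "DFE",
                                 leafMap = leafSpecies(tree$tip.label),
                                 factor = 2) {
  sp <- unname(leafMap[tree$tip.label])
  far <- which(sp == farOutgroup)
  if (!length(far)) return(tree)
  depth <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  medOther <- median(depth[-far])
  drop <- far[depth[far] > factor * medOther]
  if (!length(drop)) return(tree)
  ape::drop.tip(tree, tree$tip.label[drop])
}

#' Pool passing duplication dates and fit their distribution
#'
#' Collects the duplication ages of passing [screenTree()] calls and
#' fits a normal mixture ([selectModel()]) on the myr scale; the
#' dominant (largest-proportion) component summarizes the inferred WGD
#' date.
#'
#' @param calls data.frame of screen results (rbind of [screenTree()]
#'   rows) or a numeric vector of ages.
#' @param kRange candidate component counts (default 1:3).
#' @param seed integer seed.
#' @param ... passed to [selectModel()].
#' @return list: \code{fit} ([KsMixtureFit-class] or NULL when
#'   degenerate), \code{dominantMean}, \code{dominantSd}, \code{n},
#'   \code{degenerate}.
#' @export
collectAndFitDates <- function(calls, kRange = 1:3, seed = 1L, ...) {
  ages <- if (is.numeric(calls)) calls else calls$age[calls$passes]
  ages <- ages[is.finite(ages)]
  if (length(ages) < 10) stop("fewer than 10 passing duplication dates")
  if (var(ages) < 1e-12) {
    warning("all duplication dates identical; degenerate fit")
    return(list(fit = NULL, dominantMean = ages[1], dominantSd = 0,
                n = length(ages), degenerate = TRUE))
  }
  fit <- selectModel(ages, kRange = kRange, seed = seed, scale = "myr",
                     varFloor = 1e-2, ...)
  comp <- components(fit)
  dom <- which.max(comp$proportion)
  list(fit = fit, dominantMean = comp$mean[dom], dominantSd = comp$sd[dom],
       n = length(ages), degenerate = FALSE)
}
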