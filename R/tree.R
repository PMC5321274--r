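# Dated species tree of the ten study taxa and WGD placement hypotheses.
#
# Topology and the two calibration node ages (Cornus+Alangium split at
# 80.21 myr, root at 95.75 myr) plus the Cornus crown range (deepest
# splits 70.33-72.77 myr) are fixed study constants supplied as
# configuration; the remaining internal node ages are synthetic
# stand-ins chosen inside conventional ranges for the group, since they
# are not individually published.  They matter only for simulation.

.CORNUS_SPECIES <- c("CAL", "CCO", "COF", "CCN", "CFL", "CKO", "CEL", "CCA")
.OUTGROUP_SPECIES <- c("ACH", "DFE")
.BW_SPECIES <- c("CAL", "CCO")

#' Species codes of the study taxa
#' @return list with elements \code{cornus}, \code{outgroups}, \code{bw}
#'   (the blue/white-fruited clade on one side of the deepest ingroup
#'   split).
#' @export
speciesGroups <- function() {
  list(cornus = .CORNUS_SPECIES, outgroups = .OUTGROUP_SPECIES,
       bw = .BW_SPECIES)
}

#' Dated species tree of the eight dogwoods and two outgroups
#'
#' Ultrametric `ape::phylo` tree with the fixed study topology
#' \code{(DFE,(ACH,((CAL,CCO),(COF,(CCN,(CFL,(CKO,(CEL,CCA))))))))} and
#' node ages in myr.  Root age 95.75, ingroup+Alangium node 80.21,
#' ingroup crown 72.77.  Younger internal node ages are synthetic
#' stand-ins (see the package vignette).
#'
#' @return an ultrametric `phylo` object with edge lengths in myr.
#' @export
cornusSpeciesTree <- function() {
  nwk <- paste0(
    "((((CAL:30,CCO:30):42.77,",
    "(COF:70.33,(CCN:58,(CFL:25,(CKO:15,(CEL:8,CCA:8):7):10):33):12.33)",
    ":2.44):7.44,ACH:80.21):15.54,DFE:95.75);")
  ape::read.tree(text = nwk)
}

# edge index whose child subtree has exactly the given tip set
.edgeForClade <- function(tree, tips) {
  stopifnot(all(tips %in% tree$tip.label))
  node <- if (length(tips) == 1L) which(tree$tip.label == tips)
          else ape::getMRCA(tree, tips)
  desc <- if (node <= length(tree$tip.label)) tree$tip.label[node]
          else ape::extract.clade(tree, node)$tip.label
  if (!setequal(desc, tips))
    stop("tip set is not a clade on this tree: ", paste(tips, collapse = ","))
  e <- which(tree$edge[, 2] == node)
  if (!length(e)) stop("no parent edge (clade is the root)")
  e
}

#' Named WGD placement branches on the species tree
#'
#' Resolves the branch identifiers used by the placement hypotheses to
#' edge indices of [cornusSpeciesTree()] (or a compatible tree):
#' \describe{
#'   \item{cornus_stem}{branch subtending the ingroup crown}
#'   \item{alangium_stem}{terminal branch of ACH}
#'   \item{cornus_alangium_stem}{branch subtending ingroup + ACH}
#'   \item{bw_stem}{branch subtending the CAL+CCO clade}
#'   \item{nonbw_stem}{branch subtending the remaining ingroup species}
#' }
#'
#' @param tree a `phylo`; default [cornusSpeciesTree()].
#' @return named integer vector of edge indices.
#' @export
placementBranches <- function(tree = cornusSpeciesTree()) {
  g <- speciesGroups()
  nonbw <- setdiff(g$cornus, g$bw)
  c(cornus_stem = .edgeForClade(tree, g$cornus),
    alangium_stem = .edgeForClade(tree, "ACH"),
    cornus_alangium_stem = .edgeForClade(tree, c(g$cornus, "ACH")),
    bw_stem = .edgeForClade(tree, g$bw),
    nonbw_stem = .edgeForClade(tree, nonbw))
}

#' The five standard WGD placement hypotheses
#'
#' H1: one WGD on the ingroup+Alangium stem.  H2: one WGD on the ingroup
#' stem.  H3: independent WGDs on the ingroup stem and the Alangium
#' stem.  H4: independent WGDs on the BW stem and the non-BW stem.
#' H5: independent WGDs on the Alangium, BW and non-BW stems.
#'
#' @return named list of character vectors of branch ids (names of
#'   [placementBranches()]).
#' @export
wgdHypotheses <- function() {
  list(H1 = "cornus_alangium_stem",
       H2 = "cornus_stem",
       H3 = c("cornus_stem", "alangium_stem"),
       H4 = c("bw_stem", "nonbw_stem"),
       H5 = c("alangium_stem", "bw_stem", "nonbw_stem"))
}

# postorder traversal bookkeeping shared by pruning and simulation
.treeInfo <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  nTip <- length(tree$tip.label)
  list(tree = tree, nTip = nTip, root = nTip + 1L,
       edge = tree$edge, len = tree$edge.length,
       tips = tree$tip.label)
}
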