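# Gene-count likelihood of WGD placement hypotheses.
#
# Felsenstein pruning over copy-number states 0..maxN: each branch gets
# the linear birth-death transition matrix; a WGD event on a branch is a
# binomial retention step at the branch midpoint,
# P(t/2) %*% W(q) %*% P(t/2).  The likelihood can be conditioned on the
# family being observable under the data filter (present in >= 2
# ingroup species and >= 1 outgroup); the conditioning probability is
# data-independent and computed by the same pruning with clamped leaves.

.leafIndicator <- function(counts, maxN) {
  counts <- pmin(counts, maxN)
  m <- matrix(0, length(counts), maxN + 1L)
  m[cbind(seq_along(counts), counts + 1L)] <- 1
  m
}

# generic pruning: leafLik is a list (by tip index) of nFam x (maxN+1)
# matrices; edgeP a list (by edge index) of transition matrices.
# Returns log P(data | root state) as log-scaled matrix + scale vector.
.pruneLik <- function(info, leafLik, edgeP) {
  nNode <- max(info$edge)
  L <- vector("list", nNode)
  nFam <- nrow(leafLik[[1L]])
  logScale <- numeric(nFam)
  for (tip in seq_len(info$nTip)) L[[tip]] <- leafLik[[tip]]
  for (e in seq_len(nrow(info$edge))) {
    p <- info$edge[e, 1L]; ch <- info$edge[e, 2L]
    M <- L[[ch]] %*% t(edgeP[[e]])
    mx <- pmax(M[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))],
               .Machine$double.xmin)
    M <- M / mx
    logScale <- logScale + log(mx)
    L[[p]] <- if (is.null(L[[p]])) M else L[[p]] * M
  }
  list(root = L[[info$root]], logScale = logScale)
}

.rootPriorVec <- function(rootPrior, maxN) {
  if (is.numeric(rootPrior)) {
    stopifnot(length(rootPrior) == maxN + 1L)
    return(rootPrior / sum(rootPrior))
  }
  switch(rootPrior,
    single = { v <- numeric(maxN + 1L); v[2L] <- 1; v },
    geometric = { v <- 0.5^(1:(maxN + 1L)); v[1L] <- 0; v / sum(v) },
    stop("unknown root prior"))
}

.edgeMatrices <- function(info, lambda, mu, events, maxN) {
  edgeP <- vector("list", nrow(info$edge))
  evEdge <- if (is.null(events)) integer(0) else events$edge
  for (e in seq_len(nrow(info$edge))) {
    t <- info$len[e]
    if (e %in% evEdge) {
      q <- events$q[match(e, evEdge)]
      half <- .bdpMatrix(t / 2, lambda, mu, maxN)
      edgeP[[e]] <- half %*% .wgdMatrix(q, maxN) %*% half
    } else {
      edgeP[[e]] <- .bdpMatrix(t, lambda, mu, maxN)
    }
  }
  edgeP
}

# log probability that a family is observable under the >=2-ingroup
# plus >=1-outgroup presence filter.  Augmented pruning: at each node,
# for each copy-number state, the joint probability over (number of
# ingroup species present below, capped at 2) x (any outgroup present
# below).  Direct computation -- no near-one cancellation at extreme
# rates -- with per-node log scaling.
.logPObservable <- function(info, edgeP, prior, groups, maxN) {
  tips <- info$tips
  nS <- maxN + 1L
  # G[[node]]: nS x 3 x 2 array over (state, cornusPresent 0:2, outgroup 0:1)
  G <- vector("list", max(info$edge))
  logScale <- 0
  for (tip in seq_len(info$nTip)) {
    g <- array(0, c(nS, 3L, 2L))
    present <- c(FALSE, rep(TRUE, maxN))
    if (tips[tip] %in% groups$cornus) {
      g[!present, 1L, 1L] <- 1
      g[present, 2L, 1L] <- 1
    } else if (tips[tip] %in% groups$outgroups) {
      g[!present, 1L, 1L] <- 1
      g[present, 1L, 2L] <- 1
    } else {
      g[, 1L, 1L] <- 1
    }
    G[[tip]] <- g
  }
  combine <- function(a, b) {
    out <- array(0, c(nS, 3L, 2L))
    for (c1 in 1:3) for (o1 in 1:2) {
      va <- a[, c1, o1]
      if (!any(va > 0)) next
      for (c2 in 1:3) for (o2 in 1:2) {
        cc <- min(c1 + c2 - 1L, 3L)
        oo <- max(o1, o2)
        out[, cc, oo] <- out[, cc, oo] + va * b[, c2, o2]
      }
    }
    out
  }
  for (e in seq_len(nrow(info$edge))) {
    p <- info$edge[e, 1L]; ch <- info$edge[e, 2L]
    g <- G[[ch]]
    m <- array(0, dim(g))
    for (cc in 1:3) for (oo in 1:2) m[, cc, oo] <- edgeP[[e]] %*% g[, cc, oo]
    G[[p]] <- if (is.null(G[[p]])) m else combine(G[[p]], m)
    mx <- max(G[[p]])
    if (mx > 0 && (mx < 1e-100 || mx > 1e100)) {
      G[[p]] <- G[[p]] / mx
      logScale <- logScale + log(mx)
    }
  }
  pObs <- sum(prior * G[[info$root]][, 3L, 2L])
  if (pObs <= 0) return(-Inf)
  log(pObs) + logScale
}

.resolveEvents <- function(tree, branches, q) {
  if (is.null(branches) || !length(branches)) return(NULL)
  ids <- placementBranches(tree)
  unknown <- setdiff(branches, names(ids))
  if (length(unknown)) stop("unknown branch id(s): ", paste(unknown, collapse = ", "))
  stopifnot(length(q) == length(branches), all(q >= 0 & q <= 1))
  data.frame(edge = unname(ids[branches]), q = q)
}

#' Gene-count log-likelihood under a WGD placement
#'
#' Log-likelihood of a family-by-species gene-count matrix under the
#' linear birth-death copy-number model on a dated tree, with optional
#' WGD events (binomial retention with rate q at branch midpoints) and
#' optional conditioning on the observability filter.
#'
#' @param counts integer matrix (families x species; column names are
#'   species codes matching the tree tips) or a single named count row.
#' @param tree dated `phylo`; default [cornusSpeciesTree()].
#' @param lambda,mu per-copy birth and death rates (1/myr).
#' @param branches character vector of branch ids (see
#'   [placementBranches()]) carrying WGD events; NULL for none.
#' @param q retention rate(s), one per branch in \code{branches}.
#' @param maxN copy-number truncation bound (default 20).
#' @param rootPrior \code{"single"} (one copy at the root),
#'   \code{"geometric"}, or a probability vector over 0..maxN.
#' @param condition \code{"none"} or \code{"filter"} (condition each
#'   family on passing the >= 2 ingroup species + >= 1 outgroup filter).
#' @param groups species groups as from [speciesGroups()].
#' @return list: \code{total} log-likelihood, \code{perFamily} vector,
#'   \code{pObserve} (the conditioning probability, 1 when
#'   unconditioned).
#' @export
geneCountLoglik <- function(counts, tree = cornusSpeciesTree(),
                            lambda, mu, branches = NULL, q = numeric(0),
                            maxN = 20, rootPrior = "single",
                            condition = c("none", "filter"),
                            groups = speciesGroups()) {
  condition <- match.arg(condition)
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1,
                                             dimnames = list(NULL, names(counts)))
  if (is.null(colnames(counts))) stop("'counts' needs species column names")
  info <- .treeInfo(tree)
  missing <- setdiff(info$tips, colnames(counts))
  if (length(missing)) stop("counts lack species: ", paste(missing, collapse = ", "))
  events <- .resolveEvents(info$tree, branches, q)
  edgeP <- .edgeMatrices(info, lambda, mu, events, maxN)
  prior <- .rootPriorVec(rootPrior, maxN)
  leafLik <- lapply(seq_len(info$nTip), function(tip)
    .leafIndicator(counts[, info$tips[tip]], maxN))
  pr <- .pruneLik(info, leafLik, edgeP)
  perFam <- as.numeric(log(pmax(pr$root %*% prior, .Machine$double.xmin)) +
                         pr$logScale)
  pObs <- 1
  if (condition == "filter") {
    lp <- .logPObservable(info, edgeP, prior, groups, maxN)
    if (!is.finite(lp)) {
      # numerically unreachable parameter region (observability underflows):
      # report a uniformly terrible likelihood so optimizers retreat
      perFam <- rep(-1e8, length(perFam))
      return(list(total = sum(perFam), perFamily = perFam, pObserve = 0))
    }
    perFam <- perFam - lp
    pObs <- exp(lp)
  }
  list(total = sum(perFam), perFamily = perFam, pObserve = pObs)
}

#' @rdname geneCountLoglik
#' @param countsRow a single named count vector (one family).
#' @export
familyLoglik <- function(countsRow, tree = cornusSpeciesTree(), lambda, mu,
                         branches = NULL, q = numeric(0), ...) {
  geneCountLoglik(countsRow, tree = tree, lambda = lambda, mu = mu,
                  branches = branches, q = q, ...)$total
}

#' Load a gene-count matrix from an orthogroup table
#'
#' Reads a TSV mapping family ids to member gene ids (either one row per
#' family with members in the second column separated by commas or
#' spaces, or one row per family-gene pair), converts membership to
#' per-species copy counts, and applies the observability filter:
#' families present in fewer than \code{minCornus} ingroup species or in
#' no outgroup are removed and counted.
#'
#' @param path TSV path (no header), or a data.frame in either layout.
#' @param speciesMap named character vector gene id -> species code.
#' @param groups species groups as from [speciesGroups()].
#' @param minCornus minimum number of ingroup species with a copy
#'   (default 2).
#' @return list: \code{counts} (families x species integer matrix with
#'   family ids as rownames), \code{nRemoved}.
#' @export
loadGeneCounts <- function(path, speciesMap, groups = speciesGroups(),
                           minCornus = 2) {
  tab <- if (is.data.frame(path)) path
         else read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("orthogroup table needs >= 2 columns")
  fam <- rep(tab[[1]], lengths(strsplit(as.character(tab[[2]]), "[,[:space:]]+")))
  gene <- unlist(strsplit(as.character(tab[[2]]), "[,[:space:]]+"))
  keep <- gene != ""
  fam <- fam[keep]; gene <- gene[keep]
  unknown <- setdiff(gene, names(speciesMap))
  if (length(unknown))
    stop("unknown species for gene(s): ", paste(head(unknown, 5), collapse = ", "))
  sp <- unname(speciesMap[gene])
  allSp <- unique(c(groups$cornus, groups$outgroups, sp))
  counts <- table(factor(fam, levels = unique(fam)),
                  factor(sp, levels = allSp))
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  filt <- filterGeneCounts(counts, groups, minCornus)
  filt
}

#' @rdname loadGeneCounts
#' @param counts a families x species integer matrix.
#' @export
filterGeneCounts <- function(counts, groups = speciesGroups(), minCornus = 2) {
  corCols <- intersect(colnames(counts), groups$cornus)
  outCols <- intersect(colnames(counts), groups$outgroups)
  pass <- rowSums(counts[, corCols, drop = FALSE] >= 1) >= minCornus &
          rowSums(counts[, outCols, drop = FALSE] >= 1) >= 1
  list(counts = counts[pass, , drop = FALSE], nRemoved = sum(!pass))
}

.optimRates <- function(negll, start = c(-6, -6)) {
  fit <- optim(start, negll, method = "L-BFGS-B",
               lower = c(-14, -14), upper = c(2, 2),
               control = list(factr = 1e10))
  fit
}

#' Score WGD placement hypotheses on gene-count data
#'
#' For each hypothesis, maximizes the conditioned gene-count likelihood
#' over the shared birth and death rates with retention rates on the
#' grid \code{qGrid}.  \code{qSearch = "grid"} profiles (lambda, mu)
#' at every grid combination (exact, exponential in the number of
#' events); \code{"joint"} (default) first optimizes (log lambda,
#' log mu, logit q) jointly, then snaps each q to its neighbouring grid
#' values and re-optimizes the rates at each candidate combination.
#' Hypotheses are compared by AIC (2p - 2 logL with p = 2 + number of
#' events) and Akaike weights.
#'
#' @param counts families x species integer matrix (already filtered).
#' @param tree dated `phylo`; default [cornusSpeciesTree()].
#' @param hypotheses named list of branch-id vectors; default
#'   [wgdHypotheses()].
#' @param qGrid retention-rate grid (default 0, 0.1, ..., 1).
#' @param qSearch \code{"joint"} or \code{"grid"}.
#' @param maxN,rootPrior,condition,groups as in [geneCountLoglik()].
#' @return a [WGDPlacementFit-class].
#' @export
testHypotheses <- function(counts, tree = cornusSpeciesTree(),
                           hypotheses = wgdHypotheses(),
                           qGrid = seq(0, 1, by = 0.1),
                           qSearch = c("joint", "grid"),
                           maxN = 20, rootPrior = "single",
                           condition = c("filter", "none"),
                           groups = speciesGroups()) {
  qSearch <- match.arg(qSearch)
  condition <- match.arg(condition)
  if (!nrow(counts)) stop("'counts' is empty")
  # aggregate identical count patterns for speed
  key <- apply(counts, 1, paste, collapse = ",")
  uniq <- !duplicated(key)
  w <- as.vector(table(key)[key[uniq]])
  ucounts <- counts[uniq, , drop = FALSE]
  nFam <- nrow(counts)
  llFun <- function(lambda, mu, branches, q) {
    r <- geneCountLoglik(ucounts, tree = tree, lambda = lambda, mu = mu,
                         branches = branches, q = q, maxN = maxN,
                         rootPrior = rootPrior, condition = condition,
                         groups = groups)
    sum(w * r$perFamily)
  }
  rows <- list()
  for (hid in names(hypotheses)) {
    branches <- hypotheses[[hid]]
    nEv <- length(branches)
    bestFit <- NULL
    evalCombo <- function(qs, start) {
      negll <- function(p) -llFun(exp(p[1]), exp(p[2]), branches, qs)
      fit <- .optimRates(negll, start)
      list(q = qs, logLik = -fit$value, par = fit$par,
           converged = fit$convergence == 0)
    }
    if (qSearch == "grid") {
      combos <- do.call(expand.grid, rep(list(qGrid), nEv))
      start <- c(-6, -6)
      for (ci in seq_len(nrow(combos))) {
        res <- evalCombo(as.numeric(combos[ci, ]), start)
        start <- res$par
        if (is.null(bestFit) || res$logLik > bestFit$logLik) bestFit <- res
      }
    } else {
      negllJ <- function(p) -llFun(exp(p[1]), exp(p[2]), branches,
                                   stats::plogis(p[-(1:2)]))
      fitJ <- optim(c(-6, -6, rep(0, nEv)), negllJ, method = "L-BFGS-B",
                    lower = c(-14, -14, rep(-9, nEv)),
                    upper = c(2, 2, rep(9, nEv)),
                    control = list(factr = 1e10))
      qHat <- stats::plogis(fitJ$par[-(1:2)])
      cand <- lapply(qHat, function(qh) {
        i <- which.min(abs(qGrid - qh))
        unique(qGrid[pmax(1, pmin(length(qGrid), c(i - 1, i, i + 1)))])
      })
      combos <- do.call(expand.grid, cand)
      # screen grid combinations at the jointly fitted rates, then
      # re-optimize the rates only at the best-scoring combination
      screenLL <- vapply(seq_len(nrow(combos)), function(ci)
        llFun(exp(fitJ$par[1]), exp(fitJ$par[2]), branches,
              as.numeric(combos[ci, ])), numeric(1))
      bestFit <- evalCombo(as.numeric(combos[which.max(screenLL), ]),
                           fitJ$par[1:2])
    }
    p <- 2 + nEv
    rows[[hid]] <- data.frame(
      hypothesis = hid, logLik = bestFit$logLik,
      lambda = exp(bestFit$par[1]), mu = exp(bestFit$par[2]),
      q = paste(format(bestFit$q, trim = TRUE), collapse = ","),
      nEvents = nEv, nParams = p, AIC = 2 * p - 2 * bestFit$logLik,
      converged = bestFit$converged)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  d <- res$AIC - min(res$AIC)
  res$weight <- exp(-d / 2) / sum(exp(-d / 2))
  new("WGDPlacementFit", results = res,
      best = res$hypothesis[which.min(res$AIC)],
      nFamilies = as.integer(nFam))
}
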