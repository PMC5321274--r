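# Independent brute-force oracles.  Each re-derives its quantity from
# first principles with a different code path than the implementation.

# --- NG86 oracle -----------------------------------------------------
# recursion over all orderings of the differing positions; explicit
# per-position site classification from the genetic code
.oracleGC <- as.list(Biostrings::GENETIC_CODE)

oracleSynSites <- function(codon) {
  sp <- strsplit(codon, "")[[1]]
  aa <- .oracleGC[[codon]]
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"), sp[pos])) {
      alt <- sp; alt[pos] <- b
      altAa <- .oracleGC[[paste(alt, collapse = "")]]
      if (altAa == "*") next
      if (altAa == aa) s <- s + 1 / 3
    }
  }
  s
}

oraclePathways <- function(ca, cb) {
  sa <- strsplit(ca, "")[[1]]; sb <- strsplit(cb, "")[[1]]
  dif <- which(sa != sb)
  if (!length(dif)) return(c(0, 0))
  walk <- function(cur, remaining) {
    if (!length(remaining)) return(list(c(0, 0)))
    out <- list()
    for (ri in seq_along(remaining)) {
      pos <- remaining[ri]
      nxt <- cur; nxt[pos] <- sb[pos]
      aaN <- .oracleGC[[paste(nxt, collapse = "")]]
      if (aaN == "*") next
      aaC <- .oracleGC[[paste(cur, collapse = "")]]
      step <- if (aaN == aaC) c(1, 0) else c(0, 1)
      for (tail in walk(nxt, remaining[-ri]))
        out[[length(out) + 1]] <- step + tail
    }
    out
  }
  paths <- walk(sa, dif)
  if (!length(paths)) {
    # all paths stop-blocked: average over all orderings ignoring stops
    walkAll <- function(cur, remaining) {
      if (!length(remaining)) return(list(c(0, 0)))
      out <- list()
      for (ri in seq_along(remaining)) {
        pos <- remaining[ri]
        nxt <- cur; nxt[pos] <- sb[pos]
        aaN <- .oracleGC[[paste(nxt, collapse = "")]]
        aaC <- .oracleGC[[paste(cur, collapse = "")]]
        step <- if (aaN == aaC) c(1, 0) else c(0, 1)
        for (tail in walkAll(nxt, remaining[-ri]))
          out[[length(out) + 1]] <- step + tail
      }
      out
    }
    paths <- walkAll(sa, dif)
  }
  Reduce(`+`, paths) / length(paths)
}

oracleNg86 <- function(codonsA, codonsB) {
  L <- length(codonsA)
  S <- (sum(vapply(codonsA, oracleSynSites, numeric(1))) +
        sum(vapply(codonsB, oracleSynSites, numeric(1)))) / 2
  N <- 3 * L - S
  sd <- 0; nd <- 0
  for (i in seq_len(L)) {
    p <- oraclePathways(codonsA[i], codonsB[i])
    sd <- sd + p[1]; nd <- nd + p[2]
  }
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = sd, Nd = nd,
       ks = jc(sd / S), ka = jc(nd / N))
}

randomSenseCodons <- function(n) {
  sense <- names(.oracleGC)[unlist(.oracleGC) != "*"]
  sample(sense, n, replace = TRUE)
}

# mutate a codon vector at `k` random positions avoiding stops
mutateCodons <- function(codons, k) {
  for (i in seq_len(k)) {
    repeat {
      ci <- sample(seq_along(codons), 1)
      sp <- strsplit(codons[ci], "")[[1]]
      pos <- sample(1:3, 1)
      sp[pos] <- sample(setdiff(c("A", "C", "G", "T"), sp[pos]), 1)
      cand <- paste(sp, collapse = "")
      if (.oracleGC[[cand]] != "*") { codons[ci] <- cand; break }
    }
  }
  codons
}

# --- pairing oracle --------------------------------------------------
# direct nested-loop re-derivation of best-match pairing
oracleBestPairs <- function(hits, mode, speciesMap, requireReciprocal = TRUE,
                            parentPattern = "(_i\\d+|\\.\\d+)$") {
  h <- hits[hits$queryId != hits$subjectId, , drop = FALSE]
  sameSp <- speciesMap[h$queryId] == speciesMap[h$subjectId]
  h <- if (mode == "within") {
    hh <- h[sameSp, , drop = FALSE]
    hh[sub(parentPattern, "", hh$queryId) !=
         sub(parentPattern, "", hh$subjectId), , drop = FALSE]
  } else h[!sameSp, , drop = FALSE]
  if (!nrow(h)) return(character(0))
  # collapse multi-hits per ordered gene pair: longest, then best score
  best <- list()
  for (i in seq_len(nrow(h))) {
    k <- paste(h$queryId[i], h$subjectId[i])
    cur <- best[[k]]
    if (is.null(cur) || h$alignLength[i] > cur$alignLength ||
        (h$alignLength[i] == cur$alignLength && h$bitscore[i] > cur$bitscore))
      best[[k]] <- h[i, ]
  }
  h <- do.call(rbind, best)
  topOf <- function(g) {
    cand <- h[h$queryId == g, , drop = FALSE]
    if (!nrow(cand)) return(NA_character_)
    cand <- cand[order(-cand$bitscore, -cand$alignLength, cand$subjectId), ]
    cand$subjectId[1]
  }
  pairs <- character(0)
  for (g in unique(h$queryId)) {
    m <- topOf(g)
    if (is.na(m)) next
    if (requireReciprocal && !identical(topOf(m), g)) next
    pairs <- c(pairs, paste(min(g, m), max(g, m)))
  }
  sort(unique(pairs))
}

# --- birth-death Monte Carlo oracle ----------------------------------
# event-driven simulation written independently of the package
oracleBdpSim <- function(n0, t, lambda, mu, nRep) {
  out <- integer(nRep)
  for (r in seq_len(nRep)) {
    n <- n0; clock <- 0
    repeat {
      if (n == 0) break
      total <- n * (lambda + mu)
      if (total == 0) break
      clock <- clock + stats::rexp(1, total)
      if (clock > t) break
      n <- n + if (stats::runif(1) < lambda / (lambda + mu)) 1L else -1L
    }
    out[r] <- n
  }
  out
}

# --- two-leaf family likelihood oracle -------------------------------
# exhaustive enumeration over root and internal states
oracleTwoLeafLoglik <- function(tLeft, tRight, cLeft, cRight, lambda, mu,
                                maxState = 10) {
  p <- 0
  for (s in 0:maxState) {
    pr <- as.numeric(s == 1)  # single-copy root prior
    if (pr == 0) next
    p <- p + pr *
      bdpTransitionProb(s, cLeft, tLeft, lambda, mu) *
      bdpTransitionProb(s, cRight, tRight, lambda, mu)
  }
  log(p)
}

# --- gene-tree criterion oracle --------------------------------------
# evaluate every internal node via ape clade extraction
oracleScreen <- function(tree, groups = speciesGroups()) {
  nTip <- length(tree$tip.label)
  sp <- sub("_.*$", "", tree$tip.label)
  cornus <- groups$cornus; bw <- groups$bw
  nonbw <- setdiff(cornus, bw)
  ages <- numeric(0)
  dn <- ape::dist.nodes(tree)
  for (node in (nTip + 1):(nTip + tree$Nnode)) {
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    if (length(kids) != 2) next
    tipsOf <- function(k) {
      if (k <= nTip) sp[k]
      else sp[match(ape::extract.clade(tree, k)$tip.label, tree$tip.label)]
    }
    ok <- function(s) all(s %in% cornus) && any(s %in% bw) && any(s %in% nonbw)
    if (ok(tipsOf(kids[1])) && ok(tipsOf(kids[2]))) {
      desc <- unlist(lapply(kids, function(k)
        if (k <= nTip) k else match(ape::extract.clade(tree, k)$tip.label,
                                    tree$tip.label)))
      ages <- c(ages, max(dn[node, desc]))
    }
  }
  if (!length(ages)) list(passes = FALSE, age = NA_real_)
  else list(passes = TRUE, age = max(ages))
}

# assert the EM trace and BIC bookkeeping of a fit
expectValidFit <- function(fit) {
  tr <- fit@logLikTrace
  expect_true(all(diff(tr) >= -1e-8 * pmax(1, abs(tr[-length(tr)]))))
  p <- 3 * fit@k - 1
  expect_equal(fit@bic, -2 * fit@logLik + p * log(fit@n), tolerance = 1e-10)
  expect_equal(sum(fit@proportion), 1, tolerance = 1e-9)
}
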