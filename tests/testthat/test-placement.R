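test_that("birth-death transition probabilities satisfy their limits", {
  expect_equal(bdpTransitionProb(3, 0:6, 0, 0.01, 0.02),
               c(0, 0, 0, 1, 0, 0, 0))
  expect_equal(bdpTransitionProb(2, 0:4, 50, 0, 0), c(0, 0, 1, 0, 0))
  expect_equal(bdpTransitionProb(0, 0:3, 5, 0.1, 0.1), c(1, 0, 0, 0))
  # normalization over j for several regimes (truncation tolerance)
  for (par in list(c(1, 5, 0.01, 0.02), c(3, 20, 0.005, 0.005),
                   c(5, 10, 0.02, 0), c(2, 30, 0, 0.03))) {
    tot <- sum(bdpTransitionProb(par[1], 0:80, par[2], par[3], par[4]))
    expect_equal(tot, 1, tolerance = 1e-8)
  }
  expect_error(bdpTransitionProb(-1, 0, 1, 0.1, 0.1), "invalid")
})

test_that("closed-form probabilities match Monte-Carlo frequencies", {
  set.seed(77)
  nRep <- 1e5
  sim <- oracleBdpSim(1, 1, 0.002, 0.002, nRep)
  for (j in 0:5) {
    pHat <- mean(sim == j)
    p <- bdpTransitionProb(1, j, 1, 0.002, 0.002)
    se <- sqrt(max(p * (1 - p), 1e-12) / nRep)
    expect_lt(abs(pHat - p), 3 * se + 1e-6)
  }
  # a stronger regime with real dynamics
  set.seed(78)
  sim2 <- oracleBdpSim(2, 40, 0.01, 0.008, 2e4)
  for (j in 0:6) {
    p <- bdpTransitionProb(2, j, 40, 0.01, 0.008)
    se <- sqrt(p * (1 - p) / 2e4)
    expect_lt(abs(mean(sim2 == j) - p), 4 * se + 1e-4)
  }
})

test_that("orthogroup tables load, count and filter families", {
  tsv <- tempfile()
  writeLines(c("fam1\tCAL_g1,CAL_g2,ACH_g1",
               "fam2\tCAL_g3,CCO_g1,ACH_g2,ACH_g3",
               "fam3\tCAL_g4,CCO_g2",
               "fam4\tCFL_g1,CKO_g1,DFE_g1"), tsv)
  genes <- c(CAL_g1 = "CAL", CAL_g2 = "CAL", CAL_g3 = "CAL", CAL_g4 = "CAL",
             ACH_g1 = "ACH", ACH_g2 = "ACH", ACH_g3 = "ACH",
             CCO_g1 = "CCO", CCO_g2 = "CCO", CFL_g1 = "CFL",
             CKO_g1 = "CKO", DFE_g1 = "DFE")
  got <- loadGeneCounts(tsv, genes)
  # fam1: one ingroup species only; fam3: no outgroup -> removed
  expect_equal(rownames(got$counts), c("fam2", "fam4"))
  expect_equal(got$nRemoved, 2L)
  expect_equal(got$counts["fam2", "ACH"], 2L)
  expect_equal(got$counts["fam2", "CAL"], 1L)
  expect_error(loadGeneCounts(tsv, genes[-1]), "unknown species")

  # matrix filter equals a brute-force reimplementation
  set.seed(4)
  g <- speciesGroups()
  cm <- matrix(rpois(50 * 10, 0.7), 50, 10,
               dimnames = list(paste0("f", 1:50), c(g$cornus, g$outgroups)))
  filt <- filterGeneCounts(cm)
  brute <- apply(cm, 1, function(r)
    sum(r[g$cornus] >= 1) >= 2 && sum(r[g$outgroups] >= 1) >= 1)
  expect_equal(nrow(filt$counts), sum(brute))
  expect_equal(filt$nRemoved, sum(!brute))
})

test_that("family likelihood matches enumeration and degenerate cases", {
  # star-like check on the real tree: lambda = mu = 0, all counts 1
  tr <- cornusSpeciesTree()
  cts <- setNames(rep(1L, 10), tr$tip.label)
  expect_equal(familyLoglik(cts, lambda = 0, mu = 0), 0)
  # a multifurcating star tree behaves identically
  star <- ape::read.tree(text = "(A:10,B:10,C:10);")
  expect_equal(familyLoglik(setNames(rep(1L, 3), c("A", "B", "C")),
                            tree = star, lambda = 0, mu = 0), 0)
  # WGD with q = 1 on the ingroup stem forces doubled ingroup counts
  g <- speciesGroups()
  cts2 <- cts; cts2[g$cornus] <- 2L
  expect_equal(familyLoglik(cts2, lambda = 0, mu = 0,
                            branches = "cornus_stem", q = 1), 0)
  expect_lt(familyLoglik(cts, lambda = 0, mu = 0,
                         branches = "cornus_stem", q = 1), -100)

  # two-leaf tree: pruning equals exhaustive enumeration
  two <- ape::read.tree(text = "(L:12,R:30);")
  for (cl in 0:3) for (cr in 0:3) {
    got <- familyLoglik(setNames(c(cl, cr), c("L", "R")), tree = two,
                        lambda = 0.01, mu = 0.015)
    want <- oracleTwoLeafLoglik(12, 30, cl, cr, 0.01, 0.015)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("observability conditioning matches simulated filter rates", {
  # empirical fraction of families passing the filter vs the computed
  # conditioning probability, on event-level simulations
  n <- 3000
  cm <- simulateGeneCounts(n, birth = 0.004, death = 0.006,
                           wgdBranch = NULL, q = 0, seed = 31)
  empirical <- nrow(filterGeneCounts(cm)$counts) / n
  r <- geneCountLoglik(cm[1, , drop = FALSE], lambda = 0.004, mu = 0.006,
                       condition = "filter")
  se <- sqrt(empirical * (1 - empirical) / n)
  expect_lt(abs(r$pObserve - empirical), 4 * se)
})

test_that("hypothesis scoring behaves on edge cases", {
  cm <- simulateGeneCounts(400, birth = 0.002, death = 0.002,
                           wgdBranch = NULL, q = 0, seed = 51)
  counts <- filterGeneCounts(cm)$counts
  # single hypothesis: weight 1
  one <- testHypotheses(counts, hypotheses = wgdHypotheses()["H2"])
  expect_equal(placementTable(one)$weight, 1)
  expect_s4_class(one, "WGDPlacementFit")
  # no-WGD data: the fitted grid q is 0
  expect_equal(placementTable(one)$q, "0")
  # grid search agrees with the joint-then-snap default on one event
  oneGrid <- testHypotheses(counts, hypotheses = wgdHypotheses()["H2"],
                            qGrid = seq(0, 0.3, 0.1), qSearch = "grid")
  expect_equal(placementTable(oneGrid)$q, "0")
  expect_equal(placementTable(oneGrid)$logLik, placementTable(one)$logLik,
               tolerance = 1e-4)
  expect_error(testHypotheses(counts[0, ]), "empty")
})

test_that("Akaike weights are a proper weighting across hypotheses", {
  cm <- simulateGeneCounts(500, birth = 0.002, death = 0.002,
                           wgdBranch = "cornus_stem", q = 0.2, seed = 61)
  counts <- filterGeneCounts(cm)$counts
  fit <- testHypotheses(counts, hypotheses = wgdHypotheses()[c("H1", "H2")])
  tab <- placementTable(fit)
  expect_equal(sum(tab$weight), 1, tolerance = 1e-9)
  expect_equal(tab$AIC, 2 * tab$nParams - 2 * tab$logLik)
  expect_equal(bestHypothesis(fit), tab$hypothesis[which.min(tab$AIC)])
})
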