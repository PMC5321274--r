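test_that("paralog Ks generator plants components where the clock puts them", {
  ev <- data.frame(age = 74, proportion = 0.4, sd = 5)
  clock <- 2.7e-3
  sim <- simulateParalogKs(20000, clock, ev, ssdRate = 0.05, seed = 11)
  expect_equal(nrow(sim), 20000)
  expect_true(all(sim$ks >= 0))
  expect_true(all(sim$label %in% c("SSD", "WGD_1")))
  # planted proportion within binomial error (4 sd)
  pHat <- mean(sim$label == "WGD_1")
  expect_lt(abs(pHat - 0.4), 4 * sqrt(0.4 * 0.6 / 20000))
  # component mean in Ks: 2 * C_Ks * age = 0.3996
  wgd <- sim$ks[sim$label == "WGD_1"]
  expect_equal(mean(wgd), 2 * clock * 74, tolerance = 0.01)
  # determinism and the empty edge case
  again <- simulateParalogKs(20000, clock, ev, ssdRate = 0.05, seed = 11)
  expect_identical(sim, again)
  expect_equal(nrow(simulateParalogKs(0, clock, ev, 0.05, seed = 1)), 0)
  expect_error(simulateParalogKs(10, -1, ev, 0.05), "positive")
})

test_that("ortholog Ks peak converges to 2*C_Ks*T and respects symmetry", {
  ks <- simulateOrthologKs(20000, 2.67e-3, 80.21, sigma = 0.08, seed = 3)
  expect_equal(kdePeak(ks), 2 * 2.67e-3 * 80.21, tolerance = 0.01)
  expect_true(all(simulateOrthologKs(50, 2.7e-3, 0, seed = 1) == 0))
  a <- simulateOrthologKs(500, 3e-3, 50, seed = 9)
  b <- simulateOrthologKs(500, 3e-3, 50, seed = 9)
  expect_identical(a, b)
  expect_error(simulateOrthologKs(10, 3e-3, NA), "missing")
})

test_that("codon-pair generator honours its targets and bounds", {
  same <- simulateCodonPair(0, 0, nCodons = 60, seed = 5)
  expect_identical(same$seqA, same$seqB)
  expect_error(simulateCodonPair(0.1, 0.02, nCodons = 49), "50")
  ok <- simulateCodonPair(0.1, 0.02, nCodons = 50, seed = 1)
  expect_equal(nchar(ok$seqA), 150)
  expect_false(ok$saturationRisk)
  expect_true(simulateCodonPair(5, 0.1, nCodons = 60, seed = 1)$saturationRisk)
  cp <- simulateCodonPair(0.3, 0.05, nCodons = 300, seed = 2)
  expect_equal(cp$realizedKs, cp$nSyn / cp$S)
  expect_false(grepl("(TAA|TAG|TGA)",
                     paste(substring(cp$seqB, seq(1, nchar(cp$seqB), 3),
                                     seq(3, nchar(cp$seqB), 3)),
                           collapse = "|")))
})

test_that("gene-count simulation matches its degenerate limits", {
  m0 <- simulateGeneCounts(30, birth = 0, death = 0, wgdBranch = NULL,
                           q = 0, seed = 1)
  expect_true(all(m0 == 1L))
  m1 <- simulateGeneCounts(30, birth = 0, death = 0,
                           wgdBranch = "cornus_alangium_stem", q = 1, seed = 1)
  g <- speciesGroups()
  expect_true(all(m1[, c(g$cornus, "ACH")] == 2L))
  expect_true(all(m1[, "DFE"] == 1L))
  expect_identical(simulateGeneCounts(50, seed = 4),
                   simulateGeneCounts(50, seed = 4))
})

test_that("event-level count simulation agrees with the closed form", {
  # single terminal branch: DFE tip spans the full root-to-tip 95.75 myr
  # on a no-WGD tree, so the DFE count is one lineage evolving for t=95.75
  n <- 4000
  m <- simulateGeneCounts(n, birth = 0.004, death = 0.003, wgdBranch = NULL,
                          q = 0, seed = 21)
  emp <- tabulate(m[, "DFE"] + 1L, nbins = 8) / n
  theo <- bdpTransitionProb(1, 0:7, 95.75, 0.004, 0.003)
  se <- sqrt(theo * (1 - theo) / n)
  expect_true(all(abs(emp - theo) <= 4 * se + 1e-4))
})

test_that("simulated gene trees carry the planted duplication", {
  gt <- simulateGeneTrees(15, dupAge = 76, dupSd = 0, dropout = 0, seed = 2)
  calls <- do.call(rbind, lapply(gt$trees, screenTree))
  expect_true(all(calls$passes))
  expect_equal(calls$age, rep(76, 15), tolerance = 1e-9)
  # removing one whole subclade defeats the criterion
  tr <- gt$trees[[1]]
  half <- grep("_1$", tr$tip.label, value = TRUE)
  pruned <- ape::drop.tip(tr, half)
  expect_false(screenTree(pruned)$passes)
  expect_error(simulateGeneTrees(3, dupAge = 50), "crown")
})

test_that("cohort generation is reproducible and carries truth labels", {
  cfg <- simulationConfig(nPairs = 50, orthoN = 30, nFamilies = 20,
                          nTrees = 5, nSeqPairs = 2, seed = 9)
  c1 <- simulateCohort(cfg)
  c2 <- simulateCohort(cfg)
  expect_identical(c1$paralogKs, c2$paralogKs)
  expect_identical(c1$geneCounts, c2$geneCounts)
  expect_identical(c1$transcripts, c2$transcripts)
  expect_true(all(unlist(lapply(c1$paralogKs, function(d)
    d$label %in% c("SSD", "WGD_1", "WGD_2", "WGD_3")))))
  expect_error(simulationConfig(wgdEvents = data.frame(
    age = 10, proportion = 1.2, sd = 1)), "proportion")
  expect_error(simulationConfig(speciesClocks = c(A = -1)), "positive")
  # writer produces the expected plain-text files
  td <- tempfile(); files <- writeCohort(c1, td)
  expect_true(all(file.exists(files)))
})
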