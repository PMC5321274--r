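# exhaustive six-frame oracle: length of the longest stop-free codon run
oracleLongestOrf <- function(s) {
  stops <- c("TAA", "TAG", "TGA")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  best <- 0
  for (x in c(s, rc)) for (f in 0:2) {
    sub <- substr(x, f + 1, nchar(x))
    n <- nchar(sub) %/% 3
    if (n < 1) next
    cods <- substring(sub, seq(1, n * 3, 3), seq(3, n * 3, 3))
    r <- rle(cods %in% stops)
    runs <- r$lengths[!r$values]
    if (length(runs)) best <- max(best, max(runs))
  }
  best * 3
}

test_that("ORF inference scans all six frames", {
  # TCA repeats: stop-free forward frame 0, TGA-stops on the reverse
  clean <- strrep("TCA", 121)
  got <- inferCds(clean)
  expect_equal(got$strand, "+")
  expect_equal(got$frame, 0)
  expect_equal(nchar(got$cds), oracleLongestOrf(clean))

  # reverse strand ORF is found and reverse-complemented back
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(clean)))
  gotRc <- inferCds(rc)
  expect_equal(gotRc$strand, "-")
  expect_equal(gotRc$cds, got$cds)

  # two stop-separated ORFs: the longer one wins (oracle-verified length)
  two <- paste0(strrep("TTAA", 3), strrep("TCA", 100), strrep("TTAA", 3),
                strrep("TCA", 150), strrep("TTAA", 3))
  best <- inferCds(two)
  expect_equal(nchar(best$cds), oracleLongestOrf(two))
  expect_gte(nchar(best$cds), 450)
  expect_true(grepl(strrep("TCA", 150), best$cds, fixed = TRUE))

  # random transcripts agree with the oracle on ORF length
  set.seed(12)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
               collapse = "")
    want <- oracleLongestOrf(s)
    got <- inferCds(s)
    if (want >= 150) expect_equal(nchar(got$cds), want) else expect_null(got)
  }

  expect_error(inferCds("ATGAAA"), "300")
  # stops in every frame on both strands: nothing to return
  expect_null(inferCds(strrep("TTAA", 90)))
})

test_that("codon alignment removes gap columns and enforces the floor", {
  cds <- paste(randomSenseCodons(80), collapse = "")
  al <- codonAlignPair(cds, cds)
  expect_equal(al$nCodons, 80)
  expect_equal(al$nGapColumns, 0)
  expect_identical(al$codonsA, al$codonsB)

  # one internal codon insertion: that column is removed
  set.seed(3)
  base <- randomSenseCodons(70)
  ins <- append(base, "GCT", after = 35)
  al2 <- codonAlignPair(paste(base, collapse = ""), paste(ins, collapse = ""))
  expect_equal(al2$nCodons, 70)
  expect_equal(al2$nGapColumns, 1)
  expect_identical(al2$codonsA, al2$codonsB)

  # below 50 ungapped codons the pair is dropped
  expect_null(codonAlignPair(paste(randomSenseCodons(20), collapse = ""),
                             paste(randomSenseCodons(20), collapse = "")))
})

test_that("NG86 handles the textbook single-difference case exactly", {
  a <- strrep("TTTGCT", 50)
  b <- sub("^TTT", "TTC", a)
  est <- ng86Rates(a, b)
  # TTT has 1/3 synonymous site, GCT has 1: S = 50/3 + 50
  expect_equal(est$S, 50 / 3 + 50)
  expect_equal(est$N, 300 - est$S)
  expect_equal(est$Sd, 1)
  expect_equal(est$Nd, 0)
  expect_equal(est$ks, -0.75 * log(1 - 4 / (3 * est$S)))
  expect_equal(est$ka, 0)
  expect_identical(ng86Rates(a, a)$ks, 0)

  # symmetry in the two sequences
  est2 <- ng86Rates(b, a)
  expect_equal(est$ks, est2$ks)
  expect_equal(est$ka, est2$ka)
})

test_that("NG86 equals the pathway-enumeration oracle on small alignments", {
  set.seed(17)
  for (rep in 1:25) {
    L <- sample(3:10, 1)
    ca <- randomSenseCodons(L)
    cb <- mutateCodons(ca, sample(0:5, 1))
    got <- ng86Rates(ca, cb)
    want <- oracleNg86(ca, cb)
    expect_equal(got$S, want$S, tolerance = 1e-12)
    expect_equal(got$Sd, want$Sd, tolerance = 1e-12)
    expect_equal(got$Nd, want$Nd, tolerance = 1e-12)
    expect_equal(got$ks, want$ks, tolerance = 1e-12)
    expect_equal(got$ka, want$ka, tolerance = 1e-12)
    expect_equal(got$S + got$N, 3 * L)   # exact site conservation
  }
})

test_that("adding synonymous differences never decreases Ks", {
  # GCx codons: every third-position change is synonymous
  base <- rep("GCT", 100)
  prev <- 0
  for (k in 1:30) {
    mut <- base
    mut[seq_len(k)] <- "GCC"
    ks <- ng86Rates(base, mut)$ks
    expect_gte(ks, prev)
    prev <- ks
  }
})

test_that("NG86 flags saturation instead of returning numbers", {
  # force pS beyond 3/4 with a fully divergent synonymous-only pair
  a <- rep("GCT", 60)
  est <- ng86Rates(a, a)
  expect_equal(est$status, "ok")
  # an alignment with omega undefined at ks = 0
  expect_true(is.na(ng86Rates(a, a)$omega))
})

test_that("batch estimation bookkeeps drops and deduplicates", {
  empty <- batchRates(data.frame(geneA = character(0), geneB = character(0)),
                      character(0))
  expect_equal(nrow(empty), 0)

  cp <- simulateCodonPair(0.2, 0.04, nCodons = 150, seed = 8)
  tx <- c(p1a = cp$seqA, p1b = cp$seqB,
          junk = strrep("TTAA", 90))
  pairs <- data.frame(geneA = c("p1a", "p1a", "p1a"),
                      geneB = c("p1b", "p1b", "junk"),
                      kind = "paralog")
  rt <- batchRates(pairs, tx)
  expect_equal(nrow(rt), 2)            # duplicate collapsed
  expect_equal(sum(rt$status == "ok"), 1)
  expect_true("no_orf_b" %in% rt$status)
  expect_error(batchRates(data.frame(geneA = "a", geneB = "zz"), tx),
               "missing sequences")
})

test_that("estimator recovers simulated divergence at moderate Ks", {
  ests <- vapply(1:12, function(s) {
    cp <- simulateCodonPair(0.4, 0.08, nCodons = 500, seed = 100 + s)
    ng86Rates(cp$seqA, cp$seqB)$ks
  }, numeric(1))
  expect_lt(abs(mean(ests) - 0.4), 0.05)
})
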