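mkHits <- function(q, s, ident, len, bits, ev = 1e-50) {
  data.frame(queryId = q, subjectId = s, identity = ident,
             alignLength = as.integer(len), mismatches = 0L, gapOpens = 0L,
             queryStart = 1L, queryEnd = as.integer(len),
             subjectStart = 1L, subjectEnd = as.integer(len),
             evalue = ev, bitscore = bits)
}

test_that("tabular hit files parse with validation and line diagnostics", {
  f <- tempfile()
  writeLines(c("g1\tg2\t95.5\t300\t10\t0\t1\t300\t1\t300\t1e-100\t500",
               "g2\tg1\t95.5\t300\t10\t0\t1\t300\t1\t300\t1e-100\t500",
               "g1\tg3\t80.0\t200\t30\t2\t1\t200\t5\t204\t1e-50\t200"), f)
  h <- readTabularHits(f)
  expect_equal(nrow(h), 3)
  expect_equal(h$queryId[1], "g1")
  expect_equal(h$subjectEnd[3], 204L)

  writeLines(character(0), f)
  expect_equal(nrow(readTabularHits(f)), 0)

  writeLines("g1\tg2\t101.0\t300\t0\t0\t1\t300\t1\t300\t1e-10\t100", f)
  expect_error(readTabularHits(f), "identity")

  writeLines(c("g1\tg2\t90\t300\t0\t0\t1\t300\t1\t300\t1e-10\t100",
               "g1\tg2\tonly\tfive\tcols"), f)
  expect_error(readTabularHits(f), "line 2")
})

test_that("internal all-vs-all aligner applies both thresholds", {
  set.seed(42)
  s1 <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  seqs <- c(a = s1, b = s1)
  h <- allVsAllAlign(seqs)
  expect_true(nrow(h) >= 2)
  self <- h[h$queryId == "a" & h$subjectId == "b", ]
  expect_equal(self$identity, 100)
  expect_equal(self$alignLength, 300L)
  # unrelated random sequences at these lengths never clear 1e-6
  for (sd in 1:5) {
    set.seed(sd)
    r1 <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
    r2 <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
    expect_equal(nrow(allVsAllAlign(c(x = r1, y = r2))), 0)
  }
  expect_error(allVsAllAlign(c(a = "ACGT")), "at least 2")
})

test_that("best-match pairing follows ranking, exclusion and reciprocality", {
  sp <- c(a = "S1", b = "S1", c = "S1")
  hits <- mkHits(c("a", "b", "a", "c"), c("b", "a", "c", "a"),
                 c(90, 90, 80, 80), c(300, 300, 200, 200),
                 c(200, 200, 100, 100))
  p <- bestMatchPairs(hits, "within", sp)
  expect_equal(nrow(p), 1)
  expect_equal(c(p$geneA, p$geneB), c("a", "b"))

  # isoforms of one parent never pair
  spIso <- c(g1_i1 = "S1", g1_i2 = "S1")
  hitsIso <- mkHits(c("g1_i1", "g1_i2"), c("g1_i2", "g1_i1"),
                    95, 400, 300)
  expect_equal(nrow(bestMatchPairs(hitsIso, "within", spIso)), 0)

  # mutual best between species gives one ortholog pair
  sp2 <- c(x = "S1", y = "S2")
  h2 <- mkHits(c("x", "y"), c("y", "x"), 85, 250, 150)
  o <- bestMatchPairs(h2, "between", sp2)
  expect_equal(o$kind, "ortholog")
  expect_equal(nrow(o), 1)

  # self-hits are discarded even as sole input
  h3 <- rbind(mkHits("x", "x", 100, 500, 900), h2)
  expect_equal(nrow(bestMatchPairs(h3, "between", sp2)), 1)
  expect_error(bestMatchPairs(h2, "between", c(x = "S1")), "species map")
})

test_that("pairing is invariant to hit order and symmetric", {
  set.seed(7)
  genes <- paste0("g", 1:8)
  sp <- setNames(rep(c("S1", "S2"), each = 4), genes)
  idx <- t(combn(8, 2))
  hits <- do.call(rbind, lapply(seq_len(nrow(idx)), function(i) {
    b <- round(runif(1, 50, 300))
    l <- round(runif(1, 100, 400))
    rbind(mkHits(genes[idx[i, 1]], genes[idx[i, 2]], 80, l, b),
          mkHits(genes[idx[i, 2]], genes[idx[i, 1]], 80, l, b))
  }))
  p1 <- bestMatchPairs(hits, "between", sp)
  p2 <- bestMatchPairs(hits[sample(nrow(hits)), ], "between", sp)
  expect_identical(p1, p2)
  # symmetric tables give symmetric output: every pair's mirror exists
  expect_true(all(p1$geneA < p1$geneB))
})

test_that("pairing and filtering match the exhaustive oracle", {
  for (sd in 1:6) {
    set.seed(sd)
    n <- sample(6:20, 1)
    genes <- paste0("g", seq_len(n))
    sp <- setNames(sample(c("S1", "S2"), n, replace = TRUE), genes)
    m <- sample(10:40, 1)
    hits <- do.call(rbind, lapply(seq_len(m), function(i) {
      qs <- sample(genes, 2)
      mkHits(qs[1], qs[2], round(runif(1, 40, 100), 1),
             sample(80:400, 1), sample(50:500, 1))
    }))
    for (mode in c("within", "between")) {
      got <- bestMatchPairs(hits, mode, sp)
      want <- oracleBestPairs(hits, mode, sp)
      expect_identical(paste(got$geneA, got$geneB), want)
    }
  }
})

test_that("pair filtering uses closed thresholds and matches brute force", {
  pairs <- data.frame(kind = "paralog",
                      geneA = paste0("a", 1:10), geneB = paste0("b", 1:10),
                      speciesA = "S", speciesB = "S",
                      alignLength = c(150, 149, 300, 151, 100, 200, 150,
                                      400, 120, 180),
                      identity = c(60, 99, 59.9, 60.1, 80, 60, 100, 45,
                                   75, 61),
                      bitscore = 100)
  kept <- filterPairs(pairs)
  manual <- pairs[pairs$alignLength >= 150 & pairs$identity >= 60, ]
  expect_equal(nrow(kept), nrow(manual))
  expect_true(all(kept$geneA %in% manual$geneA))
  expect_true("a1" %in% kept$geneA)    # exactly 150 bp / 60.0%
  expect_false("a2" %in% kept$geneA)   # 149 bp
})
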