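#' Read similarity hits in 12-column tabular format
#'
#' Parses the standard tab-separated hit table (qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore;
#' coordinates 1-based inclusive).  Malformed lines are reported with
#' their line numbers.
#'
#' @param path path to the file; lines starting with '#' are skipped.
#' @return data.frame with columns queryId, subjectId, identity,
#'   alignLength, mismatches, gapOpens, queryStart, queryEnd,
#'   subjectStart, subjectEnd, evalue, bitscore.
#' @export
readTabularHits <- function(path) {
  cols <- c("queryId", "subjectId", "identity", "alignLength", "mismatches",
            "gapOpens", "queryStart", "queryEnd", "subjectStart",
            "subjectEnd", "evalue", "bitscore")
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineNo <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    out <- as.data.frame(setNames(rep(list(character(0)), 12), cols))
    for (nm in cols[-(1:2)]) out[[nm]] <- numeric(0)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 12L)
  if (length(bad))
    stop("malformed hit line(s) (expected 12 tab-separated columns): line ",
         paste(lineNo[bad], collapse = ", "))
  m <- do.call(rbind, fields)
  out <- data.frame(queryId = m[, 1], subjectId = m[, 2],
                    identity = as.numeric(m[, 3]),
                    alignLength = as.integer(m[, 4]),
                    mismatches = as.integer(m[, 5]),
                    gapOpens = as.integer(m[, 6]),
                    queryStart = as.integer(m[, 7]),
                    queryEnd = as.integer(m[, 8]),
                    subjectStart = as.integer(m[, 9]),
                    subjectEnd = as.integer(m[, 10]),
                    evalue = as.numeric(m[, 11]),
                    bitscore = as.numeric(m[, 12]))
  badNum <- which(apply(is.na(out[, 3:12]), 1, any))
  if (length(badNum))
    stop("non-numeric field(s) at line ", paste(lineNo[badNum], collapse = ", "))
  badId <- which(out$identity < 0 | out$identity > 100)
  if (length(badId))
    stop("identity outside [0,100] at line ", paste(lineNo[badId], collapse = ", "))
  badLen <- which(out$alignLength < 1 | out$evalue < 0)
  if (length(badLen))
    stop("invalid alignment length or e-value at line ",
         paste(lineNo[badLen], collapse = ", "))
  out
}

# Karlin-Altschul lambda for an ungapped match/mismatch score with
# uniform base frequencies: solve sum p_i p_j exp(lambda s_ij) = 1.
.kaLambda <- function(match, mismatch) {
  f <- function(l) (4 * exp(l * match) + 12 * exp(l * mismatch)) / 16 - 1
  stats::uniroot(f, c(1e-6, 10))$root
}

#' All-vs-all local alignment producing hit records
#'
#' Desk-scale substitute for an external all-by-all nucleotide search:
#' every unordered sequence pair is locally aligned (Smith-Waterman via
#' `Biostrings::pairwiseAlignment`) with simple match/mismatch scoring,
#' and hits passing the e-value and identity thresholds are emitted in
#' both orientations (like a symmetric search).  E-values use the
#' ungapped Karlin-Altschul approximation E = K m n exp(-lambda S) with
#' lambda solved for the scoring scheme and K = 0.1.
#'
#' @param seqs named character vector or `Biostrings::DNAStringSet`
#'   (>= 2 sequences).
#' @param minEvalue e-value cutoff (default 1e-6).
#' @param minIdentity percent identity cutoff (default 40).
#' @param match,mismatch,gapOpening,gapExtension alignment scoring.
#' @return data.frame in the layout of [readTabularHits()].
#' @export
allVsAllAlign <- function(seqs, minEvalue = 1e-6, minIdentity = 40,
                          match = 1, mismatch = -2,
                          gapOpening = 5, gapExtension = 2) {
  if (is(seqs, "DNAStringSet"))
    seqs <- setNames(as.character(seqs), names(seqs))
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("sequences must be named")
  lambda <- .kaLambda(match, mismatch)
  K <- 0.1
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch)
  ids <- names(seqs)
  rows <- list()
  for (i in seq_len(length(seqs) - 1L)) for (j in seq((i + 1L), length(seqs))) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(seqs[[i]]), Biostrings::DNAString(seqs[[j]]),
      type = "local", substitutionMatrix = mat,
      gapOpening = gapOpening, gapExtension = gapExtension)
    score <- Biostrings::score(pa)
    alnLen <- nchar(as.character(Biostrings::alignedPattern(pa)))
    if (alnLen < 1) next
    nmatch <- Biostrings::nmatch(pa)
    identity <- 100 * nmatch / alnLen
    bitscore <- (lambda * score - log(K)) / log(2)
    evalue <- K * nchar(seqs[[i]]) * nchar(seqs[[j]]) * exp(-lambda * score)
    if (evalue > minEvalue || identity < minIdentity) next
    qr <- as.integer(c(Biostrings::start(Biostrings::pattern(pa)),
                       Biostrings::end(Biostrings::pattern(pa))))
    sr <- as.integer(c(Biostrings::start(Biostrings::subject(pa)),
                       Biostrings::end(Biostrings::subject(pa))))
    mism <- as.integer(alnLen - nmatch)
    base <- data.frame(identity = identity, alignLength = alnLen,
                       mismatches = mism, gapOpens = 0L,
                       evalue = evalue, bitscore = bitscore)
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(queryId = ids[i], subjectId = ids[j]),
      base[, 1:4, drop = FALSE],
      data.frame(queryStart = qr[1], queryEnd = qr[2],
                 subjectStart = sr[1], subjectEnd = sr[2]),
      base[, 5:6, drop = FALSE])
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(queryId = ids[j], subjectId = ids[i]),
      base[, 1:4, drop = FALSE],
      data.frame(queryStart = sr[1], queryEnd = sr[2],
                 subjectStart = qr[1], subjectEnd = qr[2]),
      base[, 5:6, drop = FALSE])
  }
  if (!length(rows)) {
    out <- data.frame(queryId = character(0), subjectId = character(0),
                      identity = numeric(0), alignLength = integer(0),
                      mismatches = integer(0), gapOpens = integer(0),
                      queryStart = integer(0), queryEnd = integer(0),
                      subjectStart = integer(0), subjectEnd = integer(0),
                      evalue = numeric(0), bitscore = numeric(0))
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
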