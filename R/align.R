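#' Codon alignment of two coding regions
#'
#' Globally aligns the two translated proteins (Needleman-Wunsch, BLOSUM62,
#' affine gaps: open 10, extend 0.5), back-translates the alignment to
#' codons and removes every column containing a gap, so the result is a
#' strictly gap-free codon alignment.  Pairs retaining fewer than
#' \code{minCodons} ungapped codons are rejected.
#'
#' @param cdsA,cdsB coding nucleotide strings (length divisible by 3, no
#'   internal stops; a trailing stop codon is trimmed).
#' @param minCodons minimum ungapped codon columns (default 50).
#' @param gapOpening,gapExtension affine gap penalties for the protein
#'   alignment.
#' @return list with \code{codonsA}, \code{codonsB} (character vectors of
#'   aligned codons), \code{nCodons}, and \code{nGapColumns} removed; or
#'   \code{NULL} when fewer than \code{minCodons} columns survive.
#' @export
codonAlignPair <- function(cdsA, cdsB, minCodons = 50,
                           gapOpening = 10, gapExtension = 0.5) {
  .codonTable()
  trimStop <- function(x) {
    cod <- .splitCodons(x)
    if (length(cod) && .ng86$aa[[cod[length(cod)]]] == "*")
      cod <- cod[-length(cod)]
    if (any(.ng86$aa[cod] == "*")) stop("internal stop codon in CDS")
    cod
  }
  codA <- trimStop(cdsA)
  codB <- trimStop(cdsB)
  protA <- paste(.ng86$aa[codA], collapse = "")
  protB <- paste(.ng86$aa[codB], collapse = "")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(protA), Biostrings::AAString(protB),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = gapOpening, gapExtension = gapExtension
  )
  alnA <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  alnB <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  iA <- 0L; iB <- 0L
  keepA <- character(0); keepB <- character(0)
  for (i in seq_along(alnA)) {
    ga <- alnA[i] == "-"; gb <- alnB[i] == "-"
    if (!ga) iA <- iA + 1L
    if (!gb) iB <- iB + 1L
    if (!ga && !gb) {
      keepA <- c(keepA, codA[iA])
      keepB <- c(keepB, codB[iB])
    }
  }
  nGap <- length(alnA) - length(keepA)
  if (length(keepA) < minCodons) return(NULL)
  list(codonsA = keepA, codonsB = keepB,
       nCodons = length(keepA), nGapColumns = nGap)
}

#' Batch Ks/Ka estimation over homolog pairs
#'
#' For each pair: infer the CDS of both transcripts ([inferCds()]),
#' build a gap-free codon alignment ([codonAlignPair()]) and estimate
#' rates ([ng86Rates()]).  Pairs failing any stage are kept in the
#' output with a drop reason instead of estimates; duplicated unordered
#' pairs are collapsed first.  Deterministic given its inputs.
#'
#' @param pairs data.frame with columns \code{geneA}, \code{geneB} (and
#'   optionally \code{kind}, carried through).
#' @param transcripts named character vector (or `Biostrings::DNAStringSet`)
#'   of transcript sequences covering every gene id.
#' @param minOrf,requireAtg passed to [inferCds()].
#' @param minCodons passed to [codonAlignPair()].
#' @return data.frame: geneA, geneB, kind, nCodons, S, N, ks, ka, omega,
#'   status.  status is "ok", a saturation flag, or a drop reason
#'   ("no_orf_a", "no_orf_b", "short_alignment").
#' @export
batchRates <- function(pairs, transcripts, minOrf = 150, requireAtg = FALSE,
                       minCodons = 50) {
  if (!all(c("geneA", "geneB") %in% names(pairs)))
    stop("'pairs' needs columns geneA and geneB")
  if (is(transcripts, "DNAStringSet"))
    transcripts <- setNames(as.character(transcripts), names(transcripts))
  if (nrow(pairs) == 0L)
    return(data.frame(geneA = character(), geneB = character(),
                      kind = character(), nCodons = integer(),
                      S = numeric(), N = numeric(), ks = numeric(),
                      ka = numeric(), omega = numeric(), status = character()))
  key <- ifelse(pairs$geneA < pairs$geneB,
                paste(pairs$geneA, pairs$geneB),
                paste(pairs$geneB, pairs$geneA))
  pairs <- pairs[!duplicated(key), , drop = FALSE]
  kind <- if ("kind" %in% names(pairs)) pairs$kind else rep(NA_character_, nrow(pairs))
  missing <- setdiff(unique(c(pairs$geneA, pairs$geneB)), names(transcripts))
  if (length(missing))
    stop("missing sequences for: ", paste(head(missing, 5), collapse = ", "))
  cdsCache <- new.env(parent = emptyenv())
  getCds <- function(id) {
    if (!is.null(cdsCache[[id]])) return(cdsCache[[id]])
    val <- tryCatch(inferCds(transcripts[[id]], minOrf = minOrf,
                             requireAtg = requireAtg),
                    error = function(e) NULL)
    cdsCache[[id]] <- if (is.null(val)) list(cds = NULL) else val
    cdsCache[[id]]
  }
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    ga <- pairs$geneA[i]; gb <- pairs$geneB[i]
    empty <- function(status) data.frame(
      geneA = ga, geneB = gb, kind = kind[i], nCodons = NA_integer_,
      S = NA_real_, N = NA_real_, ks = NA_real_, ka = NA_real_,
      omega = NA_real_, status = status)
    ca <- getCds(ga)
    if (is.null(ca$cds)) { rows[[i]] <- empty("no_orf_a"); next }
    cb <- getCds(gb)
    if (is.null(cb$cds)) { rows[[i]] <- empty("no_orf_b"); next }
    aln <- codonAlignPair(ca$cds, cb$cds, minCodons = minCodons)
    if (is.null(aln)) { rows[[i]] <- empty("short_alignment"); next }
    est <- ng86Rates(aln$codonsA, aln$codonsB)
    rows[[i]] <- data.frame(
      geneA = ga, geneB = gb, kind = kind[i], nCodons = est$nCodons,
      S = est$S, N = est$N, ks = est$ks, ka = est$ka,
      omega = est$omega, status = est$status)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
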