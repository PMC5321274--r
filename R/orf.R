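#' Infer the coding region of a transcript
#'
#' Six-frame scan for the longest open reading frame: the longest
#' stop-free codon stretch across the three forward and three
#' reverse-complement frames.  With \code{requireAtg = TRUE} the ORF is
#' trimmed to start at its first ATG.  Transcripts whose best ORF falls
#' below \code{minOrf} nucleotides yield \code{NULL} (callers record the
#' drop reason); this replaces dedicated coding-region predictors for
#' assembled transcripts.
#'
#' @param transcript a nucleotide string or `Biostrings::DNAString`;
#'   must be at least 300 nt.
#' @param minOrf minimum ORF length in nt (default 150, i.e. 50 codons).
#' @param requireAtg logical; trim the ORF to its first ATG.
#' @return list with elements \code{cds} (string, length divisible by 3,
#'   no internal stop), \code{frame} (0..2), \code{strand} ("+"/"-"),
#'   or \code{NULL} when no ORF of \code{minOrf} nt exists.
#' @examples
#' tx <- paste0("ATG", strrep("GCT", 120), "TAA")
#' inferCds(tx)$frame
#' @export
inferCds <- function(transcript, minOrf = 150, requireAtg = FALSE) {
  .codonTable()
  s <- toupper(as.character(transcript))
  if (nchar(s) < 300) stop("transcript must be at least 300 nt")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  best <- NULL
  for (strand in c("+", "-")) {
    seqs <- if (strand == "+") s else rc
    for (frame in 0:2) {
      sub <- substr(seqs, frame + 1, nchar(seqs))
      ncod <- nchar(sub) %/% 3
      if (ncod < 1) next
      sub <- substr(sub, 1, ncod * 3)
      codons <- .splitCodons(sub)
      aas <- .ng86$aa[codons]
      aas[is.na(aas)] <- "X"   # ambiguous codons break an ORF run? keep them
      isStop <- aas == "*"
      # runs of non-stop codons
      r <- rle(isStop)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (j in seq_along(r$values)) {
        if (r$values[j]) next
        from <- starts[j]; to <- ends[j]
        if (requireAtg) {
          atg <- which(codons[from:to] == "ATG")
          if (!length(atg)) next
          from <- from + atg[1L] - 1L
        }
        len <- (to - from + 1L) * 3L
        if (len >= minOrf && (is.null(best) || len > best$len)) {
          best <- list(
            cds = paste(codons[from:to], collapse = ""),
            frame = frame, strand = strand, len = len
          )
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  best$len <- NULL
  best
}
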