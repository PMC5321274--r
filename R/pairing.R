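# Best-match homolog pairing.
#
# Ranking of a gene's candidate matches: highest bitscore, ties broken by
# longer alignment, then lexicographically smaller subject id.  Self-hits
# are always discarded; in paralog mode, hits between isoforms of the
# same parent gene are removed before ranking.

#' Derive the parent gene of a transcript id
#'
#' Assembled transcript ids usually encode gene/isoform structure
#' (e.g. \code{"TRINITY_DN123_c0_g1_i2"}: the parent is everything before
#' the isoform suffix).  The default pattern strips a trailing
#' \code{_i<digits>} or \code{.<digits>} suffix; pass another regex to
#' match other conventions.
#'
#' @param ids character vector of transcript ids.
#' @param pattern regex whose match is removed to obtain the parent id.
#' @return character vector of parent gene ids.
#' @export
parentGene <- function(ids, pattern = "(_i\\d+|\\.\\d+)$") {
  sub(pattern, "", ids)
}

.rankHits <- function(df) {
  # best first: bitscore desc, alignLength desc, subjectId asc
  df[order(-df$bitscore, -df$alignLength, df$subjectId), , drop = FALSE]
}

#' Best-match ortholog/paralog pairs from similarity hits
#'
#' For every gene, its best match among hits to other genes of the same
#' species (\code{mode = "within"}, paralogs) or of a different species
#' (\code{mode = "between"}, orthologs).  Same-parent-gene hits (isoform
#' redundancy) are excluded before ranking in paralog mode.  When a gene
#' pair is connected by several hits only the longest alignment is kept.
#' With \code{requireReciprocal = TRUE} (default) a pair is emitted only
#' when each gene is the other's best match; otherwise every gene's best
#' match yields a pair.  Output pairs are unordered and unique, sorted
#' by gene ids; pair order does not depend on input hit order.
#'
#' @param hits data.frame as returned by [readTabularHits()] or
#'   [allVsAllAlign()].
#' @param mode \code{"within"} or \code{"between"}.
#' @param speciesMap named character vector mapping gene id to species
#'   code; must cover every gene appearing in \code{hits}.
#' @param requireReciprocal logical (default TRUE).
#' @param parentPattern regex for [parentGene()].
#' @return data.frame: kind, geneA, geneB, speciesA, speciesB,
#'   alignLength, identity, bitscore (geneA < geneB).
#' @export
bestMatchPairs <- function(hits, mode = c("within", "between"), speciesMap,
                           requireReciprocal = TRUE,
                           parentPattern = "(_i\\d+|\\.\\d+)$") {
  mode <- match.arg(mode)
  if (nrow(hits) == 0L) stop("'hits' is empty")
  genes <- unique(c(hits$queryId, hits$subjectId))
  unknown <- setdiff(genes, names(speciesMap))
  if (length(unknown))
    stop("gene id(s) absent from species map: ",
         paste(head(unknown, 5), collapse = ", "))
  h <- hits
  h <- h[h$queryId != h$subjectId, , drop = FALSE]          # self-hits
  h$speciesQ <- unname(speciesMap[h$queryId])
  h$speciesS <- unname(speciesMap[h$subjectId])
  h <- if (mode == "within") {
    hh <- h[h$speciesQ == h$speciesS, , drop = FALSE]
    pg <- parentGene(hh$queryId, parentPattern)
    ps <- parentGene(hh$subjectId, parentPattern)
    hh[pg != ps, , drop = FALSE]                            # same-contig exclusion
  } else {
    h[h$speciesQ != h$speciesS, , drop = FALSE]
  }
  if (nrow(h) == 0L) return(.emptyPairs())
  # collapse multiple hits between the same two genes: keep longest alignment
  # (ties by bitscore then deterministic), applied to ordered (query,subject)
  ord <- order(h$queryId, h$subjectId, -h$alignLength, -h$bitscore)
  h <- h[ord, , drop = FALSE]
  h <- h[!duplicated(paste(h$queryId, h$subjectId)), , drop = FALSE]
  # best match per query
  h <- .rankHits(h)
  best <- h[!duplicated(h$queryId), , drop = FALSE]
  bestOf <- setNames(best$subjectId, best$queryId)
  if (requireReciprocal) {
    keep <- !is.na(bestOf[best$subjectId]) &
      bestOf[best$subjectId] == best$queryId
    best <- best[keep, , drop = FALSE]
  }
  if (nrow(best) == 0L) return(.emptyPairs())
  a <- pmin(best$queryId, best$subjectId)
  b <- pmax(best$queryId, best$subjectId)
  out <- data.frame(
    kind = if (mode == "within") "paralog" else "ortholog",
    geneA = a, geneB = b,
    speciesA = unname(speciesMap[a]), speciesB = unname(speciesMap[b]),
    alignLength = best$alignLength, identity = best$identity,
    bitscore = best$bitscore)
  out <- out[!duplicated(paste(out$geneA, out$geneB)), , drop = FALSE]
  out <- out[order(out$geneA, out$geneB), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.emptyPairs <- function() {
  data.frame(kind = character(0), geneA = character(0), geneB = character(0),
             speciesA = character(0), speciesB = character(0),
             alignLength = integer(0), identity = numeric(0),
             bitscore = numeric(0))
}

#' Filter homolog pairs on alignment length and identity
#'
#' Retains pairs with alignment length >= \code{minAlign} bp and percent
#' identity >= \code{minIdentity} (closed thresholds: a pair at exactly
#' 150 bp / 60 percent is kept).  The defaults guarantee a minimum of 50
#' codons for downstream rate estimation.
#'
#' @param pairs data.frame from [bestMatchPairs()].
#' @param minAlign minimum alignment length in bp (default 150).
#' @param minIdentity minimum percent identity (default 60).
#' @return the retained rows.
#' @export
filterPairs <- function(pairs, minAlign = 150, minIdentity = 60) {
  keep <- pairs$alignLength >= minAlign & pairs$identity >= minIdentity
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
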