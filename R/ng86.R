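# NG86 counting estimator of synonymous / nonsynonymous divergence.
#
# Site counting: for each codon, each of the 9 single-nucleotide changes
# is classified synonymous or not; changes creating a stop codon add
# nothing to the synonymous site count, and N is defined as 3L - S so
# that S + N = 3 * n_codons holds exactly.  Difference counting averages
# the synonymous/nonsynonymous step classification over all minimal
# mutational pathways between two codons, excluding pathways that pass
# through a stop codon.  Proportions are corrected for multiple hits by
# the Jukes-Cantor formula d = -(3/4) log(1 - (4/3) p).

.ng86 <- new.env(parent = emptyenv())

.codonTable <- function() {
  if (!is.null(.ng86$aa)) return(invisible(NULL))
  bases <- c("A", "C", "G", "T")
  codons <- as.character(outer(outer(bases, bases, paste0), bases, paste0))
  codons <- sort(codons)
  gc <- Biostrings::GENETIC_CODE
  .ng86$codons <- codons
  .ng86$aa <- unname(gc[codons])
  names(.ng86$aa) <- codons
  # synonymous site count per codon
  syn <- setNames(numeric(64), codons)
  for (cd in codons) {
    if (.ng86$aa[[cd]] == "*") { syn[[cd]] <- NA_real_; next }
    s <- 0
    sp <- strsplit(cd, "")[[1]]
    for (pos in 1:3) for (b in setdiff(bases, sp[pos])) {
      alt <- sp; alt[pos] <- b
      altc <- paste(alt, collapse = "")
      if (.ng86$aa[[altc]] == "*") next      # stop mutations: not synonymous
      if (.ng86$aa[[altc]] == .ng86$aa[[cd]]) s <- s + 1 / 3
    }
    syn[[cd]] <- s
  }
  .ng86$synSites <- syn
  invisible(NULL)
}

# average (syn, nonsyn) step counts over stop-free minimal pathways
.pathwayCounts <- function(codonA, codonB) {
  .codonTable()
  aa <- .ng86$aa
  sa <- strsplit(codonA, "")[[1]]
  sb <- strsplit(codonB, "")[[1]]
  diffPos <- which(sa != sb)
  d <- length(diffPos)
  if (d == 0L) return(c(sd = 0, nd = 0))
  perms <- if (d == 1L) list(diffPos) else {
    idx <- do.call(expand.grid, rep(list(seq_len(d)), d))
    idx <- idx[apply(idx, 1, function(r) length(unique(r)) == d), , drop = FALSE]
    lapply(seq_len(nrow(idx)), function(i) diffPos[as.integer(idx[i, ])])
  }
  paths <- list()
  for (ord in perms) {
    cur <- sa; steps <- c(0, 0); ok <- TRUE
    for (pos in ord) {
      prev <- paste(cur, collapse = "")
      cur[pos] <- sb[pos]
      nxt <- paste(cur, collapse = "")
      if (aa[[nxt]] == "*") { ok <- FALSE; break }
      if (aa[[nxt]] == aa[[prev]]) steps[1] <- steps[1] + 1
      else steps[2] <- steps[2] + 1
    }
    if (ok) paths[[length(paths) + 1L]] <- steps
  }
  if (!length(paths)) {
    # all pathways blocked by stops (possible only for contrived pairs):
    # fall back to averaging over all minimal pathways
    for (ord in perms) {
      cur <- sa; steps <- c(0, 0)
      for (pos in ord) {
        prev <- paste(cur, collapse = "")
        cur[pos] <- sb[pos]
        nxt <- paste(cur, collapse = "")
        same <- !is.na(aa[[nxt]]) && !is.na(aa[[prev]]) && aa[[nxt]] == aa[[prev]]
        if (same) steps[1] <- steps[1] + 1 else steps[2] <- steps[2] + 1
      }
      paths[[length(paths) + 1L]] <- steps
    }
  }
  m <- colMeans(do.call(rbind, paths))
  c(sd = m[[1]], nd = m[[2]])
}

.pairCountsCached <- function(codonA, codonB) {
  if (is.null(.ng86$pairCache)) .ng86$pairCache <- new.env(parent = emptyenv())
  key <- paste0(codonA, codonB)
  hit <- .ng86$pairCache[[key]]
  if (!is.null(hit)) return(hit)
  val <- .pathwayCounts(codonA, codonB)
  assign(key, val, envir = .ng86$pairCache)
  assign(paste0(codonB, codonA), val, envir = .ng86$pairCache)
  val
}

.splitCodons <- function(x) {
  x <- toupper(as.character(x))
  if (nchar(x) %% 3 != 0) stop("sequence length not a multiple of 3")
  substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
}

#' Translate a coding sequence with the standard code
#' @param cds nucleotide string, length a multiple of 3.
#' @return amino-acid string ('*' for stops).
#' @export
translateCds <- function(cds) {
  .codonTable()
  paste(.ng86$aa[.splitCodons(cds)], collapse = "")
}

#' NG86 pairwise substitution-rate estimates
#'
#' Counting estimator of Ks (synonymous substitutions per synonymous
#' site), Ka (nonsynonymous substitutions per nonsynonymous site) and
#' their ratio omega from a gap-free codon alignment.  Synonymous site
#' fractions per codon are averaged over the two sequences; observed
#' differences are classified by averaging over all minimal mutational
#' pathways between differing codons, excluding pathways through stop
#' codons; proportions are Jukes-Cantor corrected.
#'
#' When a corrected distance is undefined (proportion >= 3/4, i.e.
#' saturation) the estimate is \code{NA} and \code{status} flags it;
#' omega is \code{NA} when Ks = 0.
#'
#' @param codonsA,codonsB character vectors of aligned codons (equal
#'   length, no gaps), or two nucleotide strings of equal length
#'   divisible by 3.
#' @return one-row data.frame: nCodons, S, N, Sd, Nd, pS, pN, ks, ka,
#'   omega, status ("ok", "saturated_ks", "saturated_ka",
#'   "saturated_both").
#' @examples
#' a <- strrep("TTTGCT", 50)   # 100 codons
#' b <- sub("^TTT", "TTC", a)  # one synonymous difference
#' ng86Rates(a, b)
#' @export
ng86Rates <- function(codonsA, codonsB) {
  .codonTable()
  if (length(codonsA) == 1L && nchar(codonsA[[1]]) > 3) codonsA <- .splitCodons(codonsA)
  if (length(codonsB) == 1L && nchar(codonsB[[1]]) > 3) codonsB <- .splitCodons(codonsB)
  codonsA <- toupper(codonsA); codonsB <- toupper(codonsB)
  if (length(codonsA) != length(codonsB))
    stop("aligned codon vectors must have equal length")
  if (any(grepl("-", codonsA, fixed = TRUE)) || any(grepl("-", codonsB, fixed = TRUE)))
    stop("alignment contains gap characters; remove gap columns first")
  aa <- .ng86$aa
  if (any(aa[codonsA] == "*") || any(aa[codonsB] == "*"))
    stop("alignment contains stop codons")
  L <- length(codonsA)
  sA <- sum(.ng86$synSites[codonsA])
  sB <- sum(.ng86$synSites[codonsB])
  S <- (sA + sB) / 2
  N <- 3 * L - S
  Sd <- 0; Nd <- 0
  for (i in seq_len(L)) {
    if (codonsA[[i]] == codonsB[[i]]) next
    cnt <- .pairCountsCached(codonsA[[i]], codonsB[[i]])
    Sd <- Sd + cnt[["sd"]]; Nd <- Nd + cnt[["nd"]]
  }
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) if (p >= 3 / 4) NA_real_ else -3 / 4 * log(1 - 4 / 3 * p)
  ks <- jc(pS); ka <- jc(pN)
  status <- if (is.na(ks) && is.na(ka)) "saturated_both"
            else if (is.na(ks)) "saturated_ks"
            else if (is.na(ka)) "saturated_ka"
            else "ok"
  omega <- if (!is.na(ks) && !is.na(ka) && ks > 0) ka / ks else NA_real_
  data.frame(nCodons = L, S = S, N = N, Sd = Sd, Nd = Nd,
             pS = pS, pN = pN, ks = ks, ka = ka, omega = omega,
             status = status)
}
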