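#' Bin Ka/Ks of dated paralog pairs through time
#'
#' Summarizes omega (Ka/Ks) in half-open age bins \code{[0,w), [w,2w),
#' ...} tiling \code{window}; with the defaults, 5-myr bins over
#' [0, 200).  Pairs with undefined omega (Ks = 0 or saturated rates) or
#' ages outside the window are excluded and counted.  Both the mean and
#' the median omega per bin are reported.
#'
#' @param ages numeric ages in myr.
#' @param omega numeric Ka/Ks per pair (NA = undefined).
#' @param window two numbers, default \code{c(0, 200)}.
#' @param width bin width in myr, default 5.
#' @return list with \code{bins} (data.frame: start, end, nPairs,
#'   meanOmega, medianOmega, fracOmegaGt1 — statistics NA when
#'   nPairs = 0), \code{nExcludedOmega}, \code{nExcludedAge}.
#' @export
binOmega <- function(ages, omega, window = c(0, 200), width = 5) {
  if (length(ages) != length(omega)) stop("ages and omega lengths differ")
  bad <- !is.finite(omega)
  nExclOmega <- sum(bad)
  ages2 <- ages[!bad]; om <- omega[!bad]
  inWin <- ages2 >= window[1] & ages2 < window[2]
  nExclAge <- sum(!inWin)
  ages2 <- ages2[inWin]; om <- om[inWin]
  starts <- seq(window[1], window[2] - width, by = width)
  idx <- findInterval(ages2, c(starts, window[2]), rightmost.closed = FALSE)
  bins <- data.frame(start = starts, end = starts + width)
  stat <- function(f) vapply(seq_along(starts), function(b) {
    v <- om[idx == b]
    if (!length(v)) NA_real_ else f(v)
  }, numeric(1))
  bins$nPairs <- vapply(seq_along(starts), function(b) sum(idx == b), integer(1))
  bins$meanOmega <- stat(mean)
  bins$medianOmega <- stat(median)
  bins$fracOmegaGt1 <- stat(function(v) mean(v > 1))
  list(bins = bins, nExcludedOmega = nExclOmega, nExcludedAge = nExclAge)
}

#' Descriptive omega shift around a WGD age
#'
#' Compares mean omega in the \code{nBins} bins immediately younger than
#' (after, in clock time) \code{wgdAge} with the \code{nBins} bins
#' immediately older, and counts pairs with omega > 1 younger than
#' \code{referenceAge}.  Purely descriptive: no test statistic is
#' attached.
#'
#' @param binned result of [binOmega()] (or its \code{bins} element).
#' @param wgdAge WGD age in myr, inside the binning window.
#' @param nBins number of bins on each side (default 4, i.e. 20 myr).
#' @param referenceAge age below which omega > 1 pairs are counted
#'   (default \code{wgdAge}).
#' @return list: meanBefore (older side), meanAfter (younger side),
#'   shift (after - before, NA when a side is empty), nOmegaGt1Young.
#' @export
omegaShiftReport <- function(binned, wgdAge, nBins = 4, referenceAge = wgdAge) {
  bins <- if (is.data.frame(binned)) binned else binned$bins
  if (wgdAge < min(bins$start) || wgdAge > max(bins$end))
    stop("'wgdAge' outside the binned window")
  young <- bins[bins$end <= wgdAge, , drop = FALSE]      # after the WGD
  old <- bins[bins$start >= wgdAge, , drop = FALSE]      # before the WGD
  young <- utils::tail(young[order(young$start), , drop = FALSE], nBins)
  old <- utils::head(old[order(old$start), , drop = FALSE], nBins)
  wmean <- function(df) {
    df <- df[df$nPairs > 0, , drop = FALSE]
    if (!nrow(df)) return(NA_real_)
    sum(df$meanOmega * df$nPairs) / sum(df$nPairs)
  }
  meanAfter <- wmean(young)
  meanBefore <- wmean(old)
  yb <- bins[bins$end <= referenceAge & bins$nPairs > 0, , drop = FALSE]
  nGt1 <- if (nrow(yb)) sum(round(yb$fracOmegaGt1 * yb$nPairs)) else 0L
  list(meanBefore = meanBefore, meanAfter = meanAfter,
       shift = meanAfter - meanBefore, nOmegaGt1Young = as.integer(nGt1))
}
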