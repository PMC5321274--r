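#' @import methods
#' @importFrom stats density dnorm rnorm rexp runif rbinom rpois quantile
#'   sd optim kmeans setNames median var dbinom rgamma aggregate
#' @importFrom utils read.table write.table head combn
#' @importFrom tools md5sum
NULL

#' Per-species synonymous molecular clock
#'
#' Holds the calibration of a species' synonymous substitution clock
#' \eqn{C_{Ks}} against two dated outgroup nodes: the node uniting the
#' ingroup with the first outgroup (age \code{tA}) and the root node
#' (age \code{tD}).  The clock is the average of the two per-node rates,
#' \deqn{C_{Ks} = (Ks_A / 2T_A + Ks_D / 2T_D) / 2,}
#' in substitutions per synonymous site per million years.  \code{ksA}
#' and \code{ksD} are kernel-density peaks of ortholog Ks distributions
#' against each outgroup.
#'
#' @slot species single species code.
#' @slot ksA,ksD ortholog Ks peaks against outgroup 1 and the root
#'   outgroup (substitutions per synonymous site).
#' @slot tA,tD node ages in myr, \code{tD > tA > 0}.
#' @slot cKs the calibrated clock (substitutions/site/myr).
#'
#' @seealso [calibrateClock()], [ksToTime()], [maxKsForWindow()]
#' @exportClass ClockCalibration
setClass("ClockCalibration",
  representation(
    species = "character",
    ksA = "numeric", ksD = "numeric",
    tA = "numeric", tD = "numeric",
    cKs = "numeric"
  )
)

setValidity("ClockCalibration", function(object) {
  msg <- character()
  num1 <- function(x) length(x) == 1L && is.finite(x)
  if (length(object@species) != 1L) msg <- c(msg, "'species' must be a single code")
  for (sl in c("ksA", "ksD", "tA", "tD", "cKs")) {
    v <- slot(object, sl)
    if (!num1(v) || v <= 0) msg <- c(msg, sprintf("'%s' must be a single positive number", sl))
  }
  if (length(msg)) return(msg)
  if (object@tD <= object@tA) msg <- c(msg, "'tD' must exceed 'tA' (root older than ingroup+outgroup node)")
  expected <- (object@ksA / (2 * object@tA) + object@ksD / (2 * object@tD)) / 2
  if (abs(object@cKs - expected) > 1e-12 * max(1, expected))
    msg <- c(msg, "'cKs' does not equal the average of ksA/2tA and ksD/2tD")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ClockCalibration", function(object) {
  cat("ClockCalibration for", object@species, "\n")
  cat(sprintf("  Ks_A = %.4f at T_A = %.2f myr\n", object@ksA, object@tA))
  cat(sprintf("  Ks_D = %.4f at T_D = %.2f myr\n", object@ksD, object@tD))
  cat(sprintf("  C_Ks = %.3g substitutions/site/myr\n", object@cKs))
  cat(sprintf("  max Ks in 0-200 myr window: %.2f\n", 2 * object@cKs * 200))
  invisible(NULL)
})

#' Univariate Gaussian mixture fit for a Ks or age distribution
#'
#' Result of EM fitting of a k-component normal mixture to paralog Ks
#' values (scale \code{"ks"}) or absolute ages (scale \code{"myr"}).
#' Components are stored sorted by increasing mean.  \code{bicTable} is
#' filled by [selectModel()] with one row per candidate k.
#'
#' @slot k number of components.
#' @slot mean,sd,proportion numeric vectors of length \code{k}.
#' @slot logLik maximized log-likelihood.
#' @slot bic \eqn{-2\log L + p\log n} with \eqn{p = 3k - 1} free parameters.
#' @slot n sample size.
#' @slot scale \code{"ks"} or \code{"myr"}.
#' @slot converged logical.
#' @slot logLikTrace per-iteration log-likelihood of the winning EM run
#'   (monotone non-decreasing by construction).
#' @slot seed integer seed that produced the fit.
#' @slot bicTable data.frame (k, logLik, BIC, converged) or empty.
#'
#' @seealso [fitGmm()], [selectModel()], [retainComponents()]
#' @exportClass KsMixtureFit
setClass("KsMixtureFit",
  representation(
    k = "integer",
    mean = "numeric", sd = "numeric", proportion = "numeric",
    logLik = "numeric", bic = "numeric", n = "integer",
    scale = "character", converged = "logical",
    logLikTrace = "numeric", seed = "integer",
    bicTable = "data.frame"
  )
)

setValidity("KsMixtureFit", function(object) {
  msg <- character()
  k <- object@k
  if (length(object@mean) != k || length(object@sd) != k || length(object@proportion) != k)
    msg <- c(msg, "component vectors must have length k")
  if (any(object@sd <= 0)) msg <- c(msg, "component sds must be positive")
  if (any(object@proportion <= 0) || abs(sum(object@proportion) - 1) > 1e-9)
    msg <- c(msg, "proportions must be positive and sum to 1 (tol 1e-9)")
  if (!object@scale %in% c("ks", "myr")) msg <- c(msg, "scale must be 'ks' or 'myr'")
  p <- 3 * k - 1
  if (is.finite(object@logLik) &&
      abs(object@bic - (-2 * object@logLik + p * log(object@n))) > 1e-6)
    msg <- c(msg, "BIC inconsistent with logLik, k and n")
  if (length(msg)) msg else TRUE
})

setMethod("show", "KsMixtureFit", function(object) {
  cat(sprintf("KsMixtureFit: %d components on %s scale (n = %d)\n",
              object@k, object@scale, object@n))
  comp <- components(object)
  print(format(comp, digits = 4), row.names = FALSE)
  cat(sprintf("  logLik = %.3f  BIC = %.3f  converged: %s\n",
              object@logLik, object@bic, object@converged))
  invisible(NULL)
})

#' Scored WGD placement hypotheses
#'
#' Result of likelihood scoring of alternative WGD placements on a dated
#' species tree from gene-count data.  One row of \code{results} per
#' hypothesis: maximized log-likelihood, MLE birth/death rates, retention
#' rate(s) on the search grid, AIC and Akaike weight.
#'
#' @slot results data.frame with columns hypothesis, logLik, lambda, mu,
#'   q (comma-separated when multiple events), nEvents, nParams, AIC,
#'   weight, converged.
#' @slot best id of the minimum-AIC hypothesis.
#' @slot nFamilies number of gene families scored.
#'
#' @seealso [testHypotheses()]
#' @exportClass WGDPlacementFit
setClass("WGDPlacementFit",
  representation(
    results = "data.frame",
    best = "character",
    nFamilies = "integer"
  )
)

setValidity("WGDPlacementFit", function(object) {
  msg <- character()
  w <- object@results$weight
  if (length(w) && abs(sum(w) - 1) > 1e-6)
    msg <- c(msg, "Akaike weights must sum to 1")
  if (length(object@best) != 1L || !object@best %in% object@results$hypothesis)
    msg <- c(msg, "'best' must name one row of results")
  if (length(msg)) msg else TRUE
})

setMethod("show", "WGDPlacementFit", function(object) {
  cat(sprintf("WGDPlacementFit over %d hypotheses (%d families)\n",
              nrow(object@results), object@nFamilies))
  print(format(object@results, digits = 4), row.names = FALSE)
  cat("  best hypothesis:", object@best, "\n")
  invisible(NULL)
})
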