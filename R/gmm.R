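# Univariate Gaussian mixture EM with multi-start initialisation.
#
# Input values are sorted on entry so every downstream step (k-means
# seeding included) is invariant to input order.  Each EM iteration
# asserts that the log-likelihood did not decrease.

.emRun <- function(x, w, mu, sigma, tol, maxIter, varFloor) {
  n <- length(x)
  k <- length(mu)
  trace <- numeric(0)
  prev <- -Inf
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    # E-step in log space
    lp <- vapply(seq_len(k), function(j)
      log(w[j]) + dnorm(x, mu[j], sigma[j], log = TRUE), numeric(n))
    if (k == 1L) dim(lp) <- c(n, 1L)
    m <- lp[cbind(seq_len(n), max.col(lp, ties.method = "first"))]
    lse <- m + log(rowSums(exp(lp - m)))
    ll <- sum(lse)
    if (!is.finite(ll)) return(NULL)
    if (ll < prev - 1e-8 * max(1, abs(prev)))
      stop("EM log-likelihood decreased: numerical failure")
    trace <- c(trace, ll)
    if (is.finite(prev) && abs(ll - prev) < tol * max(1, abs(ll))) {
      converged <- TRUE
      break
    }
    prev <- ll
    r <- exp(lp - lse)                 # responsibilities, rows sum to 1
    nk <- colSums(r)
    if (any(nk < 1e-8)) return(NULL)   # degenerate start
    w <- nk / n
    mu <- colSums(r * x) / nk
    sigma <- sqrt(pmax(colSums(r * (x - rep(mu, each = n))^2) / nk, varFloor))
  }
  list(w = w / sum(w), mu = mu, sigma = sigma, logLik = trace[length(trace)],
       trace = trace, converged = converged)
}

.kmppCenters <- function(x, k) {
  centers <- numeric(k)
  centers[1] <- x[sample.int(length(x), 1L)]
  for (j in seq_len(k - 1L) + 1L) {
    d2 <- vapply(x, function(v) min((v - centers[seq_len(j - 1L)])^2), numeric(1))
    if (sum(d2) == 0) centers[j] <- x[sample.int(length(x), 1L)]
    else centers[j] <- x[sample.int(length(x), 1L, prob = d2)]
  }
  centers
}

.startParams <- function(x, k, type) {
  n <- length(x)
  sdx <- sd(x)
  if (type == "random") {
    g <- rgamma(k, 1)
    w <- g / sum(g)
    mu <- unname(quantile(x, runif(k)))
    sigma <- rep(sdx, k)
  } else if (k == 1L) {
    w <- 1; mu <- mean(x); sigma <- max(sdx, 1e-6)
  } else {
    centers <- unique(.kmppCenters(x, k))
    if (length(centers) < k)
      centers <- c(centers, unname(quantile(x, runif(k - length(centers)))))
    km <- suppressWarnings(kmeans(x, centers = matrix(centers, ncol = 1),
                                  iter.max = 50))
    w <- km$size / n
    mu <- as.numeric(km$centers)
    sigma <- vapply(seq_len(k), function(j) {
      xs <- x[km$cluster == j]
      if (length(xs) > 1) sd(xs) else sdx / k
    }, numeric(1))
    sigma[!is.finite(sigma) | sigma <= 0] <- sdx / k
    w[w == 0] <- 1e-6; w <- w / sum(w)
  }
  list(w = w, mu = mu, sigma = pmax(sigma, 1e-6))
}

#' Fit a k-component Gaussian mixture by multi-start EM
#'
#' Fits a univariate normal mixture by expectation-maximisation with
#' \code{nRandomStarts} random initialisations (Dirichlet weights, means
#' drawn from data quantiles, data-sd component scales) plus
#' \code{nKmeansStarts} k-means initialisations with k-means++ seeding.
#' Each start is run for \code{shortIter} iterations and the
#' \code{nPolish} most promising are iterated to convergence
#' (\code{|dlogL| < tol} relative, or \code{maxIter}); the best final
#' log-likelihood wins.  Component variances are floored at
#' \code{varFloor} to prevent singular solutions.  Input order does not
#' affect the result (values are sorted internally) and a fixed seed
#' reproduces the fit exactly.
#'
#' @param values numeric data (Ks or ages); \code{length >= 10 * k}.
#' @param k number of components.
#' @param seed integer seed.
#' @param nRandomStarts,nKmeansStarts numbers of EM starts (defaults 100
#'   and 100).
#' @param tol relative log-likelihood convergence tolerance.
#' @param maxIter maximum EM iterations per polished run.
#' @param varFloor variance floor (1e-6 on the Ks scale; use 1e-2 for
#'   ages in myr).
#' @param scale \code{"ks"} or \code{"myr"} (tags the result).
#' @param shortIter,nPolish multi-start schedule: iterations per
#'   screening run and number of runs polished to convergence.
#' @return a [KsMixtureFit-class].
#' @examples
#' set.seed(1)
#' x <- c(rnorm(300, 0.05, 0.02), rnorm(200, 0.45, 0.08))
#' fitGmm(abs(x), k = 2, seed = 7, nRandomStarts = 10, nKmeansStarts = 10)
#' @export
fitGmm <- function(values, k, seed = 1L, nRandomStarts = 100,
                   nKmeansStarts = 100, tol = 1e-8, maxIter = 1000,
                   varFloor = 1e-6, scale = c("ks", "myr"),
                   shortIter = 25, nPolish = 5) {
  scale <- match.arg(scale)
  x <- sort(as.numeric(values))
  n <- length(x)
  if (n < 10 * k) stop("need at least 10*k values to fit k components")
  set.seed(as.integer(seed))
  types <- c(rep("random", nRandomStarts), rep("kmeans", nKmeansStarts))
  runs <- vector("list", length(types))
  for (i in seq_along(types)) {
    st <- .startParams(x, k, types[i])
    runs[[i]] <- .emRun(x, st$w, st$mu, st$sigma, tol = tol,
                        maxIter = shortIter, varFloor = varFloor)
  }
  ok <- !vapply(runs, is.null, logical(1))
  if (!any(ok)) stop("all EM starts degenerate; cannot fit ", k, " components")
  runs <- runs[ok]
  lls <- vapply(runs, `[[`, numeric(1), "logLik")
  topIdx <- order(lls, decreasing = TRUE)[seq_len(min(nPolish, length(runs)))]
  best <- NULL
  for (i in topIdx) {
    r0 <- runs[[i]]
    r <- .emRun(x, r0$w, r0$mu, r0$sigma, tol = tol, maxIter = maxIter,
                varFloor = varFloor)
    if (is.null(r)) next
    r$trace <- c(r0$trace, r$trace)
    if (is.null(best) || r$logLik > best$logLik) best <- r
  }
  if (is.null(best)) stop("all polished EM runs degenerate")
  ord <- order(best$mu)
  p <- 3 * k - 1
  new("KsMixtureFit",
      k = as.integer(k),
      mean = best$mu[ord], sd = best$sigma[ord],
      proportion = best$w[ord] / sum(best$w),
      logLik = best$logLik,
      bic = -2 * best$logLik + p * log(n),
      n = as.integer(n), scale = scale, converged = best$converged,
      logLikTrace = best$trace, seed = as.integer(seed),
      bicTable = data.frame())
}

#' Select the number of mixture components by BIC
#'
#' Fits [fitGmm()] for each k in \code{kRange} and returns the
#' minimum-BIC fit; the per-k table (k, logLik, BIC, converged) is
#' attached and readable with [bicTable()].  Failed fits reduce the
#' candidate set with a warning.
#'
#' @param values numeric data.
#' @param kRange candidate component counts (default \code{2:5}; k = 1
#'   is permitted).
#' @param seed integer seed.
#' @param ... passed to [fitGmm()].
#' @return the selected [KsMixtureFit-class].
#' @export
selectModel <- function(values, kRange = 2:5, seed = 1L, ...) {
  fits <- list()
  rows <- list()
  for (k in kRange) {
    f <- tryCatch(fitGmm(values, k, seed = seed, ...),
                  error = function(e) e)
    if (inherits(f, "error")) {
      warning("k = ", k, " failed: ", conditionMessage(f))
      next
    }
    fits[[as.character(k)]] <- f
    rows[[as.character(k)]] <- data.frame(k = k, logLik = f@logLik,
                                          BIC = f@bic,
                                          converged = f@converged)
  }
  if (!length(fits)) stop("no component count could be fitted")
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  best <- fits[[which.min(tab$BIC)]]
  best@bicTable <- tab
  best
}

#' Retain mixture components above a proportion cutoff
#'
#' Applies the strictly-greater-than retention rule: only components
#' containing more than \code{minProportion} of the pairs are kept
#' (default > 20 percent).
#'
#' @param fit a [KsMixtureFit-class].
#' @param minProportion retention cutoff (default 0.20, strict).
#' @return data.frame of the retained components (mean, sd, proportion);
#'   empty with a warning when none qualifies.
#' @export
retainComponents <- function(fit, minProportion = 0.20) {
  comp <- components(fit)
  out <- comp[comp$proportion > minProportion, , drop = FALSE]
  if (nrow(out) == 0L)
    warning("no component exceeds the retention proportion of ", minProportion)
  rownames(out) <- NULL
  out
}

#' Convert Ks-scale mixture components to absolute ages
#'
#' Divides component means and standard deviations by \eqn{2 C_{Ks}}
#' and attaches descriptive labels from configurable age windows
#' (defaults: mean <= 25 myr "SSD-candidate"; 40-120 myr
#' "WGD-candidate"; otherwise "unclassified").  The labels are a
#' reporting convenience, not an inference.
#'
#' @param comp data.frame with mean, sd, proportion (Ks scale), or a
#'   [KsMixtureFit-class] on the ks scale.
#' @param clock a [ClockCalibration-class] or positive rate.
#' @param ssdMax upper age bound for the SSD label (myr); \code{NA}
#'   disables labelling.
#' @param wgdWindow two ages bounding the WGD label (myr).
#' @return data.frame: meanKs, sdKs, proportion, meanMyr, sdMyr, label.
#' @export
dateComponents <- function(comp, clock, ssdMax = 25, wgdWindow = c(40, 120)) {
  if (is(comp, "KsMixtureFit")) {
    if (comp@scale != "ks") stop("fit is already on the myr scale")
    comp <- components(comp)
  }
  rate <- if (is(clock, "ClockCalibration")) clockRate(clock) else clock
  meanMyr <- comp$mean / (2 * rate)
  sdMyr <- comp$sd / (2 * rate)
  label <- rep("unclassified", nrow(comp))
  if (!is.na(ssdMax)) {
    label[meanMyr <= ssdMax] <- "SSD-candidate"
    label[meanMyr >= wgdWindow[1] & meanMyr <= wgdWindow[2]] <- "WGD-candidate"
  }
  data.frame(meanKs = comp$mean, sdKs = comp$sd, proportion = comp$proportion,
             meanMyr = meanMyr, sdMyr = sdMyr, label = label)
}

#' Pooled multi-species mixture analysis on the age scale
#'
#' Pools per-species age samples (paralog ages in myr, already converted
#' with each species' own clock) into one dataset and fits the mixture
#' on the myr scale directly, with the variance floor appropriate to
#' that scale.
#'
#' @param ageSamples list of numeric vectors (one per species) or a
#'   single numeric vector.
#' @param kRange candidate component counts.
#' @param seed integer seed.
#' @param varFloor variance floor on the myr^2 scale (default 1e-2).
#' @param ... passed to [fitGmm()] via [selectModel()].
#' @return the selected [KsMixtureFit-class] with scale \code{"myr"}.
#' @export
pooledAnalysis <- function(ageSamples, kRange = 2:5, seed = 1L,
                           varFloor = 1e-2, ...) {
  ages <- if (is.list(ageSamples)) unlist(ageSamples, use.names = FALSE)
          else as.numeric(ageSamples)
  if (is.list(ageSamples) && length(ageSamples) < 1L)
    stop("no age samples supplied")
  selectModel(ages, kRange = kRange, seed = seed, scale = "myr",
              varFloor = varFloor, ...)
}
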