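# Linear birth-death transition probabilities for gene copy number.
#
# A single lineage evolving for time t under birth rate lambda and death
# rate mu leaves 0 descendants with probability alpha and n >= 1 with
# probability (1-alpha)(1-beta)beta^(n-1), where for lambda != mu
#   alpha = mu (E-1) / (lambda E - mu),  beta = lambda (E-1) / (lambda E - mu),
#   E = exp((lambda-mu) t),
# and alpha = beta = lambda t / (1 + lambda t) in the lambda = mu limit.
# i independent starting copies give the convolution over k surviving
# lineages.

.bdpAlphaBeta <- function(t, lambda, mu) {
  if (t == 0 || (lambda == 0 && mu == 0)) return(c(alpha = 0, beta = 0))
  if (abs(lambda - mu) < 1e-12) {
    a <- lambda * t / (1 + lambda * t)
    return(c(alpha = a, beta = a))
  }
  E <- exp((lambda - mu) * t)
  denom <- lambda * E - mu
  c(alpha = mu * (E - 1) / denom, beta = lambda * (E - 1) / denom)
}

#' Transition probability of a linear birth-death gene-count process
#'
#' Probability that \code{i} gene copies at the start of a branch leave
#' \code{j} copies after time \code{t} under per-copy birth rate
#' \code{lambda} and death rate \code{mu} (the composition of \code{i}
#' independent single-copy processes).  The \code{lambda = mu} case uses
#' its limit form.
#'
#' @param i starting copy number (>= 0; i = 0 is absorbing).
#' @param j ending copy number (vectorized).
#' @param t branch length (myr), >= 0.
#' @param lambda,mu per-copy birth and death rates (1/myr), >= 0.
#' @return numeric vector of probabilities, one per \code{j}.
#' @examples
#' bdpTransitionProb(1, 0:3, t = 10, lambda = 0.002, mu = 0.002)
#' @export
bdpTransitionProb <- function(i, j, t, lambda, mu) {
  if (i < 0 || t < 0 || lambda < 0 || mu < 0) stop("invalid arguments")
  if (i == 0) return(as.numeric(j == 0))
  ab <- .bdpAlphaBeta(t, lambda, mu)
  alpha <- ab[["alpha"]]; beta <- ab[["beta"]]
  pl <- function(e, base) if (e == 0) 0 else e * log(base)  # 0*log(0) = 0
  vapply(j, function(jj) {
    if (jj < 0) return(0)
    if (alpha == 0 && beta == 0) return(as.numeric(jj == i))
    tot <- if (jj == 0) alpha^i else 0
    kmax <- min(i, jj)
    if (kmax >= 1) for (k in seq_len(kmax)) {
      tot <- tot + exp(
        lchoose(i, k) + pl(i - k, alpha) + k * log1p(-alpha) +
        k * log1p(-beta) + pl(jj - k, beta) + lchoose(jj - 1, k - 1))
    }
    tot
  }, numeric(1))
}

# (maxN+1) x (maxN+1) transition matrix over states 0..maxN, computed
# as P[i, j>=1] = sum_k C(i,k) a^(i-k) * [(1-a)(1-b)]^k b^(j-k) C(j-1,k-1),
# a lower-triangular x upper-band matrix product over k = surviving
# founder lineages.
.bdpMatrix <- function(t, lambda, mu, maxN) {
  ab <- .bdpAlphaBeta(t, lambda, mu)
  alpha <- ab[["alpha"]]; beta <- ab[["beta"]]
  n1 <- maxN + 1L
  if (alpha == 0 && beta == 0) return(diag(n1))
  i <- seq_len(maxN); k <- seq_len(maxN); j <- seq_len(maxN)
  powLog <- function(e, base) ifelse(e == 0, 0, e * log(base))  # 0*log(0)=0
  A <- exp(outer(i, k, lchoose) + powLog(outer(i, k, `-`), alpha) +
             rep(k, each = maxN) * (log1p(-alpha) + log1p(-beta)))
  A[outer(i, k, `<`)] <- 0
  B <- exp(outer(k - 1, j - 1, function(kk, jj) lchoose(jj, kk)) +
             powLog(outer(k, j, function(kk, jj) jj - kk), beta))
  B[outer(k, j, `>`)] <- 0
  P <- matrix(0, n1, n1)
  P[1L, 1L] <- 1
  P[i + 1L, j + 1L] <- A %*% B
  P[i + 1L, 1L] <- alpha^i
  P
}

# WGD retention matrix: each of i copies independently gains a surviving
# duplicate with probability q; mass beyond maxN is truncated.
.wgdMatrix <- function(q, maxN) {
  W <- matrix(0, maxN + 1L, maxN + 1L)
  W[1L, 1L] <- 1
  for (i in seq_len(maxN)) {
    m <- 0:min(i, maxN - i)
    W[i + 1L, i + m + 1L] <- dbinom(m, i, q)
  }
  W
}
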