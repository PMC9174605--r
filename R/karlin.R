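# Karlin-Altschul statistics for ungapped lattice scoring systems, used to
# assign E-values to seed-and-extend hits so the published E <= 1E-6 filter
# can be honoured.

.karlin_cache <- new.env(parent = emptyenv())

#' Karlin-Altschul parameters for a match/mismatch scoring system
#'
#' Solves \eqn{\sum_{ij} p_i p_j e^{\lambda s_{ij}} = 1} for \eqn{\lambda}
#' by root finding and computes \eqn{K} by the lattice-case convolution
#' series
#' \deqn{K = \frac{d\,\lambda\,e^{-2\sigma}}{H\,(1 - e^{-\lambda d})},\quad
#'   \sigma = \sum_{k\ge1} \frac{1}{k}\left[E(e^{\lambda S_k}; S_k<0)
#'   + P(S_k \ge 0)\right]}
#' where \eqn{S_k} is a sum of k i.i.d. letter-pair scores, d the score
#' lattice span, and H the relative entropy. For the +1/-2 system with
#' uniform base composition this reproduces the published ungapped constants
#' (lambda 1.33, K 0.621).
#'
#' A scoring system whose expected score is non-negative has no valid
#' \eqn{\lambda} and is refused.
#'
#' @param reward match reward (> 0).
#' @param penalty mismatch penalty (< 0).
#' @param bg background base frequencies (length 4, summing to 1).
#' @param max_terms number of convolution terms in the sigma series.
#' @return List with `lambda`, `K`, `H`.
#' @export
karlinParams <- function(reward = 2L, penalty = -3L, bg = rep(0.25, 4),
                         max_terms = 80L) {
  key <- paste(reward, penalty, paste(signif(bg, 10), collapse = ","), sep = "|")
  if (!is.null(.karlin_cache[[key]])) return(.karlin_cache[[key]])
  stopifnot(reward > 0, penalty < 0, abs(sum(bg) - 1) < 1e-9)
  p_match <- sum(bg^2)
  scores <- c(reward, penalty)
  probs <- c(p_match, 1 - p_match)
  if (sum(probs * scores) >= 0)
    stop("scoring system has non-negative expected score; no valid Karlin-Altschul lambda")
  f <- function(l) sum(probs * exp(l * scores)) - 1
  lambda <- stats::uniroot(f, c(1e-9, 50), tol = 1e-14)$root
  H <- lambda * sum(probs * scores * exp(lambda * scores))
  gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
  d <- gcd2(abs(reward), abs(penalty))
  lo <- min(scores); hi <- max(scores)
  pvec <- numeric(hi - lo + 1L)
  pvec[scores - lo + 1L] <- probs
  curv <- 1; curlo <- 0L
  sigma <- 0
  for (k in seq_len(max_terms)) {
    newv <- numeric(length(curv) + length(pvec) - 1L)
    for (i in seq_along(curv))
      newv[i:(i + length(pvec) - 1L)] <- newv[i:(i + length(pvec) - 1L)] + curv[i] * pvec
    curv <- newv
    curlo <- curlo + lo
    vals <- curlo + seq_along(curv) - 1L
    neg <- vals < 0
    term <- sum(curv[neg] * exp(lambda * vals[neg])) + sum(curv[!neg])
    sigma <- sigma + term / k
    if (term / k < 1e-12) break
  }
  K <- d * lambda * exp(-2 * sigma) / (H * (1 - exp(-lambda * d)))
  out <- list(lambda = lambda, K = K, H = H)
  .karlin_cache[[key]] <- out
  out
}

#' E-value of an alignment score
#'
#' \eqn{E = K m n e^{-\lambda s}}: the expected number of chance alignments
#' scoring at least `score` between random sequences of lengths `m` and `n`.
#' Strictly decreasing in the score.
#'
#' @param score alignment score(s).
#' @param m,n sequence lengths of the compared molecules.
#' @param kp Karlin-Altschul parameters from [karlinParams()].
#' @return Numeric E-value(s).
#' @export
evalueOf <- function(score, m, n, kp = karlinParams()) {
  kp$K * as.numeric(m) * as.numeric(n) * exp(-kp$lambda * score)
}

#' Minimum score reaching an E-value cutoff
#'
#' @param max_evalue E-value threshold.
#' @param m,n sequence lengths.
#' @param kp Karlin-Altschul parameters.
#' @return Smallest integer score with `evalueOf(score, m, n, kp) <= max_evalue`.
#' @export
minScoreForEvalue <- function(max_evalue, m, n, kp = karlinParams()) {
  as.integer(ceiling(log(kp$K * as.numeric(m) * as.numeric(n) / max_evalue) / kp$lambda))
}
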