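# Pairwise shared-DNA quantification and divergence-time decay regression.

#' Shared DNA between two genomes
#'
#' Aligns the two genomes with the same seed-and-extend scanner used for
#' repeat discovery (cross-genome mode, both strands, E-value filter), then
#' measures directional coverage: the bp of genome 1 covered by the merged
#' query-side intervals ("S1 to S2") and the bp of genome 2 covered by the
#' merged subject-side intervals, each as a percentage of the respective
#' genome length. The mean percentage is the arithmetic mean of the two
#' directions. Swapping the arguments swaps the roles but leaves the numbers
#' unchanged.
#'
#' @param g1,g2 [GenomeSeq-class] objects.
#' @param params [scanParams()].
#' @param t_mya optional divergence time of the pair (million years),
#'   carried into the result for the decay regression.
#' @return One-row data.frame with columns `species1`, `species2`, `t_mya`,
#'   `shared_bp_1to2`, `shared_bp_2to1`, `pct_1`, `pct_2`, `pct_mean`.
#' @seealso [decayRegression()]
#' @export
sharedFraction <- function(g1, g2, params = scanParams(), t_mya = NA_real_) {
  stopifnot(is(g1, "GenomeSeq"), is(g2, "GenomeSeq"))
  L1 <- genomeLength(g1); L2 <- genomeLength(g2)
  kp <- karlinParams(params$reward, params$penalty)
  min_score <- minScoreForEvalue(params$max_evalue, L1, L2, kp)
  s1 <- as.character(genomeSeq(g1))
  s2 <- as.character(genomeSeq(g2))
  w <- params$word_size
  if (isCircular(g1)) s1 <- paste0(s1, substr(s1, 1L, w - 1L))
  if (isCircular(g2)) s2 <- paste0(s2, substr(s2, 1L, w - 1L))
  h <- .scan_both_strands(s1, s2, self = FALSE, params, min_score)
  if (nrow(h)) {
    h <- h[evalueOf(h$score, L1, L2, kp) <= params$max_evalue, , drop = FALSE]
  }
  cov1 <- if (nrow(h)) mergeIntervals(h$q_start, h$q_end, L1, isCircular(g1))$total_bp else 0L
  cov2 <- if (nrow(h)) mergeIntervals(h$s_start, h$s_end, L2, isCircular(g2))$total_bp else 0L
  pct1 <- 100 * cov1 / L1
  pct2 <- 100 * cov2 / L2
  data.frame(species1 = genomeId(g1), species2 = genomeId(g2),
             t_mya = t_mya, shared_bp_1to2 = cov1, shared_bp_2to1 = cov2,
             pct_1 = pct1, pct_2 = pct2, pct_mean = (pct1 + pct2) / 2,
             stringsAsFactors = FALSE)
}

#' Decay of shared DNA with divergence time
#'
#' Unweighted Pearson correlation and least-squares line between divergence
#' time (million years) and mean shared-DNA percentage over a set of genome
#' pairs. The p-value is the two-sided t-test on the correlation with n - 2
#' degrees of freedom, \eqn{t = r\sqrt{(n-2)/(1-r^2)}}.
#'
#' The signed correlation is reported; comparative summaries often quote the
#' magnitude of this (negative) correlation.
#'
#' @param results data.frame with columns `t_mya` and `pct_mean`, one row
#'   per genome pair (at least 3).
#' @return List of class `decayFit` with `n_pairs`, `pearson_r`, `p_value`,
#'   `slope`, `intercept`, and `degenerate` (TRUE when either variable has
#'   zero variance, in which case the fit is flagged and r is `NA`).
#' @export
decayRegression <- function(results) {
  need <- c("t_mya", "pct_mean")
  miss <- setdiff(need, names(results))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  ok <- stats::complete.cases(results[, need])
  x <- results$t_mya[ok]; y <- results$pct_mean[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs with divergence times for a fit")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    out <- list(n_pairs = n, pearson_r = NA_real_, p_value = NA_real_,
                slope = NA_real_, intercept = NA_real_, degenerate = TRUE)
    class(out) <- "decayFit"
    return(out)
  }
  r <- stats::cor(x, y)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  fit <- stats::lm.fit(cbind(1, x), y)
  out <- list(n_pairs = n, pearson_r = r, p_value = p,
              slope = unname(fit$coefficients[2]),
              intercept = unname(fit$coefficients[1]),
              degenerate = FALSE)
  class(out) <- "decayFit"
  out
}

#' @export
print.decayFit <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat(sprintf("Shared-DNA decay fit over %d pairs: degenerate (zero variance)\n",
                x$n_pairs))
  } else {
    cat(sprintf("Shared-DNA decay fit over %d pairs: r = %.3f (p = %.4f), %%shared = %.2f %+.4f * MY\n",
                x$n_pairs, x$pearson_r, x$p_value, x$intercept, x$slope))
  }
  invisible(x)
}
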