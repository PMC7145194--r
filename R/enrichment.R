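#' Permutation test for 5'-positional bias of heterochromatic introns
#'
#' The statistic is the mean ordinal of the heterochromatic intron set. The
#' null distribution is obtained by drawing size-matched subsets without
#' replacement from the full ordinal multiset. The default alternative is
#' lower-tail (5' bias = smaller mean ordinal); p-values carry the add-one
#' correction p = (1 + #{null <= observed}) / (n_perm + 1).
#'
#' @param het_ordinals ordinals of the heterochromatic introns.
#' @param all_ordinals ordinals of all introns (a superset).
#' @param n_perm number of permutations (default 1e6; reduce for quick
#'   exploratory runs).
#' @param seed RNG seed.
#' @param alternative \code{"less"} (default), \code{"greater"} or
#'   \code{"two.sided"}.
#' @return list with \code{observed}, \code{p_value}, \code{n_perm},
#'   \code{alternative}.
#' @export
positionalPermutationTest <- function(het_ordinals, all_ordinals,
                                      n_perm = 1e6, seed = 1L,
                                      alternative = c("less", "greater",
                                                      "two.sided")) {
  alternative <- match.arg(alternative)
  k <- length(het_ordinals)
  n <- length(all_ordinals)
  if (k > n) stop("heterochromatic set larger than full set")
  stopifnot(n_perm >= 1)
  obs <- mean(het_ordinals)
  set.seed(seed)
  null_means <- vapply(seq_len(n_perm),
                       function(i) mean(all_ordinals[sample.int(n, k)]), 0)
  p <- permPValue(obs, null_means, alternative)
  list(observed = obs, p_value = p, n_perm = as.integer(n_perm),
       alternative = alternative)
}

permPValue <- function(obs, null, alternative) {
  eps <- 1e-12 * (1 + abs(obs))
  lo <- (1 + sum(null <= obs + eps)) / (length(null) + 1)
  hi <- (1 + sum(null >= obs - eps)) / (length(null) + 1)
  switch(alternative,
         less = lo, greater = hi, two.sided = min(1, 2 * min(lo, hi)))
}

#' Fisher's exact enrichment test on a 2x2 table
#'
#' Exact two-sided p (sum of hypergeometric table probabilities not
#' exceeding the observed table's) together with the sample odds ratio
#' (a d)/(b c).
#'
#' @param a,b,c,d table cells: rows = in/out of the gene class, columns =
#'   with/without the property.
#' @return list with \code{odds_ratio} and \code{p_value}.
#' @export
fisherEnrichment <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  m <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    return(list(odds_ratio = NA_real_, p_value = 1))
  p <- fisher.test(m)$p.value
  or <- (a * d) / (b * c)
  list(odds_ratio = or, p_value = p)
}

#' One-step Tukey biweight location estimate
#'
#' The robust location used by the ROKU specificity measure: weights
#' \eqn{w_i = (1-u_i^2)^2} for \eqn{|u_i| \le 1} with
#' \eqn{u_i = (x_i - m)/(c\,S + \epsilon)}, \eqn{m} the median and \eqn{S}
#' the median absolute deviation (unscaled).
#'
#' @param x numeric vector.
#' @param c_const biweight tuning constant (default 5).
#' @param epsilon guard against zero spread (default 1e-4).
#' @return the one-step biweight location.
#' @export
tukeyBiweight <- function(x, c_const = 5, epsilon = 1e-4) {
  m <- stats::median(x)
  s <- stats::median(abs(x - m))
  u <- (x - m) / (c_const * s + epsilon)
  w <- ifelse(abs(u) <= 1, (1 - u^2)^2, 0)
  sum(w * x) / sum(w)
}

#' ROKU-style expression-specificity entropy (modified H)
#'
#' Deviations of the expression vector from its one-step Tukey biweight are
#' normalised to a probability vector and their Shannon entropy (log2) is
#' returned. Low values indicate condition-specific expression; a constant
#' vector (all deviations zero) returns the maximal value log2(n).
#'
#' @param x non-negative finite expression vector, length >= 2.
#' @param c_const,epsilon passed to [tukeyBiweight()].
#' @return modified entropy H' in [0, log2(n)].
#' @export
rokuEntropy <- function(x, c_const = 5, epsilon = 1e-4) {
  if (length(x) < 2L) stop("need at least 2 conditions")
  if (any(!is.finite(x)) || any(x < 0)) stop("x must be non-negative finite")
  w <- tukeyBiweight(x, c_const, epsilon)
  dev <- abs(x - w)
  tot <- sum(dev)
  if (tot == 0) return(log2(length(x)))
  p <- dev / tot
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Rank-sum effect size r
#'
#' r = |Z| / sqrt(n_a + n_b), with Z the tie-corrected normal approximation
#' of the Wilcoxon rank-sum statistic (no continuity correction).
#'
#' @param group_a,group_b numeric samples.
#' @return effect size r in [0, 1].
#' @export
wilcoxonEffectSize <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  stopifnot(na >= 1, nb >= 1)
  x <- c(group_a, group_b)
  r <- rank(x)
  W <- sum(r[seq_len(na)])
  mu <- na * (nb + na + 1) / 2
  N <- na + nb
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  v <- na * nb / 12 * ((N + 1) - tie_term)
  if (v <= 0) return(0)
  z <- (W - mu) / sqrt(v)
  abs(z) / sqrt(N)
}

#' Transcripts per million
#'
#' TPM_i = 1e6 (c_i / L_i) / sum_j (c_j / L_j).
#'
#' @param counts read counts per gene (vector or genes x samples matrix).
#' @param effective_lengths positive effective lengths per gene.
#' @return TPM values with the shape of \code{counts}; columns sum to 1e6
#'   whenever any count is positive.
#' @export
computeTpm <- function(counts, effective_lengths) {
  stopifnot(all(effective_lengths > 0))
  if (is.matrix(counts)) {
    dens <- counts / effective_lengths
    tot <- colSums(dens)
    tot[tot == 0] <- 1  # all-zero column stays all-zero
    sweep(dens, 2, tot, "/") * 1e6
  } else {
    dens <- counts / effective_lengths
    tot <- sum(dens)
    if (tot == 0) return(dens)
    dens / tot * 1e6
  }
}
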