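#' Logistic-regression test for changed downstream transcription
#'
#' For each intron, read counts upstream (pre) and downstream (post) of the
#' intron are modelled as binomial proportions post/(pre+post) with genotype
#' as the sole predictor; the p-value is the likelihood-ratio test of the
#' genotype term and q-values are Benjamini-Hochberg across all tested
#' introns. With a genotype-only logistic model the per-genotype aggregate
#' counts are sufficient, so the LRT is computed in closed form as the
#' G-statistic of the aggregated 2x2 table (identical to the glm() deviance
#' difference; asserted in the test suite). Introns whose total (pre+post)
#' count is below \code{min_total} in either genotype are skipped. When any
#' aggregate cell is zero (complete separation), 0.5 is added to all four
#' cells and the intron is flagged.
#'
#' @param pairs data.frame with columns \code{intron_id}, \code{sample_id},
#'   \code{genotype}, \code{pre_count}, \code{post_count}; exactly two
#'   genotype levels.
#' @param reference reference (control) genotype label; default the first
#'   level encountered.
#' @param q_threshold significance level on q (default 0.01).
#' @param min_total minimum per-genotype total count (default 10).
#' @return data.frame with \code{intron_id}, \code{coefficient} (log-odds
#'   change of the post fraction in the non-reference genotype),
#'   \code{p_value}, \code{q_value}, \code{significant}, \code{direction}
#'   ("down" = reduced post-intron transcription), \code{corrected}.
#' @export
prePostRatioGlmTest <- function(pairs, reference = NULL, q_threshold = 0.01,
                                min_total = 10L) {
  stopifnot(all(c("intron_id", "genotype", "pre_count", "post_count") %in%
                  colnames(pairs)))
  gts <- unique(as.character(pairs$genotype))
  if (length(gts) != 2L) stop("exactly two genotypes required")
  if (is.null(reference)) reference <- gts[1]
  other <- setdiff(gts, reference)
  ref <- pairs$genotype == reference
  agg <- function(x, sel) {
    pre <- tapply(x$pre_count[sel], x$intron_id[sel], sum)
    post <- tapply(x$post_count[sel], x$intron_id[sel], sum)
    list(pre = pre, post = post)
  }
  ids <- sort(unique(as.character(pairs$intron_id)))
  a1 <- agg(pairs, ref); a2 <- agg(pairs, !ref)
  P1 <- as.numeric(a1$pre[ids]); Q1 <- as.numeric(a1$post[ids])
  P2 <- as.numeric(a2$pre[ids]); Q2 <- as.numeric(a2$post[ids])
  P1[is.na(P1)] <- 0; Q1[is.na(Q1)] <- 0
  P2[is.na(P2)] <- 0; Q2[is.na(Q2)] <- 0
  tested <- (P1 + Q1) >= min_total & (P2 + Q2) >= min_total
  corrected <- tested & (P1 == 0 | Q1 == 0 | P2 == 0 | Q2 == 0)
  P1c <- P1 + 0.5 * corrected; Q1c <- Q1 + 0.5 * corrected
  P2c <- P2 + 0.5 * corrected; Q2c <- Q2 + 0.5 * corrected
  G <- gStatistic2x2(P1c, Q1c, P2c, Q2c)
  p <- pchisq(G, df = 1, lower.tail = FALSE)
  coef <- log(Q2c / P2c) - log(Q1c / P1c)
  p[!tested] <- NA_real_
  q <- rep(NA_real_, length(p))
  q[tested] <- p.adjust(p[tested], method = "BH")
  data.frame(intron_id = ids, coefficient = ifelse(tested, coef, NA_real_),
             p_value = p, q_value = q,
             significant = !is.na(q) & q <= q_threshold,
             direction = ifelse(!tested, NA_character_,
                                ifelse(coef < 0, "down", "up")),
             corrected = corrected, row.names = NULL)
}

gStatistic2x2 <- function(P1, Q1, P2, Q2) {
  tot <- P1 + Q1 + P2 + Q2
  cell <- function(o, rm, cm) {
    e <- rm * cm / tot
    term <- ifelse(o > 0, o * log(o / e), 0)
    term
  }
  r1 <- P1 + Q1; r2 <- P2 + Q2
  cp <- P1 + P2; cq <- Q1 + Q2
  2 * (cell(P1, r1, cp) + cell(Q1, r1, cq) +
       cell(P2, r2, cp) + cell(Q2, r2, cq))
}

#' Binomial test variant for single-replicate comparisons
#'
#' When a genotype has a single library, each intron's mutant post-intron
#' fraction post/(pre+post) is tested against the control library's observed
#' fraction by an exact two-sided binomial test, with Benjamini-Hochberg
#' correction across introns. Introns with zero control total are skipped.
#'
#' @param mutant,control data.frames with \code{intron_id},
#'   \code{pre_count}, \code{post_count} (one row per intron).
#' @param q_threshold significance level on q (default 0.01).
#' @param min_total minimum mutant total count (default 1).
#' @return data.frame as in [prePostRatioGlmTest()] (coefficient = log odds
#'   ratio of mutant vs control post fraction).
#' @export
prePostBinomialTest <- function(mutant, control, q_threshold = 0.01,
                                min_total = 1L) {
  m <- merge(mutant, control, by = "intron_id",
             suffixes = c("_mut", "_ctl"))
  tot_ctl <- m$pre_count_ctl + m$post_count_ctl
  tot_mut <- m$pre_count_mut + m$post_count_mut
  tested <- tot_ctl > 0 & tot_mut >= min_total
  p <- rep(NA_real_, nrow(m))
  p0 <- ifelse(tot_ctl > 0, m$post_count_ctl / tot_ctl, NA_real_)
  for (i in which(tested)) {
    p[i] <- binom.test(m$post_count_mut[i], tot_mut[i], p = p0[i])$p.value
  }
  q <- rep(NA_real_, length(p))
  q[tested] <- p.adjust(p[tested], method = "BH")
  coef <- log((m$post_count_mut + 0.5) / (m$pre_count_mut + 0.5)) -
    log((m$post_count_ctl + 0.5) / (m$pre_count_ctl + 0.5))
  data.frame(intron_id = m$intron_id, coefficient = coef, p_value = p,
             q_value = q, significant = !is.na(q) & q <= q_threshold,
             direction = ifelse(is.na(p), NA_character_,
                                ifelse(coef < 0, "down", "up")),
             row.names = NULL)
}

#' Roll intron-level calls up to genes and intersect comparisons
#'
#' A gene is differentially expressed (DEG) in a comparison when any of its
#' introns is significant. Returns the per-comparison DEG sets, their
#' intersection, pairwise Fisher overlap tests, and the Fisher enrichment of
#' heterochromatic-intron genes among intersected DEGs against the full gene
#' universe.
#'
#' @param result_sets named list of >= 2 result data.frames from
#'   [prePostRatioGlmTest()] / [prePostBinomialTest()].
#' @param gene_map data.frame with \code{intron_id}, \code{gene_id} covering
#'   the shared intron universe.
#' @param het_genes character vector of heterochromatic-gene ids.
#' @return list with \code{deg_sets}, \code{intersection},
#'   \code{overlap_tests} (per pair: odds ratio and p), and
#'   \code{het_enrichment}.
#' @export
callDegsAndIntersect <- function(result_sets, gene_map, het_genes) {
  stopifnot(length(result_sets) >= 2L, nrow(gene_map) > 0L)
  universe <- unique(gene_map$gene_id)
  deg_sets <- lapply(result_sets, function(res) {
    sig <- res$intron_id[res$significant]
    unique(gene_map$gene_id[gene_map$intron_id %in% sig])
  })
  inter <- Reduce(intersect, deg_sets)
  pairs <- utils::combn(length(deg_sets), 2, simplify = FALSE)
  overlap_tests <- lapply(pairs, function(ij) {
    A <- deg_sets[[ij[1]]]; B <- deg_sets[[ij[2]]]
    a <- length(intersect(A, B))
    b <- length(setdiff(A, B))
    cc <- length(setdiff(B, A))
    d <- length(universe) - a - b - cc
    c(list(sets = paste(names(deg_sets)[ij], collapse = " & ")),
      fisherEnrichment(a, b, cc, d))
  })
  a <- sum(inter %in% het_genes)
  b <- length(inter) - a
  cc <- sum(universe %in% het_genes) - a
  d <- length(universe) - a - b - cc
  list(deg_sets = deg_sets, intersection = inter,
       overlap_tests = overlap_tests,
       het_enrichment = fisherEnrichment(a, b, cc, d))
}

#' Relative 5'/3' read ratio
#'
#' (pre_mut/post_mut) / (pre_wt/post_wt): the fold change, relative to wild
#' type, of the ratio of reads mapped upstream vs downstream of an intron.
#'
#' @param pre_mut,post_mut,pre_wt,post_wt positive read counts.
#' @return the relative ratio (vectorised).
#' @export
relativeFiveThreeRatio <- function(pre_mut, post_mut, pre_wt, post_wt) {
  if (any(c(pre_mut, post_mut, pre_wt, post_wt) <= 0))
    stop("all four counts must be positive")
  (pre_mut / post_mut) / (pre_wt / post_wt)
}
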