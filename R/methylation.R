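#' Estimate the bisulfite conversion rate from control sites
#'
#' The conversion rate is the pooled fraction of reads read as T over an
#' unmethylated control sequence (in the study system, the chloroplast
#' genome): sum(n_unmeth) / sum(n_meth + n_unmeth).
#'
#' @param control_sites \linkS4class{CytosineSites} from the unmethylated
#'   control contig.
#' @return conversion rate in [0, 1].
#' @export
estimateConversionRate <- function(control_sites) {
  tot <- sum(control_sites$n_meth) + sum(control_sites$n_unmeth)
  if (tot == 0L) stop("no informative reads on control sites")
  sum(control_sites$n_unmeth) / tot
}

#' Filter cytosine sites by read coverage
#'
#' Removes sites covered by fewer than \code{min_cov} reads and sites with
#' unnaturally high coverage above \code{max_cov}; both bounds are
#' inclusive for retained sites (3 <= coverage <= 100 by default).
#'
#' @param sites \linkS4class{CytosineSites}.
#' @param min_cov,max_cov inclusive coverage bounds.
#' @return filtered \linkS4class{CytosineSites}.
#' @export
filterCoverage <- function(sites, min_cov = 3L, max_cov = 100L) {
  cov <- sites$n_meth + sites$n_unmeth
  sites[cov >= min_cov & cov <= max_cov]
}

#' Methylation level of sites
#'
#' #C/(#C+#T) per site; errors on zero coverage.
#'
#' @param sites \linkS4class{CytosineSites}.
#' @return numeric vector of levels in [0, 1].
#' @export
methylationLevel <- function(sites) {
  cov <- sites$n_meth + sites$n_unmeth
  if (any(cov == 0L)) stop("methylation level undefined at zero coverage")
  sites$n_meth / cov
}

#' Call methylcytosines by binomial test against non-conversion
#'
#' Per site, the p-value is the upper-tail binomial probability of observing
#' at least the seen number of methylated reads when every methylated read is
#' a bisulfite non-conversion failure (error rate 1 - conversion rate).
#' Benjamini-Hochberg q-values are computed within each sequence context and
#' a site is called methylated when q <= \code{fdr_threshold}.
#'
#' @param sites coverage-filtered \linkS4class{CytosineSites}.
#' @param conversion_rate bisulfite conversion rate in (0, 1].
#' @param fdr_threshold FDR level for the call (default 0.05).
#' @param adjust multiple-testing scheme (default \code{"BH"}; any
#'   [stats::p.adjust()] method, or \code{"none"}).
#' @return A \linkS4class{MethylationCalls}.
#' @export
callMethylcytosines <- function(sites, conversion_rate, fdr_threshold = 0.05,
                                adjust = "BH") {
  stopifnot(conversion_rate > 0, conversion_rate <= 1)
  err <- 1 - conversion_rate
  n <- sites$n_meth + sites$n_unmeth
  # P(X >= n_meth), with the n_meth = 0 convention p = 1
  p <- pbinom(sites$n_meth - 1L, n, err, lower.tail = FALSE)
  q <- rep(NA_real_, length(p))
  for (ctx in unique(sites$context)) {
    i <- sites$context == ctx
    q[i] <- p.adjust(p[i], method = adjust)
  }
  gr <- granges(sites)
  mcols(gr) <- DataFrame(context = sites$context, n_meth = sites$n_meth,
                         n_unmeth = sites$n_unmeth,
                         level = ifelse(n > 0, sites$n_meth / n, NA_real_),
                         p_value = p, q_value = q,
                         called = q <= fdr_threshold)
  new("MethylationCalls", gr)
}

#' Summarize methylation over regions
#'
#' Per region and per context, the unweighted mean of site-level methylation
#' over sites falling inside the region; a context mean is only reported when
#' the region has at least \code{min_sites} informative sites in that context
#' (NA otherwise).
#'
#' @param regions \code{GRanges} of regions (names or a \code{name}/
#'   \code{intron_id} column used as region id when present).
#' @param calls \linkS4class{MethylationCalls} (both strands pooled).
#' @param min_sites minimum informative sites per context (default 5).
#' @return data.frame with region id and, per context, \code{mean_<ctx>} and
#'   \code{n_<ctx>} columns.
#' @export
summarizeRegionMethylation <- function(regions, calls, min_sites = 5L) {
  ids <- regionIds(regions)
  hits <- findOverlaps(calls, regions, ignore.strand = TRUE)
  out <- data.frame(region_id = ids)
  for (ctx in VALID_CONTEXTS) {
    m <- rep(NA_real_, length(regions))
    cnt <- integer(length(regions))
    sel <- calls$context[queryHits(hits)] == ctx
    if (any(sel)) {
      ri <- subjectHits(hits)[sel]
      lv <- calls$level[queryHits(hits)[sel]]
      cnt_tab <- tapply(lv, ri, length)
      mean_tab <- tapply(lv, ri, mean)
      idx <- as.integer(names(cnt_tab))
      cnt[idx] <- as.integer(cnt_tab)
      m[idx] <- as.numeric(mean_tab)
    }
    m[cnt < min_sites] <- NA_real_
    out[[paste0("mean_", ctx)]] <- m
    out[[paste0("n_", ctx)]] <- cnt
  }
  out
}

regionIds <- function(regions) {
  if (!is.null(names(regions)) && !anyNA(names(regions))) return(names(regions))
  mc <- mcols(regions)
  for (col in c("intron_id", "name", "id"))
    if (col %in% colnames(mc)) return(as.character(mc[[col]]))
  paste0("region_", seq_along(regions))
}

#' Write methylation calls as TSV
#'
#' @param calls \linkS4class{MethylationCalls}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeMethylationCalls <- function(calls, path) {
  d <- data.frame(chrom = as.character(seqnames(calls)), pos = start(calls),
                  strand = as.character(strand(calls)),
                  context = calls$context, n_meth = calls$n_meth,
                  n_unmeth = calls$n_unmeth,
                  level = formatC(calls$level, digits = 6, format = "g"),
                  p_value = formatC(calls$p_value, digits = 6, format = "g"),
                  q_value = formatC(calls$q_value, digits = 6, format = "g"),
                  called = calls$called)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
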