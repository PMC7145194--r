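#' Call heterochromatic domains from CHG methylation calls
#'
#' A heterochromatic domain is a maximal run of consecutively *called*
#' methylated CHG sites (both strands pooled, genomic order) containing at
#' least \code{min_sites} sites with unweighted mean methylation level at
#' least \code{min_mean}. A CHG site that failed the methylcytosine call
#' breaks a run; cytosines in other contexts are invisible to the rule. The
#' domain interval spans the first through the last member site.
#'
#' @param chg_calls \linkS4class{MethylationCalls} restricted to CHG context
#'   (other contexts are dropped with a warning), sorted by position.
#' @param min_sites minimum run length (default 5).
#' @param min_mean minimum mean level (default 0.5).
#' @param require_call if FALSE, a site only needs level data (not a positive
#'   call) to extend a run; the default TRUE requires the binomial call.
#' @return A \linkS4class{HeterochromatinDomains}.
#' @export
findHeterochromaticDomains <- function(chg_calls, min_sites = 5L,
                                       min_mean = 0.5, require_call = TRUE) {
  if (any(chg_calls$context != "CHG")) {
    warning("dropping non-CHG sites")
    chg_calls <- chg_calls[chg_calls$context == "CHG"]
  }
  if (length(chg_calls) == 0L) return(emptyDomains())
  chr <- as.character(seqnames(chg_calls))
  pos <- start(chg_calls)
  o <- order(factor(chr, levels = unique(chr)), pos)
  if (!identical(o, seq_along(o))) stop("calls must be sorted by position")
  ok <- if (require_call) chg_calls$called else !is.na(chg_calls$level)
  ok[is.na(ok)] <- FALSE
  # run ids over called sites; a new chromosome or an uncalled site breaks
  newchr <- c(TRUE, chr[-1L] != chr[-length(chr)])
  run_break <- !ok | newchr | c(TRUE, !ok[-length(ok)])
  run_id <- cumsum(run_break)
  run_id[!ok] <- NA_integer_
  keep <- !is.na(run_id)
  if (!any(keep)) return(emptyDomains())
  rid <- run_id[keep]
  lv <- chg_calls$level[keep]
  n_sites <- tapply(lv, rid, length)
  mean_lv <- tapply(lv, rid, mean)
  first <- tapply(pos[keep], rid, min)
  last <- tapply(pos[keep], rid, max)
  chrom <- tapply(chr[keep], rid, function(x) x[[1]])
  sel <- n_sites >= min_sites & mean_lv >= min_mean
  gr <- GRanges(as.character(chrom[sel]),
                IRanges(as.integer(first[sel]), as.integer(last[sel])),
                seqinfo = seqinfo(chg_calls))
  mcols(gr)$n_sites <- as.integer(n_sites[sel])
  mcols(gr)$mean_mCHG <- as.numeric(mean_lv[sel])
  gr <- sort(gr, ignore.strand = TRUE)
  new("HeterochromatinDomains", gr)
}

emptyDomains <- function() {
  gr <- GRanges()
  mcols(gr) <- DataFrame(n_sites = integer(), mean_mCHG = numeric())
  new("HeterochromatinDomains", gr)
}

#' Flag heterochromatic introns and genes
#'
#' An intron is heterochromatic when at least one domain is fully contained
#' within its interval (the default; set \code{mode = "any"} for >= 1 bp
#' overlap). A gene is heterochromatic when any of its introns is.
#'
#' @param introns intron \code{GRanges} from [deriveIntrons()].
#' @param domains \linkS4class{HeterochromatinDomains}.
#' @param mode \code{"within"} (containment, default) or \code{"any"}.
#' @return \code{introns} with a logical \code{heterochromatic} column.
#' @export
classifyHeterochromaticIntrons <- function(introns, domains,
                                           mode = c("within", "any")) {
  mode <- match.arg(mode)
  type <- if (mode == "within") "within" else "any"
  hits <- findOverlaps(domains, introns, type = type, ignore.strand = TRUE)
  flag <- logical(length(introns))
  flag[unique(subjectHits(hits))] <- TRUE
  mcols(introns)$heterochromatic <- flag
  introns
}

#' Gene ids flagged as heterochromatic
#'
#' @param introns introns carrying the \code{heterochromatic} flag.
#' @return character vector of gene ids with >= 1 heterochromatic intron.
#' @export
heterochromaticGenes <- function(introns) {
  unique(introns$gene_id[introns$heterochromatic])
}

#' Distribution of intron ordinals
#'
#' Fractions per ordinal position (ordinals >= \code{max_bin} pooled into the
#' last bin) plus the mean of raw, unpooled ordinals.
#'
#' @param introns intron \code{GRanges} (or integer vector of ordinals).
#' @param max_bin pooling bin (default 10).
#' @return list with \code{fraction} (named numeric, sums to 1) and
#'   \code{mean_ordinal}.
#' @export
intronPositionDistribution <- function(introns, max_bin = 10L) {
  ords <- if (is.numeric(introns)) as.integer(introns) else introns$ordinal
  if (length(ords) == 0L) stop("mean ordinal undefined for empty input")
  pooled <- pmin(ords, max_bin)
  tab <- table(factor(pooled, levels = seq_len(max_bin)))
  labels <- c(as.character(seq_len(max_bin - 1L)), paste0(">=", max_bin))
  frac <- as.numeric(tab) / length(ords)
  names(frac) <- labels
  list(fraction = frac, mean_ordinal = mean(ords))
}

#' Write domains as BED6
#'
#' Score encodes the mean mCHG level scaled to 0-1000.
#'
#' @param domains \linkS4class{HeterochromatinDomains}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeDomainsBed <- function(domains, path) {
  gr <- granges(domains)
  mcols(gr)$name <- paste0("domain_", seq_along(gr))
  mcols(gr)$score <- round(domains$mean_mCHG * 1000)
  writeBedIntervals(gr, path)
}
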