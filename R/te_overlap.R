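#' Filter RepeatMasker-style repeat hits to putative TE segments
#'
#' Keeps TE-class hits (non-TE repeats such as simple repeats, rRNA and
#' satellites are excluded), then removes hits shorter than 100 bp, hits
#' covering less than 70% of the library repeat's length, and hits whose
#' divergence from the library repeat exceeds 20%.
#'
#' @param hits data.frame with columns \code{chrom}, \code{start},
#'   \code{end} (1-based closed), \code{strand}, \code{repeat_family},
#'   \code{library_length}, \code{divergence} (fraction), \code{is_te}.
#' @param min_length minimum hit length in bp (default 100).
#' @param min_coverage minimum hit length / library length (default 0.70).
#' @param max_divergence maximum divergence (default 0.20).
#' @return filtered data.frame.
#' @export
filterRepeatHits <- function(hits, min_length = 100L, min_coverage = 0.70,
                             max_divergence = 0.20) {
  stopifnot(all(hits$library_length > 0))
  len <- hits$end - hits$start + 1L
  keep <- hits$is_te &
    len >= min_length &
    len / hits$library_length >= min_coverage &
    hits$divergence <= max_divergence
  hits[keep, , drop = FALSE]
}

#' Read a RepeatMasker .out file
#'
#' Parses the standard fixed-layout \code{.out} (two header lines + one row
#' per hit) or a minimal TSV dialect with a header row carrying the
#' [filterRepeatHits()] column names.
#'
#' @param path file path.
#' @param non_te_classes repeat classes treated as non-TE (matched against
#'   the class/family field).
#' @return data.frame suitable for [filterRepeatHits()].
#' @export
readRepeatMaskerOut <- function(path,
    non_te_classes = c("Simple_repeat", "Low_complexity", "Satellite",
                       "rRNA", "snRNA", "tRNA", "ARTEFACT")) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) {
    d <- read.delim(path, header = TRUE, sep = "\t")
    return(d)
  }
  lines <- readLines(path)
  lines <- lines[-seq_len(min(3L, length(lines)))]  # banner + blank
  lines <- lines[nzchar(trimws(lines))]
  f <- strsplit(trimws(lines), "\\s+")
  d <- data.frame(
    divergence = vapply(f, function(x) as.numeric(x[2]), 0) / 100,
    chrom = vapply(f, function(x) x[5], ""),
    start = vapply(f, function(x) as.integer(x[6]), 0L),
    end = vapply(f, function(x) as.integer(x[7]), 0L),
    strand = ifelse(vapply(f, function(x) x[9], "") == "C", "-", "+"),
    repeat_name = vapply(f, function(x) x[10], ""),
    repeat_family = vapply(f, function(x) x[11], ""))
  # library length = consensus end + remaining (left) bases; for complement
  # hits the repeat columns are laid out (left) end begin
  f12 <- vapply(f, function(x) as.integer(gsub("[()]", "", x[12])), 0L)
  f13 <- vapply(f, function(x) as.integer(gsub("[()]", "", x[13])), 0L)
  f14 <- vapply(f, function(x) as.integer(gsub("[()]", "", x[14])), 0L)
  strand_c <- vapply(f, function(x) x[9], "") == "C"
  d$library_length <- f13 + ifelse(strand_c, f12, f14)
  d$is_te <- !(sub("/.*", "", d$repeat_family) %in% non_te_classes)
  d
}

#' Filter BLAST hits for exact full-length MITE instances
#'
#' Retains hits with e-value <= 1e-40, alignment length equal to the query
#' length, no mismatches and no gap openings.
#'
#' @param blast_hits data.frame in BLAST 12-column tabular layout (columns
#'   \code{qseqid, sseqid, pident, length, mismatch, gapopen, qstart, qend,
#'   sstart, send, evalue, bitscore}) plus a \code{qlen} query-length column.
#' @param max_evalue e-value cutoff (default 1e-40).
#' @return filtered data.frame.
#' @export
filterMiteHits <- function(blast_hits, max_evalue = 1e-40) {
  keep <- blast_hits$evalue <= max_evalue &
    blast_hits$length == blast_hits$qlen &
    blast_hits$mismatch == 0L &
    blast_hits$gapopen == 0L
  blast_hits[keep, , drop = FALSE]
}

#' Classify the genomic location of TEs
#'
#' Each TE receives exactly one class: \code{intergenic} (no gene overlap),
#' \code{other} (overlapping both gene and intergenic sequence),
#' \code{exon-intron} (within a gene, overlapping both exon and intron of
#' one transcript), \code{exon/intron} (fully inside an exon of one
#' transcript and fully inside an intron of another), \code{exon} or
#' \code{intron} (fully contained). "Included in" means full containment;
#' "overlapping" means >= 1 bp. When a TE qualifies as both exon-intron and
#' exon/intron across variants, exon-intron wins.
#'
#' @param tes \code{GRanges} of TE annotations.
#' @param exons exon \code{GRanges} with \code{gene_id}, \code{transcript_id}.
#' @return \code{tes} with \code{location_class} and \code{host_gene} (the
#'   overlapped gene id, NA for intergenic) metadata columns.
#' @export
classifyTeLocation <- function(tes, exons) {
  introns <- deriveIntrons(exons)
  tx_spans <- unlist(range(split(granges(exons), exons$transcript_id)))
  tx_gene <- tapply(exons$gene_id, exons$transcript_id,
                    function(x) x[[1]])[names(tx_spans)]
  gene_spans <- unlist(range(split(granges(exons), exons$gene_id)))

  ov_gene <- findOverlaps(tes, gene_spans, ignore.strand = TRUE)
  within_gene <- findOverlaps(tes, gene_spans, type = "within",
                              ignore.strand = TRUE)
  in_exon <- findOverlaps(tes, exons, type = "within", ignore.strand = TRUE)
  in_intron <- findOverlaps(tes, introns, type = "within",
                            ignore.strand = TRUE)
  ov_exon <- findOverlaps(tes, exons, ignore.strand = TRUE)
  ov_intron <- findOverlaps(tes, introns, ignore.strand = TRUE)

  cls <- rep("intergenic", length(tes))
  host <- rep(NA_character_, length(tes))
  genic <- unique(queryHits(ov_gene))
  host[genic] <- names(gene_spans)[subjectHits(ov_gene)[
    match(genic, queryHits(ov_gene))]]
  fully <- unique(queryHits(within_gene))
  cls[setdiff(genic, fully)] <- "other"

  # per transcript: does the TE overlap exon and intron of the same tx?
  exon_tx <- split(exons$transcript_id[subjectHits(ov_exon)],
                   queryHits(ov_exon))
  intron_tx <- split(introns$transcript_id[subjectHits(ov_intron)],
                     queryHits(ov_intron))
  in_exon_tx <- split(exons$transcript_id[subjectHits(in_exon)],
                      queryHits(in_exon))
  in_intron_tx <- split(introns$transcript_id[subjectHits(in_intron)],
                        queryHits(in_intron))
  for (i in fully) {
    key <- as.character(i)
    etx <- unique(exon_tx[[key]])
    itx <- unique(intron_tx[[key]])
    fe <- unique(in_exon_tx[[key]])
    fi <- unique(in_intron_tx[[key]])
    if (length(intersect(etx, itx))) {
      cls[i] <- "exon-intron"
    } else if (length(fe) && length(fi)) {
      cls[i] <- "exon/intron"
    } else if (length(fe)) {
      cls[i] <- "exon"
    } else if (length(fi)) {
      cls[i] <- "intron"
    } else {
      # inside the gene span but partly in flanking UTR-less gaps between
      # transcripts' spans; treat as other
      cls[i] <- "other"
    }
  }
  mcols(tes)$location_class <- cls
  mcols(tes)$host_gene <- host
  tes
}

#' Two-sided binomial test for TE orientation bias
#'
#' Exact two-sided binomial test of sense vs antisense insertion counts
#' (relative to the host gene's strand) at null proportion 0.5.
#'
#' @param n_sense,n_antisense insertion counts.
#' @return two-sided p-value.
#' @export
teOrientationBiasTest <- function(n_sense, n_antisense) {
  n <- n_sense + n_antisense
  if (n < 1L) stop("orientation test undefined with zero TEs")
  binom.test(n_sense, n, p = 0.5)$p.value
}

#' Classify TE methylation per context
#'
#' Applies the high/low thresholds (mCG 0.9, mCHG 0.2, mCHH 0.1) to region
#' methylation summaries; a context with fewer than \code{min_sites}
#' informative cytosines is \code{"excluded"}.
#'
#' @param summary data.frame from [summarizeRegionMethylation()].
#' @param thresholds named vector of per-context high/low cutoffs.
#' @param min_sites minimum informative Cs (default 5).
#' @return \code{summary} with added \code{class_CG/CHG/CHH} columns.
#' @export
classifyTeMethylation <- function(summary,
    thresholds = c(CG = 0.9, CHG = 0.2, CHH = 0.1), min_sites = 5L) {
  for (ctx in VALID_CONTEXTS) {
    m <- summary[[paste0("mean_", ctx)]]
    n <- summary[[paste0("n_", ctx)]]
    cls <- ifelse(n < min_sites | is.na(m), "excluded",
                  ifelse(m >= thresholds[[ctx]], "high", "low"))
    summary[[paste0("class_", ctx)]] <- cls
  }
  summary
}

#' Counts of the seven heterochromatin/TE/repeat intron overlap classes
#'
#' Tabulates introns over the three boolean flags (heterochromatic,
#' contains TE, contains other repeat), returning the seven non-empty
#' membership classes of the Venn diagram.
#'
#' @param introns intron \code{GRanges} (or data.frame) carrying logical
#'   columns \code{heterochromatic}, \code{contains_te},
#'   \code{contains_repeat}.
#' @return named integer vector over the 7 classes
#'   (\code{het}, \code{te}, \code{repeat}, \code{het+te}, \code{het+repeat},
#'   \code{te+repeat}, \code{het+te+repeat}).
#' @export
vennHetIntronTeRepeat <- function(introns) {
  d <- if (is(introns, "GRanges")) as.data.frame(mcols(introns)) else introns
  h <- d$heterochromatic; t <- d$contains_te; r <- d$contains_repeat
  c(`het` = sum(h & !t & !r),
    `te` = sum(!h & t & !r),
    `repeat` = sum(!h & !t & r),
    `het+te` = sum(h & t & !r),
    `het+repeat` = sum(h & !t & r),
    `te+repeat` = sum(!h & t & r),
    `het+te+repeat` = sum(h & t & r))
}

#' Flag introns containing TEs or repeats
#'
#' Containment (the TE/repeat fully inside the intron) by default, matching
#' the heterochromatic-intron rule; \code{mode = "any"} flags any overlap.
#'
#' @param introns intron \code{GRanges}.
#' @param tes,repeats \code{GRanges} of TE and other-repeat annotations.
#' @param mode \code{"within"} or \code{"any"}.
#' @return \code{introns} with logical \code{contains_te},
#'   \code{contains_repeat} columns.
#' @export
flagIntronTeRepeat <- function(introns, tes, repeats = GRanges(),
                               mode = c("within", "any")) {
  mode <- match.arg(mode)
  type <- if (mode == "within") "within" else "any"
  te_flag <- logical(length(introns))
  te_flag[unique(subjectHits(findOverlaps(tes, introns, type = type,
                                          ignore.strand = TRUE)))] <- TRUE
  rep_flag <- logical(length(introns))
  rep_flag[unique(subjectHits(findOverlaps(repeats, introns, type = type,
                                           ignore.strand = TRUE)))] <- TRUE
  mcols(introns)$contains_te <- te_flag
  mcols(introns)$contains_repeat <- rep_flag
  introns
}
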