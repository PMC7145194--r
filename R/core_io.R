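#' Read gene models from a GFF3 file
#'
#' Imports gene/mRNA/exon features and returns the package's working
#' representation of gene models: a \code{GRanges} of exons carrying
#' \code{gene_id} and \code{transcript_id} metadata columns. GFF3 1-based
#' closed coordinates are converted by \pkg{rtracklayer} at the boundary.
#'
#' @param path GFF3 file path.
#' @return Exon \code{GRanges} with \code{gene_id}, \code{transcript_id}.
#' @seealso [writeGeneModels()], [deriveIntrons()]
#' @export
readGeneModels <- function(path) {
  gff <- rtracklayer::import(path, format = "gff3")
  ex <- gff[gff$type == "exon"]
  mrna <- gff[gff$type == "mRNA"]
  tx2gene <- setNames(as.character(mrna$Parent), mrna$ID)
  tx <- as.character(unlist(ex$Parent))
  exons <- granges(ex)
  mcols(exons)$gene_id <- unname(tx2gene[tx])
  mcols(exons)$transcript_id <- tx
  validateGeneModels(exons)
  sortExonsByTranscript(exons)
}

#' Write gene models as GFF3
#'
#' Reconstructs gene and mRNA spans from the exon set and exports a
#' three-level GFF3 (gene/mRNA/exon).
#'
#' @param exons exon \code{GRanges} as returned by [readGeneModels()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeGeneModels <- function(exons, path) {
  validateGeneModels(exons)
  exons <- sortExonsByTranscript(exons)
  txs <- unlist(range(split(granges(exons), exons$transcript_id)))
  tx2gene <- tapply(exons$gene_id, exons$transcript_id,
                    function(x) x[[1]])[names(txs)]
  txstrand <- tapply(as.character(strand(exons)), exons$transcript_id,
                     function(x) x[[1]])[names(txs)]
  strand(txs) <- unname(txstrand)
  genes <- unlist(range(split(txs, unname(tx2gene))))
  gstrand <- tapply(as.character(strand(txs)), unname(tx2gene),
                    function(x) x[[1]])[names(genes)]
  strand(genes) <- unname(gstrand)

  gene_gr <- granges(genes)
  mcols(gene_gr)$type <- "gene"
  mcols(gene_gr)$ID <- names(genes)
  mcols(gene_gr)$Parent <- CharacterList(vector("list", length(genes)))
  mrna_gr <- granges(txs)
  mcols(mrna_gr)$type <- "mRNA"
  mcols(mrna_gr)$ID <- names(txs)
  mcols(mrna_gr)$Parent <- CharacterList(as.list(unname(tx2gene)))
  exon_gr <- granges(exons)
  mcols(exon_gr)$type <- "exon"
  mcols(exon_gr)$ID <- NA_character_
  mcols(exon_gr)$Parent <- CharacterList(as.list(exons$transcript_id))
  out <- c(gene_gr, mrna_gr, exon_gr)
  out <- out[order(as.factor(seqnames(out)), start(out),
                   match(out$type, c("gene", "mRNA", "exon")))]
  names(out) <- NULL
  rtracklayer::export(out, path, format = "gff3")
  invisible(path)
}

sortExonsByTranscript <- function(exons) {
  exons[order(exons$transcript_id, start(exons))]
}

validateGeneModels <- function(exons) {
  stopifnot(is(exons, "GRanges"),
            all(c("gene_id", "transcript_id") %in% colnames(mcols(exons))))
  if (any(width(exons) <= 0L)) stop("exon with non-positive width")
  o <- order(exons$transcript_id, start(exons))
  tx <- exons$transcript_id[o]
  st <- start(exons)[o]; en <- end(exons)[o]
  same <- tx[-1L] == tx[-length(tx)]
  if (length(tx) > 1L) {
    bad <- same & st[-1L] <= en[-length(en)]
    if (any(bad))
      stop("overlapping exons within transcript ",
           paste(unique(tx[-1L][bad]), collapse = ", "))
    chr <- as.character(seqnames(exons))[o]
    str <- as.character(strand(exons))[o]
    if (any(same & (chr[-1L] != chr[-length(chr)] |
                    str[-1L] != str[-length(str)])))
      stop("transcript with exons on multiple chromosomes or strands")
  }
  invisible(TRUE)
}

#' Derive introns with transcript-relative ordinals
#'
#' One intron per inter-exon gap per transcript; identical genomic intervals
#' appearing in several splice variants yield several records. Ordinals count
#' from the transcript's 5' end, so on the minus strand the genomically last
#' gap is ordinal 1.
#'
#' @param exons exon \code{GRanges} with \code{gene_id}, \code{transcript_id}.
#' @return Intron \code{GRanges} with \code{gene_id}, \code{transcript_id},
#'   \code{ordinal} and an \code{intron_id} of the form
#'   \code{gene:transcript:ordinal}.
#' @examples
#' ex <- GenomicRanges::GRanges("chr1",
#'   IRanges::IRanges(c(1, 201, 401), c(100, 300, 500)), strand = "-",
#'   gene_id = "g1", transcript_id = "t1")
#' deriveIntrons(ex)   # ordinal 1 is the 3'-most genomic gap
#' @export
deriveIntrons <- function(exons) {
  validateGeneModels(exons)
  exons <- sortExonsByTranscript(exons)
  tx <- exons$transcript_id
  n <- length(exons)
  if (n < 2L) return(emptyIntrons())
  same <- tx[-1L] == tx[-n]
  gap_start <- end(exons)[-n] + 1L
  gap_end <- start(exons)[-1L] - 1L
  keep <- same & gap_end >= gap_start
  if (!any(keep)) return(emptyIntrons())
  idx <- which(keep)
  introns <- GRanges(seqnames(exons)[idx],
                     IRanges(gap_start[idx], gap_end[idx]),
                     strand = strand(exons)[idx],
                     seqinfo = seqinfo(exons))
  mcols(introns)$gene_id <- exons$gene_id[idx]
  mcols(introns)$transcript_id <- tx[idx]
  # genomic rank within transcript, then reverse on minus strand
  rank_genomic <- stats::ave(seq_along(idx), tx[idx], FUN = seq_along)
  n_per_tx <- stats::ave(seq_along(idx), tx[idx], FUN = length)
  minus <- as.character(strand(introns)) == "-"
  ord <- ifelse(minus, n_per_tx - rank_genomic + 1L, rank_genomic)
  mcols(introns)$ordinal <- as.integer(ord)
  mcols(introns)$intron_id <- paste(introns$gene_id, introns$transcript_id,
                                    introns$ordinal, sep = ":")
  introns
}

emptyIntrons <- function() {
  gr <- GRanges()
  mcols(gr) <- DataFrame(gene_id = character(), transcript_id = character(),
                         ordinal = integer(), intron_id = character())
  gr
}

#' Count feature starts in fixed-width genomic bins
#'
#' Each feature is counted once, in the bin containing its start coordinate;
#' bins tile each chromosome so counts sum to the number of features.
#'
#' @param features \code{GRanges} of features.
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param bin_size bin width in bp (> 0).
#' @return \code{GRanges} of tiling bins with a \code{count} column.
#' @export
densityInBins <- function(features, chrom_lengths, bin_size) {
  stopifnot(bin_size > 0)
  chrom_lengths <- chrom_lengths[!is.na(chrom_lengths)]
  chr <- as.character(seqnames(features))
  if (!all(chr %in% names(chrom_lengths)))
    stop("feature on chromosome absent from chrom_lengths")
  if (any(end(features) > chrom_lengths[chr] | start(features) < 1L))
    stop("feature coordinates out of chromosome range")
  bins <- unlist(GRangesList(lapply(names(chrom_lengths), function(cn) {
    len <- chrom_lengths[[cn]]
    starts <- seq(1L, len, by = bin_size)
    GRanges(cn, IRanges(starts, pmin(starts + bin_size - 1L, len)))
  })))
  bin_idx <- floor((start(features) - 1L) / bin_size)
  key <- paste(chr, bin_idx)
  bkey <- paste(as.character(seqnames(bins)),
                floor((start(bins) - 1L) / bin_size))
  counts <- table(factor(key, levels = bkey))
  mcols(bins)$count <- as.integer(counts)
  bins
}

#' Read a per-cytosine methylation report
#'
#' Tab-separated, six columns: chrom, 1-based position, strand, context
#' (CG/CHG/CHH), methylated count, unmethylated count. A header line is
#' detected automatically (non-numeric second field).
#'
#' @param path report file path.
#' @return A \linkS4class{CytosineSites}.
#' @export
readCytosineReport <- function(path) {
  first <- strsplit(readLines(path, n = 1L), "\t")[[1]]
  has_header <- length(first) >= 2L && is.na(suppressWarnings(
    as.numeric(first[2])))
  d <- read.delim(path, header = has_header, sep = "\t",
                  col.names = c("chrom", "pos", "strand", "context",
                                "n_meth", "n_unmeth"),
                  colClasses = c("character", "integer", "character",
                                 "character", "integer", "integer"))
  CytosineSites(d$chrom, d$pos, d$strand, d$context, d$n_meth, d$n_unmeth)
}

#' Write a per-cytosine methylation report
#'
#' @param sites a \linkS4class{CytosineSites}.
#' @param path output path.
#' @param header write a header line (default TRUE).
#' @return \code{path}, invisibly.
#' @export
writeCytosineReport <- function(sites, path, header = TRUE) {
  d <- data.frame(chrom = as.character(seqnames(sites)),
                  pos = start(sites),
                  strand = as.character(strand(sites)),
                  context = sites$context,
                  n_meth = sites$n_meth, n_unmeth = sites$n_unmeth)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = header)
  invisible(path)
}

#' Read/write BED6 interval files
#'
#' Thin wrappers over \pkg{rtracklayer}; BED's 0-based half-open coordinates
#' are converted to the in-memory 1-based \code{GRanges} convention at the
#' boundary.
#'
#' @param path BED file path.
#' @return [readBedIntervals()]: a \code{GRanges} (with \code{name}/
#'   \code{score} columns when present).
#' @export
readBedIntervals <- function(path) {
  rtracklayer::import(path, format = "bed")
}

#' @rdname readBedIntervals
#' @param gr \code{GRanges} to write; \code{name} and \code{score} metadata
#'   columns are used when present.
#' @export
writeBedIntervals <- function(gr, path) {
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a TSV table with a header row
#'
#' Used for pre/post-intron count tables and gene-by-condition expression
#' matrices.
#'
#' @param path TSV path.
#' @param rownames_col optional column name to move into row names (for
#'   expression matrices).
#' @return data.frame (or numeric matrix when \code{rownames_col} is given).
#' @export
readTsvTable <- function(path, rownames_col = NULL) {
  d <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  if (!is.null(rownames_col)) {
    rn <- d[[rownames_col]]
    d <- as.matrix(d[setdiff(colnames(d), rownames_col)])
    rownames(d) <- rn
  }
  d
}

#' @rdname readTsvTable
#' @param x data.frame or matrix to write.
#' @export
writeTsvTable <- function(x, path) {
  if (is.matrix(x))
    x <- data.frame(id = rownames(x), x, check.names = FALSE)
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
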