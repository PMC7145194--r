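#' @import methods
#' @import BiocGenerics
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels seqnames
#'   seqinfo Seqinfo
#' @importFrom stats pbinom pchisq p.adjust rbeta rbinom rgamma rlnorm
#'   rnbinom rnorm rpois runif binom.test fisher.test setNames
#' @importFrom utils read.delim write.table
NULL

VALID_CONTEXTS <- c("CG", "CHG", "CHH")

#' Per-cytosine bisulfite counts
#'
#' A \linkS4class{GRanges}-derived container holding one range per cytosine
#' site (width 1) with metadata columns \code{context} (one of CG, CHG, CHH),
#' \code{n_meth} and \code{n_unmeth} (non-negative read counts).
#'
#' @slot .  Inherits all GRanges slots.
#' @seealso [CytosineSites()], [readCytosineReport()]
#' @export
setClass("CytosineSites", contains = "GRanges")

setValidity("CytosineSites", function(object) {
  mc <- mcols(object)
  need <- c("context", "n_meth", "n_unmeth")
  miss <- setdiff(need, colnames(mc))
  if (length(miss))
    return(paste("missing metadata column(s):", paste(miss, collapse = ", ")))
  if (length(object)) {
    if (!all(mc$context %in% VALID_CONTEXTS))
      return("context must be one of CG, CHG, CHH")
    if (any(mc$n_meth < 0) || any(mc$n_unmeth < 0))
      return("read counts must be non-negative")
    if (any(width(object) != 1L))
      return("cytosine sites must have width 1")
  }
  TRUE
})

#' Construct a CytosineSites object
#'
#' @param chrom character vector of chromosome names.
#' @param pos 1-based cytosine positions.
#' @param strand strand characters ("+"/"-").
#' @param context methylation context, one of \code{"CG"}, \code{"CHG"},
#'   \code{"CHH"}.
#' @param n_meth,n_unmeth integer read counts supporting the methylated
#'   (read as C) and unmethylated (read as T) state.
#' @param seqlengths optional named vector of chromosome lengths.
#' @return A \linkS4class{CytosineSites} object sorted by position.
#' @examples
#' CytosineSites("chr1", c(10, 25), c("+", "-"), c("CHG", "CG"), c(5, 0), c(1, 9))
#' @export
CytosineSites <- function(chrom, pos, strand, context, n_meth, n_unmeth,
                          seqlengths = NULL) {
  gr <- GRanges(chrom, IRanges(as.integer(pos), width = 1L), strand = strand,
                context = as.character(context),
                n_meth = as.integer(n_meth), n_unmeth = as.integer(n_unmeth))
  if (!is.null(seqlengths))
    seqlengths(gr) <- seqlengths[seqlevels(gr)]
  gr <- sort(gr, ignore.strand = TRUE)
  new("CytosineSites", gr)
}

#' Per-site methylcytosine calls
#'
#' GRanges-derived container produced by [callMethylcytosines()]. Carries, in
#' addition to the \linkS4class{CytosineSites} columns, \code{level}
#' (methylation level #C/(#C+#T)), \code{p_value}, \code{q_value}
#' (Benjamini-Hochberg within context) and the logical \code{called}.
#'
#' @export
setClass("MethylationCalls", contains = "GRanges")

setValidity("MethylationCalls", function(object) {
  mc <- mcols(object)
  need <- c("context", "n_meth", "n_unmeth", "level", "p_value", "q_value",
            "called")
  miss <- setdiff(need, colnames(mc))
  if (length(miss))
    return(paste("missing metadata column(s):", paste(miss, collapse = ", ")))
  if (length(object)) {
    if (any(mc$level < 0 | mc$level > 1, na.rm = TRUE))
      return("level must lie in [0, 1]")
    if (any(mc$p_value < 0 | mc$p_value > 1, na.rm = TRUE))
      return("p_value must lie in [0, 1]")
  }
  TRUE
})

#' Heterochromatic CHG-methylation domains
#'
#' GRanges-derived container produced by [findHeterochromaticDomains()]: one
#' range per maximal run of consecutively called methylated CHG sites that
#' satisfies the domain rule (>= 5 sites, mean level >= 0.5). Metadata
#' columns: \code{n_sites}, \code{mean_mCHG}.
#'
#' @export
setClass("HeterochromatinDomains", contains = "GRanges")

setValidity("HeterochromatinDomains", function(object) {
  mc <- mcols(object)
  need <- c("n_sites", "mean_mCHG")
  miss <- setdiff(need, colnames(mc))
  if (length(miss))
    return(paste("missing metadata column(s):", paste(miss, collapse = ", ")))
  if (length(object)) {
    if (any(mc$n_sites < 5L))
      return("domains must contain >= 5 sites")
    if (any(mc$mean_mCHG < 0.5))
      return("domain mean mCHG must be >= 0.5")
  }
  TRUE
})

#' A pairwise ortholog alignment
#'
#' Holds the aligned coding sequences of one gene in two species (gaps
#' allowed; no internal stop codons after gap removal), optionally an aligned
#' intron pair with a per-column repeat mask, and optionally a per-column
#' exon/intron annotation-state matrix used for structure-conservation
#' screening.
#'
#' @slot geneId single gene identifier.
#' @slot coding \code{DNAStringSet} of length 2 (equal widths) with the
#'   aligned coding sequences.
#' @slot introns list of \code{DNAStringSet}s of length 2, one per aligned
#'   intron.
#' @slot masks list of logical vectors (TRUE = repeat-masked column),
#'   parallel to \code{introns}.
#' @slot states character matrix with 2 rows ("E"/"I" per column per
#'   species) or a 0-column matrix when unused.
#' @export
setClass("OrthologPair",
  representation(geneId = "character", coding = "DNAStringSet",
                 introns = "list", masks = "list", states = "matrix"),
  prototype(introns = list(), masks = list(),
            states = matrix(character(), nrow = 2)))

setValidity("OrthologPair", function(object) {
  if (length(object@geneId) != 1L) return("geneId must be a single string")
  if (length(object@coding) != 2L) return("coding must hold exactly 2 rows")
  w <- Biostrings::width(object@coding)
  if (w[1] != w[2]) return("aligned coding rows must have equal width")
  for (s in as.character(object@coding)) {
    bare <- gsub("-", "", s)
    if (nchar(bare) %% 3L != 0L)
      return("ungapped coding length must be divisible by 3")
    if (nchar(bare) >= 3L) {
      aa <- as.character(Biostrings::translate(
        Biostrings::DNAString(bare), if.fuzzy.codon = "X"))
      if (grepl("\\*", substr(aa, 1L, nchar(aa) - 1L)))
        return("internal stop codon in coding sequence")
    }
  }
  if (length(object@masks) != length(object@introns))
    return("introns and masks must be parallel lists")
  for (i in seq_along(object@introns)) {
    iw <- Biostrings::width(object@introns[[i]])
    if (length(iw) != 2L || iw[1] != iw[2])
      return("each intron alignment must hold 2 equal-width rows")
    if (length(object@masks[[i]]) != iw[1])
      return("mask length must equal intron alignment width")
  }
  TRUE
})

#' @rdname OrthologPair-class
#' @param geneId,coding,introns,masks,states see slot documentation.
#' @return An \linkS4class{OrthologPair}.
#' @export
OrthologPair <- function(geneId, coding, introns = list(), masks = list(),
                         states = matrix(character(), nrow = 2)) {
  if (is.character(coding)) coding <- Biostrings::DNAStringSet(coding)
  new("OrthologPair", geneId = as.character(geneId), coding = coding,
      introns = introns, masks = masks, states = states)
}

setMethod("show", "OrthologPair", function(object) {
  cat("OrthologPair", object@geneId, "| aligned coding width",
      Biostrings::width(object@coding)[1], "|", length(object@introns),
      "intron alignment(s)\n")
})

#' @rdname OrthologPair-class
#' @param x an OrthologPair.
#' @export
codingAlignment <- function(x) x@coding

#' @rdname OrthologPair-class
#' @export
intronAlignments <- function(x) x@introns

#' @rdname OrthologPair-class
#' @export
repeatMasks <- function(x) x@masks

#' Ground truth of a simulated dataset
#'
#' Generators record here which introns were made heterochromatic, which
#' genes carry a premature-termination effect (and its fold), the true
#' per-gene dN/dS and per-intron substitution rates, and the true
#' expression-specificity class, so downstream recovery can be measured by
#' joining on identifiers.
#'
#' @slot hetIntronIds character ids (\code{gene:transcript:ordinal}) of
#'   heterochromatic introns.
#' @slot hetRegions GRanges of the simulated heterochromatic intervals.
#' @slot terminationEffects data.frame with \code{gene_id}, \code{fold}.
#' @slot dndsTruth data.frame with \code{gene_id}, \code{dnds}, \code{ks},
#'   \code{intron_rate}.
#' @slot specificityTruth data.frame with \code{gene_id}, \code{class}.
#' @export
setClass("SimulationTruth",
  representation(hetIntronIds = "character", hetRegions = "GRanges",
                 terminationEffects = "data.frame", dndsTruth = "data.frame",
                 specificityTruth = "data.frame"),
  prototype(hetIntronIds = character(), hetRegions = GRanges(),
            terminationEffects = data.frame(gene_id = character(),
                                            fold = numeric()),
            dndsTruth = data.frame(), specificityTruth = data.frame()))

setMethod("show", "SimulationTruth", function(object) {
  cat("SimulationTruth:", length(object@hetIntronIds),
      "heterochromatic introns,", nrow(object@terminationEffects),
      "termination effects,", nrow(object@dndsTruth), "dN/dS truths,",
      nrow(object@specificityTruth), "specificity truths\n")
})

#' @rdname SimulationTruth-class
#' @param x a SimulationTruth.
#' @export
hetIntronIds <- function(x) x@hetIntronIds

#' @rdname SimulationTruth-class
#' @export
terminationEffects <- function(x) x@terminationEffects
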