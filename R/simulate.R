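#' Simulate a gene/TE annotation with known heterochromatin truth
#'
#' Lays out single-transcript gene models along two chromosomes. A fraction
#' \code{te_density} of genes receives a transposable element inside one of
#' its introns; the hosting intron is chosen with 5'-biased probability
#' (geometric weights over ordinals), the insertion intron is drawn long
#' enough to hold the TE with a flanking margin, and the TE interval is
#' recorded as the gene's heterochromatic region in the returned truth.
#' A fraction \code{repeat_density} of genes additionally carries a short
#' non-TE repeat in a random intron, and intergenic TEs are scattered
#' between genes. All output is a pure function of the arguments and seed.
#'
#' @param n_genes number of genes (>= 1).
#' @param introns_per_gene_range integer range of intron counts per gene.
#' @param te_density fraction of genes with an intronic TE.
#' @param seed RNG seed.
#' @param repeat_density fraction of genes with a non-TE intronic repeat.
#' @param intergenic_te_fraction intergenic TE count as a fraction of
#'   \code{n_genes}.
#' @param exon_length_range,intron_length_range base exon/intron lengths.
#' @param te_length_range intronic TE lengths.
#' @param te_margin minimum distance between TE and intron boundary (bp).
#' @param gene_gap intergenic gap (bp).
#' @return list with \code{exons} (gene-model GRanges), \code{tes},
#'   \code{repeats} (GRanges), \code{chrom_lengths} (named vector including
#'   the unmethylated \code{control_chloroplast} contig) and \code{truth}
#'   (\linkS4class{SimulationTruth}).
#' @export
simulateAnnotation <- function(n_genes, introns_per_gene_range = c(2L, 6L),
                               te_density = 0.3, seed = 1L,
                               repeat_density = 0.15,
                               intergenic_te_fraction = 0.5,
                               exon_length_range = c(150L, 300L),
                               intron_length_range = c(100L, 400L),
                               te_length_range = c(400L, 600L),
                               te_margin = 100L, gene_gap = 500L) {
  stopifnot(n_genes >= 1)
  if (te_margin < 0L || te_length_range[1] > te_length_range[2] ||
      te_length_range[2] + 2L * te_margin > 2000L)
    stop("impossible geometry: intron shorter than TE")
  set.seed(seed)
  n_chrom <- if (n_genes >= 10L) 2L else 1L
  chrom_of <- rep(paste0("chr", seq_len(n_chrom)), length.out = n_genes)
  chrom_of <- sort(chrom_of)
  cursor <- setNames(rep(1L, n_chrom), paste0("chr", seq_len(n_chrom)))

  exon_l <- list(); te_l <- list(); rep_l <- list()
  het_ids <- character(); het_regions <- list()
  has_te_gene <- runif(n_genes) < te_density
  has_rep_gene <- runif(n_genes) < repeat_density

  for (g in seq_len(n_genes)) {
    gid <- sprintf("g%05d", g)
    tid <- sprintf("t%05d", g)
    chrom <- chrom_of[g]
    strand <- sample(c("+", "-"), 1L)
    n_int <- if (introns_per_gene_range[2] > introns_per_gene_range[1])
      sample(seq(introns_per_gene_range[1], introns_per_gene_range[2]), 1L)
      else as.integer(introns_per_gene_range[1])
    n_ex <- n_int + 1L
    ex_len <- sample(seq(exon_length_range[1], exon_length_range[2]), n_ex,
                     replace = TRUE)
    int_len <- if (n_int > 0L)
      sample(seq(intron_length_range[1], intron_length_range[2]), n_int,
             replace = TRUE) else integer()
    te_ordinal <- NA_integer_
    te_len_g <- NA_integer_
    if (has_te_gene[g] && n_int > 0L) {
      # 5'-biased intron choice: geometric weights over transcript ordinals
      w <- 0.5 ^ (seq_len(n_int) - 1L)
      te_ordinal <- sample.int(n_int, 1L, prob = w)
      te_len_g <- sample(seq(te_length_range[1], te_length_range[2]), 1L)
      host_len <- te_len_g + 2L * te_margin + sample(0:200, 1L)
      # ordinal counts from the 5' end; genomic index depends on strand
      gidx <- if (strand == "+") te_ordinal else n_int - te_ordinal + 1L
      int_len[gidx] <- host_len
    }
    gstart <- cursor[[chrom]]
    starts <- integer(n_ex); ends <- integer(n_ex)
    pos <- gstart
    for (e in seq_len(n_ex)) {
      starts[e] <- pos
      ends[e] <- pos + ex_len[e] - 1L
      pos <- ends[e] + 1L + if (e <= n_int) int_len[e] else 0L
    }
    cursor[[chrom]] <- ends[n_ex] + gene_gap
    exon_l[[g]] <- data.frame(chrom = chrom, start = starts, end = ends,
                              strand = strand, gene_id = gid,
                              transcript_id = tid)
    if (!is.na(te_ordinal)) {
      gidx <- if (strand == "+") te_ordinal else n_int - te_ordinal + 1L
      istart <- ends[gidx] + 1L
      iend <- starts[gidx + 1L] - 1L
      ilen <- iend - istart + 1L
      te_len <- te_len_g
      max_off <- ilen - te_len - 2L * te_margin
      off <- if (max_off > 0L) sample.int(max_off + 1L, 1L) - 1L else 0L
      ts <- istart + te_margin + off
      te_l[[length(te_l) + 1L]] <- data.frame(
        chrom = chrom, start = ts, end = ts + te_len - 1L,
        strand = sample(c("+", "-"), 1L),
        name = sprintf("TE_intronic_%s", gid))
      het_ids <- c(het_ids, paste(gid, tid, te_ordinal, sep = ":"))
      het_regions[[length(het_regions) + 1L]] <- data.frame(
        chrom = chrom, start = ts, end = ts + te_len - 1L,
        intron_id = paste(gid, tid, te_ordinal, sep = ":"))
    }
    if (has_rep_gene[g] && n_int > 0L) {
      ro <- sample.int(n_int, 1L)
      gidx <- if (strand == "+") ro else n_int - ro + 1L
      istart <- ends[gidx] + 1L; iend <- starts[gidx + 1L] - 1L
      rlen <- min(sample(60:120, 1L), iend - istart - 19L)
      if (rlen >= 20L) {
        rs <- istart + sample.int(iend - istart - rlen + 1L, 1L)
        rep_l[[length(rep_l) + 1L]] <- data.frame(
          chrom = chrom, start = rs, end = rs + rlen - 1L, strand = "+",
          name = sprintf("repeat_%s", gid))
      }
    }
  }
  chrom_lengths <- setNames(as.integer(cursor + 1000L), names(cursor))
  # intergenic TEs in the gaps upstream of gene starts
  n_ig <- round(n_genes * intergenic_te_fraction)
  ig <- list()
  if (n_ig > 0L) {
    pick <- sample.int(n_genes, n_ig, replace = n_ig > n_genes)
    for (k in seq_len(n_ig)) {
      g <- pick[k]
      gd <- exon_l[[g]]
      if (min(gd$start) <= gene_gap) next  # no upstream gap on this gene
      len <- sample(100:300, 1L)
      s <- min(gd$start) - gene_gap + sample.int(gene_gap - 320L, 1L)
      ig[[k]] <- data.frame(chrom = gd$chrom[1], start = s,
                            end = s + len - 1L,
                            strand = sample(c("+", "-"), 1L),
                            name = sprintf("TE_intergenic_%03d", k))
    }
    ig <- ig[!vapply(ig, is.null, TRUE)]
  }
  exdf <- do.call(rbind, exon_l)
  exons <- GRanges(exdf$chrom, IRanges(exdf$start, exdf$end),
                   strand = exdf$strand, gene_id = exdf$gene_id,
                   transcript_id = exdf$transcript_id)
  seqlengths(exons) <- chrom_lengths[seqlevels(exons)]
  tedf <- do.call(rbind, c(te_l, ig))
  tes <- if (is.null(tedf)) GRanges() else
    GRanges(tedf$chrom, IRanges(tedf$start, tedf$end), strand = tedf$strand,
            name = tedf$name)
  repdf <- do.call(rbind, rep_l)
  reps <- if (is.null(repdf)) GRanges() else
    GRanges(repdf$chrom, IRanges(repdf$start, repdf$end),
            strand = repdf$strand, name = repdf$name)
  hrdf <- do.call(rbind, het_regions)
  hr <- if (is.null(hrdf)) GRanges() else
    GRanges(hrdf$chrom, IRanges(hrdf$start, hrdf$end),
            intron_id = hrdf$intron_id)
  chrom_lengths <- c(chrom_lengths, control_chloroplast = 30000L)
  truth <- new("SimulationTruth", hetIntronIds = het_ids, hetRegions = hr,
               terminationEffects = data.frame(gene_id = character(),
                                               fold = numeric()))
  list(exons = exons, tes = tes, repeats = reps,
       chrom_lengths = chrom_lengths, truth = truth)
}

defaultLevelParams <- function() {
  list(het = c(CG = 0.9, CHG = 0.6, CHH = 0.10),
       euch = c(CG = 0.05, CHG = 0.02, CHH = 0.01))
}

#' Simulate a whole-genome bisulfite cytosine report
#'
#' Cytosine sites of all three contexts are placed along each chromosome at
#' uniform random spacings; per-site methylation levels are drawn from
#' context-specific Beta distributions (heterochromatic state inside the
#' truth regions, euchromatic elsewhere), read depth is Poisson, and
#' methylated read counts are binomial at the site level plus bisulfite
#' non-conversion at rate 1 - \code{conversion_rate} (the beta-binomial
#' overdispersion model). An unmethylated \code{control_chloroplast} contig
#' is included for conversion-rate estimation.
#'
#' @param annotation list from [simulateAnnotation()].
#' @param depth_mean mean Poisson read depth (default 30).
#' @param conversion_rate bisulfite conversion rate (default 0.995).
#' @param level_params per-context Beta means for het/euch states (see
#'   \code{intronHet:::defaultLevelParams()}).
#' @param concentration Beta concentration (default 20).
#' @param spacing inter-site spacing range in bp (default 10-60).
#' @param control_spacing site spacing on the control contig.
#' @param seed RNG seed.
#' @return A \linkS4class{CytosineSites} report.
#' @export
simulateMethylome <- function(annotation, depth_mean = 30,
                              conversion_rate = 0.995,
                              level_params = defaultLevelParams(),
                              concentration = 20, spacing = c(10L, 60L),
                              control_spacing = c(5L, 15L), seed = 1L) {
  stopifnot(conversion_rate > 0, conversion_rate <= 1)
  if (depth_mean <= 0) {
    warning("zero depth: empty report")
    return(CytosineSites(character(), integer(), character(), character(),
                         integer(), integer()))
  }
  set.seed(seed)
  lens <- annotation$chrom_lengths
  het <- annotation$truth@hetRegions
  out <- list()
  for (chrom in names(lens)) {
    len <- lens[[chrom]]
    ctrl <- chrom == "control_chloroplast"
    sp <- if (ctrl) control_spacing else spacing
    for (ctx in VALID_CONTEXTS) {
      n_max <- ceiling(len / sp[1]) + 1L
      pos <- cumsum(ceiling(runif(n_max, sp[1] - 1, sp[2])))
      pos <- pos[pos <= len]
      n <- length(pos)
      if (n == 0L) next
      het_chr <- het[as.character(seqnames(het)) == chrom]
      is_het <- if (ctrl || length(het_chr) == 0L) rep(FALSE, n) else
        overlapsAny(IRanges(pos, width = 1L), ranges(het_chr))
      mu <- ifelse(is_het, level_params$het[[ctx]],
                   if (ctrl) 0 else level_params$euch[[ctx]])
      m <- numeric(n)
      pos_mu <- mu > 0 & mu < 1
      m[pos_mu] <- rbeta(sum(pos_mu), mu[pos_mu] * concentration,
                         (1 - mu[pos_mu]) * concentration)
      m[mu >= 1] <- 1
      depth <- rpois(n, depth_mean)
      p_obs <- m + (1 - m) * (1 - conversion_rate)
      n_meth <- rbinom(n, depth, p_obs)
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, pos = pos,
        strand = sample(c("+", "-"), n, replace = TRUE),
        context = ctx, n_meth = n_meth, n_unmeth = depth - n_meth)
    }
  }
  d <- do.call(rbind, out)
  CytosineSites(d$chrom, d$pos, d$strand, d$context, d$n_meth, d$n_unmeth,
                seqlengths = lens)
}

#' Simulate pre/post-intron read-count pairs
#'
#' Each replicate library draws a Gamma(size, size) expression factor per
#' intron, shared by the pre- and post-intron segment (pre and post reads
#' come from the same library and transcript, so library and expression
#' variation act on both); counts are then Poisson, giving
#' negative-binomial marginals. Genes in the termination-effect set have
#' their post-intron mean divided by the stated fold in the mutant genotype
#' only.
#'
#' @param introns character vector of intron ids, or data.frame with
#'   \code{intron_id} and \code{gene_id} columns (ids double as gene ids for
#'   a plain vector).
#' @param effects data.frame with \code{gene_id}, \code{fold}, or a
#'   \linkS4class{SimulationTruth}.
#' @param mean_count mean pre/post read count (default 100).
#' @param dispersion negative-binomial size of the shared expression factor
#'   (default 20).
#' @param n_reps replicates per genotype (>= 1, default 2).
#' @param genotypes two genotype labels, reference first.
#' @param seed RNG seed.
#' @return long data.frame: \code{intron_id}, \code{sample_id},
#'   \code{genotype}, \code{pre_count}, \code{post_count}.
#' @export
simulateIntronCounts <- function(introns, effects, mean_count = 100,
                                 dispersion = 20, n_reps = 2L,
                                 genotypes = c("wt", "mut"), seed = 1L) {
  stopifnot(n_reps >= 1)
  if (is.character(introns))
    introns <- data.frame(intron_id = introns, gene_id = introns)
  if (is(effects, "SimulationTruth")) effects <- terminationEffects(effects)
  fold <- setNames(rep(1, nrow(introns)), introns$intron_id)
  hit <- introns$gene_id %in% effects$gene_id
  fold[hit] <- effects$fold[match(introns$gene_id[hit], effects$gene_id)]
  set.seed(seed)
  rows <- list()
  n <- nrow(introns)
  for (gt in genotypes) {
    eff <- if (gt == genotypes[2]) fold else rep(1, n)
    for (r in seq_len(n_reps)) {
      lambda <- rgamma(n, shape = dispersion, rate = dispersion)
      pre <- rpois(n, lambda * mean_count)
      post <- rpois(n, lambda * mean_count / eff)
      rows[[length(rows) + 1L]] <- data.frame(
        intron_id = introns$intron_id,
        sample_id = paste(gt, r, sep = "_"), genotype = gt,
        pre_count = pre, post_count = post)
    }
  }
  do.call(rbind, rows)
}

#' Simulate a gene-by-condition expression atlas
#'
#' "Specific" genes are expressed in exactly one condition (zero elsewhere);
#' "broad" genes are near-uniform with multiplicative log-normal noise.
#'
#' @param n_genes number of genes.
#' @param n_conditions number of conditions (>= 2).
#' @param specific_fraction fraction of condition-specific genes.
#' @param base_level mean expression of expressed entries (default 100).
#' @param noise_sd log-scale noise sd (default 0.2).
#' @param seed RNG seed.
#' @return list with \code{matrix} (genes x conditions) and \code{truth}
#'   (data.frame \code{gene_id}, \code{class}).
#' @export
simulateExpressionAtlas <- function(n_genes, n_conditions = 10L,
                                    specific_fraction = 0.2,
                                    base_level = 100, noise_sd = 0.2,
                                    seed = 1L) {
  stopifnot(n_conditions >= 2)
  set.seed(seed)
  n_spec <- round(n_genes * specific_fraction)
  cls <- sample(c(rep("specific", n_spec),
                  rep("broad", n_genes - n_spec)))
  m <- matrix(0, nrow = n_genes, ncol = n_conditions,
              dimnames = list(sprintf("g%05d", seq_len(n_genes)),
                              sprintf("cond_%02d", seq_len(n_conditions))))
  for (i in seq_len(n_genes)) {
    if (cls[i] == "specific") {
      j <- sample.int(n_conditions, 1L)
      m[i, j] <- base_level * rlnorm(1, 0, noise_sd)
    } else {
      m[i, ] <- base_level * rlnorm(n_conditions, 0, noise_sd)
    }
  }
  list(matrix = m,
       truth = data.frame(gene_id = rownames(m), class = cls))
}

#' Simulate diverged ortholog alignment pairs
#'
#' Coding sequences evolve under a uniform per-site mutation process in
#' which synonymous changes are always accepted and nonsynonymous changes
#' are accepted with probability \code{dNdS} (changes creating stop codons
#' are rejected), so the expected synonymous divergence is \code{Ks_target}
#' and the expected Ka/Ks is \code{dNdS}. Intron alignments diverge at
#' \code{intron_rate} per site outside a repeat-masked block, which receives
#' substitutions at \code{mask_rate_multiplier} times that rate and must be
#' excluded downstream. Per-column exon/intron annotation states are emitted
#' with a per-pair conservation drawn from
#' \code{structure_conservation_range} for ortholog screening.
#'
#' @param n_genes number of ortholog pairs.
#' @param codons_per_gene codons per coding alignment (default 300).
#' @param dNdS true nonsynonymous/synonymous rate ratio (> 0 allowed 0).
#' @param Ks_target expected synonymous divergence (0 < Ks <= 0.1).
#' @param intron_rate true per-site intron substitution rate.
#' @param repeat_mask_fraction masked fraction of each intron alignment.
#' @param intron_length intron alignment length (default 300).
#' @param mask_rate_multiplier substitution-rate multiplier inside the mask.
#' @param structure_conservation_range range of per-pair annotation-state
#'   agreement fractions.
#' @param seed RNG seed.
#' @return list with \code{pairs} (named list of
#'   \linkS4class{OrthologPair}), \code{hit_table} (one row per pair) and
#'   \code{truth} (\linkS4class{SimulationTruth} with \code{dndsTruth}).
#' @export
simulateOrthologPairs <- function(n_genes, codons_per_gene = 300L,
                                  dNdS = 0.4, Ks_target = 0.05,
                                  intron_rate = 0.02,
                                  repeat_mask_fraction = 0.2,
                                  intron_length = 300L,
                                  mask_rate_multiplier = 10,
                                  structure_conservation_range = c(0.85, 1),
                                  seed = 1L) {
  stopifnot(Ks_target > 0, Ks_target <= 0.1, dNdS >= 0)
  set.seed(seed)
  gc <- geneticCode()
  sense <- names(gc)[gc != "*"]
  pairs <- list()
  for (g in seq_len(n_genes)) {
    gid <- sprintf("g%05d", g)
    cod <- sample(sense, codons_per_gene, replace = TRUE)
    a <- unlist(strsplit(cod, ""))
    b <- a
    L <- length(a)
    for (site in which(runif(L) < Ks_target)) {
      prop <- sample(setdiff(BASES, b[site]), 1L)
      ci <- ((site - 1L) %/% 3L) + 1L
      idx <- (3L * ci - 2L):(3L * ci)
      old_cod <- paste(b[idx], collapse = "")
      new <- b; new[site] <- prop
      new_cod <- paste(new[idx], collapse = "")
      if (gc[[new_cod]] == "*") next
      if (gc[[new_cod]] == gc[[old_cod]] || runif(1) < dNdS)
        b[site] <- prop
    }
    ia <- sample(BASES, intron_length, replace = TRUE)
    ib <- ia
    mask <- rep(FALSE, intron_length)
    mlen <- round(intron_length * repeat_mask_fraction)
    if (mlen > 0L) {
      ms <- sample.int(intron_length - mlen + 1L, 1L)
      mask[ms:(ms + mlen - 1L)] <- TRUE
    }
    rate <- ifelse(mask, pmin(1, intron_rate * mask_rate_multiplier),
                   intron_rate)
    mut <- which(runif(intron_length) < rate)
    for (site in mut)
      ib[site] <- sample(setdiff(BASES, ib[site]), 1L)
    cons <- runif(1, structure_conservation_range[1],
                  structure_conservation_range[2])
    scol <- 3L * codons_per_gene
    st1 <- sample(c("E", "I"), scol, replace = TRUE, prob = c(0.7, 0.3))
    st2 <- st1
    flip <- which(runif(scol) > cons)
    st2[flip] <- ifelse(st1[flip] == "E", "I", "E")
    pairs[[gid]] <- OrthologPair(
      gid,
      Biostrings::DNAStringSet(setNames(
        c(paste(a, collapse = ""), paste(b, collapse = "")),
        paste0(gid, c("_sp1", "_sp2")))),
      introns = list(Biostrings::DNAStringSet(setNames(
        c(paste(ia, collapse = ""), paste(ib, collapse = "")),
        paste0(gid, c("_intron_sp1", "_intron_sp2"))))),
      masks = list(mask),
      states = rbind(st1, st2))
  }
  truth <- new("SimulationTruth",
               dndsTruth = data.frame(gene_id = names(pairs), dnds = dNdS,
                                      ks = Ks_target,
                                      intron_rate = intron_rate))
  list(pairs = pairs,
       hit_table = data.frame(query = names(pairs),
                              subject = paste0(names(pairs), "_m")),
       truth = truth)
}

#' Write/read ortholog alignment pairs as FASTA
#'
#' Three files: coding alignment (two records per gene), intron alignment
#' (two records per gene) and a 0/1-character mask FASTA (1 = repeat-masked
#' column), all keyed by gene id.
#'
#' @param pairs named list of \linkS4class{OrthologPair}.
#' @param prefix output path prefix; files \code{<prefix>_coding.fa},
#'   \code{<prefix>_intron.fa}, \code{<prefix>_mask.fa}.
#' @return the three paths, invisibly.
#' @export
writeOrthologFasta <- function(pairs, prefix) {
  coding <- do.call(c, unname(lapply(pairs, codingAlignment)))
  introns <- do.call(c, unname(lapply(pairs, function(p)
    intronAlignments(p)[[1]])))
  masks <- Biostrings::BStringSet(setNames(
    vapply(pairs, function(p)
      paste(as.integer(repeatMasks(p)[[1]]), collapse = ""), ""),
    paste0(names(pairs), "_mask")))
  paths <- paste0(prefix, c("_coding.fa", "_intron.fa", "_mask.fa"))
  Biostrings::writeXStringSet(coding, paths[1])
  Biostrings::writeXStringSet(introns, paths[2])
  Biostrings::writeXStringSet(masks, paths[3])
  invisible(paths)
}

#' @rdname writeOrthologFasta
#' @export
readOrthologFasta <- function(prefix) {
  coding <- Biostrings::readDNAStringSet(paste0(prefix, "_coding.fa"))
  introns <- Biostrings::readDNAStringSet(paste0(prefix, "_intron.fa"))
  masks <- Biostrings::readBStringSet(paste0(prefix, "_mask.fa"))
  ids <- unique(sub("_sp[12]$", "", names(coding)))
  pairs <- lapply(ids, function(gid) {
    OrthologPair(gid, coding[paste0(gid, c("_sp1", "_sp2"))],
      introns = list(introns[paste0(gid, c("_intron_sp1", "_intron_sp2"))]),
      masks = list(as.integer(strsplit(as.character(
        masks[[paste0(gid, "_mask")]]), "")[[1]]) == 1L))
  })
  setNames(pairs, ids)
}

#' Serialize / load simulation ground truth
#'
#' JSON sidecar so downstream recovery analyses can join on identifiers.
#'
#' @param truth a \linkS4class{SimulationTruth}.
#' @param path JSON path.
#' @return [readSimulationTruth()]: a \linkS4class{SimulationTruth}.
#' @export
writeSimulationTruth <- function(truth, path) {
  hr <- truth@hetRegions
  obj <- list(
    het_intron_ids = truth@hetIntronIds,
    het_regions = data.frame(
      chrom = as.character(seqnames(hr)), start = start(hr), end = end(hr),
      intron_id = if (length(hr)) hr$intron_id else character()),
    termination_effects = truth@terminationEffects,
    dnds_truth = truth@dndsTruth,
    specificity_truth = truth@specificityTruth)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname writeSimulationTruth
#' @export
readSimulationTruth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  hr <- if (length(obj$het_regions) && nrow(as.data.frame(obj$het_regions)))
    with(as.data.frame(obj$het_regions),
         GRanges(chrom, IRanges(start, end), intron_id = intron_id))
  else GRanges()
  asdf <- function(x, proto) {
    d <- as.data.frame(x)
    if (!nrow(d)) proto else d
  }
  new("SimulationTruth",
      hetIntronIds = as.character(obj$het_intron_ids),
      hetRegions = hr,
      terminationEffects = asdf(obj$termination_effects,
        data.frame(gene_id = character(), fold = numeric())),
      dndsTruth = asdf(obj$dnds_truth, data.frame()),
      specificityTruth = asdf(obj$specificity_truth, data.frame()))
}
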