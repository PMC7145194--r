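#' Default pipeline configuration
#'
#' All analysis thresholds default to the published values: coverage bounds
#' 3-100, domain rule >= 5 sites / mean >= 0.5, repeat-hit filters 100 bp /
#' 70% coverage / 20% divergence, q <= 0.01 for the termination test,
#' Ks <= 0.1, 80% structure conservation. Simulation scale and permutation
#' draws are package choices sized for a desk-scale run.
#'
#' @param out_dir run directory (created; outputs are write-once per run).
#' @param seed global seed, expanded deterministically into per-stage seeds.
#' @param n_genes simulated gene count (default 200).
#' @param ... overrides for any config entry.
#' @return named list of configuration values.
#' @export
pipelineConfig <- function(out_dir, seed = 1L, n_genes = 200L, ...) {
  cfg <- list(
    out_dir = out_dir, seed = as.integer(seed), n_genes = as.integer(n_genes),
    te_density = 0.3, depth_mean = 30, conversion_rate = 0.995,
    min_coverage = 3L, max_coverage = 100L, call_fdr = 0.05,
    domain_min_sites = 5L, domain_min_mean = 0.5,
    region_min_sites = 5L,
    ratio_q_threshold = 0.01, ratio_min_total = 10L,
    termination_n_effects = 20L, termination_fold = 10,
    ks_max = 0.1, structure_conservation = 0.8,
    ortho_dnds = 0.4, ortho_ks = 0.05, intron_rate = 0.02,
    n_perm = 1e4,
    stages = c("simulate", "call-methylation", "call-domains",
               "classify-te", "enrich", "specificity", "ratio-test",
               "evolution"))
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  validatePipelineConfig(cfg)
  cfg
}

validatePipelineConfig <- function(cfg) {
  with(cfg, {
    stopifnot(min_coverage >= 0, max_coverage >= min_coverage,
              domain_min_sites >= 1, domain_min_mean >= 0,
              domain_min_mean <= 1, ratio_q_threshold > 0,
              ratio_q_threshold < 1, ks_max > 0, n_perm >= 1,
              conversion_rate > 0, conversion_rate <= 1)
  })
  invisible(TRUE)
}

stageSeed <- function(cfg, k) (cfg$seed %% 100000L) * 10000L + k

#' Run the analysis pipeline end-to-end
#'
#' Executes the enabled stages in dependency order on a run directory:
#' data simulation (annotation, methylome, counts, expression atlas,
#' ortholog alignments, truth sidecar), methylcytosine calling,
#' heterochromatic-domain calling and intron classification, TE location/
#' methylation classification, positional enrichment, expression
#' specificity, the pre/post-intron ratio test, and ortholog substitution
#' rates. Returns (and writes) a manifest with an md5 checksum per output;
#' rerunning with the same config and seed reproduces identical checksums.
#'
#' @param config list from [pipelineConfig()].
#' @return data.frame manifest (file, md5), invisibly written to
#'   \code{manifest.tsv} in the run directory.
#' @export
runPipeline <- function(config) {
  validatePipelineConfig(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  pathOf <- function(f) file.path(out, f)
  stages <- config$stages

  if ("simulate" %in% stages) {
    ann <- simulateAnnotation(config$n_genes, te_density = config$te_density,
                              seed = stageSeed(config, 1L))
    writeGeneModels(ann$exons, pathOf("annotation.gff3"))
    writeBedIntervals(ann$tes, pathOf("tes.bed"))
    writeBedIntervals(ann$repeats, pathOf("repeats.bed"))
    writeTsvTable(data.frame(chrom = names(ann$chrom_lengths),
                             length = as.integer(ann$chrom_lengths)),
                  pathOf("chrom_lengths.tsv"))
    meth <- simulateMethylome(ann, depth_mean = config$depth_mean,
                              conversion_rate = config$conversion_rate,
                              seed = stageSeed(config, 2L))
    writeCytosineReport(meth, pathOf("cytosine_report.tsv"))
    introns <- deriveIntrons(ann$exons)
    genes <- unique(ann$exons$gene_id)
    het_genes_truth <- unique(sub(":.*", "", hetIntronIds(ann$truth)))
    eff_genes <- utils::head(het_genes_truth, config$termination_n_effects)
    truth <- ann$truth
    truth@terminationEffects <- data.frame(
      gene_id = eff_genes,
      fold = rep(config$termination_fold, length(eff_genes)))
    counts <- simulateIntronCounts(
      data.frame(intron_id = introns$intron_id, gene_id = introns$gene_id),
      truth, n_reps = 2L, seed = stageSeed(config, 3L))
    writeTsvTable(counts, pathOf("intron_counts.tsv"))
    atlas <- simulateExpressionAtlas(length(genes),
                                     seed = stageSeed(config, 4L))
    rownames(atlas$matrix) <- genes
    atlas$truth$gene_id <- genes
    writeTsvTable(atlas$matrix, pathOf("expression_atlas.tsv"))
    truth@specificityTruth <- atlas$truth
    orth <- simulateOrthologPairs(min(config$n_genes, length(genes)),
                                  dNdS = config$ortho_dnds,
                                  Ks_target = config$ortho_ks,
                                  intron_rate = config$intron_rate,
                                  seed = stageSeed(config, 5L))
    writeOrthologFasta(orth$pairs, pathOf("orthologs"))
    truth@dndsTruth <- orth$truth@dndsTruth
    writeSimulationTruth(truth, pathOf("truth.json"))
  }

  exons <- readGeneModels(pathOf("annotation.gff3"))
  introns <- deriveIntrons(exons)
  truth <- readSimulationTruth(pathOf("truth.json"))
  tes <- readBedIntervals(pathOf("tes.bed"))
  reps <- readBedIntervals(pathOf("repeats.bed"))

  if ("call-methylation" %in% stages) {
    sites <- readCytosineReport(pathOf("cytosine_report.tsv"))
    ctrl <- sites[as.character(seqnames(sites)) == "control_chloroplast"]
    conv <- estimateConversionRate(filterCoverage(ctrl, 1L, Inf))
    covered <- filterCoverage(sites, config$min_coverage,
                              config$max_coverage)
    calls <- callMethylcytosines(
      covered[as.character(seqnames(covered)) != "control_chloroplast"],
      conv, fdr_threshold = config$call_fdr)
    writeMethylationCalls(calls, pathOf("methylation_calls.tsv"))
    writeTsvTable(data.frame(metric = "conversion_rate",
                             value = formatC(conv, digits = 8,
                                             format = "g")),
                  pathOf("conversion_rate.tsv"))
  }

  if ("call-domains" %in% stages) {
    calls <- readMethylationCallsTsv(pathOf("methylation_calls.tsv"))
    domains <- findHeterochromaticDomains(
      calls[calls$context == "CHG"], min_sites = config$domain_min_sites,
      min_mean = config$domain_min_mean)
    writeDomainsBed(domains, pathOf("domains.bed"))
    introns <- classifyHeterochromaticIntrons(introns, domains)
    introns <- flagIntronTeRepeat(introns, tes, reps)
    flagged <- granges(introns)
    mcols(flagged)$name <- introns$intron_id
    mcols(flagged)$score <- as.integer(introns$heterochromatic)
    writeBedIntervals(flagged, pathOf("heterochromatic_introns.bed"))
    writeTsvTable(as.data.frame(mcols(introns)), pathOf("intron_flags.tsv"))
  }

  if ("classify-te" %in% stages) {
    te_cls <- classifyTeLocation(tes, exons)
    writeTsvTable(data.frame(name = te_cls$name,
                             class = te_cls$location_class,
                             host_gene = te_cls$host_gene),
                  pathOf("te_location_classes.tsv"))
  }

  if ("enrich" %in% stages) {
    fl <- readTsvTable(pathOf("intron_flags.tsv"))
    dist_all <- intronPositionDistribution(fl$ordinal)
    het <- fl$ordinal[fl$heterochromatic]
    res <- if (length(het))
      positionalPermutationTest(het, fl$ordinal, n_perm = config$n_perm,
                                seed = stageSeed(config, 6L))
    else list(observed = NA_real_, p_value = NA_real_)
    venn <- vennHetIntronTeRepeat(fl)
    writeTsvTable(data.frame(
      metric = c("mean_ordinal_all", "mean_ordinal_het", "permutation_p",
                 names(venn)),
      value = formatC(c(dist_all$mean_ordinal, res$observed, res$p_value,
                        as.numeric(venn)), digits = 8, format = "g")),
      pathOf("enrichment.tsv"))
  }

  if ("specificity" %in% stages) {
    mat <- readTsvTable(pathOf("expression_atlas.tsv"), rownames_col = "id")
    H <- apply(mat, 1, rokuEntropy)
    writeTsvTable(data.frame(gene_id = rownames(mat),
                             entropy = formatC(H, digits = 8, format = "g")),
                  pathOf("specificity.tsv"))
  }

  if ("ratio-test" %in% stages) {
    counts <- readTsvTable(pathOf("intron_counts.tsv"))
    res <- prePostRatioGlmTest(counts, reference = "wt",
                               q_threshold = config$ratio_q_threshold,
                               min_total = config$ratio_min_total)
    res$coefficient <- formatC(res$coefficient, digits = 8, format = "g")
    res$p_value <- formatC(res$p_value, digits = 8, format = "g")
    res$q_value <- formatC(res$q_value, digits = 8, format = "g")
    writeTsvTable(res, pathOf("ratio_test.tsv"))
  }

  if ("evolution" %in% stages) {
    pairs <- readOrthologFasta(pathOf("orthologs"))
    div <- do.call(rbind, lapply(names(pairs), function(gid) {
      ng <- neiGojoboriRates(pairs[[gid]])
      data.frame(gene_id = gid, Ka = ng$Ka, Ks = ng$Ks,
                 Ki = intronPDistance(pairs[[gid]]))
    }))
    div <- ksFilter(div, config$ks_max)
    out_div <- div
    for (col in c("Ka", "Ks", "Ki"))
      out_div[[col]] <- formatC(div[[col]], digits = 8, format = "g")
    writeTsvTable(out_div, pathOf("ortholog_divergence.tsv"))
  }

  files <- sort(setdiff(list.files(out), "manifest.tsv"))
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(out, files))))
  writeTsvTable(manifest, pathOf("manifest.tsv"))
  invisible(manifest)
}

#' Read a methylation-call TSV back into a MethylationCalls object
#'
#' @param path TSV written by [writeMethylationCalls()].
#' @return A \linkS4class{MethylationCalls}.
#' @export
readMethylationCallsTsv <- function(path) {
  d <- read.delim(path, header = TRUE, sep = "\t")
  gr <- GRanges(d$chrom, IRanges(d$pos, width = 1L), strand = d$strand)
  mcols(gr) <- DataFrame(context = d$context, n_meth = as.integer(d$n_meth),
                         n_unmeth = as.integer(d$n_unmeth),
                         level = as.numeric(d$level),
                         p_value = as.numeric(d$p_value),
                         q_value = as.numeric(d$q_value),
                         called = as.logical(d$called))
  o <- order(as.factor(seqnames(gr)), start(gr))
  new("MethylationCalls", gr[o])
}
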