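---
title: "Methods: detecting and analysing intronic heterochromatin"
author: "intronHet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and analysing intronic heterochromatin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intronHet)
```

# Scope and data model

`intronHet` implements the computational chain used to study heterochromatic
introns in plant genomes: per-cytosine methylcytosine calling from a WGBS
cytosine report, CHG-methylation domain detection, classification of introns
and genes by intronic heterochromatin, TE location/methylation taxonomy,
enrichment and expression-specificity statistics, a pre/post-intron
read-ratio test for premature transcription termination, and Nei–Gojobori
substitution-rate comparisons between ortholog pairs.

All genomic intervals live in `GRanges` objects (1-based, closed — the
R/Bioconductor convention). File formats keep their native conventions
(GFF3 1-based closed, BED 0-based half-open, cytosine reports 1-based) and
`rtracklayer` performs the conversion at the I/O boundary, so no coordinate
arithmetic crosses a convention silently. Cytosine data use a fixed
six-column tab-separated dialect (chrom, 1-based position, strand, context,
methylated count, unmethylated count) with an auto-detected optional header.

Introns are derived **per transcript**, not per gene: an intron interval
shared by several splice variants yields one record per variant, each with
its own 5′-relative ordinal (ordinal 1 = the most promoter-proximal intron
in transcript orientation, so on the minus strand the genomically last gap).
This matches how positional statistics over splice variants are counted in
the field.

# Methylcytosine calling

The conversion rate $c$ is the pooled unmethylated-read fraction over an
unmethylated control sequence; in real data the chloroplast genome, in the
simulator a contig named `control_chloroplast`. Per site the p-value is the
exact upper-tail binomial probability of the observed methylated reads under
error rate $1-c$; multiple testing uses Benjamini–Hochberg **within each
sequence context**, since CG, CHG and CHH have very different truly
methylated fractions and pooling would couple their thresholds. The
correction scheme is exposed (`adjust=`) because the underlying study names
only the binomial test.

Numerical and boundary choices:

* coverage bounds are inclusive, $3 \le \text{coverage} \le 100$: "fewer
  than 3" and "more than 100" reads are removed. The high cutoff stands in
  for a data-derived extreme-coverage trim and is a plain parameter.
* $n_C = 0$ gives $p = 1$ exactly; $c = 1$ with $n_C > 0$ gives $p = 0$
  without division errors.
* strands are kept separate at the site level; region summaries pool both
  strands. Region context means are reported only at ≥ 5 informative sites
  (`min_sites`), and regions below that are marked excluded rather than
  averaged on noise.

# Heterochromatic domains

A domain is a maximal run of consecutively *called* mCHG sites with at least
5 members and unweighted mean level ≥ 0.5. Three readings of "consecutive"
were possible; the package takes the most literal one:

* consecutiveness is counted **among CHG sites in genomic order, both
  strands pooled**; intervening CG/CHH cytosines are invisible;
* only a CHG site that *failed* the methylcytosine call breaks a run —
  distance does not. Requiring the call (not merely level data) is the
  stricter reading; `require_call = FALSE` gives the alternative;
* a maximal run whose mean is below 0.5 yields nothing: no sub-run search is
  attempted, because the rule describes a single filter, not an
  optimisation.

Domain intervals span the first through last member site and are not
extended toward the next unmethylated site (the data give no basis for a
wider span). Intron classification uses **full containment** of a domain,
matching the notion of an intron that "contains" a domain; `mode = "any"`
provides the overlap variant. Genes inherit the flag from any intron.

# Premature-termination (pre/post-intron ratio) test

For each intron, pre- and post-intron read counts per replicate are
modelled as binomial observations of the proportion
$\mathrm{post}/(\mathrm{pre}+\mathrm{post})$ with genotype as the sole
predictor, and the p-value is the likelihood-ratio test of the genotype
term. Replicates enter as separate observations; because the model has only
the genotype factor, the per-genotype aggregated counts are sufficient and
the LRT is computed in closed form as the G-statistic of the aggregated
2×2 table — the test suite asserts exact equality with `glm()` deviances.
Introns with total counts below `min_total = 10` in either genotype are
skipped (degenerate fits), and a zero aggregate cell (complete separation)
adds 0.5 to all four cells and flags the intron. Direction "down" means
reduced downstream transcription. Gene-level calls use the any-intron rule;
comparisons are intersected and heterochromatic genes tested for enrichment
among intersected DEGs by Fisher's exact test. A single-replicate variant
tests the mutant proportion against the control's observed proportion with
an exact binomial test.

The modelling choice worth stating: the binomial proportion model assumes
the within-replicate post fraction is binomial given the totals. That is
exact when pre and post counts share a common per-replicate scale factor
(same library, same transcript), which is also how the simulator generates
data; strong extra-binomial variation between replicates would make the
test anti-conservative, and a quasi-binomial extension would then be the
appropriate refinement.

# Molecular evolution

Nei–Gojobori rates: per codon position the three possible changes (those
creating stop codons excluded) are split into synonymous and nonsynonymous
fractions and the position contributes exactly one site, so $S + N =
3\times$codons; site counts are averaged over the two sequences.
Differences average synonymous/nonsynonymous steps over all minimal
substitution pathways per codon with equal weights, dropping pathways that
pass through stop codons (renormalising; if every pathway is blocked, all
are used). Codons with a gap or ambiguity in either row are skipped whole.
Proportions are Jukes–Cantor corrected, with an explicit saturation error
at $p \ge 3/4$.

Ortholog screening keeps queries with exactly one candidate and ≥ 80%
column-wise exon/intron annotation-state agreement. Genes with $K_S > 0.1$
are discarded ($K_S = 0.1$ exactly is retained — the rule discards strictly
greater values). Intron divergence $K_I$ is the p-distance over columns
that are neither gapped nor repeat-masked; only gap and masked columns are
excluded, not gap-adjacent ones.

Group aggregates use $\overline{K_A}/\overline{K_S}$ (ratio of means)
rather than the mean of per-gene ratios: with $K_S$ capped at 0.1, per-gene
ratios explode as $K_S \to 0$, while the ratio of means is stable;
`aggregate = "mean_ratio"` provides the alternative, and neither published
group value is claimed reproducible without the real genomes. Permutation
tests report one-sided p-values in the observed direction with the add-one
correction $p = (1 + \#\{\text{null} \ge \text{obs}\})/(N+1)$, so $p$ can
never be 0 and the minimum attainable p is $1/(N+1)$. The function default
is $N = 10^6$ draws, chosen so the smallest attainable p lies below the
$10^{-5}$ reporting threshold used for genome-scale claims; package tests
and the bundled pipeline pass smaller explicit $N$ ($10^4$–$10^5$), which
bounds their minimum attainable p accordingly.

# Enrichment and specificity statistics

* Positional bias: statistic = mean ordinal of heterochromatic introns;
  null = size-matched subsets drawn without replacement from all ordinals;
  lower tail by default (5′ bias = smaller mean), two-sided behind a flag.
* Fisher enrichment: the conventional exact two-sided definition (sum of
  hypergeometric table probabilities ≤ the observed table's); the sample
  odds ratio $(ad)/(bc)$ is reported, not the conditional MLE. No mid-p.
* ROKU-style entropy: deviations from a one-step Tukey biweight
  ($c = 5$, $\epsilon = 10^{-4}$, the ROKU defaults) normalised to
  probabilities; Shannon entropy in **bits** (log2) with $0\log 0 := 0$. A
  constant vector returns $\log_2 n$ (maximally unspecific) by convention.
  Because $\epsilon$ is a fixed additive guard, scale invariance is exact
  only in the $\epsilon \to 0$ limit; observed deviations are $\sim10^{-4}$
  bits.
* Effect size $r = |Z|/\sqrt{N}$ from the tie-corrected normal
  approximation of the rank-sum statistic, without continuity correction;
  all-tied inputs return 0.

# The synthetic-data generator

The generator produces data *with the structure the analyses assume*, with
ground truth recorded in a `SimulationTruth` sidecar:

* **Annotation**: single-transcript genes laid along two chromosomes
  (exons 150–300 bp, introns 100–400 bp, intergenic gap 500 bp). A fraction
  `te_density` (default 0.3) of genes receives one intronic TE (400–600 bp)
  with ≥ 100 bp flanking margin inside a correspondingly enlarged intron;
  the host intron ordinal is drawn with geometric 5′-biased weights
  ($w \propto 0.5^{\,\text{ordinal}-1}$), emulating preferential TE
  accumulation in promoter-proximal introns. The TE interval is the truth
  heterochromatic region.
* **Methylome**: cytosine sites of all three contexts at uniform 10–60 bp
  spacings (5–15 bp on the 30 kb control contig). Site methylation is
  beta-distributed around context/state means (heterochromatic CG/CHG/CHH
  = 0.9/0.6/0.10, euchromatic = 0.05/0.02/0.01, concentration 20 — a
  realism choice creating overdispersion, not a calibrated fit to any
  dataset), read depth is Poisson(30), and non-conversion adds methylated
  reads at rate $1-c$ with $c = 0.995$.
* **Intron counts**: each replicate draws a Gamma(size, size) expression
  factor per intron shared by pre and post (size = 20), then Poisson
  counts at mean 100 — negative-binomial marginals with the pre/post ratio
  conditionally binomial, which is exactly the coupling the ratio test
  assumes since both counts come from one library and transcript.
  Termination-effect genes divide the mutant post-intron mean by the stated
  fold.
* **Expression atlas**: "specific" genes expressed in exactly one of 10
  conditions, "broad" genes near-uniform with log-normal noise (sd 0.2).
* **Ortholog pairs**: 300-codon coding alignments diverged by a uniform
  per-site mutation process in which synonymous changes fix always and
  nonsynonymous ones with probability dN/dS (stop codons rejected), giving
  expected synonymous divergence `Ks_target`; 300 bp introns diverge at
  `intron_rate` outside a contiguous masked block (20% of columns) that
  receives 10× substitutions and must be excluded downstream.

Every generator is a pure function of its parameters and seed.

What the simulations do **not** emulate — and hence what passing tests do
not show about real data: mapping bias and M-bias, strand-asymmetric
conversion, copy-number and repeat-mapping artefacts, spatially correlated
methylation beyond the het/euch dichotomy, splice-variant-rich gene models,
alignment error in ortholog pairs, codon-usage and transition/transversion
bias, and selection heterogeneity along genes.

# Problem sizes and runtime choices

The bundled pipeline and test suite run at desk scale as the package's own
choice of problem size: 40–400 simulated genes per methylome replicate, 100
seeds for domain-recovery estimates, 1,000 introns × 10 seeds for the
termination test, 500 ortholog pairs per group at 300 codons, and
$10^4$–$10^5$ permutation draws. Genome-scale magnitudes (tens of
thousands of gene models, $p < 10^{-6}$ claims at $10^6$ draws) require
the real annotation and sequencing data and are outside what the synthetic
conditions can or should reproduce.

# Known limitations

* The binomial ratio test has no overdispersion term; see above.
* The domain rule is a hard threshold pair (5 sites, 0.5 mean); no
  probabilistic segmentation (HMM) is attempted.
* Nei–Gojobori assumes equal mutation rates among nucleotides; codon
  models with transition bias (GY94-type) are out of scope.
* TE location classes resolve ambiguity by a fixed priority (exon–intron
  before exon/intron) when splice variants disagree.
* The R-gene enrichment worked example depends on the exact gene universe;
  with the printed marginal counts the exact two-sided p is
  $1.27\times10^{-6}$, computed at run time by the acceptance script.
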