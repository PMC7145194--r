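BASES <- c("A", "C", "G", "T")

geneticCode <- function() Biostrings::GENETIC_CODE

stopCodons <- function() names(geneticCode())[geneticCode() == "*"]

# fraction of synonymous changes per codon position; changes creating stop
# codons are excluded and each position contributes exactly one site, so
# S + N = 3 x codons.
synSiteTable <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    gc <- geneticCode()
    codons <- names(gc)
    m <- matrix(NA_real_, nrow = 64, ncol = 3, dimnames = list(codons, NULL))
    for (cod in codons) {
      if (gc[[cod]] == "*") next
      for (pos in 1:3) {
        nsyn <- 0L; nnon <- 0L
        for (b in setdiff(BASES, substr(cod, pos, pos))) {
          alt <- cod
          substr(alt, pos, pos) <- b
          if (gc[[alt]] == "*") next
          if (gc[[alt]] == gc[[cod]]) nsyn <- nsyn + 1L else nnon <- nnon + 1L
        }
        m[cod, pos] <- if (nsyn + nnon > 0L) nsyn / (nsyn + nnon) else 0
      }
    }
    tab <<- m
    tab
  }
})

# average synonymous/nonsynonymous step counts over all minimal substitution
# pathways between two codons; pathways through stop codons are dropped and
# the weights renormalised (all pathways used if every one is blocked).
codonPairDiffs <- local({
  cache <- new.env(parent = emptyenv())
  function(c1, c2) {
    key <- paste0(c1, c2)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    gc <- geneticCode()
    pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    paths <- permutationsOf(pos)
    stats <- lapply(paths, function(ord) {
      cur <- c1
      sd <- 0; nd <- 0; blocked <- FALSE
      for (p in ord) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (gc[[nxt]] == "*") blocked <- TRUE
        if (gc[[cur]] == gc[[nxt]]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd = sd, nd = nd, blocked = as.numeric(blocked))
    })
    m <- do.call(rbind, stats)
    use <- m[, "blocked"] == 0
    if (!any(use)) use <- rep(TRUE, nrow(m))
    res <- c(sd = mean(m[use, "sd"]), nd = mean(m[use, "nd"]))
    cache[[key]] <- res
    res
  }
})

permutationsOf <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in permutationsOf(x[-i]))
      out <- c(out, list(c(x[i], rest)))
  out
}

#' Nei-Gojobori synonymous and nonsynonymous substitution rates
#'
#' Synonymous/nonsynonymous site counts are the per-position fractions of
#' synonymous changes (stop-codon changes excluded; each position contributes
#' one site), averaged over the two sequences. Differences average the
#' synonymous/nonsynonymous steps over all minimal substitution pathways per
#' codon, skipping pathways through stop codons. Proportions are converted
#' to rates with the Jukes-Cantor correction d = -(3/4) ln(1 - (4/3) p).
#' Codons containing a gap or ambiguity character in either sequence, or an
#' (unexpected) stop codon, are skipped entirely.
#'
#' @param x an \linkS4class{OrthologPair}, or the first aligned coding
#'   sequence (character / DNAString).
#' @param y the second aligned coding sequence when \code{x} is a sequence.
#' @return named list: \code{Ka}, \code{Ks}, \code{Ka_Ks} (NA when Ks = 0),
#'   \code{S}, \code{N} site counts and the compared codon count.
#' @examples
#' neiGojoboriRates("TTATCA", "TTGTCA")  # one synonymous Leu change
#' @export
neiGojoboriRates <- function(x, y = NULL) {
  if (is(x, "OrthologPair")) {
    seqs <- as.character(codingAlignment(x))
    s1 <- seqs[1]; s2 <- seqs[2]
  } else {
    s1 <- toupper(as.character(x)); s2 <- toupper(as.character(y))
  }
  if (nchar(s1) != nchar(s2)) stop("aligned sequences differ in length")
  v1 <- strsplit(s1, "")[[1]]; v2 <- strsplit(s2, "")[[1]]
  keep <- v1 != "-" & v2 != "-"
  v1 <- v1[keep]; v2 <- v2[keep]
  ncod <- floor(length(v1) / 3)
  if (ncod == 0L) stop("no complete codons to compare")
  st <- synSiteTable()
  s_per_codon <- rowSums(st)
  gc <- geneticCode()
  i3 <- 3L * seq_len(ncod)
  cod1 <- paste0(v1[i3 - 2L], v1[i3 - 1L], v1[i3])
  cod2 <- paste0(v2[i3 - 2L], v2[i3 - 1L], v2[i3])
  ok <- cod1 %in% names(gc) & cod2 %in% names(gc)
  ok[ok] <- gc[cod1[ok]] != "*" & gc[cod2[ok]] != "*"
  used <- sum(ok)
  if (used == 0L) stop("no comparable codons")
  S1 <- sum(s_per_codon[cod1[ok]]); S2 <- sum(s_per_codon[cod2[ok]])
  Sd <- 0; Nd <- 0
  for (i in which(ok & cod1 != cod2)) {
    d <- codonPairDiffs(cod1[i], cod2[i])
    Sd <- Sd + d[["sd"]]; Nd <- Nd + d[["nd"]]
  }
  S <- (S1 + S2) / 2
  N <- 3 * used - S
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  Ks <- jukesCantor(pS)
  Ka <- jukesCantor(pN)
  list(Ka = Ka, Ks = Ks, Ka_Ks = if (Ks > 0) Ka / Ks else NA_real_,
       S = S, N = N, n_codons = used)
}

jukesCantor <- function(p) {
  if (p >= 0.75) stop("substitution proportion saturated (p >= 3/4)")
  -0.75 * log(1 - 4 * p / 3)
}

#' Screen ortholog pairs by hit uniqueness and structure conservation
#'
#' Queries matched by more than one candidate ortholog are discarded. Among
#' uniquely matched pairs, the fraction of aligned columns whose
#' exon/intron annotation state agrees between the two species must reach
#' \code{conservation_threshold}.
#'
#' @param hit_table data.frame with \code{query}, \code{subject} columns
#'   (one row per candidate ortholog).
#' @param alignments named list of \linkS4class{OrthologPair}s keyed by
#'   query id; each must carry a 2-row annotation \code{states} matrix.
#' @param conservation_threshold minimum matching-column fraction
#'   (default 0.8).
#' @return the retained subset of \code{alignments}.
#' @export
screenOrthologs <- function(hit_table, alignments,
                            conservation_threshold = 0.8) {
  nhits <- table(hit_table$query)
  unique_q <- names(nhits)[nhits == 1L]
  keep <- character()
  for (q in unique_q) {
    pair <- alignments[[q]]
    if (is.null(pair)) stop("alignment missing for retained hit: ", q)
    st <- pair@states
    if (ncol(st) == 0L) stop("annotation states missing for: ", q)
    frac <- mean(st[1, ] == st[2, ])
    if (frac >= conservation_threshold) keep <- c(keep, q)
  }
  alignments[keep]
}

#' Discard gene pairs with saturated synonymous divergence
#'
#' @param divergences data.frame with a \code{Ks} column.
#' @param ks_max maximum retained Ks (default 0.1; strictly greater values
#'   are discarded).
#' @return \code{divergences} with a logical \code{retained} column.
#' @export
ksFilter <- function(divergences, ks_max = 0.1) {
  divergences$retained <- divergences$Ks <= ks_max
  divergences
}

#' Intron substitution rate as p-distance
#'
#' Proportion of differing columns among comparable columns; columns with a
#' gap in either row and repeat-masked columns are excluded.
#'
#' @param x an \linkS4class{OrthologPair} (its first intron alignment), or
#'   the first aligned intron sequence.
#' @param y second aligned sequence (when \code{x} is a sequence).
#' @param mask logical vector, TRUE = repeat-masked column.
#' @return p-distance K_I.
#' @export
intronPDistance <- function(x, y = NULL, mask = NULL) {
  if (is(x, "OrthologPair")) {
    seqs <- as.character(intronAlignments(x)[[1]])
    mask <- repeatMasks(x)[[1]]
    s1 <- seqs[1]; s2 <- seqs[2]
  } else {
    s1 <- toupper(as.character(x)); s2 <- toupper(as.character(y))
  }
  v1 <- strsplit(s1, "")[[1]]; v2 <- strsplit(s2, "")[[1]]
  if (length(v1) != length(v2)) stop("aligned introns differ in length")
  if (is.null(mask)) mask <- rep(FALSE, length(v1))
  if (length(mask) != length(v1)) stop("mask length mismatch")
  comparable <- !mask & v1 != "-" & v2 != "-"
  if (!any(comparable)) stop("no comparable columns")
  sum(v1[comparable] != v2[comparable]) / sum(comparable)
}

#' Per-group aggregate substitution rates
#'
#' The group Ka/Ks aggregate is the ratio of means, mean(Ka)/mean(Ks), over
#' retained genes (per-gene ratios are unstable as Ks approaches 0); the
#' per-gene-mean alternative is available via \code{aggregate = "mean_ratio"}.
#' A \code{Ki} column, when present, is averaged per group.
#'
#' @param divergences data.frame with \code{Ka}, \code{Ks}, optional
#'   \code{Ki} and \code{retained} columns.
#' @param group group label per row.
#' @param aggregate \code{"ratio_of_means"} (default) or
#'   \code{"mean_ratio"}.
#' @return data.frame: one row per group with \code{n}, \code{ka_ks},
#'   \code{mean_ka}, \code{mean_ks} and (if available) \code{mean_ki}.
#' @export
groupRateSummary <- function(divergences, group,
                             aggregate = c("ratio_of_means", "mean_ratio")) {
  aggregate <- match.arg(aggregate)
  if (!"retained" %in% colnames(divergences)) divergences$retained <- TRUE
  d <- divergences[divergences$retained, , drop = FALSE]
  g <- group[divergences$retained]
  if (any(table(g) == 0L) || nrow(d) == 0L) stop("empty group")
  out <- do.call(rbind, lapply(split(seq_len(nrow(d)), g), function(i) {
    mka <- mean(d$Ka[i]); mks <- mean(d$Ks[i])
    kaks <- if (aggregate == "ratio_of_means") {
      if (mks > 0) mka / mks else NA_real_
    } else {
      ok <- d$Ks[i] > 0
      if (any(ok)) mean(d$Ka[i][ok] / d$Ks[i][ok]) else NA_real_
    }
    data.frame(n = length(i), ka_ks = kaks, mean_ka = mka, mean_ks = mks,
               mean_ki = if ("Ki" %in% colnames(d))
                 mean(d$Ki[i], na.rm = TRUE) else NA_real_)
  }))
  out$group <- rownames(out)
  rownames(out) <- NULL
  out[, c("group", "n", "ka_ks", "mean_ka", "mean_ks", "mean_ki")]
}

#' Permutation test for a difference between two groups
#'
#' Group labels are permuted; the p-value is one-sided in the observed
#' direction with the add-one correction. The statistic is either the
#' difference of group means (numeric inputs) or the difference of group
#' Ka/Ks aggregates, mean(Ka)/mean(Ks) (data.frame inputs with \code{Ka},
#' \code{Ks} columns).
#'
#' @param values_a,values_b numeric vectors, or data.frames with \code{Ka}
#'   and \code{Ks} columns.
#' @param n_perm number of permutations (default 1e6; reduce for quick
#'   runs).
#' @param seed RNG seed.
#' @param statistic \code{"mean_diff"} or \code{"aggregate_ratio_diff"}
#'   (chosen automatically from the input type when missing).
#' @return list with \code{observed}, \code{p_value}, \code{n_perm},
#'   \code{direction}.
#' @export
groupPermutationTest <- function(values_a, values_b, n_perm = 1e6, seed = 1L,
                                 statistic = NULL) {
  stopifnot(n_perm >= 1)
  if (is.null(statistic))
    statistic <- if (is.data.frame(values_a)) "aggregate_ratio_diff"
                 else "mean_diff"
  if (statistic == "aggregate_ratio_diff") {
    ka <- c(values_a$Ka, values_b$Ka)
    ks <- c(values_a$Ks, values_b$Ks)
    na <- nrow(values_a); n <- length(ka)
    stat <- function(ia) mean(ka[ia]) / mean(ks[ia]) -
      mean(ka[-ia]) / mean(ks[-ia])
  } else {
    v <- c(values_a, values_b)
    na <- length(values_a); n <- length(v)
    stat <- function(ia) mean(v[ia]) - mean(v[-ia])
  }
  if (na == 0L || na == n) stop("both groups must be non-empty")
  obs <- stat(seq_len(na))
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) stat(sample.int(n, na)), 0)
  direction <- if (obs >= 0) "greater" else "less"
  p <- permPValue(obs, null, direction)
  list(observed = obs, p_value = p, n_perm = as.integer(n_perm),
       direction = direction)
}
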