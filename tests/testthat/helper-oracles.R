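# Independent brute-force oracles used to verify the package implementations.
# These deliberately re-derive each quantity from first principles rather
# than calling the code under test.

# --- heterochromatic domain caller oracle -----------------------------------
# Enumerates every maximal run of called sites with a plain loop and applies
# the two thresholds.
oracleDomains <- function(chrom, pos, level, called, min_sites = 5,
                          min_mean = 0.5) {
  out <- list()
  run <- integer()
  flush <- function(run) {
    if (length(run) >= min_sites && mean(level[run]) >= min_mean)
      out[[length(out) + 1L]] <<- data.frame(
        chrom = chrom[run[1]], start = min(pos[run]), end = max(pos[run]),
        n_sites = length(run), mean_mCHG = mean(level[run]))
  }
  for (i in seq_along(pos)) {
    if (called[i] && (length(run) == 0L || chrom[i] == chrom[run[1]])) {
      run <- c(run, i)
    } else {
      flush(run)
      run <- if (called[i]) i else integer()
    }
  }
  flush(run)
  if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               n_sites = integer(), mean_mCHG = numeric())
}

# --- Nei-Gojobori oracle ----------------------------------------------------
# Recursive pathway enumeration over differing codon positions; site counts
# recomputed from the genetic code from scratch.
oracleGeneticCode <- Biostrings::GENETIC_CODE

oracleSynSites <- function(codon) {
  total <- 0
  for (pos in 1:3) {
    nsyn <- 0; nother <- 0
    for (b in c("A", "C", "G", "T")) {
      if (b == substr(codon, pos, pos)) next
      alt <- codon
      substr(alt, pos, pos) <- b
      if (oracleGeneticCode[[alt]] == "*") next
      if (oracleGeneticCode[[alt]] == oracleGeneticCode[[codon]])
        nsyn <- nsyn + 1 else nother <- nother + 1
    }
    total <- total + if (nsyn + nother > 0) nsyn / (nsyn + nother) else 0
  }
  total
}

oraclePathways <- function(c1, c2) {
  diffs <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  recur <- function(cur, remaining, sd, nd, blocked) {
    if (!length(remaining))
      return(list(c(sd = sd, nd = nd, blocked = blocked)))
    res <- list()
    for (p in remaining) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      step_syn <- oracleGeneticCode[[cur]] == oracleGeneticCode[[nxt]]
      res <- c(res, recur(nxt, setdiff(remaining, p),
                          sd + step_syn, nd + !step_syn,
                          blocked || oracleGeneticCode[[nxt]] == "*"))
    }
    res
  }
  m <- do.call(rbind, recur(c1, diffs, 0, 0, FALSE))
  ok <- m[, "blocked"] == 0
  if (!any(ok)) ok <- rep(TRUE, nrow(m))
  c(sd = mean(m[ok, "sd"]), nd = mean(m[ok, "nd"]))
}

oracleNeiGojobori <- function(s1, s2) {
  v1 <- strsplit(s1, "")[[1]]; v2 <- strsplit(s2, "")[[1]]
  keep <- v1 != "-" & v2 != "-"
  v1 <- v1[keep]; v2 <- v2[keep]
  ncod <- length(v1) %/% 3
  S <- 0; Sd <- 0; Nd <- 0; used <- 0
  Ssum1 <- 0; Ssum2 <- 0
  for (i in seq_len(ncod)) {
    c1 <- paste(v1[(3 * i - 2):(3 * i)], collapse = "")
    c2 <- paste(v2[(3 * i - 2):(3 * i)], collapse = "")
    if (!all(strsplit(paste0(c1, c2), "")[[1]] %in% c("A", "C", "G", "T")))
      next
    if (oracleGeneticCode[[c1]] == "*" || oracleGeneticCode[[c2]] == "*")
      next
    used <- used + 1
    Ssum1 <- Ssum1 + oracleSynSites(c1)
    Ssum2 <- Ssum2 + oracleSynSites(c2)
    if (c1 != c2) {
      pw <- oraclePathways(c1, c2)
      Sd <- Sd + pw[["sd"]]; Nd <- Nd + pw[["nd"]]
    }
  }
  S <- (Ssum1 + Ssum2) / 2
  N <- 3 * used - S
  jc <- function(p) -0.75 * log(1 - 4 * p / 3)
  list(Ka = jc(Nd / N), Ks = jc(Sd / S), S = S, N = N)
}

randomCodingPair <- function(n_codons, n_subs = 3) {
  sense <- names(oracleGeneticCode)[oracleGeneticCode != "*"]
  a <- sample(sense, n_codons, replace = TRUE)
  s1 <- paste(a, collapse = "")
  v <- strsplit(s1, "")[[1]]
  for (k in seq_len(n_subs)) {
    repeat {
      i <- sample(length(v), 1)
      b <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
      w <- v; w[i] <- b
      cod <- paste(w[(3 * ((i - 1) %/% 3) + 1):(3 * ((i - 1) %/% 3) + 3)],
                   collapse = "")
      if (oracleGeneticCode[[cod]] != "*") { v <- w; break }
    }
  }
  c(s1, paste(v, collapse = ""))
}

# --- ROKU entropy oracle ----------------------------------------------------
oracleRokuEntropy <- function(x, c_const = 5, epsilon = 1e-4) {
  med <- stats::median(x)
  mad0 <- stats::median(abs(x - med))
  u <- (x - med) / (c_const * mad0 + epsilon)
  w <- rep(0, length(x))
  inside <- abs(u) <= 1
  w[inside] <- (1 - u[inside]^2)^2
  tbi <- sum(w * x) / sum(w)
  d <- abs(x - tbi)
  if (sum(d) == 0) return(log2(length(x)))
  p <- d / sum(d)
  h <- 0
  for (pi in p) if (pi > 0) h <- h - pi * log2(pi)
  h
}

# --- Benjamini-Hochberg step-up reference -----------------------------------
oracleBH <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(n / (n:1) * p[o]))[ro]
  q
}

# --- Fisher two-sided via hypergeometric support enumeration ----------------
oracleFisherTwoSided <- function(a, b, c, d) {
  m <- a + c          # column-1 total
  n_ <- b + d         # column-2 total
  k <- a + b          # row-1 total
  support <- max(0, k - n_):min(k, m)
  probs <- stats::dhyper(support, m, n_, k)
  p_obs <- stats::dhyper(a, m, n_, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# --- Wilcoxon rank-sum effect size via explicit U computation ---------------
oracleEffectSize <- function(a, b) {
  U <- 0
  for (x in a) for (y in b) U <- U + (x > y) + 0.5 * (x == y)
  na <- length(a); nb <- length(b); N <- na + nb
  muU <- na * nb / 2
  tt <- table(c(a, b))
  varU <- na * nb / 12 * ((N + 1) - sum(tt^3 - tt) / (N * (N - 1)))
  z <- (U - muU) / sqrt(varU)
  abs(z) / sqrt(N)
}

# --- random gene-model construction -----------------------------------------
randomTranscript <- function(tx_id, gene_id, chrom, n_exons, strand) {
  starts <- integer(n_exons); ends <- integer(n_exons)
  pos <- sample(1:500, 1)
  for (e in seq_len(n_exons)) {
    starts[e] <- pos
    ends[e] <- pos + sample(20:200, 1)
    pos <- ends[e] + 1 + sample(30:300, 1)
  }
  GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends),
                         strand = strand, gene_id = gene_id,
                         transcript_id = tx_id)
}
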