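test_that("intron derivation handles strand, ordinals and degenerate cases", {
  # single-exon transcript: no inter-exon gap
  single <- GRanges("chr1", IRanges(1, 100), strand = "+",
                    gene_id = "g1", transcript_id = "t1")
  expect_length(deriveIntrons(single), 0L)

  ex <- GRanges("chr1", IRanges(c(1, 201, 401), c(100, 300, 500)),
                strand = "+", gene_id = "g1", transcript_id = "t1")
  ip <- deriveIntrons(ex)
  expect_equal(start(ip), c(101L, 301L))
  expect_equal(end(ip), c(200L, 400L))
  expect_equal(ip$ordinal, c(1L, 2L))

  strand(ex) <- "-"
  im <- deriveIntrons(ex)
  # 5'-most intron on the minus strand is the genomically last gap
  expect_equal(im$ordinal[start(im) == 301], 1L)
  expect_equal(im$ordinal[start(im) == 101], 2L)
  # identical intervals on both strands
  expect_equal(ranges(im), ranges(ip))
})

test_that("intron ordinals match exhaustive manual assignment on random models", {
  set.seed(11)
  for (rep in 1:20) {
    strand <- sample(c("+", "-"), 1)
    n_ex <- sample(2:7, 1)
    tx <- randomTranscript("t", "g", "chr1", n_ex, strand)
    introns <- deriveIntrons(tx)
    expect_length(introns, n_ex - 1L)
    # manual: gaps between sorted exons, ordinals reversed on minus strand
    st <- sort(start(tx)); en <- sort(end(tx))
    gaps_start <- en[-n_ex] + 1L
    gaps_end <- st[-1L] - 1L
    expected_ord <- if (strand == "+") seq_len(n_ex - 1L) else
      rev(seq_len(n_ex - 1L))
    o <- order(start(introns))
    expect_equal(start(introns)[o], gaps_start)
    expect_equal(end(introns)[o], gaps_end)
    expect_equal(introns$ordinal[o], expected_ord)
  }
})

test_that("malformed annotations are rejected with the transcript named", {
  bad <- GRanges("chr1", IRanges(c(1, 50), c(100, 200)), strand = "+",
                 gene_id = "g1", transcript_id = "tx_bad")
  expect_error(deriveIntrons(bad), "tx_bad")
})

test_that("total intron count equals sum over transcripts of exons minus one", {
  set.seed(7)
  txs <- lapply(1:15, function(i)
    randomTranscript(paste0("t", i), paste0("g", i), "chr1",
                     sample(1:6, 1), sample(c("+", "-"), 1)))
  exons <- do.call(c, txs)
  n_ex <- table(exons$transcript_id)
  expect_length(deriveIntrons(exons), sum(n_ex - 1L))
})

test_that("reversing strand reverses ordinals but preserves intervals", {
  set.seed(21)
  tx <- randomTranscript("t1", "g1", "chr2", 6, "+")
  fwd <- deriveIntrons(tx)
  strand(tx) <- "-"
  rev_ <- deriveIntrons(tx)
  expect_equal(ranges(sort(fwd)), ranges(sort(rev_)))
  o1 <- order(start(fwd)); o2 <- order(start(rev_))
  expect_equal(fwd$ordinal[o1], rev(rev_$ordinal[o2]))
})

test_that("bin densities agree with a per-feature loop and conserve totals", {
  lens <- c(chrA = 1000L, chrB = 2500L)
  # empty input: all bins zero
  empty <- densityInBins(GRanges(), lens, 500)
  expect_true(all(empty$count == 0L))
  # three features starting in the first bin of a 2-bin chromosome
  f3 <- GRanges("chrA", IRanges(c(10, 20, 400), width = 50))
  d3 <- densityInBins(f3, c(chrA = 1000L), 500)
  expect_equal(d3$count, c(3L, 0L))

  set.seed(5)
  chr <- sample(names(lens), 1000, replace = TRUE)
  st <- ifelse(chr == "chrA", sample(900, 1000, TRUE), sample(2400, 1000, TRUE))
  feats <- GRanges(chr, IRanges(st, width = sample(10, 1000, TRUE)))
  bins <- densityInBins(feats, lens, 300)
  expect_equal(sum(bins$count), length(feats))
  # naive loop oracle
  naive <- integer(length(bins))
  for (i in seq_along(feats)) {
    hit <- which(as.character(seqnames(bins)) == as.character(seqnames(feats[i])) &
                 start(bins) <= start(feats[i]) & end(bins) >= start(feats[i]))
    naive[hit] <- naive[hit] + 1L
  }
  expect_equal(bins$count, naive)
  expect_error(densityInBins(GRanges("chrA", IRanges(1500, 1600)), lens, 500),
               "out of")
})

test_that("GFF3 and BED round-trips preserve intervals and identifiers", {
  set.seed(9)
  txs <- lapply(1:8, function(i)
    randomTranscript(sprintf("t%02d", i), sprintf("g%02d", i), "chr1",
                     sample(1:5, 1), sample(c("+", "-"), 1)))
  exons <- do.call(c, txs)
  path <- tempfile(fileext = ".gff3")
  writeGeneModels(exons, path)
  back <- readGeneModels(path)
  o1 <- order(exons$transcript_id, start(exons))
  o2 <- order(back$transcript_id, start(back))
  expect_equal(start(exons)[o1], start(back)[o2])
  expect_equal(end(exons)[o1], end(back)[o2])
  expect_equal(exons$transcript_id[o1], back$transcript_id[o2])
  expect_equal(exons$gene_id[o1], back$gene_id[o2])
  expect_equal(as.character(strand(exons))[o1], as.character(strand(back))[o2])

  bed <- GRanges("chr3", IRanges(c(1, 100, 5000), c(10, 250, 5001)),
                 name = c("a", "b", "c"), score = c(0, 500, 1000))
  bp <- tempfile(fileext = ".bed")
  writeBedIntervals(bed, bp)
  bback <- readBedIntervals(bp)
  expect_equal(start(bed), start(bback))
  expect_equal(end(bed), end(bback))
  expect_equal(bed$name, bback$name)
})

test_that("cytosine report round-trip is exact and header is auto-detected", {
  sites <- CytosineSites(rep(c("chr1", "chr2"), 3), c(5, 10, 15, 4, 8, 12),
                         rep(c("+", "-"), 3), rep(c("CG", "CHG", "CHH"), 2),
                         0:5, 5:0)
  p1 <- tempfile(); p2 <- tempfile()
  writeCytosineReport(sites, p1, header = TRUE)
  writeCytosineReport(sites, p2, header = FALSE)
  for (p in c(p1, p2)) {
    back <- readCytosineReport(p)
    expect_equal(start(back), start(sites))
    expect_equal(back$context, sites$context)
    expect_equal(back$n_meth, sites$n_meth)
    expect_equal(back$n_unmeth, sites$n_unmeth)
  }
})

test_that("CytosineSites validity rejects bad contexts and counts", {
  expect_error(CytosineSites("chr1", 1, "+", "CHX", 1, 1), "context")
  expect_error(CytosineSites("chr1", 1, "+", "CG", -1, 1), "non-negative")
})
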