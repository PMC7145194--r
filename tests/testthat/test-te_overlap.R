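test_that("repeat-hit filters apply the published thresholds", {
  hits <- data.frame(
    chrom = "chr1", start = c(1, 1, 1, 1, 1),
    end = c(90, 150, 150, 150, 150), strand = "+",
    repeat_family = "LTR/Gypsy",
    library_length = c(100, 300, 180, 180, 180),
    divergence = c(0.05, 0.15, 0.15, 0.25, 0.15),
    is_te = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  out <- filterRepeatHits(hits)
  # row1: 90 bp < 100 -> out; row2: coverage 150/300 = 0.5 -> out
  # row3: kept; row4: divergence 0.25 -> out; row5: non-TE -> out
  expect_equal(nrow(out), 1L)
  expect_equal(out$library_length, 180)
  # idempotence
  expect_identical(filterRepeatHits(out), out)
})

test_that("MITE filter keeps only perfect full-length strong hits", {
  h <- data.frame(qseqid = c("m1", "m2", "m3", "m4"), sseqid = "chr1",
                  pident = c(100, 100, 99.5, 100),
                  length = c(200, 200, 200, 180),
                  mismatch = c(0L, 0L, 1L, 0L), gapopen = 0L,
                  qstart = 1L, qend = 200L, sstart = 1L, send = 200L,
                  evalue = c(1e-50, 1e-30, 1e-50, 1e-50), bitscore = 300,
                  qlen = 200L)
  out <- filterMiteHits(h)
  expect_equal(out$qseqid, "m1")
})

test_that("TE location classes follow the containment/overlap rules", {
  # two splice variants of one gene: TE regions can be exonic in one and
  # intronic in the other
  exons <- c(
    GRanges("chr1", IRanges(c(1001, 2001, 3001), c(1200, 2200, 3200)),
            strand = "+", gene_id = "g1", transcript_id = "t1"),
    GRanges("chr1", IRanges(c(1001, 1401, 3001), c(1200, 2600, 3200)),
            strand = "+", gene_id = "g1", transcript_id = "t2"))
  tes <- GRanges("chr1",
                 IRanges(c(1, 1150, 1500, 2500, 2700, 1050),
                         c(100, 1300, 1600, 2650, 2800, 1100)),
                 name = paste0("te", 1:6))
  cls <- classifyTeLocation(tes, exons)$location_class
  expect_equal(cls[1], "intergenic")     # between genes
  expect_equal(cls[2], "exon-intron")    # spans t1 exon1/intron1 junction
  expect_equal(cls[3], "exon/intron")    # intron of t1, inside exon2 of t2
  expect_equal(cls[4], "exon-intron")    # exon-intron in t2 wins over t1 intron
  expect_equal(cls[5], "intron")         # intron of both variants
  expect_equal(cls[6], "exon")           # inside exon 1 of both
  # partially genic TE
  edge <- GRanges("chr1", IRanges(900, 1100), name = "teE")
  expect_equal(classifyTeLocation(edge, exons)$location_class, "other")
})

test_that("location classes partition the TE set", {
  set.seed(13)
  ann <- simulateAnnotation(30, seed = 14)
  cls <- classifyTeLocation(ann$tes, ann$exons)$location_class
  expect_length(cls, length(ann$tes))
  expect_true(all(cls %in% c("intergenic", "other", "exon", "intron",
                             "exon-intron", "exon/intron")))
  # intronic TEs of the generator are placed fully inside introns
  intronic <- grepl("TE_intronic", ann$tes$name)
  expect_true(all(cls[intronic] == "intron"))
})

test_that("orientation bias test is exact, symmetric and capped", {
  expect_equal(teOrientationBiasTest(10, 10), 1.0)
  expect_equal(teOrientationBiasTest(15, 5),
               2 * sum(choose(20, 15:20)) / 2^20, tolerance = 1e-12)
  expect_equal(teOrientationBiasTest(0, 20), min(1, 2 * 2^-20),
               tolerance = 1e-12)
  for (ab in list(c(3, 9), c(0, 5), c(7, 7))) {
    expect_equal(teOrientationBiasTest(ab[1], ab[2]),
                 teOrientationBiasTest(ab[2], ab[1]))
  }
  expect_error(teOrientationBiasTest(0, 0), "zero")
})

test_that("TE methylation classes use per-context thresholds and exclusions", {
  sm <- data.frame(region_id = c("a", "b", "c"),
                   mean_CG = c(0.95, 0.85, NA), n_CG = c(10L, 10L, 2L),
                   mean_CHG = c(0.25, 0.19, 0.5), n_CHG = c(8L, 9L, 4L),
                   mean_CHH = c(0.05, 0.12, NA), n_CHH = c(7L, 6L, 0L))
  cls <- classifyTeMethylation(sm)
  expect_equal(cls$class_CG, c("high", "low", "excluded"))
  expect_equal(cls$class_CHG, c("high", "low", "excluded"))
  expect_equal(cls$class_CHH, c("low", "high", "excluded"))
})

test_that("venn counts match naive tabulation and degenerate cases", {
  none <- data.frame(heterochromatic = logical(3), contains_te = logical(3),
                     contains_repeat = logical(3))
  expect_true(all(vennHetIntronTeRepeat(none) == 0L))
  all3 <- data.frame(heterochromatic = TRUE, contains_te = TRUE,
                     contains_repeat = TRUE)
  expect_equal(vennHetIntronTeRepeat(all3)[["het+te+repeat"]], 1L)

  set.seed(8)
  d <- data.frame(heterochromatic = runif(500) < 0.3,
                  contains_te = runif(500) < 0.4,
                  contains_repeat = runif(500) < 0.2)
  v <- vennHetIntronTeRepeat(d)
  naive <- integer(7)
  for (i in seq_len(nrow(d))) {
    key <- paste0(as.integer(d$heterochromatic[i]),
                  as.integer(d$contains_te[i]),
                  as.integer(d$contains_repeat[i]))
    j <- match(key, c("100", "010", "001", "110", "101", "011", "111"))
    if (!is.na(j)) naive[j] <- naive[j] + 1L
  }
  expect_equal(unname(v), naive)
  expect_equal(sum(v), sum(d$heterochromatic | d$contains_te |
                             d$contains_repeat))
})

test_that("RepeatMasker .out parsing extracts coordinates and classes", {
  lines <- c(
    "   SW  perc perc perc  query      position in query           matching       repeat              position in  repeat",
    "score  div. del. ins.  sequence    begin     end    (left)    repeat         class/family         begin  end (left)   ID",
    "",
    "  463  10.4  0.0  0.0  chr1        100      399  (5000) +  RIRE2          LTR/Gypsy             1  300   (0)     1",
    "  300  25.0  0.0  0.0  chr1        600      690  (4700) C  OSAT           Simple_repeat       (0)   91     1     2")
  p <- tempfile(fileext = ".out")
  writeLines(lines, p)
  d <- readRepeatMaskerOut(p)
  expect_equal(nrow(d), 2L)
  expect_equal(d$chrom, c("chr1", "chr1"))
  expect_equal(d$start, c(100L, 600L))
  expect_equal(d$divergence, c(0.104, 0.25))
  expect_equal(d$is_te, c(TRUE, FALSE))
  expect_equal(d$library_length[1], 300L)
})
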