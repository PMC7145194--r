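mkPairs <- function(id, wt, mut) {
  data.frame(
    intron_id = id,
    sample_id = c("wt_1", "wt_2", "mut_1", "mut_2"),
    genotype = c("wt", "wt", "mut", "mut"),
    pre_count = c(wt[c(1, 3)], mut[c(1, 3)]),
    post_count = c(wt[c(2, 4)], mut[c(2, 4)]))
}

test_that("identical genotypes give null coefficients and large p", {
  pairs <- mkPairs("i1", c(100, 100, 100, 100), c(100, 100, 100, 100))
  res <- prePostRatioGlmTest(pairs, reference = "wt")
  expect_equal(res$coefficient, 0)
  expect_equal(res$p_value, 1)
  expect_false(res$significant)
})

test_that("a ten-fold post reduction is significant and 'down'", {
  pairs <- mkPairs("i1", c(100, 100, 100, 100), c(100, 5, 100, 5))
  res <- prePostRatioGlmTest(pairs, reference = "wt")
  expect_true(res$significant)
  expect_equal(res$direction, "down")
  # the aggregated G-test lower-bounds the chi-square: deviance is large
  expect_lt(res$p_value, 1e-10)
})

test_that("the closed-form LRT equals the glm deviance test exactly", {
  set.seed(53)
  for (rep in 1:10) {
    wt <- rpois(4, 80) + 1L
    mut <- rpois(4, 60) + 1L
    pairs <- mkPairs("i1", wt, mut)
    res <- prePostRatioGlmTest(pairs, reference = "wt")
    d <- pairs
    d$geno <- factor(d$genotype, levels = c("wt", "mut"))
    m1 <- glm(cbind(post_count, pre_count) ~ geno, binomial, d)
    m0 <- glm(cbind(post_count, pre_count) ~ 1, binomial, d)
    p_glm <- pchisq(m0$deviance - m1$deviance, 1, lower.tail = FALSE)
    expect_equal(res$p_value, p_glm, tolerance = 1e-9)
    expect_equal(res$coefficient, unname(coef(m1)[2]), tolerance = 1e-6)
  }
})

test_that("swapping genotype labels flips sign but preserves p and q", {
  set.seed(59)
  ids <- sprintf("i%02d", 1:20)
  pairs <- do.call(rbind, lapply(ids, function(id)
    mkPairs(id, rpois(4, 100) + 1L, rpois(4, 100) + 1L)))
  a <- prePostRatioGlmTest(pairs, reference = "wt")
  b <- prePostRatioGlmTest(pairs, reference = "mut")
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  expect_equal(a$q_value, b$q_value, tolerance = 1e-12)
  expect_equal(a$coefficient, -b$coefficient, tolerance = 1e-12)
})

test_that("low totals are skipped and separation is continuity-corrected", {
  pairs <- rbind(mkPairs("lowtot", c(2, 1, 1, 1), c(2, 1, 1, 1)),
                 mkPairs("sep", c(50, 50, 50, 50), c(60, 0, 55, 0)))
  res <- prePostRatioGlmTest(pairs, reference = "wt", min_total = 10)
  expect_true(is.na(res$p_value[res$intron_id == "lowtot"]))
  sep <- res[res$intron_id == "sep", ]
  expect_true(sep$corrected)
  expect_true(is.finite(sep$coefficient))
  expect_true(sep$significant)
})

test_that("BH q-values match an independent step-up implementation", {
  set.seed(67)
  ids <- sprintf("i%03d", 1:200)
  pairs <- do.call(rbind, lapply(seq_along(ids), function(k) {
    shift <- if (k <= 20) 4 else 1
    mkPairs(ids[k], rpois(4, 100) + 1L,
            c(rpois(2, 100) + 1L, rpois(2, 100 / shift) + 1L)[c(1, 3, 2, 4)])
  }))
  res <- prePostRatioGlmTest(pairs, reference = "wt")
  expect_equal(res$q_value, oracleBH(res$p_value), tolerance = 1e-12)
})

test_that("single-replicate binomial variant matches exact tails", {
  mutant <- data.frame(intron_id = c("i1", "i2"),
                       pre_count = c(100L, 100L), post_count = c(5L, 100L))
  control <- data.frame(intron_id = c("i1", "i2"),
                        pre_count = c(100L, 100L), post_count = c(100L, 100L))
  res <- prePostBinomialTest(mutant, control)
  # control proportion 0.5; exact two-sided binomial at (5, 105)
  want <- binom.test(5, 105, 0.5)$p.value
  expect_equal(res$p_value[res$intron_id == "i1"], want, tolerance = 1e-12)
  expect_equal(res$direction[res$intron_id == "i1"], "down")
  expect_gt(res$p_value[res$intron_id == "i2"], 0.5)
  # zero control total: skipped
  ctl0 <- data.frame(intron_id = "i1", pre_count = 0L, post_count = 0L)
  mut0 <- data.frame(intron_id = "i1", pre_count = 10L, post_count = 10L)
  res0 <- prePostBinomialTest(mut0, ctl0)
  expect_true(is.na(res0$p_value))
})

test_that("null simulation keeps the called fraction within the FDR bound", {
  set.seed(73)
  frac <- vapply(1:5, function(s) {
    ids <- sprintf("i%04d", 1:400)
    counts <- simulateIntronCounts(ids, data.frame(gene_id = character(),
                                                   fold = numeric()),
                                   seed = 900 + s)
    res <- prePostRatioGlmTest(counts, reference = "wt")
    mean(res$significant, na.rm = TRUE)
  }, 0)
  # under the null BH at q <= 0.01 rarely rejects anything at all
  expect_lt(mean(frac), 0.01 + 3 * sqrt(0.01 * 0.99 / 2000))
})

test_that("gene-level DEG intersection recovers simulated effects", {
  set.seed(79)
  ids <- sprintf("i%04d", 1:600)
  genes <- sub("i", "g", ids)
  gene_map <- data.frame(intron_id = ids, gene_id = genes)
  eff <- data.frame(gene_id = genes[1:50], fold = 10)
  res_sets <- lapply(1:2, function(k) {
    counts <- simulateIntronCounts(gene_map, eff, seed = 300 + k)
    prePostRatioGlmTest(counts, reference = "wt")
  })
  names(res_sets) <- c("cmpA", "cmpB")
  het_genes <- genes[1:80]
  out <- callDegsAndIntersect(res_sets, gene_map, het_genes)
  recovered <- mean(eff$gene_id %in% out$intersection)
  expect_gte(recovered, 0.9)
  expect_lt(out$het_enrichment$p_value, 1e-6)
  expect_equal(out$overlap_tests[[1]]$sets, "cmpA & cmpB")
  expect_lt(out$overlap_tests[[1]]$p_value, 1e-6)
  # disjoint and identical set behaviour
  fake <- list(
    A = data.frame(intron_id = ids[1:10], significant = TRUE),
    B = data.frame(intron_id = ids[11:20], significant = TRUE))
  expect_length(callDegsAndIntersect(fake, gene_map,
                                     het_genes)$intersection, 0L)
})

test_that("relative 5'/3' ratio is direct arithmetic", {
  expect_equal(relativeFiveThreeRatio(100, 100, 100, 100), 1.0)
  expect_equal(relativeFiveThreeRatio(100, 10, 100, 100), 10.0)
  set.seed(83)
  for (rep in 1:20) {
    v <- sample(1:500, 4)
    expect_equal(relativeFiveThreeRatio(v[1], v[2], v[3], v[4]),
                 (v[1] / v[2]) / (v[3] / v[4]))
  }
  expect_error(relativeFiveThreeRatio(1, 0, 1, 1), "positive")
})
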