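# Downstream statistics against closed forms and brute-force oracles.

test_that("similarity is the shared fraction of the union", {
  expect_equal(setSimilarity(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(setSimilarity(letters[1:3], letters[1:3]), 1)
  expect_equal(setSimilarity(c("a"), c("b")), 0)
  expect_error(setSimilarity(character(0), character(0)), "undefined")
  set.seed(1)
  for (i in 1:20) {
    a <- sample(letters, sample(1:10, 1))
    b <- sample(letters, sample(1:10, 1))
    expect_equal(setSimilarity(a, b), setSimilarity(b, a))
    if (!setequal(a, b)) expect_lt(setSimilarity(a, b), 1)
  }
})

test_that("gene proportion test matches hand-computed chi-square", {
  r <- geneProportionTest(c(10, 10), c(10, 10))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  r2 <- geneProportionTest(c(20, 0), c(0, 20))
  expect_equal(r2$statistic, 40)
  expect_equal(r2$df, 1)
  # skip rules
  expect_true(geneProportionTest(c(5, 0), c(1, 1))$skipped) # one isoform left
  expect_true(geneProportionTest(c(5, 5), c(0, 0))$skipped) # zero margin
})

test_that("chi-square matches the brute-force oracle on random tables", {
  set.seed(10)
  for (i in 1:1000) {
    k <- sample(2:5, 1)
    x1 <- rpois(k, 8) + 2
    x2 <- rpois(k, 8) + 2
    r <- geneProportionTest(x1, x2, min_reads = 0L)
    expect_equal(r$statistic, oracle_chisq(cbind(x1, x2)), tolerance = 1e-9)
  }
})

test_that("Fisher matches hypergeometric enumeration on random tables", {
  expect_equal(isoformFisher(rbind(c(2, 0), c(0, 2)))$p, 1 / 3,
               tolerance = 1e-12)
  expect_equal(isoformFisher(rbind(c(5, 5), c(5, 5)))$p, 1)
  expect_equal(isoformFisher(rbind(c(0, 0), c(3, 4)))$p, 1) # zero margin
  set.seed(11)
  for (i in 1:1000) {
    tab <- matrix(rpois(4, 5), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(isoformFisher(tab)$p, oracle_fisher2x2(tab),
                 tolerance = 1e-9)
  }
})

test_that("BH adjustment matches the step-up formula", {
  expect_equal(bhAdjust(0.05), 0.05)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(12)
  for (i in 1:1000) {
    p <- runif(sample(1:20, 1))
    a <- bhAdjust(p)
    expect_equal(a, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(diff(a[order(p)]) >= -1e-12)) # monotone in p ranks
  }
})

test_that("one-tailed binomial matches direct tail summation", {
  expect_equal(pbinom(9, 10, 0.5, lower.tail = FALSE), 0.5^10,
               tolerance = 1e-12)
  set.seed(13)
  for (i in 1:1000) {
    n <- sample(1:40, 1)
    x <- sample(0:n, 1)
    p <- runif(1)
    expect_equal(pbinom(x - 1, n, p, lower.tail = FALSE),
                 oracle_binom_upper(x, n, p), tolerance = 1e-9)
  }
})

test_that("differential-gene flags require both FDR and proportion shift", {
  expect_true(flagDifferentialGenes(0.04, 0.10))
  expect_false(flagDifferentialGenes(0.04, 0.03))
  expect_false(flagDifferentialGenes(0.06, 0.30))
})

test_that("null simulation is FDR-calibrated", {
  set.seed(14)
  n_genes <- 600
  flagged <- logical(n_genes)
  for (g in seq_len(n_genes)) {
    k <- sample(2:4, 1)
    props <- rexp(k) + 0.2
    props <- props / sum(props)
    x1 <- rmultinom(1, 120, props)[, 1]
    x2 <- rmultinom(1, 120, props)[, 1]
    r <- geneProportionTest(x1, x2)
    flagged[g] <- !r$skipped && !is.na(r$p) && r$p <= 0.05
  }
  # raw-alpha bound: BH only tightens this
  se <- sqrt(0.05 * 0.95 / n_genes)
  expect_lte(mean(flagged), 0.05 + 2 * se)
})

test_that("tissue-stable calls enforce strict proportion and read floors", {
  expect_true(tissueStable(c(8, 8, 8), c(10, 10, 10)))
  expect_false(tissueStable(c(5, 8, 8), c(10, 10, 10)))  # exactly 0.5
  expect_false(tissueStable(c(1, 8, 8), c(1, 10, 10)))   # count floor
})

test_that("tissue-specific calls cover both cases", {
  # case (i): a gene detected only in one tissue
  counts <- rbind(g1a = c(t1 = 5, t2 = 0, t3 = 0),
                  g1b = c(3, 0, 0),
                  g2a = c(4, 4, 4),
                  g2b = c(4, 4, 4))
  res <- tissueSpecific(counts, c("g1", "g1", "g2", "g2"))
  excl <- res[res$case == "exclusive", ]
  expect_setequal(excl$isoform, c("g1a", "g1b"))
  expect_true(all(excl$tissue == "t1"))
  # uniform proportions flag nothing
  expect_false(any(res$gene_id == "g2"))
  # case (ii): strong proportion shift in one tissue
  counts2 <- rbind(h1 = c(t1 = 40, t2 = 2, t3 = 2),
                   h2 = c(2, 40, 40))
  res2 <- tissueSpecific(counts2, c("h", "h"))
  expect_true(any(res2$isoform == "h1" & res2$tissue == "t1"))
  expect_true(all(res2$case == "proportion-shift"))
})

test_that("tau matches its closed forms and is scale-invariant", {
  expect_equal(tauIndex(c(5, 5, 5, 5)), 0)
  expect_equal(tauIndex(c(0, 0, 7, 0)), 1)
  expect_equal(tauIndex(c(8, 2, 2)), 0.75)
  expect_error(tauIndex(c(0, 0, 0)), "undefined")
  set.seed(15)
  for (i in 1:50) {
    x <- rexp(sample(2:12, 1))
    t1 <- tauIndex(x)
    expect_gte(t1, 0); expect_lte(t1, 1)
    expect_equal(tauIndex(x * 37.5), t1)
  }
})

test_that("enrichment test flags a diagonal table and spares the null", {
  strong <- c(rep(TRUE, 55), rep(FALSE, 55))
  gene <- c(rep(TRUE, 50), rep(FALSE, 5), rep(TRUE, 5), rep(FALSE, 50))
  r <- enrichmentTest(strong, gene)
  expect_lt(r$p, 1e-10)
  expect_gt(r$odds_ratio, 1)
  expect_equal(enrichmentTest(rep(TRUE, 10), rep(c(TRUE, FALSE), 5))$p, 1)
})

test_that("Alu classification matches the exhaustive oracle", {
  set.seed(16)
  for (w in c(1000L, 2000L)) {
    n_rep <- 200
    rep_start <- sample(1:50000, n_rep)
    reps <- GenomicRanges::GRanges("c", IRanges::IRanges(rep_start, width = 300),
                                   strand = sample(c("+", "-"), n_rep, TRUE))
    bsj_start <- sample(3000:45000, 60)
    bsj <- GenomicRanges::GRanges("c", IRanges::IRanges(bsj_start,
                                                        bsj_start + 800))
    got <- aluFlankClassify(bsj, reps, window = w)
    want <- vapply(seq_along(bsj), function(i)
      oracle_alu(bsj_start[i], bsj_start[i] + 800, rep_start,
                 rep_start + 299, as.character(GenomicRanges::strand(reps)),
                 w), character(1))
    expect_identical(got, want)
  }
  # declared convention: inward-pointing inverted pair is convergent
  reps <- GenomicRanges::GRanges("c", IRanges::IRanges(c(500, 2500),
                                                       width = 300),
                                 strand = c("+", "-"))
  bsj <- GenomicRanges::GRanges("c", IRanges::IRanges(1000, 2000))
  expect_identical(aluFlankClassify(bsj, reps, 1000L), "convergent")
  expect_identical(aluFlankClassify(bsj, reps[c()], 1000L), "none")
})

test_that("control BSJs respect geometry and exclusions", {
  td <- toy_model_data()
  set.seed(17)
  expect_warning(ctl <- makeControlBsjs(td$model, n = 10), "eligible")
  expect_equal(length(ctl), 6) # only 6 eligible start<end pairs exist
  expect_true(all(GenomicRanges::start(ctl) < GenomicRanges::end(ctl)))
  excl <- GenomicRanges::GRanges("chrT",
                                 IRanges::IRanges(td$ex_start[1],
                                                  td$ex_end[3]))
  ctl2 <- suppressWarnings(makeControlBsjs(td$model, exclude = excl, n = 10))
  expect_false(any(GenomicRanges::start(ctl2) == td$ex_start[1]))
  expect_false(any(GenomicRanges::end(ctl2) == td$ex_end[3]))
  # default n is 10,000
  expect_equal(formals(makeControlBsjs)$n, 10000L)
})

test_that("normalized BSJ count is a simple scale-invariant rate", {
  expect_equal(normalizedBsjCount(100, 1e6), 1e-4)
  expect_equal(normalizedBsjCount(0, 10), 0)
  expect_equal(normalizedBsjCount(200, 2e6), normalizedBsjCount(100, 1e6))
  expect_error(normalizedBsjCount(1, 0), "positive")
})
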