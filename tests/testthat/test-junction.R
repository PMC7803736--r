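# Spliced alignment, junction identification, splice-site correction and
# high-confidence filters.

test_that("concatemer doubling is exact", {
  expect_identical(makeConcatemer("ACGT"), "ACGTACGT")
  expect_error(makeConcatemer(""), "empty")
  set.seed(1)
  for (i in 1:5) {
    s <- rand_dna(sample(10:200, 1))
    expect_equal(nchar(makeConcatemer(s)), 2 * nchar(s))
  }
})

test_that("an exact spliced concatemer aligns with blocks tiling the exons", {
  td <- toy_model_data()
  q <- makeConcatemer(td$spliced)
  idx <- indexGenome(td$genome)
  recs <- splicedAlign(q, idx)
  best <- filterAlignments(recs, q, idx)
  expect_false(is.null(best))
  expect_identical(best$qstrand, "+")
  expect_equal(nrow(best$blocks), 6) # 3 exons x 2 copies, wrap between
  expect_setequal(unique(best$blocks[, "tstart"] + 1), td$ex_start)
  expect_setequal(unique(best$blocks[, "tend"]), td$ex_end)
  expect_equal(best$identity, 1)
})

test_that("random queries do not survive the alignment filter", {
  td <- toy_model_data()
  idx <- indexGenome(td$genome)
  set.seed(7)
  for (i in 1:100) {
    q <- rand_dna(400)
    best <- filterAlignments(splicedAlign(q, idx), q, idx)
    expect_true(is.null(best) || best$identity < 0.6)
  }
})

test_that("mild errors preserve the block structure within a few nt", {
  td <- toy_model_data()
  idx <- indexGenome(td$genome)
  set.seed(8)
  q <- circlong:::.apply_errors(makeConcatemer(td$spliced), 0.02, 0, 0)
  best <- filterAlignments(splicedAlign(q, idx), q, idx)
  expect_gte(nrow(best$blocks), 5)
  for (e in td$ex_end)
    expect_lte(min(abs(best$blocks[, "tend"] - e)), 5)
  for (st in td$ex_start)
    expect_lte(min(abs(best$blocks[, "tstart"] + 1 - st)), 5)
})

test_that("alignment filtering keeps the dominant record", {
  r1 <- list(chrom = "c", qstrand = "+", mapq = 60L, score = 50,
             blocks = cbind(qstart = 0, qend = 50, tstart = 0, tend = 50))
  r0 <- list(chrom = "c", qstrand = "+", mapq = 0L, score = 50,
             blocks = cbind(qstart = 0, qend = 50, tstart = 100, tend = 150))
  idx <- list(chroms = list(c = strrep("A", 200)), k = 13L)
  best <- filterAlignments(list(r1, r0), strrep("A", 50), idx)
  expect_equal(best$mapq, 60)
  expect_null(filterAlignments(list(r0), strrep("A", 50), idx))
  expect_null(filterAlignments(list(), "A", idx))
})

test_that("junction calling recovers planted structure exactly", {
  td <- toy_model_data()
  idx <- indexGenome(td$genome)
  q <- makeConcatemer(td$spliced)
  best <- filterAlignments(splicedAlign(q, idx), q, idx)
  jx <- callJunctions(best, td$gstr, td$model, unit_len = nchar(td$spliced))
  expect_true(jx$ok)
  expect_equal(jx$bsj$l, td$ex_start[1])
  expect_equal(jx$bsj$r, td$ex_end[3])
  expect_equal(jx$fsjs$l, td$ex_end[1:2])
  expect_equal(jx$fsjs$r, td$ex_start[2:3])
  expect_identical(jx$strand, "+")
  # single-exon circle: BSJ only, no FSJ
  single <- substr(td$gstr, td$ex_start[2], td$ex_end[2])
  bq <- makeConcatemer(single)
  b2 <- filterAlignments(splicedAlign(bq, idx), bq, idx)
  j2 <- callJunctions(b2, td$gstr, td$model, unit_len = nchar(single))
  expect_true(j2$ok)
  expect_equal(nrow(j2$fsjs), 0)
  expect_equal(j2$bsj$l, td$ex_start[2])
  expect_equal(j2$bsj$r, td$ex_end[2])
})

test_that("three-copy concatemers give the same junction set as two copies", {
  td <- toy_model_data()
  idx <- indexGenome(td$genome)
  q2 <- makeConcatemer(td$spliced)
  q3 <- paste0(td$spliced, td$spliced, td$spliced)
  b2 <- filterAlignments(splicedAlign(q2, idx), q2, idx)
  b3 <- filterAlignments(splicedAlign(q3, idx), q3, idx)
  j2 <- callJunctions(b2, td$gstr, td$model, unit_len = nchar(td$spliced))
  j3 <- callJunctions(b3, td$gstr, td$model, unit_len = nchar(td$spliced))
  expect_true(j3$ok)
  expect_equal(j3$bsj[c("l", "r")], j2$bsj[c("l", "r")])
  expect_equal(j3$fsjs[, c("l", "r")], j2$fsjs[, c("l", "r")])
})

test_that("splice-site correction snaps, is idempotent and falls through", {
  td <- toy_model_data()
  sites <- spliceSites(td$model)
  # off by 3 on one side: snapped to the annotated pair
  rf <- refineSpliceSites(td$ex_end[1] + 3L, td$ex_start[2],
                          "FSJ", td$gstr, sites)
  expect_equal(rf$l, td$ex_end[1])
  expect_equal(rf$r, td$ex_start[2])
  expect_identical(rf$strand, "+")
  expect_true(rf$annotated_left && rf$annotated_right)
  # already correct: unchanged (fixed point)
  rf2 <- refineSpliceSites(td$ex_end[1], td$ex_start[2], "FSJ", td$gstr, sites)
  expect_equal(rf2[c("l", "r")], list(l = td$ex_end[1], r = td$ex_start[2]))
  expect_equal(rf2$shifted, 0)
  # far from any annotated or canonical site: kept, low confidence
  empty_sites <- list(plus = list(starts = integer(0), ends = integer(0)),
                      minus = list(starts = integer(0), ends = integer(0)))
  g0 <- strrep("A", 500)
  rf3 <- refineSpliceSites(100L, 300L, "FSJ", g0, empty_sites)
  expect_equal(rf3$l, 100)
  expect_equal(rf3$r, 300)
  expect_identical(rf3$confidence, "low")
})

test_that("BSJ strand follows the back-splice motif", {
  # plus circle: AG upstream of start, GT downstream of end
  g <- paste0(strrep("A", 48), "AG", strrep("C", 50), "GT", strrep("A", 48))
  sites <- list(plus = list(starts = integer(0), ends = integer(0)),
                minus = list(starts = integer(0), ends = integer(0)))
  rf <- refineSpliceSites(51L, 100L, "BSJ", g, sites)
  expect_identical(rf$strand, "+")
  gm <- paste0(strrep("A", 48), "AC", strrep("G", 50), "CT", strrep("A", 48))
  rfm <- refineSpliceSites(51L, 100L, "BSJ", gm, sites)
  expect_identical(rfm$strand, "-")
})

test_that("confidence rules separate annotated and novel BSJs", {
  td <- toy_model_data()
  idx <- indexGenome(td$genome)
  q <- makeConcatemer(td$spliced)
  best <- filterAlignments(splicedAlign(q, idx), q, idx)
  jx <- callJunctions(best, td$gstr, td$model, unit_len = nchar(td$spliced))
  db <- circDb(GenomicRanges::GRanges(
    "chrT", IRanges::IRanges(td$ex_start[1], td$ex_end[3])), "dbA")
  conf <- evaluateConfidence(jx, q, td$gstr, db, "chrT")
  expect_true(conf$bsj_known)
  expect_true(conf$bsj_high)
  expect_true(conf$fsj_all_high)
  # novel BSJ (no DB, sites absent from annotation): clean window passes,
  # a 3-mismatch window fails the 0.98 identity floor
  empty <- geneModel(GenomicRanges::GRangesList(
    tx = GenomicRanges::GRanges("chrT", IRanges::IRanges(1, 2),
                                strand = "+")), c(tx = "gX"))
  jn <- callJunctions(best, td$gstr, empty, unit_len = nchar(td$spliced))
  expect_true(jn$ok)
  confn <- evaluateConfidence(jn, q, td$gstr, NULL, "chrT")
  expect_true(confn$bsj_high)
  expect_false(confn$bsj_known)
  qbad <- q
  p <- jn$bsj$qc
  for (d in c(-5L, 0L, 5L))
    substr(qbad, p + d, p + d) <- setdiff(c("A", "C", "G", "T"),
                                          substr(q, p + d, p + d))[1]
  confb <- evaluateConfidence(jn, qbad, td$gstr, NULL, "chrT")
  expect_false(confb$bsj_high)
})

test_that("error-free simulated reads give exact junction recovery", {
  cfg <- simConfig(seed = 14, n_genes = 6, n_isoforms = 10,
                   reads_per_isoform = 2, sub_rate = 0, ins_rate = 0,
                   del_rate = 0)
  sim <- simulateCircData(cfg)
  cs <- callConsensusSet(sim$reads)
  calls <- callCircReads(cs$records, sim$genome, sim$model, sim$circdb)
  ok <- calls[is.na(calls$drop_reason), ]
  expect_equal(nrow(ok), nrow(calls))
  keys <- circlong:::.isoform_key(ok$chrom, ok$strand, ok$bsj_start,
                                  ok$bsj_end, ok$fsj)
  truth <- sim$isoforms$key[match(
    sim$read_truth$isoform_id[match(ok$read_id, sim$read_truth$read_id)],
    sim$isoforms$isoform_id)]
  expect_identical(keys, truth)
  # direction conventions hold for every emitted junction
  expect_true(all(ok$bsj_start < ok$bsj_end))
  fs <- do.call(rbind, lapply(ok$fsj, circlong:::.parse_fsj))
  expect_true(all(fs[, "l"] < fs[, "r"]))
})
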