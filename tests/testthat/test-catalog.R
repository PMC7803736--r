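# Catalog collapse, classification, gene assignment, naming and
# alternative-splicing event typing.

# hand-built calls table: two samples, three reads of isoform A, one of B
toy_calls <- function() {
  a <- data.frame(read_id = paste0("r", 1:3), sample = "s1", chrom = "chrT",
                  strand = "+", bsj_start = 201, bsj_end = 1050,
                  fsj = "300-501|650-901", blocks = "201-300;501-650;901-1050",
                  bsj_known = TRUE, bsj_high = TRUE, fsj_all_high = TRUE,
                  copy_number = 10, drop_reason = NA_character_,
                  stringsAsFactors = FALSE)
  b <- a[1, ]
  b$read_id <- "r4"; b$sample <- "s2"
  b$fsj <- "300-901"; b$blocks <- "201-300;901-1050"
  rbind(a, b)
}

test_that("reads with identical keys merge and counts conserve", {
  x <- collapseIsoforms(toy_calls())
  expect_s4_class(x, "CircCatalog")
  expect_equal(nrow(x), 2)
  cn <- SummarizedExperiment::assay(x, "counts")
  expect_equal(unname(sort(rowSums(cn))), c(1, 3))
  # BSJ-level count equals the sum over isoforms sharing the BSJ
  bc <- S4Vectors::metadata(x)$bsj_counts
  expect_equal(unname(rowSums(bc)), 4)
  expect_equal(sum(cn), sum(bc))
  # read-count cutoff drops singletons
  x2 <- collapseIsoforms(toy_calls(), min_count = 2)
  expect_equal(nrow(x2), 1)
})

test_that("low-confidence reads never enter the isoform catalog", {
  calls <- toy_calls()
  calls$fsj_all_high[4] <- FALSE
  x <- collapseIsoforms(calls)
  expect_equal(nrow(x), 1)
  # ... but still count toward the BSJ catalog
  expect_equal(unname(rowSums(S4Vectors::metadata(x)$bsj_counts)), 4)
  calls$bsj_high[1:3] <- FALSE
  x2 <- collapseIsoforms(calls)
  expect_equal(unname(rowSums(S4Vectors::metadata(x2)$bsj_counts)), 1)
})

test_that("known/novel classification follows exact DB membership", {
  x <- collapseIsoforms(toy_calls())
  db1 <- GenomicRanges::GRanges("chrT", IRanges::IRanges(201, 1050))
  db <- circDb(c(db1, db1), source = c("dbA", "dbB"))
  x <- classifyBsjKnown(x, db)
  rd <- SummarizedExperiment::rowData(x)
  expect_true(all(rd$bsj_known == "known"))
  expect_true(all(rd$known_dbA & rd$known_dbB))
  dbp <- circDb(GenomicRanges::GRanges("chrT", IRanges::IRanges(999, 1050)),
                "dbA")
  x2 <- classifyBsjKnown(collapseIsoforms(toy_calls()), dbp)
  expect_true(all(SummarizedExperiment::rowData(x2)$bsj_known == "novel"))
})

test_that("BSJ categories follow the FSM/NIC/NNC rules", {
  td <- toy_model_data()
  x <- collapseIsoforms(toy_calls())
  db_in <- circDb(GenomicRanges::GRanges("chrT", IRanges::IRanges(201, 1050)),
                  "dbA")
  db_out <- circDb(GenomicRanges::GRanges("chrT", IRanges::IRanges(5, 9)),
                   "dbA")
  expect_true(all(SummarizedExperiment::rowData(
    classifyBsjCategory(x, db_in, td$model))$bsj_category == "FSM"))
  # not in DB but both sites annotated -> NIC
  expect_true(all(SummarizedExperiment::rowData(
    classifyBsjCategory(x, db_out, td$model))$bsj_category == "NIC"))
  # one unannotated site -> NNC
  calls <- toy_calls()
  calls$bsj_end <- 1040
  x3 <- classifyBsjCategory(collapseIsoforms(calls), db_out, td$model)
  expect_true(all(SummarizedExperiment::rowData(x3)$bsj_category == "NNC"))
})

test_that("FSJ categories: sub-chain FSM, annotated recombination NIC", {
  td <- toy_model_data()
  x <- classifyFsjCategory(collapseIsoforms(toy_calls()), td$model)
  rd <- SummarizedExperiment::rowData(x)
  # full chain = transcript junctions -> FSM; exon skip = novel pairing of
  # annotated sites -> NIC
  expect_identical(unname(rd$fsj_category[rd$fsj == "300-501|650-901"]), "FSM")
  expect_identical(unname(rd$fsj_category[rd$fsj == "300-901"]), "NIC")
  # single-exon circRNA -> FSM
  calls <- toy_calls()[1, ]
  calls$fsj <- ""; calls$blocks <- "201-1050"
  xs <- classifyFsjCategory(collapseIsoforms(calls), td$model)
  expect_identical(unname(SummarizedExperiment::rowData(xs)$fsj_category),
                   "FSM")
  # unannotated forward-splice site -> NNC
  calls2 <- toy_calls()[1, ]
  calls2$fsj <- "310-501"; calls2$blocks <- "201-310;501-1050"
  xn <- classifyFsjCategory(collapseIsoforms(calls2), td$model)
  expect_identical(unname(SummarizedExperiment::rowData(xn)$fsj_category),
                   "NNC")
})

test_that("gene assignment ranks by shared splice sites with tie and overlap rules", {
  # two plus-strand genes; gene A shares 4 sites, gene B shares 2
  exA <- GenomicRanges::GRanges("chrT", IRanges::IRanges(c(100, 300), c(200, 400)),
                                strand = "+")
  exB <- GenomicRanges::GRanges("chrT", IRanges::IRanges(c(100, 900), c(200, 950)),
                                strand = "+")
  model <- geneModel(GenomicRanges::GRangesList(t1 = exA, t2 = exB),
                     c(t1 = "A", t2 = "B"))
  calls <- data.frame(read_id = "r", sample = "s", chrom = "chrT",
                      strand = "+", bsj_start = 100, bsj_end = 400,
                      fsj = "200-300", blocks = "100-200;300-400",
                      bsj_known = TRUE, bsj_high = TRUE, fsj_all_high = TRUE,
                      copy_number = 5, drop_reason = NA_character_)
  x <- assignGenes(collapseIsoforms(calls), model)
  expect_identical(unname(SummarizedExperiment::rowData(x)$gene_id), "A")
  # tie -> both genes
  model2 <- geneModel(GenomicRanges::GRangesList(t1 = exA, t2 = exA),
                      c(t1 = "A", t2 = "B"))
  x2 <- assignGenes(collapseIsoforms(calls), model2)
  expect_identical(unname(SummarizedExperiment::rowData(x2)$gene_id), "A;B")
  # zero shared sites: strand-consistent overlap wins, else NA
  calls3 <- calls
  calls3$bsj_start <- 150; calls3$bsj_end <- 180
  calls3$fsj <- ""; calls3$blocks <- "150-180"
  x3 <- assignGenes(collapseIsoforms(calls3), model)
  expect_identical(unname(SummarizedExperiment::rowData(x3)$gene_id), "A;B")
  calls4 <- calls3
  calls4$bsj_start <- 2000; calls4$bsj_end <- 2100; calls4$blocks <- "2000-2100"
  x4 <- assignGenes(collapseIsoforms(calls4), model)
  expect_true(is.na(SummarizedExperiment::rowData(x4)$gene_id))
  # opposite strand is never assigned
  calls5 <- calls
  calls5$strand <- "-"
  x5 <- assignGenes(collapseIsoforms(calls5), model)
  expect_true(is.na(SummarizedExperiment::rowData(x5)$gene_id))
})

test_that("naming ranks by median, then mean, then key, order-invariantly", {
  mk_calls <- function(n, sample, key_fsj, blocks) {
    do.call(rbind, lapply(seq_len(n), function(i)
      data.frame(read_id = paste0(sample, key_fsj, i), sample = sample,
                 chrom = "chrT", strand = "+", bsj_start = 100, bsj_end = 900,
                 fsj = key_fsj, blocks = blocks, bsj_known = TRUE,
                 bsj_high = TRUE, fsj_all_high = TRUE, copy_number = 2,
                 drop_reason = NA_character_)))
  }
  calls <- rbind(mk_calls(5, "s1", "200-300", "100-200;300-900"),
                 mk_calls(5, "s2", "200-300", "100-200;300-900"),
                 mk_calls(3, "s1", "200-400", "100-200;400-900"),
                 mk_calls(3, "s2", "200-400", "100-200;400-900"))
  ex <- GenomicRanges::GRanges("chrT", IRanges::IRanges(c(100, 300), c(200, 900)),
                               strand = "+")
  model <- geneModel(GenomicRanges::GRangesList(t1 = ex), c(t1 = "G"))
  x <- nameIsoforms(assignGenes(collapseIsoforms(calls), model))
  rd <- SummarizedExperiment::rowData(x)
  expect_identical(unname(rd$isoform_name[rd$fsj == "200-300"]), "G.circRNA.1")
  expect_identical(unname(rd$isoform_name[rd$fsj == "200-400"]), "G.circRNA.2")
  # shuffled input gives identical names
  x2 <- nameIsoforms(assignGenes(
    collapseIsoforms(calls[rev(seq_len(nrow(calls))), ]), model))
  rd2 <- SummarizedExperiment::rowData(x2)
  expect_identical(rd2[rownames(x), "isoform_name"],
                   rd[rownames(x), "isoform_name"])
  # median tie broken by mean
  calls_t <- rbind(mk_calls(4, "s1", "200-300", "100-200;300-900"),
                   mk_calls(2, "s2", "200-300", "100-200;300-900"),
                   mk_calls(3, "s1", "200-400", "100-200;400-900"),
                   mk_calls(3, "s2", "200-400", "100-200;400-900"))
  xt <- nameIsoforms(assignGenes(collapseIsoforms(calls_t), model))
  rdt <- SummarizedExperiment::rowData(xt)
  expect_identical(unname(rdt$isoform_name[rdt$fsj == "200-300"]),
                   "G.circRNA.1") # medians tie at 3, means 3.0 vs 2.5
})

test_that("alternative-splicing events are typed from block differences", {
  pre <- cbind(start = c(100, 300, 500), end = c(200, 400, 600))
  se <- cbind(start = c(100, 500), end = c(200, 600))
  expect_identical(circlong:::.block_events(pre, se, "+"), "SE")
  a5 <- cbind(start = c(100, 300, 500), end = c(200, 380, 600))
  expect_identical(circlong:::.block_events(pre, a5, "+"), "A5SS")
  expect_identical(circlong:::.block_events(pre, a5, "-"), "A3SS")
  a3 <- cbind(start = c(100, 320, 500), end = c(200, 400, 600))
  expect_identical(circlong:::.block_events(pre, a3, "+"), "A3SS")
  ri <- cbind(start = c(100, 500), end = c(400, 600))
  expect_identical(circlong:::.block_events(pre, ri, "+"), "RI")
  expect_identical(circlong:::.block_events(ri, pre, "+"), "RI")
})

test_that("predominant-isoform pairing labels BSJ/FSJ differences", {
  calls <- rbind(
    data.frame(read_id = paste0("a", 1:5), sample = "s1", chrom = "chrT",
               strand = "+", bsj_start = 100, bsj_end = 900,
               fsj = "200-300", blocks = "100-200;300-900", bsj_known = TRUE,
               bsj_high = TRUE, fsj_all_high = TRUE, copy_number = 2,
               drop_reason = NA_character_),
    data.frame(read_id = "b1", sample = "s1", chrom = "chrT", strand = "+",
               bsj_start = 100, bsj_end = 900, fsj = "",
               blocks = "100-900", bsj_known = TRUE, bsj_high = TRUE,
               fsj_all_high = TRUE, copy_number = 2,
               drop_reason = NA_character_),
    data.frame(read_id = "c1", sample = "s1", chrom = "chrT", strand = "+",
               bsj_start = 100, bsj_end = 950, fsj = "200-300",
               blocks = "100-200;300-950", bsj_known = TRUE, bsj_high = TRUE,
               fsj_all_high = TRUE, copy_number = 2,
               drop_reason = NA_character_))
  ex <- GenomicRanges::GRanges("chrT", IRanges::IRanges(c(100, 300), c(200, 950)),
                               strand = "+")
  model <- geneModel(GenomicRanges::GRangesList(t1 = ex), c(t1 = "G"))
  x <- assignGenes(collapseIsoforms(calls), model)
  ev <- pairAltSplicingEvents(x)
  expect_equal(nrow(ev), 2)
  expect_setequal(ev$diff_class, c("FSJs only", "BSJ only"))
  # same-BSJ pair decomposes into a retained-intron event
  expect_identical(ev$events[ev$diff_class == "FSJs only"], "RI")
})

test_that("category invariants hold on recovered simulated isoforms", {
  sim <- small_sim()
  cs <- callConsensusSet(sim$reads)
  calls <- callCircReads(cs$records, sim$genome, sim$model, sim$circdb)
  x <- annotateCatalog(collapseIsoforms(calls, min_count = 2), sim$model,
                       sim$circdb)
  rd <- SummarizedExperiment::rowData(x)
  expect_true(all(rd$bsj_category[rd$bsj_known == "known"] == "FSM"))
  expect_true(all(rd$fsj_category[rd$fsj == ""] == "FSM"))
  # counts conservation against the BSJ table
  bc <- S4Vectors::metadata(x)$bsj_counts
  bk <- circlong:::.bsj_key(rd$chrom, rd$bsj_start, rd$bsj_end)
  for (k in unique(bk)) {
    expect_lte(sum(SummarizedExperiment::assay(x)[bk == k, ]), sum(bc[k, ]))
  }
})
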