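# Isoform catalog: collapse per-read calls into quantified isoforms,
# classify BSJs and FSJ sets (known/novel, FSM/NIC/NNC), assign genes, name
# isoforms and type alternative-splicing differences.

#' Collapse per-read junction calls into a quantified isoform catalog
#'
#' Reads with identical isoform keys (chrom, strand, BSJ, FSJ chain) merge;
#' per-sample read counts accumulate. Only full-length calls (high-confidence
#' BSJ and all FSJs high-confidence) become catalog rows; BSJ-level counts
#' over all candidate circRNAs (high-confidence BSJ regardless of FSJs) are
#' kept in `metadata(x)$bsj_counts`. Read count means independent supporting
#' reads, never within-read copy number.
#'
#' @param calls data.frame from [callCircReads()] (possibly several samples
#'   concatenated)
#' @param min_count drop isoforms whose total read count is below this
#'   (default 1 keeps everything; 2 reproduces the usual reporting cutoff)
#' @return a [CircCatalog-class]
#' @export
collapseIsoforms <- function(calls, min_count = 1L) {
  cand <- calls[is.na(calls$drop_reason) & calls$bsj_high, , drop = FALSE]
  full <- cand[cand$fsj_all_high, , drop = FALSE]
  samples <- sort(unique(calls$sample))
  key <- .isoform_key(full$chrom, full$strand, full$bsj_start, full$bsj_end,
                      full$fsj)
  ukey <- unique(key)
  counts <- matrix(0L, nrow = length(ukey), ncol = length(samples),
                   dimnames = list(ukey, samples))
  tt <- table(key, full$sample)
  counts[rownames(tt), colnames(tt)] <- as.integer(tt)
  first <- match(ukey, key)
  rd <- DataFrame(chrom = full$chrom[first],
                  circ_strand = full$strand[first],
                  bsj_start = full$bsj_start[first],
                  bsj_end = full$bsj_end[first],
                  fsj = full$fsj[first],
                  blocks = full$blocks[first])
  blk <- lapply(rd$blocks, function(b) {
    m <- .parse_blocks(b)
    GRanges(rd$chrom[1], IRanges(m[, "start"], m[, "end"]))
  })
  rr <- GRangesList(blk)
  for (i in seq_along(rr)) strand(rr[[i]]) <- rd$circ_strand[i]
  names(rr) <- ukey
  rd$n_exons <- vapply(blk, length, integer(1))
  rd$length <- vapply(blk, function(g) sum(width(g)), numeric(1))
  se <- SummarizedExperiment(assays = list(counts = counts), rowRanges = rr)
  rowData(se) <- rd
  x <- new("CircCatalog", se)
  keep <- rowSums(assay(x, "counts")) >= min_count
  x <- x[keep, ]
  # BSJ-level counts over candidate circRNAs (conservation: isoform counts
  # sharing a BSJ sum to less than or equal the BSJ count)
  bk <- .bsj_key(cand$chrom, cand$bsj_start, cand$bsj_end)
  bt <- table(bk, cand$sample)
  bsj_counts <- matrix(0L, nrow = nrow(bt), ncol = length(samples),
                       dimnames = list(rownames(bt), samples))
  bsj_counts[rownames(bt), colnames(bt)] <- as.integer(bt)
  metadata(x)$bsj_counts <- bsj_counts
  x
}

#' Classify BSJs as known or novel against circRNA databases
#'
#' A BSJ is known when its exact coordinates (chrom, start, end) appear in
#' any database; per-source membership flags are retained.
#'
#' @param x a [CircCatalog-class]
#' @param circdb a [CircDB-class]
#' @return `x` with rowData columns `bsj_known` and `known_<source>`
#' @export
classifyBsjKnown <- function(x, circdb) {
  rd <- rowData(x)
  key <- .bsj_key(rd$chrom, rd$bsj_start, rd$bsj_end)
  db <- bsjRecords(circdb)
  dbkey <- .bsj_key(as.character(seqnames(db)), start(db), end(db))
  known_any <- rep(FALSE, nrow(x))
  for (src in dbSources(circdb)) {
    hit <- key %in% dbkey[mcols(db)$source == src]
    rowData(x)[[paste0("known_", src)]] <- hit
    known_any <- known_any | hit
  }
  rowData(x)$bsj_known <- ifelse(known_any, "known", "novel")
  x
}

.site_sets_for <- function(sites, strand) {
  if (strand == "+") list(sites$plus) else if (strand == "-") list(sites$minus)
  else list(sites$plus, sites$minus)
}

#' FSM/NIC/NNC classification of BSJs
#'
#' FSM when the BSJ exists in any circRNA database; otherwise NIC when both
#' back-splice sites are cataloged in the gene annotation; NNC when either
#' site is novel.
#'
#' @param x a [CircCatalog-class]
#' @param circdb a [CircDB-class]
#' @param model a [GeneModel-class]
#' @return `x` with rowData column `bsj_category`
#' @export
classifyBsjCategory <- function(x, circdb, model) {
  rd <- rowData(x)
  key <- .bsj_key(rd$chrom, rd$bsj_start, rd$bsj_end)
  db <- bsjRecords(circdb)
  dbkey <- .bsj_key(as.character(seqnames(db)), start(db), end(db))
  sites <- spliceSites(model)
  cat <- character(nrow(x))
  for (i in seq_len(nrow(x))) {
    if (key[i] %in% dbkey) { cat[i] <- "FSM"; next }
    ok <- any(vapply(.site_sets_for(sites, rd$circ_strand[i]), function(ss)
      rd$bsj_start[i] %in% ss$starts && rd$bsj_end[i] %in% ss$ends,
      logical(1)))
    cat[i] <- if (ok) "NIC" else "NNC"
  }
  rowData(x)$bsj_category <- cat
  x
}

.chain_tokens <- function(chain) {
  if (is.na(chain) || chain == "") character(0)
  else strsplit(chain, "|", fixed = TRUE)[[1]]
}

.is_subchain <- function(iso_tok, tx_tok) {
  ni <- length(iso_tok); nt <- length(tx_tok)
  if (ni == 0) return(TRUE)
  if (ni > nt) return(FALSE)
  for (s in seq_len(nt - ni + 1L))
    if (all(tx_tok[s:(s + ni - 1L)] == iso_tok)) return(TRUE)
  FALSE
}

#' FSM/NIC/NNC classification of the FSJ set
#'
#' The FSJ set is FSM when the ordered FSJ chain is a contiguous sub-chain of
#' some annotated transcript's junction chain (a circRNA's exons are
#' consecutive in the parent transcript); otherwise NIC when every
#' forward-splice site is annotated; NNC when any site is novel. Single-exon
#' circRNAs (no FSJ) are FSM.
#'
#' @param x a [CircCatalog-class]
#' @param model a [GeneModel-class]
#' @return `x` with rowData column `fsj_category`
#' @export
classifyFsjCategory <- function(x, model) {
  rd <- rowData(x)
  tx_tok <- lapply(model@txChain, .chain_tokens)
  sites <- spliceSites(model)
  cat <- character(nrow(x))
  for (i in seq_len(nrow(x))) {
    iso_tok <- .chain_tokens(rd$fsj[i])
    if (length(iso_tok) == 0) { cat[i] <- "FSM"; next }
    if (any(vapply(tx_tok, .is_subchain, logical(1), iso_tok = iso_tok))) {
      cat[i] <- "FSM"; next
    }
    m <- .parse_fsj(rd$fsj[i])
    ok <- all(vapply(seq_len(nrow(m)), function(j)
      any(vapply(.site_sets_for(sites, rd$circ_strand[i]), function(ss)
        m[j, "l"] %in% ss$ends && m[j, "r"] %in% ss$starts, logical(1))),
      logical(1)))
    cat[i] <- if (ok) "NIC" else "NNC"
  }
  rowData(x)$fsj_category <- cat
  x
}

#' Assign genes to circRNA isoforms
#'
#' Among strand-consistent genes, the gene sharing the largest number of
#' splice sites (all block boundaries) with the isoform wins; ties assign
#' multiple genes. With zero shared sites, any strand-consistent gene with at
#' least 1 bp genomic overlap is assigned; otherwise NA.
#'
#' @param x a [CircCatalog-class]
#' @param model a [GeneModel-class]
#' @return `x` with rowData column `gene_id` (';'-joined for multi-gene)
#' @export
assignGenes <- function(x, model) {
  rd <- rowData(x)
  gr <- geneRanges(model)
  gs <- model@geneSites
  out <- character(nrow(x))
  for (i in seq_len(nrow(x))) {
    blocks <- .parse_blocks(rd$blocks[i])
    iso_sites <- unique(c(blocks[, "start"], blocks[, "end"]))
    st <- rd$circ_strand[i]
    cons <- which(as.character(seqnames(gr)) == rd$chrom[i] &
                    (st == "*" | as.character(strand(gr)) == st))
    if (!length(cons)) { out[i] <- NA_character_; next }
    shared <- vapply(cons, function(g)
      sum(iso_sites %in% gs[[names(gr)[g]]]), integer(1))
    if (max(shared) > 0) {
      out[i] <- paste(names(gr)[cons[shared == max(shared)]], collapse = ";")
      next
    }
    ov <- cons[start(gr)[cons] <= rd$bsj_end[i] &
                 end(gr)[cons] >= rd$bsj_start[i]]
    out[i] <- if (length(ov)) paste(names(gr)[ov], collapse = ";")
    else NA_character_
  }
  rowData(x)$gene_id <- out
  x
}

.rank_isoforms <- function(counts, keys) {
  med <- apply(counts, 1, median)
  mea <- rowMeans(counts)
  order(-med, -mea, keys)
}

#' Name isoforms within genes by abundance
#'
#' Within each assigned gene, `circRNA.1` is the isoform with the highest
#' median read count across samples; median ties are broken by mean, then by
#' isoform key. Names are `<gene>.circRNA.<n>`; naming is invariant to input
#' order.
#'
#' @param x a [CircCatalog-class] with `gene_id` assigned
#' @return `x` with rowData column `isoform_name`
#' @export
nameIsoforms <- function(x) {
  rd <- rowData(x)
  cn <- assay(x, "counts")
  gene <- ifelse(is.na(rd$gene_id), "NA", rd$gene_id)
  nm <- character(nrow(x))
  for (g in unique(gene)) {
    idx <- which(gene == g)
    o <- .rank_isoforms(cn[idx, , drop = FALSE], rownames(x)[idx])
    nm[idx[o]] <- paste0(g, ".circRNA.", seq_along(idx))
  }
  rowData(x)$isoform_name <- nm
  x
}

# classify the block-level difference between two same-BSJ isoforms into
# SE / A5SS / A3SS / RI events
.block_events <- function(a, b, strand) {
  key <- function(m) paste(m[, "start"], m[, "end"])
  ka <- key(a); kb <- key(b)
  a_only <- a[!(ka %in% kb), , drop = FALSE]
  b_only <- b[!(kb %in% ka), , drop = FALSE]
  ev <- character(0)
  used_a <- rep(FALSE, nrow(a_only)); used_b <- rep(FALSE, nrow(b_only))
  # RI: one block of one isoform spans two blocks of the other plus the gap;
  # the two spanned counterpart blocks are consumed by the event as well
  spans_two <- function(x, y) {
    hit1 <- which(y[, "start"] == x["start"] & y[, "end"] < x["end"])
    hit2 <- which(y[, "end"] == x["end"] & y[, "start"] > x["start"])
    if (length(hit1) == 1 && length(hit2) == 1 &&
        y[hit1, "end"] < y[hit2, "start"]) key(y)[c(hit1, hit2)]
    else NULL
  }
  for (i in seq_len(nrow(a_only))) {
    hit <- spans_two(a_only[i, ], b)
    if (!is.null(hit)) {
      ev <- c(ev, "RI"); used_a[i] <- TRUE
      used_b[key(b_only) %in% hit] <- TRUE
    }
  }
  for (i in seq_len(nrow(b_only))) {
    if (used_b[i]) next
    hit <- spans_two(b_only[i, ], a)
    if (!is.null(hit)) {
      ev <- c(ev, "RI"); used_b[i] <- TRUE
      used_a[key(a_only) %in% hit] <- TRUE
    }
  }
  # boundary shifts: blocks sharing exactly one boundary
  for (i in seq_len(nrow(a_only))) {
    if (used_a[i]) next
    j <- which(!used_b & b_only[, "start"] == a_only[i, "start"] &
                 b_only[, "end"] != a_only[i, "end"])
    if (length(j) >= 1) {
      ev <- c(ev, if (strand == "+") "A5SS" else "A3SS")
      used_a[i] <- TRUE; used_b[j[1]] <- TRUE
      next
    }
    j <- which(!used_b & b_only[, "end"] == a_only[i, "end"] &
                 b_only[, "start"] != a_only[i, "start"])
    if (length(j) >= 1) {
      ev <- c(ev, if (strand == "+") "A3SS" else "A5SS")
      used_a[i] <- TRUE; used_b[j[1]] <- TRUE
    }
  }
  # remaining unmatched whole blocks are skipped exons
  ev <- c(ev, rep("SE", sum(!used_a) + sum(!used_b)))
  ev
}

#' Pair alternative-splicing events against the predominant isoform
#'
#' Within each gene, the predominant isoform (highest median read count,
#' ties by mean) is compared to every other isoform. Pairs are labeled by
#' whether they differ in the BSJ only, the FSJs only, or both, and same-BSJ
#' internal differences are decomposed into SE / A5SS / A3SS / RI events by
#' block-set comparison (RI: one isoform's block contiguously spans the
#' other's two blocks plus the intervening intron).
#'
#' @param x a [CircCatalog-class] with genes assigned
#' @return data.frame: gene_id, predominant, other, minor_count, diff_class,
#'   events (comma-joined)
#' @export
pairAltSplicingEvents <- function(x) {
  rd <- rowData(x)
  cn <- assay(x, "counts")
  gene <- ifelse(is.na(rd$gene_id), "NA", rd$gene_id)
  out <- list()
  for (g in unique(gene)) {
    idx <- which(gene == g)
    if (length(idx) < 2) next
    o <- .rank_isoforms(cn[idx, , drop = FALSE], rownames(x)[idx])
    pre <- idx[o[1]]
    for (ot in idx[o[-1]]) {
      bsj_same <- rd$bsj_start[pre] == rd$bsj_start[ot] &&
        rd$bsj_end[pre] == rd$bsj_end[ot]
      fsj_same <- rd$fsj[pre] == rd$fsj[ot]
      diff_class <- if (!bsj_same && fsj_same) "BSJ only"
      else if (bsj_same && !fsj_same) "FSJs only" else "both"
      ev <- character(0)
      if (bsj_same && !fsj_same)
        ev <- .block_events(.parse_blocks(rd$blocks[pre]),
                            .parse_blocks(rd$blocks[ot]),
                            rd$circ_strand[pre])
      out[[length(out) + 1L]] <- data.frame(
        gene_id = g, predominant = rownames(x)[pre], other = rownames(x)[ot],
        minor_count = sum(cn[ot, ]), diff_class = diff_class,
        events = paste(ev, collapse = ","), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame(gene_id = character(0),
                                      predominant = character(0),
                                      other = character(0),
                                      minor_count = numeric(0),
                                      diff_class = character(0),
                                      events = character(0)))
  do.call(rbind, out)
}

#' Annotate a catalog in one step
#'
#' Runs known/novel and FSM/NIC/NNC classification, gene assignment and
#' isoform naming.
#'
#' @param x a [CircCatalog-class]
#' @param model a [GeneModel-class]
#' @param circdb a [CircDB-class]
#' @return the annotated catalog
#' @export
annotateCatalog <- function(x, model, circdb) {
  x <- classifyBsjKnown(x, circdb)
  x <- classifyBsjCategory(x, circdb, model)
  x <- classifyFsjCategory(x, model)
  x <- assignGenes(x, model)
  nameIsoforms(x)
}
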