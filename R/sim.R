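# Rolling-circle read simulator. Generates a toy genome with multi-exon
# genes (canonical GT-AG splice motifs planted on the correct strand),
# circRNA isoforms with alternative-splicing variants, Alu-like repeat
# annotation around BSJs, and error-bearing tandem-concatemer reads with
# full ground truth.

.ALU_LEN <- 300L
.GENE_GAP <- 2200L
.ALT_DELTA <- c(15L, 45L)

.sample_range <- function(rg, n = 1L) {
  if (rg[1] == rg[2]) rep(rg[1], n) else sample(seq(rg[1], rg[2]), n, replace = TRUE)
}

# Build one chromosome carrying all genes; returns the sequence (character),
# a per-gene structure list and base GeneModel transcripts (full exon chains).
.build_genes <- function(cfg) {
  genes <- vector("list", cfg@n_genes)
  seqs <- character(0)
  cursor <- 0L
  chrom <- "chrS"
  for (g in seq_len(cfg@n_genes)) {
    strand <- sample(c("+", "-"), 1)
    n_ex <- .sample_range(cfg@exons_per_gene)
    ex_len <- .sample_range(cfg@exon_len, n_ex)
    in_len <- if (n_ex > 1) .sample_range(cfg@intron_len, n_ex - 1L) else integer(0)
    gap <- .GENE_GAP
    gene_seq <- strsplit(.rand_seq(sum(ex_len) + sum(in_len) + 2L * gap),
                         "", fixed = TRUE)[[1]]
    off <- gap
    ex_start <- integer(n_ex); ex_end <- integer(n_ex)
    for (i in seq_len(n_ex)) {
      ex_start[i] <- off + 1L
      ex_end[i] <- off + ex_len[i]
      off <- ex_end[i] + if (i < n_ex) in_len[i] else 0L
    }
    before <- if (strand == "+") c("A", "G") else c("A", "C")
    after <- if (strand == "+") c("G", "T") else c("C", "T")
    for (i in seq_len(n_ex)) {
      gene_seq[(ex_start[i] - 2L):(ex_start[i] - 1L)] <- before
      gene_seq[(ex_end[i] + 1L):(ex_end[i] + 2L)] <- after
    }
    # alternative boundaries inside exons (canonical motifs planted) for
    # A5SS/A3SS events; kept > correction window away from the true site
    alt_start <- rep(NA_integer_, n_ex)
    alt_end <- rep(NA_integer_, n_ex)
    for (i in seq_len(n_ex)) {
      if (ex_len[i] < 2L * .ALT_DELTA[2]) next
      if (runif(1) < 0.7) {
        d <- .sample_range(.ALT_DELTA)
        alt_end[i] <- ex_end[i] - d
        gene_seq[(alt_end[i] + 1L):(alt_end[i] + 2L)] <- after
      }
      if (runif(1) < 0.7) {
        d <- .sample_range(.ALT_DELTA)
        alt_start[i] <- ex_start[i] + d
        gene_seq[(alt_start[i] - 2L):(alt_start[i] - 1L)] <- before
      }
    }
    genes[[g]] <- list(gene_id = sprintf("G%03d", g), chrom = chrom,
                       strand = strand,
                       ex_start = ex_start + cursor, ex_end = ex_end + cursor,
                       alt_start = ifelse(is.na(alt_start), NA_integer_,
                                          alt_start + cursor),
                       alt_end = ifelse(is.na(alt_end), NA_integer_,
                                        alt_end + cursor))
    seqs <- c(seqs, paste(gene_seq, collapse = ""))
    cursor <- cursor + length(gene_seq)
  }
  list(seq = paste(seqs, collapse = ""), genes = genes, chrom = chrom)
}

#' Simulate one circRNA isoform from a gene
#'
#' Chooses a contiguous exon span of the gene and applies the requested
#' alternative-splicing event: `none` uses the annotated exons, `SE` skips an
#' internal exon, `A5SS`/`A3SS` move a donor/acceptor boundary to a planted
#' alternative site, `RI` retains one intron inside a single exon block
#' (an exon-intron circRNA). The BSJ joins the span's last exon end (donor)
#' back to its first exon start (acceptor).
#'
#' @param gene a gene structure as produced by [simulateGenome()] (element of
#'   `$genes`)
#' @param event one of "none", "SE", "A5SS", "A3SS", "RI"
#' @return list with `blocks` (two-column matrix, 1-based inclusive),
#'   `bsj_start`, `bsj_end`, `strand`, `event`, and `tx_blocks`, the exon
#'   chain of the linear transcript consistent with this isoform
#' @export
simulateCircIsoform <- function(gene, event = "none") {
  n_ex <- length(gene$ex_start)
  infeasible <- function() stop("event infeasible for this gene",
                                call. = FALSE)
  min_span <- switch(event, SE = 3L, none = 1L, 2L)
  if (n_ex < min_span) infeasible()
  span <- .sample_range(c(min_span, n_ex))
  i <- .sample_range(c(1L, n_ex - span + 1L))
  j <- i + span - 1L
  bs <- gene$ex_start[i]; be <- gene$ex_end[j]
  st <- gene$ex_start[i:j]; en <- gene$ex_end[i:j]
  tx_st <- gene$ex_start; tx_en <- gene$ex_end
  if (event == "SE") {
    m <- .sample_range(c(2L, span - 1L))
    st <- st[-m]; en <- en[-m]
    tx_st <- tx_st[-(i + m - 1L)]; tx_en <- tx_en[-(i + m - 1L)]
  } else if (event == "RI") {
    m <- .sample_range(c(1L, span - 1L))
    en[m] <- en[m + 1L]
    st <- st[-(m + 1L)]; en <- en[-(m + 1L)]
    k <- i + m - 1L
    tx_en[k] <- tx_en[k + 1L]
    tx_st <- tx_st[-(k + 1L)]; tx_en <- tx_en[-(k + 1L)]
  } else if (event %in% c("A5SS", "A3SS")) {
    # A5SS shifts a donor site, A3SS an acceptor site (biological sense);
    # on the plus strand donors are exon ends, on the minus strand starts
    use_end <- (event == "A5SS") == (gene$strand == "+")
    if (use_end) {
      cand <- i:(j - 1L)
      cand <- cand[!is.na(gene$alt_end[cand])]
      if (!length(cand)) infeasible()
      m <- if (length(cand) == 1) cand else sample(cand, 1)
      en[m - i + 1L] <- gene$alt_end[m]
      tx_en[m] <- gene$alt_end[m]
    } else {
      cand <- (i + 1L):j
      cand <- cand[!is.na(gene$alt_start[cand])]
      if (!length(cand)) infeasible()
      m <- if (length(cand) == 1) cand else sample(cand, 1)
      st[m - i + 1L] <- gene$alt_start[m]
      tx_st[m] <- gene$alt_start[m]
    }
  }
  list(blocks = cbind(start = st, end = en),
       bsj_start = bs, bsj_end = be, strand = gene$strand, event = event,
       tx_blocks = cbind(start = tx_st, end = tx_en))
}

#' Simulate a toy genome, gene annotation, circRNA truth set and repeats
#'
#' Generates `n_genes` multi-exon genes on one chromosome with canonical
#' splice motifs planted on the correct strand (plus alternative boundaries
#' inside exons for A5SS/A3SS events), draws `n_isoforms` circRNA isoforms
#' according to the configured event mix, places Alu-like repeat elements in
#' the BSJ-flanking introns in configured orientations, and emits the gene
#' annotation. For each isoform a linear transcript consistent with its
#' internal structure is annotated with probability `1 - novel_site_rate`;
#' with `novel_site_rate = 0` every simulated splice site and splice pattern
#' is present in the annotation.
#'
#' @param config a [SimConfig-class]
#' @return list with `genome` (DNAStringSet), `model` ([GeneModel-class]),
#'   `circdb` ([CircDB-class] of all simulated BSJs), `repeats` (GRanges with
#'   `family`), `genes` (internal gene structures), and `isoforms`
#'   (ground-truth data.frame)
#' @export
simulateGenome <- function(config) {
  stopifnot(is(config, "SimConfig"))
  set.seed(config@seed)
  built <- .build_genes(config)
  genes <- built$genes
  chrom <- built$chrom
  # isoforms: draw gene round-robin and event from the mix; resample on
  # infeasible events or duplicate keys
  events <- names(config@as_event_mix)
  iso <- list()
  keys <- character(0)
  g_idx <- 0L
  tries <- 0L
  while (length(iso) < config@n_isoforms && tries < 50L * config@n_isoforms) {
    tries <- tries + 1L
    g_idx <- g_idx %% length(genes) + 1L
    gene <- genes[[g_idx]]
    ev <- sample(events, 1, prob = config@as_event_mix)
    res <- tryCatch(simulateCircIsoform(gene, ev), error = function(e) NULL)
    if (is.null(res)) next
    fsj <- .fsj_string(res$blocks[, 1], res$blocks[, 2])
    key <- .isoform_key(chrom, res$strand, res$bsj_start, res$bsj_end, fsj)
    if (key %in% keys) next
    keys <- c(keys, key)
    res$gene_id <- gene$gene_id
    res$key <- key
    res$fsj <- fsj
    res$annotated <- runif(1) >= config@novel_site_rate
    iso[[length(iso) + 1L]] <- res
  }
  # gene model: full exon chain per gene + annotated variant transcripts
  ex_list <- list(); tx_gene <- character(0)
  for (gene in genes) {
    tx <- paste0(gene$gene_id, ".t1")
    ex_list[[tx]] <- GRanges(chrom, IRanges(gene$ex_start, gene$ex_end),
                             strand = gene$strand)
    tx_gene[tx] <- gene$gene_id
  }
  vn <- 0L
  for (is_ in iso) {
    if (is_$event == "none" || !is_$annotated) next
    vn <- vn + 1L
    tx <- paste0(is_$gene_id, ".v", vn)
    ex_list[[tx]] <- GRanges(chrom,
                             IRanges(is_$tx_blocks[, 1], is_$tx_blocks[, 2]),
                             strand = is_$strand)
    tx_gene[tx] <- is_$gene_id
  }
  model <- geneModel(GRangesList(ex_list), tx_gene)
  # truth table
  truth <- data.frame(
    isoform_id = sprintf("iso%03d", seq_along(iso)),
    gene_id = vapply(iso, `[[`, character(1), "gene_id"),
    chrom = chrom,
    strand = vapply(iso, `[[`, character(1), "strand"),
    bsj_start = vapply(iso, `[[`, numeric(1), "bsj_start"),
    bsj_end = vapply(iso, `[[`, numeric(1), "bsj_end"),
    blocks = vapply(iso, function(x)
      .blocks_string(x$blocks[, 1], x$blocks[, 2]), character(1)),
    fsj = vapply(iso, `[[`, character(1), "fsj"),
    event = vapply(iso, `[[`, character(1), "event"),
    annotated = vapply(iso, `[[`, logical(1), "annotated"),
    spliced_len = vapply(iso, function(x)
      sum(x$blocks[, 2] - x$blocks[, 1] + 1), numeric(1)),
    key = keys,
    stringsAsFactors = FALSE)
  # Alu-like repeats flanking BSJs
  glen <- nchar(built$seq)
  ubsj <- unique(truth[, c("chrom", "bsj_start", "bsj_end")])
  rep_chr <- character(0); rep_start <- integer(0); rep_strand <- character(0)
  intended <- character(nrow(ubsj))
  place <- function(win_lo, win_hi, st) {
    lo <- max(1L, win_lo); hi <- min(glen - .ALU_LEN, win_hi - .ALU_LEN)
    if (hi < lo) return(NULL)
    s <- .sample_range(c(lo, hi))
    rep_chr <<- c(rep_chr, chrom)
    rep_start <<- c(rep_start, s)
    rep_strand <<- c(rep_strand, st)
  }
  for (b in seq_len(nrow(ubsj))) {
    ori <- sample(names(config@alu_mix), 1, prob = config@alu_mix)
    intended[b] <- ori
    up <- c(ubsj$bsj_start[b] - 1000L, ubsj$bsj_start[b] - 1L)
    dn <- c(ubsj$bsj_end[b] + 1L, ubsj$bsj_end[b] + 1000L)
    if (ori %in% c("convergent", "both")) {
      place(up[1], up[2], "+"); place(dn[1], dn[2], "-")
    }
    if (ori %in% c("divergent", "both")) {
      place(up[1], up[2], "-"); place(dn[1], dn[2], "+")
    }
    if (ori == "none" && runif(1) < 0.5) {
      # same-strand (non-inverted) pair: must not count as inverted
      place(up[1], up[2], "+"); place(dn[1], dn[2], "+")
    }
  }
  repeats <- GRanges(rep_chr,
                     IRanges(rep_start, width = .ALU_LEN),
                     strand = rep_strand)
  if (length(repeats)) mcols(repeats)$family <- "AluY"
  ubsj$intended_alu <- intended
  db <- circDb(GRanges(ubsj$chrom, IRanges(ubsj$bsj_start, ubsj$bsj_end)),
               source = "simdb")
  genome <- DNAStringSet(setNames(built$seq, chrom))
  list(genome = genome, model = model, circdb = db, repeats = repeats,
       genes = genes, isoforms = truth, bsj_truth = ubsj)
}

#' Simulate one rolling-circle concatemer read
#'
#' The error-free read is `rotation(template, offset)` repeated `k` times,
#' with `offset` uniform over the template and `k` drawn from the configured
#' copy-number distribution (truncated below at `copy_number_min`); i.i.d.
#' substitution/insertion/deletion errors are then applied per base.
#'
#' @param template circRNA spliced sequence (character)
#' @param config a [SimConfig-class]
#' @param copies optional fixed copy number overriding the distribution
#' @return list with `seq`, `error_free`, `offset` (0-based), `copies`
#' @export
simulateRcaRead <- function(template, config, copies = NULL) {
  L <- nchar(template)
  stopifnot(L >= 1)
  if (is.null(copies)) {
    copies <- switch(config@copy_number_dist,
      fixed = round(config@copy_number_mean),
      nbinom = config@copy_number_min +
        rnbinom(1, size = config@nb_size,
                mu = config@copy_number_mean - config@copy_number_min),
      geom = config@copy_number_min +
        rgeom(1, prob = 1 / (config@copy_number_mean -
                               config@copy_number_min + 1)))
  }
  copies <- max(copies, config@copy_number_min)
  offset <- sample.int(L, 1) - 1L
  unit <- rotateSeq(template, offset)
  error_free <- paste(rep(unit, copies), collapse = "")
  seq <- .apply_errors(error_free, config@sub_rate, config@ins_rate,
                       config@del_rate)
  list(seq = seq, error_free = error_free, offset = offset, copies = copies)
}

#' Simulate a complete dataset: genome, annotation, truth and reads
#'
#' Runs [simulateGenome()] and then draws `reads_per_isoform` concatemer
#' reads for every isoform. All randomness is governed by `config@seed`;
#' identical seed and configuration give byte-identical output.
#'
#' @param config a [SimConfig-class]
#' @return the [simulateGenome()] list extended with `reads` (DNAStringSet)
#'   and `read_truth` (data.frame: read_id, isoform_id, offset, copies)
#' @export
simulateCircData <- function(config) {
  sim <- simulateGenome(config)
  gstr <- as.character(sim$genome[[1]])
  reads <- character(0)
  rt <- list()
  for (i in seq_len(nrow(sim$isoforms))) {
    blocks <- .parse_blocks(sim$isoforms$blocks[i])
    tpl <- paste(vapply(seq_len(nrow(blocks)), function(b)
      substr(gstr, blocks[b, 1], blocks[b, 2]), character(1)), collapse = "")
    if (sim$isoforms$strand[i] == "-") tpl <- .revcomp_chr(tpl)
    for (r in seq_len(config@reads_per_isoform)) {
      rr <- simulateRcaRead(tpl, config)
      id <- sprintf("%s_r%02d", sim$isoforms$isoform_id[i], r)
      reads[id] <- rr$seq
      rt[[id]] <- data.frame(read_id = id,
                             isoform_id = sim$isoforms$isoform_id[i],
                             offset = rr$offset, copies = rr$copies,
                             template_len = nchar(tpl),
                             error_free = rr$error_free,
                             stringsAsFactors = FALSE)
    }
  }
  sim$reads <- DNAStringSet(reads)
  sim$read_truth <- do.call(rbind, rt)
  rownames(sim$read_truth) <- NULL
  sim
}

#' Write simulator output to disk
#'
#' Emits reads.fastq (constant quality), genome.fa (60-column FASTA),
#' annot.gtf, circ_db.bed and repeats.bed (BED6, 0-based half-open) and
#' tab-separated ground-truth tables.
#'
#' @param sim result of [simulateCircData()]
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
writeSimOutput <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  q <- Biostrings::BStringSet(vapply(width(sim$reads), function(w)
    strrep("I", w), character(1)))
  writeXStringSet(sim$reads, file.path(dir, "reads.fastq"), format = "fastq",
                  qualities = q)
  writeXStringSet(sim$genome, file.path(dir, "genome.fa"), width = 60)
  writeGeneModelGtf(sim$model, file.path(dir, "annot.gtf"))
  db <- bsjRecords(sim$circdb)
  names(db) <- paste0("bsj", seq_along(db))
  rtracklayer::export(db, file.path(dir, "circ_db.bed"), format = "BED")
  reps <- sim$repeats
  if (length(reps)) names(reps) <- mcols(reps)$family
  rtracklayer::export(reps, file.path(dir, "repeats.bed"), format = "BED")
  write.table(sim$isoforms, file.path(dir, "truth_isoforms.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$read_truth[, c("read_id", "isoform_id", "offset", "copies")],
              file.path(dir, "truth_reads.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
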