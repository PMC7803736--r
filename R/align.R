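# Spliced alignment of consensus concatemers against a toy genome: exact
# k-mer anchors, colinear chaining with intron-sized target gaps, chain
# merging across the back-splice wrap, and exact boundary refinement at
# every junction. Adequate for genomes up to a few megabases; the contract
# is the query-ordered block structure.

.ALN_KMER <- 13L
.MAX_INTRON <- 50000L
.MIN_INTRON <- 20L

#' Prepare a genome for spliced alignment
#'
#' @param genome named DNAStringSet
#' @return an index list used by [splicedAlign()]
#' @export
indexGenome <- function(genome) {
  chroms <- lapply(seq_along(genome), function(i) as.character(genome[[i]]))
  names(chroms) <- names(genome)
  list(chroms = chroms, k = .ALN_KMER)
}

# chain (anchor index vector) -> raw blocks (0-based half-open)
.chain_blocks <- function(q, t, k) {
  bs <- list()
  qs <- q[1]; ts <- t[1]; qe <- q[1] + k; te <- t[1] + k
  if (length(q) > 1) {
    for (i in 2:length(q)) {
      gd <- (t[i] - t[i - 1]) - (q[i] - q[i - 1])
      if (gd > 30) {
        bs[[length(bs) + 1L]] <- c(qs, qe, ts, te)
        qs <- q[i]; ts <- t[i]
      }
      qe <- q[i] + k; te <- t[i] + k
    }
  }
  bs[[length(bs) + 1L]] <- c(qs, qe, ts, te)
  m <- do.call(rbind, bs)
  colnames(m) <- c("qstart", "qend", "tstart", "tend")
  m
}

# choose the query split point between adjacent blocks minimizing mismatches
# on both genomic sides (no-indel model over the short unanchored segment)
.refine_pair <- function(blocks, i, qseq, gstr) {
  qe <- blocks[i, "qend"]; ts <- blocks[i + 1, "tstart"]
  qs <- blocks[i + 1, "qstart"]; te <- blocks[i, "tend"]
  if (qe > qs) { # anchors overlapping the junction in query: trim left block
    te <- te - (qe - qs); qe <- qs
  }
  glen <- nchar(gstr)
  lo <- qe; hi <- qs
  lo <- max(lo, qe - (te - 0L)) # left extension cannot run past chrom start
  hi <- min(hi, qe + (glen - te))
  best_c <- qe; best_m <- Inf
  for (c in lo:hi) {
    lm <- if (c > qe)
      .hamming_vs(substr(qseq, qe + 1L, c), substr(gstr, te + 1L, te + (c - qe)))
    else 0L
    rlen <- qs - c
    rstart <- ts - rlen
    rm <- if (rlen > 0 && rstart >= 0)
      .hamming_vs(substr(qseq, c + 1L, qs), substr(gstr, rstart + 1L, ts))
    else if (rstart < 0) Inf else 0L
    if (lm + rm < best_m) { best_m <- lm + rm; best_c <- c }
  }
  blocks[i, "qend"] <- best_c
  blocks[i, "tend"] <- te + (best_c - qe)
  blocks[i + 1, "qstart"] <- best_c
  blocks[i + 1, "tstart"] <- ts - (qs - best_c)
  blocks
}

.merge_rows <- function(blocks, i) {
  blocks[i, "qend"] <- blocks[i + 1, "qend"]
  blocks[i, "tend"] <- blocks[i + 1, "tend"]
  blocks[-(i + 1), , drop = FALSE]
}

# refine all junction boundaries; merge near-contiguous pairs (alignment
# indels, not introns)
.polish_blocks <- function(blocks, qseq, gstr) {
  # spurious terminal blocks (single stray anchors) must not drive boundary
  # refinement of their neighbors
  while (nrow(blocks) > 1 &&
         blocks[1, "qend"] - blocks[1, "qstart"] < 20)
    blocks <- blocks[-1, , drop = FALSE]
  while (nrow(blocks) > 1 &&
         blocks[nrow(blocks), "qend"] - blocks[nrow(blocks), "qstart"] < 20)
    blocks <- blocks[-nrow(blocks), , drop = FALSE]
  i <- 1L
  while (i < nrow(blocks)) {
    blocks <- .refine_pair(blocks, i, qseq, gstr)
    gd <- blocks[i + 1, "tstart"] - blocks[i, "tend"]
    if (gd > -.MIN_INTRON && gd < .MIN_INTRON) {
      blocks <- .merge_rows(blocks, i)
    } else {
      i <- i + 1L
    }
  }
  blocks
}

.records_from_chains <- function(anchors, chains, k, qseq, gstr, chrom,
                                 qstrand) {
  if (length(chains$chains) == 0) return(list())
  segs <- lapply(chains$chains, function(idx)
    .chain_blocks(anchors[idx, "qpos"], anchors[idx, "tpos"], k))
  scores <- chains$scores
  o <- order(vapply(segs, function(b) b[1, "qstart"], numeric(1)))
  segs <- segs[o]; scores <- scores[o]
  # greedy merge of query-compatible chains (the wrap shows up as a negative
  # target jump between merged chains)
  recs <- list()
  cur <- segs[[1]]; cur_score <- scores[1]
  if (length(segs) > 1) {
    for (i in 2:length(segs)) {
      prev_qend <- cur[nrow(cur), "qend"]
      if (segs[[i]][1, "qstart"] >= prev_qend - 30 &&
          abs(segs[[i]][1, "tstart"] - cur[nrow(cur), "tend"]) < 1e6) {
        cur <- rbind(cur, segs[[i]])
        cur_score <- cur_score + scores[i]
      } else {
        recs[[length(recs) + 1L]] <- list(blocks = cur, score = cur_score)
        cur <- segs[[i]]; cur_score <- scores[i]
      }
    }
  }
  recs[[length(recs) + 1L]] <- list(blocks = cur, score = cur_score)
  lapply(recs, function(r) {
    b <- .polish_blocks(r$blocks, qseq, gstr)
    list(chrom = chrom, qstrand = qstrand, blocks = b, score = r$score,
         mapq = NA_integer_)
  })
}

# alignment records for one query given precomputed per-chrom anchors
.align_one <- function(qseq_fwd, qseq_rev, anchors_fwd, anchors_rev, index) {
  recs <- list()
  for (chrom in names(index$chroms)) {
    gstr <- index$chroms[[chrom]]
    for (st in c("+", "-")) {
      a <- if (st == "+") anchors_fwd[[chrom]] else anchors_rev[[chrom]]
      if (is.null(a) || nrow(a) < 3) next
      qs <- if (st == "+") qseq_fwd else qseq_rev
      ch <- .chain_anchors_cpp(a[, "qpos"], a[, "tpos"], index$k,
                               .MAX_INTRON, 6L)
      recs <- c(recs, .records_from_chains(a, ch, index$k, qs, gstr, chrom, st))
    }
  }
  if (!length(recs)) return(list())
  sc <- vapply(recs, `[[`, numeric(1), "score")
  o <- order(-sc)
  recs <- recs[o]; sc <- sc[o]
  mapq <- if (length(recs) == 1 || sc[1] >= 1.25 * sc[2]) 60L else 2L
  recs[[1]]$mapq <- mapq
  if (length(recs) > 1)
    for (i in 2:length(recs)) recs[[i]]$mapq <- 0L
  recs
}

#' Spliced alignment of a query against the toy genome
#'
#' Exact k-mer anchoring plus colinear chaining; target gaps up to the
#' maximum intron size are spliced out, and a two-copy concatemer's
#' back-splice wrap appears as a negative target jump between blocks. Both
#' query orientations are attempted; `qstrand` records which one aligned.
#'
#' @param query character sequence
#' @param index from [indexGenome()]
#' @return list of alignment records (chrom, qstrand, blocks matrix with
#'   0-based half-open query/target coordinates, score, mapq), best first;
#'   empty list if unmappable
#' @export
splicedAlign <- function(query, index) {
  qf <- as.character(query)
  qr <- .revcomp_chr(qf)
  af <- lapply(index$chroms, function(g)
    .kmer_anchors_cpp(qf, g, index$k, 30L))
  ar <- lapply(index$chroms, function(g)
    .kmer_anchors_cpp(qr, g, index$k, 30L))
  .align_one(qf, qr, af, ar, index)
}

#' Filter alignment records and select the optimal one
#'
#' Removes records below the mapping-quality floor, then keeps the record
#' maximizing (aligned query length, identity), ties broken by leftmost
#' genomic coordinate.
#'
#' @param records list from [splicedAlign()]
#' @param query the aligned query (character); needed to compute identity
#' @param index from [indexGenome()]
#' @param mapq_min minimum mapping quality (default 1)
#' @return the selected record with an `identity` field, or NULL
#' @export
filterAlignments <- function(records, query, index, mapq_min = 1L) {
  if (!length(records)) return(NULL)
  keep <- Filter(function(r) r$mapq >= mapq_min, records)
  if (!length(keep)) return(NULL)
  qf <- as.character(query)
  stats <- lapply(keep, function(r) {
    qs <- if (r$qstrand == "+") qf else .revcomp_chr(qf)
    gstr <- index$chroms[[r$chrom]]
    qlen <- sum(r$blocks[, "qend"] - r$blocks[, "qstart"])
    ed <- 0L
    for (i in seq_len(nrow(r$blocks))) {
      b <- r$blocks[i, ]
      ed <- ed + .edit_dist_cpp(substr(qs, b["qstart"] + 1L, b["qend"]),
                                substr(gstr, b["tstart"] + 1L, b["tend"]))
    }
    c(qlen = qlen, identity = if (qlen > 0) 1 - ed / qlen else 0)
  })
  qlen <- vapply(stats, `[`, numeric(1), "qlen")
  ident <- vapply(stats, `[`, numeric(1), "identity")
  tmin <- vapply(keep, function(r) min(r$blocks[, "tstart"]), numeric(1))
  o <- order(-qlen, -ident, vapply(keep, `[[`, character(1), "chrom"), tmin)
  best <- keep[[o[1]]]
  best$identity <- ident[o[1]]
  best
}
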