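# Consensus calling from tandem-concatemer raw reads: detect the repeat
# period by k-mer recurrence voting, pick the best-supported copy as the
# draft, and polish by aligning every copy against the draft (two voting
# passes). The repeat-unit detector is deliberately self-contained; its
# contract is the (unit length, subread span, score) triple.

.TR_KMER <- 11L

.cluster_dists <- function(d, pos) {
  o <- order(d)
  d <- d[o]; pos <- pos[o]
  clusters <- list()
  cur <- 1L
  for (i in seq_along(d)[-1]) {
    med <- median(d[cur:(i - 1L)])
    if (d[i] > med * 1.12 + 5) {
      clusters[[length(clusters) + 1L]] <- list(d = d[cur:(i - 1L)],
                                                pos = pos[cur:(i - 1L)])
      cur <- i
    }
  }
  clusters[[length(clusters) + 1L]] <- list(d = d[cur:length(d)],
                                            pos = pos[cur:length(d)])
  clusters
}

# best-supported draft window: the period-length window containing the most
# period-consistent k-mer votes (ties -> leftmost). Votes mark the earlier
# copy, so a vote inside the window attests that this copy is intact there.
.best_window <- function(pos, period, n) {
  pos <- sort(pos)
  best_s <- pos[1]; best_c <- -1L
  j <- 1L
  for (i in seq_along(pos)) {
    while (j <= length(pos) && pos[j] < pos[i] + period) j <- j + 1L
    cnt <- j - i
    if (cnt > best_c) { best_c <- cnt; best_s <- pos[i] }
  }
  min(best_s, max(0L, n - period))
}

#' Detect tandem-repeat structure in a raw read
#'
#' Finds candidate repeat periods from the distances between consecutive
#' occurrences of identical k-mers, clusters them, estimates each candidate's
#' subread span, and verifies that adjacent copies actually align. Candidates
#' are returned sorted by score (vote support), best first.
#'
#' @param read character sequence (or a length-1 DNAStringSet element)
#' @param min_period,max_period allowed repeat-unit lengths in nt; periods
#'   under 20 nt are treated as low-complexity and never reported
#' @return data.frame with columns unit_length, sub_start, sub_end (0-based
#'   half-open subread span), score, draft_start; zero rows when no period
#'   explains at least two copies
#' @export
detectTandemRepeat <- function(read, min_period = 20L, max_period = 20000L) {
  stopifnot(min_period >= 20L)
  seq <- as.character(read)
  n <- nchar(seq)
  empty <- data.frame(unit_length = integer(0), sub_start = integer(0),
                      sub_end = integer(0), score = numeric(0),
                      draft_start = integer(0))
  if (n < 2L * min_period) return(empty)
  v <- .period_votes_cpp(seq, .TR_KMER, max(10L, as.integer(min_period * 0.8)),
                         as.integer(min(max_period * 1.2, n)))
  if (nrow(v) == 0) return(empty)
  cl <- .cluster_dists(v[, "dist"], v[, "pos"])
  out <- empty
  for (c in cl) {
    if (length(c$d) < 5) next
    period <- as.integer(round(median(c$d)))
    if (period < min_period || period > max_period) next
    s0 <- min(c$pos)
    s1 <- min(n, max(c$pos) + .TR_KMER + period)
    if ((s1 - s0) / period < 1.9) next
    ds <- .best_window(c$pos, period, n)
    out <- rbind(out, data.frame(unit_length = period, sub_start = s0,
                                 sub_end = s1, score = length(c$d),
                                 draft_start = ds))
  }
  out <- out[order(-out$score, out$sub_start), , drop = FALSE]
  # suppress harmonics: a period close to an integer multiple (or duplicate)
  # of a better-supported period explains nothing new
  keep <- logical(nrow(out))
  for (i in seq_len(nrow(out))) {
    harm <- FALSE
    for (j in which(keep)) {
      ratio <- out$unit_length[i] / out$unit_length[j]
      if (abs(ratio - round(ratio)) < 0.1 && round(ratio) >= 1) {
        harm <- TRUE; break
      }
    }
    keep[i] <- !harm
  }
  out <- head(out[keep, , drop = FALSE], 5L)
  # verify survivors: adjacent copies must actually align (within 35% edits)
  ok <- vapply(seq_len(nrow(out)), function(i) {
    period <- out$unit_length[i]; ds <- out$draft_start[i]
    vlen <- min(period, 500L)
    u1 <- substr(seq, ds + 1L, ds + vlen)
    u2 <- substr(seq, ds + period + 1L, min(n, ds + period + vlen))
    if (nchar(u2) < 0.5 * vlen)
      u2 <- substr(seq, max(1L, ds - period + 1L), ds)
    nchar(u2) > 0 && .infix_edit_cpp(u1, u2) <= 0.35 * vlen
  }, logical(1))
  out[ok, , drop = FALSE]
}

#' Call a consensus sequence for one repeat candidate
#'
#' Aligns every copy of the read against the draft copy with a banded
#' aligner, takes a per-column majority vote (ties keep the draft base;
#' insertions are added on strict majority), and re-aligns all copies against
#' the first-pass consensus for a second vote. The copy number is the aligned
#' subread span divided by the consensus length.
#'
#' @param read character sequence
#' @param candidate one row of [detectTandemRepeat()] output
#' @param read_id identifier carried into the record
#' @return one-row data.frame (read_id, consensus, unit_length, copy_number,
#'   sub_start, sub_end, score) or NULL when the copies disagree beyond
#'   rescue
#' @export
callConsensus <- function(read, candidate, read_id = "read") {
  seq <- as.character(read)
  res <- tryCatch(
    .consensus_call_cpp(seq, as.integer(candidate$draft_start),
                        as.integer(candidate$unit_length), passes = 2L),
    error = function(e) NULL)
  if (is.null(res)) return(NULL)
  cons <- res$consensus
  if (nchar(cons) < 0.5 * candidate$unit_length) return(NULL)
  if (res$copy_number < 1.9) return(NULL)
  aligned <- res$sub_end - res$sub_start
  if (aligned > 0 && res$edits / aligned > 0.35) return(NULL)
  data.frame(read_id = read_id, consensus = cons,
             unit_length = nchar(cons), copy_number = res$copy_number,
             sub_start = res$sub_start, sub_end = res$sub_end,
             score = res$score, stringsAsFactors = FALSE)
}

#' Select the optimal consensus among candidates of one read
#'
#' Deterministic ranking: copy-number-weighted vote score (descending), then
#' subread span (descending), then subread start (ascending).
#'
#' @param records data.frame of [callConsensus()] rows for one read
#' @return the selected row, or NULL for empty input
#' @export
selectOptimalConsensus <- function(records) {
  if (is.null(records) || nrow(records) == 0) return(NULL)
  span <- records$sub_end - records$sub_start
  o <- order(-records$score, -span, records$sub_start)
  records[o[1], , drop = FALSE]
}

#' Call consensus sequences for a read set
#'
#' Runs tandem-repeat detection, consensus calling on up to three candidate
#' periods per read, and optimal-consensus selection. Reads without a usable
#' tandem repeat are dropped with a reason code.
#'
#' @param reads named DNAStringSet (or named character vector)
#' @param min_period,max_period see [detectTandemRepeat()]
#' @return list with `records` (data.frame, one row per retained read) and
#'   `dropped` (data.frame: read_id, reason)
#' @export
callConsensusSet <- function(reads, min_period = 20L, max_period = 20000L) {
  seqs <- as.character(reads)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("read", seq_along(seqs))
  recs <- vector("list", length(seqs))
  drop_id <- character(0); drop_reason <- character(0)
  for (i in seq_along(seqs)) {
    cand <- detectTandemRepeat(seqs[i], min_period, max_period)
    if (nrow(cand) == 0) {
      drop_id <- c(drop_id, ids[i]); drop_reason <- c(drop_reason, "no_tandem_repeat")
      next
    }
    cand <- head(cand, 3L)
    calls <- do.call(rbind, lapply(seq_len(nrow(cand)), function(j)
      callConsensus(seqs[i], cand[j, ], read_id = ids[i])))
    best <- selectOptimalConsensus(calls)
    if (is.null(best)) {
      drop_id <- c(drop_id, ids[i]); drop_reason <- c(drop_reason, "no_consensus")
      next
    }
    recs[[i]] <- best
  }
  list(records = do.call(rbind, recs),
       dropped = data.frame(read_id = drop_id, reason = drop_reason,
                            stringsAsFactors = FALSE))
}

#' Write consensus records as FASTA
#'
#' Headers carry `read_id unit_length copy_number subread_span`.
#'
#' @param records data.frame from [callConsensusSet()]
#' @param path output file
#' @return `path`, invisibly
#' @export
writeConsensusFasta <- function(records, path) {
  x <- DNAStringSet(records$consensus)
  names(x) <- sprintf("%s %d %.2f %d-%d", records$read_id,
                      records$unit_length, records$copy_number,
                      records$sub_start, records$sub_end)
  writeXStringSet(x, path, width = 80)
  invisible(path)
}
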