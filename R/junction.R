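# Junction identification from two-copy concatemer alignments: locate the
# back-splice wrap, collect forward-splice junctions, correct splice sites
# against annotation and canonical motifs, and apply the high-confidence
# filters. Junction coordinates are 1-based: l/r are the last/first exonic
# bases flanking the spliced-out region.

#' Two-copy concatemer of a consensus sequence
#'
#' Doubling the consensus guarantees that every junction of the circle,
#' including the back-splice junction, is observed in a linear alignment.
#'
#' @param consensus consensus sequence (character)
#' @return the doubled sequence
#' @export
makeConcatemer <- function(consensus) {
  s <- as.character(consensus)
  if (nchar(s) == 0) stop("empty consensus")
  paste0(s, s)
}

#' Correct a splice junction against annotation and canonical motifs
#'
#' Shifts the donor and acceptor independently by up to `window` nt each to
#' the nearest positions giving (a) an annotated splice-site pair, else (b)
#' a canonical GT-AG motif (CT-AC on the minus strand); smaller total shifts
#' win, positive before negative on ties. The junction strand is set from
#' the motif (or the annotated pair). Unshiftable junctions keep their
#' coordinates with confidence "low".
#'
#' @param l,r junction coordinates: for an FSJ, `l` is the last exonic base
#'   of the upstream exon and `r` the first of the downstream exon (l < r);
#'   for a BSJ, `l` is the first base and `r` the last base of the circle
#' @param type "FSJ" or "BSJ"
#' @param gstr chromosome sequence (character)
#' @param sites splice-site sets from [spliceSites()]
#' @param window maximum shift in nt (default 10)
#' @param strand restrict the search to one strand (circRNA strand is defined
#'   by the BSJ, so FSJs are corrected on the BSJ's strand); NULL tries both
#' @return list(l, r, strand, annotated_left, annotated_right, confidence,
#'   shifted)
#' @export
refineSpliceSites <- function(l, r, type = c("FSJ", "BSJ"), gstr, sites,
                              window = 10L, strand = NULL) {
  type <- match.arg(type)
  stopifnot(window >= 0)
  strands <- if (is.null(strand) || !strand %in% c("+", "-")) c("+", "-")
  else strand
  d_order <- c(0L, as.vector(rbind(seq_len(window), -seq_len(window))))
  # per-side dinucleotide expected for each strand
  # FSJ: intron inside (l, r); BSJ: spliced-out flanks outside [l, r]
  l_dinuc <- function(d) {
    if (type == "FSJ") .dinuc(gstr, l + d + 1L) else .dinuc(gstr, l + d - 2L)
  }
  r_dinuc <- function(d) {
    if (type == "FSJ") .dinuc(gstr, r + d - 2L) else .dinuc(gstr, r + d + 1L)
  }
  want <- if (type == "FSJ")
    list("+" = c(l = "GT", r = "AG"), "-" = c(l = "CT", r = "AC"))
  else
    list("+" = c(l = "AG", r = "GT"), "-" = c(l = "AC", r = "CT"))
  side_sets <- function(st) {
    ss <- if (st == "+") sites$plus else sites$minus
    if (type == "FSJ") list(l = ss$ends, r = ss$starts)
    else list(l = ss$starts, r = ss$ends)
  }
  first_d <- function(test) {
    for (d in d_order) if (isTRUE(test(d))) return(d)
    NA_integer_
  }
  best <- NULL
  for (st in strands) { # nearest annotated site on each side
    ss <- side_sets(st)
    dl <- first_d(function(d) (l + d) %in% ss$l)
    dr <- first_d(function(d) (r + d) %in% ss$r)
    if (is.na(dl) || is.na(dr)) next
    cand <- list(dl = dl, dr = dr, strand = st, how = "annotated",
                 cost = abs(dl) + abs(dr))
    if (is.null(best) || cand$cost < best$cost) best <- cand
  }
  if (is.null(best)) { # fall back to the nearest canonical motif
    for (st in strands) {
      w <- want[[st]]
      dl <- first_d(function(d) identical(l_dinuc(d), unname(w["l"])))
      dr <- first_d(function(d) identical(r_dinuc(d), unname(w["r"])))
      if (is.na(dl) || is.na(dr)) next
      cand <- list(dl = dl, dr = dr, strand = st, how = "canonical",
                   cost = abs(dl) + abs(dr))
      if (is.null(best) || cand$cost < best$cost) best <- cand
    }
  }
  if (is.null(best)) best <- list(dl = 0L, dr = 0L, strand = "*", how = "none")
  pick <- best
  lf <- l + pick$dl; rf <- r + pick$dr
  st <- pick$strand
  ann_l <- ann_r <- FALSE
  if (st %in% c("+", "-")) {
    ss <- if (st == "+") sites$plus else sites$minus
    if (type == "FSJ") { ann_l <- lf %in% ss$ends; ann_r <- rf %in% ss$starts }
    else { ann_l <- lf %in% ss$starts; ann_r <- rf %in% ss$ends }
  }
  list(l = lf, r = rf, strand = st, annotated_left = ann_l,
       annotated_right = ann_r,
       confidence = if (pick$how == "none") "low" else "high",
       shifted = pick$dr)
}

# junctions of an alignment record in query order, each classified as FSJ
# (positive target gap) or wrap (negative target jump = BSJ evidence)
.record_junctions <- function(blocks) {
  n <- nrow(blocks)
  if (n < 2) return(NULL)
  out <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    gd <- unname(blocks[i + 1, "tstart"] - blocks[i, "tend"])
    if (gd >= .MIN_INTRON) {
      out[[i]] <- list(type = "FSJ", l = unname(blocks[i, "tend"]),
                       r = unname(blocks[i + 1, "tstart"]) + 1L,
                       qc = unname(blocks[i, "qend"]))
    } else if (gd <= -.MIN_INTRON) {
      out[[i]] <- list(type = "wrap", l = unname(blocks[i + 1, "tstart"]) + 1L,
                       r = unname(blocks[i, "tend"]),
                       qc = unname(blocks[i, "qend"]))
    } else {
      out[[i]] <- list(type = "tiny", l = NA, r = NA,
                       qc = unname(blocks[i, "qend"]))
    }
  }
  out
}

#' Call the BSJ and FSJs from a two-copy concatemer alignment
#'
#' The BSJ is the junction where the alignment wraps from the end of one
#' template copy to the start of the next; FSJs are the intron-spanning gaps
#' within a copy. All junctions are corrected with [refineSpliceSites()].
#' Every template copy must support the same junction set: with W wraps each
#' FSJ must be observed W or W + 1 times (fewer only at the query edges
#' where an observation is clipped), and all wrap observations must agree.
#'
#' @param record selected alignment record ([filterAlignments()])
#' @param unit_len template unit length (consensus length); used for the
#'   clipped-twin tolerance, derived from the aligned span when NULL
#' @param gstr chromosome sequence (character)
#' @param model a [GeneModel-class]
#' @param window splice-site correction window (default 10)
#' @return list with `ok`; on success `bsj` (refined), `fsjs` (data.frame
#'   sorted by position), `blocks` (exon structure, 1-based inclusive),
#'   `strand`; on failure `reason`
#' @export
callJunctions <- function(record, gstr, model, window = 10L,
                          unit_len = NULL) {
  fail <- function(reason) list(ok = FALSE, reason = reason)
  jx <- .record_junctions(record$blocks)
  if (is.null(jx)) return(fail("no_junction"))
  if (any(vapply(jx, function(j) j$type == "tiny", logical(1))))
    return(fail("unresolved_gap"))
  sites <- spliceSites(model)
  # back-splice wraps first: they fix the circRNA strand, which then
  # constrains forward-splice correction
  wrap_strand <- NULL
  refined <- vector("list", length(jx))
  for (i in seq_along(jx)) {
    j <- jx[[i]]
    if (j$type != "wrap") next
    rf <- refineSpliceSites(j$l, j$r, "BSJ", gstr, sites, window)
    if (is.null(wrap_strand) && rf$strand %in% c("+", "-"))
      wrap_strand <- rf$strand
    refined[[i]] <- c(j, rf[c("strand", "annotated_left", "annotated_right",
                              "confidence")],
                      list(lf = rf$l, rf = rf$r, shifted = rf$shifted))
  }
  for (i in seq_along(jx)) {
    j <- jx[[i]]
    if (j$type == "wrap") next
    rf <- refineSpliceSites(j$l, j$r, "FSJ", gstr, sites, window,
                            strand = wrap_strand)
    refined[[i]] <- c(j, rf[c("strand", "annotated_left", "annotated_right",
                              "confidence")],
                      list(lf = rf$l, rf = rf$r, shifted = rf$shifted))
  }
  types <- vapply(refined, `[[`, character(1), "type")
  wraps <- refined[types == "wrap"]
  fsjs <- refined[types == "FSJ"]
  if (length(wraps) == 0) return(fail("no_bsj"))
  wkeys <- vapply(wraps, function(w) paste(w$lf, w$rf), character(1))
  if (length(unique(wkeys)) != 1) return(fail("inconsistent_bsj"))
  bsj <- wraps[[1]]
  # copy concordance for FSJs: with W wraps the query holds W + 1 template
  # copies, so every FSJ must be seen W or W + 1 times; fewer is tolerated
  # only when the missing occurrence (one template unit away in the query)
  # would fall outside the aligned span
  n_wraps <- length(wraps)
  fkeys <- vapply(fsjs, function(f) paste(f$lf, f$rf), character(1))
  if (length(fkeys)) {
    tab <- table(fkeys)
    if (any(tab > n_wraps + 1)) return(fail("discordant_copies"))
    qmin <- unname(record$blocks[1, "qstart"])
    qmax <- unname(record$blocks[nrow(record$blocks), "qend"])
    if (is.null(unit_len)) unit_len <- (qmax - qmin) / (n_wraps + 1)
    for (k in names(tab)[tab < n_wraps]) {
      qc <- fsjs[[match(k, fkeys)]]$qc
      clipped <- (qc - unit_len) < qmin + 30 || (qc + unit_len) > qmax - 30
      if (!clipped) return(fail("discordant_copies"))
    }
  }
  ufsj <- fsjs[!duplicated(fkeys)]
  fl <- vapply(ufsj, `[[`, numeric(1), "lf")
  fr <- vapply(ufsj, `[[`, numeric(1), "rf")
  o <- order(fl)
  fl <- fl[o]; fr <- fr[o]; ufsj <- ufsj[o]
  bl <- unname(bsj$lf); br <- unname(bsj$rf)
  if (br <= bl) return(fail("degenerate_bsj"))
  if (length(fl)) {
    if (any(fl < bl | fr > br)) return(fail("fsj_outside_circle"))
    if (any(fr <= fl)) return(fail("malformed_fsj"))
    if (any(fl[-1] <= fr[-length(fr)])) return(fail("overlapping_introns"))
  }
  ex_start <- c(bl, fr)
  ex_end <- c(fl, br)
  if (any(ex_end < ex_start)) return(fail("malformed_blocks"))
  fconf <- vapply(ufsj, `[[`, character(1), "confidence")
  fstr <- vapply(ufsj, `[[`, character(1), "strand")
  list(ok = TRUE,
       bsj = list(l = bl, r = br, strand = bsj$strand,
                  annotated_left = bsj$annotated_left,
                  annotated_right = bsj$annotated_right,
                  confidence = bsj$confidence, qc = bsj$qc + bsj$shifted),
       fsjs = data.frame(l = fl, r = fr, strand = fstr, confidence = fconf,
                         stringsAsFactors = FALSE),
       blocks = cbind(start = ex_start, end = ex_end),
       strand = bsj$strand)
}

#' High-confidence evaluation of a called BSJ and FSJ set
#'
#' A BSJ whose coordinates match a database entry, or whose two sites are
#' both annotated, is high-confidence when junction correction succeeded. A
#' BSJ involving a novel site is held to a stricter standard: canonical
#' motif plus near-perfect consensus-to-genome alignment identity within
#' `novel_window` nt of the BSJ. A consensus with a high-confidence BSJ is a
#' candidate circRNA; if additionally every FSJ is high-confidence it is a
#' full-length circRNA isoform.
#'
#' @param jx result of [callJunctions()]
#' @param qseq the aligned concatemer sequence (query orientation used in the
#'   alignment)
#' @param gstr chromosome sequence
#' @param circdb a [CircDB-class] or NULL
#' @param chrom chromosome name
#' @param novel_window half-window around the BSJ for the identity check
#' @param novel_id_min minimum identity in that window (default 0.98)
#' @return list(bsj_high, fsj_all_high, bsj_known)
#' @export
evaluateConfidence <- function(jx, qseq, gstr, circdb, chrom,
                               novel_window = 20L, novel_id_min = 0.98) {
  stopifnot(isTRUE(jx$ok))
  bsj <- jx$bsj
  known <- FALSE
  if (!is.null(circdb)) {
    db <- bsjRecords(circdb)
    known <- any(as.character(seqnames(db)) == chrom &
                   start(db) == bsj$l & end(db) == bsj$r)
  }
  both_ann <- bsj$annotated_left && bsj$annotated_right
  if (known) {
    bsj_high <- TRUE
  } else if (both_ann) {
    bsj_high <- bsj$confidence == "high"
  } else {
    canonical <- !is.na(.bsj_motif_strand(gstr, bsj$l, bsj$r))
    w1 <- min(novel_window, bsj$qc)
    w2 <- min(novel_window, nchar(qseq) - bsj$qc)
    qwin <- substr(qseq, bsj$qc - w1 + 1L, bsj$qc + w2)
    gwin <- paste0(substr(gstr, bsj$r - w1 + 1L, bsj$r),
                   substr(gstr, bsj$l, bsj$l + w2 - 1L))
    ident <- if (nchar(qwin) > 0)
      1 - .edit_dist_cpp(qwin, gwin) / nchar(qwin) else 0
    bsj_high <- canonical && ident >= novel_id_min
  }
  fsj_all_high <- nrow(jx$fsjs) == 0 || all(jx$fsjs$confidence == "high")
  list(bsj_high = bsj_high, fsj_all_high = fsj_all_high, bsj_known = known)
}

#' Per-read circRNA junction calling
#'
#' Full junction stage: two-copy concatemer construction, spliced alignment,
#' alignment filtering, junction identification and correction, and
#' high-confidence evaluation, for every consensus record.
#'
#' @param records consensus records ([callConsensusSet()] `$records`)
#' @param genome named DNAStringSet
#' @param model a [GeneModel-class]
#' @param circdb a [CircDB-class] or NULL
#' @param sample sample label attached to the calls
#' @param mapq_min,window,novel_window,novel_id_min stage parameters
#' @return data.frame of per-read calls; failed reads carry a `drop_reason`
#' @export
callCircReads <- function(records, genome, model, circdb = NULL,
                          sample = "sample1", mapq_min = 1L, window = 10L,
                          novel_window = 20L, novel_id_min = 0.98) {
  index <- indexGenome(genome)
  qf <- vapply(records$consensus, makeConcatemer, character(1),
               USE.NAMES = FALSE)
  qr <- vapply(qf, .revcomp_chr, character(1), USE.NAMES = FALSE)
  anc_f <- lapply(index$chroms, function(g)
    .kmer_anchors_multi_cpp(qf, g, index$k, 30L))
  anc_r <- lapply(index$chroms, function(g)
    .kmer_anchors_multi_cpp(qr, g, index$k, 30L))
  rows <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    rid <- records$read_id[i]
    row <- data.frame(read_id = rid, sample = sample, chrom = NA_character_,
                      strand = NA_character_, bsj_start = NA_real_,
                      bsj_end = NA_real_, fsj = NA_character_,
                      blocks = NA_character_, bsj_known = NA,
                      bsj_high = NA, fsj_all_high = NA,
                      copy_number = records$copy_number[i],
                      drop_reason = NA_character_, stringsAsFactors = FALSE)
    af <- lapply(anc_f, `[[`, i)
    ar <- lapply(anc_r, `[[`, i)
    alns <- .align_one(qf[i], qr[i], af, ar, index)
    best <- filterAlignments(alns, qf[i], index, mapq_min = mapq_min)
    if (is.null(best)) {
      row$drop_reason <- "unmapped"; rows[[i]] <- row; next
    }
    gstr <- index$chroms[[best$chrom]]
    qseq <- if (best$qstrand == "+") qf[i] else qr[i]
    jx <- callJunctions(best, gstr, model, window = window,
                        unit_len = nchar(records$consensus[i]))
    if (!jx$ok) { row$drop_reason <- jx$reason; rows[[i]] <- row; next }
    conf <- evaluateConfidence(jx, qseq, gstr, circdb, best$chrom,
                               novel_window, novel_id_min)
    row$chrom <- best$chrom
    row$strand <- jx$strand
    row$bsj_start <- jx$bsj$l
    row$bsj_end <- jx$bsj$r
    row$fsj <- .fsj_string(jx$blocks[, "start"], jx$blocks[, "end"])
    row$blocks <- .blocks_string(jx$blocks[, "start"], jx$blocks[, "end"])
    row$bsj_known <- conf$bsj_known
    row$bsj_high <- conf$bsj_high
    row$fsj_all_high <- conf$fsj_all_high
    rows[[i]] <- row
  }
  do.call(rbind, rows)
}
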