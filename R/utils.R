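# Shared low-level helpers: sequence manipulation, splice-site motifs,
# junction keys. Coordinates are 1-based inclusive unless stated otherwise.

.BASES <- c("A", "C", "G", "T")

.rand_seq <- function(n) paste(sample(.BASES, n, replace = TRUE), collapse = "")

.revcomp_chr <- function(s) {
  as.character(reverseComplement(DNAStringSet(s)))
}

#' Rotate a circular sequence
#'
#' @param s character sequence
#' @param offset 0-based rotation offset; the rotated sequence starts at
#'   position `offset + 1` of `s`
#' @return rotated sequence of identical length
#' @export
rotateSeq <- function(s, offset) {
  n <- nchar(s)
  offset <- offset %% n
  if (offset == 0) return(s)
  paste0(substr(s, offset + 1, n), substr(s, 1, offset))
}

.all_rotations <- function(s) {
  vapply(seq_len(nchar(s)) - 1L, function(o) rotateSeq(s, o), character(1))
}

.dinuc <- function(gstr, pos) {
  if (pos < 1 || pos + 1 > nchar(gstr)) return(NA_character_)
  substr(gstr, pos, pos + 1)
}

# Strand implied by the splice motif of a forward-splice junction.
# l = last exonic base of the upstream exon, r = first exonic base of the
# downstream exon (l < r); the intron is (l, r) exclusive.
.fsj_motif_strand <- function(gstr, l, r) {
  d5 <- .dinuc(gstr, l + 1)
  d3 <- .dinuc(gstr, r - 2)
  if (is.na(d5) || is.na(d3)) return(NA_character_)
  if (d5 == "GT" && d3 == "AG") return("+")
  if (d5 == "CT" && d3 == "AC") return("-")
  NA_character_
}

# Strand implied by the back-splice motif. l = first base of the circle
# (low coordinate), r = last base (high coordinate); the spliced-out flanks
# lie outside [l, r].
.bsj_motif_strand <- function(gstr, l, r) {
  up <- .dinuc(gstr, l - 2)
  down <- .dinuc(gstr, r + 1)
  if (is.na(up) || is.na(down)) return(NA_character_)
  if (up == "AG" && down == "GT") return("+")
  if (up == "AC" && down == "CT") return("-")
  NA_character_
}

.fsj_string <- function(blocks_start, blocks_end) {
  n <- length(blocks_start)
  if (n < 2) return("")
  paste(paste0(blocks_end[-n], "-", blocks_start[-1]), collapse = "|")
}

.blocks_string <- function(blocks_start, blocks_end) {
  paste(paste0(blocks_start, "-", blocks_end), collapse = ";")
}

.parse_blocks <- function(s) {
  if (is.na(s) || s == "") return(matrix(numeric(0), ncol = 2))
  p <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "-", fixed = TRUE)
  m <- matrix(as.numeric(unlist(p)), ncol = 2, byrow = TRUE)
  colnames(m) <- c("start", "end")
  m
}

.parse_fsj <- function(s) {
  if (is.na(s) || s == "") return(matrix(numeric(0), ncol = 2))
  p <- strsplit(strsplit(s, "|", fixed = TRUE)[[1]], "-", fixed = TRUE)
  m <- matrix(as.numeric(unlist(p)), ncol = 2, byrow = TRUE)
  colnames(m) <- c("l", "r")
  m
}

.isoform_key <- function(chrom, strand, bsj_start, bsj_end, fsj) {
  paste(chrom, strand, bsj_start, bsj_end, ifelse(fsj == "", ".", fsj),
        sep = "|")
}

.bsj_key <- function(chrom, start, end) paste(chrom, start, end, sep = "|")

# i.i.d. per-base errors: substitutions, deletions, insertions (one random
# base inserted after a position). Vectorized; consumes RNG state.
.apply_errors <- function(seq, sub_rate, ins_rate, del_rate) {
  if (sub_rate + ins_rate + del_rate == 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  u <- runif(n)
  del <- u < del_rate
  sub <- !del & u < del_rate + sub_rate
  if (any(sub)) {
    # substitute with a uniformly chosen different base
    repl <- sample(.BASES, sum(sub), replace = TRUE)
    same <- repl == ch[sub]
    while (any(same)) {
      repl[same] <- sample(.BASES, sum(same), replace = TRUE)
      same <- repl == ch[sub]
    }
    ch[sub] <- repl
  }
  ins <- runif(n) < ins_rate
  ins_base <- character(n)
  if (any(ins)) ins_base[ins] <- sample(.BASES, sum(ins), replace = TRUE)
  out <- ch
  out[del] <- ""
  out <- paste0(out, ins_base)
  paste(out, collapse = "")
}

.hamming_vs <- function(a, b) {
  # mismatch count between equal-length strings
  if (nchar(a) != nchar(b)) stop("length mismatch")
  if (nchar(a) == 0) return(0L)
  sum(utf8ToInt(a) != utf8ToInt(b))
}
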