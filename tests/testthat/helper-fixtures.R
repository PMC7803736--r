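# Shared fixtures built in code. Everything deterministic under fixed seeds.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# small simulated dataset shared across junction/catalog tests
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simConfig(seed = 11, n_genes = 6, n_isoforms = 8,
                       reads_per_isoform = 3)
      cache <<- simulateCircData(cfg)
    }
    cache
  }
})

# a tiny hand-built gene model on a synthetic chromosome:
# plus-strand gene with 3 exons and canonical motifs planted
toy_model_data <- function(seed = 5) {
  set.seed(seed)
  g <- strsplit(rand_dna(3000), "")[[1]]
  ex_start <- c(201L, 501L, 901L)
  ex_end <- c(300L, 650L, 1050L)
  for (i in 1:3) {
    g[(ex_start[i] - 2):(ex_start[i] - 1)] <- c("A", "G")
    g[(ex_end[i] + 1):(ex_end[i] + 2)] <- c("G", "T")
  }
  gstr <- paste(g, collapse = "")
  exons <- GenomicRanges::GRangesList(
    tx1 = GenomicRanges::GRanges("chrT", IRanges::IRanges(ex_start, ex_end),
                                 strand = "+"))
  model <- geneModel(exons, c(tx1 = "geneA"))
  genome <- Biostrings::DNAStringSet(c(chrT = gstr))
  spliced <- paste(vapply(1:3, function(i)
    substr(gstr, ex_start[i], ex_end[i]), character(1)), collapse = "")
  list(genome = genome, gstr = gstr, model = model,
       ex_start = ex_start, ex_end = ex_end, spliced = spliced)
}

# brute-force oracles -------------------------------------------------------

oracle_chisq <- function(tab) {
  # Pearson chi-square from first principles
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

oracle_fisher2x2 <- function(tab) {
  # two-sided exact p by enumeration of the hypergeometric support
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  supp <- max(0, k - n):min(m, k)
  probs <- dhyper(supp, m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

oracle_bh <- function(p) {
  # step-up formula by hand
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

oracle_binom_upper <- function(x, n, p) {
  # one-tailed (greater) binomial tail by direct summation
  sum(dbinom(x:n, n, p))
}

oracle_alu <- function(bsj_start, bsj_end, rep_start, rep_end, rep_strand,
                       window) {
  # exhaustive all-pairs scan
  up <- which(rep_end >= bsj_start - window & rep_start <= bsj_start - 1)
  dn <- which(rep_end >= bsj_end + 1 & rep_start <= bsj_end + window)
  conv <- FALSE; divg <- FALSE
  for (u in up) for (d in dn) {
    if (rep_strand[u] == "+" && rep_strand[d] == "-") conv <- TRUE
    if (rep_strand[u] == "-" && rep_strand[d] == "+") divg <- TRUE
  }
  if (conv && divg) "both" else if (conv) "convergent"
  else if (divg) "divergent" else "none"
}

edit_rate <- function(a, b) circlong:::.edit_dist_cpp(a, b) / nchar(b)

# minimum edit distance between a sequence and any rotation of a template
rotation_edit <- function(seq, template) {
  circlong:::.infix_edit_cpp(seq, paste0(template, template))
}
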