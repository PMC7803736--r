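# Cross-sample statistics: replicate similarity, differential isoform usage
# between tissues (chi-square gene-level screen + per-isoform Fisher),
# tissue-stable and tissue-specific calls, the tissue-specificity index tau,
# inverted-Alu flanking classification and negative-control BSJs. The test
# kernels are the standard stats:: implementations behind this module's
# surface.

#' Degree of similarity between two detection sets
#'
#' Number of elements detected in both sets divided by the total number of
#' unique elements detected in either (Jaccard index over BSJ or isoform
#' keys).
#'
#' @param a,b vectors of keys
#' @return fraction in [0, 1]
#' @export
setSimilarity <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- union(a, b)
  if (length(u) == 0) stop("similarity undefined for two empty sets")
  length(intersect(a, b)) / length(u)
}

#' Chi-square test of isoform proportions for one gene between two tissues
#'
#' Pearson chi-square (no continuity correction) on the isoform x tissue
#' contingency table, after restricting to isoforms with at least
#' `min_reads` reads in at least one of the two tissues.
#'
#' @param x1,x2 isoform read counts of one gene in the two tissues (parallel
#'   vectors)
#' @param min_reads inclusion floor (default 2)
#' @return list(statistic, df, p, n_isoforms, skipped, reason)
#' @export
geneProportionTest <- function(x1, x2, min_reads = 2L) {
  stopifnot(length(x1) == length(x2))
  keep <- x1 >= min_reads | x2 >= min_reads
  x1 <- x1[keep]; x2 <- x2[keep]
  skip <- function(reason) list(statistic = NA_real_, df = NA_real_,
                                p = NA_real_, n_isoforms = length(x1),
                                skipped = TRUE, reason = reason)
  if (length(x1) < 2) return(skip("fewer than two isoforms"))
  if (sum(x1) == 0 || sum(x2) == 0) return(skip("zero gene total in a tissue"))
  ct <- suppressWarnings(chisq.test(cbind(x1, x2), correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value), n_isoforms = length(x1), skipped = FALSE,
       reason = NA_character_)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param p vector of p-values
#' @return adjusted values (step-up with monotonicity enforcement)
#' @export
bhAdjust <- function(p) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  p.adjust(p, method = "BH")
}

#' Flag genes with differential isoform proportions
#'
#' A gene is flagged when its BH-adjusted p-value is at most `fdr` and at
#' least one isoform shifts its within-gene proportion by at least
#' `min_delta` between the tissues.
#'
#' @param p raw gene-level p-values
#' @param max_delta per-gene maximum absolute isoform-proportion difference
#' @param fdr,min_delta thresholds (defaults 0.05 and 0.05)
#' @return logical vector
#' @export
flagDifferentialGenes <- function(p, max_delta, fdr = 0.05, min_delta = 0.05) {
  padj <- bhAdjust(p)
  !is.na(padj) & padj <= fdr & max_delta >= min_delta
}

#' Fisher's exact test for one isoform between two tissues
#'
#' 2 x 2 table of (isoform reads, all other isoforms' reads) x tissues;
#' two-sided exact p plus the isoform-proportion difference.
#'
#' @param tab 2 x 2 matrix: rows = (isoform, others), columns = tissues
#' @return list(p, delta); a zero-margin table gives p = 1 by convention
#' @export
isoformFisher <- function(tab) {
  stopifnot(identical(dim(tab), c(2L, 2L)), all(tab >= 0))
  cs <- colSums(tab)
  if (any(rowSums(tab) == 0) || any(cs == 0))
    return(list(p = 1, delta = if (all(cs > 0))
      tab[1, 1] / cs[1] - tab[1, 2] / cs[2] else NA_real_))
  ft <- fisher.test(tab, alternative = "two.sided")
  list(p = unname(ft$p.value),
       delta = unname(tab[1, 1] / cs[1] - tab[1, 2] / cs[2]))
}

#' Two-step pairwise-tissue comparison of isoform proportions
#'
#' Step one screens genes (at least two eligible isoforms) with the
#' chi-square test, BH-adjusted; a gene is differential when FDR <= `fdr`
#' and some isoform's proportion shifts by >= `min_delta`. Step two tests
#' each isoform of a differential gene with the two-sided Fisher exact test;
#' an isoform is significant when p <= `alpha_iso` and its proportion
#' difference is >= `min_delta`.
#'
#' @param counts isoform x sample count matrix
#' @param genes gene id per isoform
#' @param t1,t2 column names of the two tissues
#' @param fdr,min_delta,alpha_iso,min_reads thresholds
#' @return list(genes = data.frame, isoforms = data.frame)
#' @export
pairwiseTissueTest <- function(counts, genes, t1, t2, fdr = 0.05,
                               min_delta = 0.05, alpha_iso = 0.05,
                               min_reads = 2L) {
  x1 <- counts[, t1]; x2 <- counts[, t2]
  gdf <- list(); idf <- list()
  for (g in unique(genes)) {
    idx <- which(genes == g & (x1 >= min_reads | x2 >= min_reads))
    if (length(idx) < 2) next
    gt <- geneProportionTest(x1[idx], x2[idx], min_reads = min_reads)
    if (gt$skipped) next
    p1 <- x1[idx] / sum(x1[idx]); p2 <- x2[idx] / sum(x2[idx])
    gdf[[g]] <- data.frame(gene_id = g, statistic = gt$statistic,
                           df = gt$df, p = gt$p,
                           max_delta = max(abs(p1 - p2)),
                           stringsAsFactors = FALSE)
  }
  gout <- do.call(rbind, gdf)
  if (is.null(gout))
    return(list(genes = data.frame(), isoforms = data.frame()))
  gout$padj <- bhAdjust(gout$p)
  gout$differential <- flagDifferentialGenes(gout$p, gout$max_delta,
                                             fdr = fdr, min_delta = min_delta)
  for (g in gout$gene_id[gout$differential]) {
    idx <- which(genes == g & (x1 >= min_reads | x2 >= min_reads))
    for (i in idx) {
      tab <- rbind(c(x1[i], x2[i]),
                   c(sum(x1[idx]) - x1[i], sum(x2[idx]) - x2[i]))
      ft <- isoformFisher(tab)
      idf[[length(idf) + 1L]] <- data.frame(
        gene_id = g, isoform = rownames(counts)[i], p = ft$p,
        delta = ft$delta,
        significant = ft$p <= alpha_iso && !is.na(ft$delta) &&
          abs(ft$delta) >= min_delta,
        stringsAsFactors = FALSE)
    }
  }
  list(genes = gout, isoforms = if (length(idf)) do.call(rbind, idf)
       else data.frame())
}

#' Tissue-stable isoform call
#'
#' Stable when the isoform's within-gene proportion is strictly above
#' `min_prop` in every tissue and it has at least `min_reads` reads in every
#' tissue.
#'
#' @param iso_counts isoform read counts across tissues
#' @param gene_totals gene read totals across the same tissues
#' @param min_prop,min_reads thresholds (defaults 0.5 and 2)
#' @return logical
#' @export
tissueStable <- function(iso_counts, gene_totals, min_prop = 0.5,
                         min_reads = 2L) {
  stopifnot(length(iso_counts) == length(gene_totals))
  if (any(gene_totals == 0)) return(FALSE)
  all(iso_counts / gene_totals > min_prop) && all(iso_counts >= min_reads)
}

#' Tissue-specific isoform calls
#'
#' Case (i): genes whose reads are all confined to a single tissue have all
#' their isoforms flagged for that tissue. Case (ii): for genes whose
#' isoform proportions are not homogeneous across tissues (chi-square, BH
#' FDR <= `fdr`), isoform-tissue pairs whose proportion exceeds the overall
#' isoform proportion (one-tailed binomial, BH FDR <= `fdr`) are flagged
#' when the proportion difference between the tissue and all other tissues
#' is >= `min_delta` and the isoform has >= `min_reads` reads in the tissue.
#'
#' @param counts isoform x tissue count matrix
#' @param genes gene id per isoform
#' @param fdr,min_delta,min_reads thresholds
#' @param fdr_scope family for the binomial BH adjustment: "global" (all
#'   selected isoform-tissue pairs) or "gene"
#' @return data.frame: gene_id, isoform, tissue, case, p, padj, delta
#' @export
tissueSpecific <- function(counts, genes, fdr = 0.05, min_delta = 0.05,
                           min_reads = 2L, fdr_scope = c("global", "gene")) {
  fdr_scope <- match.arg(fdr_scope)
  eligible <- rowSums(counts >= min_reads) >= 1
  out <- list()
  gene_p <- list(); gene_rows <- list()
  for (g in unique(genes)) {
    idx <- which(genes == g & eligible)
    if (!length(idx)) next
    sub <- counts[idx, , drop = FALSE]
    tissue_tot <- colSums(sub)
    det <- which(tissue_tot > 0)
    if (length(det) == 1) { # case (i): exclusively detected in one tissue
      for (i in idx)
        out[[length(out) + 1L]] <- data.frame(
          gene_id = g, isoform = rownames(counts)[i],
          tissue = colnames(counts)[det], case = "exclusive",
          p = NA_real_, padj = NA_real_, delta = NA_real_,
          stringsAsFactors = FALSE)
      next
    }
    if (length(idx) < 2) next
    ct <- suppressWarnings(chisq.test(sub[, det, drop = FALSE],
                                      correct = FALSE))
    gene_p[[g]] <- ct$p.value
    gene_rows[[g]] <- idx
  }
  if (length(gene_p)) {
    gp <- bhAdjust(unlist(gene_p))
    names(gp) <- names(gene_p)
    pair <- list()
    for (g in names(gp)[!is.na(gp) & gp <= fdr]) {
      idx <- gene_rows[[g]]
      sub <- counts[idx, , drop = FALSE]
      tissue_tot <- colSums(sub)
      overall <- rowSums(sub) / sum(sub)
      for (r in seq_along(idx)) {
        for (t in which(tissue_tot > 0)) {
          xx <- sub[r, t]; nn <- tissue_tot[t]
          p0 <- overall[r]
          pv <- pbinom(xx - 1, nn, p0, lower.tail = FALSE)
          prop_t <- xx / nn
          other_tot <- sum(sub) - nn
          prop_o <- if (other_tot > 0) (rowSums(sub)[r] - xx) / other_tot else 0
          pair[[length(pair) + 1L]] <- data.frame(
            gene_id = g, isoform = rownames(counts)[idx[r]],
            tissue = colnames(counts)[t], case = "proportion-shift",
            p = unname(pv), padj = NA_real_,
            delta = unname(prop_t - prop_o), reads = unname(xx),
            stringsAsFactors = FALSE)
        }
      }
    }
    if (length(pair)) {
      pdf <- do.call(rbind, pair)
      pdf$padj <- if (fdr_scope == "global") bhAdjust(pdf$p)
      else ave(pdf$p, pdf$gene_id, FUN = bhAdjust)
      keep <- pdf$padj <= fdr & pdf$delta >= min_delta & pdf$reads >= min_reads
      pdf <- pdf[keep, setdiff(colnames(pdf), "reads"), drop = FALSE]
      if (nrow(pdf)) out[[length(out) + 1L]] <- pdf
    }
  }
  if (!length(out)) return(data.frame(gene_id = character(0),
                                      isoform = character(0),
                                      tissue = character(0),
                                      case = character(0), p = numeric(0),
                                      padj = numeric(0), delta = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Yanai's tissue-specificity index tau
#'
#' tau = sum_i(1 - x_i / max(x)) / (n - 1). Zero for a uniformly expressed
#' (housekeeping) gene, one for single-tissue expression.
#'
#' @param x non-negative expression vector (one value per tissue)
#' @return tau in [0, 1]
#' @export
tauIndex <- function(x) {
  stopifnot(length(x) >= 2, all(x >= 0))
  if (all(x == 0)) stop("tau undefined for an all-zero expression vector")
  sum(1 - x / max(x)) / (length(x) - 1)
}

#' Enrichment of tissue-specific isoforms in tissue-specific genes
#'
#' Fisher's exact test (two-sided) on the 2 x 2 table of isoform specificity
#' by gene specificity, under the null that tissue-specific genes are equally
#' likely to express tissue-specific isoforms.
#'
#' @param iso_specific logical per isoform
#' @param gene_specific logical per isoform (specificity of the host gene)
#' @return list(odds_ratio, p); an empty stratum gives p = 1
#' @export
enrichmentTest <- function(iso_specific, gene_specific) {
  tab <- table(factor(iso_specific, c(TRUE, FALSE)),
               factor(gene_specific, c(TRUE, FALSE)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(odds_ratio = NA_real_, p = 1))
  ft <- fisher.test(tab, alternative = "two.sided")
  list(odds_ratio = unname(ft$estimate), p = unname(ft$p.value))
}

#' Inverted-Alu classification of BSJ flanks
#'
#' Checks a window of `window` nt upstream of the back-splice acceptor and
#' downstream of the donor (clipped to chromosome bounds) for inverted Alu
#' pairs: one element in each flank on opposite strands. With element strand
#' read as pointing direction, a pair pointing toward the circle (upstream
#' "+", downstream "-") is convergent; pointing away is divergent; "both"
#' when at least one pair of each orientation exists; "none" otherwise.
#'
#' @param bsj GRanges of BSJs (start = first base, end = last base)
#' @param repeats GRanges of repeat elements with strand
#' @param window flank width in nt (1000 or 2000)
#' @return character vector over convergent, divergent, both, none
#' @export
aluFlankClassify <- function(bsj, repeats, window = 1000L) {
  stopifnot(window > 0)
  up <- GRanges(seqnames(bsj),
                IRanges(pmax(1L, start(bsj) - window), pmax(1L, start(bsj) - 1L)))
  dn <- GRanges(seqnames(bsj), IRanges(end(bsj) + 1L, end(bsj) + window))
  ovu <- findOverlaps(up, repeats, ignore.strand = TRUE)
  ovd <- findOverlaps(dn, repeats, ignore.strand = TRUE)
  rs <- as.character(strand(repeats))
  out <- character(length(bsj))
  for (i in seq_along(bsj)) {
    us <- rs[subjectHits(ovu)[queryHits(ovu) == i]]
    ds <- rs[subjectHits(ovd)[queryHits(ovd) == i]]
    conv <- any(us == "+") && any(ds == "-")
    divg <- any(us == "-") && any(ds == "+")
    out[i] <- if (conv && divg) "both" else if (conv) "convergent"
    else if (divg) "divergent" else "none"
  }
  out
}

#' Negative-control BSJs from non-BSJ splice sites
#'
#' Random pairs of a downstream 5' splice site and an upstream 3' splice
#' site (back-splice geometry: genomic start < end on the same chromosome
#' and strand), drawn without replacement from annotated splice sites that
#' do not participate in any observed or known BSJ.
#'
#' @param model a [GeneModel-class]
#' @param exclude GRanges of observed/known BSJs whose boundary sites are
#'   removed from the pools (may be NULL)
#' @param n number of control pairs (default 10000)
#' @param chrom chromosome to draw from (default: first annotated)
#' @return GRanges of control BSJs (fewer than `n` with a warning when the
#'   eligible pairs run out)
#' @export
makeControlBsjs <- function(model, exclude = NULL, n = 10000L, chrom = NULL) {
  sites <- spliceSites(model)
  gr <- geneRanges(model)
  if (is.null(chrom)) chrom <- as.character(seqnames(gr))[1]
  out <- list()
  for (st in c("+", "-")) {
    ss <- if (st == "+") sites$plus else sites$minus
    starts <- ss$starts; ends <- ss$ends
    if (!is.null(exclude) && length(exclude)) {
      keep_ex <- as.character(seqnames(exclude)) == chrom
      starts <- setdiff(starts, start(exclude)[keep_ex])
      ends <- setdiff(ends, end(exclude)[keep_ex])
    }
    if (!length(starts) || !length(ends)) next
    grid <- expand.grid(s = starts, e = ends)
    grid <- grid[grid$s < grid$e, , drop = FALSE]
    if (!nrow(grid)) next
    out[[st]] <- cbind(grid, st = st)
  }
  all <- do.call(rbind, out)
  if (is.null(all) || !nrow(all)) {
    warning("no eligible control pairs")
    return(GRanges())
  }
  if (nrow(all) < n) {
    warning("only ", nrow(all), " eligible control pairs (requested ", n, ")")
    take <- seq_len(nrow(all))
  } else {
    take <- sample.int(nrow(all), n)
  }
  GRanges(chrom, IRanges(all$s[take], all$e[take]), strand = all$st[take])
}

#' Normalized BSJ detection rate
#'
#' Number of detected BSJs divided by the total number of long reads in the
#' sample, for cross-platform and cross-tissue comparisons.
#'
#' @param bsj_count number of BSJs (each supported by at least two reads)
#' @param total_reads total long reads in the sample
#' @return rate
#' @export
normalizedBsjCount <- function(bsj_count, total_reads) {
  stopifnot(bsj_count >= 0)
  if (total_reads <= 0) stop("total_reads must be positive")
  bsj_count / total_reads
}
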