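#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importClassesFrom GenomicRanges GRanges GRangesList
NULL

# ---------------------------------------------------------------------------
# SimConfig
# ---------------------------------------------------------------------------

#' Simulation configuration
#'
#' Parameters of the rolling-circle read simulator: toy genome geometry,
#' alternative-splicing event mix, annotation completeness, copy-number
#' distribution of the concatemer reads and per-base error rates.
#'
#' @slot seed integer seed; identical seed + config gives byte-identical output
#' @slot n_genes number of multi-exon genes on the toy genome
#' @slot exons_per_gene,exon_len,intron_len integer ranges (min, max)
#' @slot n_isoforms number of circRNA isoforms to simulate
#' @slot as_event_mix named proportions over SE, A5SS, A3SS, RI, none
#' @slot novel_site_rate probability that the linear transcript matching a
#'   simulated splicing variant is omitted from the emitted annotation
#' @slot copy_number_mean,copy_number_min,copy_number_dist,nb_size copy-number
#'   model of the concatemer (shifted nbinom/geom, or fixed)
#' @slot sub_rate,ins_rate,del_rate i.i.d. per-base error probabilities
#' @slot reads_per_isoform reads simulated per isoform
#' @slot alu_mix named proportions over convergent, divergent, both, none for
#'   Alu-like repeat placement around BSJs
#' @exportClass SimConfig
setClass("SimConfig", representation(
  seed = "integer",
  n_genes = "integer",
  exons_per_gene = "integer",
  exon_len = "integer",
  intron_len = "integer",
  n_isoforms = "integer",
  as_event_mix = "numeric",
  novel_site_rate = "numeric",
  copy_number_mean = "numeric",
  copy_number_min = "integer",
  copy_number_dist = "character",
  nb_size = "numeric",
  sub_rate = "numeric",
  ins_rate = "numeric",
  del_rate = "numeric",
  reads_per_isoform = "integer",
  alu_mix = "numeric"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  rates <- c(object@novel_site_rate, object@sub_rate, object@ins_rate,
             object@del_rate)
  if (any(rates < 0 | rates > 1)) msg <- c(msg, "rates must be in [0, 1]")
  if (abs(sum(object@as_event_mix) - 1) > 1e-8)
    msg <- c(msg, "as_event_mix must sum to 1")
  if (!identical(sort(names(object@as_event_mix)),
                 sort(c("SE", "A5SS", "A3SS", "RI", "none"))))
    msg <- c(msg, "as_event_mix needs names SE, A5SS, A3SS, RI, none")
  for (nm in c("exons_per_gene", "exon_len", "intron_len")) {
    rg <- slot(object, nm)
    if (length(rg) != 2 || any(rg <= 0) || rg[1] > rg[2])
      msg <- c(msg, paste(nm, "must be a positive (min, max) range"))
  }
  if (object@copy_number_min < 1L)
    msg <- c(msg, "copy_number_min must be >= 1")
  if (object@copy_number_mean < object@copy_number_min)
    msg <- c(msg, "copy_number_mean must be >= copy_number_min")
  if (!object@copy_number_dist %in% c("nbinom", "geom", "fixed"))
    msg <- c(msg, "copy_number_dist must be nbinom, geom or fixed")
  if (abs(sum(object@alu_mix) - 1) > 1e-8)
    msg <- c(msg, "alu_mix must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Create a simulation configuration
#'
#' Defaults reflect the study conditions the pipeline targets: a mean
#' concatemer copy number of 14.5 (shifted negative binomial, minimum 2
#' copies), an 8 percent total per-base error rate split 4/2/2 over
#' substitutions, insertions and deletions, and a splicing-event mix in which
#' half the isoforms match their parent exon chain.
#'
#' @param seed integer RNG seed
#' @param n_genes,exons_per_gene,exon_len,intron_len toy genome geometry
#' @param n_isoforms,reads_per_isoform simulated catalog size
#' @param as_event_mix named proportions over SE, A5SS, A3SS, RI, none
#' @param novel_site_rate probability a splicing variant is left unannotated
#' @param copy_number_mean,copy_number_min,copy_number_dist,nb_size copy-number
#'   distribution of the rolling-circle concatemer
#' @param sub_rate,ins_rate,del_rate per-base error probabilities
#' @param alu_mix named proportions over convergent, divergent, both, none
#' @return a validated [SimConfig-class] object
#' @examples
#' cfg <- simConfig(seed = 1, n_genes = 4, n_isoforms = 6)
#' @export
simConfig <- function(seed = 1L,
                      n_genes = 20L,
                      exons_per_gene = c(3L, 8L),
                      exon_len = c(60L, 200L),
                      intron_len = c(150L, 400L),
                      n_isoforms = 50L,
                      as_event_mix = c(SE = 0.2, A5SS = 0.1, A3SS = 0.1,
                                       RI = 0.2, none = 0.4),
                      novel_site_rate = 0.1,
                      copy_number_mean = 14.5,
                      copy_number_min = 2L,
                      copy_number_dist = "nbinom",
                      nb_size = 5,
                      sub_rate = 0.04,
                      ins_rate = 0.02,
                      del_rate = 0.02,
                      reads_per_isoform = 10L,
                      alu_mix = c(convergent = 0.3, divergent = 0.2,
                                  both = 0.2, none = 0.3)) {
  new("SimConfig",
      seed = as.integer(seed), n_genes = as.integer(n_genes),
      exons_per_gene = as.integer(exons_per_gene),
      exon_len = as.integer(exon_len), intron_len = as.integer(intron_len),
      n_isoforms = as.integer(n_isoforms),
      as_event_mix = as_event_mix[c("SE", "A5SS", "A3SS", "RI", "none")],
      novel_site_rate = novel_site_rate,
      copy_number_mean = copy_number_mean,
      copy_number_min = as.integer(copy_number_min),
      copy_number_dist = copy_number_dist, nb_size = nb_size,
      sub_rate = sub_rate, ins_rate = ins_rate, del_rate = del_rate,
      reads_per_isoform = as.integer(reads_per_isoform),
      alu_mix = alu_mix[c("convergent", "divergent", "both", "none")])
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@n_genes, "genes,", object@n_isoforms,
      "isoforms,", object@reads_per_isoform, "reads/isoform\n")
  cat("  copy number:", object@copy_number_dist, "mean",
      object@copy_number_mean, "min", object@copy_number_min, "\n")
  cat("  error rates: sub", object@sub_rate, "ins", object@ins_rate,
      "del", object@del_rate, "\n")
})

# ---------------------------------------------------------------------------
# GeneModel
# ---------------------------------------------------------------------------

#' Linear-transcript gene annotation
#'
#' Exon structures of linear transcripts plus the derived splice-site sets and
#' per-transcript forward-splice-junction chains used for junction correction
#' and FSM/NIC/NNC classification. Splice-site positions are stored 1-based:
#' an exon's first and last genomic base.
#'
#' @slot exons GRangesList of exons, one element per transcript, ordered by
#'   genomic position
#' @slot txGene character, gene id per transcript (names = transcript ids)
#' @slot sites derived splice-site sets per strand
#' @slot txChain derived FSJ chain string per transcript
#' @slot geneSites derived unique splice-site positions per gene
#' @slot geneRanges derived genomic span per gene
#' @exportClass GeneModel
setClass("GeneModel", representation(
  exons = "GRangesList",
  txGene = "character",
  sites = "list",
  txChain = "character",
  geneSites = "list",
  geneRanges = "GRanges"
))

setValidity("GeneModel", function(object) {
  if (length(object@exons) != length(object@txGene))
    return("one gene id is required per transcript")
  for (i in seq_along(object@exons)) {
    ex <- object@exons[[i]]
    if (length(ex) > 1) {
      s <- start(ex); e <- end(ex)
      if (is.unsorted(s, strictly = TRUE) || any(s[-1] <= e[-length(e)]))
        return("exons within a transcript must be ordered and non-overlapping")
    }
  }
  TRUE
})

.fsj_chain <- function(ex) {
  if (length(ex) < 2) return("")
  l <- end(ex)[-length(ex)]
  r <- start(ex)[-1]
  paste(paste0(l, "-", r), collapse = "|")
}

#' Construct a GeneModel
#'
#' @param exons GRangesList of exons, one element per transcript (each
#'   element's ranges sorted by genomic start, strand set)
#' @param txGene character vector of gene ids, one per transcript; names are
#'   taken as transcript ids (defaults to names of `exons`)
#' @return a [GeneModel-class]
#' @export
geneModel <- function(exons, txGene) {
  if (is.null(names(exons))) names(exons) <- paste0("tx", seq_along(exons))
  if (is.null(names(txGene))) names(txGene) <- names(exons)
  ex_all <- unlist(exons, use.names = FALSE)
  tx_of <- rep(names(exons), lengths(exons))
  gene_of <- txGene[tx_of]
  str_of <- as.character(strand(ex_all))
  sites <- list()
  for (st in c("+", "-")) {
    keep <- str_of == st
    sites[[if (st == "+") "plus" else "minus"]] <- list(
      starts = sort(unique(start(ex_all)[keep])),
      ends = sort(unique(end(ex_all)[keep])))
  }
  chains <- vapply(exons, .fsj_chain, character(1))
  genes <- unique(unname(txGene))
  geneSites <- lapply(genes, function(g) {
    keep <- gene_of == g
    sort(unique(c(start(ex_all)[keep], end(ex_all)[keep])))
  })
  names(geneSites) <- genes
  gr <- GRanges(
    seqnames = vapply(genes, function(g)
      as.character(seqnames(ex_all)[gene_of == g][1]), character(1)),
    ranges = IRanges(
      start = vapply(genes, function(g) min(start(ex_all)[gene_of == g]), numeric(1)),
      end = vapply(genes, function(g) max(end(ex_all)[gene_of == g]), numeric(1))),
    strand = vapply(genes, function(g)
      as.character(strand(ex_all)[gene_of == g][1]), character(1)))
  names(gr) <- genes
  new("GeneModel", exons = exons, txGene = txGene, sites = sites,
      txChain = chains, geneSites = geneSites, geneRanges = gr)
}

#' @describeIn geneModel transcript exon structures
#' @param object,x a GeneModel
#' @export
setGeneric("txExons", function(x) standardGeneric("txExons"))
#' @rdname geneModel
#' @export
setMethod("txExons", "GeneModel", function(x) x@exons)

#' @describeIn geneModel gene id per transcript
#' @export
setGeneric("txGenes", function(x) standardGeneric("txGenes"))
#' @rdname geneModel
#' @export
setMethod("txGenes", "GeneModel", function(x) x@txGene)

#' @describeIn geneModel splice-site sets per strand (1-based exon first/last
#'   bases)
#' @export
setGeneric("spliceSites", function(x) standardGeneric("spliceSites"))
#' @rdname geneModel
#' @export
setMethod("spliceSites", "GeneModel", function(x) x@sites)

#' @describeIn geneModel genomic span per gene
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))
#' @rdname geneModel
#' @export
setMethod("geneRanges", "GeneModel", function(x) x@geneRanges)

setMethod("show", "GeneModel", function(object) {
  cat("GeneModel:", length(unique(object@txGene)), "genes,",
      length(object@exons), "transcripts,",
      sum(lengths(object@exons)), "exons\n")
})

# ---------------------------------------------------------------------------
# CircDB
# ---------------------------------------------------------------------------

#' Known back-splice junction database
#'
#' A set of annotated circRNA BSJs, each a genomic interval whose start is the
#' first base and whose end is the last base of the circle (1-based,
#' GRanges convention), with a source label per record.
#'
#' @slot bsjs GRanges with a `source` metadata column
#' @exportClass CircDB
setClass("CircDB", representation(bsjs = "GRanges"))

setValidity("CircDB", function(object) {
  if (is.null(mcols(object@bsjs)$source))
    return("bsjs must carry a 'source' metadata column")
  if (any(start(object@bsjs) > end(object@bsjs)))
    return("invalid BSJ coordinates")
  TRUE
})

#' Construct a BSJ database
#'
#' @param bsjs GRanges of BSJ intervals (start = first base, end = last base
#'   of the circle, 1-based)
#' @param source source label(s), recycled over records
#' @return a [CircDB-class]
#' @export
circDb <- function(bsjs, source = "db") {
  mcols(bsjs)$source <- rep(source, length.out = length(bsjs))
  new("CircDB", bsjs = bsjs)
}

#' @describeIn circDb the BSJ records
#' @param x a CircDB
#' @export
setGeneric("bsjRecords", function(x) standardGeneric("bsjRecords"))
#' @rdname circDb
#' @export
setMethod("bsjRecords", "CircDB", function(x) x@bsjs)

#' @describeIn circDb the distinct source labels
#' @export
setGeneric("dbSources", function(x) standardGeneric("dbSources"))
#' @rdname circDb
#' @export
setMethod("dbSources", "CircDB", function(x) unique(mcols(x@bsjs)$source))

setMethod("show", "CircDB", function(object) {
  cat("CircDB:", length(object@bsjs), "BSJ records from",
      length(unique(mcols(object@bsjs)$source)), "source(s)\n")
})

# ---------------------------------------------------------------------------
# CircCatalog
# ---------------------------------------------------------------------------

#' Quantified full-length circRNA isoform catalog
#'
#' A RangedSummarizedExperiment whose rows are full-length circRNA isoforms
#' (rowRanges: exon-block structure as a GRangesList) and whose columns are
#' samples; the `counts` assay holds read counts (independent supporting
#' reads, not within-read copy numbers). Row metadata records the BSJ
#' coordinates, FSJ chain, category labels and gene assignment.
#'
#' @exportClass CircCatalog
setClass("CircCatalog", contains = "RangedSummarizedExperiment")

setValidity("CircCatalog", function(object) {
  need <- c("chrom", "circ_strand", "bsj_start", "bsj_end", "fsj")
  if (!all(need %in% colnames(rowData(object))))
    return(paste("rowData must contain", paste(need, collapse = ", ")))
  if (!"counts" %in% names(assays(object)))
    return("a 'counts' assay is required")
  if (any(assay(object, "counts") < 0))
    return("read counts must be non-negative")
  TRUE
})

#' @describeIn collapseIsoforms BSJ coordinates of each isoform as GRanges
#' @param x a CircCatalog
#' @export
setGeneric("bsjCoords", function(x) standardGeneric("bsjCoords"))
#' @rdname collapseIsoforms
#' @export
setMethod("bsjCoords", "CircCatalog", function(x) {
  rd <- rowData(x)
  GRanges(rd$chrom, IRanges(rd$bsj_start, rd$bsj_end),
          strand = rd$circ_strand)
})

#' @describeIn collapseIsoforms isoform identity keys
#' @export
setGeneric("isoformKeys", function(x) standardGeneric("isoformKeys"))
#' @rdname collapseIsoforms
#' @export
setMethod("isoformKeys", "CircCatalog", function(x) rownames(x))

setMethod("show", "CircCatalog", function(object) {
  cat("CircCatalog:", nrow(object), "isoforms x", ncol(object), "sample(s)\n")
  rd <- rowData(object)
  cat("  distinct BSJs:",
      length(unique(paste(rd$chrom, rd$bsj_start, rd$bsj_end))), "\n")
  if ("bsj_category" %in% colnames(rd))
    cat("  BSJ categories:",
        paste(names(table(rd$bsj_category)), table(rd$bsj_category),
              collapse = ", "), "\n")
})
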