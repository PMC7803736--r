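# Standard-format IO: GTF gene annotation, BED BSJ databases and repeat
# tracks, catalog tables. All parsing goes through rtracklayer/Biostrings;
# this file only adapts the containers.

#' Read a gene annotation from GTF
#'
#' @param path GTF file (exon rows with gene_id and transcript_id attributes)
#' @return a [GeneModel-class]
#' @export
readGeneModelGtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  sp <- split(granges(gr), gr$transcript_id)
  sp <- GRangesList(lapply(sp, GenomicRanges::sort))
  tx2gene <- vapply(split(gr$gene_id, gr$transcript_id), `[`, character(1), 1)
  geneModel(sp, tx2gene[names(sp)])
}

#' Write a gene annotation as GTF
#'
#' @param model a [GeneModel-class]
#' @param path output file
#' @return `path`, invisibly
#' @export
writeGeneModelGtf <- function(model, path) {
  ex <- txExons(model)
  gr <- unlist(ex, use.names = FALSE)
  mcols(gr)$type <- "exon"
  mcols(gr)$source <- "circlong"
  mcols(gr)$transcript_id <- rep(names(ex), lengths(ex))
  mcols(gr)$gene_id <- txGenes(model)[mcols(gr)$transcript_id]
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read BSJ databases from BED files
#'
#' BED intervals are 0-based half-open on disk; records are stored 1-based
#' (start = first base, end = last base of the circle).
#'
#' @param paths character vector of BED files
#' @param sources labels, one per file (defaults to file base names)
#' @return a [CircDB-class]
#' @export
readCircDbBed <- function(paths, sources = NULL) {
  if (is.null(sources)) sources <- sub("\\.bed$", "", basename(paths))
  grs <- lapply(seq_along(paths), function(i) {
    g <- granges(rtracklayer::import(paths[i], format = "BED"))
    mcols(g)$source <- sources[i]
    g
  })
  new("CircDB", bsjs = do.call(c, grs))
}

#' Read a repeat-element annotation from BED
#'
#' @param path BED6 file; the name column is taken as the repeat family
#' @return GRanges with a `family` metadata column
#' @export
readRepeatsBed <- function(path) {
  g <- rtracklayer::import(path, format = "BED")
  fam <- if (!is.null(mcols(g)$name)) mcols(g)$name else "repeat"
  g <- granges(g, use.mcols = FALSE)
  mcols(g)$family <- fam
  g
}

#' Write the isoform catalog
#'
#' Emits isoforms.tsv (full records with categories, gene and per-sample
#' counts), bsj.tsv (BSJ-level counts) and isoforms.bed (BED12; blocks =
#' exon structure, score = total read count).
#'
#' @param x an annotated [CircCatalog-class]
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
writeCatalog <- function(x, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rd <- as.data.frame(rowData(x))
  cn <- assay(x, "counts")
  colnames(cn) <- paste0("count_", colnames(cn))
  out <- cbind(isoform_key = rownames(x), rd, cn)
  write.table(out, file.path(dir, "isoforms.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  bc <- metadata(x)$bsj_counts
  if (!is.null(bc)) {
    bdf <- data.frame(bsj_key = rownames(bc), bc, check.names = FALSE)
    write.table(bdf, file.path(dir, "bsj.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  bed <- rtracklayer::asBED(rowRanges(x))
  mcols(bed)$name <- if (!is.null(rd$isoform_name)) rd$isoform_name
  else rownames(x)
  mcols(bed)$score <- rowSums(assay(x, "counts"))
  rtracklayer::export(bed, file.path(dir, "isoforms.bed"), format = "BED")
  invisible(dir)
}
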