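#' Packaged reference resources
#'
#' Gene loci (GRCh37, Ensembl-75-style coordinates), exon models (protein
#' residue ranges per coding exon), protein-domain models, the JAK/STAT
#' regulator panel and the STAT5 target-gene list ship as plain TSV/TXT files
#' under `inst/extdata` and can be replaced by user files of the same schema.
#'
#' Domain residue ranges follow UniProt-style annotation; linker boundaries
#' differ between sources, so downstream summaries should not hinge on
#' boundary residues.
#'
#' @name resources
NULL

extdataPath <- function(file) {
  p <- system.file("extdata", file, package = "jakstatmeta")
  if (!nzchar(p)) stopf("packaged resource '%s' not found", file)
  p
}

#' Gene loci as a GRanges
#'
#' @param path Optional path to a TSV with columns symbol, alias, chrom,
#'   start, end, strand (1-based inclusive, GRCh37). Defaults to the packaged
#'   table.
#' @return A [GenomicRanges::GRanges] with mcols `symbol` and `alias`.
#' @examples
#' geneLoci()["JAK3"]
#' @export
geneLoci <- function(path = NULL) {
  tab <- read.delim(path %||% extdataPath("gene_loci_grch37.tsv"),
                    stringsAsFactors = FALSE, colClasses = "character")
  need <- c("symbol", "chrom", "start", "end", "strand")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stopf("gene loci table lacks column(s): %s", paste(miss, collapse = ", "))
  start <- as.integer(tab$start); end <- as.integer(tab$end)
  if (any(start > end)) stopf("gene loci table has start > end")
  gr <- GenomicRanges::GRanges(tab$chrom, IRanges::IRanges(start, end),
                               strand = tab$strand)
  S4Vectors::mcols(gr)$symbol <- tab$symbol
  S4Vectors::mcols(gr)$alias <- if ("alias" %in% names(tab)) tab$alias else tab$symbol
  names(gr) <- tab$symbol
  gr
}

#' Exon models: protein residue range of each coding exon
#'
#' @param path Optional TSV with columns gene, exon, aa_start, aa_end.
#' @return data.frame with one row per exon, ascending, non-overlapping per gene.
#' @export
exonModels <- function(path = NULL) {
  tab <- read.delim(path %||% extdataPath("exon_models.tsv"), stringsAsFactors = FALSE)
  tab <- tab[order(tab$gene, tab$exon), , drop = FALSE]
  for (g in unique(tab$gene)) {
    sub <- tab[tab$gene == g, ]
    if (any(sub$aa_start > sub$aa_end) ||
        any(diff(sub$aa_start) <= 0) ||
        any(sub$aa_start[-1] <= sub$aa_end[-nrow(sub)]))
      stopf("exon model for %s is not ascending/non-overlapping", g)
  }
  rownames(tab) <- NULL
  tab
}

#' Protein domain models
#'
#' @param path Optional TSV with columns gene, domain, aa_start, aa_end.
#' @return data.frame of ascending, non-overlapping domain intervals per gene.
#' @export
domainModels <- function(path = NULL) {
  tab <- read.delim(path %||% extdataPath("domain_models.tsv"), stringsAsFactors = FALSE)
  tab <- tab[order(tab$gene, tab$aa_start), , drop = FALSE]
  for (g in unique(tab$gene)) {
    sub <- tab[tab$gene == g, ]
    if (any(sub$aa_start > sub$aa_end) ||
        (nrow(sub) > 1L && any(sub$aa_start[-1] <= sub$aa_end[-nrow(sub)])))
      stopf("domain model for %s has overlapping intervals", g)
  }
  rownames(tab) <- NULL
  tab
}

#' The JAK/STAT regulator panel
#'
#' Seven negative regulators whose genomic loss is treated as
#' pathway-activating (DUSP4, CD45/PTPRC, TCPTP/PTPN2, SHP1/PTPN6, SOCS1,
#' SOCS3, HDAC9) and four STAT genes whose gain is (STAT2, STAT3, STAT5A,
#' STAT5B). User-replaceable.
#'
#' @param path Optional TSV with columns gene, alias, direction
#'   (loss_activating / gain_activating).
#' @return data.frame with one row per panel gene.
#' @export
regulatorPanel <- function(path = NULL) {
  tab <- read.delim(path %||% extdataPath("regulator_panel.tsv"), stringsAsFactors = FALSE)
  bad <- setdiff(unique(tab$direction), c("loss_activating", "gain_activating"))
  if (length(bad)) stopf("unknown panel direction(s): %s", paste(bad, collapse = ", "))
  if (anyDuplicated(tab$gene)) stopf("regulator panel lists a gene twice")
  tab
}

#' STAT5 target genes used for the overexpression flag
#' @param path Optional text file, one gene per line.
#' @return character vector of gene symbols.
#' @export
stat5Targets <- function(path = NULL) {
  readLines(path %||% extdataPath("stat5_targets.txt"))
}

#' Default hotspot exon windows
#'
#' Exon windows containing >90% of the observed mutations of each gene:
#' JAK1 exons 14-20, JAK3 exons 11-19, STAT5B exons 15-17. These are the
#' windows [detectHotspot()] recovers from the packaged fixture; they are kept
#' as a table so coverage declarations can refer to `GENE:hotspot` regions.
#'
#' @return data.frame with columns gene, first_exon, last_exon.
#' @export
defaultHotspots <- function() {
  data.frame(gene = c("JAK1", "JAK3", "STAT5B"),
             first_exon = c(14L, 11L, 15L),
             last_exon = c(20L, 19L, 17L),
             stringsAsFactors = FALSE)
}

#' Residue interval spanned by a gene's hotspot window
#'
#' @param gene Gene symbol present in `hotspots`.
#' @param exons Exon model table from [exonModels()].
#' @param hotspots Hotspot window table, defaults to [defaultHotspots()].
#' @return Integer vector c(start, end) of protein residues.
#' @export
hotspotResidueRange <- function(gene, exons = exonModels(), hotspots = defaultHotspots()) {
  h <- hotspots[hotspots$gene == gene, , drop = FALSE]
  if (nrow(h) != 1L) stopf("no hotspot window defined for gene %s", gene)
  e <- exons[exons$gene == gene, , drop = FALSE]
  if (nrow(e) == 0L) stopf("no exon model for gene %s", gene)
  c(min(e$aa_start[e$exon >= h$first_exon & e$exon <= h$last_exon]),
    max(e$aa_end[e$exon >= h$first_exon & e$exon <= h$last_exon]))
}
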