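#' Read and write cohort bundles
#'
#' A bundle directory holds plain TSV files: `cases.tsv`, `assays.tsv`,
#' `mutations.tsv`, `clinical.tsv`, a SEG-style `segments.seg`,
#' `expression.tsv` (genes x samples) with `expression_samples.tsv`
#' (sample, batch, group), and `manifest.json` when the bundle carries
#' simulation ground truth. Missing values are encoded as empty strings,
#' never as sentinel numbers. All coordinates are 1-based inclusive (GRCh37).
#'
#' The exchanged-table schema is this package's own; published studies share
#' no machine-readable per-case format, so one is defined and documented here.
#'
#' @name cohort-io
NULL

BUNDLE_FILES <- c(cases = "cases.tsv", assays = "assays.tsv",
                  mutations = "mutations.tsv", clinical = "clinical.tsv",
                  segments = "segments.seg")

readTsv <- function(path, required, classes = NULL) {
  if (!file.exists(path)) stopf("bundle file missing: %s", path)
  tab <- read.delim(path, stringsAsFactors = FALSE, na.strings = "",
                    colClasses = "character", check.names = FALSE)
  miss <- setdiff(required, names(tab))
  if (length(miss))
    stopf("schema error in %s: missing column(s) %s", basename(path),
          paste(miss, collapse = ", "))
  for (col in names(classes)) {
    if (!col %in% names(tab)) next
    tab[[col]] <- switch(classes[[col]],
      integer = as.integer(tab[[col]]),
      numeric = as.numeric(tab[[col]]),
      logical = as.logical(tab[[col]]),
      tab[[col]])
  }
  tab
}

checkEnum <- function(values, allowed, file, column) {
  bad <- which(!is.na(values) & !(values %in% allowed))
  if (length(bad))
    stopf("parse error in %s, column %s, row %d: '%s' not one of {%s}",
          file, column, bad[1L], values[bad[1L]], paste(allowed, collapse = ", "))
  invisible(values)
}

#' Read a SEG-style segment file
#'
#' @param path TSV with header sample, chrom, start, end, state.
#' @return GRanges with mcols `sample` and `state`; empty file (header only)
#'   gives an empty GRanges.
#' @export
readSegments <- function(path) {
  tab <- readTsv(path, c("sample", "chrom", "start", "end", "state"),
                 c(start = "integer", end = "integer"))
  if (nrow(tab) == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$sample <- character(0)
    S4Vectors::mcols(gr)$state <- character(0)
    return(gr)
  }
  bad <- which(tab$start > tab$end)
  if (length(bad))
    stopf("validation error in %s row %d: start > end", basename(path), bad[1L])
  checkEnum(tab$state, CN_STATES, basename(path), "state")
  gr <- GenomicRanges::GRanges(tab$chrom, IRanges::IRanges(tab$start, tab$end))
  S4Vectors::mcols(gr)$sample <- tab$sample
  S4Vectors::mcols(gr)$state <- tab$state
  gr
}

#' Read a cohort bundle from a directory
#'
#' @param dir Directory containing the bundle files (see [cohort-io]).
#' @param verbose Log row counts to stderr.
#' @return A validated [TpllCohort-class].
#' @export
readCohortBundle <- function(dir, verbose = FALSE) {
  if (!dir.exists(dir)) stopf("bundle directory not found: %s", dir)
  p <- function(f) file.path(dir, f)

  cases <- readTsv(p("cases.tsv"), c("study_id", "local_id", "identity_token"))
  assays <- readTsv(p("assays.tsv"),
                    c("study_id", "local_id", "method", "covered_regions",
                      "germline_matched"),
                    c(germline_matched = "logical"))
  checkEnum(assays$method, names(ASSAY_METHODS), "assays.tsv", "method")
  calls <- readTsv(p("mutations.tsv"),
                   c("study_id", "local_id", "gene", "chrom", "pos", "ref",
                     "alt", "protein_change", "variant_class", "vaf", "method",
                     "somatic_status"),
                   c(pos = "integer", vaf = "numeric"))
  calls$alt[is.na(calls$alt)] <- ""   # empty alt-span allowed for deletions
  checkEnum(calls$variant_class, VARIANT_CLASSES, "mutations.tsv", "variant_class")
  checkEnum(calls$method, names(ASSAY_METHODS), "mutations.tsv", "method")
  checkEnum(calls$somatic_status, c("matched_somatic", "unmatched_filtered"),
            "mutations.tsv", "somatic_status")
  clinical <- readTsv(p("clinical.tsv"), c("study_id", "local_id"))
  for (col in intersect(c("os_months", "wbc"), names(clinical)))
    clinical[[col]] <- as.numeric(clinical[[col]])
  for (col in intersect(c("event", "treatment_naive", "cd40l_positive",
                          "notch2_mut", "inv14"), names(clinical)))
    clinical[[col]] <- as.logical(clinical[[col]])
  segments <- readSegments(p("segments.seg"))

  expression <- list()
  if (file.exists(p("expression.tsv"))) {
    em <- read.delim(p("expression.tsv"), stringsAsFactors = FALSE, check.names = FALSE)
    if (names(em)[1L] != "gene") stopf("schema error in expression.tsv: first column must be 'gene'")
    vals <- as.matrix(em[, -1L, drop = FALSE])
    rownames(vals) <- em$gene
    smp <- readTsv(p("expression_samples.tsv"), c("sample", "batch", "group"))
    expression <- list(values = vals,
                       batch = setNames(smp$batch, smp$sample),
                       group = setNames(smp$group, smp$sample))
  }

  truth <- list()
  if (file.exists(p("manifest.json")))
    truth <- jsonlite::fromJSON(p("manifest.json"), simplifyDataFrame = TRUE)

  # dangling references are integrity errors, surfaced through class validity
  bundle <- TpllCohort(cases, assays, calls, segments, clinical, expression, truth)
  validObject(bundle)
  if (verbose)
    message(sprintf("read bundle: %d case records, %d assays, %d calls, %d segments",
                    nrow(cases), nrow(assays), nrow(calls), length(segments)))
  bundle
}

numToChr <- function(x, digits = 10) {
  out <- ifelse(is.na(x), "", vapply(x, function(v)
    if (is.na(v)) "" else format(v, scientific = FALSE, trim = TRUE, digits = digits), ""))
  out
}

writeTsv <- function(tab, path) {
  tab <- as.data.frame(lapply(tab, function(col) {
    if (is.logical(col)) ifelse(is.na(col), "", ifelse(col, "TRUE", "FALSE"))
    else if (is.numeric(col)) numToChr(col)
    else ifelse(is.na(col), "", as.character(col))
  }), stringsAsFactors = FALSE, check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a cohort bundle to a directory
#'
#' Rows are written in a deterministic order (case key, then coordinate), so
#' two writes of the same bundle are byte-identical and
#' `readCohortBundle(writeCohortBundle(b))` restores `b` field-by-field.
#'
#' @param bundle A [TpllCohort-class].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written file paths.
#' @export
writeCohortBundle <- function(bundle, dir) {
  validObject(bundle)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  ord <- function(df, extra = NULL) {
    if (nrow(df) == 0L) return(df)
    o <- do.call(order, c(list(df$study_id, df$local_id), unname(df[extra])))
    df[o, , drop = FALSE]
  }
  writeTsv(ord(bundle@cases), p("cases.tsv"))
  writeTsv(ord(bundle@assays, "method"), p("assays.tsv"))
  writeTsv(ord(bundle@calls, c("chrom", "pos", "protein_change")), p("mutations.tsv"))
  writeTsv(ord(bundle@clinical), p("clinical.tsv"))

  sg <- bundle@segments
  seg <- data.frame(sample = S4Vectors::mcols(sg)$sample,
                    chrom = as.character(GenomicRanges::seqnames(sg)),
                    start = GenomicRanges::start(sg),
                    end = GenomicRanges::end(sg),
                    state = S4Vectors::mcols(sg)$state,
                    stringsAsFactors = FALSE)
  seg <- seg[order(seg$sample, seg$chrom, seg$start, seg$end), , drop = FALSE]
  writeTsv(seg, p("segments.seg"))

  files <- p(c("cases.tsv", "assays.tsv", "mutations.tsv", "clinical.tsv", "segments.seg"))
  if (length(bundle@expression)) {
    ex <- bundle@expression
    em <- data.frame(gene = rownames(ex$values), ex$values,
                     stringsAsFactors = FALSE, check.names = FALSE)
    writeTsv(em, p("expression.tsv"))
    smp <- data.frame(sample = colnames(ex$values),
                      batch = unname(ex$batch[colnames(ex$values)]),
                      group = unname(ex$group[colnames(ex$values)]),
                      stringsAsFactors = FALSE)
    writeTsv(smp, p("expression_samples.tsv"))
    files <- c(files, p(c("expression.tsv", "expression_samples.tsv")))
  }
  if (length(bundle@truth)) {
    jsonlite::write_json(bundle@truth, p("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    files <- c(files, p("manifest.json"))
  }
  invisible(files)
}
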