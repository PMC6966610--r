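#' TpllCohort: the full multi-study input bundle
#'
#' An S4 container holding the per-study case table, assay-coverage
#' declarations, harmonized mutation calls, copy-number segments, clinical
#' covariates and (optionally) a log2 expression matrix, plus a ground-truth
#' manifest when the bundle was simulated. Records are keyed by
#' `(study_id, local_id)`; patients re-analyzed by several studies share an
#' `identity_token`, the handle used for cross-study deduplication.
#'
#' @slot cases data.frame with columns study_id, local_id, identity_token
#'   (one row per study-level case record).
#' @slot assays data.frame with columns study_id, local_id, method (WGS, WES,
#'   TAS, SANGER), covered_regions (semicolon-joined region ids, `GENE` or
#'   `GENE:hotspot`), germline_matched (logical).
#' @slot calls data.frame of somatic variant calls: study_id, local_id, gene,
#'   chrom, pos, ref, alt, protein_change, variant_class, vaf, method,
#'   somatic_status.
#' @slot segments [GenomicRanges::GRanges] of copy-number segments with mcols
#'   `sample` ("study_id:local_id") and `state` (loss/neutral/gain);
#'   1-based inclusive coordinates.
#' @slot clinical data.frame keyed by study_id, local_id with os_months,
#'   event and free-form covariate columns.
#' @slot expression list with elements `values` (gene x sample log2 matrix),
#'   `batch` and `group` (named character vectors over samples); empty list
#'   when absent.
#' @slot truth list: simulation ground-truth manifest (empty for real data).
#'
#' @examples
#' bundle <- publishedFixture()$bundle
#' bundle
#' @name TpllCohort-class
#' @aliases TpllCohort
#' @export
setClass("TpllCohort",
  representation(cases = "data.frame", assays = "data.frame",
                 calls = "data.frame", segments = "GRanges",
                 clinical = "data.frame", expression = "list",
                 truth = "list"))

caseKeyOf <- function(df) paste(df$study_id, df$local_id, sep = ":")

validTpllCohort <- function(object) {
  msgs <- character()
  cs <- object@cases
  need <- c("study_id", "local_id", "identity_token")
  if (!all(need %in% names(cs)))
    return(sprintf("cases table lacks column(s): %s",
                   paste(setdiff(need, names(cs)), collapse = ", ")))
  if (any(!nzchar(cs$identity_token) | is.na(cs$identity_token)))
    msgs <- c(msgs, "identity_token must be non-empty for every case record")
  if (anyDuplicated(caseKeyOf(cs)))
    msgs <- c(msgs, "(study_id, local_id) must be unique within a study")
  known <- caseKeyOf(cs)

  as_ <- object@assays
  if (nrow(as_) > 0L) {
    bad <- setdiff(unique(as_$method), names(ASSAY_METHODS))
    if (length(bad)) msgs <- c(msgs, sprintf("unknown assay method(s): %s", paste(bad, collapse = ", ")))
    if (any(!nzchar(as_$covered_regions)))
      msgs <- c(msgs, "covered_regions must be non-empty for every assay record")
    dangle <- setdiff(caseKeyOf(as_), known)
    if (length(dangle)) msgs <- c(msgs, sprintf("assay record(s) reference unknown case(s): %s",
                                                paste(head(dangle, 3L), collapse = ", ")))
  }

  cl <- object@calls
  if (nrow(cl) > 0L) {
    dangle <- setdiff(caseKeyOf(cl), known)
    if (length(dangle)) msgs <- c(msgs, sprintf("mutation call(s) reference unknown case(s): %s",
                                                paste(head(dangle, 3L), collapse = ", ")))
    v <- cl$vaf[!is.na(cl$vaf)]
    if (length(v) && (any(v < 0) || any(v > 1)))
      msgs <- c(msgs, "vaf must lie in [0, 1] when present")
    bad <- setdiff(unique(cl$variant_class), VARIANT_CLASSES)
    if (length(bad)) msgs <- c(msgs, sprintf("unknown variant_class: %s", paste(bad, collapse = ", ")))
    bad <- setdiff(unique(cl$somatic_status), c("matched_somatic", "unmatched_filtered"))
    if (length(bad)) msgs <- c(msgs, sprintf("unknown somatic_status: %s", paste(bad, collapse = ", ")))
  }

  sg <- object@segments
  if (length(sg) > 0L) {
    mc <- S4Vectors::mcols(sg)
    if (!all(c("sample", "state") %in% names(mc))) {
      msgs <- c(msgs, "segments need mcols 'sample' and 'state'")
    } else {
      bad <- setdiff(unique(mc$state), CN_STATES)
      if (length(bad)) msgs <- c(msgs, sprintf("unknown segment state(s): %s", paste(bad, collapse = ", ")))
      dangle <- setdiff(unique(mc$sample), known)
      if (length(dangle)) msgs <- c(msgs, sprintf("segment(s) reference unknown case(s): %s",
                                                  paste(head(dangle, 3L), collapse = ", ")))
    }
  }

  cli <- object@clinical
  if (nrow(cli) > 0L && all(c("os_months", "event") %in% names(cli))) {
    if (any(!is.na(cli$os_months) & is.na(cli$event)))
      msgs <- c(msgs, "event must be present whenever os_months is present")
    if (any(!is.na(cli$os_months) & cli$os_months < 0))
      msgs <- c(msgs, "os_months must be non-negative")
  }

  ex <- object@expression
  if (length(ex) > 0L) {
    if (anyDuplicated(rownames(ex$values)))
      msgs <- c(msgs, "expression matrix has duplicated gene rows")
    if (!all(colnames(ex$values) %in% names(ex$batch)))
      msgs <- c(msgs, "every expression sample needs a batch label")
  }

  if (length(msgs)) msgs else TRUE
}

setValidity("TpllCohort", validTpllCohort)

#' Construct a TpllCohort bundle
#'
#' @param cases,assays,calls,clinical data.frames (see [TpllCohort-class]).
#' @param segments GRanges of CNA segments (may be empty).
#' @param expression list(values, batch, group) or empty list.
#' @param truth Optional simulation ground-truth manifest.
#' @return A validated [TpllCohort-class] object.
#' @export
TpllCohort <- function(cases, assays, calls,
                       segments = GenomicRanges::GRanges(),
                       clinical = data.frame(), expression = list(),
                       truth = list()) {
  if (length(segments) == 0L) {
    segments <- GenomicRanges::GRanges()
    S4Vectors::mcols(segments)$sample <- character(0)
    S4Vectors::mcols(segments)$state <- character(0)
  }
  if (ncol(clinical) == 0L)
    clinical <- data.frame(study_id = character(0), local_id = character(0),
                           stringsAsFactors = FALSE)
  new("TpllCohort", cases = cases, assays = assays, calls = calls,
      segments = segments, clinical = clinical, expression = expression,
      truth = truth)
}

#' @describeIn TpllCohort-class per-study case records
#' @param x A TpllCohort.
#' @export
caseTable <- function(x) x@cases

#' @describeIn TpllCohort-class assay-coverage declarations
#' @export
assayTable <- function(x) x@assays

#' @describeIn TpllCohort-class somatic mutation calls
#' @export
mutationCalls <- function(x) x@calls

#' @describeIn TpllCohort-class copy-number segments (GRanges)
#' @export
cnaSegments <- function(x) x@segments

#' @describeIn TpllCohort-class clinical covariates
#' @export
clinicalTable <- function(x) x@clinical

#' @describeIn TpllCohort-class expression matrix, batch and group labels
#' @export
expressionData <- function(x) x@expression

#' @describeIn TpllCohort-class simulation ground-truth manifest (if any)
#' @export
truthManifest <- function(x) x@truth

#' @export
setMethod("show", "TpllCohort", function(object) {
  cat("TpllCohort bundle\n")
  cat(sprintf("  study-case records : %d (%d studies, %d unique patients)\n",
              nrow(object@cases), length(unique(object@cases$study_id)),
              length(unique(object@cases$identity_token))))
  cat(sprintf("  assay records      : %d\n", nrow(object@assays)))
  cat(sprintf("  mutation calls     : %d\n", nrow(object@calls)))
  cat(sprintf("  CNA segments       : %d\n", length(object@segments)))
  cat(sprintf("  clinical records   : %d\n", nrow(object@clinical)))
  if (length(object@expression))
    cat(sprintf("  expression         : %d genes x %d samples\n",
                nrow(object@expression$values), ncol(object@expression$values)))
  if (length(object@truth)) cat("  ground truth       : present\n")
  invisible(object)
})
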