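#' Cross-study deduplication and best-assay selection
#'
#' Patients re-analyzed by several studies are merged by exact matching of
#' their `identity_token` (the anonymized linkage handle provided by the
#' contributing centers). For every unique patient and sequenced region the
#' authoritative assay is the widest one, ranking WGS > WES > TAS > Sanger;
#' ties prefer germline-matched records, then the larger covered-region set,
#' then the lexicographically smallest study id, giving a reproducible total
#' order.
#'
#' @name cohort-dedup
NULL

#' Collapse overlapping study cohorts into a unique-case registry
#'
#' @param x A [TpllCohort-class] or a data.frame with columns study_id,
#'   local_id, identity_token (optionally immutable attributes such as `sex`,
#'   checked for within-token consistency).
#' @return An object of class `CaseRegistry`: list with `cases`
#'   (data.frame case_id, identity_token), `contributors` (case_id, study_id,
#'   local_id) and `size`.
#' @examples
#' reg <- resolveOverlaps(publishedFixture()$bundle)
#' reg$size
#' @export
resolveOverlaps <- function(x) {
  cases <- if (is(x, "TpllCohort")) caseTable(x) else x
  if (any(!nzchar(cases$identity_token) | is.na(cases$identity_token)))
    stopf("every case record needs a non-empty identity_token")
  for (attr in intersect(c("sex"), names(cases))) {
    per <- tapply(cases[[attr]], cases$identity_token,
                  function(v) length(unique(v[!is.na(v)])))
    bad <- names(per)[per > 1L]
    if (length(bad))
      stopf("conflicting '%s' within identity token(s): %s",
            attr, paste(head(bad, 5L), collapse = ", "))
  }
  tokens <- sort(unique(cases$identity_token))
  contributors <- data.frame(case_id = cases$identity_token,
                             study_id = cases$study_id,
                             local_id = cases$local_id,
                             stringsAsFactors = FALSE)
  contributors <- contributors[order(contributors$case_id,
                                     contributors$study_id,
                                     contributors$local_id), , drop = FALSE]
  rownames(contributors) <- NULL
  structure(list(cases = data.frame(case_id = tokens, identity_token = tokens,
                                    stringsAsFactors = FALSE),
                 contributors = contributors,
                 size = length(tokens)),
            class = "CaseRegistry")
}

#' @export
print.CaseRegistry <- function(x, ...) {
  cat(sprintf("CaseRegistry: %d unique cases from %d study-records (%d studies)\n",
              x$size, nrow(x$contributors), length(unique(x$contributors$study_id))))
  invisible(x)
}

# A record covering GENE:hotspot implicitly covers GENE (nested region sets).
normalizeRegions <- function(regions) {
  genes <- sub(":hotspot$", "", regions[grepl(":hotspot$", regions)])
  sort(unique(c(regions, genes)))
}

#' Select the authoritative assay record for one case and one region
#'
#' @param records data.frame of assay records (columns study_id, local_id,
#'   method, covered_regions, germline_matched) all belonging to one case.
#' @param region Region identifier (`GENE` or `GENE:hotspot`).
#' @return The single best covering record (one-row data.frame), or `NULL`
#'   when no record covers the region (the case is then outside the
#'   denominator, which is a signal rather than an error).
#' @export
selectBestAssay <- function(records, region) {
  if (nrow(records) == 0L) return(NULL)
  checkMethod(records$method)
  regs <- lapply(splitRegions(records$covered_regions), normalizeRegions)
  covering <- vapply(regs, function(r) region %in% r, TRUE)
  if (!any(covering)) return(NULL)
  cand <- records[covering, , drop = FALSE]
  sizes <- vapply(regs[covering], length, 0L)
  o <- order(-ASSAY_METHODS[cand$method],           # widest assay first
             -as.integer(cand$germline_matched),    # then germline-matched
             -sizes,                                # then larger covered set
             cand$study_id)                         # then smallest study id
  cand[o[1L], , drop = FALSE]
}

#' Build the per-case, per-region coverage matrix from best assays
#'
#' The source of every frequency denominator: a case is assayed for a region
#' only when one of its records covers the entire region, with
#' `GENE:hotspot` coverage implying `GENE` coverage.
#'
#' @param bundle A [TpllCohort-class].
#' @param registry A `CaseRegistry` (defaults to `resolveOverlaps(bundle)`).
#' @return Object of class `CoverageMatrix`: data.frame with columns case_id,
#'   region, method, germline_matched (one row per assayed case x region).
#' @export
buildCoverage <- function(bundle, registry = resolveOverlaps(bundle)) {
  assays <- assayTable(bundle)
  key2case <- setNames(registry$contributors$case_id,
                       paste(registry$contributors$study_id,
                             registry$contributors$local_id, sep = ":"))
  case_of <- key2case[caseKeyOf(assays)]
  if (anyNA(case_of)) stopf("assay record references a case absent from the registry")
  regs <- lapply(splitRegions(assays$covered_regions), normalizeRegions)
  long <- data.frame(case_id = rep(case_of, lengths(regs)),
                     region = unlist(regs),
                     method = rep(assays$method, lengths(regs)),
                     germline_matched = rep(assays$germline_matched, lengths(regs)),
                     study_id = rep(assays$study_id, lengths(regs)),
                     nreg = rep(lengths(regs), lengths(regs)),
                     stringsAsFactors = FALSE)
  o <- order(long$case_id, long$region,
             -ASSAY_METHODS[long$method],
             -as.integer(long$germline_matched),
             -long$nreg, long$study_id)
  long <- long[o, , drop = FALSE]
  best <- long[!duplicated(paste(long$case_id, long$region, sep = "\r")), , drop = FALSE]
  out <- best[, c("case_id", "region", "method", "germline_matched")]
  rownames(out) <- NULL
  class(out) <- c("CoverageMatrix", "data.frame")
  out
}

#' Study-intersection report (UpSet-style counts)
#'
#' @param registry A `CaseRegistry`.
#' @return data.frame with columns `studies` (sorted study ids joined by "+"),
#'   `n_studies` and `count` of unique cases reported by exactly that
#'   combination; counts sum to the registry size.
#' @export
dedupReport <- function(registry) {
  combos <- tapply(registry$contributors$study_id, registry$contributors$case_id,
                   function(s) paste(sort(unique(s)), collapse = "+"))
  tab <- table(combos)
  out <- data.frame(studies = names(tab),
                    n_studies = lengths(strsplit(names(tab), "+", fixed = TRUE)),
                    count = as.integer(tab), stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$studies), , drop = FALSE]
  rownames(out) <- NULL
  stopifnot(sum(out$count) == registry$size)
  out
}

# Map call/clinical/segment record keys to unique case ids.
caseIdsFor <- function(df_or_keys, registry) {
  keys <- if (is.data.frame(df_or_keys)) caseKeyOf(df_or_keys) else df_or_keys
  key2case <- setNames(registry$contributors$case_id,
                       paste(registry$contributors$study_id,
                             registry$contributors$local_id, sep = ":"))
  out <- key2case[keys]
  if (anyNA(out)) stopf("record references a case absent from the registry")
  unname(out)
}
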