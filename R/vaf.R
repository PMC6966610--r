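#' Variant allele fraction summaries and clonality
#'
#' VAFs are stored as fractions in [0, 1] and reported on the percent scale.
#' Quartiles use linear interpolation between order statistics (R's default
#' type-7 quantile), the common box-plot convention. A lesion is in the
#' clonal range when its VAF strictly exceeds the threshold (default 0.5);
#' no purity or copy-number adjustment is applied — raw fractions are
#' summarized as reported by the contributing assays.
#'
#' @name vaf-clonality
NULL

#' Summarize the VAF distribution of one gene's mutations
#'
#' @param calls Harmonized calls.
#' @param gene Gene symbol.
#' @param variant_class Class filter, default `"missense"` (pooling all calls
#'   of the class; set `NULL` for all classes).
#' @param clonal_threshold Strict VAF threshold for the clonal range.
#' @param per_case Summarize one value per patient (the maximum VAF of a
#'   case's calls) instead of pooling all calls; requires a `case_id` column.
#' @return List of class `VafSummary` (gene, n, n_missing, median, q1, q3 on
#'   the percent scale, n_clonal), or `NULL` when no call has a VAF.
#' @export
vafSummary <- function(calls, gene, variant_class = "missense",
                       clonal_threshold = 0.5, per_case = FALSE) {
  sub <- calls[calls$gene == gene, , drop = FALSE]
  if (!is.null(variant_class))
    sub <- sub[sub$variant_class %in% variant_class, , drop = FALSE]
  if (per_case) {
    if (is.null(sub$case_id)) stopf("per_case summaries need a case_id column")
    keep <- !is.na(sub$vaf)
    best <- tapply(sub$vaf[keep], sub$case_id[keep], max)
    n_missing <- length(unique(sub$case_id[!sub$case_id %in% names(best)]))
    v <- as.numeric(best)
    if (length(v) == 0L) return(NULL)
    qs <- unname(quantile(v, c(0.25, 0.5, 0.75), type = 7))
    return(structure(list(gene = gene, n = length(v), n_missing = n_missing,
                          median = 100 * qs[2L], q1 = 100 * qs[1L],
                          q3 = 100 * qs[3L],
                          n_clonal = sum(v > clonal_threshold)),
                     class = "VafSummary"))
  }
  v <- sub$vaf
  n_missing <- sum(is.na(v))
  v <- v[!is.na(v)]
  if (length(v) == 0L) return(NULL)
  qs <- unname(quantile(v, c(0.25, 0.5, 0.75), type = 7))
  structure(list(gene = gene, n = length(v), n_missing = n_missing,
                 median = 100 * qs[2L], q1 = 100 * qs[1L], q3 = 100 * qs[3L],
                 n_clonal = sum(v > clonal_threshold)),
            class = "VafSummary")
}

#' @export
print.VafSummary <- function(x, ...) {
  cat(sprintf("%s VAF: median %.1f%% [Q1 %.1f, Q3 %.1f], n = %d (%d without VAF), clonal-range %d\n",
              x$gene, x$median, x$q1, x$q3, x$n, x$n_missing, x$n_clonal))
  invisible(x)
}

#' Classify VAFs as subclonal or clonal-range
#'
#' @param vaf Numeric VAF fractions in [0, 1]; NA gives NA (undefined).
#' @param threshold Strict threshold, default 0.5.
#' @return Character vector: "subclonal" or "clonal_range" (NA preserved).
#' @export
clonalityClass <- function(vaf, threshold = 0.5) {
  if (any(!is.na(vaf) & (vaf < 0 | vaf > 1))) stopf("vaf must lie in [0, 1]")
  ifelse(is.na(vaf), NA_character_,
         ifelse(vaf > threshold, "clonal_range", "subclonal"))
}

#' Count carriers of a lesion above a VAF threshold
#'
#' @param calls Harmonized calls.
#' @param gene Gene symbol.
#' @param protein_change Exact protein change.
#' @param threshold Strict VAF threshold, default 0.5.
#' @return Integer count of calls with `vaf > threshold`.
#' @export
highVafCount <- function(calls, gene, protein_change, threshold = 0.5) {
  sub <- calls[calls$gene == gene & calls$protein_change == protein_change, , drop = FALSE]
  sum(!is.na(sub$vaf) & sub$vaf > threshold)
}
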