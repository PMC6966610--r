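#' Variant harmonization: whitelist filter and variant-type classification
#'
#' Cases without a matched germline sample cannot be population-filtered
#' reliably, so only variants already identified in the germline-matched
#' subset of the cohort are accepted for them. The whitelist key is genomic
#' (chrom, pos, ref, alt) whenever coordinates are available and falls back
#' to (gene, protein_change) for calls reported in protein notation only.
#'
#' @name variant-harmonize
NULL

#' Parse a short HGVS-p style protein change
#'
#' @param protein_change Strings like "M511I", "N642H" or "E583del".
#' @return data.frame with columns ref_aa, position, alt_aa ("del" for
#'   in-frame deletions). Unparseable input is a classification error.
#' @export
parseProteinChange <- function(protein_change) {
  m <- regmatches(protein_change,
                  regexec("^([A-Z])([0-9]+)([A-Z]|del)$", protein_change))
  bad <- which(lengths(m) != 4L)
  if (length(bad))
    stopf("unparseable protein change: '%s'", protein_change[bad[1L]])
  data.frame(ref_aa = vapply(m, `[`, "", 2L),
             position = as.integer(vapply(m, `[`, "", 3L)),
             alt_aa = vapply(m, `[`, "", 4L),
             stringsAsFactors = FALSE)
}

variantKeys <- function(calls) {
  has_genomic <- !is.na(calls$chrom) & nzchar(calls$chrom) &
    !is.na(calls$pos) & !is.na(calls$ref) & nzchar(calls$ref)
  genomic <- ifelse(has_genomic,
                    paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":"),
                    NA_character_)
  protein <- paste(calls$gene, calls$protein_change, sep = ":")
  list(genomic = genomic, protein = protein, has_genomic = has_genomic)
}

#' Build the variant whitelist from germline-matched calls
#'
#' @param calls data.frame of mutation calls, all with
#'   `somatic_status == "matched_somatic"` (anything else is a contract error).
#' @return Object of class `VariantWhitelist`: list with character sets
#'   `genomic` and `protein` plus `n_calls`.
#' @export
buildWhitelist <- function(calls) {
  if (nrow(calls) > 0L && any(calls$somatic_status != "matched_somatic"))
    stopf("buildWhitelist expects matched_somatic calls only")
  k <- variantKeys(calls)
  structure(list(genomic = sort(unique(k$genomic[k$has_genomic])),
                 protein = sort(unique(k$protein)),
                 n_calls = nrow(calls)),
            class = "VariantWhitelist")
}

#' @export
print.VariantWhitelist <- function(x, ...) {
  cat(sprintf("VariantWhitelist: %d genomic keys, %d protein keys (from %d matched calls)\n",
              length(x$genomic), length(x$protein), x$n_calls))
  invisible(x)
}

#' Filter calls from unmatched cases against the whitelist
#'
#' @param calls data.frame of calls from cases lacking a germline control.
#' @param whitelist A `VariantWhitelist`.
#' @return The retained calls, with `somatic_status` set to
#'   `"unmatched_filtered"`.
#' @export
whitelistFilter <- function(calls, whitelist) {
  if (nrow(calls) == 0L) return(calls)
  k <- variantKeys(calls)
  keep <- ifelse(k$has_genomic,
                 k$genomic %in% whitelist$genomic,
                 k$protein %in% whitelist$protein)
  out <- calls[keep, , drop = FALSE]
  if (nrow(out)) out$somatic_status <- "unmatched_filtered"
  rownames(out) <- NULL
  out
}

#' Classify variants into missense / in-frame deletion / other
#'
#' A single-base substitution that changes one residue is missense; a
#' deletion whose length is divisible by 3 (preserving frame) is an in-frame
#' deletion; everything else (synonymous changes, frameshifts) is "other".
#'
#' @param calls data.frame with ref, alt and protein_change columns.
#' @return Character vector of classes, one per call.
#' @export
classifyVariantType <- function(calls) {
  pp <- parseProteinChange(calls$protein_change)
  alt <- ifelse(is.na(calls$alt), "", calls$alt)
  has_genomic <- !is.na(calls$ref) & nzchar(calls$ref)
  vapply(seq_len(nrow(calls)), function(i) {
    if (pp$alt_aa[i] == "del" ||
        (has_genomic[i] && nchar(calls$ref[i]) > nchar(alt[i]))) {
      del_len <- if (has_genomic[i]) nchar(calls$ref[i]) - nchar(alt[i]) else 3L
      if (del_len %% 3L == 0L && pp$alt_aa[i] == "del") "inframe_del" else "other"
    } else if (pp$alt_aa[i] == pp$ref_aa[i]) {
      "other"                                  # synonymous
    } else if (!has_genomic[i] ||
               (nchar(calls$ref[i]) == 1L && nchar(alt[i]) == 1L &&
                calls$ref[i] != alt[i])) {
      "missense"
    } else "other"
  }, "")
}

#' Variant-type spectrum of a call set
#'
#' @param calls data.frame of calls (typically restricted to the WGS/WES
#'   subset, where the whole coding region was interrogated).
#' @return Named list of [newFrequency()] objects, one per variant class with
#'   at least one call; `NULL` when there are no calls (undefined, not an
#'   error). Proportions sum to 1.
#' @export
variantTypeSpectrum <- function(calls) {
  if (nrow(calls) == 0L) return(NULL)
  cls <- factor(calls$variant_class, levels = VARIANT_CLASSES)
  counts <- table(cls)
  total <- nrow(calls)
  out <- lapply(as.integer(counts), newFrequency, denominator = total)
  names(out) <- names(counts)
  out[counts > 0L]
}
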