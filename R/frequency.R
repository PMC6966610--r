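#' Coverage-aware frequency estimation and hotspot detection
#'
#' Every frequency reported by this package is a numerator over the set of
#' cases whose best assay covers the *entire* region in question — never the
#' global cohort size. Gene-level denominators (cases sequenced for the gene
#' in any way) and hotspot-level denominators (cases covering the full
#' hotspot exon window) therefore differ, reproducing the distinct printed
#' denominators of targeted versus genome-wide assays.
#'
#' @name coverage-frequency
NULL

#' Harmonize a bundle's calls to unique cases
#'
#' Maps calls to unique case ids, applies the germline whitelist filter to
#' calls from unmatched cases (see [buildWhitelist()]), and collapses
#' duplicate reports of the same lesion in the same patient from overlapping
#' studies.
#'
#' @param bundle A [TpllCohort-class].
#' @param registry A `CaseRegistry` (defaults to `resolveOverlaps(bundle)`).
#' @return data.frame of calls with a `case_id` column.
#' @export
harmonizeCalls <- function(bundle, registry = resolveOverlaps(bundle)) {
  calls <- mutationCalls(bundle)
  assays <- assayTable(bundle)
  if (nrow(calls) == 0L) return(cbind(case_id = character(0), calls))
  calls$case_id <- caseIdsFor(calls, registry)
  matched_cases <- unique(caseIdsFor(assays, registry)[assays$germline_matched %in% TRUE])
  is_matched <- calls$case_id %in% matched_cases
  matched <- calls[is_matched, , drop = FALSE]
  unmatched <- calls[!is_matched, , drop = FALSE]
  if (nrow(matched)) matched$somatic_status <- "matched_somatic"
  if (nrow(unmatched)) {
    wl <- buildWhitelist(matched)
    unmatched$somatic_status <- "matched_somatic"  # neutral before filtering
    unmatched <- whitelistFilter(unmatched, wl)
  }
  out <- rbind(matched, unmatched)
  key <- paste(out$case_id, out$gene, out$protein_change, out$chrom, out$pos, sep = "\r")
  out <- out[!duplicated(key), , drop = FALSE]
  out <- out[order(out$case_id, out$gene, out$protein_change), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("case_id", setdiff(names(out), "case_id"))]
}

knownRegions <- function(coverage, hotspots = defaultHotspots()) {
  unique(c(coverage$region, JAKSTAT_GENES,
           paste0(hotspots$gene, ":hotspot")))
}

#' Cases whose best assay covers a region
#'
#' @param coverage A `CoverageMatrix` from [buildCoverage()].
#' @param region Region id (`GENE` or `GENE:hotspot`).
#' @return Character vector of unique case ids (possibly empty).
#' @export
assayedCases <- function(coverage, region) {
  if (!region %in% knownRegions(coverage))
    stopf("unknown region: %s", region)
  sort(unique(coverage$case_id[coverage$region == region]))
}

# Which calls fall inside a region (gene body, or its hotspot exon window)?
callsInRegion <- function(calls, region, exons = exonModels(),
                          hotspots = defaultHotspots()) {
  if (nrow(calls) == 0L) return(logical(0))
  if (grepl(":hotspot$", region)) {
    gene <- sub(":hotspot$", "", region)
    rng <- hotspotResidueRange(gene, exons, hotspots)
    pos <- parseProteinChange(calls$protein_change)$position
    calls$gene == gene & pos >= rng[1L] & pos <= rng[2L]
  } else {
    calls$gene == region
  }
}

#' Coverage-aware mutation frequency of a region
#'
#' Numerator: assayed cases carrying at least one call inside the region (a
#' case never counts twice). Denominator: all cases assayed for the region.
#' Carriers outside the assayed set are excluded from the numerator and
#' logged as an integrity warning.
#'
#' @param calls Harmonized calls with a `case_id` column ([harmonizeCalls()]).
#' @param coverage A `CoverageMatrix`.
#' @param region Region id.
#' @param exons,hotspots Exon model and hotspot windows for `GENE:hotspot`
#'   regions.
#' @return A [newFrequency()] object, or `NULL` when nobody was assayed
#'   (undefined, not an error).
#' @export
regionMutationFrequency <- function(calls, coverage, region,
                                    exons = exonModels(),
                                    hotspots = defaultHotspots()) {
  assayed <- assayedCases(coverage, region)
  if (length(assayed) == 0L) return(NULL)
  inreg <- callsInRegion(calls, region, exons, hotspots)
  carriers <- unique(calls$case_id[inreg])
  outside <- setdiff(carriers, assayed)
  if (length(outside))
    message(sprintf("integrity: %d carrier(s) of %s calls outside the assayed set (excluded)",
                    length(outside), region))
  newFrequency(length(intersect(carriers, assayed)), length(assayed))
}

#' Frequency of one exact protein lesion among gene-level assayed cases
#'
#' @param calls Harmonized calls with `case_id`.
#' @param coverage A `CoverageMatrix`.
#' @param gene Gene symbol.
#' @param protein_change Exact protein change, e.g. "M511I".
#' @return A [newFrequency()], or `NULL` when nobody was assayed for the gene.
#' @export
lesionFrequency <- function(calls, coverage, gene, protein_change) {
  assayed <- assayedCases(coverage, gene)
  if (length(assayed) == 0L) return(NULL)
  carriers <- unique(calls$case_id[calls$gene == gene &
                                   calls$protein_change == protein_change])
  outside <- setdiff(carriers, assayed)
  if (length(outside))
    message(sprintf("integrity: %d carrier(s) of %s %s outside the assayed set (excluded)",
                    length(outside), gene, protein_change))
  newFrequency(length(intersect(carriers, assayed)), length(assayed))
}

#' Detect the minimal contiguous exon window holding >q of mutations
#'
#' Scans all contiguous exon windows and returns the one minimal in exon
#' count (leftmost on ties) that contains strictly more than `q` of the
#' mutation occurrences (occurrence-counted, not per case).
#'
#' @param positions Integer protein residues of a gene's mutations (multiset).
#' @param exon_model Exon rows for one gene (columns exon, aa_start, aa_end).
#' @param q Fraction threshold, strict; default 0.9.
#' @return List of class `HotspotInterval`: first_exon, last_exon, contained,
#'   total, fraction.
#' @export
detectHotspot <- function(positions, exon_model, q = 0.9) {
  if (length(positions) == 0L) stopf("detectHotspot needs at least one mutation position")
  em <- exon_model[order(exon_model$exon), , drop = FALSE]
  exon_of <- vapply(positions, function(p) {
    hit <- which(p >= em$aa_start & p <= em$aa_end)
    if (length(hit) != 1L)
      stopf("mutation position %d maps to no exon of the model", p)
    em$exon[hit]
  }, 0L)
  n <- length(positions)
  exons <- em$exon
  counts <- vapply(exons, function(e) sum(exon_of == e), 0L)
  E <- length(exons)
  for (L in seq_len(E)) {
    for (s in seq_len(E - L + 1L)) {
      inside <- sum(counts[s:(s + L - 1L)])
      if (inside > q * n) {
        return(structure(list(first_exon = exons[s], last_exon = exons[s + L - 1L],
                              contained = inside, total = n,
                              fraction = inside / n, q = q),
                         class = "HotspotInterval"))
      }
    }
  }
  stopf("no contiguous exon window exceeds q = %g", q)  # unreachable for q < 1
}

#' @export
print.HotspotInterval <- function(x, ...) {
  cat(sprintf("Hotspot: exons %d-%d containing %d/%d mutations (%.1f%%, q = %g)\n",
              x$first_exon, x$last_exon, x$contained, x$total, 100 * x$fraction, x$q))
  invisible(x)
}

#' Co-occurrence of mutated JAK/STAT genes per case
#'
#' @param calls Harmonized calls with `case_id`.
#' @param cohort Character vector of case ids defining the cohort (e.g., the
#'   WGS/WES subset).
#' @param genes Gene panel; defaults to the 11 JAK/STAT genes.
#' @return List with `per_case` (case_id, n_genes), `k_counts` (named vector,
#'   cases with exactly k mutated genes, k = 0..max; sums to cohort size) and
#'   `pairs` (symmetric pair counts as a data.frame gene_a, gene_b, count).
#' @export
cooccurrenceCounts <- function(calls, cohort, genes = JAKSTAT_GENES) {
  sub <- calls[calls$case_id %in% cohort & calls$gene %in% genes, , drop = FALSE]
  gene_sets <- lapply(setNames(cohort, cohort),
                      function(cs) sort(unique(sub$gene[sub$case_id == cs])))
  n_genes <- lengths(gene_sets)
  kmax <- max(c(0L, n_genes))
  k_counts <- vapply(0:kmax, function(k) sum(n_genes == k), 0L)
  names(k_counts) <- as.character(0:kmax)
  pairs <- list()
  for (gs in gene_sets) {
    if (length(gs) >= 2L) {
      cmb <- utils::combn(gs, 2L)
      for (j in seq_len(ncol(cmb))) {
        key <- paste(cmb[1L, j], cmb[2L, j], sep = "|")
        pairs[[key]] <- (pairs[[key]] %||% 0L) + 1L
      }
    }
  }
  pair_df <- if (length(pairs)) {
    sp <- strsplit(names(pairs), "|", fixed = TRUE)
    data.frame(gene_a = vapply(sp, `[`, "", 1L),
               gene_b = vapply(sp, `[`, "", 2L),
               count = as.integer(unlist(pairs)), stringsAsFactors = FALSE)
  } else data.frame(gene_a = character(0), gene_b = character(0),
                    count = integer(0), stringsAsFactors = FALSE)
  list(per_case = data.frame(case_id = names(gene_sets), n_genes = unname(n_genes),
                             stringsAsFactors = FALSE),
       k_counts = k_counts, pairs = pair_df)
}

#' Fraction of cohort cases mutated in at least one panel gene
#'
#' @inheritParams cooccurrenceCounts
#' @return A [newFrequency()].
#' @export
unionMutatedFraction <- function(calls, cohort, genes = JAKSTAT_GENES) {
  if (length(cohort) == 0L) stopf("empty cohort")
  carriers <- unique(calls$case_id[calls$gene %in% genes])
  newFrequency(length(intersect(carriers, cohort)), length(cohort))
}
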