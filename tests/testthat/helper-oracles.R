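# Independent brute-force oracles used to cross-check the implementation.

# Exhaustive contiguous-window scan: minimal exon count, leftmost on ties,
# counting residues directly against exon bounds (no shared code with
# detectHotspot).
oracle_hotspot <- function(positions, em, q = 0.9) {
  em <- em[order(em$exon), ]
  best <- NULL
  for (i in seq_len(nrow(em))) {
    for (j in i:nrow(em)) {
      lo <- em$aa_start[i]; hi <- em$aa_end[j]
      inside <- sum(positions >= lo & positions <= hi)
      if (inside > q * length(positions)) {
        len <- j - i + 1L
        if (is.null(best) || len < best$len ||
            (len == best$len && i < best$i)) {
          best <- list(i = i, j = j, len = len, inside = inside)
        }
      }
    }
  }
  c(first = em$exon[best$i], last = em$exon[best$j])
}

# O(S*G) per-pair interval overlap with the documented conflict rule.
oracle_segment_map <- function(seg, loci_df, min_overlap = 0) {
  out <- list()
  for (ci in unique(seg$sample)) {
    s <- seg[seg$sample == ci, , drop = FALSE]
    for (gi in seq_len(nrow(loci_df))) {
      g <- loci_df[gi, ]
      tot <- c(loss = 0, neutral = 0, gain = 0)
      for (si in seq_len(nrow(s))) {
        if (s$chrom[si] != g$chrom) next
        ov <- min(s$end[si], g$end) - max(s$start[si], g$start) + 1
        min_bp <- max(1, ceiling(min_overlap * (g$end - g$start + 1)))
        if (ov >= min_bp) tot[s$state[si]] <- tot[s$state[si]] + ov
      }
      if (sum(tot) == 0) next
      # conflict rule: largest overlapped length wins; ties loss > gain > neutral
      pref <- c("loss", "gain", "neutral")
      present <- pref[tot[pref] > 0]
      state <- present[order(-tot[present], match(present, pref))][1L]
      out[[length(out) + 1L]] <- data.frame(case_id = ci, gene = g$symbol,
                                            state = state, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame(case_id = character(0), gene = character(0),
                                      state = character(0)))
  res <- do.call(rbind, out)
  res[order(res$case_id, res$gene), ]
}

# Two-sided Fisher p by direct hypergeometric enumeration.
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- dhyper(ks, r1, n - r1, c1)
  p_obs <- dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Minimal hand-built bundle: `spec` is a list of case entries, each with
# token, study, method, regions, matched, and optional calls (gene, pchg).
tiny_bundle <- function(spec, segments = NULL) {
  loci <- geneLoci()
  cases <- do.call(rbind, lapply(seq_along(spec), function(i) {
    s <- spec[[i]]
    data.frame(study_id = s$study, local_id = sprintf("C%02d", i),
               identity_token = s$token, stringsAsFactors = FALSE)
  }))
  assays <- do.call(rbind, lapply(seq_along(spec), function(i) {
    s <- spec[[i]]
    data.frame(study_id = s$study, local_id = sprintf("C%02d", i),
               method = s$method,
               covered_regions = paste(s$regions, collapse = ";"),
               germline_matched = isTRUE(s$matched), stringsAsFactors = FALSE)
  }))
  calls <- do.call(rbind, lapply(seq_along(spec), function(i) {
    s <- spec[[i]]
    if (is.null(s$calls)) return(NULL)
    do.call(rbind, lapply(s$calls, function(cl) {
      pp <- parseProteinChange(cl$pchg)
      data.frame(study_id = s$study, local_id = sprintf("C%02d", i),
                 gene = cl$gene,
                 chrom = as.character(GenomicRanges::seqnames(loci[cl$gene])),
                 pos = GenomicRanges::start(loci[cl$gene]) + 3L * (pp$position - 1L),
                 ref = "A", alt = if (pp$alt_aa == "del") "" else "G",
                 protein_change = cl$pchg,
                 variant_class = if (pp$alt_aa == "del") "inframe_del" else "missense",
                 vaf = cl$vaf %||% NA_real_, method = s$method,
                 somatic_status = if (isTRUE(s$matched)) "matched_somatic"
                                  else "unmatched_filtered",
                 stringsAsFactors = FALSE)
    }))
  }))
  if (is.null(calls))
    calls <- data.frame(study_id = character(0), local_id = character(0),
                        gene = character(0), chrom = character(0), pos = integer(0),
                        ref = character(0), alt = character(0),
                        protein_change = character(0), variant_class = character(0),
                        vaf = numeric(0), method = character(0),
                        somatic_status = character(0), stringsAsFactors = FALSE)
  gr <- if (is.null(segments)) GenomicRanges::GRanges() else {
    g <- GenomicRanges::GRanges(segments$chrom,
                                IRanges::IRanges(segments$start, segments$end))
    S4Vectors::mcols(g)$sample <- segments$sample
    S4Vectors::mcols(g)$state <- segments$state
    g
  }
  TpllCohort(cases = cases, assays = assays, calls = calls, segments = gr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Cached fixture shared across test files (building it is cheap but not free).
fixture_cache <- local({
  fx <- NULL
  function() {
    if (is.null(fx)) fx <<- publishedFixture()
    fx
  }
})

fixture_parts <- local({
  parts <- NULL
  function() {
    if (is.null(parts)) {
      fx <- fixture_cache()
      reg <- resolveOverlaps(fx$bundle)
      parts <<- list(bundle = fx$bundle, manifest = fx$manifest, registry = reg,
                     coverage = buildCoverage(fx$bundle, reg),
                     calls = suppressMessages(harmonizeCalls(fx$bundle, reg)))
    }
    parts
  }
})
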