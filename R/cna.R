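#' CNA segment-to-gene mapping and pathway-activation classification
#'
#' Copy-number segments are mapped to genes by interval overlap (1 bp of
#' overlap flags the gene by default; a minimum overlap fraction is
#' configurable). A case's pathway activation is classified from two flag
#' sets: somatic JAK/STAT mutations and activating regulator lesions (loss of
#' a negative regulator, gain of a STAT gene, or an HDAC9 sequence mutation).
#' All prevalences use the dual-platform denominator: cases analyzed by both
#' WGS/WES and SNP array.
#'
#' @name cna-lesions
NULL

#' Map CNA segments to per-case, per-gene copy-number states
#'
#' A gene is called loss/gain for a case when at least one segment of that
#' state overlaps the gene locus by `>= max(1, min_overlap * width(gene))`
#' bp. When overlapping segments disagree, the state with the larger
#' overlapped length wins; ties resolve to loss (conservative).
#'
#' @param segments GRanges with mcols `sample` and `state`.
#' @param loci GRanges of gene loci ([geneLoci()]) with mcol `symbol`.
#' @param registry Optional `CaseRegistry`; when given, segment samples
#'   ("study_id:local_id") are mapped to unique case ids.
#' @param min_overlap Minimum overlap as a fraction of the gene length
#'   (default 0: any 1-bp overlap counts).
#' @return data.frame with columns case_id, gene, state (only genes touched
#'   by at least one segment appear; absent pairs are copy-neutral).
#' @export
mapSegmentsToGenes <- function(segments, loci, registry = NULL, min_overlap = 0) {
  if (length(segments) == 0L)
    return(data.frame(case_id = character(0), gene = character(0),
                      state = character(0), stringsAsFactors = FALSE))
  # "chr8" and "8" are treated as the same chromosome (convention normalized)
  norm <- function(x) sub("^chr", "", as.character(x))
  chr_seg <- norm(GenomicRanges::seqnames(segments))
  chr_loc <- norm(GenomicRanges::seqnames(loci))
  lv <- union(unique(chr_seg), unique(chr_loc))
  seg <- GenomicRanges::GRanges(factor(chr_seg, lv), IRanges::ranges(segments))
  loc <- GenomicRanges::GRanges(factor(chr_loc, lv), IRanges::ranges(loci))
  hits <- GenomicRanges::findOverlaps(seg, loc, ignore.strand = TRUE)
  if (length(hits) == 0L)
    return(data.frame(case_id = character(0), gene = character(0),
                      state = character(0), stringsAsFactors = FALSE))
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(seg[qi], loc[si]))
  min_bp <- pmax(1, ceiling(min_overlap * GenomicRanges::width(loc[si])))
  keep <- ov >= min_bp
  qi <- qi[keep]; si <- si[keep]; ov <- ov[keep]
  if (length(qi) == 0L)
    return(data.frame(case_id = character(0), gene = character(0),
                      state = character(0), stringsAsFactors = FALSE))
  sample <- S4Vectors::mcols(segments)$sample[qi]
  case_id <- if (is.null(registry)) sample else caseIdsFor(sample, registry)
  df <- data.frame(case_id = case_id,
                   gene = S4Vectors::mcols(loci)$symbol[si],
                   state = S4Vectors::mcols(segments)$state[qi],
                   overlap = ov, stringsAsFactors = FALSE)
  # aggregate overlapped length per (case, gene, state)
  agg <- stats::aggregate(overlap ~ case_id + gene + state, df, sum)
  pick <- function(sub) {
    if (nrow(sub) == 1L) return(sub$state)
    o <- order(-sub$overlap, match(sub$state, c("loss", "gain", "neutral")))
    sub$state[o[1L]]
  }
  keys <- paste(agg$case_id, agg$gene, sep = "\r")
  out <- do.call(rbind, lapply(split(agg, keys), function(sub)
    data.frame(case_id = sub$case_id[1L], gene = sub$gene[1L],
               state = pick(sub), stringsAsFactors = FALSE)))
  out <- out[order(out$case_id, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Activating regulator-lesion flags per case
#'
#' @param cn_states data.frame case_id, gene, state ([mapSegmentsToGenes()]).
#' @param panel Regulator panel ([regulatorPanel()]).
#' @param calls Optional harmonized calls; sequence mutations of HDAC9 count
#'   as activating lesions alongside its losses (all other regulators count
#'   CNAs only).
#' @return data.frame case_id, gene, lesion ("loss", "gain" or "mutation"),
#'   one row per activating lesion.
#' @export
regulatorLesionFlags <- function(cn_states, panel = regulatorPanel(), calls = NULL) {
  m <- merge(cn_states, panel[, c("gene", "direction")], by = "gene")
  act <- m[(m$direction == "loss_activating" & m$state == "loss") |
           (m$direction == "gain_activating" & m$state == "gain"), , drop = FALSE]
  out <- data.frame(case_id = act$case_id, gene = act$gene,
                    lesion = act$state, stringsAsFactors = FALSE)
  if (!is.null(calls) && nrow(calls)) {
    hd <- calls[calls$gene == "HDAC9", , drop = FALSE]
    if (nrow(hd))
      out <- rbind(out, data.frame(case_id = unique(hd$case_id), gene = "HDAC9",
                                   lesion = "mutation", stringsAsFactors = FALSE))
  }
  out <- unique(out)
  out <- out[order(out$case_id, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify per-case pathway activation
#'
#' @param mutation_flag,regulator_flag Logical vectors (per case, aligned).
#' @return Character vector over {"both", "mutation_only", "regulator_only",
#'   "none"}.
#' @export
classifyActivation <- function(mutation_flag, regulator_flag) {
  stopifnot(length(mutation_flag) == length(regulator_flag))
  ifelse(mutation_flag & regulator_flag, "both",
    ifelse(mutation_flag, "mutation_only",
      ifelse(regulator_flag, "regulator_only", "none")))
}

#' Cases analyzed by both WGS/WES and SNP array
#'
#' @param bundle A [TpllCohort-class].
#' @param registry A `CaseRegistry`.
#' @return Character vector of unique case ids: cases with a WGS or WES assay
#'   record that also appear in the segment table.
#' @export
dualPlatformCases <- function(bundle, registry = resolveOverlaps(bundle)) {
  assays <- assayTable(bundle)
  seq_cases <- unique(caseIdsFor(assays, registry)[assays$method %in% c("WGS", "WES")])
  samples <- unique(S4Vectors::mcols(cnaSegments(bundle))$sample)
  cna_cases <- if (length(samples)) unique(caseIdsFor(samples, registry)) else character(0)
  sort(intersect(seq_cases, cna_cases))
}

#' Per-case lesion profiles over the dual-platform subset
#'
#' @param bundle A [TpllCohort-class].
#' @param registry A `CaseRegistry`.
#' @param panel Regulator panel.
#' @param loci Gene loci.
#' @param genes JAK/STAT gene panel for the mutation flag.
#' @param min_overlap Passed to [mapSegmentsToGenes()].
#' @return data.frame case_id, mutation (logical), regulator (logical),
#'   category, any_activating, restricted to the dual-platform subset.
#' @export
lesionProfiles <- function(bundle, registry = resolveOverlaps(bundle),
                           panel = regulatorPanel(), loci = geneLoci(),
                           genes = JAKSTAT_GENES, min_overlap = 0) {
  cohort <- dualPlatformCases(bundle, registry)
  calls <- harmonizeCalls(bundle, registry)
  cn <- mapSegmentsToGenes(cnaSegments(bundle), loci, registry, min_overlap)
  flags <- regulatorLesionFlags(cn, panel, calls)
  mutation <- cohort %in% unique(calls$case_id[calls$gene %in% genes])
  regulator <- cohort %in% unique(flags$case_id)
  category <- classifyActivation(mutation, regulator)
  data.frame(case_id = cohort, mutation = mutation, regulator = regulator,
             category = category, any_activating = category != "none",
             stringsAsFactors = FALSE)
}

#' Prevalence of activation categories and their union
#'
#' @param profiles data.frame from [lesionProfiles()] (or with columns
#'   case_id, category).
#' @param cohort Case ids of the dual-platform subset; profiles outside it
#'   are dropped with a warning.
#' @return List with per-category [newFrequency()] objects, `regulator_lesion`
#'   (cases with any activating regulator lesion) and `union` (any activating
#'   lesion = 1 - fraction none).
#' @export
activationPrevalence <- function(profiles, cohort = profiles$case_id) {
  extra <- setdiff(profiles$case_id, cohort)
  if (length(extra)) {
    warnf("%d profile(s) outside the dual-assay subset excluded", length(extra))
    profiles <- profiles[profiles$case_id %in% cohort, , drop = FALSE]
  }
  n <- length(cohort)
  cat_counts <- table(factor(profiles$category, levels = ACTIVATION_CATEGORIES))
  stopifnot(sum(cat_counts) == n)
  out <- lapply(as.integer(cat_counts), newFrequency, denominator = n)
  names(out) <- names(cat_counts)
  out$regulator_lesion <- newFrequency(
    sum(profiles$category %in% c("regulator_only", "both")), n)
  out$union <- newFrequency(n - as.integer(cat_counts[["none"]]), n)
  out
}
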