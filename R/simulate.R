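#' Synthetic multi-study cohort generator
#'
#' Simulates bundles with the statistical structure the analysis assumes:
#' overlapping study cohorts over shared patients, nested assay coverage
#' (gene-level and hotspot-level, by method), per-gene mutation rates with a
#' lesion catalogue and Beta-distributed subclonal VAFs, a CNA process
#' hitting the regulator panel, exponential survival with optional group
#' hazard effects and censoring, and an expression matrix with batch offsets
#' and injected group shifts. Ground truth is returned as a manifest so
#' every pipeline estimate can be checked for parameter recovery.
#'
#' @name synthetic-data
NULL

#' Simulation configuration with study-condition defaults
#'
#' Defaults mirror the conditions of the meta-analyzed cohort: per-gene
#' mutation rates of the WGS/WES subset (JAK3 0.345, STAT5B 0.253, JAK1
#' 0.092, TYK2 0.023, STAT4 0.023, STAT5A 0.011), a lesion catalogue led by
#' M511I/N642H/V658F, per-gene Beta VAF shapes centered near the published
#' medians, regulator loss probabilities led by DUSP4, a median OS around
#' two years with ~30% censoring, a TCL1A log2 shift of 2 and a STAT5-target
#' shift of 2.5.
#'
#' @param seed Mandatory integer seed; all randomness derives from it.
#' @param study_sizes Integer sizes of the simulated studies.
#' @param overlap Named list: combination label (study indices joined "+")
#'   to number of patients reported by exactly that combination; must cover
#'   all study sizes exactly.
#' @param coverage_probs Probability that a non-core case is covered
#'   gene-level / hotspot-level for each of JAK1, JAK3, STAT5B.
#' @param wgs_wes_fraction Fraction of unique cases carrying a WGS/WES assay
#'   (full coverage).
#' @param mutation_rates Named per-gene probabilities that a fully covered
#'   case is mutated.
#' @param lesions Named list per gene: data.frame(protein_change, prob).
#' @param vaf_shape Named list per gene: c(alpha, beta) of the VAF Beta.
#' @param cna_probs Named per-regulator loss (or STAT-gain) probabilities for
#'   dual-platform cases.
#' @param dual_fraction Fraction of WGS/WES cases that also have SNP-array
#'   segments.
#' @param os_median_months Baseline exponential median OS.
#' @param os_hr Hazard ratio of mutated versus unmutated cases (1 = null).
#' @param censor_rate Fraction of follow-up ending in censoring.
#' @param expr_genes,expr_tcl1a_shift,expr_target_shift,expr_batch_offset,expr_noise_sd
#'   Expression model: filler gene count, injected TCL1A log2 shift in
#'   mutated cases, STAT5-target shift in lesion carriers, additive batch
#'   offset, residual SD.
#' @return List of class `SimulationConfig`.
#' @export
simConfig <- function(seed,
                      study_sizes = c(150L, 90L, 60L),
                      overlap = NULL,
                      coverage_probs = list(JAK1 = c(gene = 0.85, hotspot = 0.45),
                                            JAK3 = c(gene = 0.98, hotspot = 0.63),
                                            STAT5B = c(gene = 0.65, hotspot = 0.61)),
                      wgs_wes_fraction = 0.32,
                      mutation_rates = c(JAK3 = 0.345, STAT5B = 0.253, JAK1 = 0.092,
                                         TYK2 = 0.023, STAT4 = 0.023, STAT5A = 0.011),
                      lesions = list(
                        JAK3 = data.frame(protein_change = c("M511I", "Q507P", "A573V", "V674A"),
                                          prob = c(0.62, 0.14, 0.14, 0.10)),
                        STAT5B = data.frame(protein_change = c("N642H", "T628S", "Y665F", "R659C"),
                                            prob = c(0.42, 0.26, 0.16, 0.16)),
                        JAK1 = data.frame(protein_change = c("V658F", "L653F", "S703I"),
                                          prob = c(0.6, 0.2, 0.2)),
                        TYK2 = data.frame(protein_change = "V678F", prob = 1),
                        STAT4 = data.frame(protein_change = "E652G", prob = 1),
                        STAT5A = data.frame(protein_change = "S710F", prob = 1)),
                      vaf_shape = list(JAK3 = c(2.5, 6), JAK1 = c(1.5, 15),
                                       STAT5B = c(2, 7.5), TYK2 = c(2, 8),
                                       STAT4 = c(2, 8), STAT5A = c(2, 8)),
                      cna_probs = c(DUSP4 = 0.41, PTPRC = 0.37, SOCS3 = 0.31,
                                    PTPN6 = 0.24, HDAC9 = 0.20, SOCS1 = 0.12,
                                    PTPN2 = 0.06, STAT3 = 0.10, STAT5A = 0.10,
                                    STAT5B = 0.10, STAT2 = 0.02),
                      dual_fraction = 0.56,
                      os_median_months = 24,
                      os_hr = 1,
                      censor_rate = 0.3,
                      expr_genes = 25L,
                      expr_tcl1a_shift = 2,
                      expr_target_shift = 2.5,
                      expr_batch_offset = 0.6,
                      expr_noise_sd = 0.8) {
  if (missing(seed)) stopf("a seed is mandatory")
  if (any(study_sizes <= 0L)) stopf("study sizes must be positive")
  probs <- c(unlist(coverage_probs), mutation_rates, cna_probs,
             wgs_wes_fraction, dual_fraction, censor_rate)
  if (any(probs < 0 | probs > 1)) stopf("probabilities must lie in [0, 1]")
  cfg <- as.list(environment())
  class(cfg) <- "SimulationConfig"
  cfg
}

defaultOverlap <- function(study_sizes) {
  # every pair of consecutive studies shares ~10% of the smaller one
  n <- length(study_sizes)
  shared <- if (n >= 2L) pmax(1L, floor(0.1 * pmin(study_sizes[-n], study_sizes[-1L])))
            else integer(0)
  overlap <- list()
  for (j in seq_len(n)) {
    solo <- study_sizes[j] -
      (if (j > 1L) shared[j - 1L] else 0L) - (if (j < n) shared[j] else 0L)
    if (solo < 0L) stopf("infeasible overlap design for study %d", j)
    overlap[[as.character(j)]] <- solo
  }
  for (j in seq_len(n - 1L)) overlap[[paste(j, j + 1L, sep = "+")]] <- shared[j]
  overlap
}

#' Simulate a multi-study cohort bundle with ground truth
#'
#' @param config A `SimulationConfig` from [simConfig()].
#' @return List with `bundle` ([TpllCohort-class]) and `manifest` (per-case
#'   truth: tokens, study memberships, coverage, true mutations with VAFs,
#'   true CN states, activation category, true survival parameters).
#' @export
simulateCohort <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  withSeed(config$seed, simulateCohortImpl(config))
}

simulateCohortImpl <- function(config) {
  sizes <- as.integer(config$study_sizes)
  n_st <- length(sizes)
  overlap <- config$overlap %||% defaultOverlap(sizes)
  combos <- lapply(strsplit(names(overlap), "+", fixed = TRUE), as.integer)
  counts <- as.integer(unlist(overlap))
  per_study <- vapply(seq_len(n_st), function(j)
    sum(counts[vapply(combos, function(cb) j %in% cb, TRUE)]), 0L)
  if (!all(per_study == sizes))
    stopf("infeasible overlap design: combination counts do not add up to study sizes")
  n_unique <- sum(counts)
  tokens <- sprintf("SIM-%04d", seq_len(n_unique))
  membership <- rep(combos, counts)          # studies per unique case

  hotspots3 <- paste0(c("JAK1", "JAK3", "STAT5B"), ":hotspot")
  full_panel <- sort(c(JAKSTAT_GENES, hotspots3))
  genes3 <- c("JAK1", "JAK3", "STAT5B")

  core <- runif(n_unique) < config$wgs_wes_fraction
  cov_regions <- lapply(seq_len(n_unique), function(i) {
    if (core[i]) return(full_panel)
    regions <- character(0)
    for (g in genes3) {
      p <- config$coverage_probs[[g]]
      if (runif(1) < p[["gene"]]) {
        regions <- c(regions, g)
        if (runif(1) < p[["hotspot"]] / max(p[["gene"]], 1e-9))
          regions <- c(regions, paste0(g, ":hotspot"))
      }
    }
    sort(regions)
  })
  has_cov <- lengths(cov_regions) > 0L
  method <- ifelse(core, ifelse(runif(n_unique) < 0.25, "WGS", "WES"),
                   ifelse(runif(n_unique) < 0.6, "TAS", "SANGER"))
  matched <- core & (runif(n_unique) < 0.55)

  cases <- do.call(rbind, lapply(seq_len(n_st), function(j) {
    members <- which(vapply(membership, function(cb) j %in% cb, TRUE))
    if (!length(members)) return(NULL)
    data.frame(study_id = sprintf("ST%02d", j),
               local_id = sprintf("ST%02d-%04d", j, seq_along(members)),
               identity_token = tokens[members], stringsAsFactors = FALSE)
  }))
  primary <- vapply(membership, min, 0L)      # calls attach to the first study
  localOf <- function(i) {
    j <- primary[i]
    members <- which(vapply(membership, function(cb) j %in% cb, TRUE))
    sprintf("ST%02d-%04d", j, match(i, members))
  }
  locals <- vapply(seq_len(n_unique), localOf, "")
  studyOf <- sprintf("ST%02d", primary)

  assays <- do.call(rbind, lapply(which(has_cov), function(i) {
    data.frame(study_id = studyOf[i], local_id = locals[i], method = method[i],
               covered_regions = paste(cov_regions[[i]], collapse = ";"),
               germline_matched = matched[i], stringsAsFactors = FALSE)
  }))

  loci <- geneLoci()
  locus_start <- setNames(GenomicRanges::start(loci), names(loci))
  bases <- c("A", "C", "G", "T")
  sim_genes <- names(config$mutation_rates)
  truth_mut <- list(); call_rows <- list()
  for (i in seq_len(n_unique)) {
    if (!has_cov[i]) next
    covered <- normalizeRegions(cov_regions[[i]])
    for (g in sim_genes) {
      if (!g %in% covered) next
      if (runif(1) >= config$mutation_rates[[g]]) next
      cat_ <- config$lesions[[g]]
      pc <- sample(cat_$protein_change, 1L, prob = cat_$prob)
      pp <- parseProteinChange(pc)
      shape <- config$vaf_shape[[g]] %||% c(2, 8)
      vaf <- if (method[i] == "SANGER") NA_real_ else
        round(rbeta(1L, shape[1L], shape[2L]), 4)
      call_rows[[length(call_rows) + 1L]] <- data.frame(
        study_id = studyOf[i], local_id = locals[i], gene = g,
        chrom = as.character(GenomicRanges::seqnames(loci[g])),
        pos = unname(locus_start[g]) + 3L * (pp$position - 1L),
        ref = bases[(pp$position %% 4) + 1],
        alt = bases[((pp$position + 1) %% 4) + 1],
        protein_change = pc, variant_class = "missense", vaf = vaf,
        method = method[i],
        somatic_status = if (matched[i]) "matched_somatic" else "unmatched_filtered",
        stringsAsFactors = FALSE)
      truth_mut[[length(truth_mut) + 1L]] <- data.frame(
        case_id = tokens[i], gene = g, protein_change = pc, vaf = vaf,
        stringsAsFactors = FALSE)
    }
  }
  calls <- if (length(call_rows)) do.call(rbind, call_rows) else
    data.frame(study_id = character(0), local_id = character(0), gene = character(0),
               chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), protein_change = character(0),
               variant_class = character(0), vaf = numeric(0), method = character(0),
               somatic_status = character(0), stringsAsFactors = FALSE)
  truth_mut <- if (length(truth_mut)) do.call(rbind, truth_mut) else NULL

  # CNA process over the dual-platform subset
  dual <- which(core & runif(n_unique) < config$dual_fraction)
  panel <- regulatorPanel()
  seg_rows <- list(); truth_cn <- list()
  for (i in dual) {
    seg_rows[[length(seg_rows) + 1L]] <- data.frame(
      sample = paste(studyOf[i], locals[i], sep = ":"),
      chrom = "20", start = 100000L, end = 500000L, state = "neutral",
      stringsAsFactors = FALSE)
    for (g in names(config$cna_probs)) {
      if (runif(1) >= config$cna_probs[[g]]) next
      state <- if (g %in% panel$gene[panel$direction == "gain_activating"]) "gain" else "loss"
      gr <- loci[g]
      seg_rows[[length(seg_rows) + 1L]] <- data.frame(
        sample = paste(studyOf[i], locals[i], sep = ":"),
        chrom = as.character(GenomicRanges::seqnames(gr)),
        start = GenomicRanges::start(gr) + 10L,
        end = GenomicRanges::end(gr) - 10L, state = state,
        stringsAsFactors = FALSE)
      truth_cn[[length(truth_cn) + 1L]] <- data.frame(
        case_id = tokens[i], gene = g, state = state, stringsAsFactors = FALSE)
    }
  }
  seg_df <- do.call(rbind, seg_rows)
  segments <- if (is.null(seg_df)) GenomicRanges::GRanges() else {
    gr <- GenomicRanges::GRanges(seg_df$chrom,
                                 IRanges::IRanges(seg_df$start, seg_df$end))
    S4Vectors::mcols(gr)$sample <- seg_df$sample
    S4Vectors::mcols(gr)$state <- seg_df$state
    gr
  }
  truth_cn <- if (length(truth_cn)) do.call(rbind, truth_cn) else NULL

  # survival: exponential OS, hazard scaled for mutated cases, censoring
  mutated <- tokens %in% unique(truth_mut$case_id)
  base_rate <- log(2) / config$os_median_months
  rate <- base_rate * ifelse(mutated, config$os_hr, 1)
  t_event <- rexp(n_unique, rate)
  p_c <- min(max(config$censor_rate, 1e-6), 0.999)
  t_cens <- rexp(n_unique, base_rate * p_c / (1 - p_c))
  os <- pmin(t_event, t_cens)
  event <- t_event <= t_cens
  clinical <- data.frame(study_id = studyOf, local_id = locals,
                         os_months = round(os, 2), event = event,
                         cd40l_positive = runif(n_unique) < 0.55,
                         notch2_mut = runif(n_unique) < 0.12,
                         inv14 = runif(n_unique) < 0.6,
                         wbc = round(exp(rnorm(n_unique, log(80), 0.6)), 1),
                         treatment_naive = runif(n_unique) < 0.727,
                         stringsAsFactors = FALSE)

  # expression: tumor samples for core cases + 10 healthy controls
  targets <- stat5Targets()
  genes_ex <- c("TCL1A", targets, sprintf("GENE%02d", seq_len(config$expr_genes)))
  tumor <- which(core)
  samples <- c(tokens[tumor], sprintf("HC%02d", 1:10))
  vals <- matrix(rnorm(length(genes_ex) * length(samples), 8, config$expr_noise_sd),
                 nrow = length(genes_ex),
                 dimnames = list(genes_ex, samples))
  batch <- setNames(rep(c("A", "B"), length.out = length(samples)), samples)
  vals[, batch == "B"] <- vals[, batch == "B"] + config$expr_batch_offset
  group <- setNames(c(rep("case", length(tumor)), rep("control", 10)), samples)
  vals["TCL1A", tokens[intersect(tumor, which(mutated))]] <-
    vals["TCL1A", tokens[intersect(tumor, which(mutated))]] + config$expr_tcl1a_shift
  lesion_cases <- union(unique(truth_mut$case_id), unique(truth_cn$case_id))
  shift <- intersect(tokens[tumor], lesion_cases)
  vals[targets, shift] <- vals[targets, shift] + config$expr_target_shift
  expression <- list(values = vals, batch = batch, group = group)

  manifest <- list(
    seed = config$seed,
    n_unique = n_unique,
    mutation_rates = as.list(config$mutation_rates),
    cna_probs = as.list(config$cna_probs),
    os_median_months = config$os_median_months, os_hr = config$os_hr,
    expr_tcl1a_shift = config$expr_tcl1a_shift,
    expr_batch_offset = config$expr_batch_offset,
    per_case = data.frame(case_id = tokens,
                          studies = vapply(membership, paste, "", collapse = "+"),
                          core_wgs_wes = core, dual_platform = tokens %in% tokens[dual],
                          mutated = mutated,
                          os_true = round(t_event, 4), stringsAsFactors = FALSE),
    mutations = truth_mut, cn_states = truth_cn)

  bundle <- TpllCohort(cases = cases, assays = assays, calls = calls,
                       segments = segments, clinical = clinical,
                       expression = list(), truth = list())
  # expression kept out of the bundle slot only when no core case exists
  if (length(tumor)) bundle@expression <- expression
  validObject(bundle)
  list(bundle = bundle, manifest = manifest)
}

#' Recovery report: pipeline estimates versus simulation ground truth
#'
#' @param sim Output of [simulateCohort()].
#' @return data.frame with one row per checked quantity: quantity, truth,
#'   estimate, abs_error.
#' @export
truthRecoveryReport <- function(sim) {
  bundle <- sim$bundle; manifest <- sim$manifest
  if (is.null(manifest$per_case)) stopf("manifest/bundle mismatch: no per-case truth")
  registry <- resolveOverlaps(bundle)
  if (registry$size != manifest$n_unique)
    stopf("manifest/bundle mismatch: %d cases vs %d in manifest",
          registry$size, manifest$n_unique)
  coverage <- buildCoverage(bundle, registry)
  calls <- harmonizeCalls(bundle, registry)
  rows <- list()
  for (g in names(manifest$mutation_rates)) {
    fr <- tryCatch(regionMutationFrequency(calls, coverage, g), error = function(e) NULL)
    if (is.null(fr)) next
    rows[[length(rows) + 1L]] <- data.frame(
      quantity = sprintf("mutation_rate_%s", g),
      truth = manifest$mutation_rates[[g]], estimate = fr$proportion,
      stringsAsFactors = FALSE)
  }
  ex <- expressionData(bundle)
  if (length(ex)) {
    de <- groupDE(ex$values, ex$group, "TCL1A")
    # compare against carriers-vs-rest on the same samples
    mut <- manifest$per_case$case_id[manifest$per_case$mutated]
    grp <- ifelse(colnames(ex$values) %in% mut, "mutated", "other")
    de2 <- groupDE(ex$values, setNames(grp, colnames(ex$values)), "TCL1A",
                   case_level = "mutated")
    rows[[length(rows) + 1L]] <- data.frame(
      quantity = "tcl1a_log2_shift", truth = manifest$expr_tcl1a_shift,
      estimate = log2(de2$fold_change), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$abs_error <- abs(out$truth - out$estimate)
  out
}
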