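#' Clinical association screen
#'
#' Lesion-status stratifiers are screened against categorical covariates
#' (two-sided Fisher's exact test), continuous covariates (Shapiro-Wilk at
#' alpha = 0.05 in each group gating Student's t-test versus Wilcoxon
#' rank-sum) and overall survival (Kaplan-Meier with two-sided log-rank).
#' Raw p-values reproduce the screening behaviour of uncorrected testing;
#' Benjamini-Hochberg adjusted p-values are reported alongside for honesty.
#' The control arm of a gene-stratified test is cases wild-type for *all*
#' JAK/STAT genes, not merely the stratifier gene.
#'
#' @name clinical-associations
NULL

associationResult <- function(stratifier, variable, test, statistic, p,
                              effect, n1, n0, note = NA_character_) {
  data.frame(stratifier = stratifier, variable = variable, test = test,
             statistic = statistic, p = p, p_adj = NA_real_, effect = effect,
             n_flagged = n1, n_control = n0, note = note,
             stringsAsFactors = FALSE)
}

untestable <- function(stratifier, variable, note) {
  associationResult(stratifier, variable, "untestable", NA_real_, NA_real_,
                    NA_real_, NA_integer_, NA_integer_, note)
}

#' Fisher's exact association of a lesion flag with a categorical variable
#'
#' @param flag Logical vector (lesion carrier per case).
#' @param variable Logical/two-level vector, pairwise missing removed.
#' @param stratifier,name Labels carried into the result row.
#' @return One-row data.frame (see [associationScreen()]); untestable when a
#'   contingency margin is empty.
#' @export
categoricalAssociation <- function(flag, variable, stratifier = "flag",
                                   name = "variable") {
  keep <- !is.na(flag) & !is.na(variable)
  flag <- flag[keep]; variable <- variable[keep]
  tab <- table(factor(flag, levels = c(FALSE, TRUE)),
               factor(as.logical(variable), levels = c(FALSE, TRUE)))
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L))
    return(untestable(stratifier, name, "degenerate 2x2 table"))
  ft <- fisher.test(tab, alternative = "two.sided")
  associationResult(stratifier, name, "fisher", unname(ft$estimate), ft$p.value,
                    unname(ft$estimate), sum(flag), sum(!flag))
}

#' Shapiro-gated continuous association (Student's t or Wilcoxon)
#'
#' Shapiro-Wilk normality is tested in each arm at alpha = 0.05; if both
#' arms pass, a two-sided equal-variance Student's t-test is used (Welch via
#' `welch = TRUE`), otherwise the Wilcoxon rank-sum test.
#'
#' @param flag Logical vector per case.
#' @param variable Numeric vector per case.
#' @param stratifier,name Labels.
#' @param shapiro_alpha Gate level, default 0.05.
#' @param welch Use Welch's t-test instead of the equal-variance variant.
#' @return One-row data.frame; untestable with < 3 values per arm or a
#'   constant variable.
#' @export
continuousAssociation <- function(flag, variable, stratifier = "flag",
                                  name = "variable", shapiro_alpha = 0.05,
                                  welch = FALSE) {
  keep <- !is.na(flag) & !is.na(variable)
  x <- variable[keep & flag]; y <- variable[keep & !flag]
  if (length(x) < 3L || length(y) < 3L)
    return(untestable(stratifier, name, "fewer than 3 values per arm"))
  if (stats::sd(c(x, y)) == 0)
    return(untestable(stratifier, name, "constant variable"))
  normal <- function(v) {
    if (stats::sd(v) == 0) return(FALSE)
    shapiro.test(v)$p.value >= shapiro_alpha
  }
  if (normal(x) && normal(y)) {
    tt <- t.test(x, y, var.equal = !welch)
    associationResult(stratifier, name, "t_test", unname(tt$statistic),
                      tt$p.value, mean(x) - mean(y), length(x), length(y))
  } else {
    wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE))
    associationResult(stratifier, name, "wilcoxon", unname(wt$statistic),
                      wt$p.value, median(x) - median(y), length(x), length(y))
  }
}

#' Kaplan-Meier / log-rank comparison of overall survival by lesion status
#'
#' @param flag Logical per case.
#' @param os_months Follow-up time (months, from diagnosis to event or
#'   censoring).
#' @param event Logical death indicator.
#' @param stratifier Label.
#' @return One-row data.frame with the log-rank chi-square statistic and p,
#'   plus per-arm KM median OS (NA when the curve never crosses 0.5, reported
#'   as missing rather than infinity) in `median_flagged`/`median_control`.
#' @export
survivalCompare <- function(flag, os_months, event, stratifier = "flag") {
  keep <- !is.na(flag) & !is.na(os_months) & !is.na(event)
  flag <- flag[keep]; os_months <- os_months[keep]; event <- as.logical(event[keep])
  if (sum(flag) == 0L || sum(!flag) == 0L)
    return(untestable(stratifier, "os_months", "empty arm"))
  if (sum(event[flag]) == 0L || sum(event[!flag]) == 0L)
    return(untestable(stratifier, "os_months", "arm without events"))
  grp <- factor(flag, levels = c(FALSE, TRUE))
  sd_ <- survival::survdiff(survival::Surv(os_months, event) ~ grp)
  p <- pchisq(sd_$chisq, df = 1L, lower.tail = FALSE)
  fit <- survival::survfit(survival::Surv(os_months, event) ~ grp)
  med <- summary(fit)$table[, "median"]
  out <- associationResult(stratifier, "os_months", "logrank", sd_$chisq, p,
                           NA_real_, sum(flag), sum(!flag))
  out$median_flagged <- unname(med[2L])
  out$median_control <- unname(med[1L])
  out
}

#' Kaplan-Meier curve export
#'
#' @param flag,os_months,event As in [survivalCompare()].
#' @return data.frame (arm, time, survival, n_risk) suitable for plotting.
#' @export
kmCurves <- function(flag, os_months, event) {
  keep <- !is.na(flag) & !is.na(os_months) & !is.na(event)
  grp <- factor(flag[keep], levels = c(FALSE, TRUE),
                labels = c("control", "flagged"))
  fit <- survival::survfit(survival::Surv(os_months[keep], as.logical(event[keep])) ~ grp)
  data.frame(arm = rep(sub("^grp=", "", names(fit$strata)), fit$strata),
             time = fit$time, survival = fit$surv, n_risk = fit$n.risk,
             stringsAsFactors = FALSE)
}

#' Run the full association screen
#'
#' Crosses every stratifier with every clinical variable, auto-selecting the
#' test by variable type, applies Benjamini-Hochberg adjustment across the
#' whole screen and sorts by raw p. Untestable cells are reported as rows
#' with `test = "untestable"`.
#'
#' @param bundle A [TpllCohort-class] with clinical data.
#' @param stratifiers Named list of logical vectors over unique case ids
#'   (each named by case id); defaults to per-gene mutation flags plus the
#'   any-JAK/STAT flag, with controls wild-type for all panel genes.
#' @param variables Character vector of clinical columns to screen; defaults
#'   to all covariate columns present.
#' @param registry A `CaseRegistry`.
#' @return data.frame of association rows, BH-adjusted, sorted by raw p.
#' @export
associationScreen <- function(bundle, stratifiers = NULL, variables = NULL,
                              registry = resolveOverlaps(bundle)) {
  clin <- clinicalTable(bundle)
  if (nrow(clin) == 0L) stopf("bundle has no clinical data")
  clin$case_id <- caseIdsFor(clin, registry)
  clin <- clin[!duplicated(clin$case_id), , drop = FALSE]
  calls <- harmonizeCalls(bundle, registry)
  if (is.null(stratifiers)) {
    carriers <- function(g) unique(calls$case_id[calls$gene == g])
    any_carriers <- unique(calls$case_id[calls$gene %in% JAKSTAT_GENES])
    mk <- function(pos) setNames(ifelse(clin$case_id %in% pos, TRUE,
                                        ifelse(clin$case_id %in% any_carriers, NA, FALSE)),
                                 clin$case_id)
    stratifiers <- c(list(any_jakstat = setNames(clin$case_id %in% any_carriers,
                                                 clin$case_id)),
                     lapply(setNames(nm = intersect(JAKSTAT_GENES, unique(calls$gene))),
                            function(g) mk(carriers(g))))
  }
  if (is.null(variables))
    variables <- setdiff(names(clin), c("study_id", "local_id", "case_id",
                                        "os_months", "event"))
  rows <- list()
  for (sname in names(stratifiers)) {
    flag <- stratifiers[[sname]][clin$case_id]
    for (v in variables) {
      col <- clin[[v]]
      rows[[length(rows) + 1L]] <-
        if (is.logical(col) || length(unique(col[!is.na(col)])) <= 2L) {
          categoricalAssociation(flag, as.logical(col), sname, v)
        } else if (is.numeric(col)) {
          continuousAssociation(flag, col, sname, v)
        } else untestable(sname, v, "unsupported variable type")
    }
    if (all(c("os_months", "event") %in% names(clin))) {
      sr <- survivalCompare(flag, clin$os_months, clin$event, sname)
      sr$median_flagged <- NULL; sr$median_control <- NULL
      rows[[length(rows) + 1L]] <- sr
    }
  }
  out <- do.call(rbind, rows)
  tested <- !is.na(out$p)
  out$p_adj[tested] <- p.adjust(out$p[tested], method = "BH")
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}
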