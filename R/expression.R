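#' Expression side-analyses
#'
#' Batch adjustment by per-gene ordinary least squares on batch indicators
#' (residuals plus grand mean, equalizing within-batch means), two-group
#' differential expression by equal-variance Student's t-test on log2 values
#' with fold change 2^(mean difference), a per-case STAT5-target
#' overexpression flag (any target above healthy mean + 2 SD by default),
#' and a centered PCA summary with a fixed sign convention.
#'
#' @name expression-analyses
NULL

#' Remove batch effects by per-gene linear regression
#'
#' @param matrix Gene x sample log2 matrix.
#' @param batch Batch label per sample (named or aligned to columns).
#' @return Adjusted matrix of the same shape: per gene, OLS residuals on
#'   batch indicators plus the gene's grand mean, so within-batch means are
#'   equalized and the per-gene grand mean is preserved.
#' @export
batchAdjust <- function(matrix, batch) {
  if (!is.null(names(batch))) batch <- batch[colnames(matrix)]
  batch <- factor(batch)
  if (anyNA(batch)) stopf("every sample needs a batch label")
  sizes <- table(batch)
  if (any(sizes < 2L))
    stopf("singleton batch '%s': cannot estimate its offset",
          names(sizes)[sizes < 2L][1L])
  if (nlevels(batch) < 2L) return(matrix)
  design <- stats::model.matrix(~batch)
  fit <- lm.fit(design, t(matrix))
  adjusted <- t(fit$residuals) + rowMeans(matrix)
  dimnames(adjusted) <- dimnames(matrix)
  adjusted
}

#' Two-group differential expression for one gene
#'
#' @param matrix Gene x sample log2 matrix.
#' @param group Two-level label per sample (named or aligned to columns).
#' @param gene Gene (row) name.
#' @param case_level Which group label is the case (numerator) arm; defaults
#'   to `"case"` when present, otherwise the second factor level.
#' @return List of class `DEResult`: gene, fold_change (linear scale,
#'   2^(case mean - control mean) of log2 values), p (two-sided
#'   equal-variance t), group means and sizes; `NULL` for a constant gene
#'   (untestable).
#' @export
groupDE <- function(matrix, group, gene, case_level = NULL) {
  if (!gene %in% rownames(matrix)) stopf("gene %s absent from the matrix", gene)
  if (!is.null(names(group))) group <- group[colnames(matrix)]
  group <- factor(group)
  if (nlevels(group) != 2L) stopf("group must have exactly two levels")
  case_level <- case_level %||% (if ("case" %in% levels(group)) "case"
                                 else levels(group)[2L])
  if (!case_level %in% levels(group)) stopf("case_level '%s' not a group label", case_level)
  x <- matrix[gene, group == case_level]
  y <- matrix[gene, group != case_level]
  if (length(x) < 2L || length(y) < 2L) stopf("need >= 2 samples per group")
  if (stats::sd(c(x, y)) == 0) return(NULL)
  tt <- t.test(x, y, var.equal = TRUE)
  structure(list(gene = gene, fold_change = 2^(mean(x) - mean(y)),
                 p = tt$p.value, statistic = unname(tt$statistic),
                 mean_case = mean(x), mean_control = mean(y),
                 n_case = length(x), n_control = length(y),
                 case_level = case_level),
            class = "DEResult")
}

#' @export
print.DEResult <- function(x, ...) {
  cat(sprintf("%s: Fc = %.2f, p = %.3g (t = %.2f, n = %d/%d)\n",
              x$gene, x$fold_change, x$p, x$statistic, x$n_case, x$n_control))
  invisible(x)
}

#' Flag overexpression of at least one STAT5 target gene
#'
#' @param values Named numeric vector: one case's log2 expression per gene.
#' @param targets Character vector of STAT5 target genes (non-empty).
#' @param healthy Gene x sample log2 matrix of healthy reference samples
#'   (>= 3 samples per target).
#' @param n_sd Threshold in healthy standard deviations above the healthy
#'   mean (default 2).
#' @return TRUE when any target exceeds healthy mean + `n_sd` * SD.
#' @export
stat5TargetOverexpression <- function(values, targets, healthy, n_sd = 2) {
  if (length(targets) == 0L) stopf("empty STAT5 target list")
  targets <- intersect(targets, rownames(healthy))
  if (length(targets) == 0L) stopf("no target gene present in the healthy reference")
  if (ncol(healthy) < 3L) stopf("healthy reference needs >= 3 samples")
  any(vapply(targets, function(g) {
    thr <- mean(healthy[g, ]) + n_sd * stats::sd(healthy[g, ])
    !is.na(values[g]) && values[g] > thr
  }, TRUE))
}

#' Centered PCA summary of an expression matrix
#'
#' @param matrix Gene x sample log2 matrix (>= 2 genes, >= 2 samples).
#' @param n_components Number of leading components to return.
#' @return List with `coordinates` (sample x component scores),
#'   `variance_fraction` per returned component, and `loadings`. The sign of
#'   each component is fixed so its largest-magnitude gene loading is
#'   positive, making coordinates deterministic.
#' @export
pcaSummary <- function(matrix, n_components = 2L) {
  if (nrow(matrix) < 2L || ncol(matrix) < 2L)
    stopf("PCA needs at least 2 genes and 2 samples")
  if (n_components > ncol(matrix))
    stopf("cannot request %d components from %d samples", n_components, ncol(matrix))
  pc <- prcomp(t(matrix), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) { rot[, j] <- -rot[, j]; scores[, j] <- -scores[, j] }
  }
  var_frac <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  list(coordinates = scores, variance_fraction = var_frac, loadings = rot)
}
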