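#' @importFrom methods new validObject is slotNames
#' @importFrom stats median quantile fisher.test t.test wilcox.test shapiro.test
#'   p.adjust prcomp lm lm.fit coef rbinom rbeta rexp rnorm runif setNames pchisq
#' @importFrom utils read.delim write.table head
NULL

# Fixed assay ranking: WGS > WES > TAS > SANGER (larger is better).
ASSAY_METHODS <- c(SANGER = 1L, TAS = 2L, WES = 3L, WGS = 4L)

VARIANT_CLASSES <- c("missense", "inframe_del", "other")
CN_STATES <- c("loss", "neutral", "gain")
ACTIVATION_CATEGORIES <- c("mutation_only", "regulator_only", "both", "none")

# The 11-gene JAK/STAT panel used for union/co-occurrence accounting.
JAKSTAT_GENES <- c("JAK1", "JAK2", "JAK3", "TYK2", "STAT1", "STAT2", "STAT3",
                   "STAT4", "STAT5A", "STAT5B", "STAT6")

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

checkMethod <- function(method) {
  bad <- setdiff(unique(method), names(ASSAY_METHODS))
  if (length(bad) > 0L)
    stopf("unknown assay method(s): %s (allowed: %s)",
          paste(bad, collapse = ", "), paste(names(ASSAY_METHODS), collapse = ", "))
  invisible(method)
}

#' Run code with a temporary RNG seed, restoring global state afterwards
#'
#' All stochastic code in the package funnels through this helper so that a
#' single user-supplied seed makes a whole simulation reproducible without
#' clobbering the caller's random-number stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stopf("a single integer seed is required")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Semicolon-joined region sets in assays.tsv <-> character vectors in memory.
joinRegions <- function(x) vapply(x, function(r) paste(sort(unique(r)), collapse = ";"), "")

splitRegions <- function(x) strsplit(x, ";", fixed = TRUE)

#' Construct a frequency (numerator / denominator) record
#'
#' The unit of reporting throughout the package: an integer numerator over an
#' explicitly stated denominator, in the style `n = 54/87`.
#'
#' @param numerator,denominator Non-negative integer counts.
#' @return A list of class `Frequency` with fields `numerator`, `denominator`,
#'   `proportion` and `percent`.
#' @examples
#' newFrequency(54, 87)
#' @export
newFrequency <- function(numerator, denominator) {
  numerator <- as.integer(numerator)
  denominator <- as.integer(denominator)
  if (denominator <= 0L) stopf("Frequency denominator must be > 0")
  if (numerator < 0L || numerator > denominator)
    stopf("Frequency numerator must satisfy 0 <= n <= N (got %d/%d)",
          numerator, denominator)
  structure(list(numerator = numerator, denominator = denominator,
                 proportion = numerator / denominator,
                 percent = 100 * numerator / denominator),
            class = "Frequency")
}

#' @export
format.Frequency <- function(x, ...) {
  sprintf("%.1f%% (n = %d/%d)", x$percent, x$numerator, x$denominator)
}

#' @export
print.Frequency <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}
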