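test_that("assayed case sets honour full-region coverage", {
  fx <- fixture_parts()
  expect_length(assayedCases(fx$coverage, "JAK3:hotspot"), 206L)
  expect_length(assayedCases(fx$coverage, "JAK3"), 272L)
  expect_length(assayedCases(fx$coverage, "STAT6"), 87L)   # WGS/WES only
  expect_error(assayedCases(fx$coverage, "BRAF"), "unknown region")

  b <- tiny_bundle(list(list(token = "T1", study = "A", method = "TAS",
                             regions = "JAK3")))
  cov <- buildCoverage(b)
  expect_length(assayedCases(cov, "STAT5B"), 0L)           # covered by nobody
})

test_that("region frequencies equal a brute-force per-case scan on random cohorts", {
  set.seed(501)
  for (rep in 1:30) {
    n <- sample(5:30, 1)
    spec <- lapply(seq_len(n), function(i) {
      covered <- runif(1) < 0.7
      muts <- if (covered && runif(1) < 0.4)
        lapply(seq_len(sample(2, 1)), function(k)
          list(gene = "JAK3", pchg = sprintf("M%dI", sample(c(511, 530, 958), 1))))
      list(token = sprintf("T%02d", i), study = "A", method = "WES",
           regions = if (covered) c("JAK3", "JAK3:hotspot") else "JAK1",
           matched = TRUE, calls = muts)
    })
    b <- tiny_bundle(spec)
    reg <- resolveOverlaps(b)
    cov <- buildCoverage(b, reg)
    calls <- harmonizeCalls(b, reg)
    assayed <- assayedCases(cov, "JAK3")
    if (length(assayed) == 0L) next
    fr <- regionMutationFrequency(calls, cov, "JAK3")
    brute <- sum(vapply(assayed, function(cs)
      any(calls$case_id == cs & calls$gene == "JAK3"), TRUE))
    expect_equal(fr$numerator, brute)
    expect_equal(fr$denominator, length(assayed))
  }
})

test_that("one assayed case with one in-region call gives 1/1", {
  b <- tiny_bundle(list(list(token = "T1", study = "A", method = "WES",
                             regions = c("JAK3", "JAK3:hotspot"), matched = TRUE,
                             calls = list(list(gene = "JAK3", pchg = "M511I")))))
  fr <- regionMutationFrequency(harmonizeCalls(b), buildCoverage(b), "JAK3:hotspot")
  expect_equal(c(fr$numerator, fr$denominator), c(1L, 1L))
})

test_that("denominators are the assayed sets, never the global cohort", {
  fx <- fixture_parts()
  fr <- regionMutationFrequency(fx$calls, fx$coverage, "JAK3:hotspot")
  expect_equal(fr$denominator, 206L)
  naive <- newFrequency(fr$numerator, fx$registry$size)   # the wrong way
  expect_false(isTRUE(all.equal(naive$percent, fr$percent)))
  # a gene-level carrier not covered for the hotspot never inflates the numerator
  expect_equal(fr$numerator, 75L)
  m511i <- lesionFrequency(fx$calls, fx$coverage, "JAK3", "M511I")
  expect_gt(m511i$numerator, fr$numerator - 2L)  # carriers live across both sets
  expect_equal(m511i$denominator, 272L)
})

test_that("adding unmutated assayed cases dilutes and mutated ones enrich", {
  base <- list(list(token = "T1", study = "A", method = "WES", regions = "JAK3",
                    matched = TRUE, calls = list(list(gene = "JAK3", pchg = "M511I"))),
               list(token = "T2", study = "A", method = "WES", regions = "JAK3",
                    matched = TRUE))
  p <- function(spec) {
    b <- tiny_bundle(spec)
    regionMutationFrequency(harmonizeCalls(b), buildCoverage(b), "JAK3")$proportion
  }
  p0 <- p(base)
  p_unmut <- p(c(base, list(list(token = "T3", study = "A", method = "WES",
                                 regions = "JAK3", matched = TRUE))))
  p_mut <- p(c(base, list(list(token = "T3", study = "A", method = "WES",
                               regions = "JAK3", matched = TRUE,
                               calls = list(list(gene = "JAK3", pchg = "M511I"))))))
  expect_lte(p_unmut, p0)
  expect_gte(p_mut, p0)
})

test_that("hotspot windows match the exhaustive oracle and are minimal", {
  em <- exonModels()
  jak3 <- em[em$gene == "JAK3", ]

  hs <- detectHotspot(rep(670L, 5), jak3)
  expect_equal(c(hs$first_exon, hs$last_exon), c(16L, 16L))
  expect_equal(hs$fraction, 1.0)

  set.seed(502)
  for (rep in 1:100) {
    pos <- sample(seq_len(1124), sample(5:20, 1), replace = TRUE)
    got <- detectHotspot(pos, jak3)
    want <- oracle_hotspot(pos, jak3)
    expect_equal(c(got$first_exon, got$last_exon), unname(want))
    # window holds > q; shrinking one exon on either side drops to <= q
    expect_gt(got$fraction, 0.9)
    shrink <- function(fe, le) {
      if (le < fe) return(0)
      lo <- jak3$aa_start[jak3$exon == fe]; hi <- jak3$aa_end[jak3$exon == le]
      sum(pos >= lo & pos <= hi) / length(pos)
    }
    if (got$last_exon > got$first_exon) {
      expect_lte(shrink(got$first_exon + 1L, got$last_exon), 0.9)
      expect_lte(shrink(got$first_exon, got$last_exon - 1L), 0.9)
    }
  }
  expect_error(detectHotspot(2000L, jak3), "maps to no exon")
})

test_that("co-occurrence counts match brute-force per-case gene sets", {
  fx <- fixture_parts()
  cc <- cooccurrenceCounts(fx$calls, fx$manifest$wgs_wes_subset)
  expect_equal(unname(cc$k_counts[c("2", "3")]), c(9L, 1L))
  expect_equal(sum(cc$k_counts), 87L)
  pair <- cc$pairs
  expect_equal(pair$count[pair$gene_a == "JAK3" & pair$gene_b == "STAT5B"], 5L)

  cohort <- sprintf("X%d", 1:7)
  cc0 <- cooccurrenceCounts(fx$calls[0, ], cohort)
  expect_equal(unname(cc0$k_counts["0"]), 7L)

  set.seed(503)
  for (rep in 1:20) {
    cohort <- sprintf("C%02d", 1:10)
    calls <- data.frame(case_id = sample(cohort, 25, TRUE),
                        gene = sample(c("JAK1", "JAK3", "STAT5B"), 25, TRUE),
                        stringsAsFactors = FALSE)
    cc <- cooccurrenceCounts(calls, cohort)
    brute <- vapply(cohort, function(cs)
      length(unique(calls$gene[calls$case_id == cs])), 0L)
    for (k in names(cc$k_counts))
      expect_equal(unname(cc$k_counts[k]), sum(brute == as.integer(k)))
  }
})

test_that("union-mutated fraction obeys inclusion-exclusion", {
  fx <- fixture_parts()
  fr <- unionMutatedFraction(fx$calls, fx$manifest$wgs_wes_subset)
  expect_equal(c(fr$numerator, fr$denominator), c(54L, 87L))

  # disjoint single-gene carriers: union = sum of marginals
  calls <- data.frame(case_id = c("A", "B", "C"),
                      gene = c("JAK1", "JAK3", "STAT5B"), stringsAsFactors = FALSE)
  expect_equal(unionMutatedFraction(calls, c("A", "B", "C", "D"))$numerator, 3L)

  set.seed(504)
  for (rep in 1:20) {
    cohort <- sprintf("C%02d", 1:12)
    calls <- data.frame(case_id = sample(cohort, 30, TRUE),
                        gene = sample(c("JAK1", "JAK3", "STAT5B"), 30, TRUE),
                        stringsAsFactors = FALSE)
    u <- unionMutatedFraction(calls, cohort)
    sets <- lapply(c("JAK1", "JAK3", "STAT5B"), function(g)
      unique(calls$case_id[calls$gene == g]))
    singles <- sum(lengths(sets))
    pairs <- sum(vapply(utils::combn(3, 2, simplify = FALSE), function(ij)
      length(intersect(sets[[ij[1]]], sets[[ij[2]]])), 0L))
    triple <- length(Reduce(intersect, sets))
    expect_equal(u$numerator, singles - pairs + triple)
    # union never exceeds the sum of per-gene frequencies
    expect_lte(u$numerator, singles)
  }
})
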