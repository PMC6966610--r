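mk_seg <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(sample = r[[1]], chrom = as.character(r[[2]]),
               start = as.integer(r[[3]]), end = as.integer(r[[4]]),
               state = r[[5]], stringsAsFactors = FALSE)))
}
seg_gr <- function(df) {
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
  S4Vectors::mcols(gr)$sample <- df$sample
  S4Vectors::mcols(gr)$state <- df$state
  gr
}

test_that("segment-to-gene mapping flags any 1-bp overlap and respects boundaries", {
  loci <- geneLoci()
  dusp4 <- loci["DUSP4"]
  s0 <- GenomicRanges::start(dusp4); e0 <- GenomicRanges::end(dusp4)

  cn <- mapSegmentsToGenes(seg_gr(mk_seg(list("A:1", "8", 1, 1e8, "loss"))), loci)
  expect_equal(cn$state[cn$gene == "DUSP4"], "loss")

  # ends exactly 1 bp before the gene: neutral (no row)
  cn <- mapSegmentsToGenes(seg_gr(mk_seg(list("A:1", "8", s0 - 1e5, s0 - 1, "loss"))), loci)
  expect_false("DUSP4" %in% cn$gene)
  # overlaps by exactly 1 bp: flagged
  cn <- mapSegmentsToGenes(seg_gr(mk_seg(list("A:1", "8", s0 - 1e5, s0, "loss"))), loci)
  expect_equal(cn$state[cn$gene == "DUSP4"], "loss")

  # min_overlap fraction can demand more than 1 bp
  cn <- mapSegmentsToGenes(seg_gr(mk_seg(list("A:1", "8", s0, s0 + 99, "loss"))), loci,
                           min_overlap = 0.5)
  expect_false("DUSP4" %in% cn$gene)

  # conflicting states: larger overlapped length wins; exact ties go to loss
  cn <- mapSegmentsToGenes(seg_gr(mk_seg(list("A:1", "8", s0, e0, "gain"),
                                         list("A:1", "8", s0, s0 + 10, "loss"))), loci)
  expect_equal(cn$state[cn$gene == "DUSP4"], "gain")
  cn <- mapSegmentsToGenes(seg_gr(mk_seg(list("A:1", "8", s0, e0, "gain"),
                                         list("A:1", "8", s0, e0, "loss"))), loci)
  expect_equal(cn$state[cn$gene == "DUSP4"], "loss")

  # chromosome naming conventions are normalized: chr8 == 8
  cn <- mapSegmentsToGenes(seg_gr(mk_seg(list("A:1", "chr8", 1, 1e8, "loss"))), loci)
  expect_equal(cn$state[cn$gene == "DUSP4"], "loss")
  # segments on chromosomes without panel genes simply map to nothing
  cn <- mapSegmentsToGenes(seg_gr(mk_seg(list("A:1", "21", 1, 2, "loss"))), loci)
  expect_equal(nrow(cn), 0L)
})

test_that("mapping agrees with the O(SxG) brute-force oracle on random instances", {
  loci <- geneLoci()
  loci_df <- data.frame(symbol = names(loci),
                        chrom = as.character(GenomicRanges::seqnames(loci)),
                        start = GenomicRanges::start(loci),
                        end = GenomicRanges::end(loci), stringsAsFactors = FALSE)
  set.seed(801)
  for (rep in 1:60) {
    n <- sample(10:50, 1)
    gi <- sample(nrow(loci_df), n, TRUE)
    offs <- sample(c(-2e5, -1e4, -1, 0, 1, 1e4), n, TRUE)
    len <- sample(c(1, 100, 1e4, 5e5), n, TRUE)
    df <- data.frame(sample = sprintf("A:%d", sample(5, n, TRUE)),
                     chrom = loci_df$chrom[gi],
                     start = pmax(1L, as.integer(loci_df$start[gi] + offs)),
                     stringsAsFactors = FALSE)
    df$end <- as.integer(df$start + len)
    df$state <- sample(c("loss", "gain", "neutral"), n, TRUE)
    got <- mapSegmentsToGenes(seg_gr(df), loci)
    got <- got[got$state != "neutral", ]
    want <- oracle_segment_map(df, loci_df)
    want <- want[want$state != "neutral", ]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("regulator flags follow panel direction and HDAC9 mutations count", {
  panel <- regulatorPanel()
  cn <- data.frame(case_id = c("A", "B", "C", "D"),
                   gene = c("SOCS3", "SOCS3", "STAT5B", "STAT5B"),
                   state = c("loss", "gain", "gain", "loss"), stringsAsFactors = FALSE)
  fl <- regulatorLesionFlags(cn, panel)
  expect_setequal(fl$case_id, c("A", "C"))
  calls <- data.frame(case_id = "E", gene = "HDAC9", stringsAsFactors = FALSE)
  fl2 <- regulatorLesionFlags(cn, panel, calls)
  expect_true(any(fl2$case_id == "E" & fl2$lesion == "mutation"))
})

test_that("activation categories cover all flag combinations", {
  expect_equal(classifyActivation(c(TRUE, TRUE, FALSE, FALSE),
                                  c(TRUE, FALSE, TRUE, FALSE)),
               c("both", "mutation_only", "regulator_only", "none"))
})

test_that("fixture activation prevalences reproduce the dual-platform accounting", {
  fx <- fixture_parts()
  prof <- suppressMessages(lesionProfiles(fx$bundle, fx$registry))
  expect_equal(nrow(prof), 49L)
  ap <- activationPrevalence(prof)
  expect_equal(c(ap$regulator_lesion$numerator, ap$regulator_lesion$denominator),
               c(35L, 49L))
  expect_equal(c(ap$union$numerator, ap$union$denominator), c(44L, 49L))
  expect_equal(ap$mutation_only$numerator, 9L)
  expect_equal(ap$both$numerator, 24L)
  expect_equal(ap$regulator_only$numerator, 11L)
  # categories partition the cohort; union bounded by category sums
  tot <- ap$both$numerator + ap$mutation_only$numerator +
    ap$regulator_only$numerator + ap$none$numerator
  expect_equal(tot, 49L)
  expect_gte(ap$union$proportion,
             max(ap$both$proportion, ap$mutation_only$proportion,
                 ap$regulator_only$proportion))
  expect_lte(ap$union$proportion,
             ap$both$proportion + ap$mutation_only$proportion +
             ap$regulator_only$proportion)
})

test_that("an all-none cohort has union zero and profiles outside the subset warn", {
  prof <- data.frame(case_id = c("A", "B"), category = c("none", "none"),
                     stringsAsFactors = FALSE)
  ap <- activationPrevalence(prof)
  expect_equal(ap$union$numerator, 0L)
  expect_warning(activationPrevalence(rbind(prof,
    data.frame(case_id = "Z", category = "both")), cohort = c("A", "B")),
    "excluded")
})

test_that("removing a regulator from the panel never increases the union", {
  fx <- fixture_parts()
  panel <- regulatorPanel()
  full <- activationPrevalence(
    suppressMessages(lesionProfiles(fx$bundle, fx$registry, panel)))$union$proportion
  for (g in panel$gene) {
    red <- activationPrevalence(suppressMessages(
      lesionProfiles(fx$bundle, fx$registry, panel[panel$gene != g, ])))$union$proportion
    expect_lte(red, full)
  }
})
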