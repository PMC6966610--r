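mk_cases <- function(...) {
  specs <- list(...)
  do.call(rbind, lapply(names(specs), function(st)
    data.frame(study_id = st,
               local_id = sprintf("%s-%d", st, seq_along(specs[[st]])),
               identity_token = specs[[st]], stringsAsFactors = FALSE)))
}

test_that("disjoint studies add up and shared tokens merge with full provenance", {
  reg <- resolveOverlaps(mk_cases(A = paste0("a", 1:3), B = paste0("b", 1:4),
                                  C = paste0("c", 1:5)))
  expect_equal(reg$size, 12L)

  reg <- resolveOverlaps(mk_cases(A = c("t1", "t2"), B = c("t2", "t3"), C = "t2"))
  expect_equal(reg$size, 3L)
  expect_equal(sum(reg$contributors$case_id == "t2"), 3L)
  expect_setequal(reg$contributors$study_id[reg$contributors$case_id == "t2"],
                  c("A", "B", "C"))
})

test_that("registry size equals brute-force token union on random instances", {
  set.seed(401)
  for (rep in 1:100) {
    n_studies <- sample(2:5, 1)
    pool <- sprintf("t%02d", 1:sample(5:50, 1))
    specs <- lapply(seq_len(n_studies), function(j)
      sample(pool, sample(seq_len(min(20, length(pool))), 1)))
    names(specs) <- sprintf("S%d", seq_len(n_studies))
    reg <- resolveOverlaps(do.call(mk_cases, specs))
    expect_equal(reg$size, length(Reduce(union, specs)))
    # count identity: unique = sum sizes - multi-membership excess
    memb <- table(unlist(lapply(specs, unique)))
    expect_equal(reg$size, sum(lengths(lapply(specs, unique))) - sum(memb - 1L))
  }
})

test_that("resolution is idempotent and order-invariant", {
  set.seed(402)
  cases <- mk_cases(A = c("t1", "t2", "t3"), B = c("t2", "t4"), C = c("t4", "t1"))
  reg1 <- resolveOverlaps(cases)
  reg2 <- resolveOverlaps(cases[sample(nrow(cases)), ])
  expect_identical(reg1, reg2)
  collapsed <- data.frame(study_id = "registry", local_id = reg1$cases$case_id,
                          identity_token = reg1$cases$identity_token,
                          stringsAsFactors = FALSE)
  expect_identical(resolveOverlaps(collapsed)$cases, reg1$cases)
})

test_that("conflicting immutable attributes within a token are an error", {
  cases <- mk_cases(A = c("t1", "t2"), B = "t1")
  cases$sex <- c("F", "M", "M")
  expect_error(resolveOverlaps(cases), "conflicting 'sex'.*t1")
})

test_that("best-assay selection follows the ranking and documented tie-breaks", {
  rec <- function(study, method, regions, matched = FALSE)
    data.frame(study_id = study, local_id = "L1", method = method,
               covered_regions = paste(regions, collapse = ";"),
               germline_matched = matched, stringsAsFactors = FALSE)

  expect_equal(selectBestAssay(rbind(rec("A", "WES", "JAK3"),
                                     rec("B", "SANGER", "JAK3")), "JAK3")$method, "WES")
  expect_equal(selectBestAssay(rec("A", "TAS", "JAK3"), "JAK3")$method, "TAS")
  expect_null(selectBestAssay(rec("A", "TAS", "JAK3"), "STAT5B"))
  # hotspot coverage implies gene coverage
  expect_equal(selectBestAssay(rec("A", "TAS", "JAK3:hotspot"), "JAK3")$method, "TAS")

  # exhaustive enumeration of 2-record tie cases against the documented order
  set.seed(403)
  combos <- expand.grid(m1 = c(TRUE, FALSE), m2 = c(TRUE, FALSE),
                        r1 = 1:2, r2 = 1:2)
  for (k in seq_len(nrow(combos))) {
    g <- combos[k, ]
    regions1 <- c("JAK3", "JAK1")[seq_len(g$r1)]
    regions2 <- c("JAK3", "STAT5B")[seq_len(g$r2)]
    recs <- rbind(rec("B", "WES", regions1, g$m1), rec("A", "WES", regions2, g$m2))
    best <- selectBestAssay(recs, "JAK3")
    want <- if (g$m1 != g$m2) ifelse(g$m1, "B", "A")
      else if (g$r1 != g$r2) ifelse(g$r1 > g$r2, "B", "A")
      else "A"                                    # lexicographic study id
    expect_equal(best$study_id, want)
    # invariant under record order
    expect_equal(selectBestAssay(recs[2:1, ], "JAK3")$study_id, want)
  }
})

test_that("dedup report counts each study combination and sums to registry size", {
  reg <- resolveOverlaps(mk_cases(A = paste0("t", 1:5)))
  rep1 <- dedupReport(reg)
  expect_equal(nrow(rep1), 1L)
  expect_equal(rep1$count, 5L)

  reg <- resolveOverlaps(mk_cases(A = c("t1", "t2"), B = "t2"))
  rep2 <- dedupReport(reg)
  expect_equal(rep2$count[rep2$studies == "A"], 1L)
  expect_equal(rep2$count[rep2$studies == "A+B"], 1L)

  fx <- fixture_parts()
  rep3 <- dedupReport(fx$registry)
  expect_equal(sum(rep3$count), 275L)
  expect_gt(nrow(fx$registry$contributors), 275L)  # real overlap present
})

test_that("coverage matrix uses best assays and keeps hotspot/gene nesting", {
  fx <- fixture_parts()
  cov <- fx$coverage
  hs <- cov[grepl(":hotspot$", cov$region), ]
  gene_keys <- paste(cov$case_id, cov$region)
  expect_true(all(paste(hs$case_id, sub(":hotspot$", "", hs$region)) %in% gene_keys))
  # WGS/WES cases keep their widest method at every covered region
  wgs_case <- fx$manifest$wgs_wes_subset[1]
  expect_true(all(cov$method[cov$case_id == wgs_case] == "WGS"))
})
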