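test_that("a zero-mutation-rate cohort has no calls and no activation", {
  cfg <- simConfig(seed = 21L, study_sizes = c(30L, 20L),
                   mutation_rates = c(JAK3 = 0, STAT5B = 0, JAK1 = 0),
                   cna_probs = c(DUSP4 = 0))
  sim <- simulateCohort(cfg)
  expect_equal(nrow(mutationCalls(sim$bundle)), 0L)
  prof <- suppressMessages(lesionProfiles(sim$bundle))
  if (nrow(prof)) expect_true(all(prof$category == "none"))
})

test_that("the same seed reproduces byte-identical bundles", {
  cfg <- simConfig(seed = 22L, study_sizes = c(40L, 25L))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeCohortBundle(simulateCohort(cfg)$bundle, d1)
  writeCohortBundle(simulateCohort(cfg)$bundle, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
})

test_that("an infeasible overlap design is rejected", {
  expect_error(simulateCohort(simConfig(seed = 23L, study_sizes = c(10L, 10L),
                                        overlap = list("1" = 2L, "2" = 10L,
                                                       "1+2" = 3L))),
               "infeasible")
  expect_error(simConfig(seed = 24L, study_sizes = c(-5L, 10L)), "positive")
  expect_error(simConfig(seed = 25L, wgs_wes_fraction = 1.4), "probabilities")
})

test_that("manifest and bundle are one-to-one and truth recovery runs clean", {
  sim <- simulateCohort(simConfig(seed = 26L, study_sizes = c(60L, 40L)))
  reg <- resolveOverlaps(sim$bundle)
  expect_equal(reg$size, sim$manifest$n_unique)
  expect_setequal(reg$cases$case_id, sim$manifest$per_case$case_id)
  rec <- suppressMessages(truthRecoveryReport(sim))
  expect_true(all(c("quantity", "truth", "estimate", "abs_error") %in% names(rec)))
  expect_true(all(rec$abs_error >= 0))

  # deterministic (rate 1) mutation process recovers with zero error
  sim1 <- simulateCohort(simConfig(seed = 27L, study_sizes = 40L,
                                   wgs_wes_fraction = 1,
                                   mutation_rates = c(JAK3 = 1)))
  rec1 <- suppressMessages(truthRecoveryReport(sim1))
  expect_equal(rec1$abs_error[rec1$quantity == "mutation_rate_JAK3"], 0)
})

test_that("simulated frequencies converge to configured rates with n", {
  errs <- vapply(c(100L, 1000L), function(n) {
    sim <- simulateCohort(simConfig(seed = 28L, study_sizes = n,
                                    wgs_wes_fraction = 1))
    rec <- suppressMessages(truthRecoveryReport(sim))
    mean(rec$abs_error[grepl("mutation_rate", rec$quantity)])
  }, 0)
  expect_lt(errs[2], errs[1] + 0.01)  # no blow-up; large n close to truth
  expect_lt(errs[2], 0.05)
})

test_that("the fixture regenerates identically and satisfies its inter-count design", {
  fx1 <- publishedFixture(); fx2 <- publishedFixture()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeCohortBundle(fx1$bundle, d1); writeCohortBundle(fx2$bundle, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)

  fx <- fixture_parts()
  ex <- fx$manifest$expected
  wes <- fx$manifest$wgs_wes_subset
  sub <- fx$calls[fx$calls$case_id %in% wes, ]
  expect_equal(nrow(sub), ex$variants[["total"]])
  expect_equal(sum(sub$variant_class == "missense"), ex$variants[["missense"]])
  expect_equal(sum(sub$variant_class == "inframe_del"), ex$variants[["inframe_del"]])
  for (g in names(ex$gene_coverage))
    expect_length(assayedCases(fx$coverage, g), ex$gene_coverage[[g]])
  for (g in names(ex$hotspot_coverage))
    expect_length(assayedCases(fx$coverage, paste0(g, ":hotspot")),
                  ex$hotspot_coverage[[g]])
  for (g in names(ex$hotspot_mutated)) {
    fr <- suppressMessages(
      regionMutationFrequency(fx$calls, fx$coverage, paste0(g, ":hotspot")))
    expect_equal(fr$numerator, ex$hotspot_mutated[[g]])
  }
  les <- list(M511I = "JAK3", N642H = "STAT5B", V658F = "JAK1",
              Y665F = "STAT5B")
  for (pc in names(les)) {
    fr <- suppressMessages(lesionFrequency(fx$calls, fx$coverage, les[[pc]], pc))
    expect_equal(c(fr$numerator, fr$denominator), unname(ex$lesions[[pc]]))
  }
  # the one denominator the published counts keep inconsistent: T628S carriers
  # all sit inside the hotspot-covered subset (n = 202)
  t628s <- unique(fx$calls$case_id[fx$calls$protein_change == "T628S"])
  expect_length(t628s, ex$lesions$T628S[[1]])
  expect_true(all(t628s %in% assayedCases(fx$coverage, "STAT5B:hotspot")))
  # per-case truth matches the bundle-derived activation categories
  prof <- suppressMessages(lesionProfiles(fx$bundle, fx$registry))
  truth_cat <- fx$manifest$per_case
  truth_cat <- truth_cat[truth_cat$dual_platform, ]
  m <- merge(prof, truth_cat, by = "case_id")
  expect_equal(m$category.x, m$category.y)
})
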