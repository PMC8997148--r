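small_config <- function(seed = 1, ...) {
  sim_config(n_patients = 30, panel_size = 60, n_gold_like = 12,
             n_silver_like = 10, n_bronze_like = 5, n_noise = 30,
             n_artifact_positions = 2, n_common_positions = 1,
             artifact_carriers = 4, seed = seed, ...)
}

test_that("generation is deterministic: same seed, identical files", {
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  unlink(c(d1, d2), recursive = TRUE)
  simulate_cohort(small_config(seed = 11), dir = d1)
  simulate_cohort(small_config(seed = 11), dir = d2)
  f1 <- list.files(d1, recursive = TRUE, full.names = TRUE)
  f2 <- list.files(d2, recursive = TRUE, full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  # and a different seed changes the data
  d3 <- file.path(tempdir(), "simC")
  unlink(d3, recursive = TRUE)
  simulate_cohort(small_config(seed = 12), dir = d3)
  f3 <- list.files(d3, recursive = TRUE, full.names = TRUE)
  expect_false(all(unname(tools::md5sum(f1)) == unname(tools::md5sum(f3))))
})

test_that("generated VCFs are valid and re-readable without warnings", {
  d <- file.path(tempdir(), "simvcf")
  unlink(d, recursive = TRUE)
  sim <- simulate_cohort(small_config(seed = 3), dir = d)
  paths <- list.files(file.path(d, "vcf"), full.names = TRUE)
  expect_equal(length(paths), 30)
  expect_no_warning(back <- read_cohort_vcf(paths))
  a <- dplyr::arrange(sim$records, patient, chrom, pos, alt)
  b <- dplyr::arrange(back, patient, chrom, pos, alt)
  expect_equal(b$pos, a$pos)
  expect_equal(b$ref_depth, a$ref_depth)
  expect_equal(b$alt_depth, a$alt_depth)
  expect_equal(b$genotype, a$genotype)
})

test_that("planted variants carry the promised structure", {
  sim <- simulate_cohort(small_config(seed = 5))
  tv <- sim$truth$variants
  rec <- sim$records
  # planted depth draws pass both filter stages
  planted <- rec[varmedal:::variant_id(rec$chrom, rec$pos, rec$ref, rec$alt) %in%
                   varmedal:::variant_id(tv$chrom, tv$pos, tv$ref, tv$alt)[
                     tv$planted_class %in% c("gold", "silver", "silver_matched",
                                             "bronze")], ]
  expect_equal(nrow(apply_post_filters(planted)), nrow(planted))
  # gold variants are rare
  pf <- sim$evidence$popfreq
  gold_keys <- varmedal:::variant_id(tv$chrom, tv$pos, tv$ref, tv$alt)[
    tv$planted_class == "gold"]
  expect_true(all(pf$popmax_af[varmedal:::variant_id(pf$chrom, pf$pos, pf$ref,
                                                     pf$alt) %in% gold_keys]
                  < 0.01))
  # artifact positions: several carriers, varied alts, alt always below ref
  art_pos <- unique(tv$pos[tv$planted_class == "artifact"])
  expect_equal(length(art_pos), 2)
  for (p in art_pos) {
    cells <- rec[rec$pos == p, ]
    expect_gte(length(unique(cells$patient)), 4)
    expect_gte(length(unique(cells$alt)), 2)
    expect_true(all(cells$alt_depth < cells$ref_depth))
  }
  # common position carried by every patient
  com_pos <- tv$pos[tv$planted_class == "common"]
  expect_equal(sort(unique(rec$patient[rec$pos == com_pos])),
               sort(sim$patients$patient))
  # infeasible configuration rejected
  expect_error(sim_config(panel_size = 5, n_gold_like = 100), "panel_size")
})

test_that("pipeline recovers exactly the planted gold set", {
  sim <- simulate_cohort(small_config(seed = 7))
  res <- suppressWarnings(prioritize_cohort(sim$records, sim$panel,
                                            sim$evidence,
                                            patients = sim$patients$patient))
  tv <- sim$truth$variants
  want <- sort(varmedal:::variant_id(tv$chrom, tv$pos, tv$ref, tv$alt)[
    tv$planted_class == "gold"])
  got <- sort(varmedal:::variant_id(res$gold$chrom, res$gold$pos,
                                    res$gold$ref, res$gold$alt))
  expect_equal(got, want)    # precision = recall = 1
  # retained silver calls are exactly the somatically matched planted silver
  want_s <- sort(varmedal:::variant_id(tv$chrom, tv$pos, tv$ref, tv$alt)[
    tv$planted_class == "silver_matched"])
  got_s <- sort(varmedal:::variant_id(res$silver$chrom, res$silver$pos,
                                      res$silver$ref, res$silver$alt))
  expect_equal(got_s, want_s)
  # gold and retained-silver are disjoint by variant-patient pair
  gid <- paste(varmedal:::variant_id(res$gold$chrom, res$gold$pos,
                                     res$gold$ref, res$gold$alt),
               res$gold$patient)
  sid <- paste(varmedal:::variant_id(res$silver$chrom, res$silver$pos,
                                     res$silver$ref, res$silver$alt),
               res$silver$patient)
  expect_equal(length(intersect(gid, sid)), 0)
  # the funnel shrinks through the filtering stages
  f <- setNames(res$funnel$n, res$funnel$stage)
  expect_lte(f["caller_filtered"], f["raw"])
  expect_lte(f["in_panel"], f["caller_filtered"])
  expect_lte(f["curated"], f["silver_refined"])
})

test_that("ambiguous evidence degrades planted gold to the consequence tier", {
  sim <- simulate_cohort(small_config(seed = 9))
  stripped <- sim$evidence
  stripped$assertions <- stripped$assertions[0, ]
  res <- suppressWarnings(prioritize_cohort(sim$records, sim$panel, stripped,
                                            patients = sim$patients$patient))
  expect_equal(nrow(res$gold), 0)
  # truncations in tumor suppressors without assertions cannot even be
  # silver (silver needs a database match), so nothing is retained
  expect_equal(nrow(res$silver), 0)
})

test_that("artifact detector is sensitive and specific across replicates", {
  hits <- 0; planted <- 0; false_flags <- 0; positions <- 0
  for (seed in 1:50) {
    sim <- simulate_cohort(small_config(seed = seed))
    tv <- sim$truth$variants
    mat <- cohort_matrix(sim$records, sim$patients$patient)
    flags <- detect_mapping_artifacts(mat, min_patients = 3)
    art <- unique(varmedal:::position_id(
      tv$chrom[tv$planted_class == "artifact"],
      tv$pos[tv$planted_class == "artifact"]))
    flagged <- varmedal:::position_id(flags$chrom, flags$pos)[
      flags$flag == "mapping_artifact"]
    hits <- hits + sum(art %in% flagged)
    planted <- planted + length(art)
    false_flags <- false_flags + length(setdiff(flagged, art))
    positions <- positions + nrow(flags) - length(art)
  }
  expect_gte(hits / planted, 0.95)
  expect_lte(false_flags / positions, 0.01)
})

test_that("patient covariates and survival have the configured structure", {
  p <- simulate_patients(5000, sim_config(), seed = 2)
  expect_true(all(p$age_at_diagnosis <= 40))
  expect_true(all(p$followup_months >= 0))
  # carrier prevalence is calibrated
  expect_lt(abs(mean(p$gold_carrier) - 0.34), 0.03)
  # carriers have worse event-free survival (hazard ratio > 1)
  lr <- log_rank(p$followup_months, p$recurrence_event, p$gold_carrier)
  km_c <- km_estimate(p$followup_months[p$gold_carrier],
                      p$recurrence_event[p$gold_carrier])
  km_n <- km_estimate(p$followup_months[!p$gold_carrier],
                      p$recurrence_event[!p$gold_carrier])
  expect_lt(km_surv(km_c, 60), km_surv(km_n, 60))
  expect_lt(lr$p_value, 0.01)
})
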