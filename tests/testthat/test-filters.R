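test_that("VAF and ABHet follow their depth definitions", {
  expect_equal(vaf(21, 19), 0.475)
  expect_equal(vaf(30, 0), 0)
  expect_equal(vaf(0, 30), 1)
  expect_equal(abhet(21, 19), 0.525)
  expect_equal(abhet(50, 50), 0.5)
  expect_equal(abhet(9, 1), 0.9)
  expect_error(vaf(0, 0), "zero total depth")
  expect_error(abhet(0, 0), "zero total depth")
})

test_that("caller filters exclude by depth, allele balance, frequency, and support", {
  rec <- make_records(ref_depth = c(21, 5, 95), alt_depth = c(19, 4, 5))
  pf <- tibble::tibble(chrom = "1", pos = 100L, ref = "G", alt = "A",
                       popmax_af = 1e-4)
  res <- apply_caller_filters(rec, pf)
  # (21,19) with popmax 1e-4 passes every rule
  expect_equal(res$passed$pos, 100L)
  # total depth 9 -> min-depth rule
  expect_true(res$log$rule_low_depth[2])
  # (95,5): ABHet 0.95, minor fraction 0.05, alt reads 5 -> three rules fire
  expect_true(res$log$rule_abhet_outside[3])
  expect_true(res$log$rule_low_minor_fraction[3])
  expect_true(res$log$rule_low_alt_reads[3])
  # log partitions the input
  expect_equal(nrow(res$passed) + sum(res$log$excluded), nrow(rec))
})

test_that("common variants are excluded at the popmax threshold", {
  rec <- make_records(ref_depth = c(20, 20), alt_depth = c(20, 20),
                      pos = c(100L, 200L))
  pf <- tibble::tibble(chrom = "1", pos = c(100L, 200L), ref = "G", alt = "A",
                       popmax_af = c(0.01, 0.0099))
  res <- apply_caller_filters(rec, pf)
  expect_true(res$log$rule_common_popmax[1])   # 0.01 is not "below 0.01"
  expect_false(res$log$rule_common_popmax[2])
  # unobserved frequency is treated as 0 and passes
  res2 <- apply_caller_filters(rec, pf[0, ])
  expect_equal(nrow(res2$passed), 2)
})

test_that("homozygous alternates bypass the heterozygous balance rules", {
  rec <- make_records(ref_depth = 2, alt_depth = 38, genotype = "hom_alt")
  res <- apply_caller_filters(rec)
  expect_equal(nrow(res$passed), 1)
  het <- make_records(ref_depth = 2, alt_depth = 38, genotype = "het")
  expect_equal(nrow(apply_caller_filters(het)$passed), 0)
})

test_that("post-classification filters keep well-supported calls", {
  expect_equal(nrow(apply_post_filters(make_records(11, 14))), 1)  # VAF 0.56
  expect_equal(nrow(apply_post_filters(make_records(28, 11))), 1)  # VAF 0.282
  expect_equal(nrow(apply_post_filters(make_records(16, 4))), 0)   # VAF 0.20
})

test_that("filter boundaries follow the stated comparators", {
  cfg <- filter_config()
  relaxed <- filter_config(min_alt_reads = 0, min_minor_allelic_fraction = 0)
  # total depth exactly 10 passes; 9 fails (hom-alt bypasses balance rules)
  expect_equal(nrow(apply_caller_filters(make_records(0, 10, "hom_alt"),
                                         config = cfg)$passed), 1)
  expect_equal(nrow(apply_caller_filters(make_records(0, 9, "hom_alt"),
                                         config = relaxed)$passed), 0)
  # ABHet exactly 0.8 and 0.2 pass; strictly outside fails
  expect_equal(nrow(apply_caller_filters(make_records(32, 8),
                                         config = relaxed)$passed), 1)
  expect_equal(nrow(apply_caller_filters(make_records(8, 32),
                                         config = relaxed)$passed), 1)
  expect_equal(nrow(apply_caller_filters(make_records(33, 7),
                                         config = relaxed)$passed), 0)
  # minor allelic fraction exactly 0.25 passes
  expect_equal(nrow(apply_caller_filters(make_records(30, 10),
                                         config = cfg)$passed), 1)
  # post filters: total exactly 20 and VAF exactly 0.25 pass
  expect_equal(nrow(apply_post_filters(make_records(15, 5), cfg)), 1)
  expect_equal(nrow(apply_post_filters(make_records(14, 5), cfg)), 0)
  expect_equal(nrow(apply_post_filters(make_records(60, 20), cfg)), 1)
  expect_equal(nrow(apply_post_filters(make_records(61, 20), cfg)), 0)
})

test_that("filters are idempotent and monotone in their thresholds", {
  withr::local_seed(42)
  n <- 1000
  rec <- make_records(
    ref_depth = rpois(n, 20), alt_depth = rpois(n, 12),
    genotype = sample(c("het", "hom_alt"), n, replace = TRUE),
    pos = seq_len(n) * 10L
  )
  pf <- tibble::tibble(chrom = "1", pos = rec$pos, ref = "G", alt = "A",
                       popmax_af = runif(n, 0, 0.02))
  keep <- rec$ref_depth + rec$alt_depth > 0
  rec <- rec[keep, ]; pf <- pf[keep, ]

  p1 <- apply_caller_filters(rec, pf)$passed
  p2 <- apply_caller_filters(p1, pf)$passed
  expect_equal(p2, p1)
  q1 <- apply_post_filters(rec)
  expect_equal(apply_post_filters(q1), q1)

  base <- nrow(p1)
  stricter <- list(
    filter_config(min_depth = 20), filter_config(abhet_low = 0.35),
    filter_config(abhet_high = 0.65), filter_config(max_popmax_af = 0.005),
    filter_config(min_alt_reads = 15),
    filter_config(min_minor_allelic_fraction = 0.4)
  )
  for (cfg in stricter) {
    expect_lte(nrow(apply_caller_filters(rec, pf, cfg)$passed), base)
  }
  expect_lte(nrow(apply_post_filters(rec, filter_config(min_total_reads_post = 30))),
             nrow(q1))
  expect_lte(nrow(apply_post_filters(rec, filter_config(min_vaf_post = 0.4))),
             nrow(q1))
})

test_that("filter configuration validates its thresholds and loads from JSON", {
  expect_error(filter_config(abhet_low = 0.9, abhet_high = 0.8), "abhet")
  expect_error(filter_config(min_vaf_post = 1.5), "\\[0, 1\\]")
  path <- tempfile(fileext = ".json")
  writeLines('{"min_depth": 15, "min_vaf_post": 0.3}', path)
  cfg <- read_filter_config(path)
  expect_equal(cfg$min_depth, 15)
  expect_equal(cfg$min_vaf_post, 0.3)
  expect_equal(cfg$abhet_low, 0.2)
  writeLines('{"bogus_threshold": 1}', path)
  expect_error(read_filter_config(path), "bogus_threshold")
})
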