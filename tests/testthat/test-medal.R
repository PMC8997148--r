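path_2star <- function() make_assertions("clinvar", "pathogenic", 2L)

test_that("medal assignment follows the tiered rule set", {
  # truncating variant in a tumor suppressor with a 2-star pathogenic
  # assertion -> gold
  g <- classify_germline(make_bundle("frameshift", is_tsg = TRUE,
                                     lof_mech = TRUE,
                                     assertions = path_2star()))
  expect_equal(g$germline_medal, "gold")
  expect_match(g$medal_reasons, "truncating_consequence")

  # in-frame deletion in a non-TSG gene with one locus-database assertion
  s <- classify_germline(make_bundle("inframe_indel", is_tsg = FALSE,
                                     lof_mech = FALSE,
                                     assertions = make_assertions(
                                       "lovd", "vus", NA)))
  expect_equal(s$germline_medal, "silver")

  # tolerated-predicted missense with no assertions -> bronze
  b <- classify_germline(make_bundle("missense", is_tsg = FALSE,
                                     lof_mech = FALSE, tolerated = TRUE))
  expect_equal(b$germline_medal, "bronze")

  # synonymous with no evidence -> unknown, no fired rules
  u <- classify_germline(make_bundle("synonymous", is_tsg = FALSE,
                                     lof_mech = FALSE))
  expect_equal(u$germline_medal, "unknown")
  expect_equal(u$medal_reasons, "")

  # gold requires a disease-associated gene
  ng <- classify_germline(make_bundle("frameshift", is_tsg = FALSE,
                                      lof_mech = FALSE,
                                      assertions = path_2star()))
  expect_false(ng$germline_medal == "gold")

  # a 1-star pathogenic clinvar assertion is not enough for gold, but a
  # specialty-source pathogenic assertion is
  one_star <- classify_germline(make_bundle("frameshift",
    assertions = make_assertions("clinvar", "pathogenic", 1L)))
  expect_equal(one_star$germline_medal, "unknown")
  spec <- classify_germline(make_bundle("frameshift",
    assertions = make_assertions("bic", "pathogenic", NA)))
  expect_equal(spec$germline_medal, "gold")
})

test_that("classification is independent of assertion ordering", {
  a <- make_assertions(c("lovd", "clinvar"), c("vus", "pathogenic"),
                       c(NA, 2L))
  m1 <- classify_germline(make_bundle("frameshift", assertions = a))
  m2 <- classify_germline(make_bundle("frameshift",
                                      assertions = a[2:1, ]))
  expect_equal(m1$germline_medal, m2$germline_medal)
})

test_that("classifier matches the exhaustively enumerated truth table", {
  grid <- medal_grid()
  bundles <- dplyr::bind_rows(lapply(seq_len(nrow(grid)),
                                     function(i) grid_bundle(grid[i, ])))
  got <- classify_germline(bundles)$germline_medal
  want <- vapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    oracle_medal(g$consequence, g$tsg, g$lof, g$clinvar_stars, g$specialty,
                 g$tolerated)
  }, "")
  expect_equal(got, want)
})

test_that("adding a 2-star pathogenic assertion never lowers the medal", {
  grid <- medal_grid()
  withr::local_seed(99)
  idx <- sample(nrow(grid), 400)
  for (i in idx) {
    g <- grid[i, ]
    base <- grid_bundle(g)
    boosted <- base
    boosted$assertions <- list(rbind(base$assertions[[1]], path_2star()))
    m0 <- classify_germline(base)$germline_medal
    m1 <- classify_germline(boosted)$germline_medal
    expect_gte(medal_rank(m1), medal_rank(m0))
  }
  # and removing all assertions never raises the medal
  for (i in idx[1:100]) {
    g <- grid[i, ]
    base <- grid_bundle(g)
    stripped <- base
    stripped$assertions <- list(make_assertions())
    m0 <- classify_germline(stripped)$germline_medal
    m1 <- classify_germline(base)$germline_medal
    expect_gte(medal_rank(m1), medal_rank(m0))
  }
})

test_that("silver refinement keeps only somatically matched silver calls", {
  calls <- dplyr::bind_rows(
    classify_germline(make_bundle("inframe_indel", is_tsg = FALSE,
                                  lof_mech = FALSE, somatic = "gold",
                                  assertions = make_assertions("lovd", "vus", NA))),
    classify_germline(make_bundle("inframe_indel", is_tsg = FALSE,
                                  lof_mech = FALSE, somatic = "none",
                                  assertions = make_assertions("lovd", "vus", NA))),
    classify_germline(make_bundle("frameshift", somatic = "none",
                                  assertions = path_2star()))
  )
  out <- refine_silver(calls)
  expect_equal(out$germline_medal, c("silver", "silver", "gold"))
  expect_equal(out$retained_after_refinement, c(TRUE, FALSE, TRUE))
  # silver + somatic silver also retained
  alt <- calls; alt$somatic_category[2] <- "silver"
  expect_true(refine_silver(alt)$retained_after_refinement[2])
})

test_that("C-terminal caution flags truncations near the protein end", {
  # stop at the final residue
  expect_true(flag_cterm_caution("nonsense", 678L, 678L))
  # 1334/1360 = 0.981
  expect_true(flag_cterm_caution("splice", 1334L, 1360L))
  # 1892/3056 = 0.62: no caution
  expect_false(flag_cterm_caution("splice", 1892L, 3056L))
  # 779/1186 = 0.657: no caution
  expect_false(flag_cterm_caution("nonsense", 779L, 1186L))
  # early truncation in the final coding exon is still flagged
  expect_true(flag_cterm_caution("nonsense", 788L, 4061L, final_exon = TRUE))
  expect_false(flag_cterm_caution("nonsense", 788L, 4061L))
  # fraction 0.899 rounds to 0.90 and meets the threshold
  expect_true(flag_cterm_caution("frameshift", 2424L, 2696L))
  # non-truncating consequences are never flagged
  expect_false(flag_cterm_caution("missense", 393L, 393L, final_exon = TRUE))
})

test_that("pLI tiers follow the 0.9/0.5 boundaries", {
  expect_equal(pli_tier(c(1, 0.9, 0.79, 0.5, 0.49, 0, NA)),
               c("high", "high", "intermediate", "intermediate", "low",
                 "low", "absent"))
  expect_error(pli_tier(1.2), "\\[0, 1\\]")
})

test_that("somatic categories pass through with 'none' for unmatched", {
  expect_equal(somatic_category(c("gold", "silver", NA, "weird")),
               c("gold", "silver", "none", "none"))
})
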