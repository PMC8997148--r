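# independent enumeration of the published medal rule text, used as the
# brute-force oracle for the classifier
oracle_medal <- function(consequence, tsg, lof, clinvar_stars, specialty,
                         tolerated) {
  truncating <- consequence %in% c("frameshift", "nonsense", "splice")
  has_clinvar <- !is.na(clinvar_stars)
  pathogenic_reported <- has_clinvar || specialty
  strong_support <- (has_clinvar && clinvar_stars >= 2) || specialty
  if ((truncating || pathogenic_reported) && (lof || tsg) && strong_support) {
    return("gold")
  }
  damaging_missense <- consequence == "missense" &&
    identical(tolerated, FALSE)
  silver_shape <- consequence == "inframe_indel" ||
    (truncating && !tsg) || damaging_missense
  if (silver_shape && has_clinvar) return("silver")  # clinvar is the only
  if (isTRUE(tolerated)) return("bronze")            # silver-listed source
  "unknown"                                          # in the grid
}

medal_grid <- function() {
  expand.grid(
    consequence = c("splice", "frameshift", "nonsense", "missense", "utr5",
                    "inframe_indel", "splice_region", "synonymous", "other"),
    tsg = c(TRUE, FALSE), lof = c(TRUE, FALSE),
    clinvar_stars = c(NA, 0L, 1L, 2L, 3L, 4L),
    specialty = c(TRUE, FALSE), tolerated = c(TRUE, FALSE, NA),
    stringsAsFactors = FALSE
  )
}

grid_bundle <- function(g) {
  asr <- make_assertions()
  if (!is.na(g$clinvar_stars)) {
    asr <- rbind(asr, make_assertions("clinvar", "pathogenic",
                                      g$clinvar_stars))
  }
  if (g$specialty) {
    asr <- rbind(asr, make_assertions("bic", "pathogenic", NA))
  }
  make_bundle(g$consequence, is_tsg = g$tsg, lof_mech = g$lof,
              tolerated = g$tolerated, assertions = asr)
}

# candidate call set mirroring the curated cohort: the 50 bundled calls plus
# two recurrent artifact positions and one cohort-wide variant
make_candidate_calls <- function(roster) {
  t2 <- gold_variant_table()
  base <- t2[, c("chrom", "pos", "ref", "alt", "patient",
                 "ref_depth", "alt_depth", "gene", "consequence")]
  art <- dplyr::bind_rows(lapply(c(34945343L, 34945354L), function(p) {
    carriers <- roster[1:6]
    tibble::tibble(
      chrom = "19", pos = p, ref = "C",
      alt = c("A", "G", "T", "A", "G", "T"),
      patient = carriers,
      ref_depth = c(40L, 35L, 50L, 44L, 38L, 41L),
      alt_depth = c(12L, 11L, 15L, 13L, 12L, 14L),
      gene = "UBA2LIKE", consequence = "frameshift"
    )
  }))
  common <- tibble::tibble(
    chrom = "16", pos = 72991715L, ref = "G", alt = "A",
    patient = roster,
    ref_depth = 30L, alt_depth = 25L,
    gene = "ZFHX3LIKE", consequence = "splice"
  )
  dplyr::bind_rows(base, art, common)
}
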