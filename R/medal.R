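MEDAL_LEVELS <- c("gold", "silver", "bronze", "unknown")

#' Medal-classification configuration
#'
#' Thresholds and database source-tag sets for the four-tier medal
#' classifier. The defaults encode the published rule set:
#'
#' * **Gold** — a truncating consequence (frameshift, nonsense, splice) or a
#'   pathogenic/likely-pathogenic assertion, in a disease-associated gene
#'   (loss-of-function disease mechanism or tumor suppressor), supported by
#'   a star-rated pathogenic assertion with at least `min_stars` stars or by
#'   a pathogenic assertion from a specialty locus database.
#' * **Silver** — not Gold, with an in-frame indel, a truncation in a
#'   non-tumor-suppressor gene, or a damaging-predicted missense, and at
#'   least one assertion from a configured Silver source.
#' * **Bronze** — predicted tolerated by in-silico algorithms and no higher
#'   tier reached.
#' * **Unknown** — otherwise.
#'
#' @param star_sources Source tags whose assertions carry review-status
#'   stars (default `"clinvar"`).
#' @param min_stars Minimum stars for a star-rated pathogenic assertion to
#'   support Gold (default 2).
#' @param specialty_sources Specialty locus databases whose pathogenic
#'   assertions support Gold regardless of stars.
#' @param silver_sources Source tags counting as database support for
#'   Silver.
#' @param cterm_fraction_threshold Truncations at or beyond this fraction of
#'   the protein (after rounding to 2 decimals) are flagged
#'   "C-terminal caution" (default 0.90); see [flag_cterm_caution()].
#' @param pli_high,pli_low pLI tier boundaries (defaults 0.9 and 0.5); see
#'   [pli_tier()].
#' @return A `medal_config` list.
#' @export
medal_config <- function(star_sources = "clinvar",
                         min_stars = 2,
                         specialty_sources = c("iarc_tp53", "asu_tert",
                                               "arup_ret", "bic", "pcfp",
                                               "cosmic"),
                         silver_sources = c("clinvar", "umd", "lovd",
                                            "rb1_db", "alsod", "brca_share",
                                            "locus_db"),
                         cterm_fraction_threshold = 0.90,
                         pli_high = 0.9,
                         pli_low = 0.5) {
  structure(list(star_sources = star_sources, min_stars = min_stars,
                 specialty_sources = specialty_sources,
                 silver_sources = silver_sources,
                 cterm_fraction_threshold = cterm_fraction_threshold,
                 pli_high = pli_high, pli_low = pli_low),
            class = "medal_config")
}

PATHOGENIC_CLASSES <- c("pathogenic", "likely_pathogenic")

# evidence summary for one assertion table
assertion_features <- function(a, config) {
  if (is.null(a) || nrow(a) == 0) {
    return(list(any = FALSE, pathogenic = FALSE, star_ok = FALSE,
                specialty_ok = FALSE, silver_src = FALSE))
  }
  path <- a$classification %in% PATHOGENIC_CLASSES
  stars <- if ("stars" %in% names(a)) a$stars else NA_integer_
  list(
    any = TRUE,
    pathogenic = any(path),
    star_ok = any(path & a$source %in% config$star_sources &
                    !is.na(stars) & stars >= config$min_stars),
    specialty_ok = any(path & a$source %in% config$specialty_sources),
    silver_src = any(a$source %in% config$silver_sources)
  )
}

#' Assign germline medals to annotated calls
#'
#' Applies the tiered rule set of [medal_config()] to each annotated call.
#' Tiers are tried in fixed precedence gold > silver > bronze > unknown; the
#' first matching tier wins. Classification is a pure function of the
#' evidence bundle: it does not depend on the order of assertion rows.
#'
#' @param annotated Output of [annotate()] (or any table with columns
#'   `consequence`, `is_tumor_suppressor`, `lof_disease_mechanism`,
#'   `insilico_tolerated`, and list column `assertions`).
#' @param config A [medal_config()].
#' @return The input with `germline_medal` and `medal_reasons`
#'   (semicolon-joined labels of the fired rules; empty for `"unknown"`).
#' @export
classify_germline <- function(annotated, config = medal_config()) {
  assert_columns(annotated, c("consequence", "is_tumor_suppressor",
                              "lof_disease_mechanism", "insilico_tolerated",
                              "assertions"),
                 what = "annotated call table")
  n <- nrow(annotated)
  medal <- character(n)
  reasons <- character(n)
  for (i in seq_len(n)) {
    res <- classify_one(
      consequence = annotated$consequence[i],
      is_tsg = isTRUE(annotated$is_tumor_suppressor[i]),
      lof_mech = isTRUE(annotated$lof_disease_mechanism[i]),
      tolerated = annotated$insilico_tolerated[i],
      assertions = annotated$assertions[[i]],
      config = config
    )
    medal[i] <- res$medal
    reasons[i] <- paste(res$reasons, collapse = ";")
  }
  out <- tibble::as_tibble(annotated)
  out$germline_medal <- medal
  out$medal_reasons <- reasons
  out
}

classify_one <- function(consequence, is_tsg, lof_mech, tolerated,
                         assertions, config) {
  feat <- assertion_features(assertions, config)
  truncating <- consequence %in% TRUNCATING_CONSEQUENCES
  disease_gene <- lof_mech || is_tsg

  # Gold: severe or asserted-pathogenic variant in a disease-associated
  # gene, with high-confidence database support
  if ((truncating || feat$pathogenic) && disease_gene &&
      (feat$star_ok || feat$specialty_ok)) {
    reasons <- c(
      if (truncating) "truncating_consequence" else "pathogenic_assertion",
      if (lof_mech) "lof_disease_gene" else "tumor_suppressor_gene",
      if (feat$star_ok) "starred_pathogenic_assertion"
      else "specialty_source_pathogenic"
    )
    return(list(medal = "gold", reasons = reasons))
  }

  # Silver: moderate consequence with at least one database match
  damaging_missense <- consequence == "missense" &&
    identical(as.logical(tolerated), FALSE)
  silver_conseq <- consequence == "inframe_indel" ||
    (truncating && !is_tsg) || damaging_missense
  if (silver_conseq && feat$silver_src) {
    reasons <- c(
      if (consequence == "inframe_indel") "inframe_indel"
      else if (truncating) "truncating_non_tsg"
      else "damaging_missense",
      "silver_source_match"
    )
    return(list(medal = "silver", reasons = reasons))
  }

  # Bronze: predicted tolerated, nothing stronger
  if (identical(as.logical(tolerated), TRUE)) {
    return(list(medal = "bronze", reasons = "insilico_tolerated"))
  }

  list(medal = "unknown", reasons = character())
}

#' Normalize a somatic-catalogue category
#'
#' Pass-through of the catalogue's category with unmatched variants mapped
#' to `"none"`.
#'
#' @param x Character vector of catalogue categories (`"gold"`, `"silver"`,
#'   `NA`/missing).
#' @return Character vector over `"gold"`, `"silver"`, `"none"`.
#' @export
somatic_category <- function(x) {
  out <- ifelse(is.na(x) | !(x %in% c("gold", "silver")), "none", x)
  as.character(out)
}

#' Refine Silver calls by somatic-catalogue cross-match
#'
#' A germline Silver call is retained only when the same variant is
#' categorized Gold or Silver in the somatic catalogue — recurrence as a
#' somatic mutation in tumors raises confidence in a borderline germline
#' call. Gold calls are unaffected (retained); Bronze and Unknown calls are
#' outside the scope of the refinement (`NA`).
#'
#' @param calls Classified calls with `germline_medal` and
#'   `somatic_category`.
#' @return The input with logical `retained_after_refinement`.
#' @export
refine_silver <- function(calls) {
  assert_columns(calls, c("germline_medal", "somatic_category"),
                 what = "classified call table")
  sc <- somatic_category(calls$somatic_category)
  out <- tibble::as_tibble(calls)
  out$retained_after_refinement <- dplyr::case_when(
    calls$germline_medal == "gold" ~ TRUE,
    calls$germline_medal == "silver" ~ sc %in% c("gold", "silver"),
    TRUE ~ NA
  )
  out
}

#' Flag truncations close to the C-terminus
#'
#' Truncating variants near the protein end may escape nonsense-mediated
#' decay and yield near-full-length protein, so their functional impact is
#' uncertain ("caution"). A truncating call is flagged when its
#' [truncation_protein_fraction()], rounded to two decimals, reaches the
#' configured threshold, or when the annotation places it in the final
#' coding exon. Non-truncating calls are never flagged.
#'
#' @param consequence,aa_position,protein_size Vectorized call features.
#' @param final_exon Logical; variant falls in the last coding exon
#'   (default `FALSE`).
#' @param config A [medal_config()] supplying `cterm_fraction_threshold`.
#' @return Logical vector.
#' @export
flag_cterm_caution <- function(consequence, aa_position, protein_size,
                               final_exon = FALSE,
                               config = medal_config()) {
  frac <- truncation_protein_fraction(consequence, aa_position, protein_size)
  truncating <- consequence %in% TRUNCATING_CONSEQUENCES
  near_end <- !is.na(frac) &
    round_half_up(frac, 2) >= config$cterm_fraction_threshold
  truncating & (near_end | isTRUE_vec(final_exon))
}

#' Tier a gene's loss-of-function intolerance score
#'
#' pLI at or above 0.9 is a strong indicator of LoF intolerance (`"high"`),
#' 0.5 to below 0.9 `"intermediate"`, below 0.5 `"low"`; missing scores
#' return `"absent"`.
#'
#' @param pli Numeric vector of pLI scores in `[0, 1]` (or `NA`).
#' @param config A [medal_config()] supplying the boundaries.
#' @return Character vector over `"high"`, `"intermediate"`, `"low"`,
#'   `"absent"`.
#' @export
pli_tier <- function(pli, config = medal_config()) {
  if (any(!is.na(pli) & (pli < 0 | pli > 1))) {
    stop("pLI values must lie in [0, 1]", call. = FALSE)
  }
  dplyr::case_when(
    is.na(pli) ~ "absent",
    pli >= config$pli_high ~ "high",
    pli >= config$pli_low ~ "intermediate",
    TRUE ~ "low"
  )
}
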