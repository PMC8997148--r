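#' Run the full prioritization pipeline on a cohort
#'
#' Chains the pipeline stages in order: caller-level quality filters,
#' panel restriction and evidence annotation, medal classification,
#' post-classification read-support filters on the Gold and Silver calls,
#' somatic refinement of Silver calls, cohort-level curation of
#' mapping-artifact and cohort-common positions, C-terminal caution and pLI
#' triage, and the final Gold summary. A per-stage record-count "funnel" is
#' returned and (optionally) logged to stderr.
#'
#' @param records Raw call table (see [read_cohort_vcf()]).
#' @param panel A [build_panel()] object.
#' @param evidence An [evidence_tables()] bundle.
#' @param patients Full cohort patient roster (defaults to the patients in
#'   `records`); determines cohort size for carrier fractions and
#'   common-variant detection.
#' @param filter_cfg A [filter_config()].
#' @param medal_cfg A [medal_config()].
#' @param min_artifact_patients Passed to [detect_mapping_artifacts()].
#' @param common_fraction Passed to [detect_common_variants()].
#' @param verbose Log the funnel to stderr (default `FALSE`).
#' @return A `medal_prioritization` list: `calls` (curated Gold and
#'   retained Silver calls with triage columns), `gold`, `silver`,
#'   `funnel` (stage/count tibble), `curation` (per-position flags),
#'   `exclusion_log` (caller-filter log), and `summary_gold`
#'   (a [summarize_cohort()] of the curated Gold calls).
#' @export
prioritize_cohort <- function(records, panel, evidence,
                              patients = NULL,
                              filter_cfg = filter_config(),
                              medal_cfg = medal_config(),
                              min_artifact_patients = 3,
                              common_fraction = 1.0,
                              verbose = FALSE) {
  patients <- patients %||% sort(unique(records$patient))
  funnel <- list()
  note <- function(stage, n) {
    funnel[[length(funnel) + 1]] <<- tibble::tibble(stage = stage, n = n)
    if (verbose) message("[funnel] ", stage, ": ", n)
  }
  note("raw", nrow(records))

  cf <- apply_caller_filters(records, evidence$popfreq, filter_cfg)
  note("caller_filtered", nrow(cf$passed))

  ann <- annotate(cf$passed, panel, evidence)
  note("in_panel", nrow(ann))

  cls <- classify_germline(ann, medal_cfg)
  note("classified_gold", sum(cls$germline_medal == "gold"))
  note("classified_silver", sum(cls$germline_medal == "silver"))

  cand <- cls[cls$germline_medal %in% c("gold", "silver"), , drop = FALSE]
  post <- apply_post_filters(cand, filter_cfg)
  note("post_filtered", nrow(post))

  post <- refine_silver(post)
  kept <- post[is.na(post$retained_after_refinement) |
                 post$retained_after_refinement, , drop = FALSE]
  note("silver_refined", nrow(kept))

  mat <- cohort_matrix(kept, patients = patients)
  flags <- curation_flags(mat, min_patients = min_artifact_patients,
                          fraction_threshold = common_fraction)
  curated <- curate(kept, flags)
  note("curated", nrow(curated))

  curated$caution_cterm <- flag_cterm_caution(
    curated$consequence, curated$aa_position, curated$protein_size,
    final_exon = curated$final_exon, config = medal_cfg)
  curated$pli_tier <- pli_tier(curated$pli, medal_cfg)

  gold <- curated[curated$germline_medal == "gold", , drop = FALSE]
  silver <- curated[curated$germline_medal == "silver", , drop = FALSE]
  note("curated_gold", nrow(gold))

  structure(list(
    calls = curated,
    gold = gold,
    silver = silver,
    funnel = dplyr::bind_rows(funnel),
    curation = flags[flags$flag != "clean", , drop = FALSE],
    curation_log = attr(curated, "curation_log"),
    exclusion_log = cf$log,
    summary_gold = if (nrow(gold) > 0)
      summarize_cohort(gold, n_patients = length(patients)) else NULL,
    patients = patients
  ), class = "medal_prioritization")
}

#' @export
print.medal_prioritization <- function(x, ...) {
  cat("<medal_prioritization>\n")
  for (i in seq_len(nrow(x$funnel))) {
    cat(sprintf("  %-18s %d\n", x$funnel$stage[i], x$funnel$n[i]))
  }
  invisible(x)
}
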