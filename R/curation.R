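#' Build a patients-by-positions cohort matrix
#'
#' Long-format container of which patient carries which variant, with
#' per-cell alternate-allele identity and depths, used by the cohort-level
#' curation rules and per-patient summaries.
#'
#' @param calls Call table with `chrom`, `pos`, `ref`, `alt`, `patient`,
#'   `ref_depth`, `alt_depth`.
#' @param patients Character vector of all cohort patient ids (defaults to
#'   the patients observed in `calls`; pass the full roster so carrier
#'   fractions use the true cohort size).
#' @return A `cohort_matrix` object.
#' @export
cohort_matrix <- function(calls, patients = NULL) {
  assert_columns(calls, c("chrom", "pos", "ref", "alt", "patient",
                          "ref_depth", "alt_depth"),
                 what = "call table")
  calls <- tibble::as_tibble(calls)
  patients <- patients %||% sort(unique(calls$patient))
  unknown <- setdiff(unique(calls$patient), patients)
  if (length(unknown) > 0) {
    stop("call table names patient(s) outside the roster: ",
         paste(head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  structure(list(patients = patients, calls = calls),
            class = "cohort_matrix")
}

#' @export
print.cohort_matrix <- function(x, ...) {
  cat("<cohort_matrix> ", length(x$patients), " patients, ",
      length(unique(position_id(x$calls$chrom, x$calls$pos))),
      " positions, ", nrow(x$calls), " calls\n", sep = "")
  invisible(x)
}

#' Carrier incidence matrix
#'
#' @param mat A [cohort_matrix()].
#' @return Logical matrix, patients in rows, positions (`"chrom:pos"`) in
#'   columns.
#' @export
carrier_matrix <- function(mat) {
  stopifnot(inherits(mat, "cohort_matrix"))
  posid <- sort(unique(position_id(mat$calls$chrom, mat$calls$pos)))
  m <- matrix(FALSE, nrow = length(mat$patients), ncol = length(posid),
              dimnames = list(mat$patients, posid))
  cells <- unique(cbind(mat$calls$patient,
                        position_id(mat$calls$chrom, mat$calls$pos)))
  m[cells] <- TRUE
  m
}

per_position <- function(mat) {
  calls <- mat$calls
  calls$.pos_id <- position_id(calls$chrom, calls$pos)
  dplyr::summarise(
    dplyr::group_by(calls, .data$.pos_id, .data$chrom, .data$pos),
    carriers = dplyr::n_distinct(.data$patient),
    n_alt_alleles = dplyr::n_distinct(.data$alt),
    all_alt_deficit = all(!is.na(.data$alt_depth) & !is.na(.data$ref_depth) &
                            .data$alt_depth < .data$ref_depth),
    .groups = "drop"
  )
}

#' Detect recurrent multi-allelic positions with depleted alternate reads
#'
#' Flags genomic positions whose call pattern suggests a mapping or
#' sequencing artifact rather than real variation: at least `min_patients`
#' carriers, at least two distinct alternate alleles across carriers, and
#' every carrier showing fewer alternate than reference reads (a systematic
#' alternate-read deficit).
#'
#' @param mat A [cohort_matrix()].
#' @param min_patients Minimum carriers for the pattern to be assessable
#'   (default 3).
#' @return A tibble with one row per position: `chrom`, `pos`, `flag`
#'   (`"mapping_artifact"` or `"clean"`), and `rationale`.
#' @export
detect_mapping_artifacts <- function(mat, min_patients = 3) {
  stopifnot(inherits(mat, "cohort_matrix"))
  pp <- per_position(mat)
  hit <- pp$carriers >= min_patients & pp$n_alt_alleles >= 2 &
    pp$all_alt_deficit
  tibble::tibble(
    chrom = pp$chrom, pos = pp$pos,
    flag = ifelse(hit, "mapping_artifact", "clean"),
    rationale = ifelse(
      hit,
      sprintf("%d carriers, %d distinct alt alleles, alt < ref in all",
              pp$carriers, pp$n_alt_alleles),
      ""
    )
  )
}

#' Detect cohort-common positions
#'
#' Flags positions carried by at least `fraction_threshold` of the cohort;
#' at the default threshold of 1.0 a position must be present in every
#' patient, the signature of a common population variant missed by the
#' reference-frequency filter.
#'
#' @param mat A [cohort_matrix()].
#' @param fraction_threshold Carrier fraction at or above which a position
#'   is flagged (default 1.0).
#' @return A tibble with one row per position: `chrom`, `pos`, `flag`
#'   (`"common_in_cohort"` or `"clean"`), and `rationale`.
#' @export
detect_common_variants <- function(mat, fraction_threshold = 1.0) {
  stopifnot(inherits(mat, "cohort_matrix"))
  n <- length(mat$patients)
  if (n == 0) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          flag = character(), rationale = character()))
  }
  pp <- per_position(mat)
  frac <- pp$carriers / n
  hit <- frac >= fraction_threshold
  tibble::tibble(
    chrom = pp$chrom, pos = pp$pos,
    flag = ifelse(hit, "common_in_cohort", "clean"),
    rationale = ifelse(hit,
                       sprintf("carried by %d/%d patients", pp$carriers, n),
                       "")
  )
}

#' Combine per-position curation flags
#'
#' Runs both cohort-level detectors and merges their verdicts (a position
#' flagged by both keeps the mapping-artifact label).
#'
#' @inheritParams detect_mapping_artifacts
#' @inheritParams detect_common_variants
#' @return A per-position flag tibble as in the detectors.
#' @export
curation_flags <- function(mat, min_patients = 3, fraction_threshold = 1.0) {
  art <- detect_mapping_artifacts(mat, min_patients = min_patients)
  com <- detect_common_variants(mat, fraction_threshold = fraction_threshold)
  flag <- ifelse(art$flag != "clean", art$flag, com$flag)
  rationale <- ifelse(art$flag != "clean", art$rationale, com$rationale)
  tibble::tibble(chrom = art$chrom, pos = art$pos,
                 flag = flag, rationale = rationale)
}

#' Remove calls at flagged positions
#'
#' @param calls Call table with `chrom`, `pos`.
#' @param flags Per-position flag tibble from the detectors or
#'   [curation_flags()].
#' @return The retained calls; removed calls with their rationale are
#'   attached as `attr(, "curation_log")`.
#' @export
curate <- function(calls, flags) {
  assert_columns(calls, c("chrom", "pos"), what = "call table")
  assert_columns(flags, c("chrom", "pos", "flag"), what = "flag table")
  bad <- flags[flags$flag != "clean", , drop = FALSE]
  hit <- position_id(calls$chrom, calls$pos) %in%
    position_id(bad$chrom, bad$pos)
  removed <- tibble::as_tibble(calls)[hit, , drop = FALSE]
  if (nrow(removed) > 0) {
    idx <- match(position_id(removed$chrom, removed$pos),
                 position_id(bad$chrom, bad$pos))
    removed$curation_flag <- bad$flag[idx]
    removed$curation_rationale <-
      if ("rationale" %in% names(bad)) bad$rationale[idx] else ""
  }
  out <- tibble::as_tibble(calls)[!hit, , drop = FALSE]
  attr(out, "curation_log") <- removed
  out
}

#' Summarize a curated call set over the cohort
#'
#' Variant identity for unique-variant counts is the full allele key
#' (`chrom`, `pos`, `ref`, `alt`); a variant recurring in several patients
#' counts once at the variant level and once per patient at the occurrence
#' level. Carrier frequency is carriers divided by cohort size (not allele
#' counts over 2n). Patient percentages are rounded half-up to integers,
#' carrier frequencies to one decimal.
#'
#' @param calls Curated calls with `chrom`, `pos`, `ref`, `alt`, `patient`,
#'   `gene`, `consequence`.
#' @param n_patients Cohort size (must exceed 0 and the number of distinct
#'   carriers).
#' @return A `cohort_summary` list: `n_occurrences`, `n_unique_variants`,
#'   `n_genes`, `n_carrier_patients`, `pct_carrier_patients`,
#'   `consequence_counts` (named integer vector over unique variants),
#'   `gene_recurrence` (tibble `gene`, `n_patients`),
#'   `calls_per_patient` (tibble `n_calls`, `n_patients`),
#'   `variant_carrier_freq` (tibble with per-variant carrier counts and
#'   `freq_pct`).
#' @export
summarize_cohort <- function(calls, n_patients) {
  assert_columns(calls, c("chrom", "pos", "ref", "alt", "patient", "gene",
                          "consequence"),
                 what = "call table")
  if (!is.numeric(n_patients) || n_patients <= 0) {
    stop("n_patients must be a positive count", call. = FALSE)
  }
  calls <- tibble::as_tibble(calls)
  vid <- variant_id(calls$chrom, calls$pos, calls$ref, calls$alt)
  uniq <- !duplicated(vid)

  conseq <- table(calls$consequence[uniq])
  per_patient <- table(table(calls$patient))
  gene_rec <- dplyr::summarise(dplyr::group_by(calls, .data$gene),
                               n_patients = dplyr::n_distinct(.data$patient),
                               .groups = "drop")
  gene_rec <- gene_rec[order(-gene_rec$n_patients, gene_rec$gene), ]

  vfreq <- dplyr::summarise(
    dplyr::group_by(calls, .data$chrom, .data$pos, .data$ref, .data$alt),
    carriers = dplyr::n_distinct(.data$patient), .groups = "drop")
  vfreq$freq_pct <- round_half_up(100 * vfreq$carriers / n_patients, 1)

  carriers <- unique(calls$patient)
  structure(list(
    n_occurrences = nrow(calls),
    n_unique_variants = sum(uniq),
    n_genes = length(unique(calls$gene)),
    n_carrier_patients = length(carriers),
    pct_carrier_patients = round_half_up(100 * length(carriers) / n_patients),
    consequence_counts = setNames(as.integer(conseq), names(conseq)),
    gene_recurrence = gene_rec,
    calls_per_patient = tibble::tibble(
      n_calls = as.integer(names(per_patient)),
      n_patients = as.integer(per_patient)
    ),
    variant_carrier_freq = order_calls(vfreq),
    n_patients = n_patients
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>\n")
  cat("  occurrences:      ", x$n_occurrences, "\n")
  cat("  unique variants:  ", x$n_unique_variants, "\n")
  cat("  genes:            ", x$n_genes, "\n")
  cat("  carrier patients: ", x$n_carrier_patients, " of ", x$n_patients,
      " (", x$pct_carrier_patients, "%)\n", sep = "")
  if (length(x$consequence_counts) > 0) {
    cat("  consequences:     ",
        paste(names(x$consequence_counts), x$consequence_counts,
              sep = "=", collapse = ", "), "\n")
  }
  if (nrow(x$calls_per_patient) > 0) {
    cat("  calls/patient:    ",
        paste(x$calls_per_patient$n_calls, "call(s) x",
              x$calls_per_patient$n_patients, collapse = "; "), "\n")
  }
  invisible(x)
}
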